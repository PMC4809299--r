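#' Schwarz Bayesian Criterion for a least-squares fit
#'
#' `SBC = n * ln(rss / n) + k * ln(n)` with `k` counting all estimated
#' coefficients including the intercept and family contrasts.  A (near)
#' perfect fit returns `-Inf` so that comparisons short-circuit in its
#' favour.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of observations.
#' @param k number of estimated coefficients (n > k >= 1).
#' @return the criterion value (smaller is better).
#' @examples
#' schwarz_criterion(100, 100, 2)  # 2 * log(100)
#' @export
schwarz_criterion <- function(rss, n, k) {
  if (rss < 0) stop("`rss` must be >= 0")
  if (k < 1 || n <= k) stop("need n > k >= 1")
  if (rss <= .Machine$double.eps * n) return(-Inf)
  n * log(rss / n) + k * log(n)
}

# impute missing dosages by the within-family mean dosage; families with a
# fully missing marker fall back to the overall mean
impute_dosage <- function(geno) {
  d <- geno$dosage
  if (!anyNA(d)) return(list(dosage = d * 1.0, n_imputed = 0L))
  d <- d * 1.0
  n_imp <- sum(is.na(d))
  for (f in levels(geno$family)) {
    rows <- which(geno$family == f)
    block <- d[rows, , drop = FALSE]
    if (!anyNA(block)) next
    fm <- colMeans(block, na.rm = TRUE)
    idx <- which(is.na(block), arr.ind = TRUE)
    block[idx] <- fm[idx[, 2]]
    d[rows, ] <- block
  }
  if (anyNA(d)) { # family entirely missing for a marker
    om <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- om[idx[, 2]]
  }
  list(dosage = d, n_imputed = n_imp)
}

# intercept + family one-hot contrasts (first family as reference)
family_design <- function(family) {
  family <- droplevels(factor(family))
  if (nlevels(family) > 1) stats::model.matrix(~family)
  else matrix(1, length(family), 1, dimnames = list(NULL, "(Intercept)"))
}

#' Forward cofactor selection minimizing the Schwarz criterion
#'
#' Starting from the base association model (intercept + family effects),
#' greedily adds the marker whose inclusion most decreases the Schwarz
#' Bayesian Criterion, considering all markers simultaneously as candidates,
#' and stops when no remaining marker decreases it.  Deterministic given the
#' data: ties are broken by map position (when a map is supplied), then by
#' marker id.
#'
#' @param geno a [nam_geno()] (missing dosages imputed by family mean).
#' @param blues numeric vector of line BLUEs, aligned with the lines of
#'   `geno` (or named by line id).
#' @param family family labels (default taken from `geno`).
#' @param map optional [genetic_map()] used for tie-breaking.
#' @param max_cofactors optional cap on the number of cofactors.
#' @return a `cofactor_set`: list with `cofactors` (ordered marker ids),
#'   `sbc` (criterion value after each addition) and `sbc_base`.
#' @export
select_cofactors <- function(geno, blues, family = geno$family, map = NULL,
                             max_cofactors = Inf) {
  y <- align_blues(blues, geno)
  n <- length(y)
  X0 <- family_design(family)
  if (n <= ncol(X0)) stop("fewer lines than base-model parameters")
  M <- impute_dosage(geno)$dosage
  # candidate order for tie-breaks
  ord <- order_markers(colnames(M), map)
  Q <- qr.Q(qr(X0))
  k <- ncol(X0)
  resid <- y - Q %*% crossprod(Q, y)
  rss <- sum(resid^2)
  sbc <- schwarz_criterion(max(rss, .Machine$double.xmin), n, k)
  sbc_base <- sbc
  Mp <- M - Q %*% crossprod(Q, M) # candidates orthogonal to current model
  selected <- character(0)
  traj <- numeric(0)
  repeat {
    if (length(selected) >= max_cofactors || n <= k + 1) break
    den <- colSums(Mp^2)
    num <- as.vector(crossprod(Mp, resid))^2
    gain <- ifelse(den > 1e-8 * n, num / den, -Inf)
    gain[colnames(M) %in% selected] <- -Inf
    best_gain <- max(gain)
    if (!is.finite(best_gain)) break
    cand <- which(gain >= best_gain - 1e-12 * max(rss, 1))
    j <- cand[which.min(ord[cand])]
    rss_new <- rss - gain[j]
    sbc_new <- schwarz_criterion(max(rss_new, 0), n, k + 1)
    if (!(sbc_new < sbc - 1e-10)) break
    qnew <- Mp[, j] / sqrt(den[j])
    Q <- cbind(Q, qnew)
    Mp <- Mp - qnew %*% crossprod(qnew, Mp)
    resid <- resid - qnew * sum(qnew * resid)
    rss <- rss_new; k <- k + 1; sbc <- sbc_new
    selected <- c(selected, colnames(M)[j])
    traj <- c(traj, sbc)
    if (sbc == -Inf) break
  }
  structure(list(cofactors = selected, sbc = traj, sbc_base = sbc_base),
            class = "cofactor_set")
}

order_markers <- function(markers, map) {
  if (is.null(map)) return(order(order(markers)))
  i <- match(markers, map$marker)
  rank_key <- order(map$chrom[i], map$pos[i], markers)
  order(rank_key) # position of each marker in the sorted order
}

align_blues <- function(blues, geno) {
  if (is.data.frame(blues)) blues <- stats::setNames(blues$blue, blues$line_id)
  if (!is.null(names(blues))) {
    idx <- match(rownames(geno$dosage), names(blues))
    if (anyNA(idx)) stop("BLUEs missing for some lines")
    blues <- blues[idx]
  }
  if (length(blues) != nrow(geno$dosage)) {
    stop("`blues` must supply one value per line")
  }
  as.numeric(blues)
}

#' Multi-family genome scan (family + cofactors + SNP dosage)
#'
#' For each marker, fits the fixed-effects multiple regression
#' `BLUE ~ intercept + family + retained cofactors + marker dosage` by
#' ordinary least squares and reports the additive effect (regression
#' coefficient of the dosage term), its two-sided t-test p-value, the
#' Bonferroni-Holm adjusted p-value, and the proportion of variance
#' explained by the marker alone.  Cofactors on the same chromosome strictly
#' closer than `exclusion_window_cM` to the tested marker (including the
#' marker itself, if selected) are dropped for that test; cofactors on other
#' chromosomes are always retained.
#'
#' @param geno a [nam_geno()].
#' @param blues numeric vector (or `compute_blues()` frame) of line BLUEs.
#' @param family family labels (default from `geno`).
#' @param cofactors a `cofactor_set` or character vector of marker ids.
#' @param map a [genetic_map()] covering all markers.
#' @param exclusion_window_cM strict exclusion radius in cM (default 1.0).
#' @param alpha significance level applied to adjusted p-values.
#' @return a `scan_result` data frame with one row per marker: `marker`,
#'   `chrom`, `pos`, `beta`, `effect_2beta` (homozygous difference), `p`,
#'   `p_holm`, `r2`, `significant`, `tested`, `excluded_cofactors`.
#' @export
scan_genome <- function(geno, blues, family = geno$family, cofactors,
                        map, exclusion_window_cM = 1.0, alpha = 0.05) {
  stopifnot(inherits(map, "genetic_map"))
  if (inherits(cofactors, "cofactor_set")) cofactors <- cofactors$cofactors
  y <- align_blues(blues, geno)
  M <- impute_dosage(geno)$dosage
  markers <- colnames(M)
  mi <- match(markers, map$marker)
  if (anyNA(mi)) stop("genotype markers missing from the map")
  chrom <- map$chrom[mi]; pos <- map$pos[mi]
  ci <- match(cofactors, map$marker)
  X0 <- family_design(family)
  n <- nrow(M)
  # exclusion set per marker -> group markers sharing a retained-cofactor set
  excl <- lapply(seq_along(markers), function(j) {
    same <- !is.na(ci) & map$chrom[ci] == chrom[j] &
      abs(map$pos[ci] - pos[j]) < exclusion_window_cM
    which(same)
  })
  key <- vapply(excl, function(e) paste(e, collapse = ","), "")
  beta <- p <- rep(NA_real_, length(markers))
  mono <- apply(M, 2, stats::sd) == 0
  for (k in unique(key)) {
    jj <- which(key == k & !mono)
    if (length(jj) == 0) next
    keep <- setdiff(seq_along(cofactors), excl[[jj[1]]])
    X <- cbind(X0, M[, cofactors[keep], drop = FALSE])
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    df <- n - qrX$rank - 1L
    if (df < 1) {
      warning("not enough residual degrees of freedom in scan group")
      next
    }
    yp <- y - Q %*% crossprod(Q, y)
    Xm <- M[, jj, drop = FALSE]
    Xp <- Xm - Q %*% crossprod(Q, Xm)
    den <- colSums(Xp^2)
    est <- as.vector(crossprod(Xp, yp)) / den
    rss <- sum(yp^2) - est^2 * den
    se <- sqrt(pmax(rss, 0) / df / den)
    tt <- est / se
    ok <- den > 1e-8 * n & is.finite(tt)
    if (any(!ok)) {
      warning("dosage collinear with cofactors for ",
              sum(!ok), " marker(s); coefficient dropped")
    }
    beta[jj[ok]] <- est[ok]
    p[jj[ok]] <- 2 * stats::pt(-abs(tt[ok]), df)
  }
  # single-marker R2: marker alone in the model, no family, no cofactors
  r2 <- rep(NA_real_, length(markers))
  sdy <- stats::sd(y)
  if (sdy > 0) {
    r2[!mono] <- suppressWarnings(stats::cor(M[, !mono, drop = FALSE], y))^2
  }
  p_holm <- rep(NA_real_, length(markers))
  tested <- !is.na(p)
  p_holm[tested] <- holm_adjust(p[tested])$p_adjusted
  out <- data.frame(
    marker = markers, chrom = chrom, pos = pos,
    beta = beta, effect_2beta = 2 * beta, p = p, p_holm = p_holm,
    r2 = r2,
    significant = !is.na(p_holm) & p_holm < alpha,
    tested = tested,
    excluded_cofactors = vapply(excl, function(e)
      paste(cofactors[e], collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sorts the m p-values ascending, multiplies the i-th by (m - i + 1),
#' enforces monotonicity with a running maximum, caps at 1 and maps back to
#' the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level for the flags.
#' @return list with `p_adjusted` and logical `significant`.
#' @examples
#' holm_adjust(c(0.01, 0.03, 0.04))$p_adjusted  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m > 0) {
    o <- order(p[idx])
    padj <- pmin(1, cummax((m - seq_len(m) + 1) * p[idx][o]))
    adj[idx[o]] <- padj
  }
  list(p_adjusted = adj, significant = !is.na(adj) & adj < alpha)
}

#' Proportion of variance explained by a single marker
#'
#' Coefficient of determination of the simple regression
#' `BLUE ~ intercept + dosage`, without family or cofactor terms.
#'
#' @param geno a [nam_geno()].
#' @param blues line BLUEs.
#' @param marker marker id.
#' @return R squared in `[0, 1]`.
#' @export
single_marker_r2 <- function(geno, blues, marker) {
  y <- align_blues(blues, geno)
  d <- impute_dosage(geno)$dosage[, marker]
  if (stats::sd(d) == 0) stop("marker ", marker, " is monomorphic")
  unname(stats::cor(d, y)^2)
}

#' Family-specific (nested) marker effects
#'
#' Fits `BLUE ~ family + family:dosage` by least squares, i.e. a general
#' family term with the marker effect nested within family.  The per-family
#' dosage coefficient is estimable only in families where the marker
#' segregates; monomorphic families are reported as not estimable.
#'
#' @param geno a [nam_geno()].
#' @param blues line BLUEs.
#' @param family family labels (default from `geno`).
#' @param marker marker id.
#' @return data frame with `family`, `n`, `estimable`, `effect` (per-dosage
#'   coefficient; NA when not estimable).
#' @export
family_nested_effects <- function(geno, blues, family = geno$family, marker) {
  y <- align_blues(blues, geno)
  d <- impute_dosage(geno)$dosage[, marker]
  if (stats::sd(d) == 0) stop("marker ", marker,
                              " is monomorphic in every family")
  family <- droplevels(factor(family))
  out <- do.call(rbind, lapply(levels(family), function(f) {
    i <- family == f
    v <- stats::var(d[i])
    eff <- if (is.finite(v) && v > 0) {
      stats::cov(d[i], y[i]) / v # within-family OLS slope
    } else NA_real_
    data.frame(family = f, n = sum(i), estimable = !is.na(eff),
               effect = eff, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
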