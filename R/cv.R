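#' Family-stratified training/hold-out split
#'
#' Samples, independently per family and without replacement,
#' `round(fraction * n_f)` training lines (round half up), guaranteeing at
#' least one training and one hold-out line per family.
#'
#' @param lines character vector of line ids.
#' @param family family label per line.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return a `subsample_split`: list with `train`, `holdout`, `seed`.
#' @export
stratified_subsample <- function(lines, family, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be strictly between 0 and 1")
  }
  family <- factor(family)
  sizes <- table(family)
  if (any(sizes < 2)) {
    stop("families of size 1 cannot be stratified: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  train <- with_seed(seed, unlist(lapply(levels(family), function(f) {
    ids <- lines[family == f]
    n_tr <- min(max(round_half_up(fraction * length(ids)), 1L),
                length(ids) - 1L)
    sample(ids, n_tr)
  }), use.names = FALSE))
  structure(list(train = train, holdout = setdiff(lines, train),
                 seed = as.integer(seed)),
            class = "subsample_split")
}

#' Fit the joint family + markers prediction model
#'
#' Least-squares fit of `BLUE ~ intercept + family + dosage of the given
#' markers` with coefficients estimated jointly; collinear marker columns
#' are dropped (and recorded).  Used for per-run explained variance and
#' hold-out prediction.
#'
#' @param geno a [nam_geno()] (training lines).
#' @param blues training-line BLUEs.
#' @param family training family labels (default from `geno`).
#' @param markers marker ids to model (may be empty: family-only model).
#' @return a `marker_model`: coefficients, retained markers, family levels,
#'   `r2` and residual df of the fit.
#' @export
fit_marker_model <- function(geno, blues, family = geno$family, markers) {
  y <- align_blues(blues, geno)
  family <- droplevels(factor(family))
  X0 <- family_design(family)
  Xm <- impute_dosage(geno)$dosage[, markers, drop = FALSE]
  X <- cbind(X0, Xm)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- setdiff(colnames(X), colnames(X)[keep_cols])
    X <- X[, keep_cols, drop = FALSE]
    qrX <- qr(X)
  }
  cf <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% cf)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(coef = cf,
                 markers = setdiff(colnames(X), colnames(X0)),
                 dropped = dropped,
                 family_levels = levels(family),
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(y), df_residual = length(y) - ncol(X)),
            class = "marker_model")
}

#' @export
predict.marker_model <- function(object, geno, family = geno$family, ...) {
  family <- factor(family, levels = object$family_levels)
  if (anyNA(family)) stop("hold-out family absent from the training fit")
  X0 <- if (length(object$family_levels) > 1) {
    stats::model.matrix(~family)
  } else {
    matrix(1, length(family), 1, dimnames = list(NULL, "(Intercept)"))
  }
  Xm <- impute_dosage(geno)$dosage[, object$markers, drop = FALSE]
  X <- cbind(X0, Xm)
  as.vector(X[, names(object$coef), drop = FALSE] %*% object$coef)
}

#' Ezekiel's adjusted R squared
#'
#' `R2_adj = 1 - (1 - R2) * (n - 1) / (n - k - 1)`.
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param k number of predictors counted in the penalty.
#' @return adjusted R squared.
#' @examples
#' adjusted_r2(0.5, 101, 10)  # 0.4444...
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("adjusted R2 undefined for n <= k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Hold-out predictive ability
#'
#' Squared Pearson correlation between hold-out BLUEs and the values
#' predicted from a training-set [fit_marker_model()] (family intercepts
#' plus jointly re-estimated additive marker effects).
#'
#' @param model a `marker_model` fitted on the training lines.
#' @param holdout_geno [nam_geno()] restricted to the hold-out lines.
#' @param holdout_blues hold-out BLUEs.
#' @param holdout_family hold-out family labels (default from the geno).
#' @return squared correlation, or NA when the predictions have zero
#'   variance.
#' @export
predictive_ability <- function(model, holdout_geno, holdout_blues,
                               holdout_family = holdout_geno$family) {
  obs <- align_blues(holdout_blues, holdout_geno)
  pred <- predict(model, holdout_geno, holdout_family)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)^2
}

#' Cross-validated multi-family GWAS
#'
#' Applies the entire scan procedure (cofactor selection, genome scan,
#' Bonferroni-Holm correction) to `n_runs` family-stratified random
#' subsamples, each containing `fraction` of the lines per family.  Records,
#' per marker, the detection rate (share of runs in which the marker is
#' significant) and the additive effect, adjusted p-value and single-marker
#' R2 averaged over the runs in which it was significant; and, per run, the
#' adjusted explained variance of the jointly modelled significant markers
#' and the hold-out predictive ability.
#'
#' @param geno a [nam_geno()].
#' @param blues line BLUEs for one trait.
#' @param family family labels (default from `geno`).
#' @param map a [genetic_map()].
#' @param n_runs number of subsampling runs (the reference protocol uses
#'   200).
#' @param fraction training fraction (default 0.8).
#' @param base_seed base seed; run i uses a derived child seed.
#' @param alpha significance level on adjusted p-values.
#' @param exclusion_window_cM cofactor exclusion radius for the scan.
#' @param max_cofactors optional cap passed to [select_cofactors()].
#' @return a `cv_result`: list with `markers` (per-marker frame), `runs`
#'   (per-run frame with `n_significant`, `r2_adj`, `r2_adj_full`,
#'   `r2_pred`), `mean_r2_adj`, `mean_r2_pred`, `n_runs`, `trait`.
#' @export
run_cross_validated_gwas <- function(geno, blues, family = geno$family, map,
                                     n_runs = 200, fraction = 0.8,
                                     base_seed = 1L, alpha = 0.05,
                                     exclusion_window_cM = 1.0,
                                     max_cofactors = Inf) {
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  y <- align_blues(blues, geno)
  names(y) <- rownames(geno$dosage)
  markers <- colnames(geno$dosage)
  m <- length(markers)
  det <- integer(m)
  sum_beta <- sum_p <- sum_r2 <- numeric(m)
  runs <- data.frame(run = seq_len(n_runs), n_significant = NA_integer_,
                     r2_adj = NA_real_, r2_adj_full = NA_real_,
                     r2_pred = NA_real_)
  lines <- rownames(geno$dosage)
  for (i in seq_len(n_runs)) {
    split <- stratified_subsample(
      lines, geno$family, fraction,
      seed = derive_seed(base_seed, pipeline_stage_offsets()["cv"], i))
    g_tr <- subset_lines(geno, split$train)
    g_ho <- subset_lines(geno, split$holdout)
    y_tr <- y[split$train]; y_ho <- y[split$holdout]
    cof <- select_cofactors(g_tr, y_tr, map = map,
                            max_cofactors = max_cofactors)
    scan <- scan_genome(g_tr, y_tr, cofactors = cof, map = map,
                        exclusion_window_cM = exclusion_window_cM,
                        alpha = alpha)
    sig <- scan$marker[scan$significant]
    hit <- markers %in% sig
    det[hit] <- det[hit] + 1L
    rowi <- match(markers[hit], scan$marker)
    sum_beta[hit] <- sum_beta[hit] + scan$beta[rowi]
    sum_p[hit] <- sum_p[hit] + scan$p_holm[rowi]
    sum_r2[hit] <- sum_r2[hit] + scan$r2[rowi]
    fit <- fit_marker_model(g_tr, y_tr, markers = sig)
    n_tr <- length(split$train)
    k_mark <- length(fit$markers)
    runs$n_significant[i] <- length(sig)
    if (n_tr > k_mark + 1 && is.finite(fit$r2)) {
      runs$r2_adj[i] <- adjusted_r2(fit$r2, n_tr, k_mark)
      k_full <- length(fit$coef) - 1L
      if (n_tr > k_full + 1) {
        runs$r2_adj_full[i] <- adjusted_r2(fit$r2, n_tr, k_full)
      }
    }
    runs$r2_pred[i] <- predictive_ability(fit, g_ho, y_ho)
  }
  mi <- match(markers, map$marker)
  mk <- data.frame(
    marker = markers, chrom = map$chrom[mi], pos = map$pos[mi],
    detection_count = det, detection_rate = det / n_runs,
    mean_beta = ifelse(det > 0, sum_beta / det, NA_real_),
    mean_p_holm = ifelse(det > 0, sum_p / det, NA_real_),
    mean_r2 = ifelse(det > 0, sum_r2 / det, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(markers = mk, runs = runs,
                 mean_r2_adj = mean(runs$r2_adj, na.rm = TRUE),
                 mean_r2_pred = mean(runs$r2_pred, na.rm = TRUE),
                 n_runs = n_runs, fraction = fraction, alpha = alpha),
            class = "cv_result")
}

#' Consolidate significant markers into putative QTL
#'
#' Markers whose detection rate reaches `min_detection` qualify; on each
#' chromosome, consecutive qualifying markers strictly less than `merge_cM`
#' apart are chained into a single QTL (single linkage).  The interval spans
#' the member markers; the peak marker is the member with the smallest mean
#' adjusted p-value.
#'
#' @param cv_result a `cv_result`, or a per-marker frame with columns
#'   `marker`, `chrom`, `pos`, `detection_rate`, `mean_p_holm`,
#'   `mean_beta`.
#' @param map a [genetic_map()] (used when positions are absent).
#' @param min_detection minimum detection rate (default 0.10).
#' @param merge_cM strict merge distance in cM (default 4.0).
#' @return a `qtl_set` data frame: `qtl`, `chrom`, `cm_from`, `cm_until`,
#'   `n_markers`, `peak_marker`, `max_detection_rate`, `markers`
#'   (comma-separated member ids).
#' @export
consolidate_qtl <- function(cv_result, map = NULL, min_detection = 0.10,
                            merge_cM = 4.0) {
  mk <- if (inherits(cv_result, "cv_result")) cv_result$markers else cv_result
  if (is.null(mk$pos) || is.null(mk$chrom)) {
    i <- match(mk$marker, map$marker)
    mk$chrom <- map$chrom[i]; mk$pos <- map$pos[i]
  }
  q <- mk[!is.na(mk$detection_rate) & mk$detection_rate >= min_detection, ,
          drop = FALSE]
  empty <- data.frame(qtl = character(0), chrom = character(0),
                      cm_from = numeric(0), cm_until = numeric(0),
                      n_markers = integer(0), peak_marker = character(0),
                      max_detection_rate = numeric(0), markers = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("qtl_set", "data.frame")
  if (nrow(q) == 0) return(empty)
  q <- q[order(q$chrom, q$pos, q$marker), , drop = FALSE]
  newgrp <- c(TRUE, q$chrom[-1] != q$chrom[-nrow(q)] |
                (q$pos[-1] - q$pos[-nrow(q)]) >= merge_cM)
  grp <- cumsum(newgrp)
  rows <- lapply(split(q, grp), function(g) {
    peak <- if (all(is.na(g$mean_p_holm))) g$marker[which.max(g$detection_rate)]
    else g$marker[which.min(g$mean_p_holm)]
    data.frame(chrom = g$chrom[1], cm_from = min(g$pos),
               cm_until = max(g$pos), n_markers = nrow(g),
               peak_marker = peak,
               max_detection_rate = max(g$detection_rate),
               markers = paste(g$marker, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$cm_from), , drop = FALSE]
  counts <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
  out <- cbind(qtl = sprintf("QTL-%s-%d", out$chrom, counts), out)
  rownames(out) <- NULL
  class(out) <- c("qtl_set", "data.frame")
  out
}

#' Multi-trait QTL summary table
#'
#' Builds one row per consolidated QTL with: chromosome, the peak marker
#' (most significant member for the reference trait), the cM interval, and
#' per trait the most extreme homozygous difference (signed `2 * mean beta`
#' with the largest absolute value) among the QTL's member markers that
#' qualify for that trait.  A trait cell is left NA (blank) when no member
#' marker reaches the detection threshold for that trait.
#'
#' @param qtl_records a `qtl_set` (typically consolidated from the pooled
#'   qualifying markers of all traits; see [consolidate_qtl()]).
#' @param cv_results_by_trait named list of `cv_result` objects.
#' @param reference_trait trait whose significance picks the peak marker.
#' @param min_detection detection-rate threshold applied per trait.
#' @return data frame: `qtl`, `chrom`, `peak_marker`, `cm_from`,
#'   `cm_until`, one effect column per trait.
#' @export
qtl_summary_table <- function(qtl_records, cv_results_by_trait,
                              reference_trait, min_detection = 0.10) {
  if (!reference_trait %in% names(cv_results_by_trait)) {
    stop("reference trait ", reference_trait, " not among the CV results")
  }
  ref <- cv_results_by_trait[[reference_trait]]$markers
  traits <- names(cv_results_by_trait)
  rows <- lapply(seq_len(nrow(qtl_records)), function(i) {
    members <- strsplit(qtl_records$markers[i], ",")[[1]]
    rr <- ref[ref$marker %in% members & !is.na(ref$mean_p_holm), ]
    peak <- if (nrow(rr) > 0) rr$marker[which.min(rr$mean_p_holm)]
    else qtl_records$peak_marker[i]
    eff <- vapply(traits, function(tr) {
      mk <- cv_results_by_trait[[tr]]$markers
      mm <- mk[mk$marker %in% members &
                 !is.na(mk$detection_rate) &
                 mk$detection_rate >= min_detection &
                 !is.na(mk$mean_beta), , drop = FALSE]
      if (nrow(mm) == 0) return(NA_real_)
      e <- 2 * mm$mean_beta
      e[which.max(abs(e))]
    }, numeric(1))
    cbind(data.frame(qtl = qtl_records$qtl[i], chrom = qtl_records$chrom[i],
                     peak_marker = peak,
                     cm_from = qtl_records$cm_from[i],
                     cm_until = qtl_records$cm_until[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(eff)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool qualifying markers across traits and consolidate
#'
#' Markers qualifying (detection rate >= `min_detection`) for any trait are
#' pooled, each keeping its best mean adjusted p-value across traits, and
#' consolidated with [consolidate_qtl()] so that one interval set aligns all
#' traits of a summary table.
#'
#' @inheritParams qtl_summary_table
#' @param map a [genetic_map()].
#' @param merge_cM strict merge distance.
#' @return a `qtl_set`.
#' @export
consolidate_multi_trait <- function(cv_results_by_trait, map,
                                    min_detection = 0.10, merge_cM = 4.0) {
  pooled <- NULL
  for (tr in names(cv_results_by_trait)) {
    mk <- cv_results_by_trait[[tr]]$markers
    mk <- mk[!is.na(mk$detection_rate) & mk$detection_rate >= min_detection,
             c("marker", "chrom", "pos", "detection_rate", "mean_p_holm",
               "mean_beta")]
    pooled <- rbind(pooled, mk)
  }
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(consolidate_qtl(
      data.frame(marker = character(0), chrom = character(0),
                 pos = numeric(0), detection_rate = numeric(0),
                 mean_p_holm = numeric(0), mean_beta = numeric(0)),
      map, min_detection, merge_cM))
  }
  best <- do.call(rbind, lapply(split(pooled, pooled$marker), function(g) {
    g[order(g$mean_p_holm, -g$detection_rate)[1], ]
  }))
  consolidate_qtl(best, map, min_detection, merge_cM)
}
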