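#' Growing degree days above a 0 degree C base
#'
#' Cumulates the mean daily temperatures of all days with a mean temperature
#' above 0 degrees C between sowing and the developmental event, both days
#' inclusive.  The inclusion of the sowing day is configurable because "days
#' from sowing" conventions differ.
#'
#' @param daily_mean_temps numeric vector of daily mean temperatures (deg C),
#'   day 1 = first day of the series.
#' @param sowing_day index of the sowing day.
#' @param event_day index (or vector of indices) of the event day(s);
#'   must be >= `sowing_day`.
#' @param include_sowing_day include the sowing day itself (default TRUE).
#' @return GDD in degree C x day, same length as `event_day`.
#' @examples
#' compute_gdd(c(5, -3, 10, 0, 7), 1, 5)  # 22: days at -3 and 0 excluded
#' @export
compute_gdd <- function(daily_mean_temps, sowing_day, event_day,
                        include_sowing_day = TRUE) {
  t <- as.numeric(daily_mean_temps)
  if (any(!is.finite(t))) stop("temperature series contains missing values")
  if (sowing_day < 1 || any(event_day > length(t))) {
    stop("sowing/event days must lie within the series")
  }
  if (any(event_day < sowing_day)) stop("event day precedes sowing day")
  start <- if (include_sowing_day) sowing_day else sowing_day + 1L
  pos <- pmax(t, 0)
  cum <- cumsum(pos)
  base <- if (start > 1) cum[start - 1L] else 0
  out <- cum[event_day] - base
  out[event_day < start] <- 0
  out
}

#' Estimate variance components for one trait
#'
#' Fits the all-random one-step model
#' `value = mu + genotype + year + genotype:year + error` to multi-year plot
#' records and returns the genotypic, genotype-by-year and residual variance
#' components.  The default estimator is REML (via \pkg{lme4}); for balanced
#' designs a deterministic ANOVA / expected-mean-squares estimator
#' (Henderson III) is available, with negative solutions clamped to zero.
#'
#' @param records long-format data frame with columns `line_id`, `year`,
#'   `rep`, `trait`, `value`.
#' @param trait trait to analyse (default: the only trait present).
#' @param method `"reml"` (default) or `"anova"` (balanced designs only).
#' @return a `variance_components` list: `V_G`, `V_GY`, `V_R`, `years`
#'   (number of years), `reps` (mean replicates per line-year), `method`.
#' @export
estimate_variance_components <- function(records, trait = NULL,
                                         method = c("reml", "anova")) {
  method <- match.arg(method)
  d <- select_trait(records, trait)
  ny <- length(unique(d$year))
  if (ny < 2) {
    stop("only one year present: genotype-by-year variance is inestimable")
  }
  nrep <- mean(table(d$line_id, d$year))
  if (stats::var(d$value) == 0) {
    vc <- c(V_G = 0, V_GY = 0, V_R = 0)
  } else if (method == "reml") {
    d$line_id <- factor(d$line_id)
    d$year <- factor(d$year)
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(value ~ (1 | line_id) + (1 | year) + (1 | line_id:year),
                 data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # near-singular fits (e.g. noise-free data) can break the REML
      # optimizer; balanced designs fall back to the exact EMS solution
      vc <- tryCatch(anova_varcomp(d), error = function(e) NULL)
      if (is.null(vc)) stop("REML failed and the design is not balanced: ",
                            conditionMessage(fit))
      message("REML optimizer failed; used the balanced EMS estimator")
    } else {
      v <- as.data.frame(lme4::VarCorr(fit))
      pick <- function(g) v$vcov[match(g, v$grp)]
      vc <- c(V_G = pick("line_id"), V_GY = pick("line_id:year"),
              V_R = pick("Residual"))
    }
  } else {
    vc <- anova_varcomp(d)
  }
  vc[vc < 0] <- 0
  structure(list(V_G = unname(vc["V_G"]), V_GY = unname(vc["V_GY"]),
                 V_R = unname(vc["V_R"]), years = ny, reps = nrep,
                 method = method),
            class = "variance_components")
}

# Henderson III / expected-mean-squares solution for a balanced two-way
# random model with replication
anova_varcomp <- function(d) {
  tab <- table(d$line_id, d$year)
  r <- unique(as.vector(tab))
  if (length(r) != 1) {
    stop("method = \"anova\" requires a balanced design; use \"reml\"")
  }
  if (r < 2) stop("ANOVA estimator needs >= 2 replicates per line-year cell")
  n <- nrow(tab); y <- ncol(tab)
  cell <- tapply(d$value, list(d$line_id, d$year), mean)
  gm <- mean(d$value)
  line_m <- rowMeans(cell); year_m <- colMeans(cell)
  ms_g <- y * r * sum((line_m - gm)^2) / (n - 1)
  ms_gy <- r * sum((cell - outer(line_m, rep(1, y)) -
                      outer(rep(1, n), year_m) + gm)^2) / ((n - 1) * (y - 1))
  ms_e <- sum((d$value - cell[cbind(as.character(d$line_id),
                                    as.character(d$year))])^2) /
    (n * y * (r - 1))
  v_r <- ms_e
  v_gy <- (ms_gy - ms_e) / r
  v_g <- (ms_g - ms_gy) / (y * r)
  c(V_G = v_g, V_GY = v_gy, V_R = v_r)
}

#' Broad-sense heritability across years
#'
#' `h2 = V_G / (V_G + V_GY / y + V_R / (y * r))`: the fraction of the
#' variance among line means attributable to genotype, for a trial with `y`
#' years and `r` replicates per year.
#'
#' @param V_G,V_GY,V_R variance components (>= 0; negative estimates should
#'   be clamped to 0 before calling).
#' @param y number of years.
#' @param r replicates per year.
#' @return heritability in `[0, 1]`.
#' @examples
#' heritability(4, 2, 4, y = 4, r = 2)  # 0.8
#' @export
heritability <- function(V_G, V_GY, V_R, y, r) {
  if (any(c(V_G, V_GY, V_R) < 0)) stop("variance components must be >= 0")
  if (y < 1 || r < 1) stop("`y` and `r` must be >= 1")
  denom <- V_G + V_GY / y + V_R / (y * r)
  if (denom == 0) stop("all variance components are zero: h2 undefined")
  V_G / denom
}

#' @rdname heritability
#' @param vc a `variance_components` object from
#'   [estimate_variance_components()].
#' @export
heritability_from_components <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  heritability(vc$V_G, vc$V_GY, vc$V_R, vc$years, vc$reps)
}

#' Best linear unbiased estimates per line
#'
#' One-step analysis over all years for one trait: genotype effects fixed,
#' year and genotype-by-year random.  For balanced data (every line observed
#' equally often in every year) the generalized-least-squares solution
#' reduces exactly to the per-line mean, which is used as a fast path;
#' unbalanced data are fitted with \pkg{lme4}.  An optional replicate term
#' nested in year can be added.
#'
#' @param records long-format phenotype records.
#' @param trait trait to analyse (default: the only trait present).
#' @param include_rep add a random `year:rep` block term (default FALSE).
#' @return data frame with columns `line_id`, `trait`, `blue`.
#' @export
compute_blues <- function(records, trait = NULL, include_rep = FALSE) {
  d <- select_trait(records, trait)
  tab <- table(d$line_id, d$year)
  balanced <- length(unique(as.vector(tab))) == 1 && !include_rep
  if (balanced || length(unique(d$year)) == 1) {
    blue <- tapply(d$value, d$line_id, mean)
  } else {
    d$line_id <- factor(d$line_id)
    d$year <- factor(d$year)
    form <- value ~ 0 + line_id + (1 | year) + (1 | line_id:year)
    if (include_rep) {
      d$rep <- factor(d$rep)
      form <- stats::update(form, . ~ . + (1 | year:rep))
    }
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    cf <- lme4::fixef(fit)
    names(cf) <- sub("^line_id", "", names(cf))
    blue <- cf[levels(d$line_id)]
    names(blue) <- levels(d$line_id)
  }
  out <- data.frame(line_id = names(blue), trait = d$trait[1],
                    blue = as.numeric(blue), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' BLUEs for several traits in wide format
#'
#' @param records long-format phenotype records.
#' @param traits traits to include (default all).
#' @param ... passed to [compute_blues()].
#' @return data frame, one row per line, one column per trait plus
#'   `line_id`.
#' @export
blues_table <- function(records, traits = NULL, ...) {
  traits <- traits %||% unique(records$trait)
  out <- NULL
  for (tr in traits) {
    b <- compute_blues(records, tr, ...)
    b <- stats::setNames(b[, c("line_id", "blue")], c("line_id", tr))
    out <- if (is.null(out)) b else merge(out, b, by = "line_id", all = TRUE)
  }
  out
}

#' Descriptive statistics of line BLUEs
#'
#' @param x numeric vector of per-line BLUEs (>= 2 values).
#' @return data frame with `n`, `mean`, `sd`, `min`, `max`, `range` and
#'   `cv_pct` (coefficient of variation, 100 * sd / mean).
#' @export
descriptive_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least two values")
  m <- mean(x); s <- stats::sd(x)
  cv <- if (m == 0) {
    warning("mean is zero: CV% undefined")
    NA_real_
  } else 100 * s / m
  data.frame(n = length(x), mean = m, sd = s, min = min(x), max = max(x),
             range = max(x) - min(x), cv_pct = cv)
}

#' Pairwise Pearson correlations between trait BLUEs
#'
#' Pairwise-complete Pearson correlations with two-sided p-values, flagging
#' significance at the conventional P < 0.0001 threshold used for
#' multi-trait BLUE tables.
#'
#' @param blues wide data frame from [blues_table()] (a `line_id` column is
#'   ignored), or a numeric matrix lines x traits.
#' @param alpha significance threshold for the flag matrix.
#' @return a `trait_cor` list with matrices `r`, `p`, `n` and `significant`.
#' @export
trait_correlations <- function(blues, alpha = 1e-4) {
  if (is.data.frame(blues)) {
    blues <- as.matrix(blues[, setdiff(names(blues), "line_id"),
                             drop = FALSE])
  }
  k <- ncol(blues)
  if (k < 2) stop("need at least two traits")
  traits <- colnames(blues)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(is.finite(blues))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- is.finite(blues[, i]) & is.finite(blues[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      if (stats::sd(blues[ok, i]) == 0 || stats::sd(blues[ok, j]) == 0) {
        warning("zero variance in a trait: correlation undefined")
        next
      }
      ct <- stats::cor.test(blues[ok, i], blues[ok, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, significant = p < alpha),
            class = "trait_cor")
}

# pull one trait out of long records and validate it
select_trait <- function(records, trait = NULL) {
  need <- c("line_id", "year", "rep", "trait", "value")
  if (!all(need %in% names(records))) {
    stop("records need columns ", paste(need, collapse = ", "))
  }
  trait <- trait %||% unique(records$trait)
  if (length(trait) != 1) {
    stop("several traits present: pass `trait` explicitly")
  }
  d <- records[records$trait == trait & is.finite(records$value), ,
               drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait ", trait)
  d
}
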