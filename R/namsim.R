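#' Construct a NAM genotype matrix
#'
#' Container for a nested association mapping population: a lines-by-markers
#' dosage matrix coding the number of wild (donor) alleles per locus
#' (0 = homozygous recurrent, 1 = heterozygous, 2 = homozygous wild) plus a
#' family label per line.  Column order must match the genetic map used
#' downstream.
#'
#' @param dosage integer matrix, lines x markers, values in \{0, 1, 2\} or NA;
#'   rownames are line ids, colnames marker ids.
#' @param family factor or character vector, one family label per line.
#' @return a `nam_geno` object (list with elements `dosage` and `family`).
#' @export
nam_geno <- function(dosage, family) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  ok <- is.na(dosage) | dosage == 0L | dosage == 1L | dosage == 2L
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage values must be 0/1/2 or NA (row %d, column %d)",
                 bad[1], bad[2]))
  }
  if (length(family) != nrow(dosage)) {
    stop("`family` must have one label per line")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("L%05d", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(rownames(dosage))) stop("line ids must be unique")
  structure(list(dosage = dosage, family = factor(family)),
            class = "nam_geno")
}

#' @export
print.nam_geno <- function(x, ...) {
  cat(sprintf("NAM genotype matrix: %d lines x %d markers, %d families\n",
              nrow(x$dosage), ncol(x$dosage), nlevels(x$family)))
  invisible(x)
}

#' @export
dim.nam_geno <- function(x) dim(x$dosage)

#' Subset a NAM genotype matrix by lines
#'
#' @param x a [nam_geno()] object.
#' @param lines line ids or indices to keep.
#' @return a `nam_geno` with the selected lines.
#' @export
subset_lines <- function(x, lines) {
  stopifnot(inherits(x, "nam_geno"))
  nam_geno(x$dosage[lines, , drop = FALSE], droplevels(x$family[
    if (is.character(lines)) match(lines, rownames(x$dosage)) else lines]))
}

# one round of meiosis for n individuals in parallel.
# h1, h2: n x m 0/1 haplotype matrices; rswitch: per-marker recombination
# fraction with the previous marker (0.5 at chromosome starts).
# Returns an n x m gamete matrix.
meiosis_gametes <- function(h1, h2, rswitch) {
  n <- nrow(h1); m <- ncol(h1)
  state <- matrix(stats::runif(n * m), n, m) <
    matrix(rswitch, n, m, byrow = TRUE)
  if (m > 1) {
    for (j in 2:m) state[, j] <- xor(state[, j - 1L], state[, j])
  }
  out <- h1
  out[state] <- h2[state]
  out
}

#' Simulate one BC1S3 family
#'
#' Emulates the breeding scheme of a backcross-selfing NAM family: a fully
#' homozygous wild donor is crossed to a fully homozygous recurrent
#' (cultivated) parent, the F1 is backcrossed once to the recurrent parent,
#' and each BC1 plant is selfed for three generations with independent
#' meioses.  Crossovers follow the Haldane model (no interference).
#' The expected wild-genome fraction is 25% and the per-locus genotype
#' frequencies are P(0) = 23/32, P(1) = 1/16, P(2) = 7/32.
#'
#' @param map a [genetic_map()].
#' @param n_lines number of lines (each descending from its own BC1 plant).
#' @param seed RNG seed.
#' @param line_prefix prefix for generated line ids.
#' @param family family label attached to all lines.
#' @return a [nam_geno()] with one family.
#' @export
simulate_bc1s3_family <- function(map, n_lines, seed = 1L,
                                  line_prefix = "L", family = "F01") {
  stopifnot(inherits(map, "genetic_map"))
  if (n_lines < 1) stop("`n_lines` must be >= 1")
  m <- nrow(map)
  rswitch <- map_switch_fractions(map)
  dosage <- with_seed(seed, {
    ones <- matrix(1L, n_lines, m)
    zeros <- matrix(0L, n_lines, m)
    # BC1: gamete from the F1 (haplotypes donor/recurrent) + recurrent gamete
    h1 <- meiosis_gametes(ones, zeros, rswitch)
    h2 <- zeros
    for (g in 1:3) { # S1..S3: self with two independent meioses
      new1 <- meiosis_gametes(h1, h2, rswitch)
      new2 <- meiosis_gametes(h1, h2, rswitch)
      h1 <- new1; h2 <- new2
    }
    h1 + h2
  })
  rownames(dosage) <- sprintf("%s%04d", line_prefix, seq_len(n_lines))
  colnames(dosage) <- map$marker
  nam_geno(dosage, rep(family, n_lines))
}

#' Build a multi-family NAM population
#'
#' Concatenates independently simulated BC1S3 families.  Each marker is
#' polymorphic (donor carries the wild allele) in a random Bernoulli subset
#' of families; in families where a marker is monomorphic its dosage is 0
#' for every line, which reproduces the family-monomorphic markers that make
#' family-specific effects estimable only in segregating families.
#'
#' @param map a [genetic_map()].
#' @param n_families number of donor families.
#' @param lines_per_family lines per family (scalar or vector).
#' @param polymorphism_rate probability in (0, 1] that a marker segregates
#'   in a given family.
#' @param seed RNG seed.
#' @return a [nam_geno()] with `n_families` families.
#' @export
build_nam_population <- function(map, n_families = 25, lines_per_family = 57,
                                 polymorphism_rate = 1, seed = 1L) {
  stopifnot(inherits(map, "genetic_map"))
  if (n_families < 1) stop("need at least one family")
  if (polymorphism_rate <= 0 || polymorphism_rate > 1) {
    stop("`polymorphism_rate` must be in (0, 1]")
  }
  npf <- rep_len(as.integer(lines_per_family), n_families)
  fam_names <- sprintf("F%02d", seq_len(n_families))
  m <- nrow(map)
  poly <- with_seed(derive_seed(seed, 11L), matrix(
    stats::runif(n_families * m) <= polymorphism_rate, n_families, m))
  parts <- lapply(seq_len(n_families), function(f) {
    g <- simulate_bc1s3_family(map, npf[f], seed = derive_seed(seed, 2L, f),
                               line_prefix = sprintf("%s_", fam_names[f]),
                               family = fam_names[f])
    g$dosage[, !poly[f, ]] <- 0L
    g
  })
  dosage <- do.call(rbind, lapply(parts, function(g) g$dosage))
  family <- unlist(lapply(parts, function(g) as.character(g$family)))
  nam_geno(dosage, family)
}

#' Draw a random additive QTL model
#'
#' Places `n_qtl` QTLs at marker positions (with a configurable minimum
#' spacing) and assigns each a per-dosage additive effect beta; the reported
#' QTL effect downstream is the homozygous difference 2*beta.  A fraction of
#' the QTLs can be made family-specific: their donor allele is functional
#' only in a strict subset of families.
#'
#' @param map a [genetic_map()].
#' @param n_qtl number of QTLs (0 gives a pure-noise trait model).
#' @param effect_sizes per-dosage effects, recycled to `n_qtl`.
#' @param family_specific_fraction fraction of QTLs restricted to a strict
#'   subset of families.
#' @param families character vector of family labels in the population
#'   (required when `family_specific_fraction > 0`).
#' @param min_spacing_cM minimum within-chromosome spacing between QTLs.
#' @param mu trait intercept.
#' @param seed RNG seed.
#' @return a `qtl_model`: list with `marker`, `chrom`, `pos`, `beta`,
#'   `family_mask` (list, NULL entries = active everywhere) and `mu`.
#' @export
draw_qtl_model <- function(map, n_qtl, effect_sizes = 1,
                           family_specific_fraction = 0, families = NULL,
                           min_spacing_cM = 0, mu = 0, seed = 1L) {
  stopifnot(inherits(map, "genetic_map"))
  if (n_qtl > nrow(map)) stop("more QTLs requested than markers on the map")
  if (family_specific_fraction > 0 &&
      (is.null(families) || length(families) < 2)) {
    stop("family-specific QTLs need >= 2 family labels")
  }
  model <- with_seed(seed, {
    idx <- integer(0)
    if (n_qtl > 0) {
      cand <- sample.int(nrow(map))
      for (i in cand) {
        ok <- !any(map$chrom[idx] == map$chrom[i] &
                     abs(map$pos[idx] - map$pos[i]) < min_spacing_cM)
        if (ok) idx <- c(idx, i)
        if (length(idx) == n_qtl) break
      }
      if (length(idx) < n_qtl) {
        stop("cannot place ", n_qtl, " QTLs with the requested spacing")
      }
      idx <- sort(idx)
    }
    beta <- rep_len(as.numeric(effect_sizes), n_qtl)
    mask <- vector("list", n_qtl)
    if (n_qtl > 0 && family_specific_fraction > 0) {
      n_spec <- round_half_up(family_specific_fraction * n_qtl)
      which_spec <- if (n_spec > 0) sample.int(n_qtl, n_spec) else integer(0)
      for (q in which_spec) {
        k <- sample.int(length(families) - 1L, 1L) # strict subset
        mask[[q]] <- sort(sample(families, k))
      }
    }
    list(marker = map$marker[idx], chrom = map$chrom[idx],
         pos = map$pos[idx], beta = beta, family_mask = mask, mu = mu)
  })
  structure(model, class = "qtl_model")
}

#' Specify phenotype variance components
#'
#' @param V_G polygenic genotypic variance (beyond the mapped QTLs).
#' @param V_GY genotype-by-year interaction variance.
#' @param V_R residual (plot error) variance.
#' @param years number of years.
#' @param reps replicates per year.
#' @param V_Y variance of the year main effects (default 0).
#' @return a `variance_spec` list.
#' @export
variance_spec <- function(V_G, V_GY, V_R, years = 4, reps = 2, V_Y = 0) {
  if (any(c(V_G, V_GY, V_R, V_Y) < 0)) stop("variances must be >= 0")
  if (years < 1 || reps < 1) stop("`years` and `reps` must be >= 1")
  structure(list(V_G = V_G, V_GY = V_GY, V_R = V_R,
                 years = as.integer(years), reps = as.integer(reps),
                 V_Y = V_Y),
            class = "variance_spec")
}

#' Simulate multi-year plot phenotypes
#'
#' Generates plot values
#' `y = mu + sum(beta * dosage) + g + year + gy + e` with
#' `g ~ N(0, V_G)` per line (polygenic background independent of the mapped
#' markers), year main effects `~ N(0, V_Y)` drawn once per year,
#' `gy ~ N(0, V_GY)` per line-year and plot error `e ~ N(0, V_R)`.  QTLs
#' with a family mask contribute only in the masked families.
#'
#' @param geno a [nam_geno()].
#' @param qtl_model a `qtl_model` from [draw_qtl_model()], or NULL.
#' @param vspec a [variance_spec()].
#' @param trait trait name written into the records.
#' @param rep_pattern optional vector of replicate counts per year (e.g.
#'   `c(1, 2, 2, 1)` for an unbalanced trial); default balanced.
#' @param seed RNG seed.
#' @return a long-format data frame (`line_id`, `year`, `rep`, `trait`,
#'   `value`).
#' @export
simulate_phenotypes <- function(geno, qtl_model = NULL, vspec, trait = "trait1",
                                rep_pattern = NULL, seed = 1L) {
  stopifnot(inherits(geno, "nam_geno"), inherits(vspec, "variance_spec"))
  n <- nrow(geno$dosage)
  y <- vspec$years
  reps <- rep_pattern %||% rep(vspec$reps, y)
  if (length(reps) != y || any(reps < 1)) {
    stop("`rep_pattern` must give >= 1 replicate for each year")
  }
  gv <- rep(qtl_model$mu %||% 0, n)
  if (!is.null(qtl_model) && length(qtl_model$marker) > 0) {
    for (q in seq_along(qtl_model$marker)) {
      d <- geno$dosage[, qtl_model$marker[q]]
      d[is.na(d)] <- 0L
      mask <- qtl_model$family_mask[[q]]
      active <- if (is.null(mask)) rep(TRUE, n) else geno$family %in% mask
      gv <- gv + qtl_model$beta[q] * d * active
    }
  }
  with_seed(seed, {
    g <- stats::rnorm(n, 0, sqrt(vspec$V_G))
    year_eff <- stats::rnorm(y, 0, sqrt(vspec$V_Y))
    gy <- matrix(stats::rnorm(n * y, 0, sqrt(vspec$V_GY)), n, y)
    rows <- lapply(seq_len(y), function(j) {
      do.call(rbind, lapply(seq_len(reps[j]), function(r) {
        data.frame(line_id = rownames(geno$dosage), year = j, rep = r,
                   trait = trait,
                   value = gv + g + year_eff[j] + gy[, j] +
                     stats::rnorm(n, 0, sqrt(vspec$V_R)),
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a daily mean-temperature series
#'
#' Sinusoid plus Gaussian noise; values may be negative (frost days), which
#' exercises the base-temperature rule of [compute_gdd()].
#'
#' @param n_days length of the series (>= 1).
#' @param mean long-run mean temperature in degrees C.
#' @param amplitude seasonal amplitude in degrees C.
#' @param noise_sd day-to-day noise SD.
#' @param period sinusoid period in days.
#' @param seed RNG seed.
#' @return numeric vector of daily mean temperatures.
#' @export
simulate_daily_temperatures <- function(n_days, mean = 12, amplitude = 8,
                                        noise_sd = 2, period = 365,
                                        seed = 1L) {
  if (n_days < 1) stop("`n_days` must be >= 1")
  day <- seq_len(n_days)
  with_seed(seed,
            mean + amplitude * sin(2 * pi * day / period) +
              stats::rnorm(n_days, 0, noise_sd))
}
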