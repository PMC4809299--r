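#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker` (unique id), `chrom` (chromosome label) and `pos` (position in
#' centimorgan, >= 0).  Rows are sorted by chromosome then position.
#'
#' @param marker character vector of unique marker ids.
#' @param chrom chromosome label per marker.
#' @param pos map position in cM per marker.
#' @return a `genetic_map` data frame.
#' @export
genetic_map <- function(marker, chrom, pos) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(marker) == 0L) stop("a genetic map needs at least one marker")
  if (anyDuplicated(marker)) stop("marker ids must be unique")
  if (any(!is.finite(pos)) || any(pos < 0)) {
    stop("map positions must be finite and >= 0")
  }
  map <- data.frame(marker = marker, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos, map$marker), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Generate a synthetic genetic map
#'
#' Places `markers_per_chrom` markers on each of `n_chromosomes`
#' chromosomes, either on a regular grid from 0 to the chromosome length or
#' uniformly at random (sorted).
#'
#' @param n_chromosomes number of chromosomes (default 7, a barley genome).
#' @param chrom_lengths_cM chromosome length(s) in cM, recycled.
#' @param markers_per_chrom markers per chromosome (>= 2), recycled.
#' @param spacing `"regular"` or `"uniform"`.
#' @param seed RNG seed (used only for uniform placement).
#' @return a [genetic_map()].
#' @examples
#' make_genetic_map(1, 100, 11)$pos  # 0, 10, ..., 100
#' @export
make_genetic_map <- function(n_chromosomes = 7, chrom_lengths_cM = 150,
                             markers_per_chrom = 50,
                             spacing = c("regular", "uniform"), seed = 1L) {
  spacing <- match.arg(spacing)
  if (n_chromosomes < 1) stop("need at least one chromosome")
  len <- rep_len(as.numeric(chrom_lengths_cM), n_chromosomes)
  mpc <- rep_len(as.integer(markers_per_chrom), n_chromosomes)
  if (any(len <= 0)) stop("chromosome lengths must be positive")
  if (any(mpc < 2)) stop("need at least 2 markers per chromosome")
  pos_list <- with_seed(seed, lapply(seq_len(n_chromosomes), function(i) {
    if (spacing == "regular") seq(0, len[i], length.out = mpc[i])
    else sort(stats::runif(mpc[i], 0, len[i]))
  }))
  chrom_names <- sprintf("%dH", seq_len(n_chromosomes))
  chrom <- rep(chrom_names, mpc)
  pos <- unlist(pos_list, use.names = FALSE)
  marker <- sprintf("M_%s_%03d", chrom, unlist(lapply(mpc, seq_len)))
  genetic_map(marker, chrom, pos)
}

# per-marker recombination fraction with the *previous* marker: Haldane
# within a chromosome, 0.5 at each chromosome start (independent assortment)
map_switch_fractions <- function(map) {
  m <- nrow(map)
  r <- rep(0.5, m)
  if (m > 1) {
    same <- map$chrom[-1] == map$chrom[-m]
    d <- map$pos[-1] - map$pos[-m]
    r[-1][same] <- haldane(d[same])
  }
  r
}

#' Haldane map function
#'
#' Recombination fraction between two loci `d` cM apart assuming no
#' crossover interference: `0.5 * (1 - exp(-2 d / 100))`.
#'
#' @param d_cM genetic distance in centimorgan (>= 0).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("distances must be >= 0")
  0.5 * (1 - exp(-2 * d_cM / 100))
}
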