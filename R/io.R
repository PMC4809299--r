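#' @name namqtl-io
#' @title Plain-text readers and writers
#' @description
#' All tables are TSV/CSV with a leading comment block (`#` lines) carrying
#' the package version, a config hash and the base seed, so that identical
#' configuration and seed produce byte-identical files.  Readers validate
#' against the type invariants and reject malformed input with the offending
#' row/column named, rather than coercing silently.
NULL

meta_header <- function(meta = NULL) {
  if (is.null(meta)) return(character(0))
  c(sprintf("# namqtl %s",
            as.character(utils::packageVersion("namqtl"))),
    sprintf("# %s: %s", names(meta), unlist(meta)))
}

write_table_meta <- function(df, path, sep, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- meta_header(meta)
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_meta <- function(path, sep) {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a dosage genotype matrix
#'
#' TSV layout: columns `line_id`, `family`, then one dosage column per
#' marker (header row = marker ids).  Accepted dosage tokens are 0, 1, 2
#' and the missing markers `NA` or `.`.
#'
#' @param geno a [nam_geno()].
#' @param path file path.
#' @param meta optional named list written into the comment header.
#' @return `write_genotypes` the path, invisibly; `read_genotypes` a
#'   [nam_geno()].
#' @export
write_genotypes <- function(geno, path, meta = NULL) {
  stopifnot(inherits(geno, "nam_geno"))
  df <- data.frame(line_id = rownames(geno$dosage),
                   family = as.character(geno$family),
                   geno$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_meta(df, path, "\t", meta)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("line_id", "family"))) {
    stop("malformed genotype header: expected line_id, family, markers...")
  }
  if (anyDuplicated(df$line_id)) {
    stop("duplicate line_id: ", df$line_id[duplicated(df$line_id)][1])
  }
  raw <- as.matrix(df[, -(1:2), drop = FALSE])
  raw[raw == "." | raw == "NA"] <- NA
  bad <- !is.na(raw) & !(raw %in% c("0", "1", "2"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage token '%s' at line %s, marker %s",
                 raw[w[1], w[2]], df$line_id[w[1]], colnames(raw)[w[2]]))
  }
  dosage <- matrix(as.integer(raw), nrow(raw), ncol(raw),
                   dimnames = list(df$line_id, colnames(raw)))
  nam_geno(dosage, df$family)
}

#' Write / read a genetic map
#'
#' Three-column TSV: `marker`, `chromosome`, `cM`.  Unsorted input is
#' sorted by (chromosome, cM) with a warning.
#'
#' @param map a [genetic_map()].
#' @param path file path.
#' @param meta optional comment-header metadata.
#' @export
write_map <- function(map, path, meta = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  df <- data.frame(marker = map$marker, chromosome = map$chrom,
                   cM = map$pos, stringsAsFactors = FALSE)
  write_table_meta(df, path, "\t", meta)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read_table_meta(path, "\t")
  if (!all(c("marker", "chromosome", "cM") %in% names(df))) {
    stop("map file needs columns marker, chromosome, cM")
  }
  o <- order(df$chromosome, df$cM, df$marker)
  if (!identical(o, seq_len(nrow(df)))) {
    warning("map rows were not sorted by (chromosome, cM); sorting")
  }
  genetic_map(df$marker, df$chromosome, df$cM)
}

#' Write / read long-format phenotype records
#'
#' CSV with columns `line_id`, `year`, `rep`, `trait`, `value`.  Rows with
#' missing values are dropped at read time with a message; duplicate
#' (line, year, rep, trait) keys are an error.
#'
#' @param records phenotype data frame.
#' @param path file path.
#' @param meta optional comment-header metadata.
#' @export
write_phenotypes <- function(records, path, meta = NULL) {
  need <- c("line_id", "year", "rep", "trait", "value")
  stopifnot(all(need %in% names(records)))
  write_table_meta(records[, need], path, ",", meta)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_table_meta(path, ",")
  need <- c("line_id", "year", "rep", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype file needs columns ", paste(need, collapse = ", "))
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  n_bad <- sum(!is.finite(df$value))
  if (n_bad > 0) {
    message(n_bad, " phenotype record(s) with missing values dropped")
    df <- df[is.finite(df$value), , drop = FALSE]
  }
  key <- paste(df$line_id, df$year, df$rep, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate phenotype record: line %s, year %s, rep %s, %s",
                 d$line_id, d$year, d$rep, d$trait))
  }
  rownames(df) <- NULL
  df
}

#' Write / read a daily temperature series
#'
#' CSV with columns `day` (consecutive integers from 1) and `mean_temp`.
#' Gaps in the day sequence are an error.
#'
#' @param temps numeric temperature vector (day 1 = first element).
#' @param path file path.
#' @param meta optional comment-header metadata.
#' @export
write_weather <- function(temps, path, meta = NULL) {
  write_table_meta(data.frame(day = seq_along(temps), mean_temp = temps),
                   path, ",", meta)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  df <- read_table_meta(path, ",")
  if (!all(c("day", "mean_temp") %in% names(df))) {
    stop("weather file needs columns day, mean_temp")
  }
  df <- df[order(df$day), ]
  gap <- which(diff(df$day) != 1)
  if (df$day[1] != 1 || length(gap)) {
    at <- if (df$day[1] != 1) 1 else df$day[gap[1]] + 1
    stop("weather series has a gap at day ", at)
  }
  as.numeric(df$mean_temp)
}

#' Write the simulated-QTL truth table
#'
#' TSV with one row per simulated QTL (`marker`, `chrom`, `cM`, `beta`,
#' `effect_2beta`, `families` — empty when active in all families), used by
#' recovery tests.
#'
#' @param qtl_model a `qtl_model`.
#' @param path file path.
#' @param meta optional comment-header metadata.
#' @export
write_qtl_truth <- function(qtl_model, path, meta = NULL) {
  stopifnot(inherits(qtl_model, "qtl_model"))
  fam <- vapply(qtl_model$family_mask,
                function(m) if (is.null(m)) "" else paste(m, collapse = ","),
                "")
  df <- data.frame(marker = qtl_model$marker, chrom = qtl_model$chrom,
                   cM = qtl_model$pos, beta = qtl_model$beta,
                   effect_2beta = 2 * qtl_model$beta, families = fam,
                   stringsAsFactors = FALSE)
  write_table_meta(df, path, "\t", meta)
}
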