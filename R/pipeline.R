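#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> blues -> gwas -> cv -> report
#' chain.  The defaults are the reference protocol's values: significance
#' level 0.05 on Holm-adjusted p-values, 1 cM cofactor exclusion, 200
#' subsampling runs of 80% of the lines per family, 10% minimum detection
#' rate and QTL merging below 4 cM.
#'
#' @param n_families,lines_per_family population size (default 25 x 57).
#' @param n_chromosomes,chrom_length_cM,markers_per_chrom map geometry.
#' @param polymorphism_rate per-family marker polymorphism probability.
#' @param n_qtl,effect_size,family_specific_fraction trait architecture.
#' @param V_G,V_GY,V_R,V_Y,years,reps variance components and trial design.
#' @param trait_name simulated trait name.
#' @param alpha significance level on adjusted p-values.
#' @param exclusion_cM cofactor exclusion radius.
#' @param n_runs,fraction subsampling settings.
#' @param min_detection,merge_cM QTL consolidation settings.
#' @param seed base seed fanned out per stage via [derive_seed()].
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_families = 25, lines_per_family = 57,
                            n_chromosomes = 7, chrom_length_cM = 150,
                            markers_per_chrom = 50, polymorphism_rate = 1,
                            n_qtl = 3, effect_size = 1,
                            family_specific_fraction = 0,
                            V_G = 1, V_GY = 0.5, V_R = 1, V_Y = 1,
                            years = 4, reps = 2, trait_name = "trait1",
                            alpha = 0.05, exclusion_cM = 1.0,
                            n_runs = 200, fraction = 0.8,
                            min_detection = 0.10, merge_cM = 4.0,
                            seed = 1L, out_dir = ".") {
  cfg <- as.list(environment())
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$fraction > 0, cfg$fraction < 1,
            cfg$min_detection >= 0, cfg$min_detection <= 1,
            cfg$exclusion_cM >= 0, cfg$merge_cM > 0, cfg$n_runs >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Plain `key = value` text format; `#` lines are comments.  Unknown keys
#' are an error; numeric fields are converted.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  defaults <- formals(pipeline_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  for (k in keys) {
    if (is.numeric(defaults[[k]])) args[[k]] <- as.numeric(vals[keys == k])
  }
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  keys <- setdiff(names(config), "out_dir")
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], as.character, "")), path)
  invisible(path)
}

# stable hash of the configuration, embedded in output headers
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Chains the stages `simulate` (synthetic population, trait and weather),
#' `blues` (per-trait BLUEs, variance components, heritability,
#' correlations), `gwas` (full-data cofactor selection and scan), `cv`
#' (repeated stratified subsampling) and `report` (consolidated QTL table).
#' Stages can be run independently; later stages read the files earlier
#' stages wrote into `config$out_dir`.  Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "blues", "gwas", "cv", "report")`.
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "blues", "gwas", "cv",
                                    "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pathto <- function(f) file.path(config$out_dir, f)
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  off <- pipeline_stage_offsets()
  artifacts <- list()
  need <- function(f, stage) {
    p <- pathto(f)
    if (!file.exists(p)) {
      stop("stage '", stage, "' needs ", f,
           ": run the earlier pipeline stages first")
    }
    p
  }

  if ("simulate" %in% stages) {
    map <- make_genetic_map(config$n_chromosomes, config$chrom_length_cM,
                            config$markers_per_chrom,
                            seed = derive_seed(config$seed, off["map"]))
    geno <- build_nam_population(map, config$n_families,
                                 config$lines_per_family,
                                 config$polymorphism_rate,
                                 seed = derive_seed(config$seed,
                                                    off["genotypes"]))
    qtl <- draw_qtl_model(map, config$n_qtl, config$effect_size,
                          config$family_specific_fraction,
                          families = levels(geno$family),
                          seed = derive_seed(config$seed, off["qtl"]))
    vs <- variance_spec(config$V_G, config$V_GY, config$V_R,
                        config$years, config$reps, config$V_Y)
    ph <- simulate_phenotypes(geno, qtl, vs, trait = config$trait_name,
                              seed = derive_seed(config$seed,
                                                 off["phenotypes"]))
    temps <- simulate_daily_temperatures(
      200, seed = derive_seed(config$seed, off["weather"]))
    artifacts$map <- write_map(map, pathto("map.tsv"), meta)
    artifacts$genotypes <- write_genotypes(geno, pathto("genotypes.tsv"),
                                           meta)
    artifacts$phenotypes <- write_phenotypes(ph, pathto("phenotypes.csv"),
                                             meta)
    artifacts$weather <- write_weather(temps, pathto("weather.csv"), meta)
    artifacts$qtl_truth <- write_qtl_truth(qtl, pathto("qtl_truth.tsv"),
                                           meta)
  }

  if ("blues" %in% stages) {
    ph <- read_phenotypes(need("phenotypes.csv", "blues"))
    traits <- unique(ph$trait)
    bl <- blues_table(ph, traits)
    artifacts$blues <- write_table_meta(bl, pathto("blues.csv"), ",", meta)
    rep_rows <- lapply(traits, function(tr) {
      vc <- tryCatch(estimate_variance_components(ph, tr),
                     error = function(e) NULL)
      if (is.null(vc)) return(NULL)
      data.frame(trait = tr, V_G = vc$V_G, V_GY = vc$V_GY, V_R = vc$V_R,
                 years = vc$years, reps = vc$reps,
                 h2 = heritability_from_components(vc))
    })
    rep_rows <- do.call(rbind, rep_rows)
    if (!is.null(rep_rows)) {
      artifacts$heritability <- write_table_meta(
        rep_rows, pathto("heritability.tsv"), "\t", meta)
    }
    if (length(traits) >= 2) {
      ct <- trait_correlations(bl)
      artifacts$correlations <- write_table_meta(
        data.frame(trait = rownames(ct$r), ct$r, check.names = FALSE),
        pathto("correlations.tsv"), "\t", meta)
    }
  }

  if (any(c("gwas", "cv") %in% stages)) {
    geno <- read_genotypes(need("genotypes.tsv", "gwas/cv"))
    map <- read_map(need("map.tsv", "gwas/cv"))
    bl <- read_table_meta(need("blues.csv", "gwas/cv"), ",")
    traits <- setdiff(names(bl), "line_id")
  }

  if ("gwas" %in% stages) {
    for (tr in traits) {
      y <- stats::setNames(bl[[tr]], bl$line_id)
      cof <- select_cofactors(geno, y, map = map)
      scan <- scan_genome(geno, y, cofactors = cof, map = map,
                          exclusion_window_cM = config$exclusion_cM,
                          alpha = config$alpha)
      artifacts[[paste0("scan_", tr)]] <- write_table_meta(
        scan, pathto(sprintf("scan_%s.tsv", tr)), "\t", meta)
    }
  }

  if ("cv" %in% stages) {
    for (tr in traits) {
      y <- stats::setNames(bl[[tr]], bl$line_id)
      cv <- run_cross_validated_gwas(
        geno, y, map = map, n_runs = config$n_runs,
        fraction = config$fraction, base_seed = config$seed,
        alpha = config$alpha,
        exclusion_window_cM = config$exclusion_cM)
      artifacts[[paste0("cv_markers_", tr)]] <- write_table_meta(
        cv$markers, pathto(sprintf("cv_markers_%s.tsv", tr)), "\t", meta)
      artifacts[[paste0("cv_runs_", tr)]] <- write_table_meta(
        cv$runs, pathto(sprintf("cv_runs_%s.tsv", tr)), "\t", meta)
    }
  }

  if ("report" %in% stages) {
    map <- read_map(need("map.tsv", "report"))
    bl <- read_table_meta(need("blues.csv", "report"), ",")
    traits <- setdiff(names(bl), "line_id")
    cvs <- lapply(traits, function(tr) {
      mk <- read_table_meta(need(sprintf("cv_markers_%s.tsv", tr),
                                 "report"), "\t")
      structure(list(markers = mk), class = "cv_result")
    })
    names(cvs) <- traits
    qtl <- consolidate_multi_trait(cvs, map, config$min_detection,
                                   config$merge_cM)
    tab <- if (nrow(qtl) > 0) {
      qtl_summary_table(qtl, cvs, traits[1], config$min_detection)
    } else {
      data.frame(qtl = character(0))
    }
    artifacts$qtl_table <- write_table_meta(tab, pathto("qtl_table.tsv"),
                                            "\t", meta)
  }

  invisible(artifacts)
}
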