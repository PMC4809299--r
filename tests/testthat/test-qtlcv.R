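test_that("stratified_subsample follows the per-family rounding rule", {
  fam <- rep(c("A", "B"), c(10, 5))
  lines <- sprintf("L%02d", 1:15)
  sp <- stratified_subsample(lines, fam, 0.8, seed = 1)
  expect_equal(sum(fam[match(sp$train, lines)] == "A"), 8)
  expect_equal(sum(fam[match(sp$train, lines)] == "B"), 4)
  expect_setequal(c(sp$train, sp$holdout), lines)
  expect_length(intersect(sp$train, sp$holdout), 0)
  # family of 57: round(45.6) = 46 training, 11 hold-out
  fam57 <- rep("A", 57)
  l57 <- sprintf("L%02d", 1:57)
  sp57 <- stratified_subsample(l57, fam57, 0.8, seed = 2)
  expect_length(sp57$train, 46)
  expect_length(sp57$holdout, 11)
  expect_error(stratified_subsample(l57, fam57, 1.0), "strictly between")
  expect_error(stratified_subsample(c("a", "b"), c("A", "B")), "size 1")
  expect_identical(stratified_subsample(lines, fam, seed = 5),
                   stratified_subsample(lines, fam, seed = 5))
})

test_that("adjusted_r2 matches Ezekiel's formula", {
  expect_equal(adjusted_r2(0.5, 101, 10), 1 - 0.5 * 100 / 90)
  expect_equal(adjusted_r2(0.42, 50, 0), 0.42)
  expect_equal(adjusted_r2(1, 30, 5), 1)
  expect_error(adjusted_r2(0.5, 11, 10), "undefined")
})

test_that("consolidate_qtl chains markers below the strict 4 cM gap", {
  mk <- function(pos, chrom = "1H", rate = 0.5, p = 1e-4) {
    data.frame(marker = sprintf("m%s_%g", chrom, pos), chrom = chrom,
               pos = pos, detection_rate = rate, mean_p_holm = p,
               mean_beta = 1)
  }
  q <- consolidate_qtl(rbind(mk(10), mk(12.5), mk(17)))
  expect_equal(nrow(q), 2)
  expect_equal(q$cm_from, c(10, 17))
  expect_equal(q$cm_until, c(12.5, 17))
  # gap of exactly 4.0 cM: not merged
  q2 <- consolidate_qtl(rbind(mk(10), mk(14)))
  expect_equal(nrow(q2), 2)
  q3 <- consolidate_qtl(rbind(mk(10), mk(13.999)))
  expect_equal(nrow(q3), 1)
  # different chromosomes never merge
  q4 <- consolidate_qtl(rbind(mk(10, "1H"), mk(10.5, "2H")))
  expect_equal(nrow(q4), 2)
  # below the detection threshold nothing qualifies
  expect_equal(nrow(consolidate_qtl(mk(10, rate = 0.05))), 0)
  # permutation invariance and idempotence of the member set
  tab <- rbind(mk(3), mk(5), mk(30), mk(31), mk(10, "2H"))
  qa <- consolidate_qtl(tab)
  qb <- consolidate_qtl(tab[sample(nrow(tab)), ])
  expect_equal(qa, qb)
  # peak marker = smallest mean adjusted p among members
  tab2 <- rbind(mk(3, p = 0.01), mk(5, p = 1e-6))
  expect_equal(consolidate_qtl(tab2)$peak_marker, "m1H_5")
})

test_that("prediction model and predictive ability behave on constructed data", {
  map <- tiny_map(1, 60, 6)
  pop <- tiny_pop(map, 3, 50, seed = 33)
  d <- namqtl:::impute_dosage(pop)$dosage[, "M_1H_004"]
  y <- 2.5 * d + as.integer(pop$family) # noise-free QTL + family shifts
  sp <- stratified_subsample(rownames(pop$dosage), pop$family, seed = 34)
  tr <- subset_lines(pop, sp$train); ho <- subset_lines(pop, sp$holdout)
  names(y) <- rownames(pop$dosage)
  fit <- fit_marker_model(tr, y[sp$train], markers = "M_1H_004")
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(predictive_ability(fit, ho, y[sp$holdout]), 1,
               tolerance = 1e-8)
  # no significant markers: family-means model
  fit0 <- fit_marker_model(tr, y[sp$train], markers = character(0))
  pred0 <- predict(fit0, ho)
  fmean <- tapply(y[sp$train], tr$family, mean)
  expect_equal(as.numeric(pred0), as.numeric(fmean[as.character(ho$family)]),
               tolerance = 1e-10)
  # collinear marker columns are dropped and recorded
  dd <- pop$dosage
  dd[, "M_1H_005"] <- dd[, "M_1H_004"]
  pop2 <- nam_geno(dd, pop$family)
  fit2 <- fit_marker_model(pop2, y, markers = c("M_1H_004", "M_1H_005"))
  expect_equal(fit2$dropped, "M_1H_005")
})

test_that("cross-validated GWAS bookkeeping and reproducibility", {
  map <- tiny_map(2, 80, 10)
  pop <- tiny_pop(map, 3, 50, seed = 35)
  y <- marker_trait(pop, "M_1H_005", beta = 1.5, sd = 1, seed = 36)
  cv <- run_cross_validated_gwas(pop, y, map = map, n_runs = 8,
                                 base_seed = 37)
  expect_equal(cv$markers$detection_rate,
               cv$markers$detection_count / cv$n_runs)
  expect_true(all(cv$markers$detection_rate >= 0 &
                    cv$markers$detection_rate <= 1))
  expect_gt(cv$markers$detection_rate[cv$markers$marker == "M_1H_005"], 0.9)
  # averages only over significant runs: detected marker carries values
  hit <- cv$markers[cv$markers$marker == "M_1H_005", ]
  expect_false(is.na(hit$mean_beta))
  expect_equal(hit$mean_beta, 1.5, tolerance = 0.25)
  # undetected markers carry NA averages
  never <- cv$markers[cv$markers$detection_count == 0, ]
  expect_true(all(is.na(never$mean_beta)))
  # bit-reproducible under the same base seed
  cv2 <- run_cross_validated_gwas(pop, y, map = map, n_runs = 8,
                                  base_seed = 37)
  expect_identical(cv$markers, cv2$markers)
  expect_identical(cv$runs, cv2$runs)
  expect_error(run_cross_validated_gwas(pop, y, map = map, n_runs = 0,
                                        base_seed = 1), ">= 1")
})

test_that("power is monotone in effect size and prediction is not optimistic", {
  map <- tiny_map(2, 80, 10)
  rates <- sapply(c(0.4, 1.2), function(beta) {
    reps <- sapply(1:3, function(r) {
      pop <- tiny_pop(map, 3, 60, seed = 400 + r)
      y <- marker_trait(pop, "M_2H_006", beta, sd = 1, seed = 500 + r)
      cv <- run_cross_validated_gwas(pop, y, map = map, n_runs = 8,
                                     base_seed = 600 + r)
      cv$markers$detection_rate[cv$markers$marker == "M_2H_006"]
    })
    mean(reps)
  })
  expect_gte(rates[2], rates[1])
  # hold-out ability does not exceed in-sample adjusted R2 in expectation;
  # per-replicate orderings can flip within sampling noise at this scale,
  # so the optimism property is asserted on the replicate average
  gaps <- vapply(1:5, function(r) {
    pop <- tiny_pop(map, 3, 60, seed = 700 + r)
    y <- marker_trait(pop, "M_1H_004", 1, sd = 1, seed = 800 + r)
    cv <- run_cross_validated_gwas(pop, y, map = map, n_runs = 10,
                                   base_seed = 900 + r)
    cv$mean_r2_adj - cv$mean_r2_pred
  }, numeric(1))
  expect_gte(mean(gaps), 0)
  expect_gte(sum(gaps >= 0), 3)
})

test_that("qtl_summary_table applies the most-extreme-effect rule", {
  fake_cv <- function(beta, rate, p = 1e-5) {
    mk <- data.frame(marker = c("m1", "m2", "m3"), chrom = "1H",
                     pos = c(10, 12, 30), detection_count = NA,
                     detection_rate = rate, mean_beta = beta,
                     mean_p_holm = p, mean_r2 = 0.1)
    structure(list(markers = mk), class = "cv_result")
  }
  cvA <- fake_cv(c(-3.7, -2.1, 1.0), c(0.5, 0.4, 0.6), c(1e-6, 1e-3, 1e-4))
  cvB <- fake_cv(c(2.0, NA, NA), c(0.2, 0, 0))
  qtl <- consolidate_qtl(cvA$markers)
  expect_equal(nrow(qtl), 2)
  tab <- qtl_summary_table(qtl, list(A = cvA, B = cvB),
                           reference_trait = "A")
  # most extreme 2 * beta among significant members: 2 * (-3.7)
  expect_equal(tab$A[1], -7.4)
  expect_equal(tab$B[1], 4.0)
  # trait B not detected at the second QTL: blank cell
  expect_true(is.na(tab$B[2]))
  # single-marker QTL: degenerate interval
  expect_equal(tab$cm_from[2], tab$cm_until[2])
  # peak marker: highest significance for the reference trait
  expect_equal(tab$peak_marker[1], "m1")
  expect_error(qtl_summary_table(qtl, list(A = cvA), "missing"),
               "not among")
})

test_that("multi-trait pooling aligns intervals across traits", {
  mkr <- function(markers, pos, rate, p) {
    data.frame(marker = markers, chrom = "1H", pos = pos,
               detection_rate = rate, mean_p_holm = p, mean_beta = 1)
  }
  cvA <- structure(list(markers = mkr("m1", 10, 0.5, 1e-5)),
                   class = "cv_result")
  cvB <- structure(list(markers = mkr("m2", 12, 0.3, 1e-4)),
                   class = "cv_result")
  q <- consolidate_multi_trait(list(A = cvA, B = cvB), map = NULL)
  expect_equal(nrow(q), 1) # 2 cM apart -> one pooled QTL row
  expect_equal(q$cm_from, 10)
  expect_equal(q$cm_until, 12)
})
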