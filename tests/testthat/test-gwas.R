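test_that("schwarz_criterion matches its closed form", {
  expect_equal(schwarz_criterion(100, 100, 2), 2 * log(100))
  expect_equal(schwarz_criterion(25, 50, 3), 50 * log(0.5) + 3 * log(50))
  # a useless extra predictor costs exactly ln(n)
  expect_equal(schwarz_criterion(40, 80, 5) - schwarz_criterion(40, 80, 4),
               log(80))
  expect_identical(schwarz_criterion(0, 10, 2), -Inf)
  expect_error(schwarz_criterion(-1, 10, 2), ">= 0")
  expect_error(schwarz_criterion(1, 3, 3), "n > k")
})

test_that("holm_adjust implements the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04))$p_adjusted,
               c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.04)$p_adjusted, 0.04)
  expect_equal(holm_adjust(rep(1, 5))$p_adjusted, rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted p >= raw p, flags at the threshold
  set.seed(52)
  p <- runif(40)
  out <- holm_adjust(p)
  expect_true(all(out$p_adjusted >= p))
  expect_identical(out$significant, out$p_adjusted < 0.05)
  # agreement with stats::p.adjust as an independent route
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    expect_equal(holm_adjust(p)$p_adjusted, p.adjust(p, "holm"))
  }
  # NA propagation: only non-missing values enter m
  pna <- c(0.01, NA, 0.04)
  expect_equal(holm_adjust(pna)$p_adjusted, c(0.02, NA, 0.04))
})

test_that("select_cofactors finds a dominant QTL and obeys SBC", {
  map <- tiny_map(2, 100, 15)
  pop <- tiny_pop(map, 3, 60, seed = 14)
  y <- marker_trait(pop, "M_1H_005", beta = 2, sd = 1, seed = 15)
  cof <- select_cofactors(pop, y, map = map)
  expect_equal(cof$cofactors[1], "M_1H_005")
  # trajectory strictly decreasing from the base criterion
  expect_true(all(diff(c(cof$sbc_base, cof$sbc)) < 0))
  # 3 lines from 3 families: as many base parameters as observations
  trio <- c(1, 61, 121)
  expect_error(select_cofactors(subset_lines(pop, trio), y[trio], map = map),
               "fewer lines")
})

test_that("a duplicated column is never selected twice", {
  map <- genetic_map(paste0("m", 1:5), rep("1H", 5), c(0, 10, 10, 20, 30))
  pop0 <- tiny_pop(tiny_map(1, 30, 5), 2, 80, seed = 16)
  d <- pop0$dosage
  colnames(d) <- paste0("m", 1:5)
  d[, 3] <- d[, 2] # m3 duplicates m2
  pop <- nam_geno(d, pop0$family)
  y <- marker_trait(pop, "m2", beta = 3, sd = 0.5, seed = 17)
  cof <- select_cofactors(pop, y, map = map)
  expect_equal(cof$cofactors[1], "m2") # tie broken by map position
  expect_false("m3" %in% cof$cofactors)
})

test_that("null traits select empty or near-empty cofactor sets", {
  # forward SBC selection admits a marker once |t| exceeds ~sqrt(ln n), so
  # an occasional chance pick is expected under the null; sets stay tiny
  map <- tiny_map(2, 100, 15)
  pop <- tiny_pop(map, 3, 60, seed = 18)
  sizes <- vapply(1:5, function(i) {
    y <- namqtl:::with_seed(100 + i, rnorm(nrow(pop$dosage)))
    length(select_cofactors(pop, y, map = map)$cofactors)
  }, numeric(1))
  expect_true(all(sizes <= 2))
  expect_gte(sum(sizes == 0), 2)
})

test_that("scan_genome agrees with lm() fits marker by marker", {
  map <- tiny_map(2, 80, 8)
  pop <- tiny_pop(map, 3, 50, seed = 19)
  y <- marker_trait(pop, "M_2H_004", beta = 1, sd = 1.5, seed = 20)
  cof <- c("M_1H_002", "M_2H_004")
  scan <- scan_genome(pop, y, cofactors = cof, map = map)
  M <- namqtl:::impute_dosage(pop)$dosage
  for (j in c("M_1H_001", "M_1H_002", "M_2H_003", "M_2H_004", "M_2H_008")) {
    same <- map$chrom[match(cof, map$marker)] ==
      map$chrom[match(j, map$marker)]
    near <- same & abs(map$pos[match(cof, map$marker)] -
                         map$pos[match(j, map$marker)]) < 1
    keep <- cof[!near]
    df <- data.frame(y = y, fam = pop$family, d = M[, j])
    df <- cbind(df, M[, keep, drop = FALSE])
    form <- stats::reformulate(c("fam", keep, "d"), "y")
    fit <- summary(stats::lm(form, df))$coefficients
    row <- scan[scan$marker == j, ]
    expect_equal(row$beta, fit["d", "Estimate"], tolerance = 1e-10)
    expect_equal(row$p, fit["d", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("scan_genome applies the strict 1 cM cofactor exclusion", {
  map <- genetic_map(c("a", "b", "c", "d"), rep("1H", 4),
                     c(0, 0.5, 1.0, 10))
  set.seed(23)
  d <- matrix(sample(0:2, 4 * 120, replace = TRUE), 120, 4,
              dimnames = list(sprintf("L%03d", 1:120), c("a", "b", "c", "d")))
  pop <- nam_geno(d, rep(c("F1", "F2"), each = 60))
  y <- rnorm(120) + d[, "a"]
  scan <- scan_genome(pop, y, cofactors = c("a", "b", "c", "d"), map = map)
  excl_a <- strsplit(scan$excluded_cofactors[scan$marker == "a"], ",")[[1]]
  expect_setequal(excl_a, c("a", "b")) # self + 0.5 cM; 1.0 cM retained
  expect_false("c" %in% excl_a)
  # the tested marker is excluded from its own cofactor set but still gets
  # a coefficient
  expect_false(is.na(scan$beta[scan$marker == "a"]))
})

test_that("noise-free dosage trait gives beta = 5 and R2 = 1", {
  map <- tiny_map(1, 60, 6)
  pop <- tiny_pop(map, 2, 40, seed = 24)
  y <- 5 * namqtl:::impute_dosage(pop)$dosage[, "M_1H_003"]
  scan <- scan_genome(pop, y, cofactors = character(0), map = map)
  row <- scan[scan$marker == "M_1H_003", ]
  expect_equal(row$beta, 5, tolerance = 1e-8)
  expect_equal(row$effect_2beta, 10, tolerance = 1e-8)
  expect_lt(row$p, 1e-12)
  expect_equal(single_marker_r2(pop, y, "M_1H_003"), 1, tolerance = 1e-10)
})

test_that("monomorphic markers are flagged untested", {
  map <- genetic_map(c("a", "b"), c("1", "1"), c(0, 10))
  set.seed(26)
  d <- cbind(a = rep(0L, 30), b = sample(rep(0:2, 10)))
  rownames(d) <- sprintf("L%02d", 1:30)
  pop <- nam_geno(d, rep("F1", 30))
  y <- rnorm(30)
  scan <- scan_genome(pop, y, cofactors = character(0), map = map)
  expect_false(scan$tested[scan$marker == "a"])
  expect_true(is.na(scan$beta[scan$marker == "a"]))
  expect_true(scan$tested[scan$marker == "b"])
  expect_error(single_marker_r2(pop, y, "a"), "monomorphic")
})

test_that("scan p-values are uniform under the global null", {
  set.seed(27)
  n <- 500; m <- 60
  d <- matrix(rbinom(n * m, 2, 0.25), n, m,
              dimnames = list(sprintf("L%03d", 1:n),
                              sprintf("mk%02d", 1:m)))
  pop <- nam_geno(d, rep(sprintf("F%d", 1:5), each = 100))
  map <- genetic_map(colnames(d), rep("1H", m), seq(0, 590, by = 10))
  y <- rnorm(n)
  scan <- scan_genome(pop, y, cofactors = character(0), map = map)
  ks <- stats::ks.test(scan$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the additive effect estimate is unbiased", {
  map <- tiny_map(1, 50, 6)
  pop <- tiny_pop(map, 3, 40, seed = 28)
  beta_true <- 0.8
  est <- vapply(1:120, function(i) {
    y <- marker_trait(pop, "M_1H_004", beta_true, sd = 1, seed = 300 + i)
    scan_genome(pop, y, cofactors = character(0),
                map = map)$beta[map$marker == "M_1H_004"]
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - beta_true), 2 * se + 1e-12)
})

test_that("family-nested effects match the nested lm and estimability", {
  map <- tiny_map(1, 40, 4)
  pop <- tiny_pop(map, 3, 50, seed = 29)
  # family-specific architecture: effect 8 in F01, 0 elsewhere, no noise
  d <- namqtl:::impute_dosage(pop)$dosage[, "M_1H_002"]
  y <- ifelse(pop$family == "F01", 8 * d, 0)
  fe <- family_nested_effects(pop, y, marker = "M_1H_002")
  expect_equal(fe$effect[fe$family == "F01"], 8, tolerance = 1e-10)
  expect_true(all(abs(fe$effect[fe$family != "F01"]) < 1e-10))
  # oracle: coefficients of lm(y ~ family + family:dosage)
  y2 <- marker_trait(pop, "M_1H_002", 1.2, sd = 1, seed = 30)
  fe2 <- family_nested_effects(pop, y2, marker = "M_1H_002")
  fit <- stats::lm(y2 ~ pop$family + pop$family:d)
  cf <- stats::coef(fit)
  for (f in levels(pop$family)) {
    expect_equal(fe2$effect[fe2$family == f],
                 unname(cf[sprintf("pop$family%s:d", f)]),
                 tolerance = 1e-10)
  }
  # marker polymorphic in exactly one family
  dd <- pop$dosage
  dd[pop$family != "F01", "M_1H_003"] <- 0L
  pop2 <- nam_geno(dd, pop$family)
  fe3 <- family_nested_effects(pop2, y2, marker = "M_1H_003")
  expect_identical(fe3$estimable, c(TRUE, FALSE, FALSE))
  # monomorphic everywhere: error
  dd[, "M_1H_004"] <- 0L
  pop3 <- nam_geno(dd, pop$family)
  expect_error(family_nested_effects(pop3, y2, marker = "M_1H_004"),
               "monomorphic")
})
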