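test_that("tertile stratification uses floor(N/3) and rank/tie rules", {
  v <- setNames(1:9, paste0("s", 1:9))
  st <- stratify_by_tertiles(v)
  expect_identical(st$low, paste0("s", 1:3))
  expect_identical(st$high, paste0("s", 7:9))

  v10 <- setNames(1:10, sprintf("s%02d", 1:10))
  st10 <- stratify_by_tertiles(v10)
  expect_length(st10$low, 3)
  expect_length(st10$high, 3)

  # tie spanning the low boundary resolved by sample-id order
  vt <- setNames(c(1, 2, 2, 2, 5, 6), c("f", "e", "d", "c", "b", "a"))
  stt <- stratify_by_tertiles(vt)
  expect_identical(stt$low, c("f", "c"))  # id order among the tied 2s

  const <- setNames(rep(3, 6), paste0("s", 1:6))
  expect_true(stratify_by_tertiles(const)$uninformative)
  expect_error(stratify_by_tertiles(setNames(1:5, paste0("s", 1:5))),
               "at least 6")
})

test_that("KM curve reproduces the hand product-limit example", {
  km <- km_curve(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(km$time, c(1, 3, 5))
  expect_equal(km$surv, c(0.8, 0.8 * (2 / 3), 0), tolerance = 1e-12)
  expect_equal(km$n_risk, c(5, 3, 1))
  # S is nonincreasing and within [0, 1]
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$surv >= 0 & km$surv <= 1))

  expect_warning(km0 <- km_curve(c(1, 2, 3), c(0, 0, 0)), "no events")
  expect_length(km0$surv, 0)

  km1 <- km_curve(7, 1)
  expect_equal(km1$surv, 0)
})

test_that("KM without censoring equals one minus the empirical CDF", {
  set.seed(51)
  times <- rexp(40)
  km <- km_curve(times, rep(1, 40))
  ecdf_surv <- 1 - ecdf(times)(km$time)
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank matches the direct O-E/V oracle and the permutation view", {
  # fully separated 3+3, all uncensored
  ta <- c(1, 2, 3); tb <- c(4, 5, 6)
  lr <- logrank_test(ta, rep(1, 3), tb, rep(1, 3))
  oracle <- logrank_oracle(c(ta, tb), rep(1, 6), rep(c(1, 0), each = 3))
  expect_equal(lr$chisq, oracle, tolerance = 1e-10)

  # exact permutation reference: statistic over all 20 label assignments
  combs <- combn(6, 3)
  stats_all <- apply(combs, 2, function(idx) {
    grp <- rep(0, 6); grp[idx] <- 1
    logrank_oracle(c(ta, tb), rep(1, 6), grp)
  })
  p_perm <- mean(stats_all >= oracle - 1e-9)
  # the observed split is the most extreme one: permutation p = 2/20
  expect_equal(p_perm, 2 / 20)
  expect_equal(max(stats_all), oracle, tolerance = 1e-10)

  # censoring-aware instance checked against the same hand O-E-V expansion
  t2a <- c(1, 2, 5); e2a <- c(1, 1, 0)
  t2b <- c(1.5, 4, 6); e2b <- c(0, 0, 1)
  lr2 <- logrank_test(t2a, e2a, t2b, e2b)
  oracle2 <- logrank_oracle(c(t2a, t2b), c(e2a, e2b), rep(c(1, 0), each = 3))
  expect_equal(lr2$chisq, oracle2, tolerance = 1e-10)
})

test_that("log-rank is symmetric, null on identical groups, and time-scale free", {
  ta <- c(2, 4, 6, 8); ea <- c(1, 0, 1, 1)
  tb <- c(1, 3, 5, 9); eb <- c(0, 1, 1, 0)
  ab <- logrank_test(ta, ea, tb, eb)
  ba <- logrank_test(tb, eb, ta, ea)
  expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  scaled <- logrank_test(ta * 365, ea, tb * 365, eb)
  expect_equal(scaled$chisq, ab$chisq, tolerance = 1e-12)

  expect_warning(nul <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "undefined")
  expect_true(is.na(nul$p))
})

test_that("LOD is the natural log ratio of p-values with a floor", {
  expect_equal(compute_lod(0.01, 0.01), 0)
  expect_equal(compute_lod(0.05 / exp(2), 0.05), -2)
  expect_equal(compute_lod(0.05, 0.005), log(10))
  # floor keeps underflowed p-values finite
  expect_equal(compute_lod(0, 1), log(1e-300))
  expect_error(compute_lod(-0.1, 0.5), "0, 1")
  expect_error(compute_lod(NA, 0.5), "missing")
})

test_that("a survival scan on identical matrices yields zero LOD everywhere", {
  sim <- small_sim(seed = 52)
  genes <- rownames(sim$expr)[1:12]
  scan <- gene_survival_scan(sim$expr, sim$expr, sim$clinical,
                             genes = genes)
  expect_equal(scan$lod, rep(0, 12))
  expect_identical(scan$sig_raw, scan$sig_norm)
  expect_equal(attr(scan, "n_tests"), 12)
  expect_true(all(scan$n_low == floor(ncol(sim$expr) / 3)))
})

test_that("the scan flags confounded prognostic genes after normalization", {
  # raw prognostic-immune expression mixes phi (sampling noise) with the
  # activity signal; normalization removes phi, so p_norm should tend to be
  # smaller than p_raw (negative LOD) for those genes
  sim <- small_sim(seed = 53, n_samples = 240)
  fit <- immfocus(sim$expr)
  norm <- predict(fit)
  cls <- sim$truth$gene_class
  prg <- names(cls)[cls == "prognostic_immune"]
  scan <- gene_survival_scan(sim$expr, norm, sim$clinical, genes = prg)
  expect_lt(median(scan$lod), 0)
  expect_gte(sum(scan$sig_norm), sum(scan$sig_raw))
})

test_that("scan errors surface misalignment and missing genes", {
  sim <- small_sim(seed = 54)
  expect_error(gene_survival_scan(sim$expr, sim$expr, sim$clinical,
                                  genes = "NOPE"), "NOPE")
  clin2 <- sim$clinical[rev(seq_len(nrow(sim$clinical))), ]
  expect_error(gene_survival_scan(sim$expr, sim$expr, clin2,
                                  genes = rownames(sim$expr)[1]),
               "aligned")
})
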