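test_that("anchor correlation matches the direct Pearson formula", {
  m <- make_expr(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   9, 8, 7, 6,
                   1, 3, 2, 4,
                   5, 5, 5, 5),
                 c("PTPRC", "prop", "anti", "mix", "flat"),
                 paste0("s", 1:4))
  cc <- correlate_with_anchor(m, "PTPRC")
  r <- setNames(cc$r, cc$gene)
  expect_equal(unname(r["prop"]), 1)
  expect_equal(unname(r["anti"]), -1)
  expect_equal(unname(r["mix"]), pearson_oracle(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_equal(cc$r2, cc$r^2)
  # zero-variance gene flagged out
  expect_false("flat" %in% cc$gene)
  expect_identical(attr(cc, "excluded"), "flat")

  expect_error(correlate_with_anchor(m, "NOPE"), "NOPE")
  m2 <- m; m2["PTPRC", ] <- 7
  expect_error(correlate_with_anchor(m2, "PTPRC"), "zero variance")
})

test_that("provisional set uses a strict r2 bound and the sign rule", {
  cc <- data.frame(gene = c("a", "b", "c", "d", "PTPRC"),
                   r = c(0.78, 0.71, 0.64, -0.8, 1),
                   r2 = c(0.6, 0.5, 0.4, 0.64, 1),   # r2 authoritative, exact
                   stringsAsFactors = FALSE)
  got <- build_provisional_ings(cc, r2_threshold = 0.5)
  expect_identical(got, c("PTPRC", "a"))        # 0.5 itself excluded
  # literal r2-only rule admits the anticorrelated gene
  got2 <- build_provisional_ings(cc, r2_threshold = 0.5,
                                 require_positive = FALSE)
  expect_true("d" %in% got2)
  # fewer than 2 members is an error
  cc3 <- data.frame(gene = c("PTPRC", "x"), r = c(1, 0.1), r2 = c(1, 0.01))
  expect_error(build_provisional_ings(cc3), "at least 2")
})

test_that("two-gene refinement CVR matches a hand oracle and perfect trackers survive", {
  # 2-gene provisional: each is the other's LOO factor
  g1 <- c(2, 3, 6); g2 <- c(1, 3, 2)
  m <- make_expr(c(g1, g2), c("g1", "g2"), paste0("s", 1:3))
  ings <- refine_ings(m, c("g1", "g2"), cvr_threshold = Inf, anchor = "g1")
  cvr_g1 <- ings$per_gene_stats$cvr[ings$per_gene_stats$gene == "g1"]
  oracle <- (sd(g1 / g2) / mean(g1 / g2)) / (sd(g1) / mean(g1))
  expect_equal(cvr_g1, oracle)

  # a gene exactly proportional to the mean of the others normalizes to a
  # constant: CVR 0, retained
  others <- rbind(c(1, 2, 3, 4), c(3, 2, 5, 2), c(2, 6, 1, 3))
  tracker <- 2 * colMeans(others)
  m2 <- make_expr(c(t(others), tracker),
                  c("a", "b", "c", "tracker"), paste0("s", 1:4))
  ings2 <- refine_ings(m2, rownames(m2), cvr_threshold = 0.8, anchor = "a")
  expect_true("tracker" %in% ings2$genes)
  expect_equal(ings2$per_gene_stats$cvr[ings2$per_gene_stats$gene == "tracker"],
               0, tolerance = 1e-12)
})

test_that("a gene independent of the provisional block is refined away", {
  set.seed(301)
  n <- 200
  phi <- rlnorm(n, 0, 0.5)
  block <- t(sapply(1:10, function(i) phi * rlnorm(n, 0, 0.1)))
  indep <- rlnorm(n, 0, 0.5)
  m <- make_expr(c(t(block), indep),
                 c(paste0("b", 1:10), "indep"), paste0("s", 1:n))
  ings <- refine_ings(m, rownames(m), cvr_threshold = 0.8, anchor = "b1")
  expect_false("indep" %in% ings$genes)
  expect_true(all(paste0("b", 1:10) %in% ings$genes))
})

test_that("INGS size is monotone in both thresholds", {
  sim <- small_sim(seed = 21)
  cc <- correlate_with_anchor(sim$expr)
  sizes_r2 <- vapply(c(0.3, 0.5, 0.7), function(th)
    length(build_provisional_ings(cc, r2_threshold = th)), numeric(1))
  expect_true(all(diff(sizes_r2) <= 0))
  prov <- build_provisional_ings(cc, 0.5)
  sizes_cvr <- vapply(c(1.2, 0.8, 0.5), function(th)
    length(refine_ings(sim$expr, prov, cvr_threshold = th)$genes),
    numeric(1))
  expect_true(all(diff(sizes_cvr) <= 0))
})

test_that("fit is invariant to gene input order and serializes losslessly", {
  sim <- small_sim(seed = 22)
  fit1 <- immfocus(sim$expr)
  perm <- sample(nrow(sim$expr))
  fit2 <- immfocus(sim$expr[perm, ])
  expect_identical(fit1$ings$genes, fit2$ings$genes)
  expect_equal(fit1$factors$f, fit2$factors$f)

  path <- withr::local_tempfile(fileext = ".json")
  write_ings(fit1$ings, path)
  back <- read_ings(path)
  expect_identical(back$genes, fit1$ings$genes)
  expect_equal(back$per_gene_stats$cvr, fit1$ings$per_gene_stats$cvr)
  expect_equal(back$r2_threshold, fit1$ings$r2_threshold)
})

test_that("the fitted object exposes factors, predictions and summaries", {
  sim <- small_sim(seed = 23)
  fit <- immfocus(sim$expr)
  expect_s3_class(fit, "immfocus")
  expect_named(coef(fit), colnames(sim$expr))
  norm <- predict(fit)
  expect_identical(dim(norm), dim(sim$expr))
  # predicting on the training matrix as newdata gives the same result
  expect_equal(unclass(predict(fit, newdata = sim$expr)), unclass(norm),
               ignore_attr = TRUE)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("final INGS", out)))
})
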