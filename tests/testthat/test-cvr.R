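test_that("coefficient of variation follows the sd/mean convention", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.70710678,
               tolerance = 1e-8)
  expect_true(is.na(coefficient_of_variation(c(0, 0, 0))))
  expect_error(coefficient_of_variation(5), "at least 2")
})

test_that("CVR table equals the independent per-row CV recomputation", {
  sim <- small_sim(seed = 41)
  fit <- immfocus(sim$expr)
  norm <- predict(fit)
  tab <- compute_cvr_table(sim$expr, norm)
  for (g in sample(tab$gene[!tab$excluded], 20)) {
    cv_r <- sd(sim$expr[g, ]) / mean(sim$expr[g, ])
    cv_n <- sd(norm[g, ]) / mean(norm[g, ])
    row <- tab[tab$gene == g, ]
    expect_equal(row$cv_raw, cv_r)
    expect_equal(row$cv_norm, cv_n)
    expect_equal(row$cvr, cv_n / cv_r)
  }
})

test_that("degenerate genes are excluded rather than given infinite ratios", {
  raw <- make_expr(c(5, 5, 5,
                     1, 2, 3,
                     0, 0, 0),
                   c("const", "ok", "zero"), paste0("s", 1:3))
  norm <- make_expr(c(1, 2, 3,
                      1, 1, 1,
                      0, 0, 0),
                    c("const", "ok", "zero"), paste0("s", 1:3))
  tab <- compute_cvr_table(raw, norm)
  expect_true(tab$excluded[tab$gene == "const"])   # cv_raw = 0
  expect_true(tab$excluded[tab$gene == "zero"])    # zero mean
  expect_false(tab$excluded[tab$gene == "ok"])
  expect_equal(tab$cvr[tab$gene == "ok"], 0)
  expect_error(compute_cvr_table(raw, norm[1:2, ]), "share")
})

test_that("cvr is invariant to rescaling a gene's raw row", {
  sim <- small_sim(seed = 42)
  fit <- immfocus(sim$expr)
  g <- "TUM0005"
  scaled <- sim$expr
  scaled[g, ] <- scaled[g, ] * 7.3
  tab1 <- compute_cvr_table(sim$expr, predict(fit))
  norm2 <- normalize_expression(as_expression_matrix(scaled), fit$ings)
  tab2 <- compute_cvr_table(as_expression_matrix(scaled), norm2)
  expect_equal(tab1$cvr[tab1$gene == g], tab2$cvr[tab2$gene == g],
               tolerance = 1e-12)
})

test_that("group selection ranks, tie-breaks by gene id, and reseeds reproducibly", {
  tab <- data.frame(gene = paste0("g", sprintf("%02d", 1:5)),
                    cv_raw = 1, cv_norm = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    cvr = c(0.1, 0.2, 0.3, 0.4, 0.5), excluded = FALSE,
                    stringsAsFactors = FALSE)
  gr <- select_cvr_groups(tab, group_size = 2, seed = 9)
  expect_identical(gr$cvr_low, c("g01", "g02"))
  expect_identical(gr$cvr_high, c("g04", "g05"))
  gr2 <- select_cvr_groups(tab, group_size = 2, seed = 9)
  expect_identical(gr$cvr_random, gr2$cvr_random)

  # ties at the boundary resolved by gene id order
  tab$cvr <- c(0.1, 0.2, 0.2, 0.2, 0.5)
  gr3 <- select_cvr_groups(tab, group_size = 2, seed = 1)
  expect_identical(gr3$cvr_low, c("g01", "g02"))

  expect_error(select_cvr_groups(tab, group_size = 10, seed = 1),
               "rankable")
})

test_that("larger rankings put low and high groups at the extremes", {
  set.seed(43)
  n <- 600
  tab <- data.frame(gene = sprintf("g%03d", 1:n), cv_raw = 1,
                    cv_norm = NA, cvr = sample(seq(0.01, 6, length.out = n)),
                    excluded = FALSE, stringsAsFactors = FALSE)
  gr <- select_cvr_groups(tab, group_size = 500, seed = 3)
  ranks <- rank(tab$cvr)
  expect_true(all(ranks[match(gr$cvr_low, tab$gene)] <= 500))
  expect_true(all(ranks[match(gr$cvr_high, tab$gene)] >= 101))
  expect_equal(length(intersect(gr$cvr_low, gr$cvr_high)), 400)
})

test_that("group CVR comparison handles null, degenerate and separated cases", {
  tab <- data.frame(gene = paste0("g", 1:6), cv_raw = 1, cv_norm = NA,
                    cvr = c(1, 1, 1, 2, 2, 2), excluded = FALSE,
                    stringsAsFactors = FALSE)
  same <- compare_group_cvr(list(a = paste0("g", 1:3), b = paste0("g", 1:3)),
                            tab)
  expect_equal(same$pairwise$p, 1)
  expect_equal(same$pairwise$t, 0)

  deg <- compare_group_cvr(list(a = paste0("g", 1:3), b = paste0("g", 4:6)),
                           tab)
  expect_true(deg$pairwise$degenerate)
  expect_true(is.na(deg$pairwise$p))
  expect_equal(deg$stats$mean, c(1, 2))
})

test_that("the group t-test detects a unit mean shift at n = 50 at its analytic power", {
  set.seed(44)
  hits <- 0L
  for (i in 1:100) {
    a <- rnorm(50, 0, 1); b <- rnorm(50, 1, 1)
    tab <- data.frame(gene = paste0("g", 1:100), cv_raw = 1, cv_norm = NA,
                      cvr = c(a, b), excluded = FALSE,
                      stringsAsFactors = FALSE)
    cmp <- compare_group_cvr(list(a = paste0("g", 1:50),
                                  b = paste0("g", 51:100)), tab)
    if (cmp$pairwise$p < 1e-4) hits <- hits + 1L
  }
  # closed-form oracle: noncentral-t power of the pooled test at alpha 1e-4
  ncp <- 1 / sqrt(2 / 50)
  crit <- qt(1 - 1e-4 / 2, df = 98)
  power <- 1 - pt(crit, df = 98, ncp = ncp) + pt(-crit, df = 98, ncp = ncp)
  expect_lt(abs(hits / 100 - power), 0.12)  # ~3 binomial sd
  expect_gte(hits, 70L)
})
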