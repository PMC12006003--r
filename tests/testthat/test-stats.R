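test_that("the normality gate picks branches as designed", {
  # operating characteristic under normal data: mostly parametric calls
  parametric_calls <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    g <- replicate(4, rnorm(15), simplify = FALSE)
    parametric_calls <- parametric_calls +
      (normality_gate(g) == "parametric")
  }
  expect_gte(parametric_calls, 14)

  bimodal <- list(rnorm(15), c(rep(0, 8), rep(10, 7)))
  expect_equal(normality_gate(bimodal), "nonparametric")

  expect_warning(gate <- normality_gate(list(rep(1, 10), rnorm(10))),
                 "zero-variance")
  expect_equal(gate, "nonparametric")
  expect_error(normality_gate(list(rnorm(2), rnorm(10))), "n >= 3")
})

test_that("Kruskal-Wallis H matches a hand-rank oracle", {
  g <- list(`0` = c(3, 1, 4, 1), `60` = c(5, 9, 2, 6), `900` = c(5, 3, 5, 8))
  res <- omnibus_with_dunns(g, gate = "nonparametric")
  x <- unlist(g)
  rk <- rank(x)
  n <- length(x)
  R <- tapply(rk, rep(1:3, each = 4), sum)
  H <- 12 / (n * (n + 1)) * sum(R^2 / 4) - 3 * (n + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(res$omnibus$statistic, H, tolerance = 1e-12)
  expect_equal(res$omnibus$test, "Kruskal-Wallis")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(9)
  g <- replicate(4, rexp(12), simplify = FALSE)
  h1 <- omnibus_with_dunns(g, gate = "nonparametric")$omnibus$statistic
  g2 <- lapply(g, function(v) log(v + 1) * 100)
  h2 <- omnibus_with_dunns(g2, gate = "nonparametric")$omnibus$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("omnibus behaves under null and extreme-effect data", {
  calm <- 0
  for (r in 1:50) {
    set.seed(200 + r)
    g <- replicate(4, rnorm(15), simplify = FALSE)
    res <- omnibus_with_dunns(g)
    calm <- calm + (res$omnibus$p > 0.05)
  }
  expect_gte(calm, 45)

  set.seed(1)
  g <- list(`0` = rnorm(15), `60` = rnorm(15), `900` = rnorm(15) + 10)
  res <- omnibus_with_dunns(g)
  expect_lt(res$omnibus$p, 0.001)
  ph <- res$posthoc
  expect_lt(ph$p_adj[ph$comparison == "900 vs 0"], 0.01)
  expect_equal(ph$stars[ph$comparison == "900 vs 0"] %in% c("**", "***"), TRUE)

  tied <- list(rep(1, 5), rep(1, 5))
  res2 <- omnibus_with_dunns(tied, gate = "nonparametric")
  expect_equal(res2$omnibus$stars, "ns")
})

test_that("Dunn adjusted p values never fall below raw ones", {
  for (r in 1:10) {
    set.seed(300 + r)
    g <- replicate(5, rnorm(10) + runif(1, 0, 1), simplify = FALSE)
    ph <- omnibus_with_dunns(g, gate = "nonparametric")$posthoc
    expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
    expect_true(all(ph$p_adj <= 1))
  }
})

test_that("gate + omnibus type-I error stays near nominal under the null", {
  hits <- 0
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    set.seed(4000 + r)
    g <- replicate(3, rnorm(10), simplify = FALSE)
    res <- omnibus_with_dunns(g)
    hits <- hits + (res$omnibus$p < 0.05)
  }
  rate <- hits / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("paired change tests gate correctly and match hand arithmetic", {
  # symmetric alternating values: no location shift
  alt <- rep(c(-1, 1), 8)
  res <- paired_change_test(alt)
  expect_gt(res$p, 0.5)

  # consistent positive change: strongly significant for n = 15
  res2 <- paired_change_test(rep(5, 15))
  expect_equal(res2$gate, "nonparametric")
  expect_lt(res2$p, 0.001)

  # t statistic on a fixed list matches mean / (sd / sqrt(n))
  v <- c(2.1, 3.4, 1.7, 2.8, 3.0, 2.2)
  res3 <- paired_change_test(v)
  expect_equal(res3$gate, "parametric")
  expect_equal(res3$statistic, mean(v) / (sd(v) / sqrt(6)), tolerance = 1e-12)

  res4 <- paired_change_test(rep(0, 8))
  expect_equal(res4$p, 1)
  expect_equal(res4$stars, "ns")
})

test_that("significance stars follow the published thresholds", {
  expect_equal(star_label(0.20), "ns")
  expect_equal(star_label(0.03), "*")
  expect_equal(star_label(0.009), "**")
  expect_equal(star_label(0.0005), "***")
  expect_equal(star_label(c(1, 0.049, 0.0099)), c("ns", "*", "**"))
})
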