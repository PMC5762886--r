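test_that("the packaged table is self-consistent", {
  t1 <- loadTable1()
  expect_equal(nrow(t1), 20)
  expect_equal(t1$bl_error[1], -0.38)
  expect_equal(t1$md_error[1], -0.33)
  expect_equal(t1$rl_error[1], 1.54)
  # all 60 printed error cells equal printed operned differences (rounding)
  expect_true(all(abs(t1$bl_error - (t1$bl_1 - t1$bl_2)) <= 0.005))
  expect_true(all(abs(t1$md_error - (t1$md_1 - t1$md_2)) <= 0.005))
  expect_true(all(abs(t1$rl_error - (t1$rl_1 - t1$rl_2)) <= 0.005))
})

test_that("csv measurement tables recompute errors rather than trusting them", {
  p <- file.path(tempdir(), "meas.csv")
  write.csv(data.frame(root_id = 1:2, bl_1 = c(9, 10), bl_2 = c(9.5, 10.2),
                       md_1 = c(5, 6), md_2 = c(5.1, 5.9),
                       rl_1 = c(12, 13), rl_2 = c(11, 12.5)),
            p, row.names = FALSE)
  t <- readMeasurementTable(p)
  expect_equal(t$bl_error, c(-0.5, -0.2))
  expect_equal(t$rl_error, c(1, 0.5))
  write.csv(data.frame(a = 1), p, row.names = FALSE)
  expect_error(readMeasurementTable(p), "columns")
})

test_that("descriptive statistics use the sample (n-1) convention", {
  t1 <- loadTable1()
  d <- descriptiveErrors(t1)
  expect_lt(abs(d["bl", "mean"] - (-0.35)), 0.005)
  expect_lt(abs(d["bl", "sd"] - 0.18), 0.005)
  expect_lt(abs(d["md", "mean"] - (-0.17)), 0.005)
  expect_lt(abs(d["rl", "mean"] - 0.477), 0.001)  # column sum 9.54/20
  expect_equal(d["rl", "sd"], sd(t1$rl_error))
  const <- data.frame(bl_error = rep(1, 5), md_error = rep(2, 5),
                      rl_error = rep(3, 5))
  expect_equal(descriptiveErrors(const)$sd, c(0, 0, 0))
  expect_error(descriptiveErrors(t1[1, ]), "2 rows")
})

test_that("k-s normality behaves on null and alternative samples", {
  set.seed(2024)
  x <- rnorm(1000)
  expect_gt(ksNormality(x), 0.05)
  u <- runif(1000)
  p_u <- ksNormality(u)
  expect_lt(p_u, 0.01)
  # cross-check the statistic against a hand-computed K-S D
  su <- sort(u)
  Fhat <- pnorm(su, mean(u), sd(u))
  D_hand <- max(pmax(seq_along(su) / 1000 - Fhat, Fhat - (seq_along(su) - 1) / 1000))
  D_impl <- suppressWarnings(ks.test(u, "pnorm", mean(u), sd(u))$statistic)
  expect_equal(unname(D_impl), D_hand, tolerance = 1e-12)
  expect_error(ksNormality(c(1, 2, 3)), "at least 5")
  expect_equal(ksNormality(rep(1, 10)), 0)
  expect_true(ksNormality(x, lilliefors = TRUE) > 0.05)
})

test_that("wilcoxon exact path equals the brute-force sign-flip enumeration", {
  set.seed(9)
  for (n in c(6, 8, 10)) {
    for (rep in 1:5) {
      a <- round(rnorm(n, 0.3, 1), 1)
      b <- round(rnorm(n, 0, 1), 1)
      d <- a - b
      d <- d[d != 0]
      if (length(d) < 2) next
      got <- wilcoxonPaired(a, b)
      # enumeration over all 2^m sign assignments of |d|
      m <- length(d)
      r <- rank(abs(d))
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
      Wall <- as.vector(signs %*% r)
      W <- sum(r[d > 0])
      p_enum <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
      expect_equal(got$p.value, p_enum, tolerance = 1e-12,
                   info = paste("n", n, "rep", rep))
      expect_equal(got$statistic, W)
    }
  }
})

test_that("wilcoxon exact path agrees with the reference implementation without ties", {
  set.seed(31)
  a <- rnorm(10); b <- rnorm(10)     # continuous, no ties or zeros
  got <- wilcoxonPaired(a, b)
  want <- wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
  expect_equal(got$p.value, want, tolerance = 1e-12)
})

test_that("a symmetric configuration of differences gives p = 1", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- a + c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5)
  expect_equal(wilcoxonPaired(a, b)$p.value, 1)
})

test_that("degenerate wilcoxon inputs are rejected", {
  expect_error(wilcoxonPaired(1:6, 1:6), "zero")
  expect_error(wilcoxonPaired(1:5, 2:6), "at least 6")
  expect_error(wilcoxonPaired(1:6, 1:5), "equal length")
})

test_that("all three paired comparisons on the packaged table are significant", {
  t1 <- loadTable1()
  for (p in list(c("bl_1", "bl_2"), c("md_1", "md_2"), c("rl_1", "rl_2"))) {
    w <- wilcoxonPaired(t1[[p[1]]], t1[[p[2]]])
    expect_lt(w$p.value, 0.05)
  }
})

test_that("anova + pooled-MSE bonferroni reproduces the published post-hoc", {
  t1 <- loadTable1()
  res <- anovaBonferroni(list(bl = t1$bl_error, md = t1$md_error,
                              rl = t1$rl_error))
  pw <- res$pairwise
  get_p <- function(g1, g2)
    pw$p_adjusted[(pw$group1 == g1 & pw$group2 == g2) |
                  (pw$group1 == g2 & pw$group2 == g1)]
  expect_lt(abs(get_p("bl", "md") - 0.172) / 0.172, 0.10)
  expect_lt(abs(get_p("bl", "rl") - 8.94e-12) / 8.94e-12, 0.10)
  expect_lt(abs(get_p("md", "rl") - 1.49e-8) / 1.49e-8, 0.10)
  expect_gt(res$levene_p, 0.05)
  # cross-check against the reference pooled-SD implementation
  x <- c(t1$bl_error, t1$md_error, t1$rl_error)
  g <- factor(rep(c("bl", "md", "rl"), each = 20))
  ref <- pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                         pool.sd = TRUE)$p.value
  expect_equal(get_p("bl", "md"), unname(ref["md", "bl"]), tolerance = 1e-12)
  expect_equal(get_p("bl", "rl"), unname(ref["rl", "bl"]), tolerance = 1e-12)
  expect_equal(get_p("md", "rl"), unname(ref["rl", "md"]), tolerance = 1e-12)
})

test_that("anova degenerates correctly and respects algebraic identities", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anovaBonferroni(same)
  expect_equal(res$F, 0)
  expect_true(all(res$pairwise$p_adjusted == 1))
  # two groups: F equals the square of the pooled t statistic
  set.seed(4)
  g1 <- rnorm(8); g2 <- rnorm(9, 1)
  r2 <- anovaBonferroni(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)$statistic
  expect_equal(r2$F, unname(tt)^2, tolerance = 1e-9)
  expect_error(anovaBonferroni(list(a = 1:3)), "at least 2")
  expect_error(anovaBonferroni(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("bonferroni adjustment is monotone, bounded, and ordered correctly", {
  set.seed(14)
  g <- list(a = rnorm(10), b = rnorm(10, 10), c = rnorm(10, 0.5))
  res <- anovaBonferroni(g)
  pw <- res$pairwise
  expect_true(all(pw$p_adjusted >= pw$p_unadjusted))
  expect_true(all(pw$p_adjusted <= 1))
  expect_equal(order(pw$p_adjusted), order(pw$p_unadjusted))
  # ordering agrees with a permutation oracle on mean differences
  perm_p <- function(x, y, B = 2000) {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    hits <- 0
    for (i in seq_len(B)) {
      s <- sample(length(pool), length(x))
      if (abs(mean(pool[s]) - mean(pool[-s])) >= obs - 1e-12) hits <- hits + 1
    }
    hits / B
  }
  set.seed(15)
  p_ab <- perm_p(g$a, g$b); p_ac <- perm_p(g$a, g$c); p_bc <- perm_p(g$b, g$c)
  get_p <- function(g1, g2)
    pw$p_adjusted[(pw$group1 == g1 & pw$group2 == g2) |
                  (pw$group1 == g2 & pw$group2 == g1)]
  # the overlapping pair is the clear non-significant one under both routes
  expect_equal(which.max(c(get_p("a", "b"), get_p("a", "c"), get_p("b", "c"))),
               which.max(c(p_ab, p_ac, p_bc)))
  expect_lt(get_p("a", "b"), get_p("a", "c"))
  expect_lt(p_ab, p_ac)
})

test_that("the full report flags match the published tables", {
  t1 <- loadTable1()
  rep <- buildReport(t1)
  expect_true(all(vapply(rep$wilcoxon, `[[`, numeric(1), "p.value") < 0.05))
  pw <- rep$anova$pairwise
  sig <- pw$p_adjusted < 0.05
  names(sig) <- paste(pw$group1, pw$group2)
  expect_false(sig[["bl md"]])
  expect_true(sig[["bl rl"]])
  expect_true(sig[["md rl"]])
  expect_length(rep$ks, 6)
  expect_true(all(rep$ks >= 0 & rep$ks <= 1))
  expect_error(buildReport(t1[0, ]), "empty")
  out <- capture.output(print(rep))
  expect_true(any(grepl("Bonferroni", out)))
  js <- reportToJSON(rep)
  expect_true(jsonlite::validate(js))
})
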