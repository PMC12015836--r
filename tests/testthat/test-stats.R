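# Statistical layer: paired tests, rm-ANOVA + Greenhouse-Geisser, effect
# sizes, Bonferroni.

test_that("Shapiro-Wilk wrapper: invariance, null calibration, power", {
  set.seed(29)
  x <- rnorm(26)
  expect_equal(shapiro_wilk(x)$statistic, shapiro_wilk(3 * x - 7)$statistic)
  # null p-values uniform: KS test over 1000 replicates
  ps <- replicate(1000, shapiro_wilk(rnorm(26))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # strongly lognormal samples are rejected > 90% of the time
  rej <- mean(replicate(300, shapiro_wilk(exp(rnorm(26, sd = 1)))$p_value
                        < 0.05))
  expect_gt(rej, 0.9)
  expect_error(shapiro_wilk(rep(1, 26)), "variance")
  expect_error(shapiro_wilk(1:2), "n")
})

test_that("Wilcoxon matches stats::wilcox.test with and without ties", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(26, 0.3); y <- rnorm(26)
    if (i > 5) { x <- round(x); y <- round(y) }       # force ties
    keep <- x != y
    if (sum(keep) < 5) next
    m <- wilcoxon_signed_rank(x, y)
    r <- stats::wilcox.test(x[keep], y[keep], paired = TRUE,
                            exact = FALSE, correct = TRUE)
    expect_equal(m$p_value, r$p.value, tolerance = 1e-12)
    expect_equal(m$W_pos, unname(r$statistic))
  }
})

test_that("Wilcoxon extreme case: all differences positive", {
  x <- 1:26 + 100; y <- rep(0, 26)
  m <- wilcoxon_signed_rank(x, y)
  expect_identical(m$W, 0)
  # maximal Z for n = 26 under the continuity-corrected normal approximation
  mu <- 26 * 27 / 4; sig <- sqrt(26 * 27 * 53 / 24)
  expect_equal(m$statistic, (26 * 27 / 2 - mu - 0.5) / sig)
  expect_error(wilcoxon_signed_rank(rep(1, 10), rep(1, 10)), "non-zero")
})

test_that("Wilcoxon p approximates exact enumeration at n = 8", {
  # oracle: exact null distribution of W+ from all 2^8 sign patterns
  exact_p <- function(w_obs) {
    n <- 8
    signs <- as.matrix(expand.grid(rep(list(0:1), n)))
    W <- signs %*% (1:n)
    mu <- n * (n + 1) / 4
    mean(abs(W - mu) >= abs(w_obs - mu))
  }
  set.seed(37)
  for (i in 1:5) {
    x <- rnorm(8, 0.5); y <- rnorm(8)
    m <- wilcoxon_signed_rank(x, y)
    expect_lt(abs(m$p_value - exact_p(m$W_pos)), 0.035)
  }
})

test_that("paired t matches the textbook formula and errors on constants", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9); y <- c(4.9, 4.9, 5.2, 5.4, 5.1)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  m <- paired_t(x, y)
  expect_equal(m$statistic, t_hand)
  expect_identical(m$df, 4L)
  expect_equal(m$p_value, 2 * pt(-abs(t_hand), 4))
  expect_error(paired_t(1:5 + 2, 1:5), "variance")
})

test_that("two-level rm-ANOVA F equals the squared paired t", {
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(26); y <- rnorm(26, 0.2)
    a <- rm_anova(data.frame(subject = rep(1:26, 2),
                             cond = rep(c("A", "B"), each = 26),
                             y = c(x, y)),
                  dv = "y", within = "cond")
    tt <- paired_t(x, y)
    expect_equal(a$F[1], tt$statistic^2, tolerance = 1e-8)
    expect_equal(a$p_uncorrected[1], tt$p_value, tolerance = 1e-8)
    expect_identical(a$gg_epsilon[1], 1)        # 2 levels: always spherical
    # F <-> partial eta^2 roundtrip
    expect_equal(partial_eta_sq_from_f(a$F[1], 1, 25),
                 a$partial_eta_sq[1], tolerance = 1e-10)
  }
})

test_that("rm-ANOVA matches a brute-force sums-of-squares oracle", {
  # 4 subjects x 2 x 3 x 2 toy table; oracle by explicit mean decomposition
  set.seed(43)
  n <- 4
  grid <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                      c = c("c1", "c2"), stringsAsFactors = FALSE)
  dat <- do.call(rbind, lapply(1:n, function(s)
    data.frame(subject = s, grid, y = rnorm(12, mean = 2 *
                                              (grid$b == "b2")))))
  res <- rm_anova(dat, dv = "y", within = c("a", "b", "c"))

  gm <- mean(dat$y)
  cellmean <- function(...) {
    by <- list(...)
    agg <- stats::aggregate(dat$y, by = lapply(by, function(f) dat[[f]]),
                            FUN = mean)
    agg
  }
  # main effect of b: SS = n_per_level * sum((mean_b - gm)^2)
  mb <- tapply(dat$y, dat$b, mean)
  ss_b <- n * 4 * sum((mb - gm)^2)
  # error term: b x subject interaction
  mbs <- tapply(dat$y, list(dat$b, dat$subject), mean)
  msub <- tapply(dat$y, dat$subject, mean)
  ss_bs <- 4 * sum((sweep(sweep(mbs, 1, mb), 2, msub) + gm)^2)
  row <- res[res$name == "b", ]
  expect_equal(row$ss_effect, ss_b, tolerance = 1e-8)
  expect_equal(row$ss_error, ss_bs, tolerance = 1e-8)
  # interaction a:b
  mab <- tapply(dat$y, list(dat$a, dat$b), mean)
  ma <- tapply(dat$y, dat$a, mean)
  ss_ab <- n * 2 * sum((sweep(sweep(mab, 1, ma), 2, mb) + gm)^2)
  expect_equal(res[res$name == "a:b", ]$ss_effect, ss_ab, tolerance = 1e-8)
  # all effects present, in main -> interaction order
  expect_identical(res$name, c("a", "b", "c", "a:b", "a:c", "b:c",
                               "a:b:c"))
})

test_that("rm-ANOVA agrees with car::Anova (F, epsilon, corrected p)", {
  set.seed(47)
  n <- 9
  grid <- expand.grid(a = paste0("a", 1:2), b = paste0("b", 1:3))
  Y <- matrix(rnorm(n * 6), n)
  dat <- do.call(rbind, lapply(1:n, function(s)
    data.frame(subject = s, grid, y = Y[s, ])))
  mine <- rm_anova(dat, dv = "y", within = c("a", "b"))
  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = grid, idesign = ~ a * b, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  u <- s$univariate.tests
  expect_equal(mine$F, unname(u[-1, "F value"]), tolerance = 1e-8)
  adj <- s$pval.adjustments
  for (eff in rownames(adj)) {
    expect_equal(mine$gg_epsilon[mine$name == eff],
                 unname(adj[eff, "GG eps"]), tolerance = 1e-8)
    expect_equal(mine$p_gg[mine$name == eff],
                 unname(adj[eff, "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("rm-ANOVA input validation", {
  d <- data.frame(subject = rep(1:3, 2), cond = rep(c("x", "y"), each = 3),
                  y = rnorm(6))
  expect_error(rm_anova(d[-1, ], dv = "y", within = "cond"), "incomplete")
  expect_error(rm_anova(rbind(d, d[1, ]), dv = "y", within = "cond"),
               "more than one observation")
  expect_error(rm_anova(d, dv = "z", within = "cond"), "'z' not found")
  expect_error(rm_anova(d[d$subject == 1, ], dv = "y", within = "cond"),
               ">= 2 subjects")
  # zero cell differences: F = 0, eta^2 = 0
  d0 <- data.frame(subject = rep(1:4, 2),
                   cond = rep(c("x", "y"), each = 4),
                   y = rep(rnorm(4), 2))
  a0 <- rm_anova(d0, dv = "y", within = "cond")
  expect_identical(a0$F[1], 0)
  expect_identical(a0$partial_eta_sq[1], 0)
})

test_that("Greenhouse-Geisser epsilon: bounds and special cases", {
  expect_identical(gg_epsilon(diag(1)), 1)                     # k = 2 case
  # compound symmetry -> 1 (on contrast covariance = spherical)
  expect_equal(gg_epsilon(diag(3) * 2), 1)
  # rank-1 covariance -> lower bound 1/q
  v <- c(1, 2, 3)
  expect_equal(gg_epsilon(outer(v, v)), 1 / 3, tolerance = 1e-12)
  expect_error(gg_epsilon(matrix(c(1, 2, 2, 1), 2)), "semi-definite")
  # toward significance the GG correction is conservative: p_gg never
  # undercuts p_uncorrected (the df-scaled and unscaled F cdfs cross only
  # around p ~ 0.3, far from any decision boundary)
  set.seed(53)
  found <- 0
  for (i in 1:30) {
    dat <- do.call(rbind, lapply(1:8, function(s)
      data.frame(subject = s, f = paste0("l", 1:4),
                 y = rnorm(4, mean = c(0, 0.8, 0, 0)) * (1:4))))
    a <- rm_anova(dat, dv = "y", within = "f")
    if (a$p_uncorrected <= 0.2) {
      expect_gte(a$p_gg, a$p_uncorrected)
      found <- found + 1
    }
  }
  expect_gte(found, 5)
})

test_that("partial eta squared reproduces published effect sizes", {
  expect_equal(round(partial_eta_sq_from_f(14.362, 1, 25), 3), 0.365)
  expect_equal(round(partial_eta_sq_from_f(8.408, 1, 25), 3), 0.252)
  expect_identical(partial_eta_sq_from_f(0, 3, 40), 0)
})

test_that("Bonferroni caps at 1 and is identity for m = 1", {
  expect_equal(bonferroni(0.01, m = 42), 0.42)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  expect_error(bonferroni(0.1, m = 0), "m")
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("latency grand averages use half-up integer rounding", {
  expect_identical(latency_grand_average(c(146, 151)), 149)
  expect_identical(latency_grand_average(c(168, 198)), 183)
  expect_identical(latency_grand_average(c(100.5, 101.5)), 101)
})

test_that("the gated chain detects a 52 ms latency shift at n = 26", {
  # measurement-model power check: latencies drawn as the generator draws
  # them (condition means 353/405, SDs 44/50)
  set.seed(59)
  hits <- mean(replicate(200, {
    st <- rnorm(26, 353, 44); dt <- rnorm(26, 405, 50)
    paired_comparison(st, dt)$p_value < 0.05
  }))
  expect_gte(hits, 0.9)
  # and stays near alpha under the null
  null_rate <- mean(replicate(400, {
    st <- rnorm(26, 353, 44); dt <- rnorm(26, 353, 44)
    paired_comparison(st, dt)$p_value < 0.05
  }))
  expect_lt(null_rate, 0.1)
})
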