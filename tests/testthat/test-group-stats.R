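test_that("partial eta-squared reproduces printed conversions", {
  expect_equal(round(partial_eta_sq(5.50, 1, 226), 3), 0.024)
  expect_equal(round(partial_eta_sq(23.95, 2, 434), 2), 0.10)
  expect_equal(partial_eta_sq(0, 1, 50), 0)
  expect_error(partial_eta_sq(1, 0, 10), "positive")
  expect_equal(eta_sq_from_wilks(0.33), 0.67)
  expect_equal(eta_sq_from_wilks(1.0), 0)
  expect_error(eta_sq_from_wilks(0), "\\(0, 1\\]")
})

test_that("one-way ANOVA matches the hand decomposition", {
  r <- oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$F, 13.5)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  expect_equal(unname(r$ss["between"]), 13.5)
  expect_equal(unname(r$ss["within"]), 4)
  # algebraic identity: eta^2 from F equals SSB/(SSB+SSW)
  expect_equal(r$eta_sq, 13.5 / 17.5, tolerance = 1e-12)

  # two identical groups: F = 0
  expect_equal(oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_error(oneway_anova(list(c(1, 1), c(1, 1))), "undefined")
  expect_error(oneway_anova(list(c(1, 2))), "two groups")
})

test_that("eta^2 identity holds on generated one-way designs", {
  set.seed(14)
  for (rep in 1:10) {
    groups <- lapply(1:3, function(g) rnorm(10, mean = g))
    r <- oneway_anova(groups)
    expect_equal(r$eta_sq, r$ss[["between"]] / sum(r$ss), tolerance = 1e-12)
    expect_equal(r$eta_sq, partial_eta_sq(r$F, r$df1, r$df2),
                 tolerance = 1e-12)
  }
})

test_that("eta^2 CI inverts the noncentral F and is 0 at the null boundary", {
  expect_equal(unname(eta_sq_ci(0, 1, 50, 0.90)), c(0, 0))
  ci <- eta_sq_ci(5.50, 1, 226, 0.90)
  # interval approximately matching the printed [0.002, 0.065]
  expect_equal(unname(ci), c(0.002, 0.065), tolerance = 0.015)
  expect_lt(ci[["lo"]], partial_eta_sq(5.50, 1, 226))
  expect_gt(ci[["hi"]], partial_eta_sq(5.50, 1, 226))
  # self-consistency of the inversion: bounds map back to the tail levels
  lam <- function(eta, df1, df2) eta / (1 - eta) * (df1 + df2 + 1)
  expect_equal(pf(5.50, 1, 226, ncp = lam(ci[["lo"]], 1, 226)), 0.95,
               tolerance = 1e-6)
  expect_equal(pf(5.50, 1, 226, ncp = lam(ci[["hi"]], 1, 226)), 0.05,
               tolerance = 1e-6)
})

test_that("wilks_manova reduces to the one-way ANOVA with one outcome", {
  set.seed(21)
  y <- rnorm(30)
  g <- rep(1:3, each = 10)
  mv <- wilks_manova(matrix(y, ncol = 1), g)
  uv <- oneway_anova(split(y, g))
  expect_equal(mv$F, uv$F, tolerance = 1e-10)
  expect_equal(mv$df1, uv$df1)
  expect_equal(mv$df2, uv$df2)
  expect_equal(mv$p, uv$p, tolerance = 1e-10)
})

test_that("wilks lambda matches the determinant-ratio and manova oracles", {
  # fixed 12-case, 2-outcome, 2-group table
  Y <- cbind(c(3, 4, 5, 4, 6, 5, 7, 8, 7, 9, 8, 7),
             c(2, 3, 2, 4, 3, 5, 6, 5, 7, 6, 8, 7))
  g <- rep(c("a", "b"), each = 6)
  r <- wilks_manova(Y, g)

  # independent determinant oracle from explicitly assembled E and H
  E <- matrix(0, 2, 2); H <- matrix(0, 2, 2)
  grand <- colMeans(Y)
  for (lev in c("a", "b")) {
    Yg <- Y[g == lev, ]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * (mg - grand) %*% t(mg - grand)
    for (i in seq_len(nrow(Yg))) {
      E <- E + (Yg[i, ] - mg) %*% t(Yg[i, ] - mg)
    }
  }
  expect_equal(r$wilks_lambda, det(E) / det(E + H), tolerance = 1e-10)

  # stats::manova as a second, fully independent reference
  sm <- summary(stats::manova(Y ~ factor(g)), test = "Wilks")$stats
  expect_equal(r$wilks_lambda, sm[1, "Wilks"], tolerance = 1e-10)
  expect_equal(r$F, sm[1, "approx F"], tolerance = 1e-10)
  expect_equal(r$p, sm[1, "Pr(>F)"], tolerance = 1e-10)
  # two groups: eta^2 = 1 - lambda
  expect_equal(r$eta_sq, eta_sq_from_wilks(r$wilks_lambda), tolerance = 1e-12)
})

test_that("wilks_manova agrees with manova for 3 groups and 3 outcomes", {
  set.seed(4)
  Y <- matrix(rnorm(90), 30, 3)
  g <- rep(1:3, each = 10)
  r <- wilks_manova(Y, g)
  sm <- summary(stats::manova(Y ~ factor(g)), test = "Wilks")$stats
  expect_equal(r$wilks_lambda, sm[1, "Wilks"], tolerance = 1e-10)
  expect_equal(r$F, sm[1, "approx F"], tolerance = 1e-8)
  expect_equal(r$p, sm[1, "Pr(>F)"], tolerance = 1e-8)
})

test_that("rao-F p agrees with a permutation oracle on gaussian data", {
  set.seed(8)
  n <- 40
  Y <- matrix(rnorm(2 * n), n, 2)
  Y[1:(n / 2), ] <- Y[1:(n / 2), ] + 0.6
  g <- rep(1:2, each = n / 2)
  obs <- wilks_manova(Y, g)
  perm <- replicate(500, {
    wilks_manova(Y, sample(g))$wilks_lambda
  })
  p_perm <- mean(perm <= obs$wilks_lambda)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("difference scores feed the repeated-measures interaction test", {
  set.seed(3)
  waves <- lapply(1:3, function(t) {
    m <- matrix(rnorm(40), 20, 2)
    colnames(m) <- c("a", "b")
    m
  })
  d <- difference_scores(waves)
  expect_equal(dim(d), c(20L, 4L))
  expect_equal(colnames(d), c("a_d1", "b_d1", "a_d2", "b_d2"))
  expect_equal(d[, "a_d1"], waves[[2]][, "a"] - waves[[1]][, "a"])
  r <- wilks_manova(d, rep(1:2, each = 10))
  expect_s3_class(r, "effect_size_result")
  expect_error(difference_scores(waves[1]), "two waves")
})

test_that("logistic fit reports OR = exp(B) with Wald intervals", {
  expect_equal(round(exp(0.164), 2), 1.18)
  set.seed(55)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 0.5 * x1 - 1.0 * x2
  y <- rbinom(n, 1, plogis(eta))
  r <- logistic_fit(data.frame(x1 = x1, x2 = x2), y)
  co <- r$coefficients
  expect_equal(co$OR, exp(co$B), tolerance = 1e-12)
  expect_true(all(co$or_lo < co$OR & co$OR < co$or_hi))
  expect_equal(co$or_lo, exp(co$B - qnorm(0.975) * co$SE), tolerance = 1e-12)
  expect_equal(r$model_chi_sq$df, 2)
  expect_true(r$pct_correct >= 50 && r$pct_correct <= 100)
  # score equations hold at the optimum
  X <- cbind(1, x1, x2)
  grad <- crossprod(X, y - fitted(r$fit))
  expect_lt(max(abs(grad)), 1e-5)
})

test_that("logistic null simulation stays near zero coefficients", {
  for (s in 1:5) {
    set.seed(s)
    n <- 2000
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    y <- rbinom(n, 1, 0.5)
    r <- logistic_fit(X, y)
    expect_true(all(abs(r$coefficients$B[-1]) < 0.15))
  }
})

test_that("logistic degenerate inputs raise informative errors", {
  expect_error(logistic_fit(data.frame(x = 1:4), rep(1L, 4)), "both classes")
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(0:1, each = 20)
  expect_error(logistic_fit(data.frame(x = x), y), "separation")
})

test_that("chi-square independence follows the Pearson formula", {
  r0 <- chi_square_independence(rbind(c(5, 5), c(5, 5)))
  expect_equal(r0$statistic, 0)
  r <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_equal(chi_square_independence(matrix(1:6, 2, 3))$df, 2)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("chi-square is invariant to permutation and transposition", {
  set.seed(2)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  s <- chi_square_independence(tab)$statistic
  expect_equal(chi_square_independence(tab[c(2, 3, 1), ])$statistic, s)
  expect_equal(chi_square_independence(tab[, c(4, 1, 3, 2)])$statistic, s)
  expect_equal(chi_square_independence(t(tab))$statistic, s)
})

test_that("pearson correlation handles exact relations and the t test", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -2 * x + 3)$r, -1)
  r <- pearson_corr(x, c(1, 3, 2, 4))
  expect_equal(r$r, 0.8, tolerance = 1e-12)
  # p via the t transform with n-2 df
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(r$p, 2 * pt(tstat, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(pearson_corr(x, rep(1, 4)), "constant")
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})

test_that("faction compliance effect on the default cohort brackets eta^2 ~ .02", {
  etas <- sapply(1:40, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    w3 <- co$waves[[3]]
    sc <- score_scale(w3, paste0("compliance_", 1:3), "compliance")
    f <- co$truth$faction_of[w3$participants]
    oneway_anova(split(sc$per_participant_mean, f))$eta_sq
  })
  expect_gte(median(etas), 0.01)
  expect_lte(median(etas), 0.05)
})
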