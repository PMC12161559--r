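test_that("gamma log-link IRLS matches glm and MASS dispersion on shared data", {
  sim <- generate_gamma_responses(
    400, c(log(0.02), 0.4, -0.3), 0.5,
    design = data.frame(g = rep(c("a", "b", "c"), length.out = 400)),
    seed = 3)
  fit <- fit_gamma_loglink(sim, "response", "g", blocking = "none")
  ref <- stats::glm(response ~ g, stats::Gamma(link = "log"), data = sim,
                    control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
  shape <- MASS::gamma.shape(ref, it.lim = 50, eps.max = 1e-10)$alpha
  expect_equal(fit$alpha, 1 / shape, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$fitted > 0))
})

test_that("intercept-only fit recovers the sample mean exactly", {
  y <- withr::with_seed(2, rgamma(150, shape = 2, rate = 3))
  fit <- fit_gamma_loglink(data.frame(response = y), "response", "1",
                           blocking = "none")
  expect_equal(unname(fit$fitted[1]), mean(y), tolerance = 1e-12)
})

test_that("fits are invariant to row order and equivariant to response scaling", {
  sim <- generate_gamma_responses(
    200, c(-1, 0.5), 0.3, design = data.frame(g = rep(c("a", "b"), 100)),
    seed = 9)
  fit <- fit_gamma_loglink(sim, "response", "g", blocking = "none")
  perm <- withr::with_seed(1, sample(nrow(sim)))
  fit_p <- fit_gamma_loglink(sim[perm, ], "response", "g", blocking = "none")
  expect_equal(coef(fit), coef(fit_p), tolerance = 1e-10)
  # multiplying the response by c shifts only the intercept, by log c
  sim2 <- sim
  sim2$response <- sim2$response * 7
  fit_c <- fit_gamma_loglink(sim2, "response", "g", blocking = "none")
  expect_equal(unname(coef(fit_c)[1] - coef(fit)[1]), log(7),
               tolerance = 1e-8)
  expect_equal(unname(coef(fit_c)[-1]), unname(coef(fit)[-1]),
               tolerance = 1e-8)
  expect_equal(fit_c$alpha, fit$alpha, tolerance = 1e-8)
  # contrasts and effect sizes unchanged
  cmp <- pairwise_comparisons(estimated_marginal_means(fit, "g"), fit)
  cmp_c <- pairwise_comparisons(estimated_marginal_means(fit_c, "g"), fit_c)
  expect_equal(cmp$difference, cmp_c$difference, tolerance = 1e-8)
  expect_equal(cmp$d, cmp_c$d, tolerance = 1e-7)
})

test_that("non-positive responses are rejected with row numbers", {
  df <- data.frame(response = c(1, -2, 3), g = c("a", "b", "a"))
  expect_error(fit_gamma_loglink(df, "response", "g", blocking = "none"), "2")
})

test_that("AICc follows its formula and exceeds AIC; likelihood is monotone", {
  sim <- generate_gamma_responses(
    100, c(0, 0.2, 0.1), 0.4,
    design = data.frame(g = rep(c("a", "b"), 50), h = rep(c("u", "v"), each = 50)),
    seed = 4)
  small <- fit_gamma_loglink(sim, "response", "g", blocking = "none")
  big <- fit_gamma_loglink(sim, "response", c("g", "h"), blocking = "none")
  expect_gte(big$log_lik, small$log_lik)   # nested-model monotonicity
  k <- small$p + 1
  n <- small$n
  expect_equal(aicc(small),
               -2 * small$log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  aic <- -2 * small$log_lik + 2 * k
  expect_gt(aicc(small), aic)
})

test_that("marginal means match emmeans on an unbalanced two-factor fixture", {
  skip_if_not_installed("emmeans")
  des <- expand.grid(g = c("a", "b", "c"), h = c("u", "v"),
                     stringsAsFactors = FALSE)
  des <- des[rep(1:6, times = c(7, 13, 5, 9, 11, 20)), ]
  sim <- generate_gamma_responses(nrow(des), c(0.5, 0.4, -0.3, 0.2), 0.4,
                                  design = des, seed = 12)
  fit <- fit_gamma_loglink(sim, "response", c("g", "h"), blocking = "none")
  ref_fit <- stats::glm(response ~ g + h, stats::Gamma(link = "log"),
                        data = sim,
                        control = stats::glm.control(epsilon = 1e-12))
  ref <- summary(emmeans::emmeans(ref_fit, "g"))
  emm <- estimated_marginal_means(fit, "g")
  expect_equal(emm$table$emmean, ref$emmean, tolerance = 1e-6)
  # balanced one-factor design: EMMs equal group log-means
  bal <- generate_gamma_responses(
    90, c(0.2, 0.5), 0.3, design = data.frame(g = rep(c("a", "b"), 45)),
    seed = 5)
  bfit <- fit_gamma_loglink(bal, "response", "g", blocking = "none")
  bemm <- estimated_marginal_means(bfit, "g")
  logmeans <- log(tapply(bal$response, bal$g, mean))
  expect_equal(bemm$table$emmean, as.numeric(logmeans), tolerance = 1e-9)
})

test_that("pairwise comparisons are antisymmetric and null for identical groups", {
  sim <- generate_gamma_responses(
    300, c(0.1, 0), 0.4, design = data.frame(g = rep(c("a", "b"), 150)),
    seed = 21)
  fit <- fit_gamma_loglink(sim, "response", "g", blocking = "none")
  emm <- estimated_marginal_means(fit, "g")
  cmp <- pairwise_comparisons(emm, fit)
  expect_lt(abs(cmp$d), 0.3)
  expect_true(cmp$lower < 0 && cmp$upper > 0)
  expect_false(cmp$flagged)
  # flipping the level order flips the sign of d
  sim_flip <- sim
  sim_flip$g <- factor(sim_flip$g, levels = c("b", "a"))
  fit_f <- fit_gamma_loglink(sim_flip, "response", "g", blocking = "none")
  cmp_f <- pairwise_comparisons(estimated_marginal_means(fit_f, "g"), fit_f)
  expect_equal(cmp_f$d, -cmp$d, tolerance = 1e-8)
})

test_that("Cohen's d converges to the known standardised gap", {
  # log-mean gap delta over sigma_pop = sqrt(trigamma(1/alpha))
  alpha <- 0.5
  delta <- 0.8
  sim <- generate_gamma_responses(
    2000, c(0, delta), alpha,
    design = data.frame(g = rep(c("a", "b"), 1000)), seed = 33)
  fit <- fit_gamma_loglink(sim, "response", "g", blocking = "none")
  cmp <- pairwise_comparisons(estimated_marginal_means(fit, "g"), fit)
  expect_lt(abs(abs(cmp$d) - delta / sqrt(trigamma(1 / alpha))), 0.08)
})

test_that("never-sampled cells make interactions aliased but main effects fit", {
  # two sites, three months, one site missing a month entirely
  des <- expand.grid(site = c("s1", "s2"), month = c("m1", "m2", "m3"),
                     stringsAsFactors = FALSE)
  des <- des[!(des$site == "s2" & des$month == "m3"), ]
  des <- des[rep(seq_len(nrow(des)), each = 30), ]
  sim <- generate_gamma_responses(nrow(des), 0.2, 0.4, design = NULL,
                                  seed = 8)
  dat <- cbind(des, response = sim$response)
  expect_message(
    fit_int <- fit_gamma_loglink(dat, "response",
                                 c("site", "month", "site:month"),
                                 blocking = "none"),
    "aliased")
  expect_true(fit_int$converged)
  expect_length(fit_int$dropped, 1)
  fit_main <- fit_gamma_loglink(dat, "response", c("site", "month"),
                                blocking = "none")
  expect_true(fit_main$converged)
  expect_length(fit_main$dropped, 0)
})

test_that("type-I error of the CI-excludes-zero rule is near nominal", {
  # no group effect: flag rate of the d-CI rule ~5% over 500 replicates
  flags <- vapply(1:500, function(s) {
    sim <- generate_gamma_responses(
      60, c(0.3, 0), 0.5, design = data.frame(g = rep(c("a", "b"), 30)),
      seed = 5000 + s)
    fit <- fit_gamma_loglink(sim, "response", "g", blocking = "none")
    cmp <- pairwise_comparisons(estimated_marginal_means(fit, "g"), fit)
    cmp$flagged
  }, logical(1))
  rate <- mean(flags)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, 0.05 - ci - 0.01)
  expect_lte(rate, 0.05 + ci + 0.01)
})
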