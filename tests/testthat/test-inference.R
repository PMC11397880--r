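test_that("Gauss-Hermite rule integrates polynomials against exp(-z^2) exactly", {
  gh <- gauss_hermite(7)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes), 0, tolerance = 1e-12)
})

test_that("marginal likelihood matches brute-force integration and the sigma = 0 limit", {
  set.seed(42)
  d <- data.frame(flight_id = rep(sprintf("f%d", 1:5), each = 6),
                  x = sample(c("a", "b"), 30, TRUE),
                  count = rpois(30, 2.5))
  X <- cbind(1, as.numeric(d$x == "b"))
  beta <- c(0.7, -0.4); sigma <- 0.6
  eta <- drop(X %*% beta)
  brute <- sum(sapply(1:5, function(i) {
    idx <- which(d$flight_id == sprintf("f%d", i))
    f <- Vectorize(function(b)
      prod(dpois(d$count[idx], exp(eta[idx] + b))) * dnorm(b, 0, sigma))
    log(integrate(f, -10, 10, rel.tol = 1e-12)$value)
  }))
  expect_equal(marginal_loglik(beta, sigma, d, predictors = "x", n_quad = 25),
               brute, tolerance = 1e-9)

  # forcing sigma = 0 reproduces the independent-Poisson log-likelihood exactly
  orc <- poisson_newton_oracle(X, d$count)
  expect_equal(marginal_loglik(orc$beta, 0, d, predictors = "x"),
               orc$loglik, tolerance = 1e-10)
})

test_that("fit recovers a fixed-effects model when the data have no group variation", {
  # simulate with sigma = 0; the mixed fit must agree with an independent
  # Newton solution of the plain Poisson regression within 3 SE
  sim <- generate_counts(sim_config(n_sites = 5, flights_per_site = 8,
                                    sigma_flight = 0, seed = 101))
  fit <- fit_poisson_glmm(sim$counts)
  X <- design_matrix(sim$counts, c("speed_m_s", "height_m", "angle_deg"))
  orc <- poisson_newton_oracle(X, sim$counts$count)
  expect_true(all(abs(fit$beta - orc$beta) < 3 * orc$se))
  expect_lt(fit$sigma, 0.1)
  expect_true(fit$converged)
  # with sigma estimated near 0 the marginal loglik approaches the Poisson one
  expect_equal(fit$loglik, orc$loglik, tolerance = 1e-2)
})

test_that("fit agrees with the study's mixed-model machinery on a simulated survey", {
  skip_if_not_installed("lme4")
  sim <- generate_counts(sim_config(seed = 11))
  fit <- fit_poisson_glmm(sim$counts)
  d <- sim$counts
  d$speed <- factor(as.character(d$speed_m_s))
  d$height <- factor(as.character(d$height_m))
  d$angle <- factor(as.character(d$angle_deg))
  ref <- lme4::glmer(count ~ speed + height + angle + (1 | flight_id),
                     data = d, family = poisson, nAGQ = 25)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-4)
  expect_equal(fit$sigma, sqrt(unlist(lme4::VarCorr(ref))[[1]]),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("quadrature is converged at the default node count", {
  sim <- generate_counts(sim_config(seed = 55))
  fit <- fit_poisson_glmm(sim$counts, n_quad = 25, compute_se = FALSE)
  ll15 <- marginal_loglik(fit$beta, fit$sigma, sim$counts, n_quad = 15)
  ll25 <- marginal_loglik(fit$beta, fit$sigma, sim$counts, n_quad = 25)
  expect_equal(ll15, ll25, tolerance = 1e-6)
  expect_equal(fit$n_quad, 25)
})

test_that("degenerate inputs give boundary fits, not exceptions", {
  # single group: intercept profile, sigma driven to the boundary
  sim <- generate_counts(sim_config(n_sites = 1, flights_per_site = 1, seed = 9))
  fit1 <- fit_poisson_glmm(sim$counts, predictors = character(0),
                           compute_se = FALSE)
  expect_equal(fit1$n_groups, 1)
  expect_equal(fit1$sigma, 0)
  expect_equal(unname(fit1$beta[1]), log(mean(sim$counts$count)), tolerance = 1e-5)

  # all-zero response: boundary fit reported
  zero <- sim$counts
  zero$count <- 0L
  fit0 <- fit_poisson_glmm(zero, predictors = character(0), compute_se = FALSE)
  expect_true(is.finite(fit0$loglik))
  # the likelihood supremum for an all-zero response is 0, reached at the
  # parameter boundary; the reported boundary fit comes arbitrarily close
  expect_equal(fit0$loglik, 0, tolerance = 1e-2)
  expect_lt(unname(fit0$beta[1]), -5)

  expect_error(fit_poisson_glmm(transform(sim$counts, count = count - 0.5)),
               "non-negative integers")
})

test_that("likelihood-ratio test maps to the chi-squared tail and checks nesting", {
  sim <- generate_counts(sim_config(n_sites = 2, flights_per_site = 4, seed = 77))
  full <- fit_poisson_glmm(sim$counts, compute_se = FALSE)
  null <- fit_poisson_glmm(sim$counts, predictors = character(0),
                           compute_se = FALSE)
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$df, 4)  # speed 2 + height 1 + angle 1
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 4, lower.tail = FALSE), tolerance = 1e-12)

  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  other <- generate_counts(sim_config(n_sites = 2, flights_per_site = 4, seed = 78))
  null_other <- fit_poisson_glmm(other$counts, predictors = character(0),
                                 compute_se = FALSE)
  expect_error(likelihood_ratio_test(full, null_other), "different data")
})

test_that("LRT statistic is invariant to factor relabelling and reference choice", {
  sim <- generate_counts(sim_config(n_sites = 3, flights_per_site = 4, seed = 31))
  d1 <- sim$counts
  full1 <- fit_poisson_glmm(d1, compute_se = FALSE)
  null1 <- fit_poisson_glmm(d1, predictors = character(0), compute_se = FALSE)
  s1 <- likelihood_ratio_test(full1, null1)$statistic

  # relabel levels so a different level sorts first (new reference)
  d2 <- d1
  d2$speed_m_s <- c("2" = "zz_slow", "4" = "mid", "6" = "aa_fast")[as.character(d1$speed_m_s)]
  d2$angle_deg <- c("-45" = "oblique", "-90" = "nadir")[as.character(d1$angle_deg)]
  full2 <- fit_poisson_glmm(d2, compute_se = FALSE)
  null2 <- fit_poisson_glmm(d2, predictors = character(0), compute_se = FALSE)
  s2 <- likelihood_ratio_test(full2, null2)$statistic
  expect_equal(s1, s2, tolerance = 1e-5)
  expect_equal(full1$loglik, full2$loglik, tolerance = 1e-6)
})

test_that("reduced-dataset filter keeps whole flights with any detection", {
  d <- expand_design(1, 3, c(40, 50), c(-45, -90), c(2, 4, 6), seed = 1)
  d$count <- 0L
  d$count[d$flight_id == "F001"][5] <- 2L
  d$count[d$flight_id == "F003"] <- 1L
  out <- reduced_dataset_filter(d)
  expect_equal(nrow(out), 24)
  expect_equal(sort(unique(out$flight_id)), c("F001", "F003"))
  # brute-force oracle: a flight survives iff max(count) >= 1
  keep <- unlist(lapply(split(d, d$flight_id), function(fl) rep(max(fl$count) >= 1, nrow(fl))))
  expect_equal(nrow(out), sum(keep))

  d$count <- 0L
  expect_equal(nrow(reduced_dataset_filter(d)), 0)
})

test_that("Cramer's V matches hand-computed tables and the balanced design", {
  x <- rep(c("a", "b"), each = 10)
  expect_equal(cramers_v(x, x), 1)
  # [[10,0],[0,10]] -> chi2 = n -> V = 1; [[5,5],[5,5]] -> 0
  y_indep <- rep(c("u", "v"), 10)
  expect_equal(cramers_v(x, y_indep), 0, tolerance = 1e-12)

  d <- expand_design(5, 8, c(40, 50), c(-45, -90), c(2, 4, 6), seed = 2)
  expect_lt(cramers_v(d$speed_m_s, d$height_m), 0.01)
  expect_lt(cramers_v(d$speed_m_s, d$angle_deg), 0.01)
  expect_lt(cramers_v(d$height_m, d$angle_deg), 0.01)
  expect_error(cramers_v(rep("a", 10), rep(c("u", "v"), 5)), "two observed levels")
})

test_that("dispersion statistic is near 1 when the model is right and above it when not", {
  sim <- generate_counts(sim_config(n_sites = 20, flights_per_site = 10, seed = 61))
  fit <- fit_poisson_glmm(sim$counts, compute_se = FALSE)
  disp <- dispersion_statistic(fit, sim$counts)
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)

  # negative-binomial counts at the same mean are overdispersed
  over <- sim$counts
  set.seed(62)
  over$count <- rnbinom(nrow(over), mu = pmax(exp(1) * exp(fit$ranef[over$flight_id]), 0.1),
                        size = 1.2)
  fit_o <- fit_poisson_glmm(over, compute_se = FALSE)
  expect_gt(dispersion_statistic(fit_o, over), 1.2)

  # all counts equal to fitted means would give 0 (degenerate direct check)
  exact <- sim$counts
  exact$count <- 2L
  fit_e <- fit_poisson_glmm(exact, predictors = character(0), compute_se = FALSE)
  expect_lt(dispersion_statistic(fit_e, exact), 0.05)
})

test_that("estimator bias shrinks as the number of flights grows", {
  sizes <- list(c(sites = 2, fps = 10, reps = 60),   # 20 flights
                c(sites = 6, fps = 10, reps = 30),   # 60 flights
                c(sites = 20, fps = 10, reps = 15))  # 200 flights
  stats <- lapply(seq_along(sizes), function(k) {
    z <- sizes[[k]]
    est <- vapply(seq_len(z["reps"]), function(r) {
      sim <- generate_counts(sim_config(n_sites = z["sites"], flights_per_site = z["fps"],
                                        beta0 = 1, seed = 5000 + 100 * k + r))
      f <- fit_poisson_glmm(sim$counts, compute_se = FALSE, n_restarts = 0)
      c(f$sigma, unname(f$beta[1]))
    }, numeric(2))
    c(sigma_rmse = sqrt(mean((est[1, ] - 0.5)^2)),
      beta0_rmse = sqrt(mean((est[2, ] - 1)^2)),
      sigma_bias = mean(est[1, ]) - 0.5)
  })
  sigma_rmse <- vapply(stats, `[[`, 0, "sigma_rmse")
  beta0_rmse <- vapply(stats, `[[`, 0, "beta0_rmse")
  expect_true(all(diff(sigma_rmse) < 0))
  expect_true(all(diff(beta0_rmse) < 0))
  # at the largest size the sigma bias is small in absolute terms
  expect_lt(abs(stats[[3]]["sigma_bias"]), 0.03)
})
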