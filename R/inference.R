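#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-z^2} f(z) dz \approx \sum_k w_k f(z_k)}
#' (physicists' convention), computed by the Golub-Welsch eigen-decomposition
#' of the Jacobi matrix.
#'
#' @param n number of nodes.
#' @return a list with `nodes` and `weights`, each of length `n`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1, n == round(n))
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# conditional modes of the random intercept given (s_i, A_i, sigma):
# solves s - A e^b - b/sigma^2 = 0 per group by damped Newton (g is strictly
# concave so the root is unique). Vectorised over groups.
.agq_modes <- function(s, A, sigma) {
  inv_s2 <- 1 / sigma^2
  b <- rep(0, length(s))
  for (it in 1:100) {
    eb <- A * exp(b)
    f <- s - eb - b * inv_s2
    step <- f / (eb + inv_s2)
    step <- pmin(pmax(step, -2), 2)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  b
}

# marginal log-likelihood of the Poisson random-intercept model via adaptive
# Gauss-Hermite quadrature. With a log link the group integral depends on the
# data only through s_i = sum_j y_ij and A_i = sum_j exp(eta_ij), so the whole
# evaluation is a handful of vectorised operations. sigma = 0 short-circuits
# to the exact independent-Poisson log-likelihood.
.agq_loglik <- function(beta, sigma, y, X, gidx, gh) {
  eta <- drop(X %*% beta)
  const <- sum(y * eta) - sum(lgamma(y + 1))
  A <- drop(rowsum(exp(eta), gidx))
  if (sigma == 0) return(const - sum(A))
  s <- drop(rowsum(y, gidx))
  G <- length(s)
  bhat <- .agq_modes(s, A, sigma)
  tau <- 1 / sqrt(A * exp(bhat) + 1 / sigma^2)
  z <- gh$nodes
  lw <- log(gh$weights)
  # G x K matrix of integrand log-values at the shifted, scaled nodes
  B <- bhat + sqrt(2) * tau %o% z
  g <- s * B - A * exp(B) - B^2 / (2 * sigma^2)
  g0 <- s * bhat - A * exp(bhat) - bhat^2 / (2 * sigma^2)
  M <- sweep(g - g0, 2, lw + z^2, "+")
  rowmax <- apply(M, 1, max)
  log_int <- log(sqrt(2) * tau) + g0 + rowmax + log(rowSums(exp(M - rowmax)))
  const + sum(log_int) - G * log(sigma * sqrt(2 * pi))
}

#' Reference-coded design matrix for the count models
#'
#' Builds the model matrix used by [fit_poisson_glmm()]: every predictor is
#' treated as categorical with levels ordered by their character
#' representation, so the reference level is the lowest speed, the lowest
#' height and the -45 gimbal angle for the study factors.
#'
#' @param data a data.frame.
#' @param predictors names of the predictor columns.
#' @return the model matrix (intercept first).
#' @export
design_matrix <- function(data, predictors) {
  fac <- lapply(data[predictors], function(v) {
    lev <- sort(unique(as.character(v)))
    if (length(lev) < 2)
      stop("predictor with a single observed level; drop it from `predictors`")
    factor(as.character(v), levels = lev)
  })
  stats::model.matrix(~ ., data = as.data.frame(fac, stringsAsFactors = FALSE))
}

.data_fingerprint <- function(y, gidx) {
  sprintf("%d:%d:%.0f:%.0f", length(y), length(unique(gidx)), sum(y),
          sum(as.double(y) * seq_along(y)) %% 1e9)
}

#' Fit a Poisson random-intercept model by adaptive Gauss-Hermite quadrature
#'
#' Maximum-likelihood fit of the mixed Poisson regression
#' \deqn{y_{ij} \sim \mathrm{Poisson}(\exp(x_{ij}'\beta + b_i)), \quad
#'       b_i \sim N(0, \sigma^2),}
#' where `i` indexes groups (flights) and `j` the observations (videos)
#' within a group. The marginal likelihood integrates each group's random
#' intercept by Gauss-Hermite quadrature adaptively centred and scaled at the
#' group's conditional mode. The SD is optimised on the log scale and
#' reported on the natural scale; estimates at the boundary
#' (\eqn{\hat\sigma < 10^{-6}}) are reported as 0. Categorical predictors are
#' reference-coded with levels in sorted character order (so the reference is
#' the lowest speed, the lowest height, and the -45 gimbal angle for the
#' study factors).
#'
#' @param data a data.frame of per-video counts (e.g. the `counts` element of
#'   [generate_counts()]).
#' @param predictors names of categorical predictor columns.
#' @param group name of the grouping column for the random intercept.
#' @param response name of the count column.
#' @param n_quad number of quadrature nodes.
#' @param n_restarts deterministic perturbed restarts after the GLM-based
#'   start; the best optimum is kept.
#' @param compute_se compute standard errors from the numerical Hessian.
#' @return an object of class `tir_glmm`: `beta` (named fixed effects),
#'   `sigma`, `loglik`, `n_quad`, `converged`, `n_obs`, `n_groups`, `se`,
#'   `ranef` (empirical-Bayes modes), and bookkeeping fields.
#' @examples
#' sim <- generate_counts(sim_config(n_sites = 2, flights_per_site = 3, seed = 7))
#' fit <- fit_poisson_glmm(sim$counts)
#' fit$sigma
#' @export
fit_poisson_glmm <- function(data,
                             predictors = c("speed_m_s", "height_m", "angle_deg"),
                             group = "flight_id", response = "count",
                             n_quad = 25, n_restarts = 2, compute_se = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data), group %in% names(data),
            all(predictors %in% names(data)))
  y <- data[[response]]
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  X <- if (length(predictors)) design_matrix(data, predictors)
       else matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  gfac <- factor(data[[group]])
  gidx <- as.integer(gfac)
  G <- nlevels(gfac)
  p <- ncol(X)
  gh <- gauss_hermite(n_quad)

  negll <- function(par) {
    ll <- .agq_loglik(par[1:p], exp(par[p + 1]), y, X, gidx, gh)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # GLM start for beta; moment-style start for sigma
  beta0 <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson())$coefficients),
    error = function(e) c(log(mean(y) + 1e-8), rep(0, p - 1)))
  beta0[!is.finite(beta0)] <- 0
  starts <- list(c(beta0, log(0.3)))
  for (r in seq_len(n_restarts))
    starts[[r + 1]] <- c(beta0 + 0.3 * (-1)^r * (seq_len(p) %% 2 * 2 - 1),
                         log(0.3) + 0.8 * (-1)^r)

  lower <- c(rep(-30, p), log(1e-8))
  upper <- c(rep(30, p), log(30))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, negll, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective - 1e-9) best <- opt
  }
  if (is.null(best)) stop("optimiser failed on all starts")

  beta <- setNames(best$par[1:p], colnames(X))
  sigma <- exp(best$par[p + 1])
  loglik <- .agq_loglik(beta, sigma, y, X, gidx, gh)
  # boundary: if the sigma = 0 likelihood is not worse, report the boundary fit
  ll0 <- .agq_loglik(beta, 0, y, X, gidx, gh)
  if (sigma < 1e-6 || ll0 >= loglik - 1e-7) {
    sigma <- 0
    loglik <- ll0
  }
  converged <- best$convergence == 0 && is.finite(loglik)

  # empirical-Bayes modes at the optimum
  eta <- drop(X %*% beta)
  A <- drop(rowsum(exp(eta), gidx))
  s <- drop(rowsum(y, gidx))
  ranef <- if (sigma > 0) setNames(.agq_modes(s, A, sigma), levels(gfac))
           else setNames(rep(0, G), levels(gfac))

  se <- vcov <- NULL
  if (compute_se) {
    H <- tryCatch(.num_hessian(negll, best$par), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(diag(vc)[1:p] > 0)) {
        vcov <- vc[1:p, 1:p, drop = FALSE]
        dimnames(vcov) <- list(names(beta), names(beta))
        se <- setNames(sqrt(diag(vcov)), names(beta))
      }
    }
  }

  structure(
    list(beta = beta, sigma = sigma, loglik = loglik, n_quad = n_quad,
         converged = converged, n_obs = length(y), n_groups = G,
         se = se, vcov = vcov, ranef = ranef,
         predictors = predictors, group = group, response = response,
         fingerprint = .data_fingerprint(y, gidx),
         diagnostics = list(objective = best$objective,
                            nlminb_convergence = best$convergence,
                            message = best$message)),
    class = "tir_glmm")
}

# central-difference Hessian; parameters are few so cost is negligible
.num_hessian <- function(f, par, h = 1e-4) {
  p <- length(par)
  H <- matrix(0, p, p)
  f0 <- f(par)
  for (i in 1:p) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(par + ei + ej) - f(par + ei - ej) - f(par - ei + ej) + f(par - ei - ej)) /
      (4 * h * h)
  }
  H
}

#' @export
print.tir_glmm <- function(x, ...) {
  cat("Poisson random-intercept model (adaptive Gauss-Hermite, ",
      x$n_quad, " nodes)\n", sep = "")
  cat(sprintf("  %d observations in %d groups; logLik = %.4f; sigma = %.4f%s\n",
              x$n_obs, x$n_groups, x$loglik, x$sigma,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- cbind(Estimate = x$beta)
  if (!is.null(x$se)) est <- cbind(est, `Std. Error` = x$se)
  print(round(est, 4))
  invisible(x)
}

#' Marginal log-likelihood at given parameter values
#'
#' Evaluates the quadrature approximation of the marginal log-likelihood of
#' the Poisson random-intercept model at user-supplied parameters; with
#' `sigma = 0` the exact independent-Poisson log-likelihood is returned.
#'
#' @param beta fixed-effect vector, aligned to the reference-coded design
#'   matrix of `predictors` (intercept first).
#' @param sigma random-intercept SD (0 for the fixed-effects limit).
#' @inheritParams fit_poisson_glmm
#' @return the log-likelihood value.
#' @export
marginal_loglik <- function(beta, sigma, data,
                            predictors = c("speed_m_s", "height_m", "angle_deg"),
                            group = "flight_id", response = "count",
                            n_quad = 25) {
  y <- data[[response]]
  X <- if (length(predictors)) design_matrix(data, predictors)
       else matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  stopifnot(length(beta) == ncol(X), sigma >= 0)
  .agq_loglik(beta, sigma, y, X, as.integer(factor(data[[group]])),
              gauss_hermite(n_quad))
}

#' Likelihood-ratio test of nested random-intercept models
#'
#' Twice the log-likelihood difference, clipped at zero, referred to the
#' chi-squared distribution with degrees of freedom equal to the difference
#' in fixed-effect parameter count. Both fits must come from the same data
#' (checked by a data fingerprint).
#'
#' @param full,null fitted [fit_poisson_glmm()] models, `null` nested in
#'   `full`.
#' @return an object of class `tir_lrt` with `statistic`, `df`, `p_value`.
#' @examples
#' pchisq(2.46, df = 4, lower.tail = FALSE)  # the tail map used
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "tir_glmm"), inherits(null, "tir_glmm"))
  if (!all(names(null$beta) %in% names(full$beta)))
    stop("null model fixed effects are not a subset of the full model's")
  if (full$fingerprint != null$fingerprint)
    stop("models were fitted to different data")
  stat <- max(0, 2 * (full$loglik - null$loglik))
  df <- length(full$beta) - length(null$beta)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p), class = "tir_lrt")
}

#' @export
print.tir_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi-squared = %.3f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Reduced-dataset filter
#'
#' Keeps every video of each flight in which at least one video recorded a
#' detection; drops whole flights whose videos are all zero. This removes
#' flights where no animals were present at the sleeping site, which carry
#' no information about detectability differences between flight parameters.
#'
#' @param data a per-video count table.
#' @param group name of the flight-id column.
#' @param response name of the count column.
#' @return the filtered data.frame.
#' @export
reduced_dataset_filter <- function(data, group = "flight_id", response = "count") {
  stopifnot(group %in% names(data), response %in% names(data))
  keep <- stats::ave(data[[response]], data[[group]], FUN = max) >= 1
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cramer's V association between two categorical variables
#'
#' \eqn{V = \sqrt{\chi^2 / (n \min(r-1, c-1))}} from the Pearson chi-squared
#' statistic of the contingency table (no continuity correction). Used to
#' screen design factors for collinearity before model fitting; a fully
#' balanced factorial design gives exactly 0.
#'
#' @param x,y equal-length categorical vectors with at least two levels each.
#' @return a value in `[0, 1]`.
#' @export
cramers_v <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("both variables need at least two observed levels")
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * min(nrow(tab) - 1, ncol(tab) - 1)))
  unname(min(max(v, 0), 1))
}

#' Pearson dispersion statistic of a fitted model
#'
#' Sum of squared Pearson residuals, conditional on the empirical-Bayes
#' modes of the random intercepts, divided by the residual degrees of
#' freedom. The residual df subtract the fixed-effect count, one for the
#' variance parameter, and the effective degrees of freedom absorbed by the
#' shrunken random intercepts (the per-group shrinkage weight
#' \eqn{h_i = \lambda_i / (\lambda_i + 1/\sigma^2)} with \eqn{\lambda_i} the
#' group's fitted total mean, each between 0 and 1). Approximately 1 under a
#' well-specified Poisson model; values well above 1 indicate
#' overdispersion.
#'
#' @param fit a converged [fit_poisson_glmm()].
#' @param data the data the model was fitted to.
#' @return the dispersion statistic.
#' @export
dispersion_statistic <- function(fit, data) {
  stopifnot(inherits(fit, "tir_glmm"))
  if (!fit$converged) stop("dispersion statistic requires a converged fit")
  y <- data[[fit$response]]
  X <- if (length(fit$predictors)) design_matrix(data, fit$predictors)
       else matrix(1, nrow(data), 1)
  gfac <- factor(data[[fit$group]])
  if (.data_fingerprint(y, as.integer(gfac)) != fit$fingerprint)
    stop("data does not match the fitted model")
  mu <- exp(drop(X %*% fit$beta) + fit$ranef[as.character(gfac)])
  lambda <- drop(rowsum(mu, as.integer(gfac)))
  h <- if (fit$sigma > 0) lambda / (lambda + 1 / fit$sigma^2) else 0
  df_resid <- fit$n_obs - (length(fit$beta) + 1) - sum(h)
  sum((y - mu)^2 / mu) / df_resid
}
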