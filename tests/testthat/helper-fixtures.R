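# shared fixtures and independent oracles

study_camera <- function() camera_model(640, 512, focal_length_mm = 9,
                                        pixel_pitch_um = 12, frame_rate_fps = 30)

small_design <- function(seed = 1) {
  expand_design(2, 3, c(40, 50), c(-45, -90), c(2, 4, 6), seed = seed)
}

# independent brute-force evaluation of the multi-rater kappa formula,
# written directly from its definition (loops, no shared code path)
fleiss_kappa_oracle <- function(ratings) {
  ratings <- as.matrix(ratings)
  N <- nrow(ratings); n <- ncol(ratings)
  cats <- sort(unique(as.vector(ratings)))
  P_i <- numeric(N)
  nij <- matrix(0, N, length(cats))
  for (i in 1:N) for (j in seq_along(cats))
    nij[i, j] <- sum(ratings[i, ] == cats[j])
  for (i in 1:N) {
    acc <- 0
    for (j in seq_along(cats)) acc <- acc + nij[i, j]^2
    P_i[i] <- (acc - n) / (n * (n - 1))
  }
  p_j <- numeric(length(cats))
  for (j in seq_along(cats)) p_j[j] <- sum(nij[, j]) / (N * n)
  Pe <- sum(p_j^2)
  (mean(P_i) - Pe) / (1 - Pe)
}

# independent plain Poisson regression by direct Newton iteration on the
# score equations (oracle for the sigma = 0 limit of the mixed model)
poisson_newton_oracle <- function(X, y, tol = 1e-10) {
  beta <- c(log(mean(y) + 1e-8), rep(0, ncol(X) - 1))
  for (it in 1:100) {
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(info))),
       loglik = sum(y * drop(X %*% beta)) - sum(exp(drop(X %*% beta))) -
         sum(lgamma(y + 1)))
}
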