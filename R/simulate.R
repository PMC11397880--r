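#' Configuration of the synthetic survey generator
#'
#' Defines the study conditions the generator emulates: a factorial flight
#' design over sleeping sites, Poisson counts with a per-flight random
#' intercept on the log mean, and a multi-coder observation model whose
#' error rates depend on the thermal-contrast zone of each video.
#'
#' Defaults reproduce a survey of 5 sleeping sites with 8 flights each and
#' 12 videos per flight (2 heights x 2 camera angles x 3 speeds), a baseline
#' of 2.7 animals per video, no flight-parameter effects (a null design), a
#' flight random-intercept SD of 0.5, and three coders who detect animals
#' more reliably in high thermal-contrast (forest-only) zones than in low
#' contrast zones near heat-retaining structures.
#'
#' @param n_sites,flights_per_site design size.
#' @param heights,angles,speeds factor levels (heights in m a.g.l., angles in
#'   signed gimbal degrees, speeds in m/s).
#' @param beta0 log baseline expected count per video.
#' @param beta_speed,beta_height,beta_angle reference-coded fixed effects on
#'   the log mean; lengths `length(levels) - 1`, levels ordered by their
#'   character representation. Defaults all zero.
#' @param sigma_flight SD of the per-flight normal random intercept.
#' @param mode `"glmm"` draws counts directly from the mixed Poisson model;
#'   `"mechanistic"` draws a latent subgroup size per flight and thins each
#'   animal with a logistic detection probability on the same linear
#'   predictor.
#' @param subgroup_mean mean latent subgroup size (mechanistic mode).
#' @param p_detect_high,p_detect_low per-animal coder detection probability
#'   by contrast zone.
#' @param fp_rate_high,fp_rate_low expected coder false positives per video
#'   by contrast zone.
#' @param n_coders number of coders rating each video.
#' @param zone_mix probability a video falls in a high-contrast zone.
#' @param seed integer master seed; the stream is split per flight and per
#'   video so enlarging the design does not perturb earlier draws.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 5, flights_per_site = 8,
                       heights = c(40, 50), angles = c(-45, -90),
                       speeds = c(2, 4, 6),
                       beta0 = log(2.7),
                       beta_speed = numeric(length(speeds) - 1),
                       beta_height = numeric(length(heights) - 1),
                       beta_angle = numeric(length(angles) - 1),
                       sigma_flight = 0.5,
                       mode = c("glmm", "mechanistic"),
                       subgroup_mean = 2.7,
                       p_detect_high = 0.95, p_detect_low = 0.75,
                       fp_rate_high = 0.02, fp_rate_low = 0.10,
                       n_coders = 3, zone_mix = 0.7, seed = 1L) {
  mode <- match.arg(mode)
  probs <- c(p_detect_high, p_detect_low, zone_mix)
  stopifnot(
    n_sites >= 1, flights_per_site >= 1,
    length(heights) >= 1, length(angles) >= 1, length(speeds) >= 1,
    length(beta_speed) == length(speeds) - 1,
    length(beta_height) == length(heights) - 1,
    length(beta_angle) == length(angles) - 1,
    sigma_flight >= 0, subgroup_mean > 0,
    all(probs >= 0), all(probs <= 1),
    fp_rate_high >= 0, fp_rate_low >= 0, n_coders >= 1
  )
  structure(
    list(n_sites = n_sites, flights_per_site = flights_per_site,
         heights = heights, angles = angles, speeds = speeds,
         beta0 = beta0, beta_speed = beta_speed, beta_height = beta_height,
         beta_angle = beta_angle, sigma_flight = sigma_flight, mode = mode,
         subgroup_mean = subgroup_mean,
         p_detect_high = p_detect_high, p_detect_low = p_detect_low,
         fp_rate_high = fp_rate_high, fp_rate_low = fp_rate_low,
         n_coders = n_coders, zone_mix = zone_mix, seed = as.integer(seed)),
    class = "sim_config")
}

# deterministic per-unit substream seed, kept below 2^31
.split_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 +
                as.double(salt) * 69621) %% 2147483647)
}

# linear predictor of the fixed effects for one video, reference coding with
# levels ordered by character representation (matches design_matrix())
.sim_eta <- function(config, speed, height, angle) {
  contr <- function(value, levels, beta) {
    lev <- sort(as.character(levels))
    i <- match(as.character(value), lev)
    if (i == 1L) 0 else beta[i - 1L]
  }
  config$beta0 +
    contr(speed, config$speeds, config$beta_speed) +
    contr(height, config$heights, config$beta_height) +
    contr(angle, config$angles, config$beta_angle)
}

#' Generate synthetic per-video counts
#'
#' Realises the count model the downstream analysis assumes. In `"glmm"`
#' mode each flight i receives a random intercept `b_i ~ N(0, sigma^2)` and
#' each of its videos an independent count
#' `y ~ Poisson(exp(beta0 + x'beta + b_i))`. In `"mechanistic"` mode a latent
#' subgroup of `S_i ~ Poisson(subgroup_mean)` animals is present at the
#' flight's sleeping site and each animal is detected independently with a
#' logistic probability on the same linear predictor (plus `b_i`).
#'
#' @param config a [sim_config()].
#' @return a list with `counts` (a data.frame with columns `video_id`,
#'   `flight_id`, `site_id`, `height_m`, `angle_deg`, `speed_m_s`, `count`)
#'   and `truth` (the generating parameters, including the realised random
#'   intercepts).
#' @examples
#' sim <- generate_counts(sim_config(seed = 42))
#' mean(sim$counts$count)
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- expand_design(config$n_sites, config$flights_per_site,
                          config$heights, config$angles, config$speeds,
                          base_speed = min(config$speeds), seed = config$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  flights <- unique(design$flight_id)
  design$count <- NA_integer_
  b <- setNames(numeric(length(flights)), flights)
  S <- setNames(rep(NA_integer_, length(flights)), flights)
  for (fi in seq_along(flights)) {
    set.seed(.split_seed(config$seed, fi, salt = 1L))
    b[fi] <- rnorm(1, 0, config$sigma_flight)
    if (config$mode == "mechanistic") S[fi] <- rpois(1, config$subgroup_mean)
    rows <- which(design$flight_id == flights[fi])
    for (r in rows) {
      eta <- .sim_eta(config, design$speed_m_s[r], design$height_m[r],
                      design$angle_deg[r])
      design$count[r] <- if (config$mode == "glmm") {
        rpois(1, exp(eta + b[fi]))
      } else {
        rbinom(1, S[fi], stats::plogis(eta + b[fi]))
      }
    }
  }
  counts <- design[, c("video_id", "flight_id", "site_id", "height_m",
                       "angle_deg", "speed_m_s", "count")]
  truth <- list(beta0 = config$beta0, beta_speed = config$beta_speed,
                beta_height = config$beta_height, beta_angle = config$beta_angle,
                sigma_flight = config$sigma_flight, mode = config$mode,
                subgroup_mean = if (config$mode == "mechanistic") config$subgroup_mean else NULL,
                random_intercepts = b,
                subgroup_sizes = if (config$mode == "mechanistic") S else NULL,
                seed = config$seed)
  list(counts = counts, truth = truth)
}

#' Generate synthetic multi-coder ratings
#'
#' Each video is assigned one thermal-contrast zone (high with probability
#' `zone_mix`). Each coder's count is a binomial thinning of the true count
#' at the zone's detection probability plus Poisson false positives at the
#' zone's false-positive rate; false positives can push a coder's count
#' above the truth.
#'
#' @param counts the `counts` data.frame from [generate_counts()] (or any
#'   table with `video_id` and `count` columns).
#' @param config a [sim_config()] with `n_coders >= 2`.
#' @return a data.frame with columns `video_id`, `coder_id`, `zone`
#'   (`"high"`/`"low"`) and `count`, one row per video x coder.
#' @export
generate_coder_ratings <- function(counts, config) {
  stopifnot(inherits(config, "sim_config"), config$n_coders >= 2,
            all(c("video_id", "count") %in% names(counts)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  n <- nrow(counts)
  zone <- character(n)
  rated <- vector("list", n)
  for (v in seq_len(n)) {
    set.seed(.split_seed(config$seed, v, salt = 2L))
    zone[v] <- if (runif(1) < config$zone_mix) "high" else "low"
    p <- if (zone[v] == "high") config$p_detect_high else config$p_detect_low
    fp <- if (zone[v] == "high") config$fp_rate_high else config$fp_rate_low
    rated[[v]] <- rbinom(config$n_coders, counts$count[v], p) +
      rpois(config$n_coders, fp)
  }
  data.frame(
    video_id = rep(counts$video_id, each = config$n_coders),
    coder_id = rep(sprintf("C%02d", seq_len(config$n_coders)), n),
    zone = rep(zone, each = config$n_coders),
    count = unlist(rated),
    stringsAsFactors = FALSE)
}
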