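#' Expand a factorial flight design into video records
#'
#' Each flight over a site is recorded once at the base speed and then cut and
#' frame-subsampled into one video per height x angle x speed combination,
#' so a full design yields one record per flight and factor combination.
#' Every record carries a randomised blind code concealing its height and
#' angle from the coder; videos remain grouped by speed (coders know the
#' speed), so the code is drawn as a seeded random permutation within each
#' speed group.
#'
#' @param n_sites number of sleeping sites surveyed.
#' @param flights_per_site flights flown over each site.
#' @param heights flight heights a.g.l. in metres (factor levels).
#' @param angles camera gimbal angles in degrees (factor levels, signed
#'   gimbal notation, e.g. `c(-45, -90)`).
#' @param speeds flight speeds in m/s (factor levels).
#' @param base_speed the speed actually flown; must be one of `speeds`.
#' @param transect_length_m transect length used to derive video duration.
#' @param seed integer seed for the blind-code permutation.
#' @return a `data.frame` of video records with columns `video_id`,
#'   `flight_id`, `site_id`, `height_m`, `angle_deg`, `speed_m_s`,
#'   `duration_s`, `blind_code`.
#' @examples
#' d <- expand_design(5, 8, c(40, 50), c(-45, -90), c(2, 4, 6), seed = 1)
#' nrow(d)  # 480
#' @export
expand_design <- function(n_sites, flights_per_site, heights, angles, speeds,
                          base_speed = min(speeds), transect_length_m = 220,
                          seed = 1L) {
  stopifnot(n_sites >= 1, flights_per_site >= 1,
            length(heights) >= 1, length(angles) >= 1, length(speeds) >= 1)
  if (!base_speed %in% speeds)
    stop("base_speed must be one of the design speeds")
  sites <- sprintf("S%02d", seq_len(n_sites))
  flights <- expand.grid(flight_in_site = seq_len(flights_per_site),
                         site_id = sites, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  flights$flight_id <- sprintf("F%03d", seq_len(nrow(flights)))
  recs <- merge(
    flights,
    expand.grid(height_m = heights, angle_deg = angles, speed_m_s = speeds,
                KEEP.OUT.ATTRS = FALSE),
    by = NULL)
  recs <- recs[order(recs$flight_id, recs$height_m, recs$angle_deg, recs$speed_m_s), ]
  recs$video_id <- sprintf("V%04d", seq_len(nrow(recs)))
  recs$duration_s <- transect_length_m / recs$speed_m_s
  # blind codes: permute within speed groups so height/angle stay concealed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  recs$blind_code <- NA_character_
  for (sp in sort(unique(recs$speed_m_s))) {
    idx <- which(recs$speed_m_s == sp)
    recs$blind_code[idx] <- sprintf("B%g-%04d", sp, sample(length(idx)))
  }
  rownames(recs) <- NULL
  recs[, c("video_id", "flight_id", "site_id", "height_m", "angle_deg",
           "speed_m_s", "duration_s", "blind_code")]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Frame sequence of a video
#'
#' @param n_frames number of frames, or `frame_times_s` given directly.
#' @param fps nominal capture rate, frames per second.
#' @param frame_times_s optional explicit strictly increasing timestamps
#'   starting at 0.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(n_frames = NULL, fps = 30, frame_times_s = NULL) {
  stopifnot(is.numeric(fps), fps > 0)
  if (is.null(frame_times_s)) {
    stopifnot(is.numeric(n_frames), n_frames >= 1)
    frame_times_s <- (seq_len(n_frames) - 1) / fps
  }
  stopifnot(frame_times_s[1] == 0, !is.unsorted(frame_times_s, strictly = TRUE))
  structure(list(nominal_fps = fps, frame_times_s = frame_times_s),
            class = "frame_sequence")
}

#' Simulate a faster flight speed by frame subsampling
#'
#' Keeping every k-th frame of a video flown at the base speed and playing
#' the result back at the original frame rate reproduces the footage of a
#' flight k times faster. Frame 0 is always retained; the target speed must
#' be an integer multiple of the base speed (no temporal interpolation).
#'
#' @param frames a [frame_sequence()].
#' @param base_speed speed at which the footage was flown, m/s.
#' @param target_speed speed to simulate, m/s.
#' @return a [frame_sequence()] with every k-th frame
#'   (`k = target_speed/base_speed`) and nominal fps divided by k.
#' @export
simulate_speed <- function(frames, base_speed, target_speed) {
  stopifnot(inherits(frames, "frame_sequence"),
            is.numeric(base_speed), base_speed > 0,
            is.numeric(target_speed), target_speed > 0)
  k <- target_speed / base_speed
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("speed must be an integer multiple of the base speed")
  k <- as.integer(round(k))
  keep <- seq(1L, length(frames$frame_times_s), by = k)
  frame_sequence(fps = frames$nominal_fps / k,
                 frame_times_s = frames$frame_times_s[keep] -
                   frames$frame_times_s[keep][1])
}

#' Transect flight duration
#'
#' @param length_m transect length, metres.
#' @param speed_m_s ground speed, m/s.
#' @return duration in seconds.
#' @export
transect_duration <- function(length_m, speed_m_s) {
  stopifnot(is.numeric(length_m), all(length_m > 0),
            is.numeric(speed_m_s), all(speed_m_s > 0))
  length_m / speed_m_s
}

#' Apply a mask to an image frame
#'
#' Converts per-side mask fractions to integer pixel bounds. Each side's
#' masked pixel count is rounded half away from zero before differencing,
#' for bit-exact reproducibility.
#'
#' @param width_px,height_px frame dimensions in pixels.
#' @param mask a [mask_spec()].
#' @return a list with the viewport rectangle: `x0`, `x1`, `y0`, `y1`
#'   (1-based inclusive pixel bounds), `width_px`, `height_px`.
#' @examples
#' apply_mask(640, 512, mask_spec_for_height(55.2))
#' @export
apply_mask <- function(width_px, height_px, mask) {
  stopifnot(is.numeric(width_px), width_px >= 1, width_px == round(width_px),
            is.numeric(height_px), height_px >= 1, height_px == round(height_px),
            inherits(mask, "mask_spec"))
  rnd <- function(x) trunc(x + 0.5)  # round half away from zero (x >= 0 here)
  l <- rnd(mask$left_frac * width_px)
  r <- rnd(mask$right_frac * width_px)
  t <- rnd(mask$top_frac * height_px)
  b <- rnd(mask$bottom_frac * height_px)
  w <- width_px - l - r
  h <- height_px - t - b
  if (w < 1 || h < 1) stop("mask leaves an empty viewport")
  list(x0 = l + 1L, x1 = width_px - r, y0 = t + 1L, y1 = height_px - b,
       width_px = as.integer(w), height_px = as.integer(h))
}
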