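#' Camera model for a TIR drone survey
#'
#' Bundles the optical and sensor parameters from which all ground-projection
#' geometry derives. The horizontal and vertical angular fields of view are
#' derived from the sensor dimensions (pixel count times pixel pitch) and the
#' focal length when not supplied; if both specs and FOV values are given they
#' must agree to within 0.5 degrees.
#'
#' @param image_width_px,image_height_px sensor resolution in pixels.
#' @param focal_length_mm lens focal length in millimetres.
#' @param pixel_pitch_um detector pixel pitch in micrometres. Defaults to 12,
#'   a typical uncooled TIR microbolometer pitch.
#' @param hfov_deg,vfov_deg optional horizontal/vertical field of view in
#'   degrees; derived from the specs when `NULL`.
#' @param frame_rate_fps video capture rate in frames per second.
#'
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(640, 512, focal_length_mm = 9)
#' cam$vfov_deg
#' @export
camera_model <- function(image_width_px, image_height_px, focal_length_mm,
                         pixel_pitch_um = 12, hfov_deg = NULL, vfov_deg = NULL,
                         frame_rate_fps = 30) {
  stopifnot(
    is.numeric(image_width_px), length(image_width_px) == 1L, image_width_px > 0,
    image_width_px == round(image_width_px),
    is.numeric(image_height_px), length(image_height_px) == 1L, image_height_px > 0,
    image_height_px == round(image_height_px),
    is.numeric(focal_length_mm), focal_length_mm > 0,
    is.numeric(pixel_pitch_um), pixel_pitch_um > 0,
    is.numeric(frame_rate_fps), frame_rate_fps > 0
  )
  fov_from_specs <- function(n_px) {
    2 * atan(n_px * pixel_pitch_um * 1e-3 / (2 * focal_length_mm)) * 180 / pi
  }
  h_derived <- fov_from_specs(image_width_px)
  v_derived <- fov_from_specs(image_height_px)
  if (is.null(hfov_deg)) hfov_deg <- h_derived
  if (is.null(vfov_deg)) vfov_deg <- v_derived
  stopifnot(hfov_deg > 0, hfov_deg < 180, vfov_deg > 0, vfov_deg < 180)
  if (abs(hfov_deg - h_derived) > 0.5 || abs(vfov_deg - v_derived) > 0.5)
    stop("supplied FOV inconsistent with sensor specs by more than 0.5 degrees")
  structure(
    list(image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         focal_length_mm = focal_length_mm,
         pixel_pitch_um = pixel_pitch_um,
         hfov_deg = hfov_deg, vfov_deg = vfov_deg,
         frame_rate_fps = frame_rate_fps),
    class = "camera_model")
}

#' Flight configuration
#'
#' Camera tilt is stored as degrees from nadir (0 = camera pointing straight
#' down, the gimbal's -90 setting; 45 = the gimbal's -45 setting). Use
#' [tilt_from_gimbal()] to convert the signed gimbal notation.
#'
#' @param height_agl_m flight height above ground level, metres.
#' @param speed_m_s ground speed, metres per second.
#' @param tilt_from_nadir_deg camera tilt from nadir in `[0, 90)` degrees.
#' @param canopy_height_m canopy (detection surface) height above ground,
#'   metres; must be below the flight height.
#' @param transect_length_m straight-line transect length, metres.
#'
#' @return An object of class `flight_config`.
#' @export
flight_config <- function(height_agl_m, speed_m_s, tilt_from_nadir_deg,
                          canopy_height_m = 0, transect_length_m = 220) {
  stopifnot(
    is.numeric(height_agl_m), height_agl_m > 0,
    is.numeric(canopy_height_m), canopy_height_m >= 0,
    is.numeric(speed_m_s), speed_m_s > 0,
    is.numeric(tilt_from_nadir_deg), tilt_from_nadir_deg >= 0, tilt_from_nadir_deg < 90,
    is.numeric(transect_length_m), transect_length_m > 0
  )
  if (height_agl_m - canopy_height_m <= 0)
    stop("flight height must exceed canopy height")
  structure(
    list(height_agl_m = height_agl_m, canopy_height_m = canopy_height_m,
         speed_m_s = speed_m_s, tilt_from_nadir_deg = tilt_from_nadir_deg,
         transect_length_m = transect_length_m),
    class = "flight_config")
}

#' Convert a signed gimbal angle to tilt from nadir
#'
#' A gimbal angle of -90 (straight down) maps to 0 tilt; -45 maps to 45.
#'
#' @param gimbal_deg signed gimbal angle in degrees, in `[-90, 0)`.
#' @return tilt from nadir in degrees.
#' @export
tilt_from_gimbal <- function(gimbal_deg) {
  stopifnot(is.numeric(gimbal_deg), all(gimbal_deg >= -90), all(gimbal_deg < 0))
  90 + gimbal_deg
}

deg2rad <- function(x) x * pi / 180

#' Ratio of projected ground distance to the nadir swath
#'
#' For a camera line of sight making angle `chi` with the vertical, the
#' ground distance subtended scales as `1/cos(chi)` relative to nadir.
#' The convenience form with `tilt_deg` and `fov_deg` evaluates the ratio at
#' the near edge of the footprint, `chi = tilt - fov/2`.
#'
#' @param chi_deg line-of-sight angle from vertical, degrees in `[0, 90)`.
#' @param tilt_deg,fov_deg alternative parameterisation: camera tilt from
#'   nadir and angular field of view (the near-edge angle is `tilt - fov/2`).
#' @return the positive projection ratio.
#' @examples
#' projected_distance_ratio(chi_deg = 45)    # sqrt(2)
#' projected_distance_ratio(tilt_deg = 45, fov_deg = 30)
#' @export
projected_distance_ratio <- function(chi_deg = NULL, tilt_deg = NULL, fov_deg = NULL) {
  if (is.null(chi_deg)) {
    stopifnot(is.numeric(tilt_deg), is.numeric(fov_deg))
    chi_deg <- tilt_deg - fov_deg / 2
  }
  stopifnot(is.numeric(chi_deg))
  chi_deg <- abs(chi_deg)
  if (any(chi_deg >= 90)) stop("footprint unbounded (horizon in view)")
  1 / cos(deg2rad(chi_deg))
}

#' Ground footprint of an oblique camera
#'
#' Projects the camera field of view onto the detection surface (the canopy
#' top). With `H` the height above that surface and `tilt` the camera tilt
#' from nadir, the near/middle/far ground distances from the sub-drone point
#' are `H tan(tilt - vfov/2)`, `H tan(tilt)` and `H tan(tilt + vfov/2)`; the
#' footprint width at each of those lines is `2 * slant * tan(hfov/2)` with
#' `slant = H / cos(angle)`. The nadir swath `2 H tan(vfov/2)` is reported for
#' reference. At small tilts the near distance is negative: the near edge lies
#' behind the sub-drone point.
#'
#' @param camera a [camera_model()].
#' @param flight a [flight_config()].
#' @return An object of class `ground_footprint` with fields
#'   `d_nadir_swath_m`, `d_near_m`, `d_mid_m`, `d_far_m`, `w_near_m`,
#'   `w_mid_m`, `w_far_m` (metres).
#' @export
ground_footprint <- function(camera, flight) {
  stopifnot(inherits(camera, "camera_model"), inherits(flight, "flight_config"))
  tilt <- flight$tilt_from_nadir_deg
  vfov <- camera$vfov_deg
  hfov <- camera$hfov_deg
  if (tilt + vfov / 2 >= 90)
    stop("footprint unbounded (horizon in view): tilt + vfov/2 must be < 90 degrees")
  H <- flight$height_agl_m - flight$canopy_height_m
  ang <- deg2rad(c(near = tilt - vfov / 2, mid = tilt, far = tilt + vfov / 2))
  d <- H * tan(ang)
  w <- 2 * (H / cos(ang)) * tan(deg2rad(hfov / 2))
  fp <- structure(
    list(d_nadir_swath_m = 2 * H * tan(deg2rad(vfov / 2)),
         d_near_m = unname(d["near"]), d_mid_m = unname(d["mid"]),
         d_far_m = unname(d["far"]),
         w_near_m = unname(w["near"]), w_mid_m = unname(w["mid"]),
         w_far_m = unname(w["far"])),
    class = "ground_footprint")
  stopifnot(fp$d_near_m <= fp$d_mid_m, fp$d_mid_m <= fp$d_far_m,
            all(is.finite(unlist(fp))))
  fp
}

#' Ground sample distance
#'
#' Length of ground represented by one pixel at a given camera-to-surface
#' distance: `GSD = distance * pixel_pitch / focal_length`. Linear in the
#' distance.
#'
#' @param camera a [camera_model()].
#' @param distance_m camera-to-surface distance in metres (may be a vector).
#' @return GSD in metres per pixel.
#' @export
ground_sample_distance <- function(camera, distance_m) {
  stopifnot(inherits(camera, "camera_model"), is.numeric(distance_m),
            all(distance_m > 0))
  distance_m * (camera$pixel_pitch_um * 1e-6) / (camera$focal_length_mm * 1e-3)
}

#' Percent ground-area excess between two flight heights
#'
#' Image ground area scales with the square of the height, so the image
#' recorded at the higher flight exceeds the lower one's area by
#' `100 * ((h_high/h_low)^2 - 1)` percent.
#'
#' @param h_low_m,h_high_m the two heights above the surface, metres,
#'   with `h_high_m > h_low_m` (equal heights give 0).
#' @return the excess in percent.
#' @export
area_excess_between_heights <- function(h_low_m, h_high_m) {
  stopifnot(is.numeric(h_low_m), is.numeric(h_high_m), h_low_m > 0)
  if (h_high_m < h_low_m) stop("h_high_m must be >= h_low_m")
  100 * ((h_high_m / h_low_m)^2 - 1)
}

#' Mask specification
#'
#' Fractions of the image width/height removed from each side of the frame.
#'
#' @param left_frac,right_frac,top_frac,bottom_frac fractions in `[0, 0.5)`.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(left_frac = 0, right_frac = 0, top_frac = 0, bottom_frac = 0) {
  fr <- c(left = left_frac, right = right_frac, top = top_frac, bottom = bottom_frac)
  stopifnot(is.numeric(fr), all(fr >= 0), all(fr < 0.5))
  if (left_frac + right_frac >= 1 || top_frac + bottom_frac >= 1)
    stop("mask removes the whole frame")
  structure(list(left_frac = left_frac, right_frac = right_frac,
                 top_frac = top_frac, bottom_frac = bottom_frac),
            class = "mask_spec")
}

#' Masking rule equalising oblique and nadir footage widths
#'
#' Oblique footage is wider on the ground than nadir footage, more so at the
#' top (far edge) of the frame than at the bottom (near edge). Given the
#' percent width excesses at the bottom and top of the frame, returns the
#' per-side horizontal mask to apply to the oblique footage so both camera
#' angles sample the same area.
#'
#' Two rules are provided. The `"survey"` rule (field practice) halves the excess per side
#' (a 10% bottom excess becomes a 5% mask on each side at the bottom rows);
#' the `"exact"` rule `per_side = (1 - 1/(1 + excess))/2` restores width
#' parity exactly.
#'
#' @param width_excess_bottom_pct,width_excess_top_pct non-negative percent
#'   width excesses of the oblique frame at its bottom and top.
#' @param rule `"survey"` (default) or `"exact"`.
#' @return An object of class `angle_mask` with `mask_spec` components
#'   `$bottom` and `$top` (horizontal masks for the bottom and top rows) and
#'   the `$rule` label.
#' @export
mask_spec_for_angle <- function(width_excess_bottom_pct, width_excess_top_pct,
                                rule = c("survey", "exact")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(width_excess_bottom_pct), width_excess_bottom_pct >= 0,
            is.numeric(width_excess_top_pct), width_excess_top_pct >= 0)
  per_side <- function(excess_pct) {
    if (rule == "survey") excess_pct / 200
    else (1 - 1 / (1 + excess_pct / 100)) / 2
  }
  structure(
    list(bottom = mask_spec(left_frac = per_side(width_excess_bottom_pct),
                            right_frac = per_side(width_excess_bottom_pct)),
         top = mask_spec(left_frac = per_side(width_excess_top_pct),
                         right_frac = per_side(width_excess_top_pct)),
         rule = rule),
    class = "angle_mask")
}

#' Masking rule equalising areas between flight heights
#'
#' Given the percent by which the higher flight's image ground area exceeds
#' the lower flight's, returns the four-sided mask to apply to the higher
#' footage. The `"survey"` rule (field practice) masks `excess/4` percent on each of the four
#' sides; the `"exact"` rule `per_side = (1 - 1/sqrt(1 + excess))/2` restores
#' area parity exactly.
#'
#' @param area_excess_pct non-negative percent area excess.
#' @param rule `"survey"` (default) or `"exact"`.
#' @return A [mask_spec()] with equal fractions on all four sides; the rule
#'   label is attached as attribute `"rule"`.
#' @export
mask_spec_for_height <- function(area_excess_pct, rule = c("survey", "exact")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(area_excess_pct), area_excess_pct >= 0)
  per_side <- if (rule == "survey") area_excess_pct / 400
              else (1 - 1 / sqrt(1 + area_excess_pct / 100)) / 2
  m <- mask_spec(per_side, per_side, per_side, per_side)
  attr(m, "rule") <- rule
  m
}

#' Maximum detection distance for a pixel-size rule
#'
#' Largest camera-to-animal distance at which an animal of the given body
#' length still spans at least `min_pixels` pixels:
#' `d = body_length * focal_length / (min_pixels * pixel_pitch)`.
#'
#' @param body_length_m animal body length in metres.
#' @param min_pixels minimum pixel span required for detection.
#' @param camera a [camera_model()].
#' @return distance in metres.
#' @export
max_detection_distance <- function(body_length_m, min_pixels, camera) {
  stopifnot(is.numeric(body_length_m), body_length_m > 0,
            is.numeric(min_pixels), min_pixels > 0,
            inherits(camera, "camera_model"))
  body_length_m * (camera$focal_length_mm * 1e-3) /
    (min_pixels * camera$pixel_pitch_um * 1e-6)
}

#' Maximum flight height for a detection-distance limit
#'
#' Converts a maximum camera-to-subject distance into a flight height above
#' ground level, assuming the subject sits at the canopy top:
#' `height_agl = max_distance * cos(tilt) + canopy_height`.
#'
#' @param max_distance_m maximum camera-to-subject distance, metres.
#' @param canopy_height_m canopy height above ground, metres.
#' @param tilt_from_nadir_deg camera tilt from nadir, degrees in `[0, 90)`.
#' @return height above ground level in metres.
#' @export
max_flight_height_agl <- function(max_distance_m, canopy_height_m = 0,
                                  tilt_from_nadir_deg = 0) {
  stopifnot(is.numeric(max_distance_m), max_distance_m > 0,
            is.numeric(canopy_height_m), canopy_height_m >= 0)
  if (tilt_from_nadir_deg >= 90) stop("tilt must be < 90 degrees")
  max_distance_m * cos(deg2rad(tilt_from_nadir_deg)) + canopy_height_m
}

#' Geometry report over a grid of heights and tilts
#'
#' One row per height x tilt combination: footprint distances and widths,
#' GSD at the mid-line slant range, and the nadir swath.
#'
#' @param camera a [camera_model()].
#' @param heights_agl_m vector of flight heights a.g.l., metres.
#' @param tilts_deg vector of camera tilts from nadir, degrees.
#' @param canopy_height_m canopy height above ground, metres.
#' @return a `data.frame`, one row per combination.
#' @export
geometry_report <- function(camera, heights_agl_m, tilts_deg, canopy_height_m = 0) {
  grid <- expand.grid(height_agl_m = heights_agl_m, tilt_deg = tilts_deg,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fl <- flight_config(height_agl_m = grid$height_agl_m[i], speed_m_s = 1,
                        tilt_from_nadir_deg = grid$tilt_deg[i],
                        canopy_height_m = canopy_height_m)
    fp <- ground_footprint(camera, fl)
    H <- fl$height_agl_m - fl$canopy_height_m
    slant_mid <- H / cos(deg2rad(fl$tilt_from_nadir_deg))
    data.frame(height_agl_m = fl$height_agl_m, tilt_deg = fl$tilt_from_nadir_deg,
               canopy_height_m = canopy_height_m,
               d_nadir_swath_m = fp$d_nadir_swath_m,
               d_near_m = fp$d_near_m, d_mid_m = fp$d_mid_m, d_far_m = fp$d_far_m,
               w_near_m = fp$w_near_m, w_mid_m = fp$w_mid_m, w_far_m = fp$w_far_m,
               gsd_mid_m_per_px = ground_sample_distance(camera, slant_mid))
  })
  do.call(rbind, rows)
}
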