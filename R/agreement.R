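#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement among a fixed number of raters assigning
#' categorical ratings. Counts are treated as unordered nominal categories:
#' agreement means the identical count, with no partial credit for close
#' counts. With \eqn{n_{ij}} the number of raters assigning subject `i` to
#' category `j`, \eqn{P_i = (\sum_j n_{ij}^2 - n) / (n(n-1))},
#' \eqn{\bar P} the mean of the \eqn{P_i},
#' \eqn{p_j = \sum_i n_{ij} / (Nn)}, \eqn{\bar P_e = \sum_j p_j^2}, and
#' \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)}.
#'
#' When every rating on every subject falls in a single category,
#' \eqn{\bar P_e = 1} and kappa is undefined; the function then returns `NA`
#' flagged with attribute `degenerate = "perfect"` (unanimity with no
#' category variation), which [agreement_summary()] counts as the strongest
#' agreement.
#'
#' @param ratings a subjects x raters matrix (or data.frame) of categorical
#'   ratings; at least 2 subjects and 2 raters, no missing values.
#' @return kappa as a single number (`<= 1`), or flagged `NA` in the
#'   degenerate-perfect case.
#' @examples
#' fleiss_kappa(rbind(c(0, 0, 1), c(1, 1, 1), c(2, 2, 2), c(0, 1, 2)))
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must not contain missing values")
  N <- nrow(ratings)
  n <- ncol(ratings)
  stopifnot(N >= 2, n >= 2)
  cats <- sort(unique(as.vector(ratings)))
  nij <- vapply(cats, function(cc) rowSums(ratings == cc), numeric(N))
  nij <- matrix(nij, nrow = N)
  P_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(nij) / (N * n)
  Pe <- sum(p_j^2)
  if (Pe >= 1 - 1e-15) {
    out <- NA_real_
    attr(out, "degenerate") <- "perfect"
    return(out)
  }
  (P_bar - Pe) / (1 - Pe)
}

#' Is a kappa value the degenerate-perfect case?
#' @param kappa a value returned by [fleiss_kappa()].
#' @return logical.
#' @export
is_degenerate_perfect <- function(kappa) {
  identical(attr(kappa, "degenerate"), "perfect")
}

#' Landis-Koch verbal band for a kappa value
#'
#' Maps kappa to the conventional six labels. Intervals are half-open with
#' closed upper ends: poor `(-Inf, 0)`, slight `[0, 0.20]`, fair
#' `(0.20, 0.40]`, moderate `(0.40, 0.60]`, substantial `(0.60, 0.80]`,
#' almost perfect `(0.80, 1]` (values just above 0.80 are "almost perfect").
#'
#' @param kappa numeric vector of kappa values (`<= 1`).
#' @return character vector of band labels.
#' @examples
#' landis_koch_band(c(-0.1, 0.15, 0.70, 0.95))
#' @export
landis_koch_band <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa <= 1 + 1e-12, na.rm = TRUE))
  labs <- c("poor", "slight", "fair", "moderate", "substantial", "almost perfect")
  idx <- ifelse(kappa < 0, 1L,
                2L + findInterval(kappa, c(0.20, 0.40, 0.60, 0.80),
                                  left.open = TRUE))
  labs[idx]
}

.lk_levels <- c("poor", "slight", "fair", "moderate", "substantial",
                "almost perfect")

#' Agreement summary by flight-parameter combination and contrast zone
#'
#' Groups rated videos by the flight-parameter combination
#' (speed x height x angle) and thermal-contrast zone, computes Fleiss'
#' kappa and its Landis-Koch band in every cell, and summarises per-band
#' shares of combinations within each zone as well as marginal shares by
#' each design factor. Degenerate-perfect cells (all coders unanimous in a
#' single category) are banded "almost perfect"; cells with fewer than two
#' rated videos are marked "insufficient data" and excluded from shares.
#'
#' Marginal shares are reported under two denominators: the fraction of
#' combination cells in a band, and the fraction of rated videos (cells
#' weighted by their number of videos).
#'
#' @param coders a coder table (`video_id`, `coder_id`, `zone`, `count`),
#'   e.g. from [generate_coder_ratings()].
#' @param design a video-record table with `video_id`, `speed_m_s`,
#'   `height_m`, `angle_deg` (e.g. from [expand_design()]).
#' @return an object of class `agreement_summary`: `cells` (one row per
#'   combination x zone with `kappa`, `band`, `n_subjects`), `zone_shares`
#'   (per-band share of combinations within each zone), and
#'   `marginal_shares` (per factor level x zone x band, both denominators).
#' @export
agreement_summary <- function(coders, design) {
  need <- c("video_id", "coder_id", "zone", "count")
  stopifnot(all(need %in% names(coders)),
            all(c("video_id", "speed_m_s", "height_m", "angle_deg") %in% names(design)))
  m <- merge(coders, design[, c("video_id", "speed_m_s", "height_m", "angle_deg")],
             by = "video_id")
  if (nrow(m) == 0) stop("coder table does not join to the design on video_id")

  combos <- unique(m[, c("speed_m_s", "height_m", "angle_deg", "zone")])
  combos <- combos[order(combos$speed_m_s, combos$height_m, combos$angle_deg,
                         combos$zone), ]
  cells <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- m[m$speed_m_s == combos$speed_m_s[i] &
             m$height_m == combos$height_m[i] &
             m$angle_deg == combos$angle_deg[i] &
             m$zone == combos$zone[i], ]
    rat <- tapply(sub$count, list(sub$video_id, sub$coder_id), function(x) x[1])
    n_subj <- nrow(rat)
    if (is.null(n_subj) || n_subj < 2 || anyNA(rat)) {
      kap <- NA_real_; band <- "insufficient data"
    } else {
      kap <- fleiss_kappa(rat)
      band <- if (is_degenerate_perfect(kap)) "almost perfect"
              else landis_koch_band(as.numeric(kap))
    }
    data.frame(speed_m_s = combos$speed_m_s[i], height_m = combos$height_m[i],
               angle_deg = combos$angle_deg[i], zone = combos$zone[i],
               n_subjects = if (is.null(n_subj)) 0L else n_subj,
               kappa = as.numeric(kap), band = band,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL

  ok <- cells$band != "insufficient data"
  zone_shares <- do.call(rbind, lapply(unique(cells$zone), function(z) {
    cz <- cells[ok & cells$zone == z, ]
    if (nrow(cz) == 0) return(NULL)
    tab <- table(factor(cz$band, levels = .lk_levels))
    data.frame(zone = z, band = .lk_levels,
               share = as.numeric(tab) / sum(tab),
               n_combinations = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(zone_shares) <- NULL

  marg <- list()
  for (f in c("speed_m_s", "height_m", "angle_deg")) {
    for (z in unique(cells$zone)) {
      for (lv in unique(cells[[f]])) {
        cz <- cells[ok & cells$zone == z & cells[[f]] == lv, ]
        if (nrow(cz) == 0) next
        for (bd in .lk_levels) {
          in_band <- cz$band == bd
          marg[[length(marg) + 1]] <- data.frame(
            factor = f, level = as.character(lv), zone = z, band = bd,
            share_combinations = mean(in_band),
            share_videos = sum(cz$n_subjects[in_band]) / sum(cz$n_subjects),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  marginal_shares <- do.call(rbind, marg)
  rownames(marginal_shares) <- NULL

  structure(list(cells = cells, zone_shares = zone_shares,
                 marginal_shares = marginal_shares,
                 band_convention = "upper-closed; >0.80 is almost perfect; degenerate-perfect counted as almost perfect"),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("Inter-coder agreement by flight-parameter combination and contrast zone\n")
  print(x$cells)
  invisible(x)
}
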