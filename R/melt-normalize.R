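#' Normalise a melt curve and call its melt peak
#'
#' Fits linear baselines to a pre-melt and a post-melt temperature
#' window, rescales fluorescence between those baselines
#' (`(F - lower) / (upper - lower)`, clipped to `[0, 1]`), and calls the
#' melt peak Tm as the temperature of the maximum of the smoothed
#' negative derivative -dF/dT of the normalised curve. Smoothing is a
#' quadratic local polynomial (Savitzky-Golay) over a 1 degree window
#' (5 points at the 0.2 degree protocol step), which suppresses dye
#' noise without shifting peaks at this sampling density; the peak
#' position is refined by parabolic interpolation of the three points
#' around the grid maximum. Ties resolve to the lower temperature.
#'
#' By default the windows are the first and last 2 degrees C of the
#' sweep; override per run for instruments that need manual melt-domain
#' placement.
#'
#' @param curve tibble with `temperature` (strictly increasing, uniform
#'   step) and `fluorescence`.
#' @param pre_window,post_window length-2 numeric temperature intervals
#'   for the upper (pre-melt) and lower (post-melt) baselines; each must
#'   span at least 5 grid points and `pre_window` must lie below
#'   `post_window`.
#' @return a `melt_features` object: list with `tm`, `normalized`
#'   (tibble `temperature`, `fluorescence` in `[0, 1]`), `derivative`
#'   (smoothed -dF/dT, same length as the curve) and the windows used.
#' @export
normalize_melt <- function(curve, pre_window = NULL, post_window = NULL) {
  tmps <- curve$temperature
  msg <- validate_melt_grid(tmps)
  if (msg != "") abort(msg)
  pre_window <- pre_window %||% c(min(tmps), min(tmps) + 2)
  post_window <- post_window %||% c(max(tmps) - 2, max(tmps))
  if (pre_window[2] >= post_window[1]) abort("pre_window must lie below post_window")
  in_pre <- tmps >= pre_window[1] & tmps <= pre_window[2]
  in_post <- tmps >= post_window[1] & tmps <= post_window[2]
  if (sum(in_pre) < 5 || sum(in_post) < 5) {
    abort("baseline windows must each span at least 5 grid points")
  }
  f <- curve$fluorescence
  upper_fit <- lm(f[in_pre] ~ tmps[in_pre])
  lower_fit <- lm(f[in_post] ~ tmps[in_post])
  upper <- coef(upper_fit)[1] + coef(upper_fit)[2] * tmps
  lower <- coef(lower_fit)[1] + coef(lower_fit)[2] * tmps
  melt_zone <- tmps > pre_window[2] & tmps < post_window[1]
  if (any(upper[melt_zone] <= lower[melt_zone])) {
    abort("degenerate baselines: upper baseline does not exceed lower in the melt window")
  }
  norm <- pmin(1, pmax(0, (f - lower) / (upper - lower)))
  deriv <- smoothed_neg_derivative(tmps, norm)
  structure(list(
    tm = tm_from_derivative(tmps, deriv),
    normalized = tibble(temperature = tmps, fluorescence = norm),
    derivative = deriv,
    pre_window = pre_window, post_window = post_window
  ), class = "melt_features")
}

#' @export
print.melt_features <- function(x, ...) {
  cat(sprintf("<melt_features> %d points, Tm = %.2f C\n",
              nrow(x$normalized), x$tm))
  invisible(x)
}

# central-difference -dF/dT (one-sided at the ends), Savitzky-Golay
# smoothed (quadratic, 5-point window)
smoothed_neg_derivative <- function(tmps, f) {
  n <- length(f)
  d <- numeric(n)
  d[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (tmps[3:n] - tmps[1:(n - 2)])
  d[1] <- (f[2] - f[1]) / (tmps[2] - tmps[1])
  d[n] <- (f[n] - f[n - 1]) / (tmps[n] - tmps[n - 1])
  neg <- -d
  if (n >= 5) signal::sgolayfilt(neg, p = 2, n = 5) else neg
}

# grid argmax (tie -> lowest temperature) + parabolic refinement
tm_from_derivative <- function(tmps, deriv) {
  i <- which(deriv >= max(deriv) - .Machine$double.eps^0.5 * max(1, abs(max(deriv))))[1]
  if (i <= 1 || i >= length(deriv)) return(tmps[i])
  y1 <- deriv[i - 1]; y2 <- deriv[i]; y3 <- deriv[i + 1]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < .Machine$double.eps) return(tmps[i])
  delta <- 0.5 * (y1 - y3) / den
  delta <- max(-0.5, min(0.5, delta))
  tmps[i] + delta * (tmps[2] - tmps[1])
}

#' Normalise every melt curve of a plate run
#'
#' Maps [normalize_melt()] over the wells of a plate run, returning the
#' feature table that the clustering functions consume.
#'
#' @param wells tibble from [read_plate()]/[screen_plate()]; wells with
#'   `qc_pass == FALSE` (when the column exists) are dropped.
#' @inheritParams normalize_melt
#' @return tibble with the well metadata plus `tm` and a `normalized`
#'   list-column of normalised curves.
#' @export
normalize_plate <- function(wells, pre_window = NULL, post_window = NULL) {
  if ("qc_pass" %in% names(wells)) wells <- wells[wells$qc_pass, ]
  feats <- lapply(wells$melt, normalize_melt,
                  pre_window = pre_window, post_window = post_window)
  keep <- intersect(c("plate_id", "well_id", "sample_id", "population_id",
                      "replicate_index", "known_haplotype"), names(wells))
  out <- wells[keep]
  out$tm <- vapply(feats, function(x) x$tm, numeric(1))
  out$normalized <- lapply(feats, function(x) x$normalized)
  as_tibble(out)
}
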