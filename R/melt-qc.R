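#' Amplification quality-control configuration
#'
#' The screen passes a well when its amplification plateau reaches at
#' least `min_plateau_frac` of the reference plateau (by default the
#' plate median) and a sigmoid (4-parameter logistic) amplification
#' model fits with positive amplitude. The instrument protocol only
#' states that replicates with insufficient PCR product were excluded;
#' the threshold here is an explicit, configurable default.
#'
#' @param min_plateau_frac minimum plateau fluorescence as a fraction of
#'   the plate median plateau.
#' @param min_cycles minimum number of cycles required to screen.
#' @export
qc_config <- function(min_plateau_frac = 0.1, min_cycles = 10L) {
  stopifnot(min_plateau_frac >= 0, min_cycles >= 2)
  structure(list(min_plateau_frac = min_plateau_frac,
                 min_cycles = as.integer(min_cycles)),
            class = "qc_config")
}

amp_plateau <- function(curve) {
  n <- nrow(curve)
  mean(sort(curve$fluorescence, decreasing = TRUE)[seq_len(min(5L, n))])
}

#' Screen a single amplification curve
#'
#' @param curve tibble with `cycle` and `fluorescence`.
#' @param config a [qc_config()].
#' @param reference_plateau plateau level the threshold is relative to
#'   (typically the plate median plateau; defaults to the curve's own
#'   plateau, which disables the relative check).
#' @return one-row tibble: `pass` (logical) and `reason`.
#' @export
screen_amplification <- function(curve, config = qc_config(),
                                 reference_plateau = NULL) {
  stopifnot(nrow(curve) >= config$min_cycles)
  f <- curve$fluorescence
  plateau <- amp_plateau(curve)
  baseline <- mean(head(f, 3))
  rise <- plateau - baseline
  if (!is.finite(rise) || rise <= 0 || max(abs(f)) < .Machine$double.eps^0.5) {
    return(tibble(pass = FALSE, reason = "no amplification"))
  }
  ref <- reference_plateau %||% plateau
  if (plateau < config$min_plateau_frac * ref) {
    return(tibble(pass = FALSE, reason = "low plateau"))
  }
  fit <- fit_amp_sigmoid(curve)
  if (is.null(fit)) {
    return(tibble(pass = FALSE, reason = "no exponential phase"))
  }
  tibble(pass = TRUE, reason = "")
}

# 4-parameter logistic fit of the amplification curve; NULL when the fit
# fails or is degenerate (no positive exponential phase within the run)
fit_amp_sigmoid <- function(curve) {
  cyc <- curve$cycle
  f <- curve$fluorescence
  start <- list(b = min(f), A = diff(range(f)),
                m = cyc[which.min(abs(f - (min(f) + diff(range(f)) / 2)))],
                s = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ b + A / (1 + exp(-(cyc - m) / s)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  if (!is.finite(p["A"]) || p["A"] <= 0 || p["s"] <= 0) return(NULL)
  if (p["m"] < min(cyc) - 5 || p["m"] > max(cyc) + 5) return(NULL)
  # amplitude must be resolvable against residual noise
  if (p["A"] < 3 * sd(residuals(fit))) return(NULL)
  fit
}

#' Screen all wells of a plate run
#'
#' Applies [screen_amplification()] well by well, using the plate median
#' plateau as the reference level.
#'
#' @param wells tibble from [read_plate()] (or the simulator).
#' @param config a [qc_config()].
#' @return `wells` with `qc_pass` and `qc_reason` columns appended.
#' @export
screen_plate <- function(wells, config = qc_config()) {
  plateaus <- vapply(wells$amplification, function(a) {
    if (is.null(a)) NA_real_ else amp_plateau(a)
  }, numeric(1))
  ref <- median(plateaus, na.rm = TRUE)
  res <- purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    a <- wells$amplification[[i]]
    if (is.null(a)) return(tibble(pass = FALSE, reason = "no amplification data"))
    screen_amplification(a, config, reference_plateau = ref)
  })
  wells$qc_pass <- res$pass
  wells$qc_reason <- res$reason
  wells
}

#' @importFrom stats residuals
NULL
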