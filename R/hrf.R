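#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical double-gamma HRF -- a positive gamma density peaking
#' about 5 s after stimulus onset minus a scaled, later gamma density
#' modelling the post-stimulus undershoot -- on the acquisition grid. The
#' kernel is peak-normalized so its maximum equals 1.
#'
#' The defaults are the field-standard canonical parameters: response delay
#' 6 s, undershoot delay 16 s, unit dispersions, and an undershoot ratio of
#' 1/6. With dispersion \eqn{d}, each lobe is a gamma density with shape
#' \eqn{\mathrm{delay}/d} and rate \eqn{1/d}.
#'
#' @param tr_s Sampling interval (repetition time) in seconds; must be > 0.
#' @param length_s Kernel support in seconds (>= 20); the kernel has
#'   `floor(length_s / tr_s)` samples starting at t = 0.
#' @param peak_delay,undershoot_delay Delays (s) of the response and
#'   undershoot gamma lobes.
#' @param peak_disp,undershoot_disp Dispersions of the two lobes.
#' @param undershoot_ratio Weight of the undershoot lobe.
#' @return Numeric vector of kernel samples with attribute `times` (seconds).
#' @examples
#' h <- double_gamma_hrf(1, 32)
#' max(h) # 1
#' @export
double_gamma_hrf <- function(tr_s, length_s = 32, peak_delay = 6,
                             undershoot_delay = 16, peak_disp = 1,
                             undershoot_disp = 1, undershoot_ratio = 1 / 6) {
  if (!is.numeric(tr_s) || length(tr_s) != 1 || !is.finite(tr_s) || tr_s <= 0) {
    abort("`tr_s` must be a single positive number.", class = "boldmvpa_invalid_argument")
  }
  if (length_s < 20) {
    abort("`length_s` must be at least 20 s to cover the undershoot.",
          class = "boldmvpa_invalid_argument")
  }
  t <- seq(0, length_s - tr_s, by = tr_s)
  h <- double_gamma_eval(t, peak_delay, undershoot_delay, peak_disp,
                         undershoot_disp, undershoot_ratio)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

# raw (unnormalized) difference of gamma densities
double_gamma_eval <- function(t, peak_delay = 6, undershoot_delay = 16,
                              peak_disp = 1, undershoot_disp = 1,
                              undershoot_ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                    rate = 1 / undershoot_disp)
}
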