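#' Parameters of the canonical double-gamma HRF
#'
#' The conventional "canonical" haemodynamic response function is a
#' difference of two gamma densities: a positive response peaking around 6 s
#' and a later undershoot around 16 s, weighted 1 : 1/6, truncated at 32 s.
#'
#' @param peak_delay_s,under_delay_s Delays (mean lag) of response and
#'   undershoot in seconds.
#' @param peak_disp_s,under_disp_s Dispersions (gamma scale) in seconds.
#' @param undershoot_ratio Amplitude ratio of undershoot to peak.
#' @param length_s Kernel length in seconds.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, under_delay_s = 16,
                       peak_disp_s = 1, under_disp_s = 1,
                       undershoot_ratio = 1 / 6, length_s = 32) {
  stopifnot(peak_delay_s > 0, under_delay_s > 0, peak_disp_s > 0,
            under_disp_s > 0, undershoot_ratio >= 0,
            length_s > peak_delay_s)
  structure(list(peak_delay_s = peak_delay_s, under_delay_s = under_delay_s,
                 peak_disp_s = peak_disp_s, under_disp_s = under_disp_s,
                 undershoot_ratio = undershoot_ratio, length_s = length_s),
            class = "hrf_params")
}

# evaluate the (unnormalized) double-gamma kernel at times t (seconds)
hrf_eval <- function(t, params) {
  shape1 <- params$peak_delay_s / params$peak_disp_s
  shape2 <- params$under_delay_s / params$under_disp_s
  dgamma(t, shape = shape1, scale = params$peak_disp_s) -
    params$undershoot_ratio *
      dgamma(t, shape = shape2, scale = params$under_disp_s)
}

#' Canonical HRF sampled at the repetition time
#'
#' Difference-of-gammas kernel sampled every `tr_s` seconds from 0 to the
#' kernel length, scaled to unit peak.
#'
#' @param tr_s Sampling interval (repetition time) in seconds, > 0.
#' @param params An [hrf_params()] object.
#' @return Numeric vector of kernel samples with unit maximum.
#' @export
canonical_hrf <- function(tr_s, params = hrf_params()) {
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a positive scalar")
  t <- seq(0, params$length_s, by = tr_s)
  h <- hrf_eval(t, params)
  h / max(h)
}
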