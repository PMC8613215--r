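#' Model parameters for the virtual-hand-illusion simulation
#'
#' Bundles every constant of the generative model and its integration into a
#' validated list. Positional quantities at the user interface (forearm length
#' `L`, localization bias `b`, condition offsets, perceived positions) are in
#' centimetres; internally the model works in SI metres, where the default
#' sensory variances and the precision floors `exp(1)` (visual) and
#' `exp(0.1)` (proprioception) are numerically meaningful.
#'
#' @param L Forearm length, cm.
#' @param b Localization perceptual bias of the predicted hand position, cm.
#' @param m Arm mass, model units.
#' @param gamma Viscosity of the mass-spring dynamics prior, model units.
#' @param K_a Action gain (step size of the action gradient flow).
#' @param kappa Causality weight in `[0, 1]`: the believed probability that
#'   visual and tactile events share a common source. 1 in the synchronous
#'   stimulation condition, 0.3 in the asynchronous one.
#' @param kappa_in_nu Logical; if `TRUE` (default) `kappa` weights the
#'   arm-vs-virtual-hand visual error wherever that error appears, i.e. in both
#'   the posture update and the perceived-virtual-hand (`nu`) update. If
#'   `FALSE` it weights only the posture update.
#' @param sigma_sp2 Initial proprioceptive (angle) variance, rad^2. Its inverse
#'   is the initial proprioceptive precision (floored at `exp(0.1)`).
#' @param sigma_spd2 Proprioceptive velocity variance, (rad/s)^2 (fixed).
#' @param sigma_v2 Initial visual variance, m^2. Its inverse is the initial
#'   visual precision (floored at `exp(1)`).
#' @param sigma_c2 Causal-channel variance (virtual-hand position vs its
#'   percept), m^2 (fixed).
#' @param sigma_mu Length-3 numeric: dynamics-model variances per generalized
#'   order.
#' @param dt Integration step, s. The 0.001 s default matches the 1 kHz force
#'   sampling of the experiment.
#' @param duration Trial duration, s (40 s of visuo-tactile stimulation).
#' @param noise_sd_proprio SD of per-sample observation noise on the
#'   proprioceptive angle reading, rad.
#' @param noise_sd_visual SD of per-sample observation noise on the measured
#'   virtual-hand position, cm.
#' @param force_scale Calibration factor mapping the accumulated action
#'   variable to Newtons of lateral force (positive toward the body midline).
#' @param hand_offset_cm Distance of the real (left) hand from the body
#'   midline, cm (documentation of the geometry; the simulation works in
#'   hand-centred coordinates).
#'
#' @return A list of class `vhi_params`.
#' @examples
#' p <- vhi_params(kappa = 0.3)
#' p$kappa
#' @export
vhi_params <- function(L = 44.7208, b = 0, m = 1, gamma = 1,
                       K_a = 0.1, kappa = 1, kappa_in_nu = TRUE,
                       sigma_sp2 = 1, sigma_spd2 = 1,
                       sigma_v2 = exp(-1), sigma_c2 = 1,
                       sigma_mu = c(1, 1, 1),
                       dt = 0.001, duration = 40,
                       noise_sd_proprio = 0.01, noise_sd_visual = 0.1,
                       force_scale = 0.74,
                       hand_offset_cm = 30) {
  stopifnot(is.numeric(L), L > 0, is.numeric(m), is.numeric(gamma),
            gamma >= 0, is.numeric(kappa), length(sigma_mu) == 3)
  if (m <= 0) stop("arm mass `m` must be positive", call. = FALSE)
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]", call. = FALSE)
  if (sigma_sp2 <= 0 || sigma_spd2 <= 0 || sigma_v2 <= 0 || sigma_c2 <= 0)
    stop("sensory variances must be positive", call. = FALSE)
  if (any(sigma_mu <= 0)) stop("`sigma_mu` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (force_scale <= 0) stop("`force_scale` must be positive", call. = FALSE)
  structure(list(
    L = L, b = b, m = m, gamma = gamma, K_a = K_a,
    kappa = kappa, kappa_in_nu = isTRUE(kappa_in_nu),
    sigma_sp2 = sigma_sp2, sigma_spd2 = sigma_spd2,
    sigma_v2 = sigma_v2, sigma_c2 = sigma_c2,
    sigma_mu = as.numeric(sigma_mu),
    floor_proprio = exp(0.1), floor_visual = exp(1),
    dt = dt, duration = duration,
    noise_sd_proprio = noise_sd_proprio, noise_sd_visual = noise_sd_visual,
    force_scale = force_scale, hand_offset_cm = hand_offset_cm
  ), class = "vhi_params")
}

#' @export
print.vhi_params <- function(x, ...) {
  cat("<vhi_params>\n")
  cat(sprintf("  arm: L = %.4f cm, b = %.4f cm, m = %g, gamma = %g\n",
              x$L, x$b, x$m, x$gamma))
  cat(sprintf("  action: K_a = %g, force_scale = %g N/unit\n",
              x$K_a, x$force_scale))
  cat(sprintf("  causality: kappa = %g (kappa_in_nu = %s)\n",
              x$kappa, x$kappa_in_nu))
  cat(sprintf("  variances: sp %.3g, spd %.3g, v %.3g, c %.3g; sigma_mu [%s]\n",
              x$sigma_sp2, x$sigma_spd2, x$sigma_v2, x$sigma_c2,
              paste(signif(x$sigma_mu, 3), collapse = ", ")))
  cat(sprintf("  integration: dt = %g s, duration = %g s\n", x$dt, x$duration))
  invisible(x)
}

# Initial per-channel precisions (proprio angle, proprio velocity, visual,
# causal), with floors applied to the adaptive channels.
initial_precisions <- function(params) {
  c(p = max(1 / params$sigma_sp2, params$floor_proprio),
    pd = 1 / params$sigma_spd2,
    v = max(1 / params$sigma_v2, params$floor_visual),
    c = 1 / params$sigma_c2)
}

# Deterministic substream seed derivation: fold integer/character keys into
# the master seed with a 31-bit multiplicative hash (exact in doubles).
derive_seed <- function(master, ...) {
  keys <- list(...)
  h <- as.numeric(master) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = ""))) else k <- as.numeric(k)
    for (ki in k) h <- (h * 69069 + ki + 1) %% 2147483647
  }
  as.integer(h)
}
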