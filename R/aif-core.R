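#' Predicted visual position of the hand from the elbow-angle belief
#'
#' The visual generative map `g_v(mu0) = L * cos(mu0 - pi/2) + b`
#' (equivalently `L * sin(mu0) + b`): the horizontal position of the hand
#' implied by an elbow angle, in the same length unit as `L` and `b`.
#' Zero angle means the forearm is parallel to the sagittal plane; positive
#' angles rotate toward the body midline.
#'
#' @param mu0 Elbow angle, rad, in `(-pi/2, pi/2)`.
#' @param params A [vhi_params()] object (uses `L`, `b`).
#' @return Predicted horizontal hand position (cm for the default `params`).
#' @examples
#' predict_visual(0.3, vhi_params(L = 44.7208, b = 0))
#' @export
predict_visual <- function(mu0, params = vhi_params()) {
  check_angle(mu0)
  params$L * cos(mu0 - pi / 2) + params$b
}

#' Jacobian of the visual generative map
#'
#' `dg_v/dmu0 = -L * sin(mu0 - pi/2) = L * cos(mu0)`, the sensitivity of the
#' predicted hand position to the elbow angle (cm/rad for default `params`).
#'
#' @inheritParams predict_visual
#' @return The derivative of [predict_visual()] at `mu0`.
#' @export
visual_jacobian <- function(mu0, params = vhi_params()) {
  check_angle(mu0)
  -params$L * sin(mu0 - pi / 2)
}

check_angle <- function(mu0) {
  if (any(!is.finite(mu0)) || any(abs(mu0) >= pi / 2))
    stop("elbow angle must be finite and inside (-pi/2, pi/2)", call. = FALSE)
  invisible(mu0)
}

#' Expected state dynamics of the arm belief
#'
#' The dynamics generative model `f(mu)`: with the arm at rest and no task,
#' the believed arm obeys a mass-spring law, so the expected derivative of
#' the generalized state `(mu0, mu1, mu2)` is
#' `(mu1, -gamma * mu0 / m, 0)`.
#'
#' @param belief Named list or vector with `mu0`, `mu1`, `mu2` (rad, rad/s,
#'   rad/s^2).
#' @param params A [vhi_params()] object (uses `gamma`, `m`).
#' @return Numeric length-3 vector, the noise-free mean of `f`.
#' @export
dynamics_model <- function(belief, params = vhi_params()) {
  b <- as.list(belief)
  c(b$mu1, -params$gamma * b$mu0 / params$m, 0)
}

#' Free-energy gradients of the posture and causal beliefs
#'
#' The coupled gradient flow that drives perception. The belief derivative is
#' the generalized shift `(mu1, mu2, 0)` minus the exact gradient of the
#' precision-weighted squared-error objective
#' \deqn{F = \tfrac12 [\Pi_p e_p^2 + \Pi_{\dot p} e_{\dot p}^2 +
#'   \kappa \Pi_v (\nu - g_v(\mu_0))^2 + \Pi_c (s_v - \nu)^2 +
#'   \Pi_{\mu,1} (\mu_2 + \gamma \mu_0 / m)^2]}
#' with respect to `(mu0, mu1, mu2)`; the perceived virtual-hand position
#' `nu` descends the same objective, so it relaxes toward a precision-weighted
#' compromise between the measured virtual-hand position `s_v` and the
#' arm-predicted position `g_v(mu0)`. The causality weight `kappa` scales the
#' visual (arm vs virtual hand) error channel; at `kappa = 0` the virtual
#' hand has no influence on the posture belief and `nu` simply tracks `s_v`.
#'
#' All positions here are in metres (the internal unit of the model); the
#' high-level trial interface converts from/to cm.
#'
#' @param belief Named list with `mu0`, `mu1`, `mu2` (rad and derivatives)
#'   and `nu` (perceived virtual-hand position, m).
#' @param sens Named list with `s_p` (observed elbow angle, rad), `s_p_dot`
#'   (observed angular velocity, rad/s) and `s_v` (measured virtual-hand
#'   position, m).
#' @param params A [vhi_params()] object.
#' @param precisions Named numeric vector `(p, pd, v, c)` of channel
#'   precisions; defaults to the initial precisions implied by `params`.
#' @return List with `dmu` (length-3 numeric) and `dnu` (scalar), the time
#'   derivatives of the beliefs.
#' @export
free_energy_gradients <- function(belief, sens, params = vhi_params(),
                                  precisions = initial_precisions(params)) {
  if (any(precisions <= 0)) stop("precisions must be positive", call. = FALSE)
  b <- as.list(belief); s <- as.list(sens)
  L <- params$L / 100; bias <- params$b / 100
  Pi_mu <- 1 / params$sigma_mu
  gv <- L * sin(b$mu0) + bias
  J <- L * cos(b$mu0)
  e1 <- s$s_p - b$mu0
  e2 <- s$s_p_dot - b$mu1
  e3 <- b$nu - gv
  e4 <- s$s_v - b$nu
  ed2 <- b$mu2 + params$gamma * b$mu0 / params$m
  kap <- params$kappa
  dmu <- c(
    b$mu1 + precisions[["p"]] * e1 + kap * precisions[["v"]] * J * e3 -
      (params$gamma / params$m) * Pi_mu[2] * ed2,
    b$mu2 + precisions[["pd"]] * e2,
    -Pi_mu[2] * ed2
  )
  dnu <- precisions[["c"]] * e4 -
    (if (params$kappa_in_nu) kap else 1) * precisions[["v"]] * e3
  list(dmu = dmu, dnu = dnu)
}

#' One Euler step of the action gradient flow
#'
#' Action descends the sensory free energy through proprioception only:
#' `da = -K_a * (ds_p/da) * Pi_p * (s_p - mu0)` with `ds_p/da = 1`. The
#' accumulated action `a` estimates the lateral force the locked arm applies
#' (it is never fed back into the true hand position, which the manipulandum
#' holds fixed).
#'
#' @param a Current accumulated action (model units).
#' @param sens,belief,params,precisions As in [free_energy_gradients()].
#' @param dt Euler step, s.
#' @return List with `a` (updated action) and `da` (its time derivative).
#' @export
action_update <- function(a, sens, belief, params = vhi_params(),
                          precisions = initial_precisions(params),
                          dt = params$dt) {
  da <- -params$K_a * precisions[["p"]] * (as.list(sens)$s_p - as.list(belief)$mu0)
  list(a = a + dt * da, da = da)
}

#' One Euler step of the sensory precision dynamics
#'
#' The adaptive channels (proprioceptive angle and visual) follow the
#' gradient rule `dPi = -(s - g(mu))^2 / 2 + Sigma_s` (with `Sigma_s = 1/Pi`
#' the current variance), then are clamped at their floors: `exp(1)` for the
#' visual precision and `exp(0.1)` for the proprioceptive one. Persistent
#' large errors therefore down-weight a channel until it saturates at its
#' floor, while well-predicted channels gain precision. The velocity and
#' causal channels keep fixed precision.
#'
#' @inheritParams action_update
#' @param precisions Named numeric vector `(p, pd, v, c)`.
#' @return The updated precision vector.
#' @export
precision_update <- function(precisions, sens, belief, params = vhi_params(),
                             dt = params$dt) {
  b <- as.list(belief); s <- as.list(sens)
  e1 <- s$s_p - b$mu0
  e3 <- b$nu - (params$L / 100 * sin(b$mu0) + params$b / 100)
  precisions[["p"]] <- precisions[["p"]] +
    dt * (-0.5 * e1^2 + 1 / precisions[["p"]])
  precisions[["v"]] <- precisions[["v"]] +
    dt * (-0.5 * e3^2 + 1 / precisions[["v"]])
  precisions[["p"]] <- max(precisions[["p"]], params$floor_proprio)
  precisions[["v"]] <- max(precisions[["v"]], params$floor_visual)
  precisions
}

#' One full Euler step of the coupled model (reference implementation)
#'
#' Advances belief, causal percept, action and precisions by one `dt` using
#' [free_energy_gradients()], [action_update()] and [precision_update()], all
#' evaluated at the incoming state. The compiled trial integrator used by
#' [simulate_trial()] performs exactly this step; this R version is the
#' readable reference.
#'
#' @param state List with `mu0`, `mu1`, `mu2`, `nu` (m), `a`, and
#'   `precisions` (named vector `(p, pd, v, c)`).
#' @param sens,params As in [free_energy_gradients()].
#' @param dt Euler step, s.
#' @return The updated state list.
#' @export
aif_step <- function(state, sens, params = vhi_params(), dt = params$dt) {
  gr <- free_energy_gradients(state, sens, params, state$precisions)
  act <- action_update(state$a, sens, state, params, state$precisions, dt)
  prec <- precision_update(state$precisions, sens, state, params, dt)
  lim <- pi / 2 - 1e-6
  state$mu0 <- min(max(state$mu0 + dt * gr$dmu[1], -lim), lim)
  state$mu1 <- state$mu1 + dt * gr$dmu[2]
  state$mu2 <- state$mu2 + dt * gr$dmu[3]
  state$nu <- state$nu + dt * gr$dnu
  state$a <- act$a
  state$precisions <- prec
  state
}

#' Simulate one 40-s stimulation trial
#'
#' Integrates the full model over a trial with the physical hand locked at
#' elbow angle 0 (forearm parallel to the sagittal plane): the proprioceptive
#' reading stays at the true angle (plus observation noise) while the virtual
#' hand is displayed at the unbiased true-hand projection plus the condition
#' offset. Lateral force is `force_scale * a`, positive toward the body
#' midline. The perceived virtual-hand position `nu` is initialized at the
#' displayed position.
#'
#' @param profile Optional one-row data frame / named list with participant
#'   fields `sigma_sp2`, `b`, `L`, `kappa` (as produced by
#'   [sample_participants()]); overrides the corresponding `params` entries.
#' @param offset_cm Condition offset of the virtual hand, cm: -15 (Left),
#'   0 (Center) or +15 (Right) in the experimental design (any value is
#'   accepted).
#' @param params A [vhi_params()] object.
#' @param noise Logical; add per-sample Gaussian observation noise to the
#'   proprioceptive and visual readings (SDs from `params`)?
#' @param seed Optional integer seed for the observation noise.
#' @return A tibble of class `vhi_trial` with columns `time` (s), `force`
#'   (N), `mu0` (rad) and `nu_cm` (perceived virtual-hand position, cm), and
#'   attributes `offset_cm`, `proprio_drift_cm` (final arm-predicted hand
#'   position minus true hand position, through the visual map) and
#'   `visual_drift_cm` (final `nu` minus the displayed position).
#' @examples
#' tr <- simulate_trial(offset_cm = 15, noise = FALSE)
#' attr(tr, "proprio_drift_cm")
#' @export
simulate_trial <- function(profile = NULL, offset_cm = 0,
                           params = vhi_params(), noise = TRUE, seed = NULL) {
  if (!is.null(profile)) {
    pr <- as.list(profile)
    for (f in intersect(c("sigma_sp2", "b", "L", "kappa"), names(pr)))
      params[[f]] <- pr[[f]]
  }
  if (params$dt <= 0 || params$duration <= 0)
    stop("trial duration and dt must be positive", call. = FALSE)
  n <- as.integer(round(params$duration / params$dt))
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(noise)) {
    noise_p <- rnorm(n, 0, params$noise_sd_proprio)
    noise_v <- rnorm(n, 0, params$noise_sd_visual / 100)
  } else {
    noise_p <- noise_v <- numeric(n)
  }
  prec <- initial_precisions(params)
  sv_mean <- params$L / 100 * sin(0) + offset_cm / 100 # unbiased projection
  out <- integrate_trial_cpp(
    n, params$dt, params$L / 100, params$b / 100, params$m, params$gamma,
    params$K_a, params$kappa, params$kappa_in_nu,
    prec[["p"]], prec[["pd"]], prec[["v"]], prec[["c"]],
    params$floor_proprio, params$floor_visual,
    1 / params$sigma_mu[2],
    0, sv_mean, sv_mean, noise_p, noise_v, params$force_scale
  )
  mu0_final <- out$mu0[n]
  res <- tibble::tibble(
    time = (seq_len(n) - 1) * params$dt,
    force = out$force,
    mu0 = out$mu0,
    nu_cm = out$nu * 100
  )
  structure(res,
            class = c("vhi_trial", class(res)),
            offset_cm = offset_cm,
            params = params,
            proprio_drift_cm = params$L * sin(mu0_final),
            visual_drift_cm = out$nu[n] * 100 - offset_cm)
}

#' @export
print.vhi_trial <- function(x, ...) {
  cat(sprintf(
    "<vhi_trial> offset %+g cm | proprioceptive drift %+.3f cm | visual drift %+.3f cm\n",
    attr(x, "offset_cm"), attr(x, "proprio_drift_cm"), attr(x, "visual_drift_cm")))
  NextMethod()
}

#' Export a simulated trial to CSV
#'
#' Writes the trace columns with a commented metadata header block (condition
#' offset, drifts, key parameters), readable back with any CSV reader that
#' skips `#` lines.
#'
#' @param trial A `vhi_trial` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  p <- attr(trial, "params")
  hdr <- c(
    sprintf("# offset_cm: %g", attr(trial, "offset_cm")),
    sprintf("# proprio_drift_cm: %g", attr(trial, "proprio_drift_cm")),
    sprintf("# visual_drift_cm: %g", attr(trial, "visual_drift_cm")),
    sprintf("# kappa: %g; L_cm: %g; b_cm: %g; K_a: %g; dt_s: %g", p$kappa,
            p$L, p$b, p$K_a, p$dt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,force_N,mu0_rad,nu_cm", con)
  utils::write.table(as.data.frame(trial), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
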