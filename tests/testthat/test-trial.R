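test_that("compiled integrator reproduces the R reference step for step", {
  p <- vhi_params(b = 2, kappa = 0.7, sigma_sp2 = 0.8)
  n <- 300
  tr <- simulate_trial(offset_cm = 15, params = p, noise = FALSE)
  sv <- 15 / 100
  state <- list(mu0 = 0, mu1 = 0, mu2 = 0, nu = sv, a = 0,
                precisions = vhisim:::initial_precisions(p))
  sens <- list(s_p = 0, s_p_dot = 0, s_v = sv)
  for (t in 1:n) {
    state <- aif_step(state, sens, p)
    expect_equal(tr$mu0[t], state$mu0, tolerance = 1e-12)
    expect_equal(tr$nu_cm[t], state$nu * 100, tolerance = 1e-10)
    expect_equal(tr$force[t], p$force_scale * state$a, tolerance = 1e-12)
  }
})

test_that("trial traces are aligned, finite and bounded", {
  tr <- simulate_trial(offset_cm = -15, params = vhi_params(), noise = TRUE,
                       seed = 7)
  expect_equal(nrow(tr), 40000)
  expect_true(all(is.finite(tr$force) & is.finite(tr$mu0) &
                    is.finite(tr$nu_cm)))
  expect_true(all(abs(tr$mu0) < pi / 2))
  expect_lt(max(abs(tr$force)), 5) # bounded over the whole 40 s
  expect_identical(names(tr), c("time", "force", "mu0", "nu_cm"))
  expect_equal(tr$time[2] - tr$time[1], 0.001)
})

test_that("same seed reproduces a trial exactly; different seeds differ", {
  a <- simulate_trial(offset_cm = 15, noise = TRUE, seed = 11)
  b <- simulate_trial(offset_cm = 15, noise = TRUE, seed = 11)
  c <- simulate_trial(offset_cm = 15, noise = TRUE, seed = 12)
  expect_identical(a$force, b$force)
  expect_false(identical(a$force, c$force))
})

test_that("perceptual drifts point toward each other's cue", {
  for (off in c(-15, 15)) {
    tr <- simulate_trial(offset_cm = off, params = vhi_params(b = 0),
                         noise = FALSE)
    p <- attr(tr, "params")
    inferred_cm <- p$L * sin(tr$mu0[nrow(tr)])
    # inferred hand strictly between the true hand (0) and the virtual hand
    expect_true(inferred_cm > min(0, off) && inferred_cm < max(0, off))
    expect_gt(sign(inferred_cm) * sign(off), 0)
    # perceived virtual hand strictly between its display and the arm estimate
    nu_final <- tr$nu_cm[nrow(tr)]
    expect_true(nu_final > min(0, off) && nu_final < max(0, off))
    expect_equal(attr(tr, "proprio_drift_cm"), inferred_cm)
    expect_equal(attr(tr, "visual_drift_cm"), nu_final - off)
  }
})

test_that("trial configuration errors are caught", {
  expect_error(simulate_trial(params = vhi_params(dt = -1)), "dt")
  expect_error(vhi_params(duration = 0), "duration")
})

test_that("trial export round-trips through the CSV with metadata header", {
  tr <- simulate_trial(offset_cm = 15, noise = FALSE,
                       params = vhi_params(duration = 2))
  path <- tempfile(fileext = ".csv")
  write_trial(tr, path)
  lines <- readLines(path, n = 6)
  expect_true(any(grepl("^# offset_cm: 15", lines)))
  df <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(df), nrow(tr))
  expect_equal(df$force_N, tr$force, tolerance = 1e-9)
})
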