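# Independent oracles used across the suite. These re-derive expected values
# from first principles (closed forms, finite differences, explicit sums) and
# never call the code paths they check.

# Precision-weighted squared-error objective whose negative gradient drives
# the belief updates. Written directly from the generative model, independent
# of the package's gradient code. All positions in metres.
fe_objective <- function(mu0, mu1, mu2, nu, s_p, s_p_dot, s_v,
                         prec, params) {
  L <- params$L / 100
  b <- params$b / 100
  gv <- L * sin(mu0) + b
  ed2 <- mu2 + params$gamma * mu0 / params$m
  0.5 * (prec[["p"]] * (s_p - mu0)^2 +
           prec[["pd"]] * (s_p_dot - mu1)^2 +
           params$kappa * prec[["v"]] * (nu - gv)^2 +
           prec[["c"]] * (s_v - nu)^2 +
           (1 / params$sigma_mu[2]) * ed2^2)
}

# Central finite-difference gradient of fe_objective wrt (mu0, mu1, mu2, nu).
fe_num_grad <- function(belief, sens, prec, params, h = 1e-6) {
  f <- function(v) fe_objective(v[1], v[2], v[3], v[4],
                                sens$s_p, sens$s_p_dot, sens$s_v,
                                prec, params)
  x <- c(belief$mu0, belief$mu1, belief$mu2, belief$nu)
  vapply(1:4, function(i) {
    e <- numeric(4); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

random_gradient_case <- function() {
  params <- vhi_params(
    L = runif(1, 35, 55), b = runif(1, -5, 5),
    gamma = runif(1, 0.2, 2), m = runif(1, 0.5, 2),
    kappa = runif(1), sigma_mu = runif(3, 0.5, 2)
  )
  belief <- list(mu0 = runif(1, -0.5, 0.5), mu1 = runif(1, -0.3, 0.3),
                 mu2 = runif(1, -0.3, 0.3), nu = runif(1, -0.3, 0.3))
  sens <- list(s_p = runif(1, -0.5, 0.5), s_p_dot = runif(1, -0.3, 0.3),
               s_v = runif(1, -0.3, 0.3))
  prec <- c(p = runif(1, 0.5, 4), pd = runif(1, 0.5, 4),
            v = runif(1, 2.8, 6), c = runif(1, 0.5, 4))
  list(params = params, belief = belief, sens = sens, prec = prec)
}

# Balanced two-way ANOVA with interaction computed from explicit sums of
# squares over cell means (equal cell sizes assumed).
anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  N <- length(y); gm <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, interaction(a, b), mean)
  n_a <- tapply(y, a, length); n_b <- tapply(y, b, length)
  n_ab <- tapply(y, interaction(a, b), length)
  ss_a <- sum(n_a * (m_a - gm)^2)
  ss_b <- sum(n_b * (m_b - gm)^2)
  cells <- interaction(a, b)
  ss_cells <- sum(n_ab * (m_ab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - m_ab[cells])^2)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- N - nlevels(a) * nlevels(b)
  mse <- ss_e / df_e
  list(
    F_a = (ss_a / df_a) / mse, F_b = (ss_b / df_b) / mse,
    F_ab = (ss_ab / df_ab) / mse,
    df = c(df_a, df_b, df_ab, df_e),
    p_a = pf((ss_a / df_a) / mse, df_a, df_e, lower.tail = FALSE),
    p_b = pf((ss_b / df_b) / mse, df_b, df_e, lower.tail = FALSE),
    p_ab = pf((ss_ab / df_ab) / mse, df_ab, df_e, lower.tail = FALSE),
    mse = mse
  )
}

# Closed-form one-sample t (two-sided p unless stated).
t_oracle <- function(x, alternative = "two.sided") {
  n <- length(x)
  t <- mean(x) / (sd(x) / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), n - 1),
              greater = pt(t, n - 1, lower.tail = FALSE),
              less = pt(t, n - 1))
  list(t = t, df = n - 1, p = p)
}

# Small trial table with every required column, balanced per participant.
toy_trial_table <- function(values_by_pid_cond, group_of_pid) {
  purrr::map_dfr(names(values_by_pid_cond), function(pid) {
    purrr::map_dfr(names(values_by_pid_cond[[pid]]), function(cond) {
      v <- values_by_pid_cond[[pid]][[cond]]
      tibble::tibble(pid = as.integer(pid), group = group_of_pid[[pid]],
                     block = 1L, trial = seq_along(v), condition = cond,
                     mean_force_N = v)
    })
  })
}
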