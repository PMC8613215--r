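test_that("block offset removal centres each block exactly", {
  tr <- tibble::tibble(pid = 1, block = 1, time = 1:100 / 1000,
                       force = rep(0.5, 100))
  out <- remove_block_offset(tr)
  expect_equal(out$force, rep(0, 100))
  # two blocks with opposite offsets around an identical signal
  sig <- sin(1:200 / 30)
  tr2 <- tibble::tibble(pid = 1, block = rep(1:2, each = 200),
                        force = c(sig + 0.2, sig - 0.2))
  out2 <- remove_block_offset(tr2)
  expect_equal(out2$force[1:200], out2$force[201:400], tolerance = 1e-12)
  blk_means <- tapply(out2$force, tr2$block, mean)
  expect_true(all(abs(blk_means) < 1e-12))
  expect_error(remove_block_offset(tr2[0, ]), "empty")
  expect_error(remove_block_offset(tibble::tibble(force = 1)), "block")
})

test_that("window mean is the half-open 10-15 s average", {
  tr <- tibble::tibble(time = (0:39999) / 1000, force = 0.04)
  expect_equal(window_mean(tr), 0.04)
  # linear ramp 0 -> 0.4 N over 40 s: closed-form mean over [10, 15) is 0.125
  ramp <- tibble::tibble(time = (0:39999) / 1000, force = 0.4 * (0:39999) / 39999)
  expect_equal(window_mean(ramp), 0.125, tolerance = 1e-4)
  expect_equal(window_mean(ramp), mean(ramp$force[ramp$time >= 10 & ramp$time < 15]))
  expect_error(window_mean(tr, 10, 10), "empty window")
  expect_error(window_mean(tibble::tibble(time = 0:5, force = 0), 10, 15),
               "not covered")
})

test_that("two-way location-by-mode ANOVA matches an explicit sums-of-squares oracle", {
  # printed-size toy table: 2 groups x 3 conditions, n = 2 per cell
  vals <- list(
    "1" = list(Left = c(-0.05, -0.03), Center = c(0.01, -0.01),
               Right = c(0.04, 0.06)),
    "2" = list(Left = c(-0.02, -0.06), Center = c(0.02, 0.00),
               Right = c(0.03, 0.05))
  )
  tab <- toy_trial_table(vals, c("1" = "synchronous", "2" = "asynchronous"))
  fit <- anova_location_mode(tab)
  orc <- anova_oracle(tab$mean_force_N, tab$condition, tab$group)
  td <- tidy(fit)
  expect_equal(td$statistic[td$term == "location"], orc$F_a, tolerance = 1e-10)
  expect_equal(td$statistic[td$term == "mode"], orc$F_b, tolerance = 1e-10)
  expect_equal(td$statistic[td$term == "location:mode"], orc$F_ab,
               tolerance = 1e-10)
  expect_equal(td$p.value, c(orc$p_a, orc$p_b, orc$p_ab), tolerance = 1e-10)
  expect_equal(unique(td$df2), orc$df[4])
  expect_equal(td$df1, orc$df[1:3])
})

test_that("residual df at trial level is N - 6 and missing cells are named", {
  tab <- synth_force_table(n_participants = 4, seed = 1)
  fit <- anova_location_mode(tab)
  expect_equal(unique(tidy(fit)$df2), nrow(tab) - 6)
  bad <- dplyr::filter(tab, !(condition == "Left" & group == "synchronous"))
  expect_error(anova_location_mode(bad), "Left/synchronous")
})

test_that("mode F equals the squared pooled two-sample t on constructed instances", {
  set.seed(8)
  tab <- synth_force_table(effects = c(Left = 0, Center = 0, Right = 0),
                           n_participants = 6, sd_participant = 0,
                           sd_slope = 0, sd_trial = 0.1, seed = 8)
  fit <- anova_location_mode(tab)
  # pooled-error two-sample t computed from explicit cell means
  cells <- interaction(tab$condition, tab$group)
  mse <- sum(tapply(tab$mean_force_N, cells,
                    function(x) sum((x - mean(x))^2))) / (nrow(tab) - 6)
  g <- split(tab$mean_force_N, tab$group)
  n1 <- length(g[[1]]); n2 <- length(g[[2]])
  t_pooled <- (mean(g[[1]]) - mean(g[[2]])) /
    sqrt(mse * (1 / n1 + 1 / n2))
  td <- tidy(fit)
  expect_equal(td$statistic[td$term == "mode"], t_pooled^2, tolerance = 1e-10)
})

test_that("post-hoc t-tests match closed forms on a 3-participant toy table", {
  vals <- list(
    "1" = list(Left = -0.05, Center = 0.01, Right = 0.03),
    "2" = list(Left = -0.02, Center = -0.01, Right = 0.06),
    "3" = list(Left = -0.04, Center = 0.00, Right = 0.02)
  )
  tab <- toy_trial_table(vals, c("1" = "synchronous", "2" = "synchronous",
                                 "3" = "synchronous"))
  ph <- tidy(posthoc_tests(tab))
  center <- c(0.01, -0.01, 0.00)
  right_d <- c(0.03 - 0.01, 0.06 + 0.01, 0.02 - 0.00)
  left_d <- c(-0.05 - 0.01, -0.02 + 0.01, -0.04 - 0.00)
  oc <- t_oracle(center); orr <- t_oracle(right_d, "greater")
  ol <- t_oracle(left_d, "less")
  expect_equal(ph$statistic[ph$test == "center_vs_zero"], oc$t,
               tolerance = 1e-12)
  expect_equal(ph$p.value[ph$test == "center_vs_zero"], oc$p,
               tolerance = 1e-12)
  expect_equal(ph$statistic[ph$test == "right_vs_center"], orr$t,
               tolerance = 1e-12)
  expect_equal(ph$p.value[ph$test == "right_vs_center"], orr$p,
               tolerance = 1e-12)
  expect_equal(ph$p.value[ph$test == "left_vs_center"], ol$p,
               tolerance = 1e-12)
  expect_true(all(ph$df == 2))
  # the one-tailed companion of the center test is also reported
  expect_equal(ph$p.value[ph$test == "center_vs_zero_upper"],
               t_oracle(center, "greater")$p, tolerance = 1e-12)
})

test_that("degenerate post-hoc inputs are handled as stated limits", {
  vals <- list(
    "1" = list(Left = -0.03, Center = 0, Right = 0.02),
    "2" = list(Left = -0.03, Center = 0, Right = 0.02)
  )
  tab <- toy_trial_table(vals, c("1" = "a", "2" = "a"))
  ph <- tidy(posthoc_tests(tab))
  # all-zero center means: t = 0, two-sided p = 1
  expect_equal(ph$statistic[ph$test == "center_vs_zero"], 0)
  expect_equal(ph$p.value[ph$test == "center_vs_zero"], 1)
  # identical positive paired differences: strict rejection
  expect_equal(ph$statistic[ph$test == "right_vs_center"], Inf)
  expect_lt(ph$p.value[ph$test == "right_vs_center"], 1e-6)
  expect_lt(ph$p.value[ph$test == "left_vs_center"], 1e-6)
  # a missing condition is reported by name
  expect_error(posthoc_tests(dplyr::filter(tab, condition != "Right")),
               "Right")
})

test_that("statistics are invariant to constant shifts once blocks are centred", {
  set.seed(21)
  traces <- tidyr::expand_grid(pid = 1:4, block = 1:2, trial = 1:3,
                               condition = c("Left", "Center", "Right")) |>
    dplyr::mutate(force = rnorm(dplyr::n(), 0.02, 0.1),
                  group = ifelse(pid %% 2 == 1, "synchronous", "asynchronous"))
  as_table <- function(tr) tr |>
    dplyr::group_by(pid, group, block, trial, condition) |>
    dplyr::summarise(mean_force_N = mean(force), .groups = "drop")
  t1 <- as_table(remove_block_offset(traces))
  t2 <- as_table(remove_block_offset(dplyr::mutate(traces, force = force + 5)))
  expect_equal(tidy(anova_location_mode(t1)), tidy(anova_location_mode(t2)),
               tolerance = 1e-9)
  expect_equal(tidy(posthoc_tests(t1)), tidy(posthoc_tests(t2)),
               tolerance = 1e-9)
})

test_that("synthetic force tables have the full design and recover their effects", {
  tab <- synth_force_table(n_participants = 14, seed = 5)
  expect_equal(nrow(tab), 1680)
  expect_equal(unname(table(tab$condition)), rep(560L, 3), ignore_attr = TRUE)
  # zero effects, zero noise: everything exactly null
  null_tab <- synth_force_table(effects = c(Left = 0, Center = 0, Right = 0),
                                n_participants = 4, sd_trial = 0,
                                sd_participant = 0, sd_slope = 0, seed = 2)
  expect_true(all(null_tab$mean_force_N == 0))
  ph <- tidy(posthoc_tests(null_tab))
  expect_true(all(ph$statistic == 0))
  expect_true(all(ph$p.value[ph$alternative == "two.sided"] == 1))
  # effect recovery within 2 SE
  eff <- c(Left = -0.039, Center = 0, Right = 0.036)
  got <- tab |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(mean_force_N), se = sd(mean_force_N) / sqrt(dplyr::n()))
  for (cond in names(eff)) {
    row <- got[got$condition == cond, ]
    expect_lt(abs(row$m - eff[[cond]]), 2 * row$se +
                2 * 0.05 / sqrt(14)) # participant-level components
  }
})

test_that("trial tables round-trip through CSV with column mapping", {
  tab <- synth_force_table(n_participants = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  # foreign column names via col_map
  odd <- tab |> dplyr::rename(subject = pid, force = mean_force_N)
  utils::write.csv(as.data.frame(odd), path, row.names = FALSE)
  back2 <- read_trial_table(path, col_map = c(pid = "subject",
                                              mean_force_N = "force"))
  expect_equal(back2$mean_force_N, tab$mean_force_N, tolerance = 1e-12)
  expect_error(read_trial_table(path), "missing column")
})
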