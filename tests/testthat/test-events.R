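test_that("event trains honour mode delay windows and pairing", {
  ev <- vt_events("synchronous", duration = 40, mean_interval = 2, seed = 1)
  offs <- ev$tactile_time_s - ev$visual_time_s
  expect_true(nrow(ev) >= 17 && nrow(ev) <= 22) # ~ one pair per 2 s over 40 s
  expect_true(all(offs >= 0 & offs <= 0.1))
  expect_true(!is.unsorted(ev$visual_time_s) && !is.unsorted(ev$tactile_time_s))
  expect_true(all(ev$visual_time_s <= 40))

  ev <- vt_events("asynchronous", duration = 40, seed = 2)
  offs <- ev$tactile_time_s - ev$visual_time_s
  expect_true(all(offs >= 0.1 & offs <= 0.8))

  expect_error(vt_events("nonsense"), "arg")
  expect_error(vt_events("synchronous", duration = -1), "duration")
})

test_that("short trains degrade gracefully and seeds control everything", {
  ev <- vt_events("synchronous", duration = 0.5, mean_interval = 2, seed = 3)
  expect_lte(nrow(ev), 1)
  a <- vt_events("asynchronous", seed = 5)
  b <- vt_events("asynchronous", seed = 5)
  c <- vt_events("asynchronous", seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$tactile_time_s, c$tactile_time_s))
})

test_that("kappa map anchors, interpolates linearly and clamps", {
  mk <- function(offs) tibble::tibble(event_index = seq_along(offs),
                                      visual_time_s = 2 * seq_along(offs),
                                      tactile_time_s = 2 * seq_along(offs) + offs,
                                      mode = "test")
  expect_equal(kappa_from_synchrony(mk(rep(0, 20))), 1)
  expect_equal(kappa_from_synchrony(mk(rep(0.05, 20))), 1) # plateau <= 0.1 s
  # ideal asynchronous train: offsets at the uniform(0.1, 0.8) quantiles
  ideal <- 0.1 + 0.7 * (seq_len(20) - 0.5) / 20
  expect_equal(kappa_from_synchrony(mk(ideal)), 0, tolerance = 1e-12)
  # midpoint of the anchors -> 0.5 by linear interpolation
  expect_equal(kappa_from_synchrony(mk(rep((0.1 + 0.45) / 2, 10))), 0.5)
  expect_error(kappa_from_synchrony(mk(numeric(0))), "empty")
})

test_that("kappa is monotone non-increasing in mean delay; weak mode lands between", {
  mk <- function(m) tibble::tibble(event_index = 1, visual_time_s = 0,
                                   tactile_time_s = m, mode = "test")
  ms <- sort(runif(30, 0, 0.9))
  ks <- vapply(ms, function(m) kappa_from_synchrony(mk(m)), numeric(1))
  expect_true(all(diff(ks) <= 1e-12))
  kw <- vapply(1:20, function(s)
    kappa_from_synchrony(vt_events("weak_asynchronous", seed = s)), numeric(1))
  expect_gt(mean(kw), 0)
  expect_lt(mean(kw), 1)
  # the default mixing fraction emulates the experimental asynchronous setting
  expect_lt(abs(mean(kw) - 0.3), 0.12)
})

test_that("event trains round-trip through CSV", {
  ev <- vt_events("weak_asynchronous", seed = 4)
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12)
  expect_error(read_events(textConnection("a,b\n1,2")), "columns")
})
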