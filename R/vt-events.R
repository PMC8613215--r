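#' Generate a synthetic visuo-tactile event train
#'
#' Emulates the stimulation of the virtual-hand-illusion experiment: a
#' virtual ball bounces on the virtual hand roughly every `mean_interval`
#' seconds (visual event) and a coin vibrator on the real hand fires with a
#' mode-dependent delay (tactile event). In the synchronous mode the delay is
#' inside the window of perceived simultaneity (under 100 ms); in the
#' asynchronous mode it is drawn up to 800 ms; the weak-asynchronous mode
#' mixes in a fraction of near-synchronous pairs, emulating the implicit
#' causal binding that random vibration timing can still produce.
#'
#' @param mode One of `"synchronous"`, `"asynchronous"`,
#'   `"weak_asynchronous"`.
#' @param duration Train duration, s (default one 40-s trial).
#' @param mean_interval Mean spacing of visual events, s (a touch event about
#'   every two seconds).
#' @param sync_fraction For the weak-asynchronous mode, the fraction of pairs
#'   drawn from the synchronous delay window.
#' @param seed Optional integer seed.
#' @return A tibble of class `vhi_events` with columns `event_index`,
#'   `visual_time_s`, `tactile_time_s` and `mode`.
#' @examples
#' ev <- vt_events("synchronous", seed = 1)
#' nrow(ev)
#' @export
vt_events <- function(mode = c("synchronous", "asynchronous",
                               "weak_asynchronous"),
                      duration = 40, mean_interval = 2,
                      sync_fraction = 0.25, seed = NULL) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (mean_interval <= 0) stop("`mean_interval` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # visual events at jittered spacing (+-10% uniform on each interval)
  visual <- numeric(0)
  t <- 0
  repeat {
    t <- t + mean_interval * runif(1, 0.9, 1.1)
    if (t > duration) break
    visual <- c(visual, t)
  }
  n <- length(visual)
  offsets <- switch(mode,
    synchronous = runif(n, 0, 0.1),
    asynchronous = runif(n, 0.1, 0.8),
    weak_asynchronous = ifelse(runif(n) < sync_fraction,
                               runif(n, 0, 0.1), runif(n, 0.1, 0.8))
  )
  res <- tibble::tibble(
    event_index = seq_len(n),
    visual_time_s = visual,
    tactile_time_s = visual + offsets,
    mode = mode
  )
  class(res) <- c("vhi_events", class(res))
  res
}

#' Map visuo-tactile synchrony to the causality weight kappa
#'
#' Converts an event train into the causality parameter `kappa`, the believed
#' probability that visual and tactile events share a common source. The map
#' is a two-anchor linear function of the mean absolute visuo-tactile delay:
#' delays at or below `sync_anchor` (the 100 ms simultaneity window) give
#' `kappa = 1`; the expected mean delay of an ideal fully-random asynchronous
#' train (uniform on 0.1-0.8 s, i.e. `async_anchor = 0.45` s) gives
#' `kappa = 0`; in between, `kappa` decreases linearly, so a weak-asynchronous
#' train with residual near-synchronous pairs lands strictly between the two
#' (about 0.3 for the default mixing fraction, the value used for the
#' experimental asynchronous condition). Experimentally anchored discrete
#' settings (1, 0.3, or sweep values) can always be imposed directly through
#' `vhi_params(kappa = ...)`.
#'
#' @param events A `vhi_events` tibble (or any data frame with
#'   `visual_time_s` and `tactile_time_s`).
#' @param sync_anchor Mean delay at/below which `kappa` saturates at 1, s.
#' @param async_anchor Mean delay at/above which `kappa` reaches 0, s.
#' @return A single numeric `kappa` in `[0, 1]`.
#' @examples
#' kappa_from_synchrony(vt_events("asynchronous", seed = 2))
#' @export
kappa_from_synchrony <- function(events, sync_anchor = 0.1,
                                 async_anchor = 0.45) {
  if (nrow(events) == 0) stop("empty event train", call. = FALSE)
  m <- mean(abs(events$tactile_time_s - events$visual_time_s))
  min(max((async_anchor - m) / (async_anchor - sync_anchor), 0), 1)
}

#' Write / read an event train as CSV
#'
#' @param events A `vhi_events` tibble.
#' @param path File path.
#' @return `path` invisibly for the writer; a `vhi_events` tibble for the
#'   reader.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_index", "visual_time_s", "tactile_time_s", "mode")
  if (!all(need %in% names(df)))
    stop("event file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  res <- tibble::as_tibble(df[need])
  class(res) <- c("vhi_events", class(res))
  res
}
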