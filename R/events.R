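#' Select temporally isolated events
#'
#' Keeps events separated from the previous one by at least `min_pre_s`
#' (default 9 s) and from the next by at least `min_post_s` (default 15 s),
#' so the event-locked window is not contaminated by neighbouring trials.
#' The first and last events use the run boundaries as virtual neighbours.
#'
#' @param events an [event_list()] (sorted onsets).
#' @param min_pre_s minimum gap to the previous event, seconds.
#' @param min_post_s minimum gap to the next event, seconds.
#' @param run_T_s run duration in seconds.
#' @return Filtered [event_list()] (possibly empty).
#' @export
select_isolated_events <- function(events, min_pre_s = 9, min_post_s = 15,
                                   run_T_s) {
  n <- nrow(events)
  if (n == 0) return(events)
  on <- events$onset
  pre <- c(on[1] - 0, diff(on))
  post <- c(diff(on), run_T_s - on[n])
  events[pre >= min_pre_s & post >= min_post_s, , drop = FALSE]
}

#' Event-locked (time-locked) averaging with grand average
#'
#' Extracts a peri-event window around each onset (nearest-frame alignment,
#' no sub-frame interpolation), averages epochs within each subject, and
#' grand-averages across subjects with a 95% t-based confidence band of the
#' across-subject mean.  Event-locked responses survive the averaging while
#' components with random phase relative to the events (the traveling sLFO)
#' attenuate as 1/sqrt(N).
#'
#' @param series a numeric vector (one subject), or a list of vectors (one
#'   per subject).
#' @param events an [event_list()], or a list of one per subject.
#' @param window_s two reals, window relative to onset (default
#'   `c(-5, 25)` s, wide enough for the breath-hold response).
#' @param tr_seconds sampling interval.
#' @param baseline_correct subtract each epoch's pre-onset mean
#'   (default `TRUE`).
#' @return An `event_average`: `time` (seconds relative to onset), `mean`
#'   (grand average), `ci_low`/`ci_high`, `subject_curves` (matrix, one
#'   column per subject), `n_events` used per subject, `n_dropped` epochs
#'   exceeding run bounds.
#' @export
timelocked_average <- function(series, events, window_s = c(-5, 25),
                               tr_seconds, baseline_correct = TRUE) {
  if (!is.list(series)) series <- list(series)
  if (inherits(events, "event_list") || is.data.frame(events))
    events <- rep(list(events), length(series))
  stopifnot(length(events) == length(series))
  w0 <- round(window_s[1] / tr_seconds)
  w1 <- round(window_s[2] / tr_seconds)
  tt <- (w0:w1) * tr_seconds
  n_dropped <- 0L
  curves <- matrix(NA_real_, length(tt), length(series))
  n_events <- integer(length(series))
  for (s in seq_along(series)) {
    x <- series[[s]]
    nT <- length(x)
    ep <- list()
    for (on in events[[s]]$onset) {
      i0 <- round(on / tr_seconds) + 1L
      idx <- i0 + (w0:w1)
      if (idx[1] < 1L || idx[length(idx)] > nT) {
        n_dropped <- n_dropped + 1L
        warning("epoch at onset ", on, " s exceeds run bounds; dropped")
        next
      }
      e <- x[idx]
      if (baseline_correct && any(tt < 0)) e <- e - mean(e[tt < 0])
      ep[[length(ep) + 1L]] <- e
    }
    n_events[s] <- length(ep)
    if (length(ep))
      curves[, s] <- rowMeans(do.call(cbind, ep))
  }
  if (all(n_events == 0)) stop("no usable events after epoch extraction")
  used <- n_events > 0
  gm <- rowMeans(curves[, used, drop = FALSE])
  ns <- sum(used)
  if (ns > 1) {
    se <- apply(curves[, used, drop = FALSE], 1L, stats::sd) / sqrt(ns)
    tq <- stats::qt(0.975, ns - 1)
    ci_low <- gm - tq * se
    ci_high <- gm + tq * se
  } else {
    ci_low <- ci_high <- rep(NA_real_, length(gm))
  }
  structure(list(time = tt, mean = gm, ci_low = ci_low, ci_high = ci_high,
                 subject_curves = curves, n_events = n_events,
                 n_dropped = n_dropped, window_s = window_s),
            class = "event_average")
}

#' @export
print.event_average <- function(x, ...) {
  cat(sprintf(
    "event_average: window %g..%g s, %d subject(s), %s events (%d dropped)\n",
    x$window_s[1], x$window_s[2], ncol(x$subject_curves),
    paste(x$n_events, collapse = "/"), x$n_dropped))
  invisible(x)
}
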