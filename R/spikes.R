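# Spike-train summaries: detection, latency, firing rate, regime labels.

#' Detect spikes in a voltage trace
#'
#' Spikes are upward crossings of `v` through `threshold`; crossings closer
#' than `refractory_min` to the previous accepted spike are merged. The
#' model's spikes have amplitude around 2, so the default threshold 0.5
#' sits comfortably inside the spike upstroke; neither the threshold nor
#' the refractory window is part of the model itself.
#'
#' @param x an `fhr_trajectory`, or a numeric voltage series (then `times`
#'   is required).
#' @param threshold crossing threshold in v units (default 0.5).
#' @param refractory_min minimum separation between spikes in ms
#'   (default 2).
#' @param times sample times, for the numeric method.
#' @param ... unused.
#' @return Object of class `spike_train`: numeric vector of spike times with
#'   the detection settings and the trace's time range as attributes.
#' @export
#' @examples
#' t <- seq(0, 1000, 0.1)
#' detect_spikes(2 * sin(2 * pi * t / 50), times = t)
detect_spikes <- function(x, threshold = 0.5, refractory_min = 2, ...) {
  UseMethod("detect_spikes")
}

#' @rdname detect_spikes
#' @export
detect_spikes.fhr_trajectory <- function(x, threshold = 0.5,
                                         refractory_min = 2, ...) {
  detect_spikes(as.numeric(x$states[, "v"]), threshold = threshold,
                refractory_min = refractory_min, times = x$times)
}

#' @rdname detect_spikes
#' @export
detect_spikes.numeric <- function(x, threshold = 0.5, refractory_min = 2,
                                  times = NULL, ...) {
  if (is.null(times)) stop("'times' is required for a bare numeric series",
                           call. = FALSE)
  stopifnot(length(times) == length(x), refractory_min >= 0)
  n <- length(x)
  idx <- which(x[-1] >= threshold & x[-n] < threshold) + 1L
  st <- times[idx]
  keep <- numeric(0)
  last <- -Inf
  for (tt in st) {
    if (tt - last >= refractory_min) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  structure(keep, threshold = threshold, refractory_min = refractory_min,
            t_range = range(times), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes (threshold %g, refractory %g ms)\n",
              length(x), attr(x, "threshold"), attr(x, "refractory_min")))
  if (length(x)) cat("  first/last:", x[1], "/", x[length(x)], "ms\n")
  invisible(x)
}

#' First-spike latency
#'
#' Time from stimulus onset (t = 0) to the first detected spike; `NA` for an
#' empty train.
#'
#' @param train a `spike_train`.
#' @return Time in ms, or `NA_real_`.
#' @export
first_spike_latency <- function(train) {
  if (length(train) == 0L) NA_real_ else as.numeric(train)[1]
}

#' Firing rate over a window
#'
#' Spike count divided by window duration, in spikes per second (times are
#' in ms).
#'
#' @param train a `spike_train`.
#' @param window `c(start, end)` in ms; defaults to the full span of the
#'   source trace.
#' @return Rate in Hz.
#' @export
firing_rate <- function(train, window = NULL) {
  if (is.null(window)) window <- attr(train, "t_range")
  stopifnot(length(window) == 2L)
  dur <- window[2] - window[1]
  if (!is.finite(dur) || dur <= 0)
    stop("window must have positive duration", call. = FALSE)
  tt <- as.numeric(train)
  1000 * sum(tt >= window[1] & tt <= window[2]) / dur
}

#' Classify the firing regime of a trajectory
#'
#' Heuristic labelling of the post-transient window as one of `quiescent`,
#' `tonic_spiking`, `bursting` or `mixed_mode`:
#' \itemize{
#'   \item `quiescent`: no post-transient spikes and the terminal state
#'     within `eq_tol` (componentwise) of the equilibrium;
#'   \item `bursting`: spikes whose inter-spike intervals are strongly
#'     bimodal (some gap exceeds 5x the median interval);
#'   \item `mixed_mode`: large spikes interleaved with sub-threshold
#'     oscillations (sub-threshold local maxima of prominence comparable to
#'     the spike count), or sustained sub-threshold oscillation with no
#'     spikes at all;
#'   \item `tonic_spiking`: everything else with spikes.
#' }
#' The labels are qualitative diagnostics, not acceptance-grade quantities;
#' only the quiescent/non-quiescent dichotomy is tied to the analytic
#' stability threshold.
#'
#' @param traj an `fhr_trajectory`.
#' @param threshold,refractory_min passed to [detect_spikes()].
#' @param transient_fraction fraction of initial samples ignored.
#' @param eq_tol tolerance on the terminal distance to the equilibrium.
#' @return List of class `fhr_regime` with `label` and `diagnostics`
#'   (spike count, ISI coefficient of variation, post-transient voltage
#'   amplitude, terminal distance to equilibrium).
#' @export
classify_regime <- function(traj, threshold = 0.5, refractory_min = 2,
                            transient_fraction = 0.5, eq_tol = 0.05) {
  stopifnot(inherits(traj, "fhr_trajectory"))
  n <- nrow(traj$states)
  t_cut <- traj$times[floor(n * transient_fraction) + 1]
  win <- traj$times >= t_cut
  vwin <- traj$states[win, "v"]
  train <- detect_spikes(traj, threshold = threshold,
                         refractory_min = refractory_min)
  sp <- as.numeric(train)[as.numeric(train) >= t_cut]
  eq <- tryCatch(fhr_equilibrium(traj$params), error = function(e) NULL)
  term_dist <- if (is.null(eq)) NA_real_ else
    max(abs(traj$states[n, ] - c(eq$v_star, eq$w_star, eq$y_star)))
  amp <- diff(range(vwin))
  isi <- diff(sp)
  cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_

  label <- if (length(sp) == 0 && is.finite(term_dist) &&
               term_dist <= eq_tol) {
    "quiescent"
  } else if (length(sp) == 0) {
    "mixed_mode"   # sustained sub-threshold oscillation / slow drift
  } else if (length(isi) >= 3 && max(isi) > 5 * median(isi)) {
    "bursting"
  } else {
    # sub-threshold local maxima with real prominence, between spikes
    im <- which(diff(sign(diff(vwin))) == -2) + 1L
    sub <- vwin[im]
    n_sub <- sum(sub < threshold & sub > min(vwin) + 0.1)
    if (n_sub >= length(sp)) "mixed_mode" else "tonic_spiking"
  }
  structure(list(label = label,
                 diagnostics = list(n_spikes = length(sp), cv_isi = cv,
                                    amplitude = amp,
                                    terminal_dist = term_dist)),
            class = "fhr_regime")
}

#' @export
print.fhr_regime <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "Firing regime: %s (%d spikes, CV(ISI)=%s, amplitude=%.3g, dist(eq)=%.3g)\n",
    x$label, d$n_spikes, format(d$cv_isi, digits = 3), d$amplitude,
    d$terminal_dist))
  invisible(x)
}
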