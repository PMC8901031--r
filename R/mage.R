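#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Classical turning-point MAGE in the style of Service: glycemic
#' excursions are peak-to-nadir swings of the glucose trace, and MAGE is
#' the mean amplitude of the swings that exceed `k` times the whole-record
#' SD, counted once each in the direction (nadir-to-peak or peak-to-nadir)
#' of the first qualifying swing.
#'
#' The algorithm, in full, so results are reproducible across
#' implementations:
#' 1. Smooth the trace with a centered moving average of `smooth_window`
#'    readings (odd; the window shrinks symmetrically at the record edges).
#' 2. Collapse runs of equal smoothed values (plateaus) to their midpoint
#'    and extract the turning points where the smoothed trace changes
#'    direction; the first and last points of the record are included as
#'    boundary turning points, so incomplete leading/trailing excursions
#'    are counted.
#' 3. Refine each turning point to the raw extremum within half a window of
#'    it, and read amplitudes from the raw (not smoothed) readings —
#'    smoothing locates excursions but must not attenuate them.
#' 4. Keep amplitudes strictly greater than `k * SD(raw)`; MAGE is the mean
#'    of the qualifying amplitudes whose direction matches the first
#'    qualifying swing.
#'
#' @inheritParams interday_mean
#' @param k Excursion threshold in whole-record SDs (default 1).
#' @param smooth_window Moving-average window in readings; must be odd
#'   (default 9, i.e. 45 min at a 5-min cadence).
#' @return mg/dL, with attributes `n_excursions` (qualifying swings in the
#'   counted direction) and `threshold` (mg/dL); an [undefined_metric()]
#'   when no swing exceeds the threshold.
#' @examples
#' s <- simulate_cgm(sim_profile(
#'   baseline = 100, circadian_amplitude = 0, noise_sd = 0,
#'   meal_events = list(c(12, 80, 30, 60)), n_days = 3, seed = 1
#' ))
#' mage(s)  # recovers the constructed 80 mg/dL excursion
#' @export
mage <- function(data, k = 1, smooth_window = 9) {
  if (!is.numeric(smooth_window) || length(smooth_window) != 1 ||
      smooth_window < 1 || smooth_window %% 2 != 1) {
    abort("`smooth_window` must be a single odd positive integer.",
          class = "cgm_parameter_error")
  }
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    abort("`k` must be a single non-negative number.",
          class = "cgm_parameter_error")
  }
  data <- prep_series(data)
  g <- data$glucose
  n <- length(g)
  if (n < 3) {
    return(undefined_metric("fewer than 3 readings"))
  }
  threshold <- k * stats::sd(g)

  ext <- mage_extrema(g, smooth_window)
  if (length(ext$value) < 2) {
    return(undefined_metric("no glycemic excursions (trace is flat)"))
  }
  amp <- abs(diff(ext$value))
  up <- diff(ext$value) > 0
  qualifying <- amp > threshold
  if (!any(qualifying)) {
    return(undefined_metric(
      sprintf("no excursion exceeds %g SD (%.3g mg/dL)", k, threshold)
    ))
  }
  first_dir <- up[which(qualifying)[1]]
  counted <- qualifying & up == first_dir
  out <- mean(amp[counted])
  attr(out, "n_excursions") <- sum(counted)
  attr(out, "threshold") <- threshold
  out
}

# Turning points of the smoothed trace, refined to raw extrema.
# Returns list(index, value, is_max) in time order, strictly alternating.
mage_extrema <- function(g, smooth_window) {
  n <- length(g)
  h <- (smooth_window - 1) / 2
  sm <- moving_average(g, smooth_window)

  # plateau runs of the smoothed trace -> representative midpoints
  run_end <- c(which(diff(sm) != 0), n)
  run_start <- c(1, head(run_end, -1) + 1)
  rep_idx <- floor((run_start + run_end) / 2)
  v <- sm[rep_idx]
  m <- length(v)
  if (m < 2) {
    return(list(index = integer(0), value = numeric(0), is_max = logical(0)))
  }

  # turning runs: endpoints always; interior runs where direction flips
  dirs <- sign(diff(v))
  turning <- c(TRUE, if (m > 2) dirs[-1] != dirs[-(m - 1)] else logical(0),
               TRUE)
  t_idx <- rep_idx[turning]
  t_val <- v[turning]
  is_max <- logical(length(t_idx))
  pos <- which(turning)
  for (j in seq_along(pos)) {
    p <- pos[j]
    is_max[j] <- if (p == 1) v[2] < v[1] else v[p] > v[p - 1]
  }

  # refine to the raw extremum within half a smoothing window
  r_idx <- integer(length(t_idx))
  r_val <- numeric(length(t_idx))
  for (j in seq_along(t_idx)) {
    win <- max(1, t_idx[j] - h):min(n, t_idx[j] + h)
    w <- if (is_max[j]) win[which.max(g[win])] else win[which.min(g[win])]
    r_idx[j] <- w
    r_val[j] <- g[w]
  }

  # merge consecutive extrema of the same type, keeping the more extreme
  keep <- rep(TRUE, length(r_idx))
  last <- 1
  for (j in seq_along(r_idx)[-1]) {
    if (is_max[j] == is_max[last]) {
      better <- if (is_max[j]) r_val[j] > r_val[last] else r_val[j] < r_val[last]
      if (better) {
        keep[last] <- FALSE
        last <- j
      } else {
        keep[j] <- FALSE
      }
    } else {
      last <- j
    }
  }
  list(index = r_idx[keep], value = r_val[keep], is_max = is_max[keep])
}

# Centered moving average with symmetric edge shrinkage: at position i the
# half-window is min(h, i - 1, n - i), so edges are smoothed less rather
# than dropped.
moving_average <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hw <- min(h, i - 1, n - i)
    out[i] <- mean(x[(i - hw):(i + hw)])
  }
  out
}
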