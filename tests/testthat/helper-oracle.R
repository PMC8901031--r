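# Independent brute-force oracles: explicit loops and first-principles
# formulas, no shared code with the package internals. Fine for the
# <= 600-reading fixtures they are used on.

o_mean <- function(g) {
  s <- 0
  for (x in g) s <- s + x
  s / length(g)
}

o_median <- function(g) {
  g <- sort(g)
  n <- length(g)
  if (n %% 2 == 1) g[(n + 1) / 2] else (g[n / 2] + g[n / 2 + 1]) / 2
}

# Linearly interpolated quantile (R type 7) from the textbook formula.
o_quantile <- function(g, p) {
  g <- sort(g)
  h <- (length(g) - 1) * p
  lo <- floor(h)
  fr <- h - lo
  if (fr == 0) g[lo + 1] else g[lo + 1] + fr * (g[lo + 2] - g[lo + 1])
}

o_sd <- function(g) {
  m <- o_mean(g)
  s <- 0
  for (x in g) s <- s + (x - m)^2
  sqrt(s / (length(g) - 1))
}

o_cv <- function(g) 100 * o_sd(g) / o_mean(g)

o_day_split <- function(series) {
  split(series$glucose, format(series$time, "%Y-%m-%d", tz = "UTC"))
}

o_intraday <- function(series, stat) {
  vals <- c()
  for (day in o_day_split(series)) {
    if (length(day) >= 2) vals <- c(vals, stat(day))
  }
  list(mean = o_mean(vals), median = o_median(vals),
       sd = if (length(vals) >= 2) o_sd(vals) else NA_real_)
}

o_band <- function(g, k) o_mean(g) + c(-1, 1) * k * o_sd(g)

o_tir <- function(series, k, sr) {
  b <- o_band(series$glucose, k)
  n_in <- 0
  for (x in series$glucose) if (x >= b[1] && x <= b[2]) n_in <- n_in + 1
  n_in * sr
}

o_clinical <- function(series, hypo, hyper, sr) {
  below <- 0; inside <- 0; above <- 0
  for (x in series$glucose) {
    if (x < hypo) below <- below + 1
    else if (x > hyper) above <- above + 1
    else inside <- inside + 1
  }
  c(below, inside, above) * sr
}

o_mge_mgn <- function(g, k) {
  b <- o_band(g, k)
  out_sum <- 0; out_n <- 0; in_sum <- 0; in_n <- 0
  for (x in g) {
    if (x < b[1] || x > b[2]) {
      out_sum <- out_sum + x; out_n <- out_n + 1
    } else {
      in_sum <- in_sum + x; in_n <- in_n + 1
    }
  }
  list(mge = if (out_n > 0) out_sum / out_n else NA_real_,
       mgn = if (in_n > 0) in_sum / in_n else NA_real_)
}

o_risk <- function(g) {
  f <- 1.509 * ((log(g))^1.084 - 5.381)
  list(f = f,
       rl = ifelse(f < 0, 10 * f^2, 0),
       rh = ifelse(f > 0, 10 * f^2, 0))
}

o_lbgi <- function(g) o_mean(o_risk(g)$rl)
o_hbgi <- function(g) o_mean(o_risk(g)$rh)

o_adrr <- function(series) {
  days <- split(seq_len(nrow(series)),
                format(series$time, "%Y-%m-%d", tz = "UTC"))
  rr <- c()
  for (idx in days) {
    if (length(idx) < 2) next
    r <- o_risk(series$glucose[idx])
    rr <- c(rr, max(r$rl) + max(r$rh))
  }
  if (length(rr) == 0) NA_real_ else o_mean(rr)
}

# Exhaustive-search lag pairing: for reading i, every j is a candidate;
# nearest |t_j - (t_i - lag)| within tolerance wins, ties to the earlier.
o_lag_diffs <- function(series, lag_hours, tol_min) {
  t_min <- as.numeric(series$time) / 60
  diffs <- c()
  for (i in seq_along(t_min)) {
    target <- t_min[i] - lag_hours * 60
    best <- NA; best_d <- Inf
    for (j in seq_along(t_min)) {
      d <- abs(t_min[j] - target)
      if (d <= tol_min && d < best_d) {
        best <- j; best_d <- d
      }
    }
    if (!is.na(best)) diffs <- c(diffs, series$glucose[i] - series$glucose[best])
  }
  diffs
}

o_modd <- function(series, tol_min) {
  d <- o_lag_diffs(series, 24, tol_min)
  if (length(d) == 0) NA_real_ else o_mean(abs(d))
}

o_conga <- function(series, n_hours, tol_min) {
  d <- o_lag_diffs(series, n_hours, tol_min)
  if (length(d) < 2) NA_real_ else o_sd(d)
}

# MAGE by explicit per-step loops, following the documented convention:
# shrinking-edge moving average, plateau runs to midpoints, boundary +
# direction-flip turning points, raw-extremum refinement within half a
# window, same-type merge, amplitudes > k*SD counted in the direction of
# the first qualifying swing.
o_mage <- function(series, k = 1, window = 9) {
  g <- series$glucose
  n <- length(g)
  h <- (window - 1) / 2
  sm <- numeric(n)
  for (i in 1:n) {
    hw <- min(h, i - 1, n - i)
    sm[i] <- mean(g[(i - hw):(i + hw)])
  }
  # plateau runs
  starts <- 1
  for (i in 2:n) if (sm[i] != sm[i - 1]) starts <- c(starts, i)
  ends <- c(starts[-1] - 1, n)
  reps <- floor((starts + ends) / 2)
  v <- sm[reps]
  m <- length(v)
  if (m < 2) return(NA_real_)
  # turning runs (boundaries always in)
  turning <- c(TRUE)
  if (m > 2) {
    for (j in 2:(m - 1)) {
      turning <- c(turning, sign(v[j] - v[j - 1]) != sign(v[j + 1] - v[j]))
    }
  }
  turning <- c(turning, TRUE)
  idx <- reps[turning]; val <- v[turning]
  is_max <- logical(length(idx))
  pos <- which(turning)
  for (j in seq_along(pos)) {
    p <- pos[j]
    is_max[j] <- if (p == 1) v[2] < v[1] else v[p] > v[p - 1]
  }
  # refine to raw extremum
  for (j in seq_along(idx)) {
    win <- max(1, idx[j] - h):min(n, idx[j] + h)
    w <- if (is_max[j]) win[which.max(g[win])] else win[which.min(g[win])]
    idx[j] <- w; val[j] <- g[w]
  }
  # merge consecutive same-type extrema
  keep <- rep(TRUE, length(idx)); last <- 1
  for (j in seq_along(idx)[-1]) {
    if (is_max[j] == is_max[last]) {
      better <- if (is_max[j]) val[j] > val[last] else val[j] < val[last]
      if (better) { keep[last] <- FALSE; last <- j } else keep[j] <- FALSE
    } else last <- j
  }
  val <- val[keep]
  if (length(val) < 2) return(NA_real_)
  amp <- abs(diff(val)); up <- diff(val) > 0
  thr <- k * o_sd(g)
  q <- amp > thr
  if (!any(q)) return(NA_real_)
  dir0 <- up[which(q)[1]]
  o_mean(amp[q & up == dir0])
}
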