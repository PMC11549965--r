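# Single-channel planar-bilayer electrophysiology: simulation and
# analysis of insertion staircases.
#
# Units: current in pA, voltage in mV, conductance in pS, time in
# seconds.  G [pS] * V [mV] * 1e-3 = I [pA].

#' Simulate a single-channel insertion recording
#'
#' Generates the staircase current trace of sequential pore insertions
#' in a planar bilayer: after the k-th insertion the mean current is
#' `k * G_single * V * 1e-3` pA, with additive white Gaussian noise.
#'
#' @param G_single single-channel conductance, pS.
#' @param voltage applied voltage, mV.
#' @param insertion_times event times in seconds (all < `duration`).
#' @param noise_sd noise standard deviation, pA (>= 0).
#' @param sampling_rate Hz.
#' @param duration recording length, seconds.
#' @param seed integer seed; the trace is deterministic given the seed.
#' @return a `current_trace` data frame with columns `t` (s) and `I`
#'   (pA); sampling rate, voltage and the generative parameters are kept
#'   as attributes.
#' @examples
#' tr <- simulate_trace(108, 100, c(1, 2, 3), noise_sd = 1,
#'                      sampling_rate = 2000, duration = 5, seed = 1)
#' @export
simulate_trace <- function(G_single, voltage = 100, insertion_times = c(1),
                           noise_sd = 1, sampling_rate = 5000,
                           duration = 10, seed = 1) {
  if (duration <= 0 || sampling_rate <= 0)
    stop("duration and sampling_rate must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(insertion_times) && max(insertion_times) >= duration)
    stop("all insertion_times must precede duration")
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  level <- vapply(t, function(tt) sum(insertion_times <= tt), numeric(1))
  step_pA <- G_single * voltage * 1e-3
  old <- .Random.seed_save()
  set.seed(seed)
  I <- level * step_pA + stats::rnorm(length(t), 0, noise_sd)
  .Random.seed_restore(old)
  out <- data.frame(t = t, I = I)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "voltage") <- voltage
  attr(out, "meta") <- list(G_single = G_single, noise_sd = noise_sd,
                            insertion_times = insertion_times, seed = seed)
  class(out) <- c("current_trace", "data.frame")
  out
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %.3g s at %g Hz, %g mV; I in [%.1f, %.1f] pA\n",
              nrow(x) / attr(x, "sampling_rate"), attr(x, "sampling_rate"),
              attr(x, "voltage"), min(x$I), max(x$I)))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  graphics::plot(x$t, x$I, type = "l", xlab = "time (s)",
                 ylab = "current (pA)", ...)
  invisible(x)
}

#' Detect insertion/closure steps in a current trace
#'
#' Change-point detection by a two-sided sliding-window mean difference:
#' at each sample the means of the preceding and following `window`
#' seconds are compared; local extrema of the difference above
#' `max(min_step, k * sigma_noise)` are reported as events, where
#' `sigma_noise` is a robust noise scale (median absolute deviation of
#' the first differences / sqrt(2)).  Events closer than `window` are
#' merged.  The step amplitude `delta_I` is the difference of the level
#' means after and before the event.
#'
#' @param trace a `current_trace` (or data frame with `t`, `I`).
#' @param min_step minimum detectable step, pA (default 5).
#' @param window half-window for the sliding means, seconds
#'   (default 0.02).
#' @param k robust threshold multiplier on the noise sd (default 5).
#' @return a `jump_events` data frame: `time` (s), `delta_I` (pA),
#'   `pre_mean`, `post_mean` (pA), `sign` (`"insertion"`/`"closure"`).
#' @export
detect_jumps <- function(trace, min_step = 5, window = 0.02, k = 5) {
  I <- trace$I; t <- trace$t
  n <- length(I)
  sr <- attr(trace, "sampling_rate")
  if (is.null(sr)) sr <- 1 / stats::median(diff(t))
  w <- max(2L, round(window * sr))
  if (2 * w >= n) stop("window must be shorter than half the trace")
  cs <- c(0, cumsum(I))
  # sliding means: pre[i] = mean(I[(i-w):(i-1)]), post[i] = mean(I[i:(i+w-1)])
  idx <- (w + 1):(n - w + 1)
  pre_m <- (cs[idx] - cs[idx - w]) / w
  post_m <- (cs[idx + w] - cs[idx]) / w
  d <- post_m - pre_m
  sig <- stats::mad(diff(I)) / sqrt(2)
  thr <- max(min_step, k * sig)
  cand <- which(abs(d) >= thr)
  if (!length(cand)) {
    return(structure(data.frame(time = numeric(), delta_I = numeric(),
                                pre_mean = numeric(), post_mean = numeric(),
                                sign = character()),
                     class = c("jump_events", "data.frame")))
  }
  # group candidates closer than the window, keep the |d| maximum of each
  grp <- cumsum(c(1, diff(cand) > w))
  picks <- vapply(split(cand, grp), function(g) g[which.max(abs(d[g]))],
                  numeric(1))
  ev <- do.call(rbind, lapply(picks, function(p) {
    i <- idx[p]
    pre <- mean(I[max(1, i - w):(i - 1)])
    post <- mean(I[i:min(n, i + w - 1)])
    data.frame(time = t[i], delta_I = post - pre,
               pre_mean = pre, post_mean = post,
               sign = if (post > pre) "insertion" else "closure")
  }))
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  class(ev) <- c("jump_events", "data.frame")
  ev
}

#' Histogram and Gaussian fit of single-channel current jumps
#'
#' Builds the histogram of insertion step amplitudes up to
#' `max_current` and fits a single Gaussian to the smallest-amplitude
#' cluster (events within +/-40 % of the smallest cluster center, which
#' excludes multi-insertion jumps at integral multiples), by
#' least squares on the bin counts with a moment fallback for degenerate
#' (near-zero spread) data.
#'
#' @param events a `jump_events` data frame (insertions are used).
#' @param bin_width histogram bin width, pA (default 1).
#' @param max_current amplitude cutoff, pA (default 50).
#' @return a `histogram_fit` list: `mu`, `sd` (pA), `n_events`,
#'   `breaks`, `counts`.
#' @export
fit_single_channel <- function(events, bin_width = 1, max_current = 50) {
  amps <- events$delta_I[events$sign == "insertion"]
  amps <- amps[amps > 0 & amps <= max_current]
  if (length(amps) < 5)
    stop("need at least 5 insertion events for a histogram fit")
  # smallest-amplitude cluster: iterate a +/-40 % window around the
  # running center, starting from the smallest observed jump
  ctr <- min(amps)
  for (it in 1:10) {
    sel <- amps[amps >= 0.6 * ctr & amps <= 1.4 * ctr]
    new_ctr <- stats::median(sel)
    if (abs(new_ctr - ctr) < 1e-9) break
    ctr <- new_ctr
  }
  cl <- amps[amps >= 0.6 * ctr & amps <= 1.4 * ctr]
  breaks <- seq(0, max_current + bin_width, by = bin_width)
  h <- graphics::hist(cl, breaks = breaks, plot = FALSE)
  mu0 <- mean(cl); sd0 <- stats::sd(cl)
  if (is.na(sd0) || sd0 < bin_width / 4) {
    fit <- list(mu = mu0, sd = ifelse(is.na(sd0), 0, sd0))
  } else {
    mids <- h$mids; cnt <- h$counts
    # least squares on the bin counts; sparse histograms can defeat the
    # Gauss-Newton fit, in which case the moment estimates stand
    est <- tryCatch(suppressWarnings({
      nf <- stats::nls(cnt ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
                       start = list(A = max(cnt), mu = mu0, s = sd0))
      co <- stats::coef(nf)
      list(mu = unname(co["mu"]), sd = abs(unname(co["s"])))
    }), error = function(e) list(mu = mu0, sd = sd0))
    fit <- est
  }
  structure(list(mu = fit$mu, sd = fit$sd, n_events = length(cl),
                 breaks = breaks, counts = h$counts,
                 n_total = length(amps)),
            class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf("Single-channel jump fit: mu = %.2f pA, sd = %.2f pA (n = %d of %d jumps)\n",
              x$mu, x$sd, x$n_events, x$n_total))
  invisible(x)
}

#' @export
plot.histogram_fit <- function(x, ...) {
  mids <- x$breaks[-1] - diff(x$breaks) / 2
  graphics::plot(mids, x$counts, type = "h", lwd = 3,
                 xlab = "current jump (pA)", ylab = "count", ...)
  if (x$sd > 0) {
    xx <- seq(min(x$breaks), max(x$breaks), length.out = 200)
    graphics::lines(xx, max(x$counts) *
                      exp(-(xx - x$mu)^2 / (2 * x$sd^2)), col = 2)
  }
  invisible(x)
}

#' Single-channel conductance from a histogram fit
#'
#' @param fit a `histogram_fit`.
#' @param voltage applied voltage, mV (nonzero).
#' @return list with `G` (pS) and `se` (standard error, pS).
#' @examples
#' ## mu = 10.8 pA at 100 mV -> 108 pS
#' @export
conductance_from_fit <- function(fit, voltage) {
  if (voltage == 0) stop("voltage must be nonzero")
  G <- fit$mu / (voltage * 1e-3)
  se <- fit$sd / sqrt(fit$n_events) / abs(voltage * 1e-3)
  list(G = abs(G), se = se)
}

#' Current/voltage analysis across recordings
#'
#' Computes the mean steady-state current per voltage and checks that
#' |I| increases monotonically with |V| on each sign branch, as expected
#' for a quiet ohmic-like pore; asymmetry between branches
#' (rectification) is reported but not flagged.
#'
#' @param traces list of `current_trace` objects recorded at different
#'   voltages (>= 3 voltages spanning both signs).
#' @param tail_frac fraction of each trace (from the end) used as the
#'   steady state (default 0.5).
#' @return an `iv_curve` list: `curve` (data frame voltage/current/G),
#'   `monotone` (per-branch logical), `rectification` (G+ / G-).
#' @export
iv_analysis <- function(traces, tail_frac = 0.5) {
  V <- vapply(traces, function(tr) attr(tr, "voltage"), numeric(1))
  if (length(unique(V)) < 3 || !any(V > 0) || !any(V < 0))
    stop("need >= 3 voltages spanning both signs")
  I <- vapply(traces, function(tr) {
    n <- nrow(tr)
    mean(tr$I[ceiling((1 - tail_frac) * n):n])
  }, numeric(1))
  ord <- order(V)
  curve <- data.frame(voltage = V[ord], current = I[ord],
                      G = I[ord] / (V[ord] * 1e-3))
  mono_branch <- function(sgn) {
    b <- curve[sign(curve$voltage) == sgn, ]
    b <- b[order(abs(b$voltage)), ]
    if (nrow(b) < 2) return(TRUE)
    all(diff(abs(b$current)) > 0)
  }
  Gp <- mean(curve$G[curve$voltage > 0])
  Gm <- mean(curve$G[curve$voltage < 0])
  structure(list(curve = curve,
                 monotone = c(positive = mono_branch(1),
                              negative = mono_branch(-1)),
                 rectification = Gp / Gm),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat("I/V analysis:\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("monotone: + %s, - %s; rectification G+/G- = %.2f\n",
              x$monotone["positive"], x$monotone["negative"],
              x$rectification))
  invisible(x)
}

#' Read / write current traces
#'
#' Two-column tab-separated dialect: `time_s`, `current_pA`, with `#`
#' header lines carrying `voltage_mV` and `sampling_rate_Hz`; the
#' sampling rate is inferred from the time column when absent.
#'
#' @param trace a `current_trace`.
#' @param path file path.
#' @return `write_trace` returns the path; `read_trace` a
#'   `current_trace`.
#' @export
write_trace <- function(trace, path) {
  hdr <- c(sprintf("# voltage_mV\t%g", attr(trace, "voltage")),
           sprintf("# sampling_rate_Hz\t%g", attr(trace, "sampling_rate")),
           "# time_s\tcurrent_pA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(t = sprintf("%.6f", trace$t),
                                I = sprintf("%.4f", trace$I)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(key, hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*\t", "", m[1])) else NA_real_
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           col.names = c("t", "I"))
  out <- data.frame(t = dat$t, I = dat$I)
  sr <- getv("sampling_rate_Hz")
  if (is.na(sr)) sr <- 1 / stats::median(diff(dat$t))
  attr(out, "sampling_rate") <- sr
  attr(out, "voltage") <- getv("voltage_mV")
  class(out) <- c("current_trace", "data.frame")
  out
}
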