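#' Step-detector configuration
#'
#' Settings for the change-point step detector and the trace quality
#' filter. Defaults mirror the published analysis settings for this class
#' of data: acceptance threshold ("critical value") 15, minimum 15 points
#' per fitted level, and an SNR filter at 5.
#'
#' @param critical_value Threshold on the standardized mean-shift statistic
#'   for accepting a change point (> 0).
#' @param min_points_per_level Minimum samples per fitted level (>= 2).
#' @param snr_threshold Traces with SNR at or below this are rejected.
#' @param merge_tolerance Fitted levels closer than
#'   `merge_tolerance * noise` are merged into one level.
#' @return A list of class `step_detector_config`.
#' @export
step_detector_config <- function(critical_value = 15,
                                 min_points_per_level = 15,
                                 snr_threshold = 5,
                                 merge_tolerance = 3) {
  if (critical_value <= 0 || min_points_per_level < 2 ||
      snr_threshold <= 0 || merge_tolerance <= 0) {
    abort("All step-detector settings must be positive (min points >= 2).")
  }
  structure(
    list(critical_value = critical_value,
         min_points_per_level = as.integer(min_points_per_level),
         snr_threshold = snr_threshold,
         merge_tolerance = merge_tolerance),
    class = "step_detector_config"
  )
}

# robust per-frame noise: MAD of first differences; differencing of iid
# noise inflates the SD by sqrt(2)
robust_noise_ <- function(x) {
  if (length(x) < 3) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

check_trace_ <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_s", "intensity") %in%
                                    names(trace))) {
    abort("A trace must be a data frame with columns `time_s`, `intensity`.")
  }
  if (nrow(trace) < 2) abort("A trace needs at least 2 samples.")
  dt <- diff(trace$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1))) {
    abort("Trace samples must be uniformly spaced.")
  }
  invisible(trace)
}

#' Signal-to-noise ratio of an intensity trace
#'
#' SNR is the drop from the initial plateau to the final plateau (means of
#' the first and last `plateau_frames` samples) divided by a robust
#' per-frame noise estimate (scaled median absolute deviation of the first
#' differences). A constant trace has SNR 0; a noiseless step trace is
#' reported at the cap `cap`.
#'
#' @param trace Data frame with columns `time_s`, `intensity`.
#' @param plateau_frames Number of frames averaged at each end.
#' @param cap Value reported when the noise estimate is zero but the
#'   plateaus differ.
#' @return A single non-negative SNR value.
#' @export
estimate_snr <- function(trace, plateau_frames = 15, cap = 1e6) {
  check_trace_(trace)
  x <- trace$intensity
  w <- max(2L, min(as.integer(plateau_frames), floor(length(x) / 3)))
  amp <- mean(head(x, w)) - mean(tail(x, w))
  sigma <- robust_noise_(x)
  if (sigma <= 0) {
    if (abs(amp) <= .Machine$double.eps * max(abs(x), 1)) return(0)
    return(cap)
  }
  min(max(amp, 0) / sigma, cap)
}

# best split of x[lo:hi]: standardized two-sample mean-shift statistic,
# maximized over splits leaving >= minp points on both sides
best_split_ <- function(x, lo, hi, minp, sigma) {
  n <- hi - lo + 1L
  if (n < 2L * minp) return(NULL)
  seg <- x[lo:hi]
  cs <- cumsum(seg)
  i <- minp:(n - minp)                 # last index of the left child
  m1 <- cs[i] / i
  m2 <- (cs[n] - cs[i]) / (n - i)
  stat <- abs(m1 - m2) / (sigma * sqrt(1 / i + 1 / (n - i)))
  j <- which.max(stat)
  list(stat = stat[j], split = lo + i[j] - 1L)
}

#' Detect photobleaching steps in an intensity trace
#'
#' Idealizes a trace into piecewise-constant intensity levels and counts
#' bleaching steps. The idealization is divisive: each segment is split at
#' the point maximizing a standardized two-sample mean-shift statistic,
#' accepted only when the statistic exceeds `critical_value` and both
#' children keep at least `min_points_per_level` samples. Segment means are
#' then merged agglomeratively while the closest pair of levels differs by
#' less than `merge_tolerance` times the noise estimate. A bleaching step
#' is a transition to a level strictly below every level visited so far:
#' upward transitions (blinking on) never count, and dropping back to an
#' already-visited level after a blink does not double-count.
#'
#' @param trace Data frame with columns `time_s`, `intensity`.
#' @param config A [step_detector_config()].
#' @return An object of class `step_fit`: a list with `level_values`
#'   (fitted level per segment, time order), `change_points` (index of the
#'   last sample of each segment but the final one), `n_steps`, `snr`,
#'   `accepted` (SNR above threshold) and `noise_sd`.
#' @export
detect_steps <- function(trace, config = step_detector_config()) {
  check_trace_(trace)
  stopifnot(inherits(config, "step_detector_config"))
  x <- trace$intensity
  n <- length(x)
  minp <- config$min_points_per_level
  if (n < 2L * minp) {
    abort(sprintf("Trace too short: %d samples, need >= %d.", n, 2L * minp))
  }
  sigma <- robust_noise_(x)
  # floor keeps the statistic finite on noiseless traces while preserving
  # affine invariance (it scales with the data range)
  sigma_eff <- max(sigma, 1e-12 * max(diff(range(x)), .Machine$double.xmin))

  # recursive binary segmentation
  splits <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    bs <- best_split_(x, seg[1], seg[2], minp, sigma_eff)
    if (!is.null(bs) && bs$stat > config$critical_value) {
      splits <- c(splits, bs$split)
      stack <- c(stack, list(c(seg[1], bs$split)),
                 list(c(bs$split + 1L, seg[2])))
    }
  }
  splits <- sort(splits)
  bounds <- c(0L, splits, n)
  seg_start <- bounds[-length(bounds)] + 1L
  seg_end <- bounds[-1]
  seg_mean <- purrr::map2_dbl(seg_start, seg_end,
                              function(a, b) mean(x[a:b]))
  seg_n <- seg_end - seg_start + 1L

  # agglomerative merging of level values
  lv <- merge_levels_(seg_mean, seg_n, config$merge_tolerance * sigma_eff)
  level_values <- lv$value
  # collapse consecutive segments assigned the same merged level
  keep <- c(TRUE, diff(level_values) != 0)
  level_values <- level_values[keep]
  change_points <- seg_end[-length(seg_end)][keep[-1]]

  n_steps <- count_down_steps_(level_values)
  snr <- estimate_snr(trace, plateau_frames = minp)
  structure(
    list(level_values = level_values, change_points = change_points,
         n_steps = n_steps, snr = snr,
         accepted = snr > config$snr_threshold, noise_sd = sigma),
    class = "step_fit"
  )
}

# merge values closer than `tol` (weighted means), return merged value per
# original segment (time order preserved)
merge_levels_ <- function(values, weights, tol) {
  group <- seq_along(values)
  centers <- values
  wts <- as.numeric(weights)
  repeat {
    u <- unique(group)
    if (length(u) < 2) break
    cu <- vapply(u, function(g) centers[match(g, group)], numeric(1))
    d <- abs(outer(cu, cu, "-"))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[ij[1], ij[2]] >= tol) break
    g1 <- u[ij[1]]; g2 <- u[ij[2]]
    sel1 <- group == g1; sel2 <- group == g2
    w1 <- sum(wts[sel1]); w2 <- sum(wts[sel2])
    newc <- (centers[sel1][1] * w1 + centers[sel2][1] * w2) / (w1 + w2)
    group[sel2] <- g1
    centers[group == g1] <- newc
  }
  list(value = centers, group = group)
}

# bleaching steps: transitions to a level strictly below the running
# minimum of visited levels
count_down_steps_ <- function(levels) {
  if (length(levels) < 2) return(0L)
  n_steps <- 0L
  min_seen <- levels[1]
  for (i in 2:length(levels)) {
    if (levels[i] < min_seen) {
      n_steps <- n_steps + 1L
      min_seen <- levels[i]
    }
  }
  n_steps
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf(
    "<step_fit> %d step(s), %d level(s), SNR %.2f (%s)\n",
    x$n_steps, length(x$level_values), x$snr,
    if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' @export
glance.step_fit <- function(x, ...) {
  tibble::tibble(n_steps = x$n_steps, n_levels = length(x$level_values),
                 snr = x$snr, accepted = x$accepted,
                 noise_sd = x$noise_sd)
}

#' Analyze a set of photobleaching traces
#'
#' Runs [estimate_snr()] and [detect_steps()] on every visible trace of a
#' data set (as produced by [simulate_photobleaching_dataset()], or any
#' tibble with a `trace` list-column) and returns one row per particle.
#'
#' @param dataset Tibble with columns `particle_id` and `trace`.
#' @param config A [step_detector_config()].
#' @return A tibble with columns `particle_id`, `snr`, `n_steps`,
#'   `accepted`.
#' @export
analyze_traces <- function(dataset, config = step_detector_config()) {
  if (!all(c("particle_id", "trace") %in% names(dataset))) {
    abort("`dataset` needs columns `particle_id` and `trace`.")
  }
  rows <- purrr::map2(dataset$particle_id, dataset$trace,
    function(id, tr) {
      if (is.null(tr)) {
        return(tibble::tibble(particle_id = id, snr = NA_real_,
                              n_steps = NA_integer_, accepted = FALSE))
      }
      fit <- detect_steps(tr, config)
      tibble::tibble(particle_id = id, snr = fit$snr,
                     n_steps = as.integer(fit$n_steps),
                     accepted = fit$accepted)
    })
  dplyr::bind_rows(rows)
}

#' Count polarization states in a polarization trace
#'
#' Clusters per-frame polarization angles (degrees, circular on
#' \[0, 180)) by average-linkage agglomeration, merges clusters closer
#' than `tolerance_deg`, and discards clusters with fewer than
#' `min_points_per_state` frames. The number of surviving clusters
#' estimates the number of labeled monomers in the particle. Dipoles whose
#' projected angles fall within the tolerance of each other are merged, so
#' the count is a lower bound on the label number for any one particle.
#'
#' @param angles Numeric vector of per-frame polarization angles in
#'   degrees, or a tibble with column `angle_deg`.
#' @param min_points_per_state Minimum frames per surviving state.
#' @param tolerance_deg Angular merge tolerance in degrees.
#' @return Integer state count.
#' @export
count_polarization_states <- function(angles, min_points_per_state = 15,
                                      tolerance_deg = 15) {
  if (is.data.frame(angles)) angles <- angles$angle_deg
  if (length(angles) == 0) abort("No polarization samples supplied.")
  if (length(angles) < min_points_per_state) {
    abort(sprintf("Need >= %d samples, got %d.",
                  as.integer(min_points_per_state), length(angles)))
  }
  a <- angles %% 180
  if (length(unique(a)) == 1) return(1L)
  d <- abs(outer(a, a, "-")) %% 180
  d <- pmin(d, 180 - d)
  h <- hclust(as.dist(d), method = "average")
  cl <- cutree(h, h = tolerance_deg)
  sum(table(cl) >= min_points_per_state)
}

#' Build a step-count histogram
#'
#' Collects accepted per-particle step (or polarization-state) counts into
#' a histogram over k = 1..k_max. SNR-rejected traces are excluded;
#' accepted traces with zero detected steps are tallied separately
#' (`n_zero` attribute) and excluded from the fit histogram, since a
#' particle is only localized through its emission.
#'
#' @param results A tibble from [analyze_traces()] (columns `n_steps`,
#'   `accepted`), or a bare integer vector of counts (all treated as
#'   accepted).
#' @return A tibble of class `step_histogram` with columns `k` (1..k_max)
#'   and `n`, plus attributes `n_total` (particles in the histogram) and
#'   `n_zero` (accepted zero-step particles).
#' @examples
#' build_step_histogram(c(1, 1, 2, 3))
#' @export
build_step_histogram <- function(results) {
  if (is.data.frame(results)) {
    if (!all(c("n_steps", "accepted") %in% names(results))) {
      abort("`results` needs columns `n_steps` and `accepted`.")
    }
    counts <- results$n_steps[results$accepted & !is.na(results$n_steps)]
  } else {
    counts <- as.integer(results)
  }
  if (length(counts) == 0) {
    abort("No accepted traces: cannot build a histogram.")
  }
  n_zero <- sum(counts == 0L)
  counts <- counts[counts >= 1L]
  if (length(counts) == 0) {
    abort("All accepted traces have zero steps: empty histogram.")
  }
  k_max <- max(counts)
  tab <- tabulate(counts, nbins = k_max)
  out <- tibble::tibble(k = seq_len(k_max), n = as.numeric(tab))
  attr(out, "n_total") <- sum(tab)
  attr(out, "n_zero") <- n_zero
  class(out) <- c("step_histogram", class(out))
  out
}
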