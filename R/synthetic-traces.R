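#' Photobleaching trace model
#'
#' Parameters of the single-particle fluorescence trace generator. Defaults
#' mirror a typical wide-field photobleaching acquisition of surface-
#' immobilized aggregates: 10 acquisitions per second for 8 minutes under
#' continuous illumination, long enough that every fluorophore bleaches.
#'
#' @param frame_rate_hz Acquisitions per second (> 0).
#' @param duration_s Trace length in seconds (> 0).
#' @param unit_intensity Mean intensity contributed by one active
#'   fluorophore, in arbitrary camera units (> 0).
#' @param noise_sd Standard deviation of additive Gaussian noise per frame.
#' @param bleach_rate_per_s Exponential photobleaching hazard per
#'   fluorophore (s^-1). Each fluorophore bleaches irreversibly at an
#'   exponential time with this rate.
#' @param blink_on_off_rates_per_s Optional length-2 numeric
#'   `c(on_rate, off_rate)` for two-state telegraph blinking, independent
#'   per fluorophore; `NULL` (default) disables blinking.
#' @param background Baseline intensity added to every frame.
#' @return A list of class `trace_model`.
#' @export
trace_model <- function(frame_rate_hz = 10, duration_s = 480,
                        unit_intensity = 10, noise_sd = 1,
                        bleach_rate_per_s = 0.01,
                        blink_on_off_rates_per_s = NULL,
                        background = 0) {
  if (frame_rate_hz <= 0) abort("`frame_rate_hz` must be > 0.")
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  if (unit_intensity <= 0) abort("`unit_intensity` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (bleach_rate_per_s < 0) abort("`bleach_rate_per_s` must be >= 0.")
  if (!is.null(blink_on_off_rates_per_s)) {
    if (length(blink_on_off_rates_per_s) != 2 ||
        any(blink_on_off_rates_per_s < 0)) {
      abort("`blink_on_off_rates_per_s` must be two non-negative rates.")
    }
  }
  structure(
    list(frame_rate_hz = frame_rate_hz, duration_s = duration_s,
         unit_intensity = unit_intensity, noise_sd = noise_sd,
         bleach_rate_per_s = bleach_rate_per_s,
         blink_on_off_rates_per_s = blink_on_off_rates_per_s,
         background = background),
    class = "trace_model"
  )
}

#' Draw per-particle fluorophore label counts
#'
#' Labeled and unlabeled monomers mix stochastically during aggregation, so
#' the number of dye-labeled subunits per m-mer is Binomial(m, p), where p
#' is the labeling efficiency. Particles with zero labels emit nothing and
#' are invisible to fluorescence detection; `visible_only = TRUE` draws from
#' the zero-truncated distribution instead, returning exactly `n` counts
#' with k >= 1.
#'
#' @param n Number of particles to draw.
#' @param m Oligomer order (monomers per aggregate, integer >= 1).
#' @param p Labeling fraction in \[0, 1\].
#' @param seed Optional RNG seed; generation is bit-reproducible given it.
#' @param visible_only If `TRUE`, condition on at least one label.
#' @return Integer vector of length `n`.
#' @examples
#' sample_label_counts(5, m = 4, p = 1)   # all 4
#' sample_label_counts(5, m = 4, p = 0.25, seed = 1)
#' @export
sample_label_counts <- function(n, m, p, seed = NULL, visible_only = FALSE) {
  n <- stopifnot_count(n, "n")
  m <- stopifnot_count(m, "m", min = 1L)
  stopifnot_scalar_prob(p)
  if (visible_only && p == 0) {
    abort("No particle is visible when `p = 0`; cannot condition on k >= 1.")
  }
  with_seed_(seed, {
    if (!visible_only) return(rbinom(n, size = m, prob = p))
    out <- integer(0)
    while (length(out) < n) {
      batch <- rbinom(max(n, 100L), size = m, prob = p)
      out <- c(out, batch[batch >= 1L])
    }
    out[seq_len(n)]
  })
}

#' Simulate one photobleaching intensity trace
#'
#' Each of `k_labels` fluorophores contributes `unit_intensity` while
#' active, bleaches irreversibly at an exponential time, and (optionally)
#' blinks via an independent two-state telegraph process before bleaching.
#' Frames carry additive Gaussian noise on top of the background.
#'
#' @param k_labels Number of fluorophores on the particle (>= 0).
#' @param model A [trace_model()].
#' @param seed Optional RNG seed.
#' @return A tibble with columns `time_s` and `intensity` and attribute
#'   `true_k`.
#' @export
simulate_trace <- function(k_labels, model = trace_model(), seed = NULL) {
  k_labels <- stopifnot_count(k_labels, "k_labels")
  stopifnot(inherits(model, "trace_model"))
  n_frames <- max(2L, floor(model$frame_rate_hz * model$duration_s))
  times <- (seq_len(n_frames) - 1L) / model$frame_rate_hz
  with_seed_(seed, {
    active <- matrix(0, nrow = n_frames, ncol = max(k_labels, 1L))
    if (k_labels > 0) {
      for (j in seq_len(k_labels)) {
        t_bleach <- if (model$bleach_rate_per_s > 0) {
          rexp(1, model$bleach_rate_per_s)
        } else {
          Inf
        }
        on <- times < t_bleach
        if (!is.null(model$blink_on_off_rates_per_s)) {
          on <- on & telegraph_on_(times, model$blink_on_off_rates_per_s)
        }
        active[, j] <- as.numeric(on)
      }
    }
    n_active <- if (k_labels > 0) rowSums(active[, seq_len(k_labels),
                                                 drop = FALSE]) else
      numeric(n_frames)
    intensity <- model$background + model$unit_intensity * n_active
    if (model$noise_sd > 0) {
      intensity <- intensity + rnorm(n_frames, 0, model$noise_sd)
    }
    out <- tibble::tibble(time_s = times, intensity = intensity)
    attr(out, "true_k") <- k_labels
    attr(out, "frame_rate_hz") <- model$frame_rate_hz
    out
  })
}

# two-state telegraph process sampled at `times`; starts in the on state
telegraph_on_ <- function(times, rates) {
  on_rate <- rates[1]; off_rate <- rates[2]
  t_end <- max(times)
  state <- TRUE
  t_cur <- 0
  on <- rep(TRUE, length(times))
  repeat {
    rate <- if (state) off_rate else on_rate
    if (rate <= 0) break
    dt <- rexp(1, rate)
    t_next <- t_cur + dt
    if (t_next > t_end) break
    if (state) {
      # switching off at t_next; mark frames until next switch later
      state <- FALSE
      off_from <- t_next
    } else {
      state <- TRUE
      on[times >= off_from & times < t_next] <- FALSE
    }
    t_cur <- t_next
  }
  if (!state) on[times >= off_from] <- FALSE
  on
}

#' Simulate a photobleaching data set
#'
#' Draws per-particle label counts from the binomial mixing model and a
#' fluorescence trace for each particle. Zero-label particles are generated
#' but flagged invisible (`visible = FALSE`): they emit nothing, so a real
#' experiment never localizes them. Set `visible_only = TRUE` to generate
#' exactly `n_particles` visible particles (zero-truncated draws), matching
#' how an observed data set is collected.
#'
#' @inheritParams sample_label_counts
#' @param n_particles Number of particles.
#' @param model A [trace_model()].
#' @param seed RNG seed (required for reproducibility; may be `NULL`).
#' @param visible_only Condition label counts on k >= 1.
#' @return A tibble with columns `particle_id`, `true_k`, `visible`, and a
#'   list-column `trace` of per-particle tibbles (`NULL` for invisible
#'   particles).
#' @export
simulate_photobleaching_dataset <- function(n_particles, m, p,
                                            model = trace_model(),
                                            seed = NULL,
                                            visible_only = FALSE) {
  with_seed_(seed, {
    ks <- sample_label_counts(n_particles, m, p, visible_only = visible_only)
    traces <- purrr::map(ks, function(k) {
      if (k == 0L) NULL else simulate_trace(k, model)
    })
    tibble::tibble(
      particle_id = seq_len(n_particles),
      true_k = as.integer(ks),
      visible = ks > 0L,
      trace = traces
    )
  })
}

#' Draw fixed dipole orientations for one particle
#'
#' At cryogenic temperature each fluorophore's emission dipole is random but
#' fixed; the detected polarization reduces each dipole to a projected
#' polarization angle, treated here as uniform on \[0, 180) degrees.
#'
#' @param k_labels Number of fluorophores (>= 0).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `k_labels` angles in degrees.
#' @export
sample_polarization_states <- function(k_labels, seed = NULL) {
  k_labels <- stopifnot_count(k_labels, "k_labels")
  with_seed_(seed, runif(k_labels, 0, 180))
}

#' Simulate a polarization time trace
#'
#' Emits one polarization reading per frame: the angle of one of the
#' particle's fixed dipoles (each frame dominated by one emitter, chosen
#' uniformly) plus Gaussian angular noise, wrapped to \[0, 180).
#'
#' @param k_labels Number of fluorophores (>= 1).
#' @param n_frames Number of frames.
#' @param angle_noise_deg Gaussian angular noise SD in degrees.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `frame` and `angle_deg`; attribute
#'   `true_angles` holds the dipole angles.
#' @export
simulate_polarization_trace <- function(k_labels, n_frames = 200,
                                        angle_noise_deg = 3, seed = NULL) {
  k_labels <- stopifnot_count(k_labels, "k_labels", min = 1L)
  n_frames <- stopifnot_count(n_frames, "n_frames", min = 1L)
  with_seed_(seed, {
    dipoles <- runif(k_labels, 0, 180)
    which_d <- sample.int(k_labels, n_frames, replace = TRUE)
    ang <- (dipoles[which_d] + rnorm(n_frames, 0, angle_noise_deg)) %% 180
    out <- tibble::tibble(frame = seq_len(n_frames), angle_deg = ang)
    attr(out, "true_angles") <- dipoles
    out
  })
}
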