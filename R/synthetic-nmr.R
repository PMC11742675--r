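#' Simulate a CODEX spin-counting decay curve
#'
#' Generates the normalized CODEX signal for a cluster of `n_spins`
#' exchanging magnetization at a uniform pairwise rate, evaluated at the
#' supplied mixing times, with optional additive Gaussian noise. The
#' noiseless curve is the closed form of [codex_signal()]: it decays from 1
#' and plateaus at 1/N, the fingerprint used to count spins.
#'
#' @param n_spins Number of spins N in the cluster (integer >= 1).
#' @param rate_per_s Uniform pairwise exchange rate (s^-1, >= 0).
#' @param mixing_times_s Non-negative mixing times (s).
#' @param noise_sd Additive Gaussian noise SD per point.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `mixing_time_s` and `signal`.
#' @examples
#' simulate_codex_curve(4, 1, c(0, 0.5, 1, 5))
#' @export
simulate_codex_curve <- function(n_spins, rate_per_s,
                                 mixing_times_s, noise_sd = 0,
                                 seed = NULL) {
  n_spins <- stopifnot_count(n_spins, "n_spins", min = 1L)
  if (rate_per_s < 0) abort("`rate_per_s` must be >= 0.")
  if (any(mixing_times_s < 0)) abort("Mixing times must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  sig <- codex_signal(mixing_times_s, n_spins, rate_per_s)
  with_seed_(seed, {
    if (noise_sd > 0) sig <- sig + rnorm(length(sig), 0, noise_sd)
    tibble::tibble(mixing_time_s = as.numeric(mixing_times_s), signal = sig)
  })
}

#' Simulate paired chemical-shift tables for two states
#'
#' Builds a reference state A from the random-coil scale over a protein
#' sequence (alpha-synuclein by default), then derives state B by adding
#' segment-localized per-nucleus shift offsets plus optional per-entry
#' Gaussian jitter. Residues outside the perturbed segments differ only by
#' jitter, emulating a pair of conformers that share most of their fold but
#' diverge in chosen segments.
#'
#' @param segments A data frame with columns `start`, `end` (1-based,
#'   inclusive residue numbers) and any of `d_ca`, `d_cb`, `d_c`, `d_n`
#'   (ppm offsets applied to CA, CB, C and N shifts). Segments must not
#'   overlap. `NULL` or zero rows means no perturbation.
#' @param baseline_noise_ppm Gaussian jitter SD (ppm) added per entry of
#'   state B.
#' @param sequence Character vector of one-letter residue codes.
#' @param coil Random-coil scale, as from [random_coil_shifts()].
#' @param seed Optional RNG seed.
#' @return A list with elements `state_a` and `state_b`, each a long tibble
#'   with columns `residue_number`, `residue_type`, `atom`, `shift_ppm`.
#' @export
simulate_shift_tables <- function(segments = NULL, baseline_noise_ppm = 0,
                                  sequence = alpha_synuclein_sequence(),
                                  coil = random_coil_shifts(),
                                  seed = NULL) {
  n_res <- length(sequence)
  if (!is.null(segments) && nrow(segments) > 0) {
    if (any(segments$start < 1) || any(segments$end > n_res) ||
        any(segments$start > segments$end)) {
      abort("Segments must satisfy 1 <= start <= end <= sequence length.")
    }
    covered <- unlist(purrr::map2(segments$start, segments$end, seq))
    if (anyDuplicated(covered)) abort("Segments must not overlap.")
  }
  state_a <- tibble::tibble(residue_number = seq_len(n_res),
                            residue_type = sequence) |>
    dplyr::left_join(coil, by = "residue_type") |>
    tidyr::pivot_longer(cols = c("CA", "CB", "C", "N"), names_to = "atom",
                        values_to = "shift_ppm") |>
    dplyr::filter(!is.na(.data$shift_ppm))

  offset_for <- function(res, atom) {
    if (is.null(segments) || nrow(segments) == 0) return(0)
    col <- c(CA = "d_ca", CB = "d_cb", C = "d_c", N = "d_n")[[atom]]
    hit <- which(segments$start <= res & segments$end >= res)
    if (length(hit) == 0 || !col %in% names(segments)) return(0)
    val <- segments[[col]][hit[1]]
    if (is.na(val)) 0 else val
  }
  state_b <- state_a
  state_b$shift_ppm <- state_b$shift_ppm +
    purrr::map2_dbl(state_b$residue_number, state_b$atom, offset_for)
  with_seed_(seed, {
    if (baseline_noise_ppm > 0) {
      state_b$shift_ppm <- state_b$shift_ppm +
        rnorm(nrow(state_b), 0, baseline_noise_ppm)
    }
    list(state_a = state_a, state_b = state_b)
  })
}

#' Isotope-dilution cross-peak intensity model
#'
#' In an NH-NH correlation spectrum of a sample in which only a fraction
#' `f` of molecules is isotope-labeled, a cross-peak requires both partner
#' nuclei to sit on labeled molecules. An intramolecular peak needs one
#' labeled molecule (intensity proportional to f), an intermolecular peak
#' needs two (proportional to f^2), and the diagonal is proportional to f.
#' After normalizing by the diagonal, intramolecular peaks retain full
#' intensity at any dilution while intermolecular peaks scale as f — a
#' 2-fold reduction at 50% labeling.
#'
#' @param labeled_fraction Fraction f of labeled molecules, in (0, 1\].
#' @return A tibble with columns `class`, `normalized_intensity` (the
#'   diagonal-normalized intensity at fraction `f` relative to full
#'   labeling) and `fold_reduction` (full / diluted).
#' @examples
#' crosspeak_dilution_model(0.5)
#' @export
crosspeak_dilution_model <- function(labeled_fraction) {
  stopifnot_scalar_prob(labeled_fraction, "labeled_fraction",
                        open_left = TRUE)
  f <- labeled_fraction
  tibble::tibble(
    class = c("intra", "inter"),
    normalized_intensity = c((f / f) / 1, (f^2 / f) / 1),
    fold_reduction = c(1, 1 / f)
  )
}

#' Simulate a diagonal-normalized cross-peak intensity table
#'
#' For each contact, produces the diagonal-normalized intensity in the
#' fully labeled sample and in a sample diluted to labeled fraction `f`,
#' following [crosspeak_dilution_model()]: intramolecular peaks keep full
#' intensity, intermolecular peaks are reduced by the factor `f`.
#' Independent multiplicative Gaussian noise is applied to each intensity
#' (two separately measured spectra).
#'
#' @param contacts A data frame with columns `pair_id` and `class`
#'   (`"intra"` or `"inter"`).
#' @param labeled_fraction Labeled fraction f in (0, 1\].
#' @param noise_sd Relative (multiplicative) Gaussian noise SD.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `pair_id`, `class`, `intensity_full`,
#'   `intensity_diluted`.
#' @export
simulate_crosspeak_table <- function(contacts, labeled_fraction = 0.5,
                                     noise_sd = 0, seed = NULL) {
  stopifnot_scalar_prob(labeled_fraction, "labeled_fraction",
                        open_left = TRUE)
  if (!all(c("pair_id", "class") %in% names(contacts))) {
    abort("`contacts` needs columns `pair_id` and `class`.")
  }
  if (!all(contacts$class %in% c("intra", "inter"))) {
    abort("`class` must be \"intra\" or \"inter\".")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  f <- labeled_fraction
  n <- nrow(contacts)
  with_seed_(seed, {
    full <- rep(1, n)
    diluted <- ifelse(contacts$class == "inter", f, 1)
    if (noise_sd > 0) {
      full <- full * (1 + rnorm(n, 0, noise_sd))
      diluted <- diluted * (1 + rnorm(n, 0, noise_sd))
    }
    tibble::tibble(pair_id = contacts$pair_id, class = contacts$class,
                   intensity_full = full, intensity_diluted = diluted)
  })
}
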