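#' End-to-end stoichiometry workflow
#'
#' Runs the full subunit-counting chain: SNR filtering and step detection
#' on raw traces (or a pre-built step histogram), binomial model selection
#' over candidate oligomer orders, and — when a CODEX decay curve is
#' supplied — an independent spin-count lower bound, with a consistency
#' verdict between the two estimators (consistent when the selected order
#' is at least the CODEX lower bound).
#'
#' @param traces Optional trace data set (tibble with `particle_id`,
#'   `trace` columns); required unless `histogram` is given.
#' @param histogram Optional pre-built step histogram (columns `k`, `n`).
#' @param p_experimental Experimental labeling fraction (> 0).
#' @param codex_curve Optional CODEX curve (columns `mixing_time_s`,
#'   `signal`).
#' @param detector A [step_detector_config()].
#' @param m_range Candidate oligomer orders.
#' @param truncated Use the zero-truncated binomial model.
#' @return An object of class `stoich_report`: list with `per_particle`
#'   (or `NULL`), `histogram`, `scan` (a `stoich_scan`), `best_m`,
#'   `p_hat`, `codex` (a `codex_fit` or `NULL`) and `consistent`.
#' @examples
#' h <- build_step_histogram(sample_label_counts(
#'   1000, m = 4, p = 0.27, seed = 7, visible_only = TRUE))
#' run_stoichiometry_workflow(histogram = h, p_experimental = 0.25)
#' @export
run_stoichiometry_workflow <- function(traces = NULL, histogram = NULL,
                                       p_experimental,
                                       codex_curve = NULL,
                                       detector = step_detector_config(),
                                       m_range = 1:8, truncated = TRUE) {
  if (is.null(traces) && is.null(histogram)) {
    abort("Supply `traces` or a pre-built `histogram`. [stage: input]")
  }
  per_particle <- NULL
  if (is.null(histogram)) {
    per_particle <- tryCatch(
      analyze_traces(traces, detector),
      error = function(e) abort(paste0(conditionMessage(e),
                                       " [stage: step detection]")))
    histogram <- tryCatch(
      build_step_histogram(per_particle),
      error = function(e) abort(paste0(conditionMessage(e),
                                       " [stage: histogram]")))
  }
  scan <- tryCatch(
    select_oligomer_order(histogram, p_experimental, m_range = m_range,
                          truncated = truncated),
    error = function(e) abort(paste0(conditionMessage(e),
                                     " [stage: model selection]")))
  codex <- NULL
  consistent <- NA
  if (!is.null(codex_curve)) {
    codex <- tryCatch(
      fit_spin_count(codex_curve),
      error = function(e) abort(paste0(conditionMessage(e),
                                       " [stage: codex]")))
    consistent <- attr(scan, "best_m") >= codex$n_reported
  }
  out <- list(per_particle = per_particle, histogram = histogram,
              scan = scan, best_m = attr(scan, "best_m"),
              p_hat = attr(scan, "best_p_hat"),
              p_experimental = p_experimental,
              codex = codex, consistent = consistent)
  class(out) <- "stoich_report"
  out
}

#' @export
print.stoich_report <- function(x, ...) {
  cat("== Oligomer stoichiometry report ==\n")
  cat(sprintf("Histogram: %d particles (k >= 1)%s\n",
              attr(x$histogram, "n_total") %||% sum(x$histogram$n),
              if (!is.null(attr(x$histogram, "n_zero")))
                sprintf(", %d zero-step traces excluded",
                        attr(x$histogram, "n_zero")) else ""))
  cat(sprintf("Selected oligomer order: m = %d (fitted labeling efficiency %.1f%%, experimental %.1f%%)\n",
              x$best_m, 100 * x$p_hat, 100 * x$p_experimental))
  if (!is.null(x$codex)) {
    cat(sprintf("CODEX spin count: at least %d (plateau %.3f)\n",
                x$codex$n_reported, x$codex$plateau_hat))
    cat(sprintf("Estimators %s.\n",
                if (isTRUE(x$consistent)) "agree" else "disagree"))
  }
  invisible(x)
}

#' @rdname run_stoichiometry_workflow
#' @param x A `stoich_report`.
#' @param ... Unused.
#' @export
glance.stoich_report <- function(x, ...) {
  tibble::tibble(
    best_m = x$best_m, p_hat = x$p_hat,
    p_experimental = x$p_experimental,
    n_particles = attr(x$histogram, "n_total") %||% sum(x$histogram$n),
    codex_n_reported = if (is.null(x$codex)) NA_integer_ else
      x$codex$n_reported,
    consistent = x$consistent
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two chemical-shift states end to end
#'
#' Builds the per-residue CSP profile between two states, reports maximal
#' similar/dissimilar segments, classifies secondary structure for both
#' states from their secondary shifts, and optionally classifies
#' cross-peaks from an isotope-dilution table.
#'
#' @param state_a,state_b Long shift tables (columns `residue_number`,
#'   `residue_type`, `atom`, `shift_ppm`).
#' @param cutoff_ppm CSP similar/dissimilar cutoff (ppm).
#' @param coil Random-coil scale for secondary shifts.
#' @param crosspeaks Optional cross-peak table (columns `pair_id`,
#'   `intensity_full`, `intensity_diluted`).
#' @param labeled_fraction Labeled fraction for cross-peak
#'   classification.
#' @return An object of class `state_comparison`: list with `profile`,
#'   `segments`, `structure_a`, `structure_b`, `crosspeaks`.
#' @export
run_state_comparison <- function(state_a, state_b, cutoff_ppm = 0.7,
                                 coil = random_coil_shifts(),
                                 crosspeaks = NULL,
                                 labeled_fraction = 0.5) {
  profile <- tryCatch(
    csp_profile(state_a, state_b, cutoff_ppm = cutoff_ppm),
    error = function(e) abort(paste0(conditionMessage(e),
                                     " [stage: csp]")))
  segments <- csp_segments(profile)
  struct <- function(state) {
    tryCatch(
      classify_secondary_structure(secondary_shifts(state, coil)),
      error = function(e) NULL)
  }
  xp <- if (is.null(crosspeaks)) NULL else tryCatch(
    classify_crosspeaks(crosspeaks, labeled_fraction = labeled_fraction),
    error = function(e) abort(paste0(conditionMessage(e),
                                     " [stage: crosspeaks]")))
  out <- list(profile = profile, segments = segments,
              structure_a = struct(state_a), structure_b = struct(state_b),
              crosspeaks = xp)
  class(out) <- "state_comparison"
  out
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("== Chemical-shift state comparison ==\n")
  n_dis <- sum(!x$profile$similar, na.rm = TRUE)
  cat(sprintf("%d residues compared, %d dissimilar (CSP >= %.2f ppm)\n",
              sum(!is.na(x$profile$similar)), n_dis,
              attr(x$profile, "cutoff_ppm")))
  if (nrow(x$segments) > 0) {
    seg <- x$segments
    lab <- sprintf("  %s %d-%d (%d residues)",
                   ifelse(seg$similar, "similar  ", "dissimilar"),
                   seg$start, seg$end, seg$n_residues)
    cat(paste(lab, collapse = "\n"), "\n")
  }
  if (!is.null(x$crosspeaks)) {
    tab <- table(x$crosspeaks$classification)
    cat("Cross-peaks:",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
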