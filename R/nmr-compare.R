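#' Weighted average chemical shift perturbation
#'
#' Combines per-nucleus backbone shift differences (ppm) between two
#' states into a single per-residue perturbation:
#'
#'   CSP = sqrt( 1/4 \[ (dCA)^2 + (2.37 dCB)^2 + (0.47 dC)^2
#'               + (1.30 dN)^2 \] )
#'
#' The nucleus weights compensate for the different shift dispersions of
#' CA, CB, CO and amide N and are exposed via `weights`. Missing nuclei
#' contribute zero while the 1/4 normalizer stays fixed; the number of
#' nuclei actually used should be tracked by the caller (see
#' [csp_profile()]) to flag low-coverage residues. All-missing input
#' yields `NA`.
#'
#' @param d_ca,d_cb,d_c,d_n Shift differences (ppm) for CA, CB, CO and
#'   amide N; vectors are recycled to a common length; `NA` = missing.
#' @param weights Named numeric vector with entries `ca`, `cb`, `c`, `n`.
#' @return Non-negative CSP value(s) in ppm.
#' @examples
#' average_csp(d_ca = 1)               # 0.5
#' average_csp(d_cb = 1)               # 1.185
#' @export
average_csp <- function(d_ca = NA, d_cb = NA, d_c = NA, d_n = NA,
                        weights = c(ca = 1, cb = 2.37, c = 0.47,
                                    n = 1.30)) {
  stopifnot(all(c("ca", "cb", "c", "n") %in% names(weights)))
  len <- max(length(d_ca), length(d_cb), length(d_c), length(d_n))
  d <- cbind(ca = rep_len(as.numeric(d_ca), len),
             cb = rep_len(as.numeric(d_cb), len),
             c = rep_len(as.numeric(d_c), len),
             n = rep_len(as.numeric(d_n), len))
  all_missing <- rowSums(!is.na(d)) == 0
  d[is.na(d)] <- 0
  w <- weights[colnames(d)]
  out <- sqrt(rowSums(sweep(d, 2, w, "*")^2) / 4)
  out[all_missing] <- NA_real_
  out
}

shift_table_wide_ <- function(state, label) {
  req <- c("residue_number", "atom", "shift_ppm")
  if (!is.data.frame(state) || !all(req %in% names(state))) {
    abort(sprintf(
      "`%s` must have columns residue_number, atom, shift_ppm.", label))
  }
  bad <- setdiff(unique(state$atom), c("CA", "CB", "C", "N"))
  if (length(bad)) {
    state <- state[state$atom %in% c("CA", "CB", "C", "N"), ]
  }
  keep <- c("residue_number",
            intersect("residue_type", names(state)), "atom", "shift_ppm")
  tidyr::pivot_wider(state[keep], names_from = "atom",
                     values_from = "shift_ppm")
}

#' Per-residue chemical shift perturbation profile
#'
#' Computes the weighted average CSP between two backbone shift tables for
#' every residue and classifies each as similar (CSP strictly below
#' `cutoff_ppm`) or dissimilar (CSP at or above the cutoff). Residues
#' present in only one table are emitted with `NA` CSP. Comparison is by
#' residue number; the tables must share at least one residue.
#'
#' @param state_a,state_b Long shift tables with columns `residue_number`,
#'   `atom` (CA/CB/C/N), `shift_ppm` (optionally `residue_type`).
#' @param cutoff_ppm Similar/dissimilar cutoff (default 0.7 ppm).
#' @param weights Passed to [average_csp()].
#' @return A tibble of class `csp_profile` with columns `residue_number`,
#'   `average_csp_ppm`, `n_nuclei_used`, `similar`.
#' @export
csp_profile <- function(state_a, state_b, cutoff_ppm = 0.7,
                        weights = c(ca = 1, cb = 2.37, c = 0.47,
                                    n = 1.30)) {
  wa <- shift_table_wide_(state_a, "state_a")
  wb <- shift_table_wide_(state_b, "state_b")
  shared <- intersect(wa$residue_number, wb$residue_number)
  if (length(shared) == 0) {
    abort("The two states share no residues; cannot build a CSP profile.")
  }
  all_res <- sort(union(wa$residue_number, wb$residue_number))
  get <- function(w, res, atom) {
    if (!atom %in% names(w)) return(rep(NA_real_, length(res)))
    w[[atom]][match(res, w$residue_number)]
  }
  delta <- function(atom) get(wb, all_res, atom) - get(wa, all_res, atom)
  d_ca <- delta("CA"); d_cb <- delta("CB")
  d_c <- delta("C"); d_n <- delta("N")
  csp <- average_csp(d_ca, d_cb, d_c, d_n, weights = weights)
  n_used <- rowSums(!is.na(cbind(d_ca, d_cb, d_c, d_n)))
  out <- tibble::tibble(
    residue_number = all_res,
    average_csp_ppm = csp,
    n_nuclei_used = as.integer(n_used),
    similar = ifelse(is.na(csp), NA, csp < cutoff_ppm)
  )
  attr(out, "cutoff_ppm") <- cutoff_ppm
  class(out) <- c("csp_profile", class(out))
  out
}

#' Maximal similar/dissimilar segments of a CSP profile
#'
#' Collapses a CSP profile into maximal runs of consecutive compared
#' residues sharing a similarity class, keeping runs of at least
#' `min_run` residues.
#'
#' @param profile A [csp_profile()] result.
#' @param min_run Minimum residues per reported segment (default 2).
#' @return A tibble with columns `start`, `end`, `n_residues`, `similar`.
#' @export
csp_segments <- function(profile, min_run = 2) {
  p <- profile[!is.na(profile$similar), ]
  if (nrow(p) == 0) return(tibble::tibble(start = integer(),
                                          end = integer(),
                                          n_residues = integer(),
                                          similar = logical()))
  # a gap in residue numbering breaks a run
  brk <- c(TRUE, diff(p$residue_number) != 1 |
             diff(as.integer(p$similar)) != 0)
  grp <- cumsum(brk)
  out <- p |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(start = min(.data$residue_number),
                     end = max(.data$residue_number),
                     n_residues = dplyr::n(),
                     similar = .data$similar[1], .groups = "drop") |>
    dplyr::select(-dplyr::any_of(".grp")) |>
    dplyr::filter(.data$n_residues >= min_run)
  out
}

#' Secondary chemical shifts relative to random coil
#'
#' Subtracts residue-type random-coil values from observed CA and CB
#' shifts and forms the helix/strand indicator
#' `delta_delta = dCA - dCB`: sustained positive values indicate helix,
#' sustained negative values strand. Glycine has no CB, so its `d_cb` and
#' `delta_delta` are `NA`; unknown residue types yield `NA` throughout.
#'
#' @param state Long shift table (columns `residue_number`,
#'   `residue_type`, `atom`, `shift_ppm`).
#' @param coil Random-coil scale, as from [random_coil_shifts()].
#' @return A tibble with columns `residue_number`, `residue_type`,
#'   `d_ca`, `d_cb`, `delta_delta`.
#' @export
secondary_shifts <- function(state, coil = random_coil_shifts()) {
  if (!"residue_type" %in% names(state)) {
    abort("`state` needs a `residue_type` column for secondary shifts.")
  }
  w <- shift_table_wide_(state, "state")
  if (!"CA" %in% names(w)) w$CA <- NA_real_
  if (!"CB" %in% names(w)) w$CB <- NA_real_
  ix <- match(w$residue_type, coil$residue_type)
  tibble::tibble(
    residue_number = w$residue_number,
    residue_type = w$residue_type,
    d_ca = w$CA - coil$CA[ix],
    d_cb = w$CB - coil$CB[ix]
  ) |>
    dplyr::mutate(delta_delta = .data$d_ca - .data$d_cb)
}

#' Classify secondary structure from secondary-shift differences
#'
#' A simple chemical-shift-index style classifier over the
#' `delta_delta = dCA - dCB` profile: residues in a run of at least
#' `window` consecutive residues with `delta_delta >= threshold_ppm` are
#' labeled `helix`, runs at or below `-threshold_ppm` are `strand`, and
#' everything else `coil`. This is a transparent stand-in for dedicated
#' torsion-angle predictors, not a reproduction of them.
#'
#' @param ss Tibble from [secondary_shifts()] (columns `residue_number`,
#'   `delta_delta`).
#' @param window Minimum run length (residues).
#' @param threshold_ppm Threshold on `delta_delta` (ppm).
#' @return The input with an added `structure` column in
#'   `c("helix", "strand", "coil")`.
#' @export
classify_secondary_structure <- function(ss, window = 3,
                                         threshold_ppm = 1.4) {
  if (nrow(ss) < window) {
    abort(sprintf("Need at least %d residues.", as.integer(window)))
  }
  dd <- ss$delta_delta
  cat0 <- dplyr::case_when(
    is.na(dd) ~ "coil",
    dd >= threshold_ppm ~ "helix",
    dd <= -threshold_ppm ~ "strand",
    TRUE ~ "coil"
  )
  # runs broken by residue-number gaps as well as by category changes
  brk <- c(TRUE, diff(ss$residue_number) != 1 |
             cat0[-1] != cat0[-length(cat0)])
  grp <- cumsum(brk)
  run_len <- ave(seq_along(grp), grp, FUN = length)
  structure_lab <- ifelse(cat0 != "coil" & run_len >= window, cat0, "coil")
  dplyr::mutate(ss, structure = structure_lab)
}

#' Classify cross-peaks as intra- or inter-molecular
#'
#' In an isotope-dilution experiment at labeled fraction f, the
#' diagonal-normalized intensity ratio r = diluted / full is expected to
#' be 1 for intramolecular contacts and f for intermolecular ones. The
#' decision boundary is the geometric mean sqrt(f) (~0.707 at f = 0.5):
#' r above it is `intra`, below it `inter`, and ratios within
#' `ambiguous_band` (relative) of the boundary are `ambiguous`.
#'
#' @param peaks Data frame with columns `pair_id`, `intensity_full`,
#'   `intensity_diluted` (both diagonal-normalized, > 0).
#' @param labeled_fraction Labeled fraction f in (0, 1).
#' @param ambiguous_band Half-width of the ambiguous zone, relative to the
#'   boundary (default 0.10).
#' @return The input tibble with added columns `ratio` and
#'   `classification`.
#' @examples
#' peaks <- tibble::tibble(pair_id = c("V63-V55", "V66-V52"),
#'                         intensity_full = c(1, 1),
#'                         intensity_diluted = c(1, 0.5))
#' classify_crosspeaks(peaks)
#' @export
classify_crosspeaks <- function(peaks, labeled_fraction = 0.5,
                                ambiguous_band = 0.10) {
  req <- c("pair_id", "intensity_full", "intensity_diluted")
  if (!is.data.frame(peaks) || !all(req %in% names(peaks))) {
    abort("`peaks` needs columns pair_id, intensity_full, intensity_diluted.")
  }
  if (labeled_fraction <= 0 || labeled_fraction >= 1) {
    abort("`labeled_fraction` must be in (0, 1).")
  }
  if (any(peaks$intensity_full <= 0) || any(peaks$intensity_diluted <= 0)) {
    abort("Intensities must be > 0.")
  }
  boundary <- sqrt(labeled_fraction)
  r <- peaks$intensity_diluted / peaks$intensity_full
  cls <- dplyr::case_when(
    abs(r - boundary) <= ambiguous_band * boundary ~ "ambiguous",
    r > boundary ~ "intra",
    TRUE ~ "inter"
  )
  dplyr::mutate(peaks, ratio = r, classification = cls)
}
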