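# build a noiseless piecewise-constant trace from level values
make_staircase <- function(levels, len_per_level = 20, frame_rate = 10) {
  intensity <- rep(levels, each = len_per_level)
  tibble::tibble(
    time_s = (seq_along(intensity) - 1) / frame_rate,
    intensity = intensity
  )
}

# matrix-exponential oracle for the N-spin symmetric exchange model:
# generator K with off-diagonal rate k and diagonal -(N-1)k, magnetization
# starts on spin 1; observed signal is the surviving population there
codex_expm_oracle <- function(t, n_spins, rate) {
  K <- matrix(rate, n_spins, n_spins)
  diag(K) <- -(n_spins - 1) * rate
  p0 <- c(1, rep(0, n_spins - 1))
  as.numeric((Matrix::expm(K * t) %*% p0)[1])
}

# minimal NMR-STAR fixture with an assigned-chemical-shift loop
write_star_fixture <- function(path, rows) {
  lines <- c(
    "data_synthetic_shifts",
    "save_assigned_chem_shift_list_1",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    sprintf("  %d %d %s %s %.3f", seq_len(nrow(rows)), rows$seq,
            rows$comp, rows$atom, rows$val),
    "stop_",
    "save_"
  )
  writeLines(lines, path)
  path
}

# exact model histogram: counts proportional to the (truncated) pmf
model_histogram <- function(m, p, n = 1e6, truncated = TRUE) {
  k <- seq_len(m)
  tibble::tibble(k = k,
                 n = n * binomial_label_pmf(k, m, p, truncated = truncated))
}
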