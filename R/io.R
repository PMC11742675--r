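#' Write a photobleaching data set to disk
#'
#' Writes one CSV per visible particle (columns `time_s`, `intensity`), a
#' manifest CSV (`particle_id`, `true_k`, `file`; invisible particles have
#' an empty `file`), and a JSON sidecar echoing the generation parameters.
#'
#' @param dataset Tibble from [simulate_photobleaching_dataset()].
#' @param dir Output directory (created if needed).
#' @param params Optional named list of generation parameters for the
#'   sidecar.
#' @return Invisibly, the manifest tibble.
#' @export
write_trace_dataset <- function(dataset, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- ifelse(dataset$visible,
                  sprintf("particle_%04d.csv", dataset$particle_id), "")
  purrr::pwalk(list(dataset$trace, files), function(tr, f) {
    if (!is.null(tr)) readr::write_csv(tr, file.path(dir, f))
  })
  manifest <- tibble::tibble(particle_id = dataset$particle_id,
                             true_k = dataset$true_k, file = files)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  if (!is.null(params)) {
    jsonlite::write_json(params, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read a photobleaching data set written by [write_trace_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and trace CSVs.
#' @return A tibble with columns `particle_id`, `true_k`, `visible`,
#'   `trace`.
#' @export
read_trace_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  traces <- purrr::map(manifest$file, function(f) {
    if (is.na(f) || !nzchar(f)) return(NULL)
    readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  })
  tibble::tibble(particle_id = manifest$particle_id,
                 true_k = manifest$true_k,
                 visible = !is.na(manifest$file) & nzchar(manifest$file),
                 trace = traces)
}

#' Read and write backbone shift tables as TSV
#'
#' The on-disk format is a four-column TSV: `residue_number`,
#' `residue_type` (one-letter), `atom` (CA, CB, C or N) and `shift_ppm`.
#'
#' @param path File path.
#' @param state Long shift table.
#' @return `read_shift_tsv()` returns the tibble; `write_shift_tsv()`
#'   returns `path` invisibly.
#' @export
read_shift_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    residue_number = readr::col_integer(),
                    residue_type = readr::col_character(),
                    atom = readr::col_character(),
                    shift_ppm = readr::col_double()))
}

#' @rdname read_shift_tsv
#' @export
write_shift_tsv <- function(state, path) {
  readr::write_tsv(state, path)
  invisible(path)
}

#' Read backbone shifts from a minimal NMR-STAR file
#'
#' Reads the assigned-chemical-shift loop of an NMR-STAR (v3) file — the
#' loop whose tags start with `_Atom_chem_shift.` — and returns backbone
#' CA/CB/C/N shifts as the package's long shift-table format. Only that
#' one loop is parsed; this is sufficient to drop in deposited
#' chemical-shift entries, not a general STAR parser.
#'
#' @param path Path to an NMR-STAR file.
#' @return A tibble with columns `residue_number`, `residue_type`,
#'   `atom`, `shift_ppm`.
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_starts <- which(lines == "loop_")
  if (length(loop_starts) == 0) abort("No loop_ found in NMR-STAR file.")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i])
      i <- i + 1L
    }
    if (!any(startsWith(tags, "_Atom_chem_shift."))) next
    rows <- list()
    while (i <= length(lines) && lines[i] != "stop_") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
        toks <- strsplit(lines[i], "\\s+")[[1]]
        if (length(toks) == length(tags)) rows[[length(rows) + 1L]] <- toks
      }
      i <- i + 1L
    }
    if (length(rows) == 0) abort("Empty _Atom_chem_shift loop.")
    mat <- do.call(rbind, rows)
    colnames(mat) <- sub("^_Atom_chem_shift\\.", "", tags)
    seq_col <- intersect(c("Seq_ID", "Comp_index_ID"), colnames(mat))[1]
    if (is.na(seq_col) || !all(c("Comp_ID", "Atom_ID", "Val") %in%
                               colnames(mat))) {
      abort("Shift loop lacks Seq_ID/Comp_index_ID, Comp_ID, Atom_ID or Val.")
    }
    out <- tibble::tibble(
      residue_number = as.integer(mat[, seq_col]),
      residue_type = unname(AA_THREE_TO_ONE[toupper(mat[, "Comp_ID"])]),
      atom = mat[, "Atom_ID"],
      shift_ppm = suppressWarnings(as.numeric(mat[, "Val"]))
    )
    out <- out[out$atom %in% c("CA", "CB", "C", "N") &
                 !is.na(out$shift_ppm), ]
    return(out)
  }
  abort("No _Atom_chem_shift loop found in NMR-STAR file.")
}

#' Read and write CODEX decay curves as CSV
#'
#' Columns `mixing_time_s` and `signal`; an optional `reference` column
#' holds the reference intensity S0, in which case the returned signal is
#' the ratio S / S0.
#'
#' @param path File path.
#' @param curve Tibble with columns `mixing_time_s`, `signal`.
#' @return `read_codex_csv()` returns a normalized curve tibble;
#'   `write_codex_csv()` returns `path` invisibly.
#' @export
read_codex_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("mixing_time_s", "signal") %in% names(x))) {
    abort("CODEX CSV needs columns mixing_time_s and signal.")
  }
  if ("reference" %in% names(x)) {
    x$signal <- x$signal / x$reference
    x$reference <- NULL
  }
  x
}

#' @rdname read_codex_csv
#' @export
write_codex_csv <- function(curve, path) {
  readr::write_csv(curve, path)
  invisible(path)
}

#' Write a step histogram to JSON
#'
#' @param hist A [build_step_histogram()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_json <- function(hist, path) {
  jsonlite::write_json(
    list(k = hist$k, n = hist$n,
         n_total = attr(hist, "n_total"),
         n_zero = attr(hist, "n_zero")),
    path, digits = NA)
  invisible(path)
}

#' Read a step histogram from JSON
#'
#' @param path Path written by [write_histogram_json()].
#' @return A `step_histogram` tibble.
#' @export
read_histogram_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::tibble(k = as.integer(x$k), n = as.numeric(x$n))
  attr(out, "n_total") <- x$n_total
  attr(out, "n_zero") <- x$n_zero
  class(out) <- c("step_histogram", class(out))
  out
}
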