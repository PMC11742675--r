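#' Human alpha-synuclein sequence
#'
#' The canonical 140-residue sequence of human alpha-synuclein (UniProt
#' P37840), used as the default residue-type backdrop for synthetic
#' chemical-shift tables. Residue numbering throughout the package is
#' 1-based over this sequence.
#'
#' @param as_string Return a single string instead of a character vector of
#'   one-letter codes.
#' @return A character vector of length 140 (default) or a single string.
#' @examples
#' alpha_synuclein_sequence()[50] # "H" (H50, the CODEX label site)
#' @export
alpha_synuclein_sequence <- function(as_string = FALSE) {
  seq <- paste0(
    "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK",
    "EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
    "DNEAYEMPSEEGYQDYEPEA"
  )
  if (as_string) seq else strsplit(seq, "")[[1]]
}

#' Random-coil backbone chemical shifts
#'
#' A built-in table of random-coil backbone chemical shifts (ppm) for the 20
#' standard residue types, in the style of the GGXGG-peptide reference scales
#' used for intrinsically disordered proteins. Used to form secondary
#' chemical shifts (observed minus random coil). Glycine has no CB entry and
#' proline no amide N entry.
#'
#' Users can substitute their own scale: any tibble with columns
#' `residue_type` (one-letter code) and numeric `CA`, `CB`, `C`, `N`
#' is accepted wherever a coil table is expected.
#'
#' @return A tibble with columns `residue_type`, `CA`, `CB`, `C`, `N`.
#' @export
random_coil_shifts <- function() {
  tibble::tribble(
    ~residue_type,   ~CA,   ~CB,    ~C,    ~N,
    "A", 52.5, 19.1, 177.8, 123.8,
    "R", 56.0, 30.9, 176.3, 120.5,
    "N", 53.1, 38.9, 175.2, 118.7,
    "D", 54.2, 41.1, 176.3, 120.4,
    "C", 58.2, 28.0, 174.6, 118.8,
    "Q", 55.7, 29.4, 176.0, 119.8,
    "E", 56.6, 29.9, 176.6, 120.2,
    "G", 45.1,   NA, 174.9, 108.8,
    "H", 55.0, 29.0, 174.1, 118.2,
    "I", 61.1, 38.8, 176.4, 119.9,
    "L", 55.1, 42.4, 177.6, 121.8,
    "K", 56.2, 33.1, 176.6, 120.4,
    "M", 55.4, 32.9, 176.3, 119.6,
    "F", 57.7, 39.6, 175.8, 120.3,
    "P", 63.3, 32.1, 177.3,    NA,
    "S", 58.3, 63.8, 174.6, 115.7,
    "T", 61.8, 69.8, 174.7, 113.6,
    "W", 57.5, 29.6, 176.1, 121.3,
    "Y", 57.9, 38.8, 175.7, 120.3,
    "V", 62.2, 32.9, 176.3, 119.2
  )
}

# three-letter -> one-letter residue codes (for NMR-STAR input)
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
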