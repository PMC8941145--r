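## Physical constants and lookup tables. The isotope and residue tables are
## shipped as plain-text files under inst/extdata and cached per session.

.sisca_cache <- new.env(parent = emptyenv())

#' Isotope mass and abundance table
#'
#' Natural isotope masses and abundances for the elements occurring in
#' unmodified peptides (C, H, N, O, S), read from the versioned constants
#' file shipped with the package.
#'
#' @return A data.frame with columns `element`, `isotope`, `mass`,
#'   `abundance`, `neutron_shift`.
#' @export
isotope_table <- function() {
  if (is.null(.sisca_cache$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "sisca",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    .sisca_cache$isotopes <- tab
  }
  .sisca_cache$isotopes
}

#' Amino-acid residue composition table
#'
#' Elemental compositions (C, H, N, O, S) of the 20 standard amino-acid
#' residues (free amino acid minus one water).
#'
#' @return A data.frame with one row per residue.
#' @export
residue_table <- function() {
  if (is.null(.sisca_cache$residues)) {
    path <- system.file("extdata", "residues.tsv", package = "sisca",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$residue
    .sisca_cache$residues <- tab
  }
  .sisca_cache$residues
}

## mass of a proton (u); used to convert neutral mass to m/z
PROTON_MASS <- 1.00727646688

## 13C - 12C mass difference (u); isotopologue spacing is this over charge
C13_C12_DELTA <- 1.0033548

#' Natural 13C abundance
#'
#' The relative isotope abundance of 13C in unlabeled biomass, from the
#' shipped isotope table (0.0107).
#' @return A single numeric fraction.
#' @export
natural_ria <- function() {
  tab <- isotope_table()
  tab$abundance[tab$element == "C" & tab$neutron_shift == 1]
}

## Fixed (non-variable) modifications supported by the search setup:
## carbamidomethylation of cysteine, oxidation of methionine.
MODIFICATIONS <- list(
  carbamidomethyl = list(adduct = c(C = 2, H = 3, N = 1, O = 1, S = 0),
                         residues = "C"),
  oxidation       = list(adduct = c(C = 0, H = 0, N = 0, O = 1, S = 0),
                         residues = "M")
)

ELEMENTS <- c("C", "H", "N", "O", "S")
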