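## Peptide elemental composition and theoretical isotopologue patterns.

#' Elemental composition of a (modified) peptide
#'
#' Sums residue compositions over the sequence and adds one water, plus the
#' adducts of any modifications. Supported modifications are
#' `"carbamidomethyl"` (cysteine; adds C2H3NO) and `"oxidation"`
#' (methionine; adds one O).
#'
#' @param sequence Peptide sequence using the 20 standard one-letter codes.
#' @param modifications Optional modification list: either a data.frame with
#'   columns `position` and `name`, or a character string like
#'   `"1:carbamidomethyl;4:oxidation"` (empty string or `NA` means none).
#' @return An object of class `elemental_composition`: a named integer
#'   vector of atom counts for C, H, N, O, S.
#' @examples
#' composition_from_peptide("GG")
#' composition_from_peptide("CAK", "1:carbamidomethyl")
#' @export
composition_from_peptide <- function(sequence, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  res <- strsplit(toupper(sequence), "")[[1]]
  tab <- residue_table()
  unknown <- setdiff(res, tab$residue)
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  }
  counts <- colSums(tab[res, ELEMENTS, drop = FALSE])
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # one water

  mods <- parse_modifications(modifications)
  if (!is.null(mods) && nrow(mods) > 0) {
    for (i in seq_len(nrow(mods))) {
      name <- mods$name[i]
      pos <- mods$position[i]
      if (!name %in% names(MODIFICATIONS)) {
        stop("unsupported modification: ", name)
      }
      spec <- MODIFICATIONS[[name]]
      if (pos < 1 || pos > length(res)) {
        stop("modification position ", pos, " outside sequence")
      }
      if (!res[pos] %in% spec$residues) {
        stop("modification '", name, "' not applicable to residue '",
             res[pos], "' at position ", pos)
      }
      counts <- counts + spec$adduct[ELEMENTS]
    }
  }
  structure(as.integer(counts), names = ELEMENTS,
            class = "elemental_composition")
}

parse_modifications <- function(modifications) {
  if (is.null(modifications)) return(NULL)
  if (is.data.frame(modifications)) {
    stopifnot(all(c("position", "name") %in% names(modifications)))
    return(modifications)
  }
  if (is.character(modifications)) {
    if (length(modifications) != 1 || is.na(modifications) ||
        !nzchar(trimws(modifications))) {
      return(NULL)
    }
    parts <- strsplit(trimws(modifications), ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(trimws(parts))]
    pieces <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(pieces, length, 1L) != 2L
    if (any(bad)) stop("malformed modification string: ", modifications)
    return(data.frame(
      position = as.integer(vapply(pieces, `[`, "", 1)),
      name = trimws(vapply(pieces, `[`, "", 2)),
      stringsAsFactors = FALSE
    ))
  }
  stop("modifications must be NULL, a data.frame, or a character string")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  cat("<elemental composition> ",
      paste0(names(nz), nz, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Sum of two elemental compositions
#' @param e1,e2 `elemental_composition` objects.
#' @export
"+.elemental_composition" <- function(e1, e2) {
  structure(as.integer(unclass(e1) + unclass(e2)), names = ELEMENTS,
            class = "elemental_composition")
}

#' Monoisotopic mass of a composition
#' @param composition An `elemental_composition` (or named count vector).
#' @return Monoisotopic (all-lightest-isotope) neutral mass in u.
#' @export
monoisotopic_mass <- function(composition) {
  tab <- isotope_table()
  mono <- tab[tab$neutron_shift == 0, ]
  masses <- stats::setNames(mono$mass, mono$element)
  sum(masses[ELEMENTS] * as.numeric(composition[ELEMENTS]))
}

## discrete convolution of two probability vectors indexed from shift 0
conv_dist <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

## n-fold convolution power by squaring
conv_pow <- function(base, n) {
  if (n == 0L) return(1)
  acc <- NULL
  sq <- base
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- if (is.null(acc)) sq else conv_dist(acc, sq)
    n <- n %/% 2L
    if (n > 0L) sq <- conv_dist(sq, sq)
  }
  acc
}

## neutron-shift distribution for n atoms of one element at natural
## abundance (abundances from the isotope table)
element_shift_dist <- function(element, n) {
  if (n == 0L) return(1)
  tab <- isotope_table()
  sub <- tab[tab$element == element, ]
  base <- numeric(max(sub$neutron_shift) + 1L)
  base[sub$neutron_shift + 1L] <- sub$abundance
  if (length(base) == 2L) return(stats::dbinom(0:n, n, base[2]))
  conv_pow(base, as.integer(n))
}

#' Predict the isotopologue pattern of a peptide at a given 13C RIA
#'
#' Carbon isotopes are drawn binomially with success probability equal to
#' the relative isotope abundance (RIA); all other elements contribute at
#' natural abundance. Per-element neutron-shift distributions are combined
#' by discrete convolution, aggregating isotopologues by nominal mass
#' shift. The pattern is truncated at the shortest prefix reaching the
#' cumulative-abundance cutoff and renormalized to sum one.
#'
#' @param composition An `elemental_composition`, or a peptide sequence
#'   string (converted with [composition_from_peptide()]).
#' @param ria Fraction of carbon atoms that are 13C, in \[0, 1\].
#' @param charge Positive integer charge state (protonation assumed).
#' @param coverage Cumulative-abundance cutoff in \[0.9, 1); default 0.999.
#' @return An object of class `isotopologue_pattern` with fields `base_mz`
#'   (monoisotopic m/z), `charge`, `intensities` (relative abundances at
#'   isotopologue index 0, 1, 2, ...; sums to 1), and `spacing`
#'   (13C-12C mass difference divided by charge).
#' @examples
#' predict_pattern(composition_from_peptide("PEPTIDEK"), ria = 0.5, charge = 2)
#' @export
predict_pattern <- function(composition, ria, charge = 1L, coverage = 0.999) {
  if (is.character(composition)) {
    composition <- composition_from_peptide(composition)
  }
  if (!is.numeric(ria) || length(ria) != 1 || is.na(ria) ||
      ria < 0 || ria > 1) {
    stop("ria must be a single value in [0, 1]")
  }
  stopifnot(charge >= 1, coverage >= 0.9, coverage < 1)
  counts <- stats::setNames(as.integer(composition[ELEMENTS]), ELEMENTS)

  dist <- stats::dbinom(0:counts[["C"]], counts[["C"]], ria)
  for (el in setdiff(ELEMENTS, "C")) {
    if (counts[[el]] > 0L) {
      dist <- conv_dist(dist, element_shift_dist(el, counts[[el]]))
    }
  }
  keep <- which(cumsum(dist) >= coverage)[1]
  if (is.na(keep)) keep <- length(dist)
  intens <- dist[seq_len(keep)]
  intens <- intens / sum(intens)

  mono <- monoisotopic_mass(counts)
  new_pattern(
    base_mz = (mono + charge * PROTON_MASS) / charge,
    charge = as.integer(charge),
    intensities = intens
  )
}

new_pattern <- function(base_mz, charge, intensities) {
  structure(
    list(base_mz = base_mz, charge = as.integer(charge),
         intensities = as.numeric(intensities),
         spacing = C13_C12_DELTA / charge),
    class = "isotopologue_pattern"
  )
}

#' @export
print.isotopologue_pattern <- function(x, ...) {
  cat(sprintf(
    "<isotopologue pattern> base m/z %.4f (%d+), %d isotopologues, spacing %.6f\n",
    x$base_mz, x$charge, length(x$intensities), x$spacing))
  print(round(x$intensities, 4))
  invisible(x)
}

#' RIA grid
#'
#' Uniform grid of 13C relative isotope abundances from 0 to 1. The default
#' step of 0.05 gives the standard 21-point grid.
#'
#' @param step Grid step; 1/step must be a whole number.
#' @return Numeric vector of grid values, class `ria_grid`.
#' @export
ria_grid <- function(step = 0.05) {
  stopifnot(step > 0, step <= 1)
  n <- 1 / step
  if (abs(n - round(n)) > 1e-9) stop("1/step must be a whole number")
  structure(seq(0, 1, length.out = round(n) + 1), class = "ria_grid")
}

#' Reference pattern set over an RIA grid
#'
#' Predicts one isotopologue pattern per grid value; the default grid
#' (step 0.05) yields 21 reference patterns per peptide.
#'
#' @inheritParams predict_pattern
#' @param grid An [ria_grid()] (or numeric vector of RIA fractions).
#' @return List of `isotopologue_pattern`, one per grid value, in grid
#'   order, with the grid attached as attribute `grid`.
#' @export
reference_pattern_set <- function(composition, charge = 1L,
                                  grid = ria_grid(), coverage = 0.999) {
  if (is.character(composition)) {
    composition <- composition_from_peptide(composition)
  }
  vals <- as.numeric(grid)
  stopifnot(length(vals) >= 2, all(vals >= 0), all(vals <= 1),
            all(diff(vals) > 0))
  out <- lapply(vals, function(r) {
    predict_pattern(composition, ria = r, charge = charge,
                    coverage = coverage)
  })
  attr(out, "grid") <- vals
  out
}
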