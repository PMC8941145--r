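## Readers and writers for the plain-text interchange formats: protein
## FASTA with MAG/genus header tokens, tab-separated identification
## tables, and tab-separated centroided peak lists.

#' Read a protein database FASTA with MAG annotations
#'
#' Headers follow the convention
#' `>proteinID MAG=<magID> genus=<genus>`; the MAG and genus tokens are
#' optional and parsed into columns when present.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A data.frame with columns `protein`, `sequence`, `mag`, `genus`
#'   (NA where a token is absent).
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  grab <- function(h, key) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (length(m) == 0) NA_character_ else sub(paste0(key, "="), "", m)
  }
  data.frame(
    protein = vapply(strsplit(headers, "\\s+"), `[`, "", 1),
    sequence = as.character(seqs),
    mag = vapply(headers, grab, "", key = "MAG", USE.NAMES = FALSE),
    genus = vapply(headers, grab, "", key = "genus", USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write a protein database FASTA with MAG annotations
#'
#' @param proteins A data.frame as returned by [read_protein_fasta()].
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  names(seqs) <- paste0(proteins$protein,
                        ifelse(is.na(proteins$mag), "",
                               paste0(" MAG=", proteins$mag)),
                        ifelse(is.na(proteins$genus), "",
                               paste0(" genus=", proteins$genus)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

ID_COLUMNS <- c("sequence", "mods", "charge", "mz", "rt_min", "sample",
                "replicate", "timepoint", "proteins", "mags", "genus")

#' Read a peptide identification table
#'
#' Tab-separated table of peptide identifications from the unlabeled (12C)
#' samples. Required columns: `sequence`, `mods` (e.g.
#' `"1:carbamidomethyl"`, empty for none), `charge`, `mz`, `rt_min`,
#' `sample`, `replicate`, `timepoint`, `proteins` (semicolon-separated
#' accessions), `mags`, `genus`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the columns above.
#' @export
read_identifications <- function(path) {
  ids <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing <- setdiff(ID_COLUMNS, names(ids))
  if (length(missing) > 0) {
    stop("identification table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(all(ids$charge >= 1), all(ids$rt_min >= 0))
  # an all-empty mods column reads back as logical NA; keep it character
  ids$mods <- as.character(ids$mods)
  for (col in c("sample", "replicate", "timepoint", "proteins", "mags",
                "genus")) {
    ids[[col]] <- as.character(ids[[col]])
  }
  ids
}

#' Write a peptide identification table
#' @param ids Identification data.frame.
#' @param path Output path.
#' @export
write_identifications <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a centroided peak list
#'
#' Tab-separated peak list with columns `mz`, `intensity`, `rt_min`.
#'
#' @param path Path to the TSV file.
#' @param sample Optional sample ID attached as attribute.
#' @return A data.frame of centroids, class `peak_list`.
#' @export
read_peaklist <- function(path, sample = NA_character_) {
  pk <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mz", "intensity", "rt_min") %in% names(pk)))
  as_peaklist(pk, sample = sample)
}

#' Construct a peak list from a data.frame
#' @param pk A data.frame with columns `mz`, `intensity`, `rt_min`.
#' @param sample Optional sample ID.
#' @export
as_peaklist <- function(pk, sample = NA_character_) {
  stopifnot(all(c("mz", "intensity", "rt_min") %in% names(pk)))
  if (nrow(pk) > 0) {
    stopifnot(all(pk$mz > 0), all(pk$intensity >= 0))
  }
  attr(pk, "sample") <- sample
  class(pk) <- c("peak_list", "data.frame")
  pk
}

#' Write a peak list
#' @param pk A `peak_list` (or compatible data.frame).
#' @param path Output path.
#' @export
write_peaklist <- function(pk, path) {
  utils::write.table(as.data.frame(pk)[, c("mz", "intensity", "rt_min")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
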