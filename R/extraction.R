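## Locating, validating, and filtering measured isotopologue patterns in
## 13C-sample peak lists, guided by 12C-sample peptide identifications.

#' Filter peptides by MAG uniqueness
#'
#' Retains a peptide only if all proteins it matches lie in a single MAG,
#' or if all matched MAGs share the same genus-level classification.
#' Retained rows carry a single resolved label: the MAG ID where unique to
#' one MAG, otherwise `genus:<genus>`.
#'
#' @param ids Identification data.frame (see [read_identifications()]).
#' @param mag_map A data.frame mapping `protein` to `mag` and `genus`; must
#'   cover every accession referenced by `ids`.
#' @return The retained subset of `ids` with added columns `label` (resolved
#'   MAG-or-genus label) and `label_level` (`"mag"` or `"genus"`).
#' @export
filter_peptides <- function(ids, mag_map) {
  stopifnot(all(c("protein", "mag", "genus") %in% names(mag_map)))
  lookup_mag <- stats::setNames(mag_map$mag, mag_map$protein)
  lookup_genus <- stats::setNames(mag_map$genus, mag_map$protein)

  labels <- character(nrow(ids))
  levels <- character(nrow(ids))
  keep <- logical(nrow(ids))
  for (i in seq_len(nrow(ids))) {
    prots <- strsplit(ids$proteins[i], ";", fixed = TRUE)[[1]]
    missing <- setdiff(prots, names(lookup_mag))
    if (length(missing) > 0) {
      stop("accession(s) missing from mag_map: ",
           paste(missing, collapse = ", "))
    }
    mags <- unique(lookup_mag[prots])
    if (length(mags) == 1) {
      keep[i] <- TRUE
      labels[i] <- mags
      levels[i] <- "mag"
    } else {
      genera <- unique(lookup_genus[prots])
      if (length(genera) == 1 && !is.na(genera)) {
        keep[i] <- TRUE
        labels[i] <- paste0("genus:", genera)
        levels[i] <- "genus"
      }
    }
  }
  out <- ids[keep, , drop = FALSE]
  out$label <- labels[keep]
  out$label_level <- levels[keep]
  rownames(out) <- NULL
  out
}

#' Locate the isotopologue pattern of an identified peptide in a peak list
#'
#' Searches candidate isotopologue positions `base_mz + k * spacing` for
#' `k = -1, 0, ..., max_index` among centroids within the mass tolerance
#' (p.p.m.) and retention-time tolerance (minutes) of the identification.
#' Among in-tolerance candidates the peak with the smallest absolute
#' p.p.m. deviation wins (ties broken by higher intensity). Positions with
#' no matching peak are recorded as zero intensity. The `k = -1` position
#' (one 13C-12C spacing before the monoisotopic peak) is searched only to
#' support downstream M-1 validation and is not part of the pattern.
#'
#' @param id One row of an identification table (list or single-row
#'   data.frame with `sequence`, `mods`, `charge`, `mz`, `rt_min`).
#' @param peaks A `peak_list` for the labeled sample.
#' @param ppm_tol Mass tolerance in p.p.m. (match requires deviation
#'   strictly below this); default 10.
#' @param rt_tol Retention-time tolerance in minutes (strictly below);
#'   default 3.
#' @param max_index Largest isotopologue index searched; defaults to the
#'   peptide's carbon count (the largest possible 13C shift).
#' @return A `measured_pattern` (list with the identification, the
#'   intensity series indexed from the monoisotopic peak, the matched m/z
#'   values, the M-1 intensity, and quality flags), or `NULL` if no
#'   position matched any peak.
#' @export
locate_pattern <- function(id, peaks, ppm_tol = 10, rt_tol = 3,
                           max_index = NULL) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  id <- as.list(id)
  comp <- composition_from_peptide(id$sequence, id$mods)
  if (is.null(max_index)) max_index <- as.integer(comp[["C"]])
  spacing <- C13_C12_DELTA / id$charge
  base_mz <- id$mz

  pk <- as.data.frame(peaks)
  in_rt <- abs(pk$rt_min - id$rt_min) < rt_tol
  pk <- pk[in_rt, , drop = FALSE]

  k_all <- c(-1L, 0:max_index)
  intens <- numeric(length(k_all))
  mzs <- rep(NA_real_, length(k_all))
  for (j in seq_along(k_all)) {
    target <- base_mz + k_all[j] * spacing
    dev_ppm <- abs(pk$mz - target) / target * 1e6
    cand <- which(dev_ppm < ppm_tol)
    if (length(cand) > 0) {
      best <- cand[order(dev_ppm[cand], -pk$intensity[cand])][1]
      intens[j] <- pk$intensity[best]
      mzs[j] <- pk$mz[best]
    }
  }
  pattern_int <- intens[-1]
  if (all(intens == 0)) return(NULL)
  structure(
    list(
      id = id,
      intensities = pattern_int,
      mz = mzs[-1],
      base_mz = base_mz,
      spacing = spacing,
      m1_intensity = intens[1],
      flags = character(0)
    ),
    class = "measured_pattern"
  )
}

#' @export
print.measured_pattern <- function(x, ...) {
  cat(sprintf("<measured pattern> %s (%d+), %d positions, total intensity %.3g\n",
              x$id$sequence, x$id$charge, length(x$intensities),
              sum(x$intensities)))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a located pattern against M-1 and overlap criteria
#'
#' Rejects a pattern if a signal exists one isotopologue spacing before the
#' monoisotopic peak (M-1) above a relative threshold, or if another
#' peptide's expected isotopologue positions intersect this pattern's
#' positions within the mass tolerance while their retention-time windows
#' overlap.
#'
#' @param p A `measured_pattern`.
#' @param neighbors List of other `measured_pattern`s (or identification
#'   rows) eluting in the same sample.
#' @param m1_rel_threshold M-1 rejection threshold as a fraction of the
#'   pattern's maximum intensity; default 0.05.
#' @param ppm_tol Mass tolerance (p.p.m.) used for the overlap test.
#' @param rt_tol Retention-time window half-width (minutes) for overlap.
#' @return `p` with `accepted = TRUE` in its flags, or a rejection: a list
#'   with `accepted = FALSE` and machine-readable `reason` (`"M-1"` or
#'   `"overlap"`).
#' @export
validate_pattern <- function(p, neighbors = list(), m1_rel_threshold = 0.05,
                             ppm_tol = 10, rt_tol = 3) {
  stopifnot(inherits(p, "measured_pattern"))
  if (p$m1_intensity > m1_rel_threshold * max(p$intensities)) {
    return(list(accepted = FALSE, reason = "M-1", pattern = p))
  }
  own_pos <- p$base_mz + (seq_along(p$intensities) - 1L) * p$spacing
  for (nb in neighbors) {
    nb <- if (inherits(nb, "measured_pattern")) {
      list(base_mz = nb$base_mz, spacing = nb$spacing,
           n = length(nb$intensities), rt = nb$id$rt_min,
           sequence = nb$id$sequence)
    } else {
      nbl <- as.list(nb)
      comp <- composition_from_peptide(nbl$sequence, nbl$mods)
      list(base_mz = nbl$mz, spacing = C13_C12_DELTA / nbl$charge,
           n = as.integer(comp[["C"]]) + 1L, rt = nbl$rt_min,
           sequence = nbl$sequence)
    }
    if (identical(nb$sequence, p$id$sequence) &&
        abs(nb$rt - p$id$rt_min) < 1e-9) next
    if (abs(nb$rt - p$id$rt_min) >= rt_tol) next
    nb_pos <- nb$base_mz + (seq_len(nb$n) - 1L) * nb$spacing
    for (pos in own_pos) {
      if (any(abs(nb_pos - pos) / pos * 1e6 < ppm_tol)) {
        return(list(accepted = FALSE, reason = "overlap", pattern = p))
      }
    }
  }
  p$flags <- union(p$flags, "accepted")
  p
}

#' Enforce replicate support per MAG and time point
#'
#' Drops MAG/time-point combinations supported by fewer than
#' `min_replicates` distinct replicates, so every aggregated profile rests
#' on replicated measurements.
#'
#' @param patterns List of accepted `measured_pattern`s whose
#'   identifications carry `label` (resolved MAG-or-genus), `timepoint`,
#'   and `replicate` fields.
#' @param min_replicates Minimum number of distinct replicates; default 2.
#' @return The retained sublist, order-stable.
#' @export
require_replicates <- function(patterns, min_replicates = 2L) {
  if (length(patterns) == 0) return(patterns)
  key <- vapply(patterns, function(p) {
    paste(p$id$label, p$id$timepoint, sep = "\r")
  }, "")
  reps <- vapply(patterns, function(p) as.character(p$id$replicate), "")
  support <- tapply(reps, key, function(r) length(unique(r)))
  keep <- support[key] >= min_replicates
  patterns[keep]
}
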