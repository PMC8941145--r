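## Bulk driver: from an identification table plus per-sample peak lists to
## the accepted measured patterns that feed sisca() and growth_table().

#' Extract measured patterns for a whole identification table
#'
#' Applies MAG-uniqueness filtering (when a `mag_map` is supplied), then
#' locates each identification's isotopologue pattern in the peak list of
#' its sample and screens it for M-1 contamination. Neighbor-overlap
#' screening can be enabled where identification density warrants it.
#'
#' @param ids Identification data.frame (see [read_identifications()]);
#'   must carry a `label` column, or a `mag_map` to derive one.
#' @param peaklists Named list of `peak_list` objects, keyed by the
#'   `sample` column of `ids`.
#' @param mag_map Optional protein-to-MAG/genus map for
#'   [filter_peptides()].
#' @param ppm_tol,rt_tol Location tolerances (p.p.m., minutes).
#' @param m1_rel_threshold M-1 rejection threshold, see
#'   [validate_pattern()].
#' @param check_overlap If TRUE, each pattern is also validated against
#'   all other identifications in the same sample (quadratic cost).
#' @param max_index Largest isotopologue index searched; default the
#'   peptide's carbon count.
#' @return List with `patterns` (accepted `measured_pattern`s) and
#'   `rejections` (data.frame of sequence, sample, reason).
#' @export
extract_patterns <- function(ids, peaklists, mag_map = NULL,
                             ppm_tol = 10, rt_tol = 3,
                             m1_rel_threshold = 0.05,
                             check_overlap = FALSE, max_index = NULL) {
  if (!is.null(mag_map)) ids <- filter_peptides(ids, mag_map)
  if (is.null(ids$label)) {
    stop("ids must have a 'label' column (or supply mag_map)")
  }
  patterns <- list()
  rej <- list()
  for (i in seq_len(nrow(ids))) {
    row <- as.list(ids[i, ])
    pk <- peaklists[[row$sample]]
    if (is.null(pk)) stop("no peak list for sample ", row$sample)
    p <- locate_pattern(row, pk, ppm_tol = ppm_tol, rt_tol = rt_tol,
                        max_index = max_index)
    if (is.null(p)) {
      rej[[length(rej) + 1]] <- data.frame(
        sequence = row$sequence, sample = row$sample, reason = "not-found",
        stringsAsFactors = FALSE)
      next
    }
    neighbors <- if (check_overlap) {
      same <- which(ids$sample == row$sample & seq_len(nrow(ids)) != i)
      lapply(same, function(j) as.list(ids[j, ]))
    } else {
      list()
    }
    v <- validate_pattern(p, neighbors = neighbors,
                          m1_rel_threshold = m1_rel_threshold,
                          ppm_tol = ppm_tol, rt_tol = rt_tol)
    if (inherits(v, "measured_pattern")) {
      patterns[[length(patterns) + 1]] <- v
    } else {
      rej[[length(rej) + 1]] <- data.frame(
        sequence = row$sequence, sample = row$sample, reason = v$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(patterns = patterns,
       rejections = if (length(rej) > 0) do.call(rbind, rej)
                    else data.frame(sequence = character(0),
                                    sample = character(0),
                                    reason = character(0)))
}
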