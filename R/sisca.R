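## The cluster-analysis core: R-squared grids per peptide, aggregation per
## MAG and time point, and the classed `sisca` fit that ties them together.

#' Coefficient of determination between measured and predicted patterns
#'
#' Computes `1 - SS_res / SS_tot`, where `SS_res` is the sum of squared
#' differences between the measured and predicted relative intensities and
#' `SS_tot` is the total sum of squares of the measured vector about its
#' mean. Patterns are aligned on isotopologue index over the union of
#' defined indices (missing positions count as zero) and normalized to sum
#' one. The value can be negative for badly mismatched patterns; comparing
#' a pattern with itself gives exactly 1.
#'
#' @param measured,predicted `isotopologue_pattern` objects, or plain
#'   numeric intensity vectors indexed from the monoisotopic peak.
#' @return A single numeric value `<= 1`.
#' @examples
#' r_squared(c(1, 0), c(0.5, 0.5))  # 0
#' @export
r_squared <- function(measured, predicted) {
  m <- pattern_intensities(measured)
  p <- pattern_intensities(predicted)
  if (sum(m) <= 0) stop("measured pattern has zero total intensity")
  if (sum(p) <= 0) stop("predicted pattern has zero total intensity")
  n <- max(length(m), length(p))
  m <- c(m, numeric(n - length(m))) / sum(m)
  p <- c(p, numeric(n - length(p))) / sum(p)
  ss_res <- sum((m - p)^2)
  ss_tot <- sum((m - mean(m))^2)
  1 - ss_res / ss_tot
}

pattern_intensities <- function(x) {
  if (inherits(x, "isotopologue_pattern")) return(x$intensities)
  if (inherits(x, "measured_pattern")) return(x$intensities)
  as.numeric(x)
}

#' R-squared profile of a measured pattern over an RIA grid
#'
#' Compares one measured isotopologue pattern against reference patterns
#' predicted at each grid RIA, retaining the full vector of R-squared
#' values — the feature vector of the cluster analysis.
#'
#' @param measured A `measured_pattern` or intensity vector.
#' @param refs Reference set from [reference_pattern_set()], generated from
#'   the peptide's own composition and charge.
#' @param grid The grid the references were built on; defaults to the
#'   reference set's `grid` attribute.
#' @return Numeric vector of R-squared values, one per grid value, with the
#'   grid attached as attribute `grid`.
#' @export
ria_profile <- function(measured, refs, grid = attr(refs, "grid")) {
  if (is.null(grid)) stop("no grid supplied or attached to refs")
  if (length(refs) != length(grid)) {
    stop("reference set and grid have different lengths")
  }
  r2 <- vapply(refs, function(p) r_squared(measured, p), 0.0)
  attr(r2, "grid") <- as.numeric(grid)
  r2
}

#' Aggregate R-squared profiles per MAG and time point
#'
#' Element-wise arithmetic mean of the profiles of all peptides and
#' replicates assigned to the same MAG (or genus-level label) and time
#' point.
#'
#' @param profiles Numeric matrix, one row per peptide-level profile
#'   (columns = grid values).
#' @param label Character vector of resolved MAG-or-genus labels, one per
#'   row.
#' @param timepoint Vector of time-point labels, one per row.
#' @return A data.frame with columns `label`, `timepoint`, and the averaged
#'   profile matrix in column `profile` (a matrix column, rows aligned).
#' @export
aggregate_profiles <- function(profiles, label, timepoint) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0) stop("empty profile set")
  stopifnot(length(label) == nrow(profiles),
            length(timepoint) == nrow(profiles))
  key <- paste(label, timepoint, sep = "\r")
  groups <- sort(unique(key))
  agg <- t(vapply(groups, function(g) {
    colMeans(profiles[key == g, , drop = FALSE])
  }, numeric(ncol(profiles))))
  parts <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  out <- data.frame(label = parts[, 1], timepoint = parts[, 2],
                    stringsAsFactors = FALSE)
  out$profile <- agg
  rownames(out) <- NULL
  out
}

order_timepoints <- function(tp) {
  u <- unique(as.character(tp))
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", u)))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Fit a stable isotope cluster analysis
#'
#' The central fitting routine: from accepted measured isotopologue
#' patterns it computes, per peptide, the R-squared profile against
#' reference patterns predicted over the RIA grid; averages profiles per
#' MAG and time point (after enforcing replicate support); and derives
#' per-MAG trajectories of the most probable RIA. The result is the input
#' to ordination, lifestyle classification, and growth quantification.
#'
#' @param patterns List of `measured_pattern`s whose identifications carry
#'   `label`, `timepoint`, and `replicate` fields (see
#'   [filter_peptides()], [locate_pattern()], [validate_pattern()]).
#' @param grid RIA grid; default 21 points at 5 percent spacing.
#' @param min_replicates Minimum distinct replicates per MAG/time point
#'   (default 2); groups below this are dropped.
#' @param coverage Cumulative-abundance cutoff for predicted patterns.
#' @return An object of class `sisca` with components `grid`,
#'   `peptide_profiles` (matrix plus `meta` data.frame), `aggregated`
#'   (per MAG/time point profiles), `trajectories` (per-MAG matrix of
#'   profiles by time point plus RIA point estimates), and `timepoints`.
#' @seealso [ordinate()], [classify_lifestyle()], [most_probable_ria()]
#' @export
sisca <- function(patterns, grid = ria_grid(), min_replicates = 2L,
                  coverage = 0.999) {
  patterns <- require_replicates(patterns, min_replicates)
  if (length(patterns) == 0) {
    stop("no patterns remain after replicate filtering")
  }
  gvals <- as.numeric(grid)

  prof <- matrix(NA_real_, nrow = length(patterns), ncol = length(gvals))
  meta <- data.frame(
    sequence = vapply(patterns, function(p) p$id$sequence, ""),
    charge = vapply(patterns, function(p) as.integer(p$id$charge), 0L),
    label = vapply(patterns, function(p) as.character(p$id$label), ""),
    timepoint = vapply(patterns, function(p) as.character(p$id$timepoint), ""),
    replicate = vapply(patterns, function(p) as.character(p$id$replicate), ""),
    stringsAsFactors = FALSE
  )
  ref_cache <- new.env(parent = emptyenv())
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    mods_chr <- if (is.null(p$id$mods) || is.na(p$id$mods)) "" else p$id$mods
    key <- paste(p$id$sequence, mods_chr, p$id$charge, sep = "\r")
    refs <- ref_cache[[key]]
    if (is.null(refs)) {
      comp <- composition_from_peptide(p$id$sequence, p$id$mods)
      refs <- reference_pattern_set(comp, charge = p$id$charge,
                                    grid = gvals, coverage = coverage)
      ref_cache[[key]] <- refs
    }
    prof[i, ] <- ria_profile(p, refs, grid = gvals)
  }

  agg <- aggregate_profiles(prof, meta$label, meta$timepoint)
  tps <- order_timepoints(agg$timepoint)

  trajectories <- lapply(split(seq_len(nrow(agg)), agg$label), function(ix) {
    sub <- agg[ix, , drop = FALSE]
    sub <- sub[match(tps, sub$timepoint), , drop = FALSE]
    mat <- sub$profile
    rownames(mat) <- tps
    ria <- vapply(seq_len(nrow(mat)), function(r) {
      if (anyNA(mat[r, ])) NA_real_ else most_probable_ria(mat[r, ], gvals)$ria
    }, 0.0)
    list(profiles = mat, ria = stats::setNames(ria, tps))
  })

  structure(
    list(grid = gvals,
         peptide_profiles = list(r2 = prof, meta = meta),
         aggregated = agg,
         trajectories = trajectories,
         timepoints = tps,
         min_replicates = min_replicates,
         call = match.call()),
    class = "sisca"
  )
}

#' @export
print.sisca <- function(x, ...) {
  cat("Stable isotope cluster analysis\n")
  cat(sprintf("  %d peptide patterns, %d MAG labels, %d time points, %d-point RIA grid\n",
              nrow(x$peptide_profiles$r2), length(x$trajectories),
              length(x$timepoints), length(x$grid)))
  invisible(x)
}

#' @export
summary.sisca <- function(object, thresholds = lifestyle_thresholds(), ...) {
  ria <- t(vapply(object$trajectories, function(t) t$ria,
                  numeric(length(object$timepoints))))
  colnames(ria) <- object$timepoints
  calls <- vapply(rownames(ria), function(m) {
    v <- ria[m, ]
    if (anyNA(v) || length(v) < 2) return(NA_character_)
    classify_lifestyle(v, thresholds)$label
  }, "")
  out <- data.frame(label = rownames(ria), ria,
                    lifestyle = calls, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("summary.sisca", "data.frame")
  out
}

#' @export
print.summary.sisca <- function(x, ...) {
  cat("Per-MAG most probable RIA by time point and lifestyle call\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Plot a fitted cluster analysis
#'
#' Ordination scatter of the first two principal components, optionally
#' with cluster confidence ellipses.
#'
#' @param x A `sisca` fit.
#' @param labels Optional cluster assignment (named by MAG) to draw
#'   confidence ellipses for.
#' @param confidence Ellipse confidence level; default 0.95.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sisca <- function(x, labels = NULL, confidence = 0.95, ...) {
  ord <- ordinate(x)
  plot(ord, labels = labels, confidence = confidence, ...)
}
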