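## Ordination of MAG carbon-utilization profiles and confidence-ellipse
## cluster validation.

#' Ordinate MAG carbon-utilization profiles
#'
#' Principal component analysis of the aggregated R-squared profiles,
#' mean-centered and unscaled (all features already share the R-squared
#' scale). In the default one-point-per-MAG layout the per-time-point
#' profiles of each MAG are concatenated into one feature vector (grid
#' length times number of time points); the alternative layout ordinates
#' each MAG/time-point profile as its own observation. A deterministic
#' sign convention is applied: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x A `sisca` fit.
#' @param layout `"per_mag"` (default, one point per MAG) or
#'   `"per_mag_time"` (one point per MAG and time point).
#' @return An object of class `sisca_ordination`: list with `scores`,
#'   `loadings`, `var_explained` (non-increasing fractions summing to at
#'   most 1), `layout`, and row metadata.
#' @export
ordinate <- function(x, layout = c("per_mag", "per_mag_time")) {
  stopifnot(inherits(x, "sisca"))
  layout <- match.arg(layout)
  if (layout == "per_mag") {
    mags <- names(x$trajectories)
    if (length(mags) < 3) stop("need at least 3 MAGs to ordinate")
    incomplete <- mags[vapply(x$trajectories,
                              function(t) anyNA(t$profiles), TRUE)]
    if (length(incomplete) > 0) {
      stop("MAG(s) missing a time point in concatenated layout: ",
           paste(incomplete, collapse = ", "))
    }
    feat <- t(vapply(x$trajectories, function(t) as.numeric(t(t$profiles)),
                     numeric(length(x$grid) * length(x$timepoints))))
    rownames(feat) <- mags
    meta <- data.frame(label = mags, stringsAsFactors = FALSE)
  } else {
    agg <- x$aggregated
    feat <- agg$profile
    rownames(feat) <- paste(agg$label, agg$timepoint, sep = "@")
    if (nrow(feat) < 3) stop("need at least 3 observations to ordinate")
    meta <- data.frame(label = agg$label, timepoint = agg$timepoint,
                       stringsAsFactors = FALSE)
  }

  pc <- stats::prcomp(feat, center = TRUE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  structure(
    list(scores = scores, loadings = loadings,
         var_explained = ve[seq_len(ncol(scores))],
         layout = layout, meta = meta, center = pc$center),
    class = "sisca_ordination"
  )
}

#' @export
print.sisca_ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d observations (%s layout), %d components\n",
              nrow(x$scores), x$layout, ncol(x$scores)))
  ve <- round(100 * x$var_explained[seq_len(min(5, length(x$var_explained)))], 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

## Standard-error ellipse of a cluster mean on the first two components,
## scaled by the chi-square quantile at the given confidence. Shape matrix
## S is such that the ellipse is {x : (x-c)' S^-1 (x-c) <= 1}.
cluster_ellipse <- function(scores2, confidence) {
  n <- nrow(scores2)
  if (n < 2) return(NULL)
  ctr <- colMeans(scores2)
  shape <- stats::cov(scores2) / n * stats::qchisq(confidence, df = 2)
  list(center = ctr, shape = shape, n = n, confidence = confidence)
}

ellipse_boundary <- function(e, n_points = 360) {
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(theta), sin(theta))
  ev <- eigen(e$shape, symmetric = TRUE)
  ax <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  t(ax %*% circ + e$center)
}

point_in_ellipse <- function(pts, e) {
  d <- sweep(pts, 2, e$center)
  q <- tryCatch(solve(e$shape), error = function(err) NULL)
  if (is.null(q)) {
    return(rowSums(d^2) <= 1e-18)  # degenerate (zero-spread) ellipse
  }
  rowSums((d %*% q) * d) <= 1 + 1e-12
}

ellipses_overlap <- function(e1, e2) {
  if (any(point_in_ellipse(matrix(e2$center, 1), e1))) return(TRUE)
  if (any(point_in_ellipse(matrix(e1$center, 1), e2))) return(TRUE)
  b1 <- ellipse_boundary(e1)
  b2 <- ellipse_boundary(e2)
  any(point_in_ellipse(b1, e2)) || any(point_in_ellipse(b2, e1))
}

#' Validate manually defined clusters with confidence ellipses
#'
#' For each cluster, builds the two-dimensional confidence ellipse of the
#' cluster mean (standard-error ellipse on the first two principal
#' components, scaled by the chi-square quantile at the stated confidence)
#' and tests every pair of ellipses for overlap. Clusters whose ellipses
#' overlap are flagged as non-distinct. Singleton clusters have no ellipse
#' and are flagged, not treated as errors.
#'
#' @param ord A `sisca_ordination`.
#' @param labels Cluster assignment: character vector, either named by
#'   observation (row names of the scores) or in score row order.
#' @param confidence Confidence level; default 0.95.
#' @return List with `ellipses` (per cluster), `overlap` (logical matrix),
#'   `distinct` (per-cluster logical), and `singletons`.
#' @export
validate_clusters <- function(ord, labels, confidence = 0.95) {
  stopifnot(inherits(ord, "sisca_ordination"))
  obs <- rownames(ord$scores)
  if (!is.null(names(labels))) {
    missing <- setdiff(obs, names(labels))
    if (length(missing) > 0) {
      stop("unlabeled observation(s): ", paste(missing, collapse = ", "))
    }
    labels <- labels[obs]
  } else if (length(labels) != nrow(ord$scores)) {
    stop("labels must be named or match the number of observations")
  }
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  s2 <- ord$scores[, 1:2, drop = FALSE]

  ellipses <- lapply(clusters, function(cl) {
    cluster_ellipse(s2[labels == cl, , drop = FALSE], confidence)
  })
  names(ellipses) <- clusters
  singletons <- clusters[vapply(ellipses, is.null, TRUE)]

  k <- length(clusters)
  overlap <- matrix(NA, k, k, dimnames = list(clusters, clusters))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (is.null(ellipses[[i]]) || is.null(ellipses[[j]])) next
      overlap[i, j] <- ellipses_overlap(ellipses[[i]], ellipses[[j]])
    }
  }
  distinct <- apply(overlap, 1, function(r) all(!r[!is.na(r)]))
  list(ellipses = ellipses, overlap = overlap, distinct = distinct,
       singletons = singletons, confidence = confidence)
}

#' Convenience Ward clustering of ordination scores
#'
#' Agglomerative (Ward) clustering of the full score vectors at a
#' user-chosen number of clusters. The number of clusters is never chosen
#' automatically — cluster definition is an analyst decision that this
#' helper only supports.
#'
#' @param ord A `sisca_ordination`.
#' @param k Number of clusters (user-chosen).
#' @return Named character vector of cluster labels.
#' @export
cluster_mags <- function(ord, k) {
  stopifnot(inherits(ord, "sisca_ordination"), k >= 1)
  hc <- stats::hclust(stats::dist(ord$scores), method = "ward.D2")
  stats::setNames(as.character(stats::cutree(hc, k = k)),
                  rownames(ord$scores))
}

#' @export
plot.sisca_ordination <- function(x, labels = NULL, confidence = 0.95,
                                  ...) {
  s2 <- x$scores[, 1:2, drop = FALSE]
  xlab <- sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1])
  ylab <- sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2])
  col <- 1
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[rownames(s2)]
    col <- as.integer(factor(labels)) + 1L
  }
  graphics::plot(s2, xlab = xlab, ylab = ylab, col = col, pch = 19, ...)
  if (!is.null(labels)) {
    val <- validate_clusters(x, labels, confidence)
    for (i in seq_along(val$ellipses)) {
      e <- val$ellipses[[i]]
      if (is.null(e)) next
      b <- ellipse_boundary(e)
      graphics::lines(b, col = i + 1L)
    }
  }
  invisible(x)
}
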