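# build a `sisca` object directly from per-MAG profile matrices
# (rows = time points, cols = grid) for ordination-focused tests
fake_fit <- function(trajs, grid = seq(0, 1, 0.05),
                     timepoints = rownames(trajs[[1]])) {
  agg <- do.call(rbind, lapply(names(trajs), function(m) {
    d <- data.frame(label = m, timepoint = rownames(trajs[[m]]),
                    stringsAsFactors = FALSE)
    d$profile <- unname(trajs[[m]])
    d
  }))
  structure(list(
    grid = grid,
    aggregated = agg,
    trajectories = lapply(trajs, function(mat) {
      list(profiles = mat,
           ria = apply(mat, 1, function(r) grid[which.max(r)]))
    }),
    timepoints = timepoints
  ), class = "sisca")
}

test_that("the coefficient of determination matches hand-computed values", {
  expect_identical(r_squared(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3)), 1)
  expect_equal(r_squared(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)), -3.0)
  expect_equal(r_squared(c(1, 0), c(0.5, 0.5)), 0.0)
  expect_error(r_squared(c(0, 0), c(0.5, 0.5)), "zero total")
  # invariant under simultaneous reordering of both vectors
  set.seed(3)
  m <- runif(8); p <- runif(8)
  o <- sample(8)
  expect_equal(r_squared(m, p), r_squared(m[o], p[o]))
  # patterns of different lengths are aligned with zero padding
  expect_equal(r_squared(c(1, 0, 0), c(1)), 1)
})

test_that("RIA profiles peak at the true RIA and match the grid length", {
  comp <- composition_from_peptide("SAMPLEK")
  refs <- reference_pattern_set(comp, charge = 2)
  # noise-free pattern simulated at a grid RIA
  meas <- sim_measured("SAMPLEK", ria = 0.65, labeled_fraction = 1)
  prof <- ria_profile(meas, refs)
  expect_length(prof, 21)
  expect_equal(most_probable_ria(prof)$ria, 0.65)
  # natural-abundance pattern matches the zero-RIA reference
  nat <- sim_measured("SAMPLEK", ria = 0, labeled_fraction = 0)
  expect_equal(most_probable_ria(ria_profile(nat, refs))$ria, 0)
  expect_error(ria_profile(meas, refs[1:5], grid = seq(0, 1, 0.05)),
               "length")
})

test_that("profile aggregation is the element-wise mean and respects grouping", {
  p1 <- c(1, 0, 0); p2 <- c(0, 1, 0)
  agg <- aggregate_profiles(rbind(p1, p1), c("A", "A"), c("T1", "T1"))
  expect_equal(unname(agg$profile[1, ]), p1)
  agg2 <- aggregate_profiles(rbind(p1, p2), c("A", "A"), c("T1", "T1"))
  expect_equal(unname(agg2$profile[1, ]), c(0.5, 0.5, 0))
  # permutation invariance and idempotence on a single profile
  agg3 <- aggregate_profiles(rbind(p2, p1), c("A", "A"), c("T1", "T1"))
  expect_equal(agg2$profile, agg3$profile)
  expect_equal(unname(aggregate_profiles(rbind(p1), "A", "T1")$profile[1, ]),
               p1)
  # counting: 3 MAGs x 3 time points x 20 peptides -> 9 aggregated rows
  set.seed(1)
  n <- 3 * 3 * 20
  profs <- matrix(runif(n * 5), nrow = n)
  labels <- rep(paste0("MAG", 1:3), each = 60)
  tps <- rep(rep(c("T1", "T2", "T3"), each = 20), times = 3)
  expect_equal(nrow(aggregate_profiles(profs, labels, tps)), 9)
  expect_error(aggregate_profiles(matrix(numeric(0), 0, 5),
                                  character(0), character(0)), "empty")
})

test_that("ordination is a centered isometry with deterministic signs", {
  set.seed(21)
  tps <- c("T1", "T2", "T3")
  mk <- function() {
    m <- matrix(runif(3 * 21), 3, 21, dimnames = list(tps, NULL))
    m
  }
  trajs <- replicate(6, mk(), simplify = FALSE)
  names(trajs) <- paste0("MAG", 1:6)
  # two identical trajectories land on the same point
  trajs$MAG2 <- trajs$MAG1
  fit <- fake_fit(trajs)
  ord <- ordinate(fit)
  expect_equal(unname(ord$scores["MAG1", ]), unname(ord$scores["MAG2", ]),
               tolerance = 1e-9)
  # explained variance is non-increasing and sums to <= 1
  expect_true(all(diff(ord$var_explained) <= 1e-12))
  expect_lte(sum(ord$var_explained), 1 + 1e-9)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(ord$loadings))) {
    expect_gte(ord$loadings[which.max(abs(ord$loadings[, j])), j], 0)
  }
  # isometry: score distances equal centered-feature distances
  feat <- t(vapply(trajs, function(m) as.numeric(t(m)), numeric(63)))
  centered <- scale(feat, center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(ord$scores)),
               unname(as.matrix(dist(centered))),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("a single differing coordinate loads entirely on PC1", {
  tps <- c("T1", "T2")
  base <- matrix(0.5, 2, 21, dimnames = list(tps, NULL))
  trajs <- list(A = base, B = base, C = base, D = base)
  trajs$C[1, 7] <- 0.9
  trajs$D[1, 7] <- 0.1
  ord <- ordinate(fake_fit(trajs))
  expect_equal(ord$var_explained[1], 1, tolerance = 1e-9)
})

test_that("ordination validates layout completeness and size", {
  tps <- c("T1", "T2")
  m <- matrix(0.5, 2, 21, dimnames = list(tps, NULL))
  short <- m[1, , drop = FALSE]
  trajs <- list(A = m, B = m, C = rbind(short, NA * short))
  rownames(trajs$C) <- tps
  expect_error(ordinate(fake_fit(trajs)), "C")
  expect_error(ordinate(fake_fit(list(A = m, B = m))), "at least 3")
})

test_that("confidence ellipses flag overlapping and distinct clusters", {
  set.seed(9)
  # two clusters drawn from the same distribution overlap
  same <- rbind(matrix(rnorm(20, 0, 1), 10, 2),
                matrix(rnorm(20, 0, 1), 10, 2))
  ord <- structure(list(scores = same, var_explained = c(0.6, 0.4)),
                   class = "sisca_ordination")
  rownames(ord$scores) <- paste0("M", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  v <- validate_clusters(ord, labels)
  expect_true(v$overlap["a", "b"])
  expect_false(v$distinct[["a"]])

  # two tight clusters far apart are distinct
  apart <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
                 matrix(rnorm(20, 50, 0.05), 10, 2))
  rownames(apart) <- paste0("M", 1:20)
  ord2 <- structure(list(scores = apart, var_explained = c(0.9, 0.1)),
                    class = "sisca_ordination")
  v2 <- validate_clusters(ord2, labels)
  expect_false(v2$overlap["a", "b"])
  expect_true(all(v2$distinct))

  # singleton cluster: flagged, no ellipse, no error
  v3 <- validate_clusters(ord2, c("solo", labels[-1]))
  expect_true("solo" %in% v3$singletons)
  expect_null(v3$ellipses$solo)
})

test_that("lifestyle rules map the archetype trajectories to their labels", {
  expect_equal(classify_lifestyle(c(0.95, 0.95, 0.95))$label,
               "strict_autotroph")
  expect_equal(classify_lifestyle(c(0.65, 0.91, 0.91))$label,
               "switching_mixotroph")
  expect_equal(classify_lifestyle(c(0.18, 0.53, 0.76))$label,
               "crossfeeding_incorporator")
  expect_equal(classify_lifestyle(c(0.06, 0.06, 0.06))$label,
               "unlabeled_heterotroph")
  expect_error(classify_lifestyle(0.5), "at least 2")
  # every call reports the rule that fired
  expect_match(classify_lifestyle(c(0.95, 0.95, 0.95))$rule, "stable")
  # thresholds are configurable
  th <- lifestyle_thresholds()
  th$high <- 0.5
  expect_equal(classify_lifestyle(c(0.6, 0.6, 0.6), th)$label,
               "strict_autotroph")
})

test_that("the fit pipeline recovers per-MAG trajectories end to end", {
  set.seed(17)
  pats <- list()
  rias <- list(MAGa = c(T1 = 0.95, T2 = 0.95), MAGb = c(T1 = 0.20, T2 = 0.50))
  for (m in names(rias)) {
    for (tp in names(rias[[m]])) {
      for (rep in c("R1", "R2")) {
        for (seq in test_peptides[1:3]) {
          pats[[length(pats) + 1]] <- sim_measured(
            seq, ria = rias[[m]][[tp]], labeled_fraction = 1,
            noise_cv = 0.01, label = m, timepoint = tp, replicate = rep)
        }
      }
    }
  }
  fit <- sisca(pats)
  expect_s3_class(fit, "sisca")
  expect_equal(sort(names(fit$trajectories)), c("MAGa", "MAGb"))
  expect_equal(unname(fit$trajectories$MAGa$ria), c(0.95, 0.95),
               tolerance = 0.051)
  expect_equal(unname(fit$trajectories$MAGb$ria), c(0.20, 0.50),
               tolerance = 0.051)
  s <- summary(fit)
  expect_true(all(c("label", "lifestyle") %in% names(s)))
})
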