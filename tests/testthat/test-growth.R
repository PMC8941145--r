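test_that("the most probable RIA is the grid argmax with documented tie-breaks", {
  grid <- seq(0, 1, 0.05)
  prof <- rep(0.1, 21)
  prof[14] <- 0.9  # 0-based index 13 -> grid value 0.65
  est <- most_probable_ria(prof, grid)
  expect_equal(est$ria, 0.65)
  expect_false(est$ambiguous)
  # flat profile: lowest grid value with the ambiguity flag
  flat <- most_probable_ria(rep(0.5, 21), grid)
  expect_equal(flat$ria, 0)
  expect_true(flat$ambiguous)
  # tie resolves to the lower grid value
  tie <- rep(0, 21); tie[c(5, 9)] <- 1
  expect_equal(most_probable_ria(tie, grid)$ria, grid[5])
  expect_true(most_probable_ria(tie, grid)$ambiguous)
  # simulator round trip at a high grid RIA
  meas <- sim_measured("SAMPLEK", ria = 0.95, labeled_fraction = 1)
  refs <- reference_pattern_set(composition_from_peptide("SAMPLEK"),
                                charge = 2)
  expect_equal(most_probable_ria(ria_profile(meas, refs))$ria, 0.95)
})

test_that("intensity decomposition is anchored on the monoisotopic peak", {
  comp <- composition_from_peptide("SAMPLEK")
  nat <- predict_pattern(comp, natural_ria(), charge = 2,
                         coverage = 0.9999)

  # pure natural pattern scaled to 100
  dec <- decompose_intensities(nat$intensities * 100, nat)
  expect_equal(dec$i_unlabeled, 100, tolerance = 1e-6)
  expect_equal(dec$i_labeled, 0, tolerance = 1e-6)

  # disjoint envelopes: exact recovery
  lab <- predict_pattern(comp, 0.9, charge = 2, coverage = 0.9999)
  n <- max(length(nat$intensities), length(lab$intensities))
  pad <- function(x) c(x, numeric(n - length(x)))
  mixed <- 30 * pad(nat$intensities) + 70 * pad(lab$intensities)
  dec2 <- decompose_intensities(mixed, nat)
  expect_equal(dec2$i_unlabeled, 30, tolerance = 1e-9)
  expect_equal(dec2$i_labeled, 70, tolerance = 1e-9)

  # overlapping envelopes at RIA 0.20: within 1% of total
  lab20 <- predict_pattern(comp, 0.20, charge = 2, coverage = 0.9999)
  n <- max(length(nat$intensities), length(lab20$intensities))
  pad <- function(x) c(x, numeric(n - length(x)))
  mixed20 <- 50 * pad(nat$intensities) + 50 * pad(lab20$intensities)
  dec3 <- decompose_intensities(mixed20, nat)
  expect_equal(dec3$i_unlabeled, 50, tolerance = 0.01 * 100)
  expect_equal(dec3$i_labeled, 50, tolerance = 0.01 * 100)

  # conservation: unlabeled + labeled = measured total + floored mass
  expect_equal(dec3$i_unlabeled + dec3$i_labeled,
               sum(mixed20) + dec3$floored, tolerance = 1e-9)
  expect_equal(dec2$i_unlabeled + dec2$i_labeled, sum(mixed),
               tolerance = 1e-9)

  # zero monoisotopic peak with downstream signal is flagged
  dz <- decompose_intensities(c(0, 0, 10, 5), nat)
  expect_equal(dz$i_unlabeled, 0)
  expect_true("zero-monoisotopic" %in% dz$flags)
})

test_that("doublings follow the printed equation and its variant", {
  expect_identical(doublings(1, 1)$n, 1)
  expect_identical(doublings(3, 1)$n, 2)
  expect_identical(doublings(0, 1)$n, 0)  # fully labeled, printed form
  # scale invariance
  expect_equal(doublings(30, 70)$n, doublings(3, 7)$n)
  # labeled intensity of zero: below detection, not an error
  bd <- doublings(5, 0)
  expect_true(is.na(bd$n))
  expect_equal(bd$flags, "below-detection")
  # alternative convention puts the unlabeled intensity in the denominator
  alt <- doublings(1, 3, convention = "unlabeled_denominator")
  expect_equal(alt$n, 2)
  expect_equal(alt$convention, "unlabeled_denominator")
})

test_that("generation times divide incubation time and censor at the limit", {
  expect_equal(generation_time(10.5, 21)$t_d, 2.0)
  expect_equal(generation_time(3, 21)$t_d, 7.0)
  gt <- generation_time(12, 21, detection_limit = 2)
  expect_true(gt$censored)
  expect_equal(gt$label, "<2 days")
  # t_d * n = delta_t exactly
  expect_identical(generation_time(3, 21)$t_d * 3, 21)
  nq <- generation_time(0, 21)
  expect_true(is.na(nq$t_d))
})

test_that("per-MAG generation times require four determinations", {
  td <- c(2, 2.5, 3, 3.5, 8)
  mag <- c(rep("A", 4), "B")
  tab <- mag_generation_times(td, mag)
  expect_true(tab$quantifiable[tab$label == "A"])
  expect_equal(tab$mean_td[tab$label == "A"], mean(td[1:4]))
  expect_false(tab$quantifiable[tab$label == "B"])
  expect_true(is.na(tab$mean_td[tab$label == "B"]))
})

test_that("community label fraction propagates RIA and natural abundance", {
  # fully labeled at RIA 1
  full <- biomass_label_fraction(c(0, 0), c(10, 20), c(1, 1))
  expect_equal(full$fraction, 1)
  # fully unlabeled community sits at natural abundance
  none <- biomass_label_fraction(c(10, 20), c(0, 0), c(0, 0))
  expect_equal(none$fraction, natural_ria())
  # intensity weighting
  w <- biomass_label_fraction(c(0, 100), c(100, 0), c(0.5, 0.5),
                              weighting = "intensity")
  e <- biomass_label_fraction(c(0, 100), c(100, 0), c(0.5, 0.5))
  expect_equal(e$fraction, mean(c(0.5, natural_ria())))
  expect_equal(w$fraction, (100 * 0.5 + 100 * natural_ria()) / 200)
  expect_error(biomass_label_fraction(numeric(0), numeric(0), numeric(0)),
               "empty")
})

test_that("the growth table recovers doublings from simulated mixtures", {
  set.seed(23)
  # true labeled fractions and the doublings they imply (printed form)
  for (f in c(0.2, 0.5, 0.8)) {
    p <- sim_measured("GLSDGEWQLVLNVWGK", ria = 0.65, labeled_fraction = f,
                      noise_cv = 0.02)
    tab <- growth_table(list(p), delta_t = 21)
    n_true <- log2(1 / f)
    expect_equal(tab$n, n_true, tolerance = 0.1 * max(n_true, 0.5))
    expect_equal(tab$ria, 0.65, tolerance = 0.051)
  }
})
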