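make_mag_map <- function() {
  data.frame(
    protein = c("P1", "P2", "P3", "P4", "P5"),
    mag = c("MAG1", "MAG1", "MAG2", "MAG3", "MAG4"),
    genus = c("Hydrogenophaga", "Hydrogenophaga", "Hydrogenophaga",
              "Thiobacillus", "Thiobacillus"),
    stringsAsFactors = FALSE
  )
}

id_row <- function(proteins, seq = "SAMPLEK") {
  data.frame(sequence = seq, mods = "", charge = 2L, mz = 400.2,
             rt_min = 40, sample = "S", replicate = "R1", timepoint = "T1",
             proteins = proteins, mags = "", genus = "",
             stringsAsFactors = FALSE)
}

test_that("peptide uniqueness filtering keeps one-MAG and one-genus peptides only", {
  mm <- make_mag_map()
  # unique to one protein of one MAG
  one <- filter_peptides(id_row("P1"), mm)
  expect_equal(nrow(one), 1)
  expect_equal(one$label, "MAG1")
  expect_equal(one$label_level, "mag")
  # two proteins, same MAG
  same_mag <- filter_peptides(id_row("P1;P2"), mm)
  expect_equal(same_mag$label, "MAG1")
  # two MAGs sharing a genus -> retained at genus level
  same_genus <- filter_peptides(id_row("P1;P3"), mm)
  expect_equal(nrow(same_genus), 1)
  expect_equal(same_genus$label, "genus:Hydrogenophaga")
  expect_equal(same_genus$label_level, "genus")
  # two MAGs of different genera -> dropped
  diff_genus <- filter_peptides(id_row("P1;P4"), mm)
  expect_equal(nrow(diff_genus), 0)
  # unmapped accession is an error naming the accession
  expect_error(filter_peptides(id_row("P9"), mm), "P9")
})

test_that("pattern location honors the ppm and retention-time gates", {
  id <- make_id("SAMPLEK", charge = 2L, rt_min = 40)
  spacing <- 1.0033548 / 2

  # candidate at +12 ppm: outside the 10 ppm gate
  pk12 <- as_peaklist(data.frame(mz = id$mz * (1 + 12e-6),
                                 intensity = 100, rt_min = 40))
  expect_null(locate_pattern(id, pk12))

  # 2.9 min away and 4 ppm off: inside both gates
  pk_ok <- as_peaklist(data.frame(mz = id$mz * (1 + 4e-6),
                                  intensity = 100, rt_min = 42.9))
  found <- locate_pattern(id, pk_ok)
  expect_false(is.null(found))
  expect_equal(found$intensities[1], 100)

  # empty peak list
  empty <- as_peaklist(data.frame(mz = numeric(0), intensity = numeric(0),
                                  rt_min = numeric(0)))
  expect_null(locate_pattern(id, empty))

  # missing intermediate isotopologues recorded as zeros, not an error
  pk_gap <- as_peaklist(data.frame(
    mz = c(id$mz, id$mz + 5 * spacing),
    intensity = c(50, 80), rt_min = 40))
  gap <- locate_pattern(id, pk_gap)
  expect_equal(gap$intensities[1:6], c(50, 0, 0, 0, 0, 80))

  # among two in-tolerance candidates the smaller |ppm| wins
  pk_two <- as_peaklist(data.frame(
    mz = c(id$mz * (1 + 6e-6), id$mz * (1 + 1e-6)),
    intensity = c(999, 10), rt_min = 40))
  expect_equal(locate_pattern(id, pk_two)$intensities[1], 10)
})

test_that("larger tolerances never lose located patterns", {
  set.seed(11)
  id <- make_id("LFTGHPETLEK", charge = 2L, rt_min = 55)
  pk <- simulate_spectrum("LFTGHPETLEK", 2, ria = 0.5, labeled_fraction = 1,
                          noise_cv = 0.02, mz_jitter_ppm = 3, rt_min = 55)
  pk <- as_peaklist(pk)
  narrow <- locate_pattern(id, pk, ppm_tol = 5, rt_tol = 1)
  wide <- locate_pattern(id, pk, ppm_tol = 10, rt_tol = 3)
  expect_true(sum(wide$intensities > 0) >= sum(narrow$intensities > 0))
})

test_that("M-1 signals and overlapping neighbors cause rejection with reasons", {
  id <- make_id("SAMPLEK", charge = 2L, rt_min = 40)
  spacing <- 1.0033548 / 2
  base <- data.frame(mz = c(id$mz, id$mz + spacing),
                     intensity = c(100, 40), rt_min = 40)

  # M-1 peak at 20% of max with 5% threshold
  with_m1 <- as_peaklist(rbind(base,
    data.frame(mz = id$mz - spacing, intensity = 20, rt_min = 40)))
  p <- locate_pattern(id, with_m1)
  verdict <- validate_pattern(p)
  expect_false(verdict$accepted)
  expect_equal(verdict$reason, "M-1")

  # clean pattern, no neighbors
  clean <- validate_pattern(locate_pattern(id, as_peaklist(base)))
  expect_s3_class(clean, "measured_pattern")
  expect_true("accepted" %in% clean$flags)

  # a neighbor peptide whose envelope crosses ours within tolerance
  other <- make_id("SAMPLEK", charge = 2L, rt_min = 41)
  other$mz <- id$mz + 2 * spacing  # expected positions collide
  overlap <- validate_pattern(locate_pattern(id, as_peaklist(base)),
                              neighbors = list(other))
  expect_false(overlap$accepted)
  expect_equal(overlap$reason, "overlap")

  # same neighbor far away in retention time does not interfere
  far <- other
  far$rt_min <- 60
  ok <- validate_pattern(locate_pattern(id, as_peaklist(base)),
                         neighbors = list(far))
  expect_s3_class(ok, "measured_pattern")
})

test_that("replicate support is enforced per MAG and time point", {
  mk <- function(rep, tp = "T1", label = "MAG1") {
    p <- sim_measured("SAMPLEK", ria = 0.5, labeled_fraction = 1,
                      label = label, timepoint = tp, replicate = rep)
    p
  }
  pats <- list(mk("A"), mk("B"), mk("A", tp = "T2"))
  kept <- require_replicates(pats, 2)
  expect_length(kept, 2)  # T1 has replicates A and B; T2 only A
  expect_true(all(vapply(kept, function(p) p$id$timepoint, "") == "T1"))
  expect_length(require_replicates(pats, 1), 3)  # identity at min 1
  # retained set does not depend on input order
  kept_rev <- require_replicates(rev(pats), 2)
  expect_length(kept_rev, 2)
})

test_that("noise-free simulated patterns are located without misses", {
  set.seed(5)
  for (seq in test_peptides[1:3]) {
    charge <- 2L
    pk <- simulate_spectrum(seq, charge, ria = 0.65, labeled_fraction = 0.7)
    id <- make_id(seq, charge = charge, rt_min = 60)
    found <- locate_pattern(id, as_peaklist(pk))
    expect_false(is.null(found))
    # every simulated peak recovered at its exact intensity
    n <- nrow(pk)
    k <- round((pk$mz - id$mz) / (1.0033548 / charge)) + 1
    expect_equal(found$intensities[k], pk$intensity)
  }
})
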