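## Ground-truth simulator: synthetic protein databases, peptide
## identifications, labeled-sample peak lists, Raman spectra, and the
## truth tables that make every pipeline stage testable end to end.

AMINO_ACIDS <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                 "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")

#' In-silico tryptic digest
#'
#' Cleaves after K or R, except before proline, allowing up to
#' `missed` missed cleavages.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param missed Maximum missed cleavages (default 0).
#' @return Character vector of peptides, in sequence order (fully cleaved
#'   first, then the missed-cleavage concatenations).
#' @examples
#' tryptic_digest("AKRPGK")  # "AK", "RPGK"
#' @export
tryptic_digest <- function(sequence, missed = 0L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  base <- substring(sequence, starts, ends)
  out <- base
  if (missed > 0L) {
    for (m in seq_len(missed)) {
      if (length(base) <= m) break
      i <- seq_len(length(base) - m)
      out <- c(out, vapply(i, function(j) {
        paste(base[j:(j + m)], collapse = "")
      }, ""))
    }
  }
  out
}

#' Archetype RIA trajectories
#'
#' Default per-time-point RIA trajectories of the four trophic archetypes
#' used by the community simulator, linearly interpolated if a different
#' number of time points is requested.
#'
#' @param archetype One of `"strict_autotroph"`, `"switching_mixotroph"`,
#'   `"crossfeeding_incorporator"`, `"unlabeled_heterotroph"`.
#' @param n_timepoints Number of time points; default 3.
#' @return Numeric RIA vector of length `n_timepoints`.
#' @export
archetype_ria <- function(archetype, n_timepoints = 3L) {
  base <- switch(
    archetype,
    strict_autotroph = c(0.95, 0.95, 0.95),
    switching_mixotroph = c(0.65, 0.91, 0.91),
    crossfeeding_incorporator = c(0.18, 0.53, 0.76),
    unlabeled_heterotroph = c(0.06, 0.06, 0.06),
    stop("unknown archetype: ", archetype)
  )
  if (n_timepoints == length(base)) return(base)
  stats::approx(seq_along(base), base,
                xout = seq(1, length(base), length.out = n_timepoints))$y
}

#' Specify one simulated MAG
#'
#' @param id MAG identifier.
#' @param genus Genus label.
#' @param archetype Trajectory archetype (see [archetype_ria()]), or
#'   `"custom"` with `ria` supplied.
#' @param ria Optional custom RIA per time point (overrides archetype).
#' @param labeled_fraction Labeled fraction of the peptide population per
#'   time point (recycled if scalar); default 0.5, 0.7, 0.85 interpolated
#'   to the number of time points.
#' @param n_peptides Peptides to simulate for this MAG; default 20.
#' @param length_range Peptide length range (residues); default c(7, 30).
#' @return A `mag_spec` list.
#' @export
mag_spec <- function(id, genus, archetype = "custom", ria = NULL,
                     labeled_fraction = NULL, n_peptides = 20L,
                     length_range = c(7L, 30L)) {
  if (is.null(ria)) {
    if (archetype == "custom") stop("custom archetype needs explicit ria")
    ria <- NULL  # resolved once the number of time points is known
  }
  stopifnot(is.null(ria) || all(ria >= 0 & ria <= 1))
  stopifnot(is.null(labeled_fraction) ||
            all(labeled_fraction >= 0 & labeled_fraction <= 1))
  structure(list(id = id, genus = genus, archetype = archetype, ria = ria,
                 labeled_fraction = labeled_fraction,
                 n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range)),
            class = "mag_spec")
}

#' Specify a simulated community
#'
#' @param mags List of [mag_spec()]s.
#' @param timepoints Named numeric vector of incubation times in days,
#'   e.g. `c(T1 = 21, T2 = 43, T3 = 70)`.
#' @param replicates Number of replicate microcosms; default 2.
#' @param noise_cv Per-peak multiplicative (lognormal) coefficient of
#'   variation; default 0.05.
#' @param noise_floor Additive intensity floor below which peaks are
#'   dropped; default 0.
#' @param mz_jitter_ppm Uniform m/z jitter half-width in p.p.m.; default 2.
#' @param shared_fraction Fraction of peptides assigned to a second MAG
#'   (to exercise uniqueness filtering); default 0.
#' @param seed Random seed (mandatory).
#' @return A `community_spec` list with archetype RIA and labeled
#'   fractions resolved per time point.
#' @export
community_spec <- function(mags,
                           timepoints = c(T1 = 21, T2 = 43, T3 = 70),
                           replicates = 2L, noise_cv = 0.05,
                           noise_floor = 0, mz_jitter_ppm = 2,
                           shared_fraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(timepoints) >= 1, !is.null(names(timepoints)),
            replicates >= 1, noise_cv >= 0, shared_fraction >= 0,
            shared_fraction < 1)
  ntp <- length(timepoints)
  mags <- lapply(mags, function(m) {
    if (is.null(m$ria)) m$ria <- archetype_ria(m$archetype, ntp)
    if (length(m$ria) != ntp) stop("MAG ", m$id, ": ria length != timepoints")
    if (is.null(m$labeled_fraction)) {
      m$labeled_fraction <- stats::approx(1:3, c(0.5, 0.7, 0.85),
                                          xout = seq(1, 3, length.out = ntp))$y
    }
    if (length(m$labeled_fraction) == 1) {
      m$labeled_fraction <- rep(m$labeled_fraction, ntp)
    }
    stopifnot(length(m$labeled_fraction) == ntp)
    m
  })
  ids <- vapply(mags, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate MAG ids")
  structure(list(mags = mags, timepoints = timepoints,
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 noise_floor = noise_floor, mz_jitter_ppm = mz_jitter_ppm,
                 shared_fraction = shared_fraction, seed = as.integer(seed)),
            class = "community_spec")
}

#' Labeled fraction implied by a doubling count
#'
#' Inverts the printed doublings relation `n = log2(total / labeled)`:
#' `f = 2^-n`.
#'
#' @param n Number of doublings.
#' @export
label_fraction_from_doublings <- function(n) 2^(-n)

random_protein <- function(length) {
  paste(sample(AMINO_ACIDS, length, replace = TRUE), collapse = "")
}

#' Simulate protein database and peptide identifications
#'
#' Draws random protein sequences per MAG (uniform residue frequencies),
#' digests them in silico with trypsin (no cleavage before proline), and
#' emits peptides in the requested length range until each MAG's quota is
#' met. Peptides are unique to their MAG by construction unless a shared
#' fraction is requested. Charges are drawn from 2-3 and retention times
#' uniformly; the identification m/z is the theoretical monoisotopic m/z.
#'
#' @param spec A [community_spec()].
#' @return List with `proteins` (data.frame: protein, sequence, mag,
#'   genus), `peptides` (one row per distinct peptide), and
#'   `identifications` (one row per peptide, time point, and replicate).
#' @export
simulate_peptides <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  proteins <- list()
  pep_rows <- list()
  seen <- character(0)

  for (m in spec$mags) {
    got <- 0L
    attempts <- 0L
    while (got < m$n_peptides) {
      attempts <- attempts + 1L
      if (attempts > 60L) {
        stop("MAG ", m$id, ": peptide count unsatisfiable from ",
             "generated sequence length")
      }
      prot_id <- sprintf("%s_P%02d", m$id, attempts)
      seq <- random_protein(300L)
      peps <- tryptic_digest(seq, missed = 0L)
      len <- nchar(peps)
      peps <- unique(peps[len >= m$length_range[1] &
                          len <= m$length_range[2]])
      peps <- setdiff(peps, seen)
      if (length(peps) == 0) next
      take <- peps[seq_len(min(length(peps), m$n_peptides - got))]
      seen <- c(seen, take)
      got <- got + length(take)
      proteins[[length(proteins) + 1L]] <- data.frame(
        protein = prot_id, sequence = seq, mag = m$id, genus = m$genus,
        stringsAsFactors = FALSE)
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        sequence = take, protein = prot_id, mag = m$id, genus = m$genus,
        stringsAsFactors = FALSE)
    }
  }
  proteins <- do.call(rbind, proteins)
  peptides <- do.call(rbind, pep_rows)
  peptides$charge <- sample(2:3, nrow(peptides), replace = TRUE)
  peptides$rt_min <- stats::runif(nrow(peptides), 10, 110)
  peptides$mz <- vapply(seq_len(nrow(peptides)), function(i) {
    comp <- composition_from_peptide(peptides$sequence[i])
    (monoisotopic_mass(comp) + peptides$charge[i] * PROTON_MASS) /
      peptides$charge[i]
  }, 0.0)

  ## optionally share a fraction of peptides with a second MAG
  peptides$proteins <- peptides$protein
  peptides$mags <- peptides$mag
  peptides$genera <- peptides$genus
  if (spec$shared_fraction > 0 && length(spec$mags) > 1) {
    n_share <- floor(spec$shared_fraction * nrow(peptides))
    if (n_share > 0) {
      share_ix <- sample(nrow(peptides), n_share)
      mag_ids <- vapply(spec$mags, `[[`, "", "id")
      genus_of <- stats::setNames(vapply(spec$mags, `[[`, "", "genus"),
                                  mag_ids)
      for (i in share_ix) {
        other <- sample(setdiff(mag_ids, peptides$mag[i]), 1)
        peptides$proteins[i] <- paste(peptides$protein[i],
                                      sprintf("%s_P00", other), sep = ";")
        peptides$mags[i] <- paste(peptides$mag[i], other, sep = ";")
        peptides$genera[i] <- paste(peptides$genus[i], genus_of[other],
                                    sep = ";")
      }
    }
  }

  tps <- names(spec$timepoints)
  grid_df <- expand.grid(pep = seq_len(nrow(peptides)), timepoint = tps,
                         replicate = seq_len(spec$replicates),
                         stringsAsFactors = FALSE)
  identifications <- data.frame(
    sequence = peptides$sequence[grid_df$pep],
    mods = "",
    charge = peptides$charge[grid_df$pep],
    mz = peptides$mz[grid_df$pep],
    rt_min = peptides$rt_min[grid_df$pep],
    sample = paste0("13C_", grid_df$timepoint, "_R", grid_df$replicate),
    replicate = paste0("R", grid_df$replicate),
    timepoint = grid_df$timepoint,
    proteins = peptides$proteins[grid_df$pep],
    mags = peptides$mags[grid_df$pep],
    genus = peptides$genera[grid_df$pep],
    stringsAsFactors = FALSE
  )
  list(proteins = proteins, peptides = peptides,
       identifications = identifications)
}

#' Simulate the labeled-sample peak series of one peptide
#'
#' Mixture model: `(1 - f)` parts natural-abundance pattern plus `f` parts
#' pattern predicted at the true RIA, scaled to a total intensity, with
#' per-peak multiplicative lognormal noise at the stated CV, peaks below
#' the additive floor dropped, and uniform m/z jitter.
#'
#' @param sequence Peptide sequence (or `elemental_composition`).
#' @param charge Charge state.
#' @param ria True RIA of the labeled population.
#' @param labeled_fraction True labeled fraction `f` in \[0, 1\].
#' @param total_intensity Total intensity the pattern is scaled to.
#' @param rt_min Retention time attached to all peaks.
#' @param noise_cv Per-peak lognormal CV (0 = noise-free).
#' @param noise_floor Peaks below this intensity are dropped.
#' @param mz_jitter_ppm Uniform jitter half-width (p.p.m.; 0 = exact).
#' @param coverage Predicted-pattern coverage cutoff.
#' @return A data.frame of peaks (`mz`, `intensity`, `rt_min`).
#' @export
simulate_spectrum <- function(sequence, charge, ria, labeled_fraction,
                              total_intensity = 1e6, rt_min = 60,
                              noise_cv = 0, noise_floor = 0,
                              mz_jitter_ppm = 0, coverage = 0.9999) {
  stopifnot(labeled_fraction >= 0, labeled_fraction <= 1)
  comp <- if (is.character(sequence)) composition_from_peptide(sequence)
          else sequence
  nat <- predict_pattern(comp, ria = natural_ria(), charge = charge,
                         coverage = coverage)
  mix <- (1 - labeled_fraction) * nat$intensities
  if (labeled_fraction > 0) {
    lab <- predict_pattern(comp, ria = ria, charge = charge,
                           coverage = coverage)
    n <- max(length(mix), length(lab$intensities))
    mix <- c(mix, numeric(n - length(mix))) +
      labeled_fraction * c(lab$intensities,
                           numeric(n - length(lab$intensities)))
  }
  intensity <- mix * total_intensity
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    intensity <- intensity *
      stats::rlnorm(length(intensity), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  mz <- nat$base_mz + (seq_along(intensity) - 1L) * nat$spacing
  if (mz_jitter_ppm > 0) {
    mz <- mz * (1 + stats::runif(length(mz), -mz_jitter_ppm,
                                 mz_jitter_ppm) * 1e-6)
  }
  keep <- intensity > noise_floor
  data.frame(mz = mz[keep], intensity = intensity[keep],
             rt_min = rt_min)[order(mz[keep]), , drop = FALSE]
}

#' Simulate a full labeled community dataset
#'
#' Generates the protein database, the identification table, one peak list
#' per labeled sample (time point x replicate), and the per-peptide truth
#' table. Fully deterministic under the spec's seed.
#'
#' @param spec A [community_spec()].
#' @return List with `proteins`, `identifications`, `mag_map` (protein to
#'   MAG/genus), `peaklists` (named list of `peak_list`), and `truth`
#'   (per peptide and time point: true RIA, labeled fraction, doublings
#'   and generation time under the printed convention).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  base <- simulate_peptides(spec)
  peptides <- base$peptides
  tps <- names(spec$timepoints)
  mag_of <- stats::setNames(vapply(spec$mags, `[[`, "", "id"),
                            vapply(spec$mags, `[[`, "", "id"))
  spec_of <- stats::setNames(spec$mags, vapply(spec$mags, `[[`, "", "id"))

  peaklists <- list()
  truth <- list()
  for (tp_i in seq_along(tps)) {
    tp <- tps[tp_i]
    for (rep_i in seq_len(spec$replicates)) {
      sample_id <- paste0("13C_", tp, "_R", rep_i)
      rows <- list()
      for (i in seq_len(nrow(peptides))) {
        m <- spec_of[[peptides$mag[i]]]
        ria <- m$ria[tp_i]
        f <- m$labeled_fraction[tp_i]
        total <- stats::rlnorm(1, meanlog = log(1e6), sdlog = 0.3)
        rows[[i]] <- simulate_spectrum(
          peptides$sequence[i], charge = peptides$charge[i], ria = ria,
          labeled_fraction = f, total_intensity = total,
          rt_min = peptides$rt_min[i], noise_cv = spec$noise_cv,
          noise_floor = spec$noise_floor,
          mz_jitter_ppm = spec$mz_jitter_ppm)
        if (rep_i == 1) {
          nn <- if (f > 0) log2(1 / f) else NA_real_
          truth[[length(truth) + 1L]] <- data.frame(
            sequence = peptides$sequence[i], mag = peptides$mag[i],
            timepoint = tp, ria = ria, labeled_fraction = f,
            n = nn,
            t_d = if (!is.na(nn) && nn > 0) spec$timepoints[[tp]] / nn
                  else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
      pk <- do.call(rbind, rows)
      peaklists[[sample_id]] <- as_peaklist(pk[order(pk$mz), , drop = FALSE],
                                            sample = sample_id)
    }
  }
  mag_map <- unique(data.frame(
    protein = unlist(strsplit(peptides$proteins, ";", fixed = TRUE)),
    stringsAsFactors = FALSE))
  ## map every accession (incl. synthetic shared ones) to its MAG prefix
  mag_map$mag <- sub("_P[0-9]+$", "", mag_map$protein)
  genus_of <- stats::setNames(vapply(spec$mags, `[[`, "", "genus"),
                              vapply(spec$mags, `[[`, "", "id"))
  mag_map$genus <- unname(genus_of[mag_map$mag])

  list(proteins = base$proteins, identifications = base$identifications,
       mag_map = mag_map, peaklists = peaklists,
       truth = do.call(rbind, truth), spec = spec)
}

#' Per-MAG truth table implied by a community spec
#'
#' @param spec A [community_spec()].
#' @return Data.frame with one row per MAG and time point: true RIA,
#'   labeled fraction, doublings `n` under the printed convention
#'   (`n = log2(total/labeled)`), and generation time.
#' @export
emit_truth <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  tps <- names(spec$timepoints)
  rows <- list()
  for (m in spec$mags) {
    for (i in seq_along(tps)) {
      f <- m$labeled_fraction[i]
      nn <- if (f > 0) log2(1 / f) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        mag = m$id, genus = m$genus, timepoint = tps[i],
        ria = m$ria[i], labeled_fraction = f, n = nn,
        t_d = if (!is.na(nn) && nn > 0) spec$timepoints[[i]] / nn
              else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate single-cell Raman spectra with known C-D ratio
#'
#' Each cell's spectrum is a Gaussian C-H band (centered in the
#' 2800-3100 cm^-1 window) and a Gaussian C-D band (2040-2300 cm^-1)
#' whose area ratio realizes the true C-D ratio, on a smooth polynomial
#' baseline with additive Gaussian noise and optional cosmic spikes.
#'
#' @param n_cells Number of cells (spectra).
#' @param true_cd_ratio True `A_CD / (A_CD + A_CH)` in \[0, 1).
#' @param noise Gaussian noise SD relative to the C-H peak height;
#'   default 0.01.
#' @param n_spikes Cosmic spikes injected per spectrum; default 0.
#' @param wavenumber Axis (cm^-1); default 600 to 3200 in 2 cm^-1 steps.
#' @param baseline_coef Polynomial baseline coefficients (intercept
#'   first); default a gentle cubic fluorescence-like background.
#' @param seed Random seed (mandatory).
#' @return List of `raman_spectrum` objects; each carries its cell ID and
#'   the true ratio in `meta`.
#' @export
simulate_raman <- function(n_cells, true_cd_ratio, noise = 0.01,
                           n_spikes = 0L,
                           wavenumber = seq(600, 3200, by = 2),
                           baseline_coef = c(0.2, 2e-4, -1.2e-7, 1.5e-11),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(true_cd_ratio >= 0, true_cd_ratio < 1)
  set.seed(seed)
  wn <- as.numeric(wavenumber)
  gauss <- function(center, sd) stats::dnorm(wn, center, sd)
  a_ch <- 1
  a_cd <- if (true_cd_ratio > 0) true_cd_ratio / (1 - true_cd_ratio) else 0
  baseline <- as.numeric(outer(wn, seq_along(baseline_coef) - 1, `^`) %*%
                           baseline_coef)
  ch_peak_height <- a_ch * stats::dnorm(0, 0, 40)

  lapply(seq_len(n_cells), function(i) {
    scale_i <- stats::rlnorm(1, 0, 0.15)
    signal <- a_ch * gauss(2935, 40)
    if (a_cd > 0) signal <- signal + a_cd * gauss(2170, 40)
    y <- scale_i * (signal + baseline) +
      stats::rnorm(length(wn), 0, noise * ch_peak_height)
    if (n_spikes > 0) {
      at <- sample(seq_along(wn), n_spikes)
      y[at] <- y[at] + 50 * ch_peak_height
    }
    raman_spectrum(wn, y, meta = list(cell = sprintf("cell%03d", i),
                                      true_cd_ratio = true_cd_ratio))
  })
}
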