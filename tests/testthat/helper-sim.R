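# Shared fixtures built in code: simulated measured patterns and small
# identification tables.

theoretical_mz <- function(sequence, charge, mods = NULL) {
  predict_pattern(composition_from_peptide(sequence, mods),
                  ria = 0, charge = charge)$base_mz
}

make_id <- function(sequence, charge = 2L, rt_min = 60, mods = "",
                    label = "MAG1", timepoint = "T1", replicate = "R1",
                    sample = "S1") {
  list(sequence = sequence, mods = mods, charge = charge,
       mz = theoretical_mz(sequence, charge,
                           if (nzchar(mods)) mods else NULL),
       rt_min = rt_min, sample = sample, replicate = replicate,
       timepoint = timepoint, label = label)
}

# Simulate one peptide's labeled-sample peaks and locate its pattern the
# way the pipeline would.
sim_measured <- function(sequence, charge = 2L, ria = 0.5,
                         labeled_fraction = 1, noise_cv = 0,
                         rt_min = 60, total_intensity = 1e6,
                         label = "MAG1", timepoint = "T1",
                         replicate = "R1", ...) {
  pk <- simulate_spectrum(sequence, charge = charge, ria = ria,
                          labeled_fraction = labeled_fraction,
                          total_intensity = total_intensity,
                          rt_min = rt_min, noise_cv = noise_cv, ...)
  id <- make_id(sequence, charge = charge, rt_min = rt_min, label = label,
                timepoint = timepoint, replicate = replicate)
  locate_pattern(id, as_peaklist(pk))
}

# A few realistic tryptic-looking peptide sequences
test_peptides <- c("SAMPLEK", "GLSDGEWQLVLNVWGK", "VEADIAGHGQEVLIR",
                   "LFTGHPETLEK", "HGTVVLTALGGILK")
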