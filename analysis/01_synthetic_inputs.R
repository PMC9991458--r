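#!/usr/bin/env Rscript
# Stage 1: synthetic stand-ins for the structural-simulation outputs.
#
# Generates the wild-type and mutant per-residue flexibility profiles (the
# mutant carries a localized flexibility bump near the substitution site,
# with amplitude solved so the downstream stiffness ratio matches the
# modeling value 31.6/60) and Gaussian interaction-energy frame ensembles
# matching the tabulated blocked/closed means and SDs.

library(thinfilament)

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 1L

amp <- calibrate_bump_amplitude(31.6 / 60)
cat(sprintf("mutant bump amplitude solved at %.2f deg (baseline 3 deg)\n", amp))

wt <- generate_flexibility_profile(3, 142, genotype = "wt",
                                   noise_sd = 0.15, seed = seed)
mut <- generate_flexibility_profile(3, 142, amplitude = amp, noise_sd = 0.15,
                                    seed = seed + 1L, genotype = "s215l")
write_flexibility_profile(wt, file.path(out, "flexibility_wt.tsv"))
write_flexibility_profile(mut, file.path(out, "flexibility_s215l.tsv"))
cat(sprintf("peak mutant flexibility %.2f deg at residue %d (wild type %.2f)\n",
            max(mut$delta), mut$residue[which.max(mut$delta)], max(wt$delta)))

tab <- read_energy_table(system.file("extdata", "interaction_energies.tsv",
                                     package = "thinfilament"))
i <- 0L
for (s in tab) {
  i <- i + 1L
  ens <- sample_energy_frames(s$mean, s$sd, s$n_frames, seed = seed + 10L + i,
                              genotype = s$genotype, state = s$state)
  write_energy_frames(ens, file.path(out, sprintf("frames_%s_%s.txt",
                                                  s$genotype, s$state)))
  ss <- summarize_frames(ens)
  cat(sprintf("%-6s %s: requested %8.1f +/- %5.1f, sampled %8.1f +/- %5.1f (n=%d)\n",
              s$genotype, s$state, s$mean, s$sd, ss$mean, ss$sd, ss$n_frames))
}
cat("wrote profiles and frame ensembles under results/\n")
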