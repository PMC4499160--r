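#!/usr/bin/env Rscript
## Osmotic pressure of a hexagonal aggregate from the recovered
## B-DNA-like pairwise PMF (additivity over the six nearest neighbours).
## Reads results/pmf_bdna_5mM.tsv (from 02_pmf_recovery.R).
## Outputs: results/osmotic.tsv

library(helixpmf)
if (!file.exists("results/pmf_bdna_5mM.tsv"))
  stop("run analysis/02_pmf_recovery.R first")
pmf <- read_pmf_tsv("results/pmf_bdna_5mM.tsv")
E <- lattice_energy(pmf)
curve <- osmotic_pressure(E, L = 15 * 3.38)
write_tsv_table(curve, "results/osmotic.tsv")
zc <- osmotic_zero_crossing(curve)
cat(sprintf("lattice energy minimum %.2f kT/helix at %.1f A\n",
            min(E$E_kBT), E$d[which.min(E$E_kBT)]))
cat(sprintf("osmotic pressure crosses zero at %.2f A (equilibrium spacing)\n",
            zc))
cat(sprintf("pressure at 24 A spacing: %.1f atm\n",
            curve$Pi_atm[which.min(abs(curve$d - 24))]))
cat("wrote results/osmotic.tsv\n")
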