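#!/usr/bin/env Rscript
## Build the three fiber-model duplexes used throughout the analysis and
## record their geometry.  Outputs: results/models/*.pdb(+.json),
## results/helix_geometry.tsv

library(helixpmf)
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (form in c("arna", "bdna", "adna")) {
  f <- helix_form(form)
  seqn <- suppressWarnings(
    default_sequence(16, if ("U" %in% f$alphabet) "rna" else "dna"))
  h <- build_helix(seqn, f)
  write_helix_pdb(h, file.path("results/models", paste0(form, "_16bp.pdb")))
  rows[[form]] <- data.frame(
    form = f$name, rise_A = f$rise, twist_deg = f$twist,
    phosphate_radius_A = f$phosphate_radius,
    major_sector_deg = major_groove_sector_deg(f),
    major_arc_A = major_groove_sector_deg(f) * pi / 180 * f$phosphate_radius,
    base_displacement_A = f$base_displacement,
    axial_extent_A = axial_extent(h),
    total_charge_e = sum(h$sites$charge))
  cat(sprintf("%-6s 16 bp: extent %.2f A, charge %+d e, major-groove arc %.1f A\n",
              f$name, axial_extent(h), sum(h$sites$charge),
              rows[[form]]$major_arc_A))
}
geom <- do.call(rbind, rows)
write_tsv_table(geom, "results/helix_geometry.tsv")

cat(sprintf("\nA-DNA major-groove arc is %.2f A narrower than A-RNA's\n",
            geom["arna", "major_arc_A"] - geom["adna", "major_arc_A"]))
cat("wrote results/helix_geometry.tsv and results/models/\n")
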