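#!/usr/bin/env Rscript

# Step 1: build the synthetic study system.
#
# Simulates founder panels for an admixed focal breed (migrant genome
# dominated by the Holstein group) plus four reference breeds on a
# 3-chromosome, 1500-marker genome; samples the 300-QTL trait
# architecture; assembles the 300-animal base generation G0 from founder
# gametes. Panels are written in the package's interchange formats under
# scratch/ (large, regenerable); small summaries go to results/.

suppressPackageStartupMessages(library(nativesel))

seed <- 101
stud <- make_study_population(seed)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/panels", recursive = TRUE, showWarnings = FALSE)

write_panel(stud$panel, "scratch/panels/founders_all_breeds.tsv")
write_panel(stud$base, "scratch/panels/base_G0.vcf")
write_marker_map(stud$map, "scratch/panels/marker_map.tsv")

mc_true <- true_migrant_fraction(stud$founders)
tbv_founders <- compute_tbv(stud$founders, stud$arch)

cat("Synthetic study system (seed", seed, ")\n")
cat("  genome:", length(unique(stud$map$chromosome)), "chromosomes,",
    nrow(stud$map), "markers,",
    round(max(stud$map$position_bp) / 1e6), "Mb per chromosome\n")
cat("  focal founders:", n_individuals(stud$founders),
    "| reference animals:", n_individuals(stud$refs), "\n")
cat("  true migrant fraction of founders: mean",
    round(mean(mc_true), 3), "sd", round(sd(mc_true), 3), "\n")
cat("  founder genic variance:",
    round(genic_variance(stud$founders, stud$arch), 4), "\n")
cat("  base generation:", n_individuals(stud$base), "animals (",
    sum(stud$base$sex == "M"), "M /", sum(stud$base$sex == "F"), "F )\n")

summary_tab <- data.frame(
  quantity = c("n_founders", "n_reference", "n_base", "n_markers",
               "n_qtl", "true_mc_mean", "true_mc_sd",
               "founder_genic_variance"),
  value = c(n_individuals(stud$founders), n_individuals(stud$refs),
            n_individuals(stud$base), nrow(stud$map),
            length(stud$arch$qtl_indices), round(mean(mc_true), 4),
            round(sd(mc_true), 4),
            round(genic_variance(stud$founders, stud$arch), 4)))
write_metrics(summary_tab, "results/01_base_system.csv")
cat("wrote results/01_base_system.csv\n")
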