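#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# Emulates a germplasm panel of 455 inbred soybean varieties scored at 89
# trait-associated QTNs spread over 20 chromosomes, phenotyped for a
# count-like yield-component trait in five environments (labelled like the
# original trials) under a randomized complete block design with three
# blocks. Variance components follow the reported multi-environment trial
# (genetic 12.421, genotype x environment 15.357, plot error 23.949), with
# part of the genetic signal carried by the QTN effects and the rest by a
# polygenic residual.

library(qtnbreed)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260927

envs <- c("21AC", "21XY", "23AC", "23QQ", "23WD")
qm <- gen_qtn_map(n_qtn = 89, n_chrom = 20, envs = envs,
                  effect_sd = 0.35, env_corr = 0.5, seed = seed)
panel <- gen_panel(455, qm, maf_low = 0.15, maf_high = 0.5, seed = seed + 1)

# QTN effects at sd 0.35 over 89 loci contribute roughly a third of the
# genetic variance; the polygenic term supplies the remainder so the total
# genetic signal sits near the reported components.
truth <- simulation_truth(
  mu_by_env = c(`21AC` = 6.6, `21XY` = 7.6, `23AC` = 9.1,
                `23QQ` = 5.7, `23WD` = 7.7),
  sigma2_G = 8, sigma2_GE = 15.357, sigma2_e = 23.949, n_blocks = 3)
pheno <- gen_phenotypes(panel, qm, truth, seed = seed + 2)

write_qtn_map(qm, file.path(out, "qtn_map.tsv"))
write_panel(panel, file.path(out, "panel.csv"))
write_pheno(pheno, file.path(out, "pheno.csv"))

cat("Wrote", nrow(qm), "QTNs,", nrow(panel), "varieties,",
    nrow(pheno), "plot records to", out, "\n")
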