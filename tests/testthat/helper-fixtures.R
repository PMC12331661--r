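# Shared in-code fixtures: a small synthetic trial and its fitted MAS model.

small_chain <- function(n_varieties = 40, n_qtn = 12, n_chrom = 5,
                        envs = c("E1", "E2"), effect_sd = 0.8,
                        sigma2_G = 4, sigma2_GE = 2, sigma2_e = 3,
                        n_blocks = 3, seed = 101) {
  qm <- gen_qtn_map(n_qtn, n_chrom, envs = envs, effect_sd = effect_sd,
                    env_corr = 0.5, seed = seed)
  panel <- gen_panel(n_varieties, qm, maf_low = 0.2, maf_high = 0.5,
                     seed = seed + 1)
  truth <- simulation_truth(stats::setNames(rep(8, length(envs)), envs),
                            sigma2_G = sigma2_G, sigma2_GE = sigma2_GE,
                            sigma2_e = sigma2_e, n_blocks = n_blocks)
  pheno <- gen_phenotypes(panel, qm, truth, seed = seed + 2)
  list(qm = qm, panel = panel, truth = truth, pheno = pheno,
       gmap = build_genetic_map(qm))
}

# noiseless phenotypes: trait is exactly the QTN linear predictor
noiseless_chain <- function(n_varieties = 60, n_qtn = 10, seed = 7,
                            mu = 10) {
  qm <- gen_qtn_map(n_qtn, 4, envs = "E1", effect_sd = 1, env_corr = 1,
                    seed = seed)
  panel <- gen_panel(n_varieties, qm, maf_low = 0.3, maf_high = 0.5,
                     seed = seed + 1)
  truth <- simulation_truth(c(E1 = mu), sigma2_G = 0, sigma2_GE = 0,
                            sigma2_e = 0, n_blocks = 1)
  pheno <- gen_phenotypes(panel, qm, truth, seed = seed + 2)
  list(qm = qm, panel = panel, pheno = pheno)
}

# a two-locus map at a given genetic distance (cM), via 1 cM/Mb
two_locus_map <- function(d_cM, same_chrom = TRUE) {
  qm <- data.frame(marker_id = c("m1", "m2"),
                   chrom = if (same_chrom) c(1L, 1L) else c(1L, 2L),
                   pos_bp = c(1e6, 1e6 + if (same_chrom) d_cM * 1e6 else 0),
                   E1 = c(1, 1))
  class(qm) <- c("qtn_map", "data.frame")
  qm
}

# MAS model built directly from known effects (no fitting)
toy_model <- function(effects, intercept = 0, gv_floor = FALSE,
                      environment = "E1") {
  m <- structure(list(environment = environment, intercept = intercept,
                      effects = effects, r2 = 1, gv_floor = gv_floor,
                      n = NA_integer_),
                 class = "mas_model")
  m$superior <- classify_superior(m)
  m
}
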