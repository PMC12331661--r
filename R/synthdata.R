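#' Generate a QTN map with per-environment additive effects
#'
#' Creates a table of trait-associated loci (QTNs) spread over `n_chrom`
#' chromosomes, each carrying one additive effect per environment. Effects are
#' drawn from a zero-mean Gaussian with an equicorrelation structure across
#' environments: `env_corr = 1` gives identical effects in every environment
#' (no QTN-by-environment interaction), `env_corr = 0` gives independent
#' effects.
#'
#' @param n_qtn Number of loci (>= 1).
#' @param n_chrom Number of chromosomes the loci are spread over (>= 1).
#' @param envs Character vector of environment labels (non-empty).
#' @param effect_sd Marginal standard deviation of the per-environment effect,
#'   in trait units per allele-code unit.
#' @param env_corr Cross-environment correlation of a locus effect, in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical maps.
#' @param chrom_length_bp Physical length assumed per chromosome (bp) when
#'   drawing positions.
#' @return A `data.frame` of class `qtn_map` with columns `marker_id`,
#'   `chrom`, `pos_bp` and one effect column per environment (named by the
#'   environment label). Positions are strictly increasing within chromosome.
#' @examples
#' qm <- gen_qtn_map(10, n_chrom = 4, envs = c("E1", "E2"), seed = 1)
#' @export
gen_qtn_map <- function(n_qtn, n_chrom = 20, envs, effect_sd = 1,
                        env_corr = 0.5, seed = 1L,
                        chrom_length_bp = 5e7) {
  if (n_qtn < 1 || n_chrom < 1) {
    stop("n_qtn and n_chrom must be positive")
  }
  if (length(envs) == 0) stop("envs must be a non-empty label vector")
  if (env_corr < 0 || env_corr > 1) stop("env_corr must lie in [0, 1]")
  if (effect_sd < 0) stop("effect_sd must be non-negative")
  set.seed(as.integer(seed))

  chrom <- sort(rep_len(seq_len(n_chrom), n_qtn))
  pos <- integer(n_qtn)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(chrom_length_bp, length(idx)))
  }
  marker_id <- sprintf("Q%04d", seq_len(n_qtn))

  # equicorrelated Gaussian: shared component + env-specific component
  n_env <- length(envs)
  shared <- stats::rnorm(n_qtn)
  eff <- sqrt(env_corr) * matrix(shared, n_qtn, n_env) +
    sqrt(1 - env_corr) * matrix(stats::rnorm(n_qtn * n_env), n_qtn, n_env)
  eff <- eff * effect_sd
  colnames(eff) <- envs

  out <- data.frame(marker_id = marker_id, chrom = chrom, pos_bp = pos,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(eff))
  class(out) <- c("qtn_map", "data.frame")
  validate_qtn_map(out)
  out
}

#' Environment labels of a QTN map
#' @param qtn_map A `qtn_map` object.
#' @return Character vector of environment labels.
#' @export
qtn_envs <- function(qtn_map) {
  setdiff(colnames(qtn_map), c("marker_id", "chrom", "pos_bp"))
}

#' Per-environment effect matrix of a QTN map
#' @param qtn_map A `qtn_map` object.
#' @return Numeric matrix loci x environments, rownames = marker ids.
#' @export
qtn_effects <- function(qtn_map) {
  envs <- qtn_envs(qtn_map)
  m <- as.matrix(qtn_map[, envs, drop = FALSE])
  rownames(m) <- qtn_map$marker_id
  m
}

validate_qtn_map <- function(qm) {
  if (anyDuplicated(qm$marker_id)) stop("marker ids must be unique")
  for (cc in unique(qm$chrom)) {
    p <- qm$pos_bp[qm$chrom == cc]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", cc)
    }
  }
  if (length(qtn_envs(qm)) == 0) stop("qtn_map carries no environment effect columns")
  invisible(qm)
}

#' Generate an inbred germplasm panel at the QTN loci
#'
#' Draws an allele frequency per locus uniformly in `[maf_low, maf_high]`,
#' then codes each variety `+1` at that locus with that frequency and `-1`
#' otherwise. Varieties are fully inbred (no heterozygotes) and independent;
#' no linkage disequilibrium between loci is simulated.
#'
#' @param n_varieties Number of inbred varieties.
#' @param qtn_map A `qtn_map` giving the loci (column order of the panel).
#' @param maf_low,maf_high Bounds of the uniform allele-frequency draw,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Integer seed.
#' @return Integer matrix varieties x loci with entries in `{-1, +1}`;
#'   rownames are variety ids, colnames marker ids.
#' @examples
#' qm <- gen_qtn_map(5, 2, envs = "E1", seed = 1)
#' p <- gen_panel(20, qm, seed = 2)
#' @export
gen_panel <- function(n_varieties, qtn_map, maf_low = 0.1, maf_high = 0.5,
                      seed = 1L) {
  if (n_varieties < 1) stop("n_varieties must be positive")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5")
  }
  set.seed(as.integer(seed))
  n_loci <- nrow(qtn_map)
  freq <- stats::runif(n_loci, maf_low, maf_high)
  codes <- matrix(0L, n_varieties, n_loci)
  for (j in seq_len(n_loci)) {
    codes[, j] <- ifelse(stats::runif(n_varieties) < freq[j], 1L, -1L)
  }
  dimnames(codes) <- list(sprintf("V%03d", seq_len(n_varieties)),
                          qtn_map$marker_id)
  attr(codes, "allele_freq") <- stats::setNames(freq, qtn_map$marker_id)
  codes
}

#' Ground-truth parameters for phenotype simulation
#'
#' Bundles the variance components and layout of the simulated
#' multi-environment trial. `sigma2_G` is a polygenic genetic variance
#' *beyond* the QTN effects (so heritability recovery can be studied with
#' null QTN effects); `sigma2_GE` the genotype-by-environment interaction
#' variance; `sigma2_e` the plot-error variance; `sigma2_block` the variance
#' of block-within-environment effects (0 by default, as block effects are
#' typically negligible in these trials).
#'
#' @param mu_by_env Named numeric vector: environment label -> environment
#'   mean, trait units.
#' @param sigma2_G,sigma2_GE,sigma2_e,sigma2_block Non-negative variances.
#' @param n_blocks Number of complete blocks per environment (R >= 1).
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(mu_by_env, sigma2_G = 0, sigma2_GE = 0,
                             sigma2_e = 1, sigma2_block = 0, n_blocks = 3L) {
  if (is.null(names(mu_by_env)) || any(!nzchar(names(mu_by_env)))) {
    stop("mu_by_env must be a named vector (environment labels)")
  }
  v <- c(sigma2_G, sigma2_GE, sigma2_e, sigma2_block)
  if (any(v < 0)) stop("variance components must be non-negative")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  structure(list(mu_by_env = mu_by_env,
                 sigma2_G = sigma2_G, sigma2_GE = sigma2_GE,
                 sigma2_e = sigma2_e, sigma2_block = sigma2_block,
                 n_env = length(mu_by_env), n_blocks = as.integer(n_blocks)),
            class = "simulation_truth")
}

#' Simulate a multi-environment replicated phenotype table
#'
#' Generates one plot record per (environment, block, variety) from
#' \deqn{y_{erv} = \mu_e + \sum_j a_{je} x_{vj} + g_v + (ge)_{ve} + b_{er} + \epsilon_{erv}}
#' where \eqn{a_{je}} are the QTN effects of `qtn_map`, \eqn{x_{vj}} the
#' panel codes, \eqn{g_v \sim N(0, \sigma^2_G)} a polygenic variety effect,
#' \eqn{(ge)_{ve} \sim N(0, \sigma^2_{GE})}, \eqn{b_{er} \sim N(0, \sigma^2_{block})}
#' and \eqn{\epsilon \sim N(0, \sigma^2_e)}. Each record plays the role of a
#' plot-level mean (e.g. a 10-plant average).
#'
#' @param panel Germplasm panel matrix from [gen_panel()].
#' @param qtn_map A `qtn_map`; its environments must match `names(truth$mu_by_env)`.
#' @param truth A [simulation_truth()] object.
#' @param seed Integer seed.
#' @param nonneg If `TRUE`, floor values at 0 (cosmetic for count-like traits;
#'   off by default because flooring breaks the ANOVA error model).
#' @return Long-format `data.frame` with columns `environment`, `block`,
#'   `variety_id`, `value`.
#' @export
gen_phenotypes <- function(panel, qtn_map, truth, seed = 1L, nonneg = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"))
  envs <- names(truth$mu_by_env)
  map_envs <- qtn_envs(qtn_map)
  if (!setequal(envs, map_envs)) {
    stop("environments in truth (", paste(envs, collapse = ", "),
         ") do not match qtn_map (", paste(map_envs, collapse = ", "), ")")
  }
  if (ncol(panel) != nrow(qtn_map)) {
    stop("panel has ", ncol(panel), " loci but qtn_map has ", nrow(qtn_map))
  }
  set.seed(as.integer(seed))
  n_var <- nrow(panel)
  R <- truth$n_blocks
  eff <- qtn_effects(qtn_map)

  g <- stats::rnorm(n_var, 0, sqrt(truth$sigma2_G))
  out <- vector("list", length(envs) * R)
  k <- 0L
  for (e in envs) {
    qtn_part <- as.numeric(panel %*% eff[, e])
    ge <- stats::rnorm(n_var, 0, sqrt(truth$sigma2_GE))
    for (r in seq_len(R)) {
      b_er <- stats::rnorm(1, 0, sqrt(truth$sigma2_block))
      val <- truth$mu_by_env[[e]] + qtn_part + g + ge + b_er +
        stats::rnorm(n_var, 0, sqrt(truth$sigma2_e))
      k <- k + 1L
      out[[k]] <- data.frame(environment = e,
                             block = sprintf("B%d", r),
                             variety_id = rownames(panel),
                             value = val,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (nonneg) res$value <- pmax(res$value, 0)
  res
}

#' Per-variety mean phenotype within one environment
#'
#' Averages plot records over blocks, the trait definition used by the
#' descriptive statistics and the MAS regression.
#'
#' @param pheno Long phenotype table (`environment`, `block`, `variety_id`, `value`).
#' @param environment Environment label to subset to.
#' @return Named numeric vector, variety id -> mean value.
#' @export
variety_means <- function(pheno, environment) {
  sub <- pheno[pheno$environment == environment, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for environment '", environment, "'")
  tapply(sub$value, sub$variety_id, mean)
}
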