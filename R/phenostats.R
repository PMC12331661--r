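#' Descriptive statistics of a trait per environment
#'
#' Computes, per environment and on per-variety means (plot records averaged
#' over blocks): mean, sample standard deviation, coefficient of variation
#' (percent), min, max, range, skewness and excess kurtosis. Skewness and
#' kurtosis use the sample-adjusted (SAS-convention) estimators
#' (`e1071::skewness`/`kurtosis` with `type = 2`).
#'
#' @param pheno Long phenotype table (`environment`, `block`, `variety_id`,
#'   `value`).
#' @return `data.frame` with one row per environment: `environment`, `n`,
#'   `mean`, `sd`, `cv_percent`, `min`, `max`, `range`, `skew`, `kurt`.
#' @examples
#' qm <- gen_qtn_map(5, 2, envs = c("E1", "E2"), seed = 1)
#' panel <- gen_panel(30, qm, seed = 2)
#' tr <- simulation_truth(c(E1 = 7, E2 = 8), sigma2_G = 4, sigma2_e = 2)
#' describe_pheno(gen_phenotypes(panel, qm, tr, seed = 3))
#' @export
describe_pheno <- function(pheno) {
  envs <- unique(pheno$environment)
  rows <- lapply(envs, function(e) {
    x <- as.numeric(variety_means(pheno, e))
    if (length(x) < 2) {
      stop("environment '", e, "' has fewer than 2 varieties")
    }
    m <- mean(x)
    s <- stats::sd(x)
    data.frame(environment = e, n = length(x), mean = m, sd = s,
               cv_percent = if (m != 0) 100 * s / m else NA_real_,
               min = min(x), max = max(x), range = max(x) - min(x),
               skew = e1071::skewness(x, type = 2),
               kurt = e1071::kurtosis(x, type = 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-environment analysis of variance for a replicated trial
#'
#' Least-squares decomposition for the balanced complete model
#' `value = mu + Env + Block(Env) + Geno + Geno x Env + error`, computed from
#' cell means (exact for the complete balanced layouts this function
#' requires). Every F ratio is taken against the error mean square, the
#' convention used in multi-environment trial reports of this kind, and p
#' values come from the F distribution.
#'
#' @param pheno Long phenotype table with every (environment, block, variety)
#'   cell observed exactly once.
#' @return `data.frame` of class `met_anova` with columns `source`
#'   (`BlockWithinEnv`, `Env`, `Geno`, `GenoxEnv`, `Error`, `Total`), `df`,
#'   `ss`, `ms`, `f`, `p`; attributes `n_env`, `n_blocks`, `n_geno`.
#' @export
pheno_anova <- function(pheno) {
  envs <- sort(unique(pheno$environment))
  gens <- sort(unique(pheno$variety_id))
  E <- length(envs); G <- length(gens)
  if (E < 2) stop("need >= 2 environments")
  if (G < 2) stop("need >= 2 varieties")
  blocks_per_env <- tapply(pheno$block, pheno$environment,
                           function(b) length(unique(b)))
  R <- unique(as.integer(blocks_per_env))
  if (length(R) != 1) stop("unequal block counts across environments")
  if (R < 2) stop("need >= 2 blocks per environment (block stratum is ",
                  "inestimable with one block)")
  # completeness: every cell exactly once
  key <- paste(pheno$environment, pheno$block, pheno$variety_id)
  if (anyDuplicated(key)) stop("duplicate (environment, block, variety) records")
  if (nrow(pheno) != E * R * G) {
    tab <- table(pheno$environment, pheno$variety_id)
    miss <- which(tab < R, arr.ind = TRUE)
    stop("incomplete design: e.g. variety '", colnames(tab)[miss[1, 2]],
         "' missing in environment '", rownames(tab)[miss[1, 1]], "'")
  }

  y <- pheno$value
  grand <- mean(y)
  m_e <- tapply(y, pheno$environment, mean)
  m_v <- tapply(y, pheno$variety_id, mean)
  m_er <- tapply(y, list(pheno$environment, pheno$block), mean)
  m_ev <- tapply(y, list(pheno$environment, pheno$variety_id), mean)

  ss_total <- sum((y - grand)^2)
  ss_env <- G * R * sum((m_e - grand)^2)
  ss_block <- G * sum(sweep(m_er, 1, as.numeric(m_e[rownames(m_er)]))^2)
  ss_geno <- E * R * sum((m_v - grand)^2)
  ss_ge <- R * sum((sweep(sweep(m_ev, 1, as.numeric(m_e[rownames(m_ev)])),
                          2, as.numeric(m_v[colnames(m_ev)])) + grand)^2)
  ss_err <- ss_total - ss_env - ss_block - ss_geno - ss_ge

  df <- c(BlockWithinEnv = E * (R - 1), Env = E - 1, Geno = G - 1,
          GenoxEnv = (E - 1) * (G - 1))
  df <- c(df, Error = E * R * G - 1 - sum(df), Total = E * R * G - 1)
  ss <- c(BlockWithinEnv = ss_block, Env = ss_env, Geno = ss_geno,
          GenoxEnv = ss_ge, Error = ss_err, Total = ss_total)

  out <- anova_from_ss(data.frame(source = names(df), df = as.integer(df),
                                  ss = as.numeric(ss),
                                  stringsAsFactors = FALSE))
  attr(out, "n_env") <- E
  attr(out, "n_blocks") <- R
  attr(out, "n_geno") <- G
  class(out) <- c("met_anova", "data.frame")
  out
}

#' Mean squares, F ratios and p values from sums of squares
#'
#' Completes an ANOVA table given its `source`, `df` and `ss` columns:
#' `ms = ss/df` for every non-Total row, F for every tested source against the
#' error mean square, and p from the F distribution. Useful both internally
#' and to audit a published table's arithmetic from its printed SS and df.
#'
#' @param tab `data.frame` with columns `source`, `df`, `ss`; one row's source
#'   must equal `error_source`, optionally one `Total`.
#' @param error_source Label of the error stratum (default `"Error"`).
#' @return The table with `ms`, `f`, `p` columns added.
#' @export
anova_from_ss <- function(tab, error_source = "Error") {
  stopifnot(all(c("source", "df", "ss") %in% colnames(tab)))
  if (!error_source %in% tab$source) {
    stop("no '", error_source, "' row in table")
  }
  tab$ms <- ifelse(tab$source == "Total", NA_real_, tab$ss / tab$df)
  ms_err <- tab$ms[tab$source == error_source]
  df_err <- tab$df[tab$source == error_source]
  tested <- !(tab$source %in% c(error_source, "Total"))
  tab$f <- ifelse(tested, tab$ms / ms_err, NA_real_)
  tab$p <- ifelse(tested, stats::pf(tab$ms / ms_err, tab$df, df_err,
                                    lower.tail = FALSE), NA_real_)
  tab
}

#' Variance components and heritability from an ANOVA table
#'
#' Method-of-moments estimates from expected mean squares with genotype and
#' genotype-by-environment random:
#' `sigma2_e = MS(Error)`, `sigma2_GE = (MS(GxE) - MS(Error)) / R`,
#' `sigma2_G = (MS(G) - MS(GxE)) / (E R)`. Negative estimates are floored at
#' zero, then broad-sense heritability is filled by [heritability()].
#'
#' @param anova_table A [pheno_anova()] result (or any table with `Geno`,
#'   `GenoxEnv`, `Error` rows carrying `ms`).
#' @param n_env,n_blocks Number of environments E and blocks per environment
#'   R; default to the attributes [pheno_anova()] stores.
#' @return List of class `variance_components`: `sigma2_G`, `sigma2_GE`,
#'   `sigma2_e`, `n_env`, `n_blocks`, `h2`.
#' @export
variance_components <- function(anova_table,
                                n_env = attr(anova_table, "n_env"),
                                n_blocks = attr(anova_table, "n_blocks")) {
  need <- c("Geno", "GenoxEnv", "Error")
  if (!all(need %in% anova_table$source)) {
    stop("anova table lacks rows: ",
         paste(setdiff(need, anova_table$source), collapse = ", "))
  }
  if (is.null(n_env) || is.null(n_blocks)) {
    stop("n_env and n_blocks must be supplied when the table carries no ",
         "layout attributes")
  }
  ms <- stats::setNames(anova_table$ms, anova_table$source)
  s2e <- ms[["Error"]]
  s2ge <- max(0, (ms[["GenoxEnv"]] - ms[["Error"]]) / n_blocks)
  s2g <- max(0, (ms[["Geno"]] - ms[["GenoxEnv"]]) / (n_env * n_blocks))
  structure(list(sigma2_G = s2g, sigma2_GE = s2ge, sigma2_e = s2e,
                 n_env = as.integer(n_env), n_blocks = as.integer(n_blocks),
                 h2 = heritability(s2g, s2ge, s2e, n_env, n_blocks)),
            class = "variance_components")
}

#' Broad-sense heritability across environments
#'
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(E R))}
#' on a variety-mean basis over E environments and R blocks.
#'
#' @param sigma2_G Genetic variance (>= 0).
#' @param sigma2_GE Genotype-by-environment interaction variance (>= 0).
#' @param sigma2_e Error variance (>= 0).
#' @param n_env Number of environments E (>= 1).
#' @param n_blocks Number of blocks per environment R (>= 1).
#' @return Heritability in `[0, 1]`.
#' @examples
#' heritability(12.421, 15.357, 23.949, n_env = 5, n_blocks = 3)  # 0.727
#' @export
heritability <- function(sigma2_G, sigma2_GE, sigma2_e, n_env, n_blocks) {
  if (any(c(sigma2_G, sigma2_GE, sigma2_e) < 0)) {
    stop("variance components must be non-negative")
  }
  if (n_env < 1 || n_blocks < 1) stop("n_env and n_blocks must be >= 1")
  denom <- sigma2_G + sigma2_GE / n_env + sigma2_e / (n_env * n_blocks)
  if (denom == 0) stop("all variance components are zero")
  sigma2_G / denom
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (method of moments, E =", x$n_env,
      ", R =", x$n_blocks, ")\n")
  cat(sprintf("  sigma2_G  = %.4f\n  sigma2_GE = %.4f\n  sigma2_e  = %.4f\n",
              x$sigma2_G, x$sigma2_GE, x$sigma2_e))
  cat(sprintf("  h2        = %.4f\n", x$h2))
  invisible(x)
}
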