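#' Fit a per-environment marker-assisted selection (MAS) model
#'
#' Ordinary least squares of the per-variety mean phenotype in one
#' environment on the full -1/+1 QTN code matrix plus an intercept. All loci
#' enter simultaneously (no selection or shrinkage); the reported `r2` is the
#' in-sample coefficient of determination, which carries an overfitting floor
#' of about `p/(n-1)` under a null trait. Superior alleles are classified by
#' the sign of each fitted effect.
#'
#' @param panel Germplasm panel matrix (varieties x loci, entries -1/+1),
#'   rownames variety ids, colnames marker ids.
#' @param pheno Long phenotype table; plot records are averaged to variety
#'   means within `environment`.
#' @param environment Environment label to fit.
#' @param qtn_map A `qtn_map`; fixes the locus order.
#' @param gv_floor Default flooring behaviour recorded in the model and used
#'   by [predict_gv()]: floor predicted genotype values at 0 (count-like
#'   traits cannot go negative).
#' @return List of class `mas_model`: `environment`, `intercept`, `effects`
#'   (named by marker), `r2`, `superior` (named vector in `{+1, -1, NA}`),
#'   `gv_floor`, `n`, `fitted`, `residuals`.
#' @export
fit_mas <- function(panel, pheno, environment, qtn_map, gv_floor = TRUE) {
  if (!identical(colnames(panel), qtn_map$marker_id)) {
    stop("panel locus order does not match qtn_map")
  }
  ym <- variety_means(pheno, environment)
  common <- intersect(rownames(panel), names(ym))
  if (length(common) < 2) stop("no overlapping varieties between panel and phenotypes")
  X <- panel[common, , drop = FALSE]
  y <- as.numeric(ym[common])
  n <- length(y); p <- ncol(X)
  if (n <= p) {
    stop("cannot fit MAS model: n = ", n, " varieties <= p = ", p, " markers")
  }

  # exact duplicate columns are the common collinearity failure; name pairs
  Xn <- sweep(X, 2, X[1, ], "*")  # sign-normalize so negated twins also match
  dup <- duplicated(t(Xn))
  if (any(dup)) {
    pairs <- vapply(which(dup), function(j) {
      twin <- which(apply(X[, seq_len(j - 1), drop = FALSE], 2, function(col)
        all(col == X[, j]) || all(col == -X[, j])))[1]
      paste0(colnames(X)[twin], "/", colnames(X)[j])
    }, character(1))
    stop("collinear (duplicated) marker columns: ", paste(pairs, collapse = ", "))
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    bad <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    stop("collinear marker columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrd, y)
  fitted <- as.numeric(D %*% beta)
  resid <- y - fitted
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)

  effects <- beta[-1]
  names(effects) <- colnames(X)
  model <- structure(list(environment = environment,
                          intercept = unname(beta[1]),
                          effects = effects,
                          r2 = r2,
                          gv_floor = isTRUE(gv_floor),
                          n = n,
                          fitted = stats::setNames(fitted, common),
                          residuals = stats::setNames(resid, common)),
                     class = "mas_model")
  model$superior <- classify_superior(model)
  model
}

#' Classify the superior allele of each QTN
#'
#' Sign rule on the fitted effect: a positive effect makes `+1` the superior
#' (trait-increasing) code, a negative effect makes `-1` superior; an exactly
#' zero effect has no superior allele (`NA`) and is excluded from
#' superior-allele counts.
#'
#' @param model A `mas_model`, or a named numeric vector of effects.
#' @return Named integer vector in `{+1, -1, NA}` per marker.
#' @export
classify_superior <- function(model) {
  eff <- if (inherits(model, "mas_model")) model$effects else model
  out <- ifelse(eff > 0, 1L, ifelse(eff < 0, -1L, NA_integer_))
  stats::setNames(as.integer(out), names(eff))
}

#' Number of superior alleles (NSA) per individual
#'
#' For inbred -1/+1 codes a locus contributes 1 to an individual's NSA when
#' its code equals the superior code. For simulated individuals carrying two
#' haplotypes, a heterozygous locus (one haplotype matching) contributes 0.5.
#' Loci without a superior allele (zero effect) are skipped entirely.
#'
#' @param genotypes Either a panel matrix (varieties x loci, -1/+1) or a
#'   cohort (see [new_cohort()]).
#' @param superior Named superior-code vector from [classify_superior()],
#'   same locus order as `genotypes`.
#' @return List of class `nsa_summary`: `nsa` (per individual),
#'   `superior_fraction` (per QTN: mean superior-allele dosage across
#'   individuals; `NA` for unscored loci), `n_scored_loci`.
#' @export
nsa <- function(genotypes, superior) {
  if (is_cohort(genotypes)) {
    hapA <- genotypes$hapA
    hapB <- genotypes$hapB
  } else {
    hapA <- hapB <- as.matrix(genotypes)
  }
  if (ncol(hapA) != length(superior)) {
    stop("locus count mismatch: genotypes have ", ncol(hapA),
         " loci, superior codes ", length(superior))
  }
  if (!is.null(colnames(hapA)) && !is.null(names(superior)) &&
      !identical(colnames(hapA), names(superior))) {
    stop("locus order mismatch between genotypes and superior codes")
  }
  scored <- which(!is.na(superior))
  sup <- superior[scored]
  contrib <- (sweep(hapA[, scored, drop = FALSE], 2, sup, "==") +
                sweep(hapB[, scored, drop = FALSE], 2, sup, "==")) / 2
  per_ind <- rowSums(contrib)
  frac <- rep(NA_real_, length(superior))
  frac[scored] <- colMeans(contrib)
  names(frac) <- names(superior)
  if (!is.null(rownames(hapA))) names(per_ind) <- rownames(hapA)
  structure(list(nsa = per_ind, superior_fraction = frac,
                 n_scored_loci = length(scored)),
            class = "nsa_summary")
}

#' Predict genotype values from a MAS model
#'
#' `gv = intercept + sum_j effect_j code_j` with codes in `{-1, 0, +1}`
#' (0 = heterozygote, additive midpoint). With `floor = TRUE` the value is
#' floored at 0, since a count-like trait cannot go negative while the linear
#' predictor can.
#'
#' @param model A `mas_model`.
#' @param genotype Code vector of length `n_qtn`, or a matrix with one row
#'   per individual.
#' @param floor Floor at zero; defaults to the model's `gv_floor` setting.
#' @return Numeric genotype value(s).
#' @export
predict_gv <- function(model, genotype, floor = model$gv_floor) {
  g <- if (is.matrix(genotype)) genotype else matrix(genotype, nrow = 1)
  if (ncol(g) != length(model$effects)) {
    stop("genotype has ", ncol(g), " loci; model expects ",
         length(model$effects))
  }
  if (!all(g %in% c(-1, 0, 1))) stop("genotype codes must be in {-1, 0, +1}")
  gv <- model$intercept + as.numeric(g %*% model$effects)
  if (isTRUE(floor)) gv <- pmax(gv, 0)
  gv
}

#' @export
print.mas_model <- function(x, ...) {
  cat("MAS model [", x$environment, "]: ", length(x$effects),
      " QTNs, n = ", x$n, ", r2 = ", sprintf("%.4f", x$r2),
      ", intercept = ", sprintf("%.3f", x$intercept),
      ", gv floor ", if (x$gv_floor) "on" else "off", "\n", sep = "")
  invisible(x)
}
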