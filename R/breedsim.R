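#' Construct a cohort of simulated plants
#'
#' A cohort stores one generation of plants as two haplotype matrices over
#' the QTN loci (entries -1/+1), a family id per plant and a generation
#' label. Inbred parents have `hapA == hapB`.
#'
#' @param hapA,hapB Integer matrices, plants x loci.
#' @param family Integer family/lineage id per plant.
#' @param generation Label such as `"F2"`.
#' @return List of class `cohort`.
#' @export
new_cohort <- function(hapA, hapB, family = rep(1L, nrow(hapA)),
                       generation = "F1") {
  stopifnot(identical(dim(hapA), dim(hapB)), length(family) == nrow(hapA))
  structure(list(hapA = hapA, hapB = hapB, family = as.integer(family),
                 generation = generation),
            class = "cohort")
}

is_cohort <- function(x) inherits(x, "cohort")

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort [", x$generation, "]: ", nrow(x$hapA), " plants, ",
      ncol(x$hapA), " loci, ", length(unique(x$family)), " families\n",
      sep = "")
  invisible(x)
}

#' Genotype codes of a cohort
#'
#' Additive codes `(hapA + hapB) / 2`, in `{-1, 0, +1}` with 0 marking a
#' heterozygous locus.
#'
#' @param cohort A `cohort`.
#' @return Numeric matrix plants x loci.
#' @export
genotype_codes <- function(cohort) {
  (cohort$hapA + cohort$hapB) / 2
}

#' Per-locus heterozygosity of a cohort
#' @param cohort A `cohort`.
#' @return Numeric vector: fraction of heterozygous plants per locus.
#' @export
heterozygosity <- function(cohort) {
  colMeans(cohort$hapA != cohort$hapB)
}

#' Simulate one gamete from an individual
#'
#' Sequential Markov model without crossover interference: on each
#' chromosome the gamete starts from either haplotype with probability 1/2
#' and switches source between adjacent loci with the Haldane recombination
#' fraction of the genetic map.
#'
#' @param ind A single individual: list with `hapA`, `hapB` code vectors, or
#'   a one-plant `cohort`.
#' @param gmap A [build_genetic_map()] result.
#' @return Integer allele-code vector (one gamete).
#' @export
meiosis <- function(ind, gmap) {
  hapA <- rbind(if (is_cohort(ind)) ind$hapA[1, ] else ind$hapA)
  hapB <- rbind(if (is_cohort(ind)) ind$hapB[1, ] else ind$hapB)
  drop(gametes_cpp(hapA, hapB, gmap$r))
}

# one gamete per row of parent haplotype matrices
gamete_matrix <- function(hapA, hapB, gmap) {
  gametes_cpp(hapA, hapB, gmap$r)
}

#' Cross two inbred parents
#'
#' Produces `n` F1 plants, each formed from one gamete per parent. For fully
#' inbred parents all F1 are identical and heterozygous exactly where the
#' parents differ.
#'
#' @param p1,p2 Parent code vectors (entries -1/+1; inbred, so a single
#'   haplotype each) with loci in map order.
#' @param n Number of F1 plants (>= 1).
#' @param gmap A `genetic_map`.
#' @return A `cohort` labelled `"F1"`.
#' @export
cross <- function(p1, p2, n = 10L, gmap) {
  if (n < 1) stop("n must be >= 1")
  if (length(p1) != length(p2)) stop("parents differ in locus count")
  h1 <- matrix(rep(as.integer(p1), each = n), n)
  h2 <- matrix(rep(as.integer(p2), each = n), n)
  colnames(h1) <- colnames(h2) <- names(p1)
  gA <- gamete_matrix(h1, h1, gmap)  # inbred: gamete == haplotype
  gB <- gamete_matrix(h2, h2, gmap)
  colnames(gA) <- colnames(gB) <- names(p1)
  new_cohort(gA, gB, family = rep(1L, n), generation = "F1")
}

# Self plants of a cohort: offspring i descends from cohort plant
# parent_idx[i]; two independent gametes per offspring.
self_progeny <- function(cohort, parent_idx, family, generation, gmap) {
  hA <- cohort$hapA[parent_idx, , drop = FALSE]
  hB <- cohort$hapB[parent_idx, , drop = FALSE]
  new_cohort(gamete_matrix(hA, hB, gmap), gamete_matrix(hA, hB, gmap),
             family = family, generation = generation)
}

#' Self every plant of a cohort
#'
#' Each plant contributes `n_per_plant` selfed offspring (two independent
#' gametes each); offspring inherit the parent's family id.
#'
#' @param cohort A `cohort`.
#' @param n_per_plant Offspring per plant.
#' @param gmap A `genetic_map`.
#' @param generation Label for the offspring generation.
#' @return A `cohort`.
#' @export
self_cohort <- function(cohort, n_per_plant = 1L, gmap,
                        generation = cohort$generation) {
  idx <- rep(seq_len(nrow(cohort$hapA)), each = n_per_plant)
  self_progeny(cohort, idx, family = cohort$family[idx], generation, gmap)
}

#' Define a breeding scheme
#'
#' A scheme fixes the advancement method (pedigree: selected plants are
#' harvested individually, each founding a family; bulk: selected plants
#' within a family are harvested mixed and the family advances as one
#' population until single-plant lines are drawn), the F2 population size,
#' the per-generation family sizes, and the truncation-selection plan.
#'
#' The default plan selects at F2, F4, F6 and F7 with among-family ratio
#' `af = 0.5` and within-family ratio `wf = 0.1`, and within families only
#' (`af = 1`) at F5; F3 is advanced without selection. Selected counts are
#' rounded up with a minimum of one survivor.
#'
#' @param method `"pedigree"` or `"bulk"`.
#' @param f2_size F2 population size per cross (the classical schemes use
#'   200, 500 or 800).
#' @param gen_sizes Named vector of per-family sizes for F1 and F3..F7.
#' @param plan Named list: generation -> `c(af = , wf = )`, ratios in (0, 1].
#'   Generations absent from the plan are advanced unselected.
#' @param line_generation Generation at which the bulk method starts drawing
#'   single-plant lines (within-family selection there founds lines).
#' @param id Scheme label; default `Ped<f2>`/`Blk<f2>`.
#' @return List of class `breeding_scheme`.
#' @export
breeding_scheme <- function(method = c("pedigree", "bulk"),
                            f2_size = 200L,
                            gen_sizes = c(F1 = 10L, F3 = 30L, F4 = 30L,
                                          F5 = 50L, F6 = 50L, F7 = 50L),
                            plan = list(F2 = c(af = 0.5, wf = 0.1),
                                        F4 = c(af = 0.5, wf = 0.1),
                                        F5 = c(af = 1.0, wf = 0.1),
                                        F6 = c(af = 0.5, wf = 0.1),
                                        F7 = c(af = 0.5, wf = 0.1)),
                            line_generation = "F5",
                            id = NULL) {
  method <- match.arg(method)
  if (f2_size < 1) stop("f2_size must be >= 1")
  for (g in names(plan)) {
    p <- plan[[g]]
    if (any(p <= 0) || any(p > 1)) {
      stop("selection ratios for ", g, " must lie in (0, 1]")
    }
  }
  if (is.null(id)) {
    id <- paste0(if (method == "pedigree") "Ped" else "Blk", f2_size)
  }
  structure(list(method = method, f2_size = as.integer(f2_size),
                 gen_sizes = gen_sizes, plan = plan,
                 line_generation = line_generation, id = id),
            class = "breeding_scheme")
}

#' The six standard schemes
#'
#' Pedigree and bulk methods at F2 sizes 200, 500 and 800
#' (`Ped200 ... Blk800`).
#'
#' @param f2_sizes F2 sizes to pair with both methods.
#' @param ... Passed to [breeding_scheme()].
#' @return Named list of `breeding_scheme` objects.
#' @export
default_schemes <- function(f2_sizes = c(200L, 500L, 800L), ...) {
  out <- list()
  for (m in c("pedigree", "bulk")) {
    for (s in f2_sizes) {
      sch <- breeding_scheme(method = m, f2_size = s, ...)
      out[[sch$id]] <- sch
    }
  }
  out
}

# truncation selection on a cohort; returns indices of kept plants in
# stable (gv desc, index asc) order within kept families
truncate_cohort <- function(gv, family, af, wf) {
  fams <- sort(unique(family))
  fam_mean <- vapply(fams, function(f) mean(gv[family == f]), numeric(1))
  n_keep_f <- max(1L, ceiling(af * length(fams)))
  ord_f <- order(-fam_mean, fams)
  keep_f <- fams[ord_f[seq_len(n_keep_f)]]
  kept <- integer(0)
  for (f in keep_f) {
    idx <- which(family == f)
    ord <- idx[order(-gv[idx], idx)]
    kept <- c(kept, ord[seq_len(max(1L, ceiling(wf * length(idx))))])
  }
  kept
}

#' Advance one cross through a breeding scheme to terminal F7 lines
#'
#' Runs the generation loop F1 -> F7 for a single cross: the F2 is produced
#' by selfing the F1 plants to `f2_size` individuals; at each selection
#' generation of the scheme's plan, families are ranked by mean MAS genotype
#' value and the top `ceiling(af * n_families)` kept, then the top
#' `ceiling(wf * n_plants)` plants within each kept family. Under the
#' pedigree method every selected plant founds its own next-generation
#' family; under the bulk method selected plants stay pooled in their family
#' until `line_generation`, where each selected plant founds a single-plant
#' line. Unselected generations advance each family by selfing random
#' members. Terminal lines are the plants selected at F7, scored by
#' [predict_gv()] and [nsa()].
#'
#' Ranking uses the raw (unfloored) linear predictor; reported genotype
#' values honour the model's `gv_floor` setting.
#'
#' @param f1 An F1 `cohort` from [cross()].
#' @param scheme A [breeding_scheme()].
#' @param model A [fit_mas()] model for the target environment.
#' @param gmap A `genetic_map`.
#' @param cross_id Label stored in the result.
#' @param selection_h2 Optional realized heritability of the selection
#'   criterion, in (0, 1]. By default (`NULL`, equivalent to 1) truncation
#'   acts on the genotype value itself; smaller values overlay Gaussian
#'   phenotypic noise scaled so that `var(gv) / var(criterion)` equals
#'   `selection_h2` at each selection stage, emulating selection on a noisy
#'   phenotype.
#' @param keep_history Record per-stage plant counts and mean genotype
#'   values before/after each selection.
#' @param keep_haplotypes Keep the terminal haplotype matrices in the result.
#' @return List of class `scheme_result`: `cross_id`, `scheme_id`, `lines`
#'   (data.frame `line_id`, `family`, `gv`, `nsa`), `summary`, optional
#'   `history` and `haplotypes`.
#' @export
advance <- function(f1, scheme, model, gmap, cross_id = "cross",
                    selection_h2 = NULL, keep_history = FALSE,
                    keep_haplotypes = FALSE) {
  stopifnot(inherits(scheme, "breeding_scheme"), inherits(model, "mas_model"))
  if (!is.null(selection_h2) &&
      (selection_h2 <= 0 || selection_h2 > 1)) {
    stop("selection_h2 must lie in (0, 1]")
  }
  gv_of <- function(coh) {
    model$intercept + as.numeric(genotype_codes(coh) %*% model$effects)
  }
  history <- list()
  note <- function(coh, stage, gv) {
    if (keep_history) {
      history[[length(history) + 1L]] <<- data.frame(
        generation = coh$generation, stage = stage, n = length(gv),
        n_families = length(unique(coh$family)), gv_mean = mean(gv))
    }
  }

  # F2: self the F1 to f2_size plants, one family (the cross)
  n_f1 <- nrow(f1$hapA)
  idx <- rep_len(seq_len(n_f1), scheme$f2_size)
  coh <- self_progeny(f1, idx, family = rep(1L, scheme$f2_size), "F2", gmap)

  gens <- c("F2", "F3", "F4", "F5", "F6", "F7")
  for (gi in seq_along(gens)) {
    g <- gens[gi]
    if (nrow(coh$hapA) == 0) stop("no plants left at generation ", g)
    gv <- gv_of(coh)
    plan <- scheme$plan[[g]]
    found_lines <- FALSE
    if (!is.null(plan)) {
      note(coh, "pre-selection", gv)
      crit <- gv
      if (!is.null(selection_h2) && selection_h2 < 1) {
        v <- stats::var(gv)
        if (v > 0) {
          crit <- gv + stats::rnorm(length(gv), 0,
                                    sqrt(v * (1 - selection_h2) /
                                           selection_h2))
        }
      }
      kept <- truncate_cohort(crit, coh$family, plan[["af"]], plan[["wf"]])
      if (length(kept) == 0) stop("selection eliminated all plants at ", g)
      found_lines <- scheme$method == "pedigree" ||
        match(g, gens) >= match(scheme$line_generation, gens)
      fam <- if (found_lines) seq_along(kept) else coh$family[kept]
      coh <- new_cohort(coh$hapA[kept, , drop = FALSE],
                        coh$hapB[kept, , drop = FALSE],
                        family = fam, generation = g)
      gv <- gv[kept]
      note(coh, "post-selection", gv)
    } else {
      note(coh, "no-selection", gv)
    }
    if (g == "F7") break
    nxt <- gens[gi + 1L]
    size <- as.integer(scheme$gen_sizes[nxt])
    if (is.na(size)) size <- scheme$f2_size
    if (found_lines) {
      # each selected plant founds a family of `size` selfed offspring
      idx <- rep(seq_len(nrow(coh$hapA)), each = size)
      fam <- coh$family[idx]
    } else {
      # maintain families: sample parents within each family
      idx <- integer(0)
      for (f in unique(coh$family)) {
        members <- which(coh$family == f)
        idx <- c(idx, members[sample.int(length(members), size,
                                         replace = TRUE)])
      }
      fam <- coh$family[idx]
    }
    coh <- self_progeny(coh, idx, family = fam, nxt, gmap)
  }

  gv_rep <- predict_gv(model, genotype_codes(coh))
  line_nsa <- nsa(coh, model$superior)$nsa
  lines <- data.frame(line_id = sprintf("L%05d", seq_along(gv_rep)),
                      family = coh$family, gv = gv_rep, nsa = line_nsa,
                      stringsAsFactors = FALSE)
  res <- structure(list(cross_id = cross_id, scheme_id = scheme$id,
                        lines = lines,
                        summary = summarize_lines(lines)),
                   class = "scheme_result")
  if (keep_history) res$history <- do.call(rbind, history)
  if (keep_haplotypes) res$haplotypes <- coh
  res
}

summarize_lines <- function(lines) {
  data.frame(n = nrow(lines),
             gv_min = min(lines$gv), gv_max = max(lines$gv),
             gv_mean = mean(lines$gv), gv_sd = stats::sd(lines$gv),
             nsa_min = min(lines$nsa), nsa_max = max(lines$nsa))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate half-diallel crosses
#'
#' All unordered pairs of distinct parents (no selfs, no reciprocals):
#' `n (n - 1) / 2` crosses.
#'
#' @param variety_ids Character vector of parent ids.
#' @return `data.frame` with `cross_id` (`"A/B"`), `parent1`, `parent2` and a
#'   stable `index` independent of any subsetting.
#' @examples
#' nrow(enumerate_crosses(sprintf("V%03d", 1:455)))  # 103285
#' @export
enumerate_crosses <- function(variety_ids) {
  n <- length(variety_ids)
  if (n < 2) stop("need at least 2 parents")
  pairs <- utils::combn(n, 2)
  data.frame(cross_id = paste(variety_ids[pairs[1, ]],
                              variety_ids[pairs[2, ]], sep = "/"),
             parent1 = variety_ids[pairs[1, ]],
             parent2 = variety_ids[pairs[2, ]],
             index = (pairs[1, ] - 1L) * n + pairs[2, ],
             stringsAsFactors = FALSE)
}

# per-(cross, scheme) RNG stream so subset runs reproduce full-run results
cross_seed <- function(seed, cross_index, scheme_index) {
  ((as.double(seed) %% 2147483629) * 48271 + cross_index * 7919 +
     scheme_index * 104729) %% 2147483629 + 1
}

#' Run breeding schemes over a half-diallel of crosses
#'
#' Enumerates all unordered parent pairs of the panel (or a given subset of
#' cross ids), simulates every scheme for every cross with [advance()], and
#' returns one `scheme_result` per cross-by-scheme combination. Each
#' combination gets its own RNG stream derived from `seed` and the cross's
#' stable index, so results are reproducible and independent of subsetting
#' or iteration order.
#'
#' @param panel Germplasm panel matrix (parents).
#' @param schemes List of [breeding_scheme()] objects.
#' @param model A [fit_mas()] model (target environment).
#' @param gmap A `genetic_map`.
#' @param seed Integer master seed.
#' @param crosses Optional character vector of cross ids (`"A/B"`) to run; by
#'   default all `n(n-1)/2`.
#' @param n_f1 F1 plants per cross.
#' @return List of `scheme_result` objects, one per cross x scheme.
#' @export
run_halfdiallel <- function(panel, schemes, model, gmap, seed = 1L,
                            crosses = NULL, n_f1 = 10L) {
  all_crosses <- enumerate_crosses(rownames(panel))
  if (!is.null(crosses)) {
    miss <- setdiff(crosses, all_crosses$cross_id)
    if (length(miss)) stop("unknown cross ids: ", paste(miss, collapse = ", "))
    all_crosses <- all_crosses[match(crosses, all_crosses$cross_id), ,
                               drop = FALSE]
  }
  if (is.list(schemes) && inherits(schemes, "breeding_scheme")) {
    schemes <- list(schemes)
  }
  results <- vector("list", nrow(all_crosses) * length(schemes))
  k <- 0L
  for (i in seq_len(nrow(all_crosses))) {
    cr <- all_crosses[i, ]
    p1 <- panel[cr$parent1, ]
    p2 <- panel[cr$parent2, ]
    for (s in seq_along(schemes)) {
      set.seed(cross_seed(seed, cr$index, s))
      f1 <- cross(p1, p2, n = n_f1, gmap)
      k <- k + 1L
      results[[k]] <- advance(f1, schemes[[s]], model, gmap,
                              cross_id = cr$cross_id)
    }
  }
  results
}

#' Pool scheme results into per-scheme summaries
#'
#' Aggregates terminal lines over all crosses, per scheme: line count, NSA
#' range and genotype-value min/max/mean/sd — the layout of a
#' progeny-summary table.
#'
#' @param results List of `scheme_result` objects.
#' @return `data.frame`, one row per scheme id.
#' @export
summarize_schemes <- function(results) {
  lines <- scheme_lines(results)
  out <- do.call(rbind, lapply(split(lines, lines$scheme_id), function(d) {
    cbind(data.frame(scheme_id = d$scheme_id[1], stringsAsFactors = FALSE),
          summarize_lines(d))
  }))
  rownames(out) <- NULL
  out
}

#' Flatten scheme results to one row per terminal line
#' @param results List of `scheme_result` objects.
#' @return `data.frame` with `cross_id`, `scheme_id`, `line_id`, `family`,
#'   `gv`, `nsa`.
#' @export
scheme_lines <- function(results) {
  if (length(results) == 0) stop("no scheme results")
  do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(cross_id = r$cross_id, scheme_id = r$scheme_id,
                     stringsAsFactors = FALSE), r$lines)
  }))
}
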