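test_that("genetic map distances convert to Haldane recombination fractions", {
  qm <- two_locus_map(1)  # 1 Mb apart at 1 cM/Mb
  gmap <- build_genetic_map(qm, cM_per_Mb = 1)
  expect_equal(recomb_fraction(gmap, "m1", "m2"), 0.5 * (1 - exp(-0.02)),
               tolerance = 1e-12)
  expect_equal(recomb_fraction(gmap, "m1", "m2"), 0.0099, tolerance = 1e-4)
  expect_equal(recomb_fraction(gmap, "m1", "m1"), 0)  # zero distance
  expect_equal(haldane(0), 0)
  gmap2 <- build_genetic_map(two_locus_map(1, same_chrom = FALSE))
  expect_equal(recomb_fraction(gmap2, "m1", "m2"), 0.5)  # independent
  expect_error(build_genetic_map(qm, cM_per_Mb = 0), "positive")
})

test_that("meiosis of a homozygote returns the haplotype unchanged", {
  gmap <- build_genetic_map(two_locus_map(10))
  ind <- list(hapA = c(1L, -1L), hapB = c(1L, -1L))
  for (s in 1:5) {
    set.seed(s)
    expect_identical(meiosis(ind, gmap), c(1L, -1L))
  }
})

test_that("recombinant fractions match Haldane closed form by Monte Carlo", {
  set.seed(314)
  n <- 50000  # two gametes per selfed offspring -> 1e5 gametes
  make_het <- function(qm) {
    gmap <- build_genetic_map(qm)
    coh <- new_cohort(hapA = matrix(1L, n, 2), hapB = matrix(-1L, n, 2))
    off <- self_cohort(coh, 1L, gmap)
    gametes <- rbind(off$hapA, off$hapB)
    mean(gametes[, 1] != gametes[, 2])  # recombinant fraction
  }
  r_linked <- make_het(two_locus_map(10))
  expect_lt(abs(r_linked - haldane(10)), 0.005)
  expect_equal(round(haldane(10), 4), 0.0906)
  r_free <- make_het(two_locus_map(10, same_chrom = FALSE))
  expect_lt(abs(r_free - 0.5), 0.005)
})

test_that("F1 of inbred parents is uniform and heterozygous where they differ", {
  ch <- small_chain(seed = 61)
  p1 <- ch$panel[1, ]; p2 <- ch$panel[2, ]
  set.seed(1)
  f1 <- cross(p1, p2, n = 10, ch$gmap)
  expect_equal(nrow(f1$hapA), 10)
  for (i in 2:10) {
    expect_identical(f1$hapA[i, ], f1$hapA[1, ])
    expect_identical(f1$hapB[i, ], f1$hapB[1, ])
  }
  het <- heterozygosity(f1)
  expect_equal(unname(het), as.numeric(p1 != p2))
  f_same <- cross(p1, p1, n = 5, ch$gmap)
  expect_true(all(f_same$hapA == matrix(p1, 5, length(p1), byrow = TRUE)))
  expect_true(all(f_same$hapA == f_same$hapB))
})

test_that("F2 single-locus genotypes segregate 1:2:1", {
  gmap <- build_genetic_map(two_locus_map(25))
  set.seed(27)
  f1 <- cross(c(m1 = 1L, m2 = 1L), c(m1 = -1L, m2 = -1L), n = 1, gmap)
  f2 <- self_cohort(new_cohort(f1$hapA[rep(1, 10000), ],
                               f1$hapB[rep(1, 10000), ]), 1L, gmap)
  codes <- genotype_codes(f2)
  for (j in 1:2) {
    counts <- table(factor(codes[, j], levels = c(-1, 0, 1)))
    p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("heterozygosity halves each selfing generation without selection", {
  ch <- small_chain(n_qtn = 8, seed = 91)
  # fully heterozygous F1 over all 8 mapped loci
  set.seed(5)
  coh <- new_cohort(matrix(1L, 10000, 8), matrix(-1L, 10000, 8))
  expected <- 0.5
  for (gen in c("F2", "F3", "F4")) {
    coh <- self_cohort(coh, 1L, ch$gmap, generation = gen)
    expect_lt(abs(mean(heterozygosity(coh)) - expected), 0.015)
    expected <- expected / 2
  }
})

test_that("alleles in offspring exist in a parent; frequencies are conserved", {
  ch <- small_chain(seed = 13)
  p1 <- ch$panel[5, ]; p2 <- ch$panel[6, ]
  set.seed(2)
  f1 <- cross(p1, p2, 5, ch$gmap)
  f2 <- self_cohort(new_cohort(f1$hapA[rep(1, 5000), ],
                               f1$hapB[rep(1, 5000), ]), 1L, ch$gmap)
  for (j in seq_along(p1)) {
    parent_alleles <- unique(c(p1[j], p2[j]))
    expect_true(all(f2$hapA[, j] %in% parent_alleles))
    expect_true(all(f2$hapB[, j] %in% parent_alleles))
  }
  # without selection the +1 allele frequency stays at the F1 value (0.5
  # where parents differ)
  seg <- which(p1 != p2)
  freq <- colMeans((f2$hapA[, seg, drop = FALSE] == 1) +
                     (f2$hapB[, seg, drop = FALSE] == 1)) / 2
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 5000) + 0.01))
})

test_that("unselected descent preserves the midparent genotype value", {
  ch <- small_chain(seed = 17)
  m <- fit_mas(ch$panel, ch$pheno, "E1", ch$qm, gv_floor = FALSE)
  ssd <- breeding_scheme("pedigree", f2_size = 2000,
                         gen_sizes = c(F1 = 10, F3 = 1, F4 = 1, F5 = 1,
                                       F6 = 1, F7 = 1),
                         plan = list(F2 = c(af = 1, wf = 1)),
                         id = "SSD")
  p1 <- ch$panel[1, ]; p2 <- ch$panel[2, ]
  midparent <- mean(c(predict_gv(m, p1, floor = FALSE),
                      predict_gv(m, p2, floor = FALSE)))
  set.seed(3)
  f1 <- cross(p1, p2, 10, ch$gmap)
  res <- advance(f1, ssd, m, ch$gmap)
  expect_equal(nrow(res$lines), 2000)
  se <- sd(res$lines$gv) / sqrt(nrow(res$lines))
  expect_lt(abs(mean(res$lines$gv) - midparent), 2 * se)
})

test_that("truncation selection never decreases the mean genotype value", {
  ch <- small_chain(seed = 23)
  m <- fit_mas(ch$panel, ch$pheno, "E1", ch$qm)
  for (s in 1:3) {
    set.seed(s)
    f1 <- cross(ch$panel[s, ], ch$panel[s + 10, ], 10, ch$gmap)
    res <- advance(f1, breeding_scheme("pedigree", 200), m, ch$gmap,
                   keep_history = TRUE)
    h <- res$history
    pre <- h[h$stage == "pre-selection", ]
    post <- h[h$stage == "post-selection", ]
    expect_equal(nrow(pre), nrow(post))
    expect_true(all(post$gv_mean >= pre$gv_mean))
  }
})

test_that("selection response: selected descent beats unselected descent", {
  ch <- small_chain(n_qtn = 8, seed = 37)
  m <- fit_mas(ch$panel, ch$pheno, "E1", ch$qm, gv_floor = FALSE)
  sizes <- c(F1 = 5, F3 = 4, F4 = 4, F5 = 4, F6 = 4, F7 = 4)
  sel <- breeding_scheme("pedigree", f2_size = 60, gen_sizes = sizes)
  none <- breeding_scheme("pedigree", f2_size = 60, gen_sizes = sizes,
                          plan = list(F2 = c(af = 1, wf = 1)), id = "none")
  p1 <- ch$panel[2, ]; p2 <- ch$panel[9, ]
  diff_sel <- vapply(1:50, function(s) {
    set.seed(s)
    f1 <- cross(p1, p2, 5, ch$gmap)
    a <- advance(f1, sel, m, ch$gmap)
    set.seed(s)
    f1 <- cross(p1, p2, 5, ch$gmap)
    b <- advance(f1, none, m, ch$gmap)
    a$summary$gv_mean - b$summary$gv_mean
  }, numeric(1))
  expect_gt(mean(diff_sel), 0)
  expect_lt(stats::t.test(diff_sel, alternative = "greater")$p.value, 0.01)
})

test_that("noisy selection criteria weaken but do not break the response", {
  ch <- small_chain(n_qtn = 8, seed = 43)
  m <- fit_mas(ch$panel, ch$pheno, "E1", ch$qm, gv_floor = FALSE)
  p1 <- ch$panel[1, ]; p2 <- ch$panel[7, ]
  sch <- breeding_scheme("pedigree", 100,
                         gen_sizes = c(F1 = 5, F3 = 4, F4 = 4, F5 = 4,
                                       F6 = 4, F7 = 4))
  # h2 = 1 is exactly the deterministic criterion
  set.seed(12)
  a <- advance(cross(p1, p2, 5, ch$gmap), sch, m, ch$gmap)
  set.seed(12)
  b <- advance(cross(p1, p2, 5, ch$gmap), sch, m, ch$gmap, selection_h2 = 1)
  expect_equal(a$lines, b$lines)
  expect_error(advance(cross(p1, p2, 5, ch$gmap), sch, m, ch$gmap,
                       selection_h2 = 0), "selection_h2")
  # a low-heritability criterion gives a smaller mean response
  gain <- vapply(1:20, function(s) {
    set.seed(s)
    exact <- advance(cross(p1, p2, 5, ch$gmap), sch, m, ch$gmap)
    set.seed(s)
    noisy <- advance(cross(p1, p2, 5, ch$gmap), sch, m, ch$gmap,
                     selection_h2 = 0.05)
    exact$summary$gv_mean - noisy$summary$gv_mean
  }, numeric(1))
  expect_gt(mean(gain), 0)
})

test_that("progeny NSA maxima reach beyond parental maxima in aggregate", {
  ch <- small_chain(n_varieties = 30, seed = 47)
  m <- fit_mas(ch$panel, ch$pheno, "E1", ch$qm)
  crosses <- enumerate_crosses(rownames(ch$panel))$cross_id[1:100]
  res <- run_halfdiallel(ch$panel, list(breeding_scheme("bulk", 200)), m,
                         ch$gmap, seed = 4, crosses = crosses)
  parent_nsa <- nsa(ch$panel, m$superior)$nsa
  prog_max <- max(scheme_lines(res)$nsa)
  expect_gte(prog_max, max(parent_nsa))
})

test_that("half-diallel enumeration counts unordered pairs", {
  expect_equal(nrow(enumerate_crosses(c("a", "b"))), 1)
  expect_equal(nrow(enumerate_crosses(sprintf("V%02d", 1:10))), 45)
  cr <- enumerate_crosses(c("a", "b", "c"))
  expect_false(any(cr$parent1 == cr$parent2))       # no selfs
  expect_equal(anyDuplicated(cr$cross_id), 0L)      # no reciprocals
  expect_error(enumerate_crosses("a"), "2 parents")
})

test_that("pedigree terminal line count grows with the F2 size", {
  ch <- small_chain(seed = 53)
  m <- fit_mas(ch$panel, ch$pheno, "E1", ch$qm)
  counts <- vapply(c(200, 500, 800), function(f2) {
    set.seed(9)
    f1 <- cross(ch$panel[1, ], ch$panel[2, ], 10, ch$gmap)
    nrow(advance(f1, breeding_scheme("pedigree", f2), m, ch$gmap)$lines)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("subset runs reproduce the matching crosses of a full run", {
  ch <- small_chain(n_varieties = 6, n_qtn = 4, seed = 67)
  m <- toy_model(qtn_effects(ch$qm)[, "E1"], intercept = 8)
  schemes <- list(breeding_scheme("bulk", 200))
  full <- run_halfdiallel(ch$panel, schemes, m, ch$gmap, seed = 10)
  ids <- vapply(full, function(r) r$cross_id, character(1))
  pick <- ids[c(3, 7)]
  sub <- run_halfdiallel(ch$panel, schemes, m, ch$gmap, seed = 10,
                         crosses = pick)
  expect_equal(sub[[1]]$lines, full[[which(ids == pick[1])]]$lines)
  expect_equal(sub[[2]]$lines, full[[which(ids == pick[2])]]$lines)
  expect_error(run_halfdiallel(ch$panel, schemes, m, ch$gmap,
                               crosses = "nope/nope"), "unknown cross")
})

test_that("scheme results summarize their own lines", {
  ch <- small_chain(seed = 59)
  m <- fit_mas(ch$panel, ch$pheno, "E2", ch$qm)
  set.seed(1)
  f1 <- cross(ch$panel[3, ], ch$panel[4, ], 10, ch$gmap)
  res <- advance(f1, breeding_scheme("bulk", 200), m, ch$gmap)
  expect_equal(res$summary$n, nrow(res$lines))
  expect_equal(res$summary$gv_mean, mean(res$lines$gv))
  expect_equal(res$summary$nsa_max, max(res$lines$nsa))
  expect_equal(res$scheme_id, "Blk200")
})
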