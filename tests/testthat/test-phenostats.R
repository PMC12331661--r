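make_pheno <- function(values_by_env, block = "B1") {
  do.call(rbind, lapply(names(values_by_env), function(e) {
    v <- values_by_env[[e]]
    data.frame(environment = e, block = block,
               variety_id = sprintf("V%02d", seq_along(v)), value = v,
               stringsAsFactors = FALSE)
  }))
}

test_that("descriptives match hand-computed and degenerate cases", {
  ph <- make_pheno(list(A = c(0, 3, 6, 9), B = rep(5, 4)))
  d <- describe_pheno(ph)
  a <- d[d$environment == "A", ]
  expect_equal(a$mean, 4.5)
  expect_equal(a$sd, sqrt(15), tolerance = 1e-12)  # sample sd of 0,3,6,9
  expect_equal(a$range, 9)
  b <- d[d$environment == "B", ]
  expect_equal(b$sd, 0)
  expect_equal(b$cv_percent, 0)
  expect_equal(b$range, 0)
  expect_error(describe_pheno(make_pheno(list(A = 1))), "A")
})

test_that("coefficient of variation reproduces a mean-6.58/sd-5.89 series", {
  set.seed(1)
  x <- as.numeric(scale(rnorm(455))) * 5.89 + 6.58  # exact sample mean/sd
  ph <- make_pheno(list(E = x))
  d <- describe_pheno(ph)
  expect_equal(d$cv_percent, 100 * 5.89 / 6.58, tolerance = 1e-10)
  expect_equal(d$cv_percent, 89.62, tolerance = 0.2)  # printed-rounding slack
})

test_that("skewness/kurtosis use sample-adjusted estimators", {
  x <- c(1, 2, 2, 3, 3, 3, 9, 15)
  ph <- make_pheno(list(E = x))
  d <- describe_pheno(ph)
  expect_equal(d$skew, e1071::skewness(x, type = 2))
  expect_equal(d$kurt, e1071::kurtosis(x, type = 2))
})

test_that("balanced ANOVA agrees with aov() stratum by stratum", {
  ch <- small_chain(n_varieties = 12, n_qtn = 6, seed = 33)
  tab <- pheno_anova(ch$pheno)
  d <- ch$pheno
  d$environment <- factor(d$environment)
  d$block <- factor(d$block)
  d$variety_id <- factor(d$variety_id)
  fit <- stats::aov(value ~ environment + environment:block + variety_id +
                      environment:variety_id, data = d)
  ref <- summary(fit)[[1]]
  ref_ss <- stats::setNames(ref[["Sum Sq"]], trimws(rownames(ref)))
  expect_equal(tab$ss[tab$source == "Env"],
               ref_ss[["environment"]], tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Geno"],
               ref_ss[["variety_id"]], tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "BlockWithinEnv"],
               ref_ss[["environment:block"]], tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "GenoxEnv"],
               ref_ss[["environment:variety_id"]], tolerance = 1e-8)
  expect_equal(tab$ss[tab$source == "Error"],
               ref_ss[["Residuals"]], tolerance = 1e-8)
})

test_that("ANOVA table satisfies its structural invariants", {
  ch <- small_chain(seed = 55)
  tab <- pheno_anova(ch$pheno)
  non_total <- tab[tab$source != "Total", ]
  expect_equal(sum(non_total$ss), tab$ss[tab$source == "Total"],
               tolerance = 1e-8)
  expect_equal(sum(non_total$df), tab$df[tab$source == "Total"])
  expect_equal(non_total$ms, non_total$ss / non_total$df)
  expect_true(all(non_total$ss >= 0))
})

test_that("degenerate designs are rejected with the stratum named", {
  ch <- small_chain(n_varieties = 8, n_blocks = 1, seed = 20)
  expect_error(pheno_anova(ch$pheno), "block")
  ch2 <- small_chain(n_varieties = 8, seed = 21)
  drop_one <- ch2$pheno[-5, ]
  expect_error(pheno_anova(drop_one), "missing in environment")
  one_env <- ch2$pheno[ch2$pheno$environment == "E1", ]
  expect_error(pheno_anova(one_env), "environments")
})

test_that("null genotype effects give F(Geno) near 1 and nominal type-I rate", {
  qm <- gen_qtn_map(3, 2, envs = c("E1", "E2"), effect_sd = 0, seed = 1)
  n_sim <- 500
  rej <- logical(n_sim)
  fvals <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    panel <- gen_panel(20, qm, seed = s)
    truth <- simulation_truth(c(E1 = 0, E2 = 0), sigma2_G = 0,
                              sigma2_GE = 0, sigma2_e = 1, n_blocks = 2)
    tab <- pheno_anova(gen_phenotypes(panel, qm, truth, seed = 1000 + s))
    g <- tab[tab$source == "Geno", ]
    fvals[s] <- g$f
    rej[s] <- g$p < 0.05
  }
  expect_equal(mean(fvals), 1, tolerance = 0.1)
  # binomial band around 0.05: 25 +/- ~3 sd
  expect_gt(sum(rej), 25 - 15)
  expect_lt(sum(rej), 25 + 15)
})

test_that("variance components follow the expected-mean-square arithmetic", {
  tab <- data.frame(source = c("Geno", "GenoxEnv", "Error"),
                    df = c(454, 1705, 4318),
                    ss = c(245.538 * 454, 69.915 * 1705, 23.949 * 4318))
  tab <- anova_from_ss(tab)
  vc <- variance_components(tab, n_env = 5, n_blocks = 3)
  expect_equal(vc$sigma2_e, 23.949, tolerance = 1e-6)
  expect_equal(vc$sigma2_GE, (69.915 - 23.949) / 3, tolerance = 1e-6)
  expect_equal(vc$sigma2_G, (245.538 - 69.915) / 15, tolerance = 1e-6)
  # no-signal case: all mean squares equal
  flat <- anova_from_ss(data.frame(source = c("Geno", "GenoxEnv", "Error"),
                                   df = c(10, 20, 30),
                                   ss = c(50, 100, 150)))
  vc0 <- variance_components(flat, n_env = 3, n_blocks = 2)
  expect_equal(vc0$sigma2_G, 0)
  expect_equal(vc0$sigma2_GE, 0)
  expect_equal(vc0$h2, 0)
})

test_that("heritability formula handles boundary cases and is monotone", {
  expect_equal(round(heritability(12.421, 15.357, 23.949, 5, 3), 3), 0.727)
  expect_equal(heritability(3.7, 0, 0, 4, 2), 1.0)
  expect_equal(heritability(0, 1, 1, 5, 3), 0.0)
  expect_error(heritability(0, 0, 0, 5, 3), "zero")
  expect_error(heritability(-1, 1, 1, 5, 3), "non-negative")
  set.seed(99)
  for (i in 1:25) {
    g <- runif(1, 0.5, 20); ge <- runif(1, 0.5, 20); e <- runif(1, 0.5, 20)
    E <- sample(2:8, 1); R <- sample(2:5, 1)
    h <- heritability(g, ge, e, E, R)
    expect_true(h >= 0 && h <= 1)
    expect_gt(heritability(g + 1, ge, e, E, R), h)
    expect_gte(heritability(g, ge, e, E + 1, R), h)
    expect_gte(heritability(g, ge, e, E, R + 1), h)
    expect_lt(heritability(g, ge + 1, e, E, R), h)
    expect_lt(heritability(g, ge, e + 1, E, R), h)
  }
})
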