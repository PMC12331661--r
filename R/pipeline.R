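#' Load and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent R list) with top-level keys:
#' `seed`, `out_dir`, and either `simulate` (synthetic inputs) or `files`
#' (paths to `panel`, `pheno`, `qtn_map`); plus optional `mas`
#' (`gv_floor`), `breeding` (`n_crosses` or `crosses`, `f2_sizes`,
#' `environments`, `cM_per_Mb`, `n_f1`) and `selection` (`bin_width`,
#' `goals`). Unknown keys are rejected; referenced files must exist.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, c("seed", "out_dir", "simulate", "files", "mas",
                       "breeding", "selection"), "top level")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$simulate) && is.null(config$files)) {
    stop("config needs either a 'simulate' or a 'files' block")
  }
  if (!is.null(config$simulate)) {
    check_keys(config$simulate,
               c("n_varieties", "n_qtn", "n_chrom", "environments",
                 "effect_sd", "env_corr", "maf", "mu", "sigma2_G",
                 "sigma2_GE", "sigma2_e", "sigma2_block", "n_blocks"),
               "simulate")
  }
  if (!is.null(config$files)) {
    check_keys(config$files, c("panel", "pheno", "qtn_map"), "files")
    for (f in unlist(config$files)) {
      if (!file.exists(f)) stop("input file does not exist: ", f)
    }
  }
  if (!is.null(config$mas)) check_keys(config$mas, "gv_floor", "mas")
  if (!is.null(config$breeding)) {
    check_keys(config$breeding,
               c("n_crosses", "crosses", "f2_sizes", "environments",
                 "cM_per_Mb", "n_f1"), "breeding")
  }
  if (!is.null(config$selection)) {
    check_keys(config$selection, c("bin_width", "goals"), "selection")
  }
  structure(config, class = c("pipeline_config", "list"))
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation or loading; per-environment
#' descriptive statistics, ANOVA and variance components with heritability;
#' per-environment MAS model fits; half-diallel breeding simulation for the
#' configured schemes and target environments; and scheme selection by
#' top-two intervals and breeding-goal thresholds. All artifacts are written
#' under `out_dir` together with a `manifest.json` (inputs, seed, option
#' values, package version) that fully determines the outputs: two runs with
#' equal manifests produce identical files.
#'
#' @param config A [pipeline_config()], YAML path or list.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  log_stage <- function(...) message("[qtnbreed] ", ...)

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    log_stage("stage simulate")
    sim <- cfg$simulate
    envs <- as.character(sim$environments)
    qm <- gen_qtn_map(n_qtn = sim$n_qtn, n_chrom = sim$n_chrom %||% 20L,
                      envs = envs, effect_sd = sim$effect_sd %||% 1,
                      env_corr = sim$env_corr %||% 0.5, seed = seed)
    maf <- sim$maf %||% c(0.1, 0.5)
    panel <- gen_panel(sim$n_varieties, qm, maf[1], maf[2], seed = seed + 1L)
    mu <- sim$mu %||% rep(0, length(envs))
    truth <- simulation_truth(stats::setNames(as.numeric(mu), envs),
                              sigma2_G = sim$sigma2_G %||% 0,
                              sigma2_GE = sim$sigma2_GE %||% 0,
                              sigma2_e = sim$sigma2_e %||% 1,
                              sigma2_block = sim$sigma2_block %||% 0,
                              n_blocks = sim$n_blocks %||% 3L)
    pheno <- gen_phenotypes(panel, qm, truth, seed = seed + 2L)
    write_qtn_map(qm, file.path(out_dir, "qtn_map.tsv"))
    write_panel(panel, file.path(out_dir, "panel.csv"))
    write_pheno(pheno, file.path(out_dir, "pheno.csv"))
  } else {
    log_stage("stage load")
    qm <- read_qtn_map(cfg$files$qtn_map)
    panel <- read_panel(cfg$files$panel, qtn_map = qm)
    pheno <- read_pheno(cfg$files$pheno)
  }
  envs <- qtn_envs(qm)

  # --- phenotype statistics ----------------------------------------------
  log_stage("stage phenostats")
  desc <- describe_pheno(pheno)
  av <- pheno_anova(pheno)
  vc <- variance_components(av)
  write_tsv <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(round_df(desc, 4), "descriptives.tsv")
  write_tsv(round_df(as.data.frame(av), 4), "anova.tsv")
  write_tsv(round_df(data.frame(sigma2_G = vc$sigma2_G,
                                sigma2_GE = vc$sigma2_GE,
                                sigma2_e = vc$sigma2_e, n_env = vc$n_env,
                                n_blocks = vc$n_blocks, h2 = vc$h2), 4),
            "variance_components.tsv")

  # --- MAS models ---------------------------------------------------------
  log_stage("stage masmodel")
  gv_floor <- cfg$mas$gv_floor %||% TRUE
  models <- lapply(envs, function(e) {
    fit_mas(panel, pheno, e, qm, gv_floor = gv_floor)
  })
  names(models) <- envs
  for (e in envs) {
    write_mas_model(models[[e]], file.path(out_dir,
                                           sprintf("mas_model_%s.tsv", e)))
  }

  # --- breeding simulation ------------------------------------------------
  br <- cfg$breeding %||% list()
  gmap <- build_genetic_map(qm, cM_per_Mb = br$cM_per_Mb %||% 1.0)
  schemes <- default_schemes(f2_sizes = as.integer(br$f2_sizes %||%
                                                     c(200L, 500L, 800L)))
  cross_ids <- if (!is.null(br$crosses)) {
    as.character(br$crosses)
  } else {
    utils::head(enumerate_crosses(rownames(panel))$cross_id,
                br$n_crosses %||% 50L)
  }
  breed_envs <- as.character(br$environments %||% envs[1])
  sel <- cfg$selection %||% list()
  goals <- sel$goals %||% stats::setNames(rep(NA_real_, length(breed_envs)),
                                          breed_envs)
  results <- list()
  reports <- list()
  for (e in breed_envs) {
    log_stage("stage breedsim [", e, "]: ", length(cross_ids), " crosses x ",
              length(schemes), " schemes")
    res <- run_halfdiallel(panel, schemes, models[[e]], gmap, seed = seed,
                           crosses = cross_ids, n_f1 = br$n_f1 %||% 10L)
    results[[e]] <- res
    lines <- scheme_lines(res)
    lines$gv <- round(lines$gv, 6)
    write_tsv(lines, sprintf("scheme_lines_%s.tsv", e))
    write_tsv(round_df(summarize_schemes(res), 4),
              sprintf("scheme_summary_%s.tsv", e))

    log_stage("stage schemeselect [", e, "]")
    hist <- gv_histogram(res, bin_width = sel$bin_width %||% 3)
    top <- select_top_intervals(hist)
    rep_e <- list(environment = e, rule = top$rule,
                  bin_width = hist$bin_width, intervals = top$bins,
                  degenerate = top$degenerate, selected = top$selected)
    goal_e <- if (!is.null(names(goals))) goals[[e]] else goals[1]
    if (!is.null(goal_e) && is.finite(goal_e)) {
      gr <- apply_breeding_goal(res, goal_e)
      rep_e$goal <- goal_e
      rep_e$selected_over_goal <- gr$selected
    }
    reports[[e]] <- rep_e
  }
  jsonlite::write_json(reports, file.path(out_dir, "selection_report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)

  manifest <- list(package = "qtnbreed",
                   version = as.character(utils::packageVersion("qtnbreed")),
                   seed = seed,
                   config = unclass(cfg),
                   artifacts = sort(setdiff(list.files(out_dir),
                                            "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: ", length(manifest$artifacts), " artifacts in ", out_dir)
  invisible(list(qtn_map = qm, panel = panel, pheno = pheno,
                 descriptives = desc, anova = av, varcomp = vc,
                 models = models, results = results, reports = reports,
                 manifest = manifest))
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits)
  d
}
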