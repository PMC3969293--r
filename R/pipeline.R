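# End-to-end orchestration: simulate -> score -> prep -> twin fits ->
# sex-limitation -> GREML, from a single YAML (or list) configuration.

.default_config <- function() {
  list(
    seed = 1L,
    out_dir = "numbersense-run",
    sessions = list(n_subjects = 200, w_mean = 0.28, w_sd = 0.13,
                    n_trials = 150),
    twins = list(a2 = 0.32, c2 = 0, e2 = 0.68, rg_os = 0.5,
                 n_pairs_by_group = list(MZm = 317, MZf = 519, DZm = 281,
                                         DZf = 452, DZos = 689),
                 missing_rate = 0.13,
                 models = c("saturated", "ACE", "AE", "E")),
    # cutoff = Inf disables relatedness pruning: the conventional 0.025
    # threshold is calibrated to million-marker GRMs, and at desk-scale
    # SNP counts the GRM's sampling noise (sd ~ 1/sqrt(M)) overlaps it
    snps = list(n_individuals = 500, n_snps = 2000, h2_snp = 0,
                n_causal = 2000, cutoff = Inf)
  )
}

.known_keys <- list(
  top = c("seed", "out_dir", "sessions", "twins", "snps", "verbose"),
  sessions = c("n_subjects", "w_mean", "w_sd", "n_trials", "outlier_rate",
               "rt_location_ms", "rt_scale_ms"),
  twins = c("a2", "c2", "e2", "a2_m", "c2_m", "e2_m", "a2_f", "c2_f",
            "e2_f", "rg_os", "n_pairs_by_group", "missing_rate", "models"),
  snps = c("n_individuals", "n_snps", "h2_snp", "n_causal", "cutoff",
           "maf_range")
)

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns diagnostics rather than
#' throwing, and never touches the filesystem. Unknown keys are errors
#' (fail-fast against typos).
#'
#' @param config Configuration list (e.g. from [yaml::read_yaml()]).
#' @return Character vector of diagnostics; empty when valid.
#' @export
validate_config <- function(config) {
  diag <- character(0)
  if (!is.list(config)) return("config must be a list")
  unknown <- setdiff(names(config), .known_keys$top)
  if (length(unknown)) {
    diag <- c(diag, paste("unknown top-level keys:",
                          paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) {
    diag <- c(diag, "missing required field: seed")
  } else if (!is.numeric(config$seed) || config$seed < 0) {
    diag <- c(diag, "seed must be a non-negative integer")
  }
  if (is.null(config$out_dir)) {
    diag <- c(diag, "missing required field: out_dir")
  }
  for (block in c("sessions", "twins", "snps")) {
    if (is.null(config[[block]])) next
    unknown <- setdiff(names(config[[block]]), .known_keys[[block]])
    if (length(unknown)) {
      diag <- c(diag, sprintf("unknown keys in `%s`: %s", block,
                              paste(unknown, collapse = ", ")))
    }
  }
  tw <- config$twins
  if (!is.null(tw) && !is.null(tw$a2) && !is.null(tw$c2) &&
      !is.null(tw$e2) && abs(tw$a2 + tw$c2 + tw$e2 - 1) > 1e-9) {
    diag <- c(diag, "twins: a2 + c2 + e2 must sum to 1")
  }
  sn <- config$snps
  if (!is.null(sn) && !is.null(sn$h2_snp) &&
      (sn$h2_snp < 0 || sn$h2_snp > 1)) {
    diag <- c(diag, "snps: h2_snp must lie in [0,1]")
  }
  diag
}

.log_stage <- function(verbose, stage, seed, t0) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] stage=%s seed=%d elapsed=%.1fs",
                    format(Sys.time(), "%H:%M:%S"), stage, seed,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: session simulation and scoring, twin phenotype
#' simulation and preparation, descriptives, intraclass correlations,
#' univariate model fitting with selection, sex-limitation fitting, and
#' (unless the `snps` block is absent) GRM construction, relatedness
#' pruning and REML heritability. Per-stage TSV artifacts and a combined
#' machine-readable `summary.json` are written under `out_dir`.
#'
#' @param config Configuration list or path to a YAML file; see
#'   [validate_config()]. Missing blocks are skipped (and marked so in
#'   the summary); missing fields take defaults.
#' @return The summary list, invisibly.
#' @export
run_all <- function(config = .default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  diag <- validate_config(config)
  if (length(diag)) stop("invalid config:\n  ", paste(diag, collapse = "\n  "))
  def <- .default_config()
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  verbose <- isTRUE(config$verbose)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  summary <- list(seed = seed,
                  version = as.character(utils::packageVersion("numbersense")))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- sessions ----
  if (!is.null(config$sessions)) {
    summary <- run_stage("sessions", {
      sc <- utils::modifyList(def$sessions, config$sessions)
      spec <- task_sim_spec(w_mean = sc$w_mean, w_sd = sc$w_sd,
                            n_trials = sc$n_trials, seed = seed)
      pop <- simulate_population_sessions(spec, sc$n_subjects)
      scores <- score_subjects(pop$trials)
      write_trials_csv(pop$trials, file.path(out_dir, "trials.csv"))
      write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))
      write_truth_file(list(w_mean = sc$w_mean, w_sd = sc$w_sd, seed = seed),
                       file.path(out_dir, "sessions_truth.txt"))
      .log_stage(verbose, "sessions", seed, t0)
      summary$sessions <- list(
        n_subjects = sc$n_subjects,
        mean_accuracy = mean(scores$accuracy),
        mean_weber = mean(scores$weber),
        cor_accuracy_weber = stats::cor(scores$accuracy, scores$weber),
        cor_weber_truth = stats::cor(scores$weber, pop$truth$w_true))
      summary
    })
  } else summary$sessions <- "skipped"

  # ---- twins ----
  if (!is.null(config$twins)) {
    summary <- run_stage("twins", {
      tc <- utils::modifyList(def$twins, config$twins)
      npg <- unlist(tc$n_pairs_by_group)
      spec <- twin_sim_spec(
        a2_m = tc$a2_m %||% tc$a2, c2_m = tc$c2_m %||% tc$c2,
        e2_m = tc$e2_m %||% tc$e2,
        a2_f = tc$a2_f %||% tc$a2, c2_f = tc$c2_f %||% tc$c2,
        e2_f = tc$e2_f %||% tc$e2,
        rg_os = tc$rg_os, n_pairs_by_group = npg,
        missing_rate = tc$missing_rate, seed = seed + 1L)
      tw <- simulate_twin_dataset(spec)
      tw <- prepare_phenotype(tw, "pheno", transform = "none")
      write_pheno_tsv(tw, file.path(out_dir, "twins.tsv"))
      desc <- descriptives(tw, "pheno_resid", seed = seed)
      utils::write.table(desc$groups, file.path(out_dir, "descriptives.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      icc <- icc_by_zygosity(tw, "pheno_resid")
      utils::write.table(icc, file.path(out_dir, "icc.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      fits <- lapply(tc$models, function(m) {
        fit_twin_model(tw, m, pheno = "pheno_resid")
      })
      sel <- select_best(fits)
      utils::write.table(sel$table, file.path(out_dir, "model_fits.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      best_fit <- fits[[match(sel$best, vapply(fits, `[[`, "", "model"))]]
      est <- NULL
      if (sel$best %in% c("ACE", "AE")) {
        comps <- intersect(c("a2", "c2", "e2"),
                           if (sel$best == "AE") c("a2", "e2")
                           else c("a2", "c2", "e2"))
        est <- do.call(rbind, lapply(comps, function(cc) {
          ci <- profile_ci(best_fit, cc)
          data.frame(component = cc, estimate = ci$estimate,
                     ci_low = ci$low, ci_high = ci$high)
        }))
        utils::write.table(est, file.path(out_dir, "estimates.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      sexlim <- sexlim_decision(tw, "pheno_resid")
      utils::write.table(sexlim$table, file.path(out_dir, "sexlim.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      .log_stage(verbose, "twins", seed, t0)
      summary$twins <- list(
        icc = icc, model_table = sel$table, selected_model = sel$best,
        estimates = est,
        sexlim_selected = sexlim$selected, sexlim_verdict = sexlim$verdict)
      summary
    })
  } else summary$twins <- "skipped"

  # ---- snps / GREML ----
  if (!is.null(config$snps)) {
    summary <- run_stage("snps", {
      sn <- utils::modifyList(def$snps, config$snps)
      spec <- snp_sim_spec(n_individuals = sn$n_individuals,
                           n_snps = sn$n_snps, h2_snp = sn$h2_snp,
                           n_causal = sn$n_causal,
                           maf_range = unlist(sn$maf_range %||% c(0.05, 0.5)),
                           seed = seed + 2L)
      panel <- simulate_snp_panel(spec)
      write_plink(panel$genotypes, file.path(out_dir, "snps"),
                  phenotype = panel$phenotype)
      res <- greml_pipeline(panel$genotypes, panel$phenotype,
                            cutoff = sn$cutoff)
      grm_tab <- data.frame(h2_snp = res$h2_snp, se = res$se,
                            sigma_g2 = res$sigma_g2, sigma_e2 = res$sigma_e2,
                            n = res$n, n_removed = res$n_removed,
                            converged = res$converged)
      utils::write.table(grm_tab, file.path(out_dir, "greml.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      .log_stage(verbose, "greml", seed, t0)
      summary$greml <- as.list(grm_tab)
      summary
    })
  } else summary$greml <- "skipped"

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  invisible(summary)
}
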