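# End-to-end experiment orchestration: generate -> search -> retrain ->
# evaluate -> report, plus the seed- and data-sensitivity protocols and the
# paired statistical comparison used in the report tables.

#' Experiment configuration
#'
#' Assembles every parameter of a full experiment.  The defaults are the
#' full-scale study conditions (79-subject cohort at 256x256, search budget
#' 200 with 15 repeats); [smoke_experiment_config()] provides a desk-scale
#' preset.  All randomness flows from `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @param cohort List: `n_train`, `n_val`, `n_test`, `n_slices`, `size`.
#' @param space A [unet_space()].
#' @param search List: `budget`, `repeats`, `eps` (robustness-estimation
#'   FGSM magnitude), `metric`, `epochs`, `batch_size`, `lr`,
#'   `n_random_models` (size of the pure-random comparison pool).
#' @param training A [train_config()] for regular full-data training.
#' @param adversarial List: `p_r`, `eps` for the adversarially trained
#'   baseline.
#' @param report List: `eps` (FGSM magnitude of the report tables, default
#'   0.06), `n_corrections` (Bonferroni), `metric`.
#' @param sweep List: `enabled`, `fgsm_levels`, `gaussian_levels`.
#' @param baseline Genotype of the handcrafted comparison anchor.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              out_dir = "robunet-out",
                              cohort = list(n_train = 63L, n_val = 9L,
                                            n_test = 7L, n_slices = 182L,
                                            size = 256L),
                              space = unet_space(),
                              search = list(budget = 200L, repeats = 15L,
                                            eps = 0.2, metric = "dice_bone",
                                            epochs = 10L, batch_size = 6L,
                                            lr = 1e-4, n_random_models = 15L),
                              training = train_config(),
                              adversarial = list(p_r = 0.5, eps = 0.2),
                              report = list(eps = 0.06, n_corrections = 3L,
                                            metric = "dice_bone"),
                              sweep = list(enabled = TRUE,
                                           fgsm_levels = fgsm_grid(),
                                           gaussian_levels = gaussian_grid()),
                              baseline = baseline_genotype()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, cohort = cohort,
                 space = space, search = search, training = training,
                 adversarial = adversarial, report = report, sweep = sweep,
                 baseline = baseline),
            class = "experiment_config")
}

#' Desk-scale smoke preset of the experiment
#'
#' Eight subjects of 16 slices at 32x32, search budget 5 with 2 repeats,
#' a reduced candidate space (filters 8/16, depths 1-2), short training
#' runs and two-level sweeps - small enough to run end to end on one CPU
#' in minutes while exercising every stage.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
smoke_experiment_config <- function(out_dir = tempfile("robunet-smoke"),
                                    seed = 1L) {
  sp <- unet_space(filters = c(8L, 16L), depths = 1:2)
  experiment_config(
    seed = seed, out_dir = out_dir,
    cohort = list(n_train = 6L, n_val = 1L, n_test = 1L,
                  n_slices = 16L, size = 32L),
    space = sp,
    search = list(budget = 5L, repeats = 2L, eps = 0.2, metric = "dice_bone",
                  epochs = 3L, batch_size = 6L, lr = 3e-3,
                  n_random_models = 2L),
    training = train_config(epochs = 6L, batch_size = 6L, lr = 3e-3,
                            patience = 5L),
    report = list(eps = 0.06, n_corrections = 3L, metric = "dice_bone"),
    sweep = list(enabled = TRUE, fgsm_levels = c(0.1, 0.2),
                 gaussian_levels = c(0.1, 0.2)),
    baseline = baseline_genotype(depth = 2L, filters = 8L))
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields in the YAML override the defaults of
#' [experiment_config()]; the `space` and `baseline` entries are parsed
#' into their package objects.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- experiment_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) base[[nm]] <- upd[[nm]]
    base
  }
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$out_dir)) cfg$out_dir <- y$out_dir
  for (nm in c("cohort", "search", "report", "sweep", "adversarial")) {
    if (!is.null(y[[nm]])) cfg[[nm]] <- merge_into(cfg[[nm]], y[[nm]])
  }
  if (!is.null(y$space)) cfg$space <- do.call(unet_space, y$space)
  if (!is.null(y$training)) cfg$training <- do.call(train_config, y$training)
  if (!is.null(y$baseline)) cfg$baseline <- record_to_genotype(y$baseline)
  cfg
}

write_trials <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in result$trials) {
    rec <- list(trial = t$trial, objective = t$objective,
                diverged = t$diverged, seed = t$seed,
                epochs_run = t$epochs_run, best_epoch = t$best_epoch,
                genotype = genotype_to_record(t$genotype))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Paired statistical comparison of two models' metrics
#'
#' Paired Wilcoxon signed-rank test on per-subject metric vectors, with
#' Bonferroni adjustment (`adjusted_p = min(1, p * n_corrections)`; the
#' report tables use n = 3) and a significance flag at 0.05.  Identical
#' vectors have no nonzero signed ranks and score p = 1.  The exact null
#' distribution is used for n <= 25 pairs without ties.
#'
#' @param metrics_a,metrics_b Paired numeric vectors of equal length.
#' @param n_corrections Number of comparisons corrected for.
#' @return A list: `p_value`, `adjusted_p`, `significant`, `n`.
#' @export
compare_models <- function(metrics_a, metrics_b, n_corrections = 3L) {
  if (length(metrics_a) != length(metrics_b))
    stop("paired metric vectors must have equal length")
  d <- metrics_a - metrics_b
  if (all(d == 0)) {
    p <- 1
  } else {
    exact <- length(d) <= 25L && !any(d == 0) && !any(duplicated(abs(d[d != 0])))
    p <- suppressWarnings(
      stats::wilcox.test(metrics_a, metrics_b, paired = TRUE,
                         exact = exact)$p.value)
  }
  adjusted <- min(1, p * n_corrections)
  list(p_value = p, adjusted_p = adjusted,
       significant = adjusted < 0.05, n = length(metrics_a))
}

train_roster_model <- function(name, g, split, config, seed) {
  cfg <- config
  cfg$seed <- seed
  set.seed(seed)
  model <- build_model(g)
  fit <- train(model, split, cfg)
  list(name = name, genotype = g, fit = fit)
}

#' Run the full experiment
#'
#' Executes the pipeline end to end: synthetic cohort generation,
#' subdataset formation, random and TPE searches (each repeated), winner
#' selection by full-data retraining, training of the comparison roster
#' (Baseline, Baseline w/AT, Random, best-of-random-search, best-of-TPE),
#' clean and adversarial evaluation, paired significance tests against the
#' baseline, optional progressive corruption sweeps, and artifact writing
#' (trial logs as JSON-lines, genotypes as JSON, metrics and report tables
#' as CSV, a machine-readable `summary.json`).  Everything is seeded from
#' `config$seed`; re-running the same configuration reproduces the summary
#' bit-identically.
#'
#' @param config An [experiment_config()].
#' @return An object of class `robunet_experiment` (invisibly): models,
#'   metrics, report table, comparisons and artifact paths.
#' @export
run_experiment <- function(config = smoke_experiment_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  co <- config$cohort
  cohort <- generate_cohort(co$n_train, co$n_val, co$n_test,
                            n_slices = co$n_slices, size = co$size,
                            seed = seed)
  subdataset <- make_subdataset(cohort$train, seed = seed + 1L)
  sr <- config$search
  objective <- robustness_objective(subdataset, eps = sr$eps,
                                    metric = sr$metric, epochs = sr$epochs,
                                    batch_size = sr$batch_size, lr = sr$lr)
  run_method <- function(method, fun, seed_base) {
    repeats <- lapply(seq_len(sr$repeats), function(r) {
      res <- fun(config$space, sr$budget, objective,
                 seed = seed_base + r * 1000L)
      write_trials(res, file.path(config$out_dir,
                                  sprintf("trials_%s_rep%02d.jsonl", method, r)))
      res
    })
    best_genos <- lapply(repeats, function(res) res$best_genotype)
    sel <- select_best(best_genos, cohort, config$training,
                       eval_eps = config$report$eps,
                       metric = config$report$metric,
                       seed = seed_base + 500L)
    list(repeats = repeats, selection = sel)
  }
  random_out <- run_method("random", random_search, seed + 10000L)
  tpe_out <- run_method("tpe", tpe_search, seed + 20000L)

  # pure-random comparison pool: random genotypes trained on the full data
  rnd_genos <- lapply(seq_len(sr$n_random_models), function(i) {
    set.seed(seed + 30000L + i)
    sample_genotype(config$space)
  })
  rnd_sel <- select_best(rnd_genos, cohort, config$training,
                         eval_eps = config$report$eps,
                         metric = config$report$metric, seed = seed + 31000L)

  at_cfg <- config$training
  at_cfg$adversarial <- TRUE
  at_cfg$p_r <- config$adversarial$p_r
  at_cfg$eps <- config$adversarial$eps
  models <- list(
    baseline = train_roster_model("Baseline", config$baseline, cohort,
                                  config$training, seed + 40001L),
    baseline_at = local({
      m <- train_roster_model("Baseline w/AT", config$baseline, cohort,
                              at_cfg, seed + 40002L)
      m
    }),
    random = list(name = "Random", genotype = rnd_sel$genotype,
                  fit = rnd_sel$fit),
    search_random = list(name = "Search-R", genotype = random_out$selection$genotype,
                         fit = random_out$selection$fit),
    search_tpe = list(name = "Search-T", genotype = tpe_out$selection$genotype,
                      fit = tpe_out$selection$fit))

  metrics <- do.call(rbind, lapply(models, function(m) {
    clean <- evaluate_model(m$fit$model, cohort$test, condition_clean())
    rob <- evaluate_model(m$fit$model, cohort$test,
                          condition_fgsm(config$report$eps))
    out <- rbind(clean, rob)
    out$model <- m$name
    out
  }))
  rownames(metrics) <- NULL
  report_table <- summarize_by_model(metrics)

  # paired tests on robust bone Dice against the plain baseline
  rob_lab <- condition_label(condition_fgsm(config$report$eps))
  base_vec <- metric_vector(metrics, "Baseline", rob_lab, "bone", "dice")
  comparisons <- lapply(models[-1], function(m) {
    v <- metric_vector(metrics, m$name, rob_lab, "bone", "dice")
    c(list(model = m$name),
      compare_models(v, base_vec, config$report$n_corrections))
  })

  sweeps <- NULL
  if (isTRUE(config$sweep$enabled)) {
    sweeps <- do.call(rbind, lapply(models, function(m) {
      set.seed(seed + 50000L)
      fg <- corruption_sweep(m$fit$model, cohort$test, "fgsm",
                             config$sweep$fgsm_levels)
      set.seed(seed + 50001L)
      ga <- corruption_sweep(m$fit$model, cohort$test, "gaussian",
                             config$sweep$gaussian_levels)
      out <- rbind(fg, ga)
      out$model <- m$name
      out
    }))
    rownames(sweeps) <- NULL
    utils::write.csv(sweeps, file.path(config$out_dir, "sweeps.csv"),
                     row.names = FALSE)
    utils::write.csv(sweep_summary_by_model(sweeps),
                     file.path(config$out_dir, "sweeps_summary.csv"),
                     row.names = FALSE)
  }

  for (m in models) {
    write_genotype(m$genotype,
                   file.path(config$out_dir,
                             paste0("genotype_", gsub("[^A-Za-z]", "_", m$name),
                                    ".json")))
  }
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report_table, file.path(config$out_dir, "report_table.csv"),
                   row.names = FALSE)
  summary_obj <- list(
    seed = seed,
    n_images = as.list(n_images(cohort)),
    models = lapply(models, function(m) {
      list(name = m$name, genotype = genotype_to_record(m$genotype),
           epochs_run = m$fit$epochs_run, best_epoch = m$fit$best_epoch,
           best_val_loss = m$fit$best_val_loss)
    }),
    search = list(
      random = list(best_objectives = vapply(random_out$repeats,
        function(r) r$best_objective, numeric(1)),
        selection_scores = random_out$selection$scores),
      tpe = list(best_objectives = vapply(tpe_out$repeats,
        function(r) r$best_objective, numeric(1)),
        selection_scores = tpe_out$selection$scores)),
    report_table = report_table,
    comparisons = comparisons)
  jsonlite::write_json(summary_obj, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(structure(list(config = config, cohort = cohort, models = models,
                           metrics = metrics, report_table = report_table,
                           comparisons = comparisons, sweeps = sweeps,
                           out_dir = config$out_dir),
                      class = "robunet_experiment"))
}

metric_vector <- function(metrics, model, condition, region, measure) {
  sel <- metrics$model == model & metrics$condition == condition &
    metrics$region == region
  d <- metrics[sel, ]
  d <- d[order(d$subject_id), ]
  d[[measure]]
}

summarize_by_model <- function(metrics) {
  sp <- split(metrics, metrics$model)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    s <- summarize_metrics(sp[[nm]])
    s$model <- nm
    s
  }))
  rownames(out) <- NULL
  out[, c("model", setdiff(names(out), "model"))]
}

sweep_summary_by_model <- function(sweeps) {
  sp <- split(sweeps, sweeps$model)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    s <- sweep_summary(sp[[nm]])
    s$model <- nm
    s
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.robunet_experiment <- function(x, ...) {
  cat("robunet experiment (seed", x$config$seed, ")\n")
  cat("artifacts in:", x$out_dir, "\n")
  cat("report table (Dice, bone region):\n")
  rt <- x$report_table
  print(rt[rt$region == "bone",
           c("model", "condition", "dice_mean", "dice_sd", "mae_mean")],
        row.names = FALSE)
  invisible(x)
}

#' Seed- and data-sensitivity protocols
#'
#' `mode = "seeds"` retrains a fixed genotype under `n_seeds` different
#' weight initializations (the study protocol uses 11) and reports the
#' robustness distribution.  `mode = "data_folds"` splits the training
#' subjects uniformly into `n_folds` groups (8 in the study protocol) with
#' a fixed seed, rotates each group out as the early-stopping validation
#' set, trains on the rest, and evaluates every fold's model on the test
#' subjects.
#'
#' @param g The genotype under study (default: the shipped reference
#'   architecture via [searched_genotype()]).
#' @param split Full `cohort_split`.
#' @param mode `"seeds"` or `"data_folds"`.
#' @param n_seeds,n_folds Protocol sizes.
#' @param config A [train_config()].
#' @param eval_eps FGSM magnitude of the robustness evaluation.
#' @param seed Base seed.
#' @return An object of class `robunet_sensitivity`: per-run region
#'   metrics plus a mean/variance summary.
#' @export
sensitivity_study <- function(g = searched_genotype(), split,
                              mode = c("seeds", "data_folds"),
                              n_seeds = 11L, n_folds = 8L,
                              config = train_config(), eval_eps = 0.06,
                              seed = 1L) {
  mode <- match.arg(mode)
  runs <- list()
  if (mode == "seeds") {
    for (i in seq_len(n_seeds)) {
      cfg <- config; cfg$seed <- seed + i
      set.seed(seed + i)
      fit <- train(build_model(g), split, cfg)
      m <- evaluate_model(fit$model, split$test, condition_fgsm(eval_eps))
      m$run <- i
      runs[[i]] <- m
    }
  } else {
    n <- length(split$train)
    if (n < n_folds) stop("need at least n_folds training subjects")
    set.seed(seed)
    groups <- split(sample(seq_len(n)), rep_len(seq_len(n_folds), n))
    for (i in seq_len(n_folds)) {
      fold_split <- new_split(train = split$train[-groups[[i]]],
                              val = split$train[groups[[i]]],
                              test = split$test)
      cfg <- config; cfg$seed <- seed      # fixed seed across folds
      set.seed(seed)
      fit <- train(build_model(g), fold_split, cfg)
      m <- evaluate_model(fit$model, split$test, condition_fgsm(eval_eps))
      m$run <- i
      runs[[i]] <- m
    }
  }
  all <- do.call(rbind, runs)
  rownames(all) <- NULL
  per_region <- do.call(rbind, lapply(split(all, all$region), function(d) {
    data.frame(region = d$region[1],
               dice_mean = mean(d$dice), dice_var = stats::var(d$dice),
               mae_mean = mean(d$mae), mae_var = stats::var(d$mae),
               n_runs = length(unique(d$run)))
  }))
  rownames(per_region) <- NULL
  structure(list(mode = mode, metrics = all, summary = per_region,
                 genotype = g),
            class = "robunet_sensitivity")
}

#' @export
print.robunet_sensitivity <- function(x, ...) {
  cat(sprintf("sensitivity study (%s): %d runs\n", x$mode,
              max(x$metrics$run)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
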