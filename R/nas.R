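# Architecture search: robustness estimation on the subdataset, random
# search, and Tree-structured Parzen Estimator (TPE) search over the
# conditional categorical space.
#
# The TPE splits the trial history at the gamma-quantile of the objective
# into good and bad sets, fits smoothed categorical densities l (good) and
# g (bad) for every hyperparameter along the tree (depth at the root,
# per-position block fields conditional on the depth reaching that
# position, SE ratio conditional on the SE flag), draws candidates from l,
# and proposes the candidate maximizing the likelihood ratio l/g over its
# active parameters.  Free parameters (gamma, warm-up length, candidate
# draws, smoothing) are design choices exposed in tpe_config().

#' Robustness objective for one candidate architecture
#'
#' Builds the genotype's network (seeded initialization), runs the inner
#' training loop (10 epochs, per-epoch checkpoints, best-validation weights)
#' on the subdataset, perturbs the subdataset test slices with FGSM at
#' `eps`, and returns the evaluation metric averaged over the test
#' subjects.  The objective is oriented so that larger is better; MAE
#' metrics are negated on entry.  A diverging inner training scores the
#' worst possible value (`-Inf`) with a flag rather than aborting the
#' search.
#'
#' @param g A `unet_genotype`.
#' @param subdataset A `cohort_split` (train/val/test).
#' @param eps FGSM magnitude for robustness estimation (default 0.2).
#' @param metric Metric name `"<measure>_<region>"`, e.g. `"dice_bone"`
#'   (default: search selects on bone-region Dice) or `"mae_soft"`.
#' @param epochs,batch_size,lr Inner-training hyperparameters.
#' @param seed Seed controlling initialization and shuffling; identical
#'   (seed, genotype) pairs give identical objective values.
#' @return Scalar objective with attributes `diverged`, `epochs_run`,
#'   `best_epoch`.
#' @export
estimate_robustness <- function(g, subdataset, eps = 0.2, metric = "dice_bone",
                                epochs = 10L, batch_size = 6L, lr = 1e-4,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- build_model(g)
  fit <- tryCatch(
    nas_inner_train(model, subdataset, epochs = epochs,
                    batch_size = batch_size, lr = lr),
    robunet_divergence = function(e) NULL)
  if (is.null(fit)) {
    return(structure(-Inf, diverged = TRUE, epochs_run = NA_integer_,
                     best_epoch = NA_integer_))
  }
  value <- metric_value(fit$model, subdataset$test, eps, metric)
  structure(value, diverged = FALSE, epochs_run = fit$epochs_run,
            best_epoch = fit$best_epoch)
}

metric_value <- function(model, subjects, eps, metric) {
  parts <- strsplit(metric, "_", fixed = TRUE)[[1]]
  measure <- match.arg(parts[1], c("dice", "mae"))
  region <- match.arg(parts[2], c("whole", "air", "bone", "soft"))
  cond <- if (eps > 0) condition_fgsm(eps) else condition_clean()
  m <- evaluate_model(model, subjects, cond)
  v <- mean(m[[measure]][m$region == region])
  if (measure == "mae") -v else v
}

#' Objective factory for searches
#'
#' Wraps [estimate_robustness()] into the `function(genotype, seed)`
#' signature the search loops expect.
#'
#' @inheritParams estimate_robustness
#' @param subdataset A `cohort_split`.
#' @return A function `(g, seed) -> objective`.
#' @export
robustness_objective <- function(subdataset, eps = 0.2, metric = "dice_bone",
                                 epochs = 10L, batch_size = 6L, lr = 1e-4) {
  function(g, seed) {
    estimate_robustness(g, subdataset, eps = eps, metric = metric,
                        epochs = epochs, batch_size = batch_size, lr = lr,
                        seed = seed)
  }
}

new_trial <- function(index, g, value, seed) {
  list(trial = index, genotype = g, objective = as.numeric(value),
       diverged = isTRUE(attr(value, "diverged")),
       epochs_run = attr(value, "epochs_run"),
       best_epoch = attr(value, "best_epoch"), seed = seed)
}

new_nas_result <- function(trials, method, space) {
  obj <- vapply(trials, function(t) t$objective, numeric(1))
  best <- which.max(obj)
  structure(list(trials = trials, method = method, space = space,
                 best_index = best, best_objective = obj[best],
                 best_genotype = trials[[best]]$genotype),
            class = "nas_result")
}

#' @export
print.nas_result <- function(x, ...) {
  obj <- vapply(x$trials, function(t) t$objective, numeric(1))
  cat(sprintf("%s search: %d trials, best objective %.4f (trial %d)\n",
              x$method, length(x$trials), x$best_objective, x$best_index))
  cat("best genotype:\n")
  print(x$best_genotype)
  invisible(x)
}

#' @export
summary.nas_result <- function(object, ...) {
  obj <- vapply(object$trials, function(t) t$objective, numeric(1))
  data.frame(trial = seq_along(obj), objective = obj,
             running_best = cummax(ifelse(is.finite(obj), obj, -Inf)))
}

#' Random architecture search
#'
#' Evaluates `budget` independent uniform genotypes and records them in
#' trial order - the best-of-N reference strategy.
#'
#' @param space A `unet_space`.
#' @param budget Number of trials (N >= 1).
#' @param objective A function `(genotype, seed) -> numeric` (larger is
#'   better), e.g. from [robustness_objective()].
#' @param seed Seed for the whole search; trial `t` evaluates under
#'   `seed + t`.
#' @return A `nas_result` holding all trial records.
#' @export
random_search <- function(space, budget, objective, seed = 1L) {
  stopifnot(budget >= 1L)
  trials <- vector("list", budget)
  for (t in seq_len(budget)) {
    set.seed(seed + t)
    g <- sample_genotype(space)
    value <- objective(g, seed + t)
    trials[[t]] <- new_trial(t, g, value, seed + t)
  }
  new_nas_result(trials, "random", space)
}

#' TPE configuration
#'
#' @param gamma Quantile splitting the history into good/bad sets.
#' @param n_startup Number of uniform warm-up trials before the density
#'   model is used.
#' @param n_candidates Candidate genotypes drawn from the good density per
#'   suggestion.
#' @param prior_weight Total pseudo-count spread uniformly over each
#'   categorical domain (add-one-style smoothing keeping densities proper
#'   under degenerate splits).
#' @return A list of class `tpe_config`.
#' @export
tpe_config <- function(gamma = 0.25, n_startup = 20L, n_candidates = 24L,
                       prior_weight = 1) {
  stopifnot(gamma > 0, gamma < 1, n_startup >= 1L, n_candidates >= 1L,
            prior_weight > 0)
  structure(list(gamma = gamma, n_startup = as.integer(n_startup),
                 n_candidates = as.integer(n_candidates),
                 prior_weight = prior_weight),
            class = "tpe_config")
}

# Smoothed categorical probabilities over `domain` from observed values.
cat_density <- function(values, domain, prior_weight) {
  counts <- table(factor(values, levels = as.character(domain)))
  p <- (as.numeric(counts) + prior_weight / length(domain)) /
    (length(values) + prior_weight)
  names(p) <- as.character(domain)
  p
}

# Extract the flat named value of one variable from a genotype, or NA when
# the variable is inactive under the genotype's structure.
geno_var <- function(g, var) {
  if (var$name == "depth") return(as.character(g$depth))
  blocks <- if (var$side == "enc") g$encoders else g$decoders
  if (var$pos > g$depth) return(NA_character_)
  b <- blocks[[var$pos]]
  switch(var$field,
         pattern = as.character(b$pattern),
         filters = as.character(b$filters),
         se = as.character(b$se),
         se_ratio = if (b$se) as.character(b$se_ratio) else NA_character_)
}

tpe_variables <- function(space) {
  vars <- list(list(name = "depth", domain = space$depths))
  for (side in c("enc", "dec")) {
    for (pos in seq_len(max(space$depths))) {
      vars <- c(vars,
                list(list(name = sprintf("%s%d.pattern", side, pos),
                          side = side, pos = pos, field = "pattern",
                          domain = space$patterns),
                     list(name = sprintf("%s%d.filters", side, pos),
                          side = side, pos = pos, field = "filters",
                          domain = space$filters)))
      if (space$se_allowed) {
        vars <- c(vars,
                  list(list(name = sprintf("%s%d.se", side, pos),
                            side = side, pos = pos, field = "se",
                            domain = c(TRUE, FALSE)),
                       list(name = sprintf("%s%d.se_ratio", side, pos),
                            side = side, pos = pos, field = "se_ratio",
                            domain = space$se_ratios)))
      }
    }
  }
  vars
}

fit_tpe_densities <- function(history, space, config) {
  obj <- vapply(history, function(t) t$objective, numeric(1))
  n_good <- max(1L, ceiling(config$gamma * length(obj)))
  ord <- order(obj, decreasing = TRUE)
  good <- history[ord[seq_len(n_good)]]
  bad <- history[ord[-seq_len(n_good)]]
  if (length(bad) == 0) bad <- history   # degenerate split: g falls back
  vars <- tpe_variables(space)
  dens <- list()
  for (var in vars) {
    gv <- vapply(good, function(t) geno_var(t$genotype, var), character(1))
    bv <- vapply(bad, function(t) geno_var(t$genotype, var), character(1))
    dens[[var$name]] <- list(
      var = var,
      l = cat_density(gv[!is.na(gv)], var$domain, config$prior_weight),
      g = cat_density(bv[!is.na(bv)], var$domain, config$prior_weight))
  }
  dens
}

sample_from_density <- function(p, domain) {
  domain[sample.int(length(domain), 1L, prob = p)]
}

tpe_draw_candidate <- function(dens, space) {
  dd <- dens[["depth"]]
  depth <- as.integer(sample_from_density(dd$l, dd$var$domain))
  make_blocks <- function(side) {
    lapply(seq_len(depth), function(pos) {
      get <- function(field) dens[[sprintf("%s%d.%s", side, pos, field)]]
      pat <- as.integer(sample_from_density(get("pattern")$l, space$patterns))
      fil <- as.integer(sample_from_density(get("filters")$l, space$filters))
      se <- FALSE; ratio <- NULL
      if (space$se_allowed) {
        se <- as.logical(sample_from_density(get("se")$l, c(TRUE, FALSE)))
        if (se) ratio <- as.integer(sample_from_density(get("se_ratio")$l,
                                                        space$se_ratios))
      }
      block_config(pat, fil, se = se, se_ratio = ratio)
    })
  }
  genotype(make_blocks("enc"), make_blocks("dec"))
}

tpe_score <- function(g, dens) {
  score <- 0
  for (d in dens) {
    v <- geno_var(g, d$var)
    if (is.na(v)) next                     # inactive parameter: no term
    score <- score + log(d$l[[v]]) - log(d$g[[v]])
  }
  score
}

#' Suggest the next genotype from a TPE state
#'
#' With fewer than `n_startup` completed trials the suggestion is a uniform
#' random genotype; afterwards it is the best of `n_candidates` draws from
#' the good-density `l`, ranked by the likelihood ratio `l/g` over the
#' candidate's active parameters.  With all-equal objectives the split is
#' degenerate and the smoothed densities make the suggestion behave like
#' random search.
#'
#' @param history List of trial records (as inside a `nas_result`).
#' @param space A `unet_space`.
#' @param config A [tpe_config()].
#' @return A valid `unet_genotype`.
#' @export
tpe_suggest <- function(history, space, config = tpe_config()) {
  if (length(history) < config$n_startup) return(sample_genotype(space))
  finite <- Filter(function(t) is.finite(t$objective), history)
  if (length(finite) < 2L) return(sample_genotype(space))
  dens <- fit_tpe_densities(finite, space, config)
  cands <- lapply(seq_len(config$n_candidates),
                  function(i) tpe_draw_candidate(dens, space))
  scores <- vapply(cands, tpe_score, numeric(1), dens = dens)
  cands[[which.max(scores)]]
}

#' Tree-structured Parzen Estimator architecture search
#'
#' Iterates suggest -> evaluate -> record for `budget` trials.  The first
#' `n_startup` trials are uniform random, so with `budget <= n_startup` the
#' search is equivalent in distribution to [random_search()].
#'
#' @inheritParams random_search
#' @param config A [tpe_config()].
#' @return A `nas_result`.
#' @export
tpe_search <- function(space, budget, objective, seed = 1L,
                       config = tpe_config()) {
  stopifnot(budget >= 1L)
  trials <- list()
  for (t in seq_len(budget)) {
    set.seed(seed + t)
    g <- tpe_suggest(trials, space, config)
    value <- objective(g, seed + t)
    trials[[t]] <- new_trial(t, g, value, seed + t)
  }
  new_nas_result(trials, "tpe", space)
}

#' Select the best genotype across search repeats
#'
#' Retrains each repeat's best genotype on the full training split with
#' the regular strategy, evaluates its robustness on the held-out test
#' subjects (FGSM at `eval_eps`; the reporting tables use eps = 0.06 on
#' the bone region), and returns the arg-max.
#'
#' @param genotypes List of candidate genotypes (one per search repeat).
#' @param split Full `cohort_split` used for retraining and evaluation.
#' @param config A [train_config()] for the retraining runs.
#' @param eval_eps FGSM magnitude of the selection evaluation.
#' @param metric Selection metric (see [estimate_robustness()]).
#' @param seed Base seed; candidate i retrains under `seed + i`.
#' @return A list with `genotype` (the winner), `index`, `scores`, and
#'   `fit` (the winner's `trained_unet`).
#' @export
select_best <- function(genotypes, split, config = train_config(),
                        eval_eps = 0.06, metric = "dice_bone", seed = 1L) {
  stopifnot(length(genotypes) >= 1L)
  fits <- vector("list", length(genotypes))
  scores <- numeric(length(genotypes))
  for (i in seq_along(genotypes)) {
    cfg <- config
    cfg$seed <- seed + i
    set.seed(seed + i)
    model <- build_model(genotypes[[i]])
    fits[[i]] <- train(model, split, cfg)
    scores[i] <- metric_value(fits[[i]]$model, split$test, eval_eps, metric)
  }
  best <- which.max(scores)
  list(genotype = genotypes[[best]], index = best, scores = scores,
       fit = fits[[best]])
}

#' Hamming-style distance between genotypes / surrogate search objective
#'
#' `genotype_distance` counts field disagreements position by position
#' (pattern, filters, SE flag, and the ratio when both blocks enable SE);
#' positions present in only one genotype count fully, and a depth
#' difference adds the missing positions.  `hamming_objective(target)`
#' wraps the negated distance as a training-free surrogate objective for
#' benchmarking search strategies.
#'
#' @param a,b,target `unet_genotype`s.
#' @return `genotype_distance`: non-negative integer;
#'   `hamming_objective`: a function `(g, seed) -> numeric`.
#' @export
genotype_distance <- function(a, b) {
  fields_per_block <- 4L
  total <- abs(a$depth - b$depth) * 2L * fields_per_block
  for (side in c("encoders", "decoders")) {
    for (pos in seq_len(min(a$depth, b$depth))) {
      ba <- a[[side]][[pos]]; bb <- b[[side]][[pos]]
      total <- total + (ba$pattern != bb$pattern) + (ba$filters != bb$filters) +
        (ba$se != bb$se)
      if (ba$se && bb$se) total <- total + (ba$se_ratio != bb$se_ratio)
    }
  }
  total
}

#' @rdname genotype_distance
#' @export
hamming_objective <- function(target) {
  function(g, seed) -genotype_distance(g, target)
}
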