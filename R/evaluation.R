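# Evaluation designs: forward validation, accuracy/RRMSE with bootstrap,
# fixed-size generation-gap scenarios, GBM-importance preselection refits,
# and overlap analyses between models.

#' Forward-validation split by generation
#'
#' Older generations form the reference, the validation generation (default the
#' youngest, 11) the validation set. Animals missing the trait are excluded
#' from the relevant side.
#'
#' @param traits a trait table (data.frame with `animal_id` and `generation`).
#' @param trait trait column name.
#' @param validation_generation generation label used for validation.
#' @return list with `reference_ids` and `validation_ids`.
#' @export
forward_split <- function(traits, trait, validation_generation = 11) {
  stopifnot(all(c("animal_id", "generation") %in% names(traits)),
            trait %in% names(traits))
  if (!validation_generation %in% traits$generation) {
    stop("validation generation ", validation_generation, " absent from data")
  }
  obs <- !is.na(traits[[trait]])
  val <- traits$generation == validation_generation
  out <- list(reference_ids = traits$animal_id[obs & !val & traits$generation < validation_generation],
              validation_ids = traits$animal_id[obs & val])
  if (length(out$validation_ids) == 0) stop("empty validation set")
  out
}

#' Prediction accuracy (Pearson correlation)
#'
#' @param ystar validation precorrected phenotypes.
#' @param yhat predictions, same order.
#' @return the sample Pearson correlation.
#' @export
accuracy <- function(ystar, yhat) {
  stopifnot(length(ystar) == length(yhat))
  ok <- !is.na(ystar) & !is.na(yhat)
  if (sum(ok) < 3) stop("need at least 3 paired values")
  if (stats::sd(ystar[ok]) == 0 || stats::sd(yhat[ok]) == 0) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(ystar[ok], yhat[ok])
}

#' Bootstrap uncertainty for the accuracy
#'
#' Resamples animal (y*, y-hat) pairs with replacement.
#'
#' @param ystar,yhat paired vectors.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf percentile interval coverage (default 0.95).
#' @return list: `estimate`, `sd`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_ci <- function(ystar, yhat, n_boot = 1000, seed = 1, conf = 0.95) {
  est <- accuracy(ystar, yhat)
  n <- length(ystar)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(ystar[i]) == 0 || stats::sd(yhat[i]) == 0) return(NA_real_)
      stats::cor(ystar[i], yhat[i])
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    list(estimate = est, sd = stats::sd(reps), lower = qs[1], upper = qs[2],
         n_boot = n_boot)
  })
}

#' Relative root mean squared error
#'
#' `sqrt(mean((y* - yhat)^2)) / sigma_p`, where `sigma_p` is the trait's
#' phenotypic standard deviation (by package default, the SD of the
#' precorrected phenotype over the full dataset).
#'
#' @param ystar,yhat paired vectors.
#' @param sigma_p phenotypic SD (> 0).
#' @export
rrmse <- function(ystar, yhat, sigma_p) {
  stopifnot(length(ystar) == length(yhat))
  if (!is.finite(sigma_p) || sigma_p <= 0) stop("sigma_p must be positive")
  sqrt(mean((ystar - yhat)^2)) / sigma_p
}

#' Generation-gap scenario specification
#'
#' @param name scenario label (e.g. "NoGAP", "GAP9", "GAP89", "full").
#' @param reference_generations generation labels available for reference
#'   sampling.
#' @param validation_generation validation generation (default 11).
#' @param n_reference fixed reference sample size (default 300); `NA` means
#'   use all available reference animals (no sampling).
#' @param n_replicates replicate count (default 20).
#' @export
scenario_spec <- function(name, reference_generations,
                          validation_generation = 11, n_reference = 300,
                          n_replicates = 20) {
  structure(list(name = name,
                 reference_generations = reference_generations,
                 validation_generation = validation_generation,
                 n_reference = n_reference,
                 n_replicates = as.integer(n_replicates)),
            class = "scenario_spec")
}

#' Default gap scenarios (NoGAP, GAP9, GAP89)
#'
#' NoGAP uses generations 4-9 as the sampling pool, GAP9 omits generation 9,
#' GAP89 omits generations 8 and 9; all three sample a fixed-size reference
#' (default 300) and validate on generation 11.
#'
#' @param n_reference fixed reference sample size.
#' @param n_replicates replicate count.
#' @export
default_gap_scenarios <- function(n_reference = 300, n_replicates = 20) {
  list(scenario_spec("NoGAP", c(4, 5, 7, 8, 9), 11, n_reference, n_replicates),
       scenario_spec("GAP9", c(4, 5, 7, 8), 11, n_reference, n_replicates),
       scenario_spec("GAP89", c(4, 5, 7), 11, n_reference, n_replicates))
}

#' Per-generation reference quotas for a scenario
#'
#' Quotas are proportional to each generation's representation in the NoGAP
#' pool (available animals per generation among all pre-validation
#' generations), renormalized over the scenario's generations and rounded by
#' largest remainder to sum exactly to the reference size.
#'
#' @param traits trait table.
#' @param trait trait column (missing phenotypes are unavailable).
#' @param spec a `scenario_spec`.
#' @param nogap_generations the NoGAP pool (default: all generations below the
#'   validation generation present in the data).
#' @return named integer vector of quotas.
#' @export
scenario_quotas <- function(traits, trait, spec,
                            nogap_generations = NULL) {
  obs <- traits[!is.na(traits[[trait]]), ]
  if (is.null(nogap_generations)) {
    nogap_generations <- sort(unique(obs$generation[obs$generation <
                                                      spec$validation_generation]))
  }
  avail <- table(factor(obs$generation[obs$generation %in% nogap_generations],
                        levels = nogap_generations))
  w <- as.numeric(avail[as.character(spec$reference_generations)])
  names(w) <- as.character(spec$reference_generations)
  quota <- largest_remainder(w, spec$n_reference)
  short <- quota > w
  if (any(short)) {
    stop("sampling error: quota exceeds available animals in generation(s) ",
         paste(names(quota)[short], collapse = ", "))
  }
  quota
}

# Fit one model on a reference set and predict the validation set.
# Z: standardized genotypes over ref+val (linear models); X: raw dosages
# (GBM). Returns list(pred, scores) where scores rank SNPs (squared effects
# for linear models, importance for GBM).
.fit_predict <- function(model, ystar, ref_ids, val_ids, Z, X, G, cfg, seed) {
  switch(model,
    gblup = {
      keep <- c(ref_ids, val_ids)
      Gs <- structure(unclass(G)[keep, keep], class = class(G),
                      kind = attr(G, "kind"))
      fit <- fit_gblup(ystar, Gs, ref_ids, cfg %||% gblup_config(15000, 5000, 10),
                       seed = seed)
      eff <- backsolve_snp_effects(fit, Z[keep, , drop = FALSE], Gs)
      list(pred = predict(fit, val_ids), scores = eff^2, fit = fit)
    },
    bayesb = {
      fit <- fit_bayesb(ystar[ref_ids], Z[ref_ids, , drop = FALSE],
                        cfg %||% bayesb_config(15000, 5000, 10), seed = seed)
      list(pred = predict(fit, Z[val_ids, , drop = FALSE]),
           scores = fit$beta^2, fit = fit)
    },
    enet = {
      if (inherits(cfg, "enet_config")) {
        fit <- fit_enet(ystar[ref_ids], Z[ref_ids, , drop = FALSE], cfg)
      } else {
        fit <- tune_enet(ystar[ref_ids], Z[ref_ids, , drop = FALSE],
                         seed = seed)$fit
      }
      list(pred = predict(fit, Z[val_ids, , drop = FALSE]),
           scores = fit$beta^2, fit = fit)
    },
    gbm = {
      if (inherits(cfg, "gbm_config")) {
        fit <- fit_gbm(ystar[ref_ids], X[ref_ids, , drop = FALSE], cfg)
      } else {
        fit <- tune_gbm(ystar[ref_ids], X[ref_ids, , drop = FALSE],
                        seed = seed)$fit
      }
      imp <- feature_importance(fit)
      list(pred = predict(fit, X[val_ids, , drop = FALSE]),
           scores = attr(imp, "scores"), fit = fit)
    },
    stop("unknown model: ", model))
}

#' Run generation-gap scenarios
#'
#' For each scenario and replicate, draws a quota-constrained reference sample
#' (seeded), fits every requested model on that same sample, predicts the
#' validation generation, and records accuracy and RRMSE. Omitted generations
#' are omitted entirely (genotypes included): gap scenarios restrict the
#' sampling pool.
#'
#' @param sim a `sim_dataset` (or list with `panel` and `traits`).
#' @param trait trait column name (its `<trait>_star` precorrected column is
#'   created if missing).
#' @param models character vector among "gblup", "bayesb", "enet", "gbm".
#' @param scenarios list of `scenario_spec`s (default [default_gap_scenarios()]).
#' @param configs named list of per-model configs; an entry of `NULL` (or a
#'   missing entry) uses desk-scale defaults. Passing `"tune"` for enet/gbm
#'   runs the grid search per replicate.
#' @param seed integer base seed; replicate r uses `seed + r`.
#' @param sigma_p phenotypic SD for RRMSE (default: SD of the precorrected
#'   phenotype over the full dataset).
#' @return data.frame (scenario, replicate, model, n_reference, accuracy,
#'   rrmse) with a `summary` attribute of replicate means and SDs.
#' @export
run_gap_scenarios <- function(sim, trait = sim$trait_name,
                              models = c("gblup", "gbm"),
                              scenarios = default_gap_scenarios(),
                              configs = list(), seed = 1, sigma_p = NULL) {
  prep <- .prepare_eval_inputs(sim, trait)
  ystar <- prep$ystar
  if (is.null(sigma_p)) sigma_p <- stats::sd(ystar)
  rows <- list()
  samples <- list()
  for (spec in scenarios) {
    quota <- scenario_quotas(prep$traits, trait, spec)
    val_ids <- prep$traits$animal_id[prep$traits$generation ==
                                       spec$validation_generation &
                                       !is.na(prep$traits[[trait]])]
    pool <- split(prep$traits$animal_id[!is.na(prep$traits[[trait]])],
                  prep$traits$generation[!is.na(prep$traits[[trait]])])
    for (r in seq_len(spec$n_replicates)) {
      ref_ids <- with_seed(seed + r, {
        unlist(lapply(names(quota), function(g) {
          sample(pool[[g]], quota[[g]])
        }), use.names = FALSE)
      })
      samples[[spec$name]][[r]] <- ref_ids
      for (mod in models) {
        res <- .fit_predict(mod, ystar, ref_ids, val_ids, prep$Z, prep$X,
                            prep$G, configs[[mod]], seed = seed + r)
        rows[[length(rows) + 1]] <- data.frame(
          scenario = spec$name, replicate = r, model = mod,
          n_reference = length(ref_ids),
          accuracy = accuracy(ystar[val_ids], res$pred),
          rrmse = rrmse(ystar[val_ids], res$pred, sigma_p))
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(accuracy, rrmse) ~ scenario + model, out, mean)
  sds <- stats::aggregate(cbind(accuracy, rrmse) ~ scenario + model, out, stats::sd)
  names(agg)[3:4] <- c("mean_accuracy", "mean_rrmse")
  agg$sd_accuracy <- sds$accuracy
  agg$sd_rrmse <- sds$rrmse
  attr(out, "summary") <- agg
  attr(out, "samples") <- samples
  out
}

# Shared preparation: precorrected phenotype, complete panel, Z, G, X.
# SNPs fixed in the realised population are dropped (the MAF filter would
# remove them, and standardized codes are undefined for them).
.prepare_eval_inputs <- function(sim, trait) {
  traits <- sim$traits
  star_col <- paste0(trait, "_star")
  if (!star_col %in% names(traits)) {
    traits <- precorrect(traits, trait_names = trait)
  }
  panel <- impute_mean(sim$panel)
  p <- colMeans(panel$dosages) / 2
  if (any(p <= 0 | p >= 1)) {
    keep <- p > 0 & p < 1
    panel <- genotype_panel(panel$dosages[, keep, drop = FALSE],
                            panel$map[keep, , drop = FALSE])
  }
  X <- panel$dosages
  Z <- standardize_dosages(panel)
  G <- build_g_additive(panel)
  ystar <- stats::setNames(traits[[star_col]], traits$animal_id)
  list(traits = traits, panel = panel, X = X, Z = Z, G = G, ystar = ystar)
}

#' Preselect SNPs by GBM importance and refit downstream models
#'
#' Ranks SNPs by the feature importance of a GBM fitted inside the reference
#' set (seeded 80-20 internal split: the importance source is trained on the
#' 80% portion only), then, for each requested subset size, restricts the panel
#' to the top SNPs (or to all nonzero-importance SNPs when fewer are
#' available), rebuilds the predictor matrices and relationship matrix, refits
#' each downstream model on the full reference, and evaluates on the
#' validation generation.
#'
#' @param sim a `sim_dataset`.
#' @param trait trait column name.
#' @param subset_sizes requested top-SNP counts (default 100, 250, 500, 1000).
#' @param models downstream models (default gblup, enet, gbm; BayesB is
#'   deliberately excluded).
#' @param importance_cfg `gbm_config` for the importance source (default
#'   desk-scale [gbm_config()]), or `"tune"` for a grid search on the 80%.
#' @param configs named list of downstream model configs (as in
#'   [run_gap_scenarios()]).
#' @param include_all also evaluate the full panel ("SNPALL").
#' @param seed integer seed (internal split and model seeds).
#' @param sigma_p phenotypic SD for RRMSE (default: full-data SD of y*).
#' @return data.frame (subset, requested, resolved, model, accuracy, rrmse).
#' @export
preselect_and_refit <- function(sim, trait = sim$trait_name,
                                subset_sizes = c(100, 250, 500, 1000),
                                models = c("gblup", "enet", "gbm"),
                                importance_cfg = gbm_config(),
                                configs = list(), include_all = TRUE,
                                seed = 1, sigma_p = NULL) {
  if (any(subset_sizes < 2)) stop("subset sizes must be at least 2")
  prep <- .prepare_eval_inputs(sim, trait)
  ystar <- prep$ystar
  if (is.null(sigma_p)) sigma_p <- stats::sd(ystar)
  fs <- forward_split(prep$traits, trait)
  ref_ids <- fs$reference_ids
  val_ids <- fs$validation_ids

  sp <- split_80_20(ref_ids, seed = seed)
  if (identical(importance_cfg, "tune")) {
    src <- tune_gbm(ystar[sp$train], prep$X[sp$train, , drop = FALSE],
                    seed = seed)$fit
  } else {
    src <- fit_gbm(ystar[sp$train], prep$X[sp$train, , drop = FALSE],
                   importance_cfg)
  }
  imp <- feature_importance(src)
  n_nonzero <- sum(imp$importance_pct > 0)
  if (n_nonzero < 2) stop("importance source selected fewer than 2 SNPs")

  rows <- list()
  eval_subset <- function(label, requested, snp_ids) {
    panel_sub <- genotype_panel(
      prep$panel$dosages[, snp_ids, drop = FALSE],
      prep$panel$map[match(snp_ids, prep$panel$map$snp_id), , drop = FALSE])
    Zs <- standardize_dosages(panel_sub)
    Gs <- build_g_additive(panel_sub)
    Xs <- panel_sub$dosages
    for (mod in models) {
      res <- .fit_predict(mod, ystar, ref_ids, val_ids, Zs, Xs, Gs,
                          configs[[mod]], seed = seed)
      rows[[length(rows) + 1]] <<- data.frame(
        subset = label, requested = requested, resolved = length(snp_ids),
        model = mod,
        accuracy = accuracy(ystar[val_ids], res$pred),
        rrmse = rrmse(ystar[val_ids], res$pred, sigma_p))
    }
  }
  for (s in sort(unique(subset_sizes))) {
    k <- min(s, n_nonzero)
    top <- imp$snp_id[seq_len(k)]
    # panel order for the subset (map order must be preserved)
    top <- prep$panel$map$snp_id[prep$panel$map$snp_id %in% top]
    label <- if (k < s) sprintf("SNP%d(resolved %d)", s, k) else sprintf("SNP%d", s)
    eval_subset(label, s, top)
  }
  if (include_all) {
    eval_subset("SNPALL", ncol(prep$X), colnames(prep$X))
  }
  out <- do.call(rbind, rows)
  attr(out, "importance") <- imp
  attr(out, "n_nonzero") <- n_nonzero
  out
}

#' Overlap of top-ranked animals between models
#'
#' Takes each model's `K` highest-predicted animals (ties broken by animal id,
#' ascending) and returns all Venn-style region counts.
#'
#' @param predictions named list (one named prediction vector per model, all
#'   over the same validation animals).
#' @param K top-list size (default 20).
#' @return list with `top` (per-model id lists), `regions` (data.frame of
#'   exclusive region counts keyed by model combination), `pairwise`
#'   (intersection-count matrix), and `unique_counts` (animals exclusive to
#'   each model).
#' @export
top_animal_overlap <- function(predictions, K = 20) {
  stopifnot(is.list(predictions), length(predictions) >= 2)
  ids0 <- sort(names(predictions[[1]]))
  for (p in predictions) stopifnot(identical(sort(names(p)), ids0))
  if (K > length(ids0)) stop("K exceeds the validation set size")
  top <- lapply(predictions, function(p) {
    ord <- order(-p, names(p))
    names(p)[ord][seq_len(K)]
  })
  models <- names(top)
  union_ids <- unique(unlist(top))
  membership <- vapply(top, function(t) union_ids %in% t,
                       logical(length(union_ids)))
  membership <- matrix(membership, nrow = length(union_ids),
                       dimnames = list(union_ids, models))
  key <- apply(membership, 1, function(r) paste(models[r], collapse = "&"))
  regions <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(regions) <- c("models", "count")
  pairwise <- matrix(0L, length(models), length(models),
                     dimnames = list(models, models))
  for (a in models) for (b in models) {
    pairwise[a, b] <- length(intersect(top[[a]], top[[b]]))
  }
  uniq <- vapply(models, function(mod) {
    sum(membership[, mod] & rowSums(membership) == 1)
  }, integer(1))
  list(top = top, regions = regions, pairwise = pairwise, unique_counts = uniq,
       K = K)
}

#' Overlap of top-ranked SNPs between models, with LD relaxation
#'
#' For an ordered model pair (A, B), counts how many of A's top-`K` SNPs are
#' identical to, or in high LD (r-squared above `r2_threshold`) with, at least
#' one of B's top-`K` SNPs. LD is computed on the supplied panel (reference
#' plus validation animals). Both directions are reported; a model with fewer
#' than `K` scored SNPs contributes all of them (labelled via `k_a`/`k_b`).
#'
#' @param scores named list of per-SNP ranking scores (squared effects for
#'   linear models, importance for GBM), named by SNP id.
#' @param panel a complete `genotype_panel` covering the scored SNPs.
#' @param K top-list size (default 1000).
#' @param r2_threshold LD threshold (default 0.90).
#' @return data.frame (model_a, model_b, k_a, k_b, overlap, r2_threshold) over
#'   all ordered pairs, including self-pairs.
#' @export
snp_rank_overlap <- function(scores, panel, K = 1000, r2_threshold = 0.90) {
  stopifnot(is.list(scores), length(scores) >= 1,
            inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  if (anyNA(dos)) stop("panel must be complete; run impute_mean() first")
  top <- lapply(scores, function(s) {
    stopifnot(!is.null(names(s)))
    ord <- order(-s, names(s))
    names(s)[ord][seq_len(min(K, length(s)))]
  })
  models <- names(top)
  out <- list()
  for (a in models) for (b in models) {
    ta <- top[[a]]; tb <- top[[b]]
    if (a == b) {
      ov <- length(ta)
    } else {
      shared <- ta %in% tb
      rest <- ta[!shared]
      ov <- sum(shared)
      if (length(rest) && length(tb)) {
        Ca <- dos[, rest, drop = FALSE]
        Cb <- dos[, tb, drop = FALSE]
        r <- suppressWarnings(stats::cor(Ca, Cb))
        hit <- apply(r^2 > r2_threshold, 1, any, na.rm = TRUE)
        ov <- ov + sum(hit)
      }
    }
    out[[length(out) + 1]] <- data.frame(model_a = a, model_b = b,
                                         k_a = length(ta), k_b = length(tb),
                                         overlap = ov,
                                         r2_threshold = r2_threshold)
  }
  do.call(rbind, out)
}

#' Write an evaluation report to disk
#'
#' Emits stable-schema CSV tables for whichever result slices are supplied,
#' plus a JSON dump of all slices and a manifest (seeds, configs, thresholds).
#' Re-running with identical inputs produces byte-identical files (no
#' timestamps).
#'
#' @param slices named list; recognised names: `accuracy`, `scenarios`,
#'   `preselection`, `overlap_animals`, `overlap_snps` (data.frames), plus
#'   `manifest` (list of run metadata).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
report <- function(slices, dir) {
  stopifnot(is.list(slices), length(slices) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tables <- c(accuracy = "results.csv", scenarios = "scenarios.csv",
              preselection = "preselection.csv",
              overlap_animals = "overlap_animals.csv",
              overlap_snps = "overlap_snps.csv")
  for (nm in names(tables)) {
    if (!is.null(slices[[nm]])) {
      f <- file.path(dir, tables[[nm]])
      utils::write.csv(slices[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  json_slices <- slices[!vapply(slices, is.null, logical(1))]
  f <- file.path(dir, "results.json")
  jsonlite::write_json(json_slices, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  files <- c(files, f)
  manifest <- slices$manifest %||% list()
  manifest$package <- "gpbench"
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
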