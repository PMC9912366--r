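# Gradient-boosted edge classifier: combines per-edge evidence scores into
# the probability that the edge would be supported by a binding experiment.
# Three training regimes: generalization (cross-validated by TF, to score
# TFs without binding data), integration (per-TF/group overfit models scored
# on their own training edges, fusing labels and features into a consensus),
# and cross-trained (fit on one dataset's features, applied to another's).

#' Default hyperparameter grid for combiner tuning
#'
#' Tree depth x learning rate x boosting rounds; minimum child weight 1 and
#' no subsampling throughout. The grid is searched by inner cross-validation
#' maximizing AUPRC.
#'
#' @return Data frame with columns `max_depth`, `eta`, `nrounds`,
#'   `min_child_weight`, `subsample`.
#' @export
default_hyper_grid <- function() {
  g <- expand.grid(max_depth = c(2L, 4L, 6L),
                   eta = c(0.05, 0.1, 0.3),
                   nrounds = c(50L, 200L, 500L),
                   KEEP.OUT.ATTRS = FALSE)
  g$min_child_weight <- 1
  g$subsample <- 1
  g
}

#' Hyperparameters for the intentional-overfit (integration) profile
#'
#' Deep trees, high learning rate, many rounds, no subsampling: integration
#' mode deliberately overfits the binding labels so that they dominate the
#' fused score wherever the expression features allow it.
#'
#' @return One-row data frame in the same layout as [default_hyper_grid()].
#' @export
overfit_profile <- function() {
  data.frame(max_depth = 10L, eta = 0.3, nrounds = 1000L,
             min_child_weight = 1, subsample = 1)
}

# Internal: fit one booster. `x` numeric matrix (NA = missing), `y` 0/1.
fit_booster <- function(x, y, hp, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "binary:logistic",
                 max_depth = hp$max_depth, eta = hp$eta,
                 min_child_weight = hp$min_child_weight,
                 subsample = hp$subsample,
                 nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dm, nrounds = hp$nrounds,
                     verbose = 0)
}

feature_matrix <- function(features, cols = feature_names(features)) {
  as.matrix(features[, cols, drop = FALSE])
}

labeled_rows <- function(features) !is.na(features$label)

# Per-TF positive label counts from a feature table's labeled rows.
tf_positive_counts <- function(features) {
  lab <- features[labeled_rows(features), , drop = FALSE]
  vapply(split(lab$label, lab$tf), sum, numeric(1))
}

# Stratified round-robin fold assignment from named positive counts.
folds_from_counts <- function(counts, k, seed) {
  if (length(counts) < k) {
    stop_tfmapr(sprintf("cannot make %d folds from %d labeled TFs", k,
                        length(counts)))
  }
  breaks <- unique(stats::quantile(counts, probs = c(0, 0.25, 0.5, 0.75, 1)))
  strata <- if (length(breaks) > 1L) {
    cut(counts, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(counts))
  fold <- stats::setNames(integer(length(counts)), names(counts))
  with_local_seed(seed, {
    start <- 0L
    for (s in sort(unique(strata))) {
      tfs <- sort(names(counts)[strata == s])
      tfs <- sample(tfs)
      # staggered round-robin so small strata do not all land in fold 1
      fold[tfs] <- ((start + seq_along(tfs) - 1L) %% k) + 1L
      start <- start + length(tfs)
    }
  })
  structure(fold, seed = seed, k = k, class = "fold_plan")
}

#' Assign labeled TFs to cross-validation folds, stratified by positive count
#'
#' TFs are binned into quartile strata of their number of positively labeled
#' targets; within each stratum they are shuffled (seeded) and dealt
#' round-robin into the K folds, so per-stratum fold sizes differ by at most
#' one.
#'
#' @param labels A binary network (or a feature table with labels).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector TF -> fold in 1..K, class `"fold_plan"`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  counts <- if (inherits(labels, "binary_network")) {
    apply(labels, 1L, function(r) sum(r == 1, na.rm = TRUE))
  } else if (inherits(labels, "feature_table")) {
    tf_positive_counts(labels)
  } else stop_tfmapr("labels must be a binary network or feature table")
  folds_from_counts(counts, k, seed)
}

#' Tune combiner hyperparameters by inner cross-validation over TFs
#'
#' Evaluates every grid point with `inner_k`-fold CV (folds split by TF, same
#' stratified scheme as the outer folds) and returns the row maximizing the
#' mean held-out AUPRC. Ties are broken by grid order.
#'
#' @param features A feature table; only labeled rows are used.
#' @param grid Hyperparameter data frame (see [default_hyper_grid()]).
#' @param inner_k Inner folds (default 5).
#' @param seed Integer seed.
#' @return One-row data frame from `grid`, with attribute `"inner_auprc"`.
#' @export
tune_hyperparameters <- function(features, grid = default_hyper_grid(),
                                 inner_k = 5L, seed = 1L) {
  lab <- features[labeled_rows(features), , drop = FALSE]
  if (length(unique(lab$label)) < 2L) {
    stop_tfmapr("cannot tune on degenerate labels (all 0 or all 1)")
  }
  if (nrow(grid) == 1L) return(grid)
  counts <- tf_positive_counts(features)
  fold <- folds_from_counts(counts, inner_k, seed)
  x <- feature_matrix(lab)
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hp <- grid[gi, , drop = FALSE]
    aps <- numeric(inner_k)
    for (f in seq_len(inner_k)) {
      test_tfs <- names(fold)[fold == f]
      te <- lab$tf %in% test_tfs
      if (length(unique(lab$label[!te])) < 2L || !any(te) ||
          length(unique(lab$label[te])) < 2L) {
        aps[f] <- NA_real_
        next
      }
      booster <- fit_booster(x[!te, , drop = FALSE], lab$label[!te], hp,
                             derive_seed(seed, gi * 100L + f))
      pred <- predict(booster, xgboost::xgb.DMatrix(x[te, , drop = FALSE],
                                                    nthread = 1))
      aps[f] <- auprc(pred, lab$label[te])
    }
    scores[gi] <- mean(aps, na.rm = TRUE)
  }
  best <- which(scores == max(scores))[1L]
  out <- grid[best, , drop = FALSE]
  attr(out, "inner_auprc") <- scores[best]
  out
}

#' Train the gradient-boosted edge combiner
#'
#' Fits a boosted-tree logistic classifier on the labeled rows of a feature
#' table. Missing evidence scores (`NA`) are handled natively by the trees'
#' default split directions. No class reweighting is applied, so predicted
#' probabilities stay calibrated against the label base rate.
#'
#' @param features A feature table with >= 1 positive and >= 1 negative
#'   labeled row.
#' @param hyperparameters One-row data frame (grid row or
#'   [overfit_profile()]).
#' @param seed Integer seed.
#' @return A `"tf_combiner"` model object.
#' @export
train_combiner <- function(features, hyperparameters = default_hyper_grid()[1L, ],
                           seed = 1L) {
  lab <- features[labeled_rows(features), , drop = FALSE]
  if (nrow(lab) == 0L || length(unique(lab$label)) < 2L) {
    stop_tfmapr("training needs at least one positive and one negative label")
  }
  booster <- fit_booster(feature_matrix(lab), lab$label,
                         hyperparameters, seed)
  structure(list(booster = booster,
                 feature_names = feature_names(features),
                 training_tfs = sort(unique(lab$tf)),
                 hyperparameters = hyperparameters,
                 seed = seed),
            class = "tf_combiner")
}

#' @export
print.tf_combiner <- function(x, ...) {
  cat(sprintf("boosted edge combiner: %d features (%s); trained on %d TFs\n",
              length(x$feature_names),
              paste(x$feature_names, collapse = ", "),
              length(x$training_tfs)))
  invisible(x)
}

#' Persist a trained combiner to disk
#'
#' Writes the booster in the library's portable UBJSON format next to a JSON
#' manifest (format version, feature names, training TFs, hyperparameters,
#' seed), so saved models remain inspectable and transferable across
#' machines — e.g. to score a new organism's features with a model trained
#' elsewhere.
#'
#' @param model A `"tf_combiner"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_combiner <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  meta <- list(format_version = 1L,
               feature_names = model$feature_names,
               training_tfs = model$training_tfs,
               hyperparameters = as.list(model$hyperparameters),
               seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a combiner saved by [save_combiner()]
#' @param dir Directory written by [save_combiner()].
#' @return A `"tf_combiner"`.
#' @export
load_combiner <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), 1L)) {
    stop_tfmapr("unsupported combiner format version: ", meta$format_version)
  }
  structure(list(booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
                 feature_names = meta$feature_names,
                 training_tfs = meta$training_tfs,
                 hyperparameters = as.data.frame(meta$hyperparameters),
                 seed = meta$seed),
            class = "tf_combiner")
}

#' Predict edge probabilities with a trained combiner
#'
#' @param object A `"tf_combiner"`.
#' @param features A feature table whose feature columns match the model's.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict.tf_combiner <- function(object, features, ...) {
  have <- feature_names(features)
  if (!identical(have, object$feature_names)) {
    offending <- c(setdiff(object$feature_names, have),
                   setdiff(have, object$feature_names))
    stop_tfmapr("feature columns do not match the trained model: ",
                paste(unique(offending), collapse = ", "))
  }
  dm <- xgboost::xgb.DMatrix(feature_matrix(features, object$feature_names),
                             nthread = 1)
  predict(object$booster, dm)
}

# Fill a TFs x genes weighted network from per-row predictions.
predictions_to_network <- function(features, pred, tfs = NULL, genes = NULL) {
  tfs <- tfs %||% sort(unique(features$tf))
  genes <- genes %||% sort(unique(features$gene))
  m <- matrix(NA_real_, length(tfs), length(genes), dimnames = list(tfs, genes))
  keep <- features$tf %in% tfs & features$gene %in% genes
  m[cbind(features$tf[keep], features$gene[keep])] <- pred[keep]
  weighted_network(m)
}

#' Generalization mode: out-of-fold predictions by TF-wise cross-validation
#'
#' For each seed, labeled TFs are dealt into `k` stratified folds; per fold,
#' hyperparameters are tuned by inner CV on the training fold, a model is
#' trained on the training fold, and the held-out TFs' edges are scored by
#' that model — so no TF's predictions ever come from a model that saw its
#' labels. Edges of unlabeled TFs are scored by the average of the fold
#' models.
#'
#' @param features A feature table with labels for >= `k` TFs.
#' @param k Outer folds (default 10).
#' @param seeds Integer vector of fold-assignment seeds (default 1:20).
#' @param grid Hyperparameter grid for inner tuning.
#' @param inner_k Inner folds (default 5).
#' @return List: `mean` and `sd` weighted networks across seeds, `per_seed`
#'   (list of per-seed networks), and `audit` — per seed, the fold plan and
#'   each fold's training-TF set, for fold-purity checks.
#' @export
run_generalization <- function(features, k = 10L, seeds = 1:20,
                               grid = default_hyper_grid(), inner_k = 5L) {
  tfs <- sort(unique(features$tf))
  genes <- sort(unique(features$gene))
  per_seed <- vector("list", length(seeds))
  audit <- vector("list", length(seeds))
  counts <- tf_positive_counts(features)
  unlabeled <- setdiff(tfs, names(counts))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    fold <- folds_from_counts(counts, k, seed)
    m <- matrix(NA_real_, length(tfs), length(genes),
                dimnames = list(tfs, genes))
    unl_acc <- NULL
    train_sets <- vector("list", k)
    for (f in seq_len(k)) {
      test_tfs <- names(fold)[fold == f]
      train_tfs <- setdiff(names(fold), test_tfs)
      train_sets[[f]] <- train_tfs
      tr <- features[features$tf %in% train_tfs, , drop = FALSE]
      hp <- tune_hyperparameters(tr, grid, inner_k,
                                 seed = derive_seed(seed, f))
      model <- train_combiner(tr, hp, seed = derive_seed(seed, 1000L + f))
      te <- features[features$tf %in% test_tfs, , drop = FALSE]
      if (nrow(te) > 0) {
        pred <- predict(model, te)
        m[cbind(te$tf, te$gene)] <- pred
      }
      if (length(unlabeled) > 0) {
        un <- features[features$tf %in% unlabeled, , drop = FALSE]
        pu <- predict(model, un)
        unl_acc <- if (is.null(unl_acc)) pu else unl_acc + pu
        if (f == k) m[cbind(un$tf, un$gene)] <- unl_acc / k
      }
    }
    per_seed[[si]] <- weighted_network(m)
    audit[[si]] <- list(fold_plan = fold, training_tfs = train_sets)
  }
  stack <- simplify2array(lapply(per_seed, unclass))
  mean_net <- weighted_network(apply(stack, c(1, 2), mean))
  sd_net <- if (length(seeds) > 1L) {
    weighted_network(apply(stack, c(1, 2), stats::sd))
  } else NULL
  list(mean = mean_net, sd = sd_net, per_seed = per_seed, audit = audit)
}

#' Integration mode: per-TF (or per-group) overfit models scored on their own
#' training edges
#'
#' TFs are partitioned into groups of `group_size` (seeded random grouping;
#' `"all"` puts every TF in one group). For each group an overfit-profile
#' model is trained on the group's labeled edges and used to score those same
#' edges; per-group predictions are concatenated into one network. The
#' result is a consensus that fuses binding labels (via intentional overfit)
#' with expression features.
#'
#' @param features A feature table in which every TF has labels.
#' @param group_size 1, 2, 5, ... or `"all"`.
#' @param hyperparameters Default [overfit_profile()].
#' @param seed Integer seed (grouping and training).
#' @return A weighted network of fused scores.
#' @export
run_integration <- function(features, group_size = 1L,
                            hyperparameters = overfit_profile(), seed = 1L) {
  tfs <- sort(unique(features$tf))
  labeled <- sort(unique(features$tf[labeled_rows(features)]))
  missing <- setdiff(tfs, labeled)
  if (length(missing) > 0) {
    stop_tfmapr("TF(s) without binding labels: ",
                paste(utils::head(missing, 3), collapse = ", "),
                "; use generalization mode to score unlabeled TFs")
  }
  groups <- if (identical(group_size, "all")) {
    list(tfs)
  } else {
    shuffled <- with_local_seed(seed, sample(tfs))
    split(shuffled, ceiling(seq_along(shuffled) / group_size))
  }
  genes <- sort(unique(features$gene))
  m <- matrix(NA_real_, length(tfs), length(genes), dimnames = list(tfs, genes))
  for (gi in seq_along(groups)) {
    rows <- features[features$tf %in% groups[[gi]], , drop = FALSE]
    lab <- rows$label[labeled_rows(rows)]
    if (length(unique(lab)) < 2L) {
      # a group whose labels are single-class cannot be fit by logistic
      # boosting; its consensus degenerates to the constant label
      warning("single-class label group (TFs: ",
              paste(groups[[gi]], collapse = ", "),
              "); emitting constant prediction", call. = FALSE)
      pred <- rep(unique(lab)[1L], nrow(rows))
    } else {
      model <- train_combiner(rows, hyperparameters,
                              seed = derive_seed(seed, gi))
      pred <- predict(model, rows)
    }
    m[cbind(rows$tf, rows$gene)] <- pred
  }
  weighted_network(m)
}

#' Cross-trained mode: fit on one dataset's features, score another's
#'
#' A single model is trained on all labeled edges of dataset A and applied
#' to every edge of dataset B. Feature column names must align (the same
#' evidence-score roles in both datasets).
#'
#' @param features_a Feature table with labels (training).
#' @param features_b Feature table to score; columns must match A's.
#' @param hyperparameters One-row grid data frame, or NULL to tune on A.
#' @param seed Integer seed.
#' @return A weighted network over B's edges.
#' @export
run_cross_trained <- function(features_a, features_b,
                              hyperparameters = NULL, seed = 1L) {
  if (!identical(feature_names(features_a), feature_names(features_b))) {
    offending <- c(setdiff(feature_names(features_a), feature_names(features_b)),
                   setdiff(feature_names(features_b), feature_names(features_a)))
    stop_tfmapr("feature columns differ between datasets: ",
                paste(unique(offending), collapse = ", "))
  }
  hp <- hyperparameters %||% tune_hyperparameters(features_a, seed = seed)
  model <- train_combiner(features_a, hp, seed = seed)
  pred <- predict(model, features_b)
  predictions_to_network(features_b, pred)
}

#' Constrained ranking: re-rank positively labeled edges by model score
#'
#' Keeps only edges with binding label 1, scored by the model prediction;
#' every label-0 edge is scored exactly 0, and only TFs present in the label
#' network are retained. By construction, every nonzero-score edge of the
#' result is supported by the binding labels.
#'
#' @param predictions A weighted network of combiner probabilities.
#' @param labels A binary network sharing axes with `predictions`.
#' @return A weighted network.
#' @export
constrained_ranking <- function(predictions, labels) {
  tfs <- intersect(rownames(labels), rownames(predictions))
  genes <- intersect(colnames(labels), colnames(predictions))
  p <- unclass(predictions)[tfs, genes, drop = FALSE]
  l <- unclass(labels)[tfs, genes, drop = FALSE]
  out <- ifelse(!is.na(l) & l == 1, p, 0)
  out[is.na(out) & !is.na(l)] <- 0
  dimnames(out) <- list(tfs, genes)
  weighted_network(out)
}

#' Calibration curve: expected versus observed binding support
#'
#' Edges are sorted by predicted probability (descending, ties broken by
#' (tf, gene)); at each requested top-n cut, the expected support is 100x
#' the mean predicted probability and the observed support is 100x the
#' fraction of label-1 edges.
#'
#' @param predictions A weighted network of probabilities.
#' @param labels A binary network sharing axes.
#' @param n_grid Integer vector of top-n cuts.
#' @return Data frame with columns `n`, `expected`, `observed`.
#' @export
calibration_curve <- function(predictions, labels, n_grid) {
  tfs <- intersect(rownames(predictions), rownames(labels))
  genes <- intersect(colnames(predictions), colnames(labels))
  p <- unclass(predictions)[tfs, genes, drop = FALSE]
  l <- unclass(labels)[tfs, genes, drop = FALSE]
  keep <- which(!is.na(p) & !is.na(l), arr.ind = TRUE)
  pv <- p[keep]; lv <- l[keep]
  tfv <- tfs[keep[, 1L]]; gv <- genes[keep[, 2L]]
  ord <- order(-pv, tfv, gv, method = "radix")
  pv <- pv[ord]; lv <- lv[ord]
  n_grid <- n_grid[n_grid <= length(pv)]
  data.frame(n = n_grid,
             expected = vapply(n_grid, function(n) 100 * mean(pv[seq_len(n)]),
                               numeric(1)),
             observed = vapply(n_grid, function(n) 100 * mean(lv[seq_len(n)]),
                               numeric(1)))
}

#' Random subsets of labeled training TFs
#'
#' Used to study how performance scales with the number of TFs that have
#' binding data: draws `repeats` uniformly random distinct subsets of
#' `n_tfs` labeled TFs.
#'
#' @param labels A binary network (its rows are the labeled TFs).
#' @param n_tfs Subset size.
#' @param repeats Number of subsets (default 20).
#' @param seed Integer seed.
#' @return List of character vectors of TF ids.
#' @export
subsample_training_tfs <- function(labels, n_tfs, repeats = 20L, seed = 1L) {
  tfs <- sort(rownames(labels))
  if (n_tfs > length(tfs)) {
    stop_tfmapr(sprintf("n_tfs = %d exceeds the %d labeled TFs", n_tfs,
                        length(tfs)))
  }
  with_local_seed(seed, {
    lapply(seq_len(repeats), function(i) sort(sample(tfs, n_tfs)))
  })
}
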