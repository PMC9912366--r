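#' Differential-expression evidence score
#'
#' For each perturbed TF, the score of gene g is the log2 fold-change (LFC)
#' of g between that TF's perturbation samples and the mean of the control
#' samples, with small responses zeroed: any LFC with `|LFC| <= tau` is
#' replaced by 0 (the boundary is inclusive). For multi-timepoint
#' perturbations the LFC with the largest absolute value across time points
#' is kept, sign preserved. TFs never perturbed get an all-`NA` row (the
#' missing-feature marker).
#'
#' @param expr An expression matrix (log2 scale).
#' @param pmap A perturbation map for its samples.
#' @param tau Zeroing cutoff on |LFC| (default 0.38).
#' @param tfs Optional TF universe for the output rows; defaults to the set
#'   of perturbed TFs.
#' @return A weighted network, TFs x genes.
#' @export
de_score <- function(expr, pmap, tau = 0.38, tfs = NULL) {
  assert_scalar_number(tau, "tau", min = 0)
  missing_samples <- setdiff(pmap$sample, colnames(expr))
  if (length(missing_samples) > 0) {
    stop_tfmapr("perturbation map samples absent from expression matrix: ",
                paste(utils::head(missing_samples, 3), collapse = ", "))
  }
  ctrl <- pmap$sample[pmap$mechanism == "none"]
  if (length(ctrl) == 0L) stop_tfmapr("no control samples (mechanism 'none')")
  ctrl_mean <- rowMeans(expr[, ctrl, drop = FALSE])
  pert <- pmap[pmap$mechanism != "none" & !is.na(pmap$perturbed_tf), , drop = FALSE]
  perturbed_tfs <- sort(unique(pert$perturbed_tf))
  out_tfs <- if (is.null(tfs)) perturbed_tfs else tfs
  absent <- setdiff(perturbed_tfs, rownames(expr))
  if (length(absent) > 0) {
    warning("perturbed TF(s) absent from expression gene list: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  genes <- rownames(expr)
  m <- matrix(NA_real_, length(out_tfs), length(genes),
              dimnames = list(out_tfs, genes))
  for (tf in intersect(out_tfs, perturbed_tfs)) {
    rows <- pert[pert$perturbed_tf == tf, , drop = FALSE]
    tp <- ifelse(is.na(rows$time_point), -Inf, rows$time_point)
    # one LFC per time point (samples at the same time point are averaged),
    # then keep the one with the largest magnitude
    lfc_best <- rep(0, length(genes))
    best_abs <- rep(-1, length(genes))
    for (t in unique(tp)) {
      smp <- rows$sample[tp == t]
      lfc <- rowMeans(expr[, smp, drop = FALSE]) - ctrl_mean
      upd <- abs(lfc) > best_abs
      lfc_best[upd] <- lfc[upd]
      best_abs[upd] <- abs(lfc[upd])
    }
    lfc_best[abs(lfc_best) <= tau] <- 0
    m[tf, ] <- lfc_best
  }
  weighted_network(m)
}

# Build the TF-expression predictor matrix (samples x TFs) shared by the
# regression-based scores. Samples are put in sorted-id order so that all
# downstream resampling (CV folds, bootstraps) is invariant to the column
# order of the input matrix.
tf_predictor_matrix <- function(expr, tf_ids) {
  missing <- setdiff(tf_ids, rownames(expr))
  if (length(missing) > 0) {
    stop_tfmapr("TF(s) absent from expression matrix: ",
                paste(utils::head(missing, 3), collapse = ", "))
  }
  t(expr[tf_ids, sort(colnames(expr)), drop = FALSE])
}

#' LASSO regression evidence score
#'
#' Each gene's expression profile is regressed on the expression profiles of
#' all TFs (excluding the gene itself when it is a TF) with an L1-penalized
#' linear model. The evidence score of edge (tf, g) is the fitted
#' coefficient, signed. The penalty is chosen per gene by internal
#' cross-validation (one-standard-error rule).
#'
#' @param expr An expression matrix with >= 3 samples.
#' @param tf_ids TF gene ids, a subset of the expression genes.
#' @param seed Integer seed controlling the CV fold assignment.
#' @param nfolds Internal CV folds for the penalty path (default 5).
#' @return A weighted network of signed coefficients.
#' @export
lasso_scores <- function(expr, tf_ids, seed = 1L, nfolds = 5L) {
  if (ncol(expr) < 3L) stop_tfmapr("lasso_scores needs at least 3 samples")
  x_all <- tf_predictor_matrix(expr, tf_ids)
  genes <- rownames(expr)
  m <- matrix(0, length(tf_ids), length(genes), dimnames = list(tf_ids, genes))
  tf_sd <- apply(x_all, 2L, stats::sd)
  const_tf <- tf_ids[tf_sd == 0]
  if (length(const_tf) > 0) {
    warning("constant-expression TF(s) get zero coefficients: ",
            paste(const_tf, collapse = ", "), call. = FALSE)
  }
  use_tfs <- tf_ids[tf_sd > 0]
  n <- nrow(x_all)
  nfolds <- min(nfolds, n)
  with_local_seed(seed, {
    for (g in genes) {
      y <- expr[g, rownames(x_all)]
      if (stats::sd(y) == 0) {
        warning("constant-expression gene '", g, "': all-zero coefficients",
                call. = FALSE)
        next
      }
      preds <- setdiff(use_tfs, g)
      if (length(preds) < 2L) next
      foldid <- sample(rep_len(seq_len(nfolds), n))
      # cv.glmnet emits advisory chatter when folds are small; not actionable
      fit <- withCallingHandlers(
        glmnet::cv.glmnet(x_all[, preds, drop = FALSE], y,
                          family = "gaussian", alpha = 1,
                          foldid = foldid, standardize = TRUE),
        warning = function(w) {
          if (grepl("grouped=FALSE", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      beta <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1L]
      m[preds, g] <- beta
    }
  })
  weighted_network(m)
}

#' Tree-ensemble (regression forest) evidence score
#'
#' Each gene's expression profile is regressed on all TF expression profiles
#' with an ensemble-of-trees regression; the evidence score of edge (tf, g)
#' is the nonnegative impurity-based variable importance of that TF. This
#' fills the role of Bayesian tree regression in multi-evidence pipelines:
#' the downstream combiner only needs a tree-based importance feature.
#'
#' @param expr An expression matrix with >= 3 samples.
#' @param tf_ids TF gene ids.
#' @param seed Integer seed for the forest.
#' @param num_trees Trees per gene (default 100).
#' @return A weighted network of nonnegative importances.
#' @export
tree_ensemble_scores <- function(expr, tf_ids, seed = 1L, num_trees = 100L) {
  if (ncol(expr) < 3L) stop_tfmapr("tree_ensemble_scores needs at least 3 samples")
  x_all <- tf_predictor_matrix(expr, tf_ids)
  genes <- rownames(expr)
  m <- matrix(0, length(tf_ids), length(genes), dimnames = list(tf_ids, genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    y <- expr[g, rownames(x_all)]
    if (stats::sd(y) == 0) next
    preds <- setdiff(tf_ids, g)
    if (length(preds) == 0L) next
    df <- data.frame(x_all[, preds, drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(x = df, y = y, num.trees = num_trees,
                          importance = "impurity",
                          seed = derive_seed(seed, i), num.threads = 1L,
                          verbose = FALSE)
    imp <- fit$variable.importance
    imp[imp < 0] <- 0
    m[names(imp), g] <- imp
  }
  weighted_network(m)
}

#' Spearman co-expression evidence score
#'
#' The rank correlation between each TF's expression profile and each gene's,
#' in \[-1, 1\]. Deliberately simple; included because multi-evidence
#' combiners should be robust to weak features.
#'
#' @param expr An expression matrix with >= 3 samples.
#' @param tf_ids TF gene ids.
#' @return A weighted network of rank correlations.
#' @export
spearman_scores <- function(expr, tf_ids) {
  if (ncol(expr) < 3L) stop_tfmapr("spearman_scores needs at least 3 samples")
  x <- tf_predictor_matrix(expr, tf_ids)
  y <- t(expr)[rownames(x), , drop = FALSE]
  zero_var <- c(colnames(x)[apply(x, 2L, stats::sd) == 0],
                colnames(y)[apply(y, 2L, stats::sd) == 0])
  if (length(zero_var) > 0) {
    warning("zero-variance series scored 0: ",
            paste(unique(zero_var), collapse = ", "), call. = FALSE)
  }
  suppressWarnings(m <- stats::cor(x, y, method = "spearman"))
  m[is.na(m)] <- 0
  weighted_network(m)
}

#' Assemble the per-edge feature table
#'
#' Rows are (TF, gene) edges over the union of pairs covered by the supplied
#' evidence networks, excluding self-edges. Each network contributes one
#' named feature column; an edge absent from a network gets `NA`, the
#' missing-feature marker, which the tree-based combiner handles natively.
#' When binding labels are supplied, edges of labeled TFs get a 0/1 `label`;
#' edges of unlabeled TFs keep `label = NA`.
#'
#' @param networks Named list of weighted networks (names become feature
#'   columns; any number of features is allowed).
#' @param labels Optional binary network of binding labels.
#' @return A data frame with class `"feature_table"`: columns `tf`, `gene`,
#'   `label`, then one column per feature.
#' @export
assemble_features <- function(networks, labels = NULL) {
  if (length(networks) == 0L) stop_tfmapr("at least one evidence network required")
  nms <- names(networks)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop_tfmapr("evidence networks must have unique non-empty names")
  }
  tfs <- sort(unique(unlist(lapply(networks, rownames))))
  genes <- sort(unique(unlist(lapply(networks, colnames))))
  edges <- expand.grid(gene = genes, tf = tfs, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)[, c("tf", "gene")]
  edges <- edges[edges$tf != edges$gene, , drop = FALSE]
  feat <- matrix(NA_real_, nrow(edges), length(networks),
                 dimnames = list(NULL, nms))
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    hit <- edges$tf %in% rownames(net) & edges$gene %in% colnames(net)
    feat[hit, k] <- net[cbind(edges$tf[hit], edges$gene[hit])]
  }
  lab <- rep(NA_real_, nrow(edges))
  if (!is.null(labels)) {
    hit <- edges$tf %in% rownames(labels) & edges$gene %in% colnames(labels)
    lab[hit] <- labels[cbind(edges$tf[hit], edges$gene[hit])]
  }
  out <- data.frame(tf = edges$tf, gene = edges$gene, label = lab,
                    feat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, feature_names = nms,
            class = c("feature_table", "data.frame"))
}

#' Feature column names of a feature table
#' @param features A feature table.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(features) attr(features, "feature_names")

#' Write a feature table to TSV
#' @param features A feature table.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  out <- features
  num <- setdiff(names(out), c("tf", "gene"))
  for (k in num) out[[k]] <- format_score(out[[k]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path Input path.
#' @return A feature table.
#' @export
load_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  nms <- setdiff(names(df), c("tf", "gene", "label"))
  for (k in c("label", nms)) df[[k]] <- as.numeric(df[[k]])
  structure(df, feature_names = nms,
            class = c("feature_table", "data.frame"))
}
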