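# Run orchestration: a validated config object, a file-driven workflow that
# computes evidence scores, trains the combiner in the requested mode, and
# writes all artifacts with fixed formatting so repeated runs are
# byte-identical.

#' Build and validate a workflow configuration
#'
#' @param expression Path(s) to expression TSV(s); two paths enable
#'   cross-trained mode and two-dataset feature sets.
#' @param perturbations Path(s) to perturbation-map TSV(s), parallel to
#'   `expression`.
#' @param labels Path to a binary binding-label edge list.
#' @param promoters Optional promoter FASTA (enables the PWM feature).
#' @param annotation Optional gene-term TSV (enables the GO metrics).
#' @param interactions Optional interaction TSV (enables the PPI metric).
#' @param mode `"generalization"`, `"integration"` or `"cross_trained"`.
#' @param features Evidence scores to compute per dataset, from
#'   `"de"`, `"lasso"`, `"bart"`, `"pwm"`, `"spearman"`.
#' @param tau DE zeroing cutoff (default 0.38).
#' @param k Outer CV folds (default 10).
#' @param inner_k Inner tuning folds (default 5).
#' @param n_seeds Fold-assignment seeds averaged in generalization mode
#'   (default 20).
#' @param group_size Integration-mode group size (default 1).
#' @param threshold_grid Evaluation thresholds (average targets per TF).
#' @param hyper_grid Hyperparameter data frame (default
#'   [default_hyper_grid()]).
#' @param seed Base seed (default 1).
#' @return List with class `"run_config"`.
#' @export
run_config <- function(expression, perturbations, labels,
                       promoters = NULL, annotation = NULL,
                       interactions = NULL,
                       mode = c("generalization", "integration", "cross_trained"),
                       features = c("de", "lasso", "bart"),
                       tau = 0.38, k = 10L, inner_k = 5L, n_seeds = 20L,
                       group_size = 1L,
                       threshold_grid = default_threshold_grid(),
                       hyper_grid = default_hyper_grid(), seed = 1L) {
  mode <- match.arg(mode)
  assert_scalar_number(tau, "tau", min = 0)
  if (k < 2L) stop_tfmapr("k (CV folds) must be >= 2")
  bad <- !all(threshold_grid == as.integer(threshold_grid)) ||
    any(threshold_grid <= 0) || any(diff(threshold_grid) <= 0)
  if (bad) stop_tfmapr("threshold_grid must be strictly increasing positive integers")
  features <- match.arg(features,
                        c("de", "lasso", "bart", "pwm", "spearman"),
                        several.ok = TRUE)
  if ("pwm" %in% features && is.null(promoters)) {
    stop_tfmapr("the pwm feature requires a promoters FASTA")
  }
  if (mode == "cross_trained" && length(expression) < 2L) {
    stop_tfmapr("cross_trained mode requires two expression datasets")
  }
  if (length(expression) != length(perturbations)) {
    stop_tfmapr("one perturbation map per expression dataset required")
  }
  structure(list(expression = expression, perturbations = perturbations,
                 labels = labels, promoters = promoters,
                 annotation = annotation, interactions = interactions,
                 mode = mode, features = features, tau = tau,
                 k = as.integer(k), inner_k = as.integer(inner_k),
                 n_seeds = as.integer(n_seeds), group_size = group_size,
                 threshold_grid = threshold_grid, hyper_grid = hyper_grid,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a workflow configuration from YAML or JSON
#' @param path Config file; keys as in [run_config()].
#' @return A `"run_config"`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$hyper_grid)) raw$hyper_grid <- as.data.frame(raw$hyper_grid)
  do.call(run_config, raw)
}

#' Compute the configured evidence-score networks for one dataset
#'
#' @param expr An expression matrix.
#' @param pmap A perturbation map.
#' @param tf_ids TF universe (default: the perturbed TFs).
#' @param features Which scores to compute.
#' @param promoters Promoter set (needed for `"pwm"`).
#' @param tau DE cutoff.
#' @param seed Integer seed.
#' @param motif_cfg A [motif_config()].
#' @return Named list of weighted networks.
#' @export
evidence_scores <- function(expr, pmap, tf_ids = NULL,
                            features = c("de", "lasso", "bart"),
                            promoters = NULL, tau = 0.38, seed = 1L,
                            motif_cfg = motif_config()) {
  tf_ids <- tf_ids %||% sort(unique(stats::na.omit(pmap$perturbed_tf)))
  out <- list()
  if ("de" %in% features) out$de <- de_score(expr, pmap, tau, tfs = tf_ids)
  if ("lasso" %in% features) {
    out$lasso <- lasso_scores(expr, tf_ids, seed = derive_seed(seed, 11L))
  }
  if ("bart" %in% features) {
    out$bart <- tree_ensemble_scores(expr, tf_ids,
                                     seed = derive_seed(seed, 12L))
  }
  if ("spearman" %in% features) out$spearman <- spearman_scores(expr, tf_ids)
  if ("pwm" %in% features) {
    prelim <- out$bart %||% tree_ensemble_scores(expr, tf_ids,
                                                 seed = derive_seed(seed, 12L))
    out$pwm <- pwm_scores(prelim, promoters, motif_cfg,
                          seed = derive_seed(seed, 13L))$network
  }
  out
}

#' Run the full mapping workflow from a configuration
#'
#' Loads the configured inputs, computes the evidence scores for each
#' expression dataset, assembles the feature table, trains the combiner in
#' the configured mode, evaluates the resulting network against whatever
#' reference data are configured, and writes: the predicted network edge
#' list, per-metric curve TSVs, and a JSON run log with a config hash.
#' Deterministic given the config (repeated runs are byte-identical).
#'
#' @param config A `"run_config"`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the predicted `network`, the feature
#'   table(s) and the metric curves.
#' @export
run_workflow <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- load_edge_list(config$labels, kind = "binary")
  promoters <- if (!is.null(config$promoters)) load_promoters(config$promoters)
  tables <- vector("list", length(config$expression))
  for (i in seq_along(config$expression)) {
    expr <- load_expression(config$expression[[i]])
    pmap <- load_perturbation_map(config$perturbations[[i]])
    nets <- evidence_scores(expr, pmap, features = config$features,
                            promoters = promoters, tau = config$tau,
                            seed = derive_seed(config$seed, i))
    if (length(config$expression) > 1L) {
      names(nets) <- paste0(names(nets), "_", i)
    }
    tables[[i]] <- nets
  }
  if (config$mode == "cross_trained") {
    features_a <- assemble_features(tables[[1L]], labels)
    nets_b <- tables[[2L]]
    names(nets_b) <- sub("_2$", "_1", names(nets_b))
    features_b <- assemble_features(nets_b, labels)
    network <- run_cross_trained(features_a, features_b,
                                 seed = config$seed)
    features <- list(features_a, features_b)
  } else if (length(config$expression) > 1L) {
    # multi-dataset feature set: all datasets' scores as one wide table
    features <- assemble_features(do.call(c, tables), labels)
    network <- fit_mode(features, config)
  } else {
    features <- assemble_features(tables[[1L]], labels)
    network <- fit_mode(features, config)
  }
  write_edge_list(network, file.path(out_dir, "network.tsv"))
  curves <- evaluate_network(network, labels = labels,
                             annotation = if (!is.null(config$annotation))
                               load_annotation(config$annotation),
                             interactions = if (!is.null(config$interactions))
                               load_interactions(config$interactions),
                             grid = config$threshold_grid)
  for (nm in names(curves)) {
    out <- curves[[nm]]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], format_score)
    utils::write.table(out, file.path(out_dir, paste0("metric_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- list(config = config[setdiff(names(config), "hyper_grid")],
              config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("tfmapr")),
              r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(network = network, features = features, curves = curves))
}

fit_mode <- function(features, config) {
  if (config$mode == "generalization") {
    run_generalization(features, k = config$k,
                       seeds = vapply(seq_len(config$n_seeds), function(i)
                         derive_seed(config$seed, 20L + i), integer(1)),
                       grid = config$hyper_grid,
                       inner_k = config$inner_k)$mean
  } else {
    run_integration(features, group_size = config$group_size,
                    seed = config$seed)
  }
}

config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 10)),
               collapse = "\n")
  # small rolling hash; enough to detect config drift in run logs
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Evaluate a network against all available reference data
#'
#' @param network A weighted network.
#' @param labels Optional binary network (binding metric, GO-directness).
#' @param annotation Optional annotation map (GO metric).
#' @param interactions Optional interaction table (PPI metric).
#' @param grid Threshold grid.
#' @param ppi_t Discretization threshold for the PPI metric (default 25).
#' @return Named list of metric-curve data frames.
#' @export
evaluate_network <- function(network, labels = NULL, annotation = NULL,
                             interactions = NULL,
                             grid = default_threshold_grid(), ppi_t = 25L) {
  out <- list()
  if (!is.null(labels)) out$binding <- binding_metric(network, labels, grid)
  if (!is.null(annotation)) {
    out$go <- go_metric(network, annotation, grid)
    if (!is.null(labels)) {
      out$go_directness <- go_directness(network, annotation, labels, grid)
    }
  }
  if (!is.null(interactions)) {
    out$ppi <- ppi_metric(network, interactions, t = ppi_t)
  }
  out
}
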