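# Shared fixtures. Heavy objects (the reference benchmark and its evidence
# scores) are computed once per test run and cached in an environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, builder(), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

# Tiny 4-gene x 5-sample expression fixture with a known perturbation layout.
tiny_expression <- function() {
  m <- rbind(
    G1 = c(1.0, 1.2, 0.8, 2.0, 1.0),
    G2 = c(0.5, 0.5, 0.5, 0.5, 0.5),
    G3 = c(2.0, 1.8, 2.2, 3.0, 2.0),
    G4 = c(0.0, 0.1, -0.1, 0.0, 0.0)
  )
  colnames(m) <- c("c1", "c2", "c3", "p1", "p2")
  expression_matrix(m)
}

tiny_pmap <- function() {
  perturbation_map(sample = c("c1", "c2", "c3", "p1", "p2"),
                   perturbed_tf = c(NA, NA, NA, "G1", "G2"),
                   mechanism = c("none", "none", "none",
                                 "overexpression", "overexpression"))
}

# A small weighted network over named axes (values chosen by hand).
toy_network <- function(values, tfs, genes) {
  weighted_network(matrix(values, length(tfs), length(genes), byrow = TRUE,
                          dimnames = list(tfs, genes)))
}

toy_binary <- function(values, tfs, genes, source = "base") {
  binary_network(matrix(values, length(tfs), length(genes), byrow = TRUE,
                        dimnames = list(tfs, genes)), source = source)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# The reference benchmark at its default study conditions (50 TFs, 500
# genes, noise SD 0.5, label noise fp 0.01 / fn 0.3), with the three
# expression-based evidence scores and the assembled feature table.
ref_bench <- function() cached("ref_bench", function() {
  bm <- make_benchmark(synthetic_config())
  d <- bm$datasets[[1L]]
  tfs <- rownames(bm$truth$network)
  nets <- list(de = de_score(d$expr, d$pmap, tfs = tfs),
               lasso = lasso_scores(d$expr, tfs, seed = 2L),
               bart = tree_ensemble_scores(d$expr, tfs, seed = 3L))
  list(bm = bm,
       nets = nets,
       features = assemble_features(nets, bm$labels),
       truth_bin = binary_network((unclass(bm$truth$network) != 0) * 1))
})

# Compact tuning grid used in tests to keep cross-validation runs fast;
# the covered corners (shallow/slow vs deeper/fast) still exercise tuning.
test_grid <- function() default_hyper_grid()[c(2L, 14L), ]

# A wider benchmark (100 labeled TFs) used for training-size scaling runs.
size_bench <- function() cached("size_bench", function() {
  bm <- make_benchmark(synthetic_config(n_tfs = 100L, n_genes = 500L,
                                        seed = 2L))
  d <- bm$datasets[[1L]]
  tfs <- rownames(bm$truth$network)
  nets <- list(de = de_score(d$expr, d$pmap, tfs = tfs),
               lasso = lasso_scores(d$expr, tfs, seed = 2L),
               bart = tree_ensemble_scores(d$expr, tfs, seed = 3L))
  list(bm = bm, features = assemble_features(nets, bm$labels))
})

ref_generalization <- function() cached("ref_gen", function() {
  run_generalization(ref_bench()$features, k = 10L, seeds = 1:5,
                     grid = test_grid(), inner_k = 5L)
})

ref_integration <- function() cached("ref_int", function() {
  run_integration(ref_bench()$features, group_size = 1L, seed = 4L)
})

# Independent metric oracles (deliberately brute-force, no shared code with
# the implementations they check).

oracle_auroc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

oracle_auprc <- function(score, label) {
  # walk distinct thresholds high to low, step-interpolating
  th <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(label == 1)
  prev_recall <- 0; area <- 0
  for (t in th) {
    sel <- score >= t
    precision <- sum(label[sel] == 1) / sum(sel)
    recall <- sum(label[sel] == 1) / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

oracle_hypergeom_tail <- function(k, m, n_univ, n_draw) {
  ks <- k:min(m, n_draw)
  sum(choose(m, ks) * choose(n_univ - m, n_draw - ks)) / choose(n_univ, n_draw)
}

# Sort-free recount of the binding metric: for threshold t, find the score
# cutoff by enumeration and count supported edges among those above it.
oracle_binding_support <- function(network, labels, t) {
  tfs <- intersect(rownames(network), rownames(labels))
  genes <- intersect(colnames(network), colnames(labels))
  vals <- c()
  for (tf in tfs) for (g in genes) {
    s <- unclass(network)[tf, g]
    if (!is.na(s) && s != 0) vals <- c(vals, abs(s))
  }
  n <- min(t * length(tfs), length(vals))
  cutoff <- sort(vals, decreasing = TRUE)[n]
  hits <- 0; total <- 0; at_cut <- list()
  for (tf in tfs) for (g in genes) {
    s <- unclass(network)[tf, g]
    if (is.na(s) || s == 0) next
    if (abs(s) > cutoff) {
      total <- total + 1
      hits <- hits + (unclass(labels)[tf, g] == 1)
    } else if (abs(s) == cutoff) {
      at_cut[[length(at_cut) + 1L]] <- c(tf, g)
    }
  }
  # fill remaining budget from tied edges in (tf, gene) lexicographic order
  ord <- order(vapply(at_cut, `[`, "", 1L), vapply(at_cut, `[`, "", 2L))
  for (i in ord[seq_len(n - total)]) {
    hits <- hits + (unclass(labels)[at_cut[[i]][1L], at_cut[[i]][2L]] == 1)
  }
  100 * hits / n
}
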