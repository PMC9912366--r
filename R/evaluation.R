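# Network evaluation: binding support, GO enrichment, GO-directness and
# protein-interaction metrics, each as a function of a per-TF-scaled edge
# budget, plus AUROC/AUPRC and a permutation baseline.

#' Default threshold grid: average targets per TF
#' @return Integer vector of thresholds.
#' @export
default_threshold_grid <- function() {
  c(10L, 15L, 20L, 25L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L)
}

# Long-format nonzero, non-missing edges of a network, sorted by |score|
# descending with stable lexicographic (tf, gene) tie-breaking.
ranked_edges <- function(network, tfs = rownames(network)) {
  sub <- unclass(network)[tfs, , drop = FALSE]
  idx <- which(!is.na(sub) & sub != 0, arr.ind = TRUE)
  tf <- tfs[idx[, 1L]]
  gene <- colnames(sub)[idx[, 2L]]
  score <- sub[idx]
  ord <- order(-abs(score), tf, gene, method = "radix")
  data.frame(tf = tf[ord], gene = gene[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Top edges at a per-TF-scaled threshold
#'
#' The edge budget at threshold `t` is `N = t x (number of evaluable TFs)`:
#' an average of t targets per TF, so networks with more TFs are evaluated
#' on proportionally more edges. Edges are ranked by absolute score
#' (descending; ties broken lexicographically by (tf, gene)); zero and
#' missing scores are never ranked. If fewer than N nonzero edges exist,
#' all are returned and the result is flagged.
#'
#' @param network A weighted network.
#' @param t Average targets per TF.
#' @param evaluable_tfs TFs whose edges enter the ranking (default: all rows).
#' @return Data frame (tf, gene, score) with attribute `"truncated"` = TRUE
#'   when the budget exceeded the available nonzero edges.
#' @export
top_edges <- function(network, t, evaluable_tfs = rownames(network)) {
  if (t < 1) stop_tfmapr("threshold t must be >= 1")
  edges <- ranked_edges(network, evaluable_tfs)
  n <- t * length(evaluable_tfs)
  flagged <- nrow(edges) < n
  out <- edges[seq_len(min(n, nrow(edges))), , drop = FALSE]
  attr(out, "truncated") <- flagged
  out
}

#' Binding evaluation metric
#'
#' Percent of top-scoring edges supported by binding labels, at each
#' per-TF-scaled threshold. Only TFs with binding data are evaluable; edges
#' of other TFs are removed before thresholds are applied.
#'
#' @param network A weighted network of predictions.
#' @param labels A binary network of binding labels.
#' @param grid Threshold grid (average targets per TF).
#' @return Data frame: `t`, `value` (percent), `n_edges`, `flagged`, plus
#'   attribute `"random_expectation"` — 100x the overall positive fraction.
#' @export
binding_metric <- function(network, labels, grid = default_threshold_grid()) {
  tfs <- intersect(rownames(network), rownames(labels))
  if (length(tfs) == 0L) stop_tfmapr("network and labels share no TFs")
  genes <- intersect(colnames(network), colnames(labels))
  lab <- unclass(labels)[tfs, genes, drop = FALSE]
  rows <- lapply(grid, function(t) {
    top <- top_edges(network, t, tfs)
    top <- top[top$gene %in% genes, , drop = FALSE]
    supported <- lab[cbind(top$tf, top$gene)] == 1
    data.frame(t = t,
               value = if (nrow(top) == 0) NA_real_ else 100 * mean(supported, na.rm = TRUE),
               n_edges = nrow(top),
               flagged = isTRUE(attr(top, "truncated")))
  })
  out <- do.call(rbind, rows)
  attr(out, "random_expectation") <- 100 * mean(lab == 1, na.rm = TRUE)
  out
}

#' Hypergeometric term over-representation for a target set
#'
#' Upper-tail hypergeometric test of each annotation term against a gene
#' universe, Bonferroni-adjusted over the tested terms. Terms annotated to
#' more than `size_cap` genes in the full annotation are excluded (they are
#' too generic to identify a TF's specific biological role), as are terms
#' with fewer than 2 annotated genes in the universe.
#'
#' @param targets Character vector of genes (subset of `universe`).
#' @param annotation An [annotation_map()].
#' @param universe Character vector of all candidate genes.
#' @param size_cap Maximum annotated-gene count per term (default 300).
#' @return Data frame: `term`, `overlap`, `term_universe_size`, `p`
#'   (raw upper-tail), `p_adj` (Bonferroni).
#' @export
hypergeom_enrichment <- function(targets, annotation, universe,
                                 size_cap = 300L) {
  targets <- intersect(targets, universe)
  empty <- data.frame(term = character(0), overlap = integer(0),
                      term_universe_size = integer(0), p = numeric(0),
                      p_adj = numeric(0))
  if (length(targets) == 0L) return(empty)
  gt <- annotation$gene_terms[intersect(names(annotation$gene_terms), universe)]
  term_genes <- split(rep(names(gt), lengths(gt)), unlist(gt, use.names = FALSE))
  sizes_full <- annotation$term_sizes[names(term_genes)]
  keep <- sizes_full <= size_cap & lengths(term_genes) >= 2L
  term_genes <- term_genes[keep]
  if (length(term_genes) == 0L) return(empty)
  n_univ <- length(universe)
  n_targ <- length(targets)
  res <- lapply(names(term_genes), function(term) {
    m <- length(term_genes[[term]])
    k <- length(intersect(term_genes[[term]], targets))
    p <- stats::phyper(k - 1L, m, n_univ - m, n_targ, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_universe_size = m, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out[order(out$p, out$term), , drop = FALSE]
}

#' GO evaluation metric
#'
#' At each threshold, every TF's top `t` predicted targets (per-TF cut; all
#' TFs participate, whether or not they have binding data) are tested for
#' term over-representation; the TF is assigned its best adjusted -log10 p.
#' The curve reports the median across TFs whose best -log10 p exceeds
#' `sig_cap`, i.e. it compares how *specific* the top term is among TFs that
#' have one, not how many TFs have one.
#'
#' @param network A weighted network.
#' @param annotation An [annotation_map()].
#' @param grid Threshold grid.
#' @param sig_cap Significance cap on -log10 adjusted p (default 4).
#' @param size_cap Term size cap (default 300).
#' @param universe Gene universe (default: network gene columns).
#' @return Data frame: `t`, `value` (median -log10 p among passing TFs; `NA`
#'   when none pass), `n_passed`.
#' @export
go_metric <- function(network, annotation, grid = default_threshold_grid(),
                      sig_cap = 4, size_cap = 300L,
                      universe = colnames(network)) {
  best <- go_best_terms(network, annotation, grid, size_cap, universe)
  rows <- lapply(grid, function(t) {
    b <- best[[as.character(t)]]
    pass <- b$neglogp[b$neglogp > sig_cap]
    data.frame(t = t,
               value = if (length(pass) == 0) NA_real_ else stats::median(pass),
               n_passed = length(pass))
  })
  do.call(rbind, rows)
}

# Per threshold, each TF's most enriched term among its top-t targets.
go_best_terms <- function(network, annotation, grid, size_cap = 300L,
                          universe = colnames(network)) {
  tfs <- rownames(network)
  ranked <- lapply(stats::setNames(tfs, tfs), function(tf) {
    ranked_edges(network, tf)$gene
  })
  out <- list()
  for (t in grid) {
    res <- lapply(stats::setNames(tfs, tfs), function(tf) {
      top <- utils::head(ranked[[tf]], t)
      if (length(top) == 0L) return(NULL)
      enr <- hypergeom_enrichment(top, annotation, universe, size_cap)
      if (nrow(enr) == 0L) return(NULL)
      list(term = enr$term[1L], neglogp = -log10(max(enr$p_adj[1L], 1e-300)),
           targets = top)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    out[[as.character(t)]] <- list(
      tf = names(res),
      term = vapply(res, `[[`, "", "term"),
      neglogp = vapply(res, `[[`, 0, "neglogp"),
      targets = lapply(res, `[[`, "targets")
    )
  }
  out
}

#' GO-directness evaluation metric
#'
#' For each TF, among its thresholded targets annotated with the TF's most
#' enriched term, the fraction supported by binding labels. Reported per
#' threshold as both the mean and the median across evaluable TFs (x100);
#' this checks whether enrichment is driven by direct edges or bought with
#' indirect ones.
#'
#' @param network A weighted network.
#' @param annotation An [annotation_map()].
#' @param labels A binary network.
#' @param grid Threshold grid.
#' @param sig_cap,size_cap As in [go_metric()].
#' @return Data frame: `t`, `value` (mean percent), `median_value`, `n_tfs`.
#' @export
go_directness <- function(network, annotation, labels,
                          grid = default_threshold_grid(),
                          sig_cap = 4, size_cap = 300L) {
  best <- go_best_terms(network, annotation, grid, size_cap)
  gt <- annotation$gene_terms
  rows <- lapply(grid, function(t) {
    b <- best[[as.character(t)]]
    pct <- c()
    for (i in seq_along(b$tf)) {
      tf <- b$tf[i]
      if (b$neglogp[i] <= sig_cap) next
      if (!tf %in% rownames(labels)) next
      term <- b$term[i]
      matched <- b$targets[[i]][vapply(b$targets[[i]], function(g) {
        term %in% (gt[[g]] %||% character(0))
      }, logical(1))]
      matched <- intersect(matched, colnames(labels))
      if (length(matched) == 0L) next
      pct <- c(pct, 100 * mean(labels[tf, matched] == 1, na.rm = TRUE))
    }
    data.frame(t = t,
               value = if (length(pct)) mean(pct) else NA_real_,
               median_value = if (length(pct)) stats::median(pct) else NA_real_,
               n_tfs = length(pct))
  })
  do.call(rbind, rows)
}

#' Jaccard similarity of two gene sets
#'
#' 1 when the sets are identical, 0 when disjoint (and, by convention, when
#' both are empty).
#'
#' @param a,b Character vectors.
#' @return Numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Protein-protein interaction evaluation metric
#'
#' Discretizes the network at `t` targets per TF (per-TF top-`t` by absolute
#' score, so every TF contributes a comparable set), computes the Jaccard
#' similarity of target sets for every TF pair, ranks pairs by similarity
#' (descending; ties broken lexicographically), and reports, for each top-n
#' cut, the percent of pairs supported by a physical interaction with
#' confidence >= `conf`.
#'
#' @param network A weighted network with >= 2 TFs.
#' @param interactions An [interaction_table()].
#' @param t Targets per TF for discretization (default 25).
#' @param n_grid Top-pair cuts (default 10, 20, ..., 100).
#' @param conf Confidence cutoff (default 0.7).
#' @return Data frame: `n`, `value` (percent), `n_pairs`, `flagged`, plus
#'   attribute `"pairs"` — the full ranked pair table.
#' @export
ppi_metric <- function(network, interactions, t = 25L,
                       n_grid = seq(10L, 100L, by = 10L), conf = 0.7) {
  tfs <- rownames(network)
  if (length(tfs) < 2L) stop_tfmapr("ppi_metric needs >= 2 TFs")
  targets <- lapply(stats::setNames(tfs, tfs), function(tf) {
    utils::head(ranked_edges(network, tf)$gene, t)
  })
  pairs <- utils::combn(sort(tfs), 2L)
  jac <- apply(pairs, 2L, function(p) jaccard(targets[[p[1L]]], targets[[p[2L]]]))
  sup <- interaction_score(interactions, pairs[1L, ], pairs[2L, ]) >= conf
  ord <- order(-jac, pairs[1L, ], pairs[2L, ], method = "radix")
  ranked <- data.frame(tf1 = pairs[1L, ord], tf2 = pairs[2L, ord],
                       jaccard = jac[ord], supported = sup[ord],
                       stringsAsFactors = FALSE)
  rows <- lapply(n_grid, function(n) {
    avail <- min(n, nrow(ranked))
    data.frame(n = n,
               value = 100 * mean(ranked$supported[seq_len(avail)]),
               n_pairs = avail,
               flagged = avail < n)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- ranked
  out
}

# Flatten matched (score, label) vectors over shared axes.
paired_scores <- function(scores, labels) {
  tfs <- intersect(rownames(scores), rownames(labels))
  genes <- intersect(colnames(scores), colnames(labels))
  s <- unclass(scores)[tfs, genes, drop = FALSE]
  l <- unclass(labels)[tfs, genes, drop = FALSE]
  keep <- !is.na(s) & !is.na(l)
  list(score = s[keep], label = l[keep])
}

#' Area under the ROC curve (rank-based, midrank ties)
#' @param score Numeric predictions (or a weighted network).
#' @param label 0/1 labels (or a binary network).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  if (inherits(score, "weighted_network")) {
    p <- paired_scores(score, label)
    score <- p$score; label <- p$label
  }
  pos <- label == 1
  if (!any(pos) || all(pos)) stop_tfmapr("AUROC needs both classes")
  r <- rank(score)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Processes scores from high to low in groups of tied values, accumulating
#' `sum(delta recall x precision)` at each distinct threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(score, label) {
  if (inherits(score, "weighted_network")) {
    p <- paired_scores(score, label)
    score <- p$score; label <- p$label
  }
  n_pos <- sum(label == 1)
  if (n_pos == 0L || n_pos == length(label)) stop_tfmapr("AUPRC needs both classes")
  ord <- order(-score)
  score <- score[ord]; label <- label[ord]
  groups <- cumsum(!duplicated(score))
  tp_g <- tapply(label, groups, sum)
  n_g <- tapply(label, groups, length)
  tp <- cumsum(tp_g)
  fp <- cumsum(n_g) - tp
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Randomly permute a network's scores across its edges
#'
#' Baseline used to estimate the chance level of the GO and binding metrics:
#' every (TF, gene) association is scrambled by permuting the scores
#' uniformly at random over all valid (non-self) edges, so the score
#' multiset is preserved exactly while any structure linking scores to
#' particular TFs or genes is destroyed.
#'
#' @param network A weighted network.
#' @param seed Integer seed.
#' @return A weighted network with the same axes and score multiset.
#' @export
permute_network <- function(network, seed = 1L) {
  m <- unclass(network)
  cells <- which(!is.na(m))
  with_local_seed(seed, {
    m[cells] <- m[sample(cells)]
  })
  weighted_network(m)
}
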