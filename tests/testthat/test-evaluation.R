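test_that("top_edges applies the per-TF-scaled budget with |score| ranking", {
  tfs <- c("A", "B", "C"); genes <- paste0("g", 1:4)
  net <- toy_network(c(0.9, 0.1, 0.2, 0.3,
                       -0.8, 0.7, 0.05, 0.4,
                       0.6, 0.5, 0.45, 0.35), tfs, genes)
  top <- top_edges(net, t = 2)
  expect_equal(nrow(top), 6L)              # 2 x 3 evaluable TFs
  # |.|-ranking: a -0.9-style edge outranks +0.5
  net2 <- toy_network(c(-0.9, 0.5), "A", c("g1", "g2"))
  expect_equal(top_edges(net2, 1)$gene, "g1")
  # removing a non-evaluable TF shrinks the budget
  top_ab <- top_edges(net, 2, evaluable_tfs = c("A", "B"))
  expect_equal(nrow(top_ab), 4L)
  expect_false("C" %in% top_ab$tf)
  # budget larger than the nonzero edges: flagged
  expect_true(attr(top_edges(net2, 5), "truncated"))
})

test_that("binding_metric matches hand counts and the brute-force recount", {
  tfs <- c("A", "B"); genes <- paste0("g", 1:4)
  # scores rank the four positive edges first
  net <- toy_network(c(0.9, 0.8, 0.1, 0.05,
                       0.7, 0.6, 0.02, 0.01), tfs, genes)
  lab <- toy_binary(c(1, 1, 0, 0,
                      1, 1, 0, 0), tfs, genes)
  bmt <- binding_metric(net, lab, grid = 2L)
  expect_equal(bmt$value, 100)
  expect_equal(bmt$n_edges, 4L)

  # all-zero labels: 0 percent at every threshold
  lab0 <- toy_binary(rep(0, 8), tfs, genes)
  expect_true(all(binding_metric(net, lab0, grid = c(1L, 2L))$value == 0))

  # oracle equivalence on a randomized 8 TF x 30 gene fixture
  set.seed(81)
  tfs <- sprintf("T%02d", 1:8); genes <- sprintf("g%02d", 1:30)
  m <- matrix(rnorm(240), 8, 30, dimnames = list(tfs, genes))
  m[sample(length(m), 40)] <- 0
  net_r <- weighted_network(m)
  lab_r <- binary_network(matrix(rbinom(240, 1, 0.3), 8, 30,
                                 dimnames = list(tfs, genes)))
  for (t in c(2L, 5L, 10L)) {
    expect_equal(binding_metric(net_r, lab_r, grid = t)$value,
                 oracle_binding_support(net_r, lab_r, t))
  }
  expect_error(binding_metric(net_r, toy_binary(1, "ZZ", "g01"), 2L),
               "share no TFs")
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  universe <- paste0("g", 1:10)
  ann <- annotation_map(list(
    g1 = "T1", g2 = "T1", g3 = "T1", g4 = "T1",
    g5 = "T2", g6 = "T2", g7 = "T2"))
  # targets g1,g2,g3,g5,g6: overlap 3 with term T1 = {g1..g4}
  res <- hypergeom_enrichment(c("g1", "g2", "g3", "g5", "g6"), ann, universe)
  # universe 10, term size 4, draw 5, overlap 3: exact tail = 66/252
  t1 <- res[res$term == "T1", ]
  expect_equal(t1$p, 66 / 252, tolerance = 1e-12)
  expect_equal(t1$p, oracle_hypergeom_tail(3, 4, 10, 5), tolerance = 1e-12)
  # zero overlap reports p = 1
  res0 <- hypergeom_enrichment(paste0("g", 8:10), ann, universe)
  expect_equal(res0$p[res0$term == "T1"], 1.0)
  # Bonferroni over tested terms
  expect_equal(t1$p_adj, min(1, t1$p * nrow(res)))
  # a term above the size cap is excluded
  gt <- stats::setNames(rep(list("BIG"), 10), paste0("g", 1:10))
  gt$g1 <- c("BIG", "SMALL"); gt$g2 <- c("BIG", "SMALL")
  big <- annotation_map(gt)
  res_cap <- hypergeom_enrichment(paste0("g", 1:3), big, universe,
                                  size_cap = 5L)
  expect_false("BIG" %in% res_cap$term)
  expect_true("SMALL" %in% res_cap$term)
  # empty target set: empty result
  expect_equal(nrow(hypergeom_enrichment(character(0), ann, universe)), 0L)
})

test_that("go_metric reports the median over TFs passing the significance cap", {
  # synthetic fixture engineered so best -log10 p per TF is known
  genes <- paste0("g", 1:60)
  tfs <- c("A", "B", "C")
  m <- matrix(0, 3, 60, dimnames = list(tfs, genes))
  # each TF's top-10 targets exactly cover its own term
  m["A", 1:10] <- seq(1, 0.1, length.out = 10)
  m["B", 11:20] <- seq(1, 0.1, length.out = 10)
  m["C", c(21:25, 55:59)] <- seq(1, 0.1, length.out = 10)
  ann <- annotation_map(c(
    stats::setNames(rep(list("TA"), 10), genes[1:10]),
    stats::setNames(rep(list("TB"), 10), genes[11:20]),
    stats::setNames(rep(list("TC"), 5), genes[21:25])))
  net <- weighted_network(m)
  gm <- go_metric(net, ann, grid = 10L, sig_cap = 4)
  bt <- tfmapr:::go_best_terms(net, ann, 10L)[["10"]]
  # A and B have perfect 10/10 overlaps; C only 5/10 from its term
  expect_equal(gm$n_passed, sum(bt$neglogp > 4))
  expect_equal(gm$value, stats::median(bt$neglogp[bt$neglogp > 4]))
  # relabeling terms leaves the metric unchanged
  ann2 <- annotation_map(lapply(ann$gene_terms, function(x) paste0("X_", x)))
  expect_equal(go_metric(net, ann2, grid = 10L)$value, gm$value)
  # when no TF passes, the point is an explicit missing marker
  expect_true(is.na(go_metric(net, ann, grid = 10L, sig_cap = 1e6)$value))
})

test_that("go_directness matches a per-TF brute-force recount", {
  set.seed(93)
  cfg <- synthetic_config(n_tfs = 6L, n_genes = 80L, targets_per_tf = 15,
                          seed = 31L)
  truth <- simulate_ground_truth(cfg)
  ann <- simulate_annotation(truth)
  labels <- simulate_binding_labels(truth, fp_rate = 0.02, fn_rate = 0.2)
  net <- truth$network
  gd <- go_directness(net, ann, labels, grid = 10L)
  # independent recount: per TF, best term over its top-10 targets, then the
  # labeled fraction of annotated targets
  bt <- tfmapr:::go_best_terms(net, ann, 10L)[["10"]]
  pcts <- c()
  for (i in seq_along(bt$tf)) {
    if (bt$neglogp[i] <= 4) next
    tf <- bt$tf[i]
    ann_targets <- bt$targets[[i]][vapply(bt$targets[[i]], function(g) {
      bt$term[i] %in% (ann$gene_terms[[g]] %||% character(0))
    }, logical(1))]
    if (length(ann_targets) == 0) next
    pcts <- c(pcts, 100 * mean(unclass(labels)[tf, ann_targets] == 1))
  }
  expect_equal(gd$value, mean(pcts))
  expect_equal(gd$median_value, stats::median(pcts))
  expect_equal(gd$n_tfs, length(pcts))
})

test_that("jaccard similarity follows its set identities", {
  expect_equal(jaccard(c("g1", "g2"), c("g1", "g2")), 1.0)
  expect_equal(jaccard(c("g1"), c("g2")), 0.0)
  expect_equal(jaccard(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 0)
})

test_that("ppi_metric equals brute-force enumeration on a 5-TF fixture", {
  set.seed(17)
  tfs <- paste0("T", 1:5); genes <- sprintf("g%02d", 1:30)
  m <- matrix(rnorm(150), 5, 30, dimnames = list(tfs, genes))
  net <- weighted_network(m)
  it <- interaction_table(c("T1", "T2", "T4"), c("T2", "T3", "T5"),
                          c(0.9, 0.65, 0.8))
  pm <- ppi_metric(net, it, t = 5L, n_grid = c(2L, 5L, 10L), conf = 0.7)
  # brute force: all pairs, per-TF top-5 target sets by |score|
  tops <- lapply(tfs, function(tf) {
    names(sort(rank(-abs(m[tf, ]))))[1:5]
  })
  names(tops) <- tfs
  pairs <- t(utils::combn(tfs, 2))
  jac <- apply(pairs, 1, function(p) {
    a <- tops[[p[1]]]; b <- tops[[p[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  sup <- apply(pairs, 1, function(p) interaction_score(it, p[1], p[2]) >= 0.7)
  ord <- order(-jac, pairs[, 1], pairs[, 2])
  for (i in seq_len(nrow(pm))) {
    n <- min(pm$n[i], length(ord))
    expect_equal(pm$value[i], 100 * mean(sup[ord][1:n]))
  }
  # scale invariance and TF-order symmetry
  pm2 <- ppi_metric(weighted_network(3 * m), it, t = 5L,
                    n_grid = c(2L, 5L, 10L))
  expect_equal(pm2$value, pm$value)
  pm3 <- ppi_metric(weighted_network(m[rev(tfs), ]), it, t = 5L,
                    n_grid = c(2L, 5L, 10L))
  expect_equal(pm3$value, pm$value)

  # degenerate cases
  two <- weighted_network(matrix(c(1, 2, 1, 2), 2, 2,
                                 dimnames = list(c("A", "B"), c("x", "y"))))
  strong <- interaction_table("A", "B", 0.9)
  expect_equal(ppi_metric(two, strong, t = 2L, n_grid = 1L)$value, 100)
  none <- interaction_table(character(0), character(0), numeric(0))
  expect_true(all(ppi_metric(net, none, t = 5L)$value == 0))
})

test_that("auroc and auprc match brute-force oracles and handle ties", {
  # perfect and inverted rankings
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auroc(s, y), 1.0)
  expect_equal(auprc(s, y), 1.0)
  expect_equal(auroc(rev(s), y), 0.0)

  set.seed(44)
  for (i in 1:20) {
    score <- sample(round(runif(12), 1))  # coarse grid forces ties
    label <- rbinom(12, 1, 0.4)
    if (length(unique(label)) < 2) next
    expect_equal(auroc(score, label), oracle_auroc(score, label))
    expect_equal(auprc(score, label), oracle_auprc(score, label))
  }
  expect_error(auroc(s, rep(1, 6)), "classes")

  # network interface drops missing cells and self-edges
  net <- toy_network(c(0.9, 0.1, 0.8, 0.2), c("A", "B"), c("g1", "g2"))
  lab <- toy_binary(c(1, 0, 1, 0), c("A", "B"), c("g1", "g2"))
  expect_equal(auroc(net, lab), 1.0)
})

test_that("permute_network preserves the score multiset and randomizes support", {
  b <- ref_bench()
  net <- b$nets$de
  p1 <- permute_network(net, seed = 5L)
  expect_identical(sort(unclass(p1)[!is.na(p1)]),
                   sort(unclass(net)[!is.na(net)]))
  expect_identical(unclass(permute_network(net, seed = 5L)), unclass(p1))
  expect_false(identical(unclass(p1), unclass(net)))

  # binding support of permuted networks hovers at the label base rate
  base <- 100 * mean(unclass(b$bm$labels) == 1, na.rm = TRUE)
  vals <- vapply(1:20, function(s) {
    binding_metric(permute_network(net, seed = s), b$bm$labels,
                   grid = 10L)$value
  }, 0)
  expect_lt(abs(mean(vals) - base), 5)
})
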