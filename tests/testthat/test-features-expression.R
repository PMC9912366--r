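test_that("de_score computes thresholded log2 fold-changes", {
  # hand fixture: controls average to known values; G1 overexpression sample
  # doubles G3 (log2 +1.0)
  expr <- tiny_expression()
  pmap <- tiny_pmap()
  de <- de_score(expr, pmap, tau = 0.38)
  # control means: G1 1.0, G2 0.5, G3 2.0, G4 0.0
  expect_equal(de["G1", "G3"], 1.0)           # 3.0 - 2.0
  expect_equal(de["G1", "G4"], 0)             # |0.0| <= tau
  expect_true(is.na(de["G1", "G1"]))          # self-edge
  expect_equal(de["G2", "G3"], 0)             # identical to control mean
  # thresholding boundary is inclusive: |LFC| == tau zeroes
  v <- c(0.5, -0.2, 0.38, -0.4)
  zeroed <- ifelse(abs(v) <= 0.38, 0, v)
  expect_equal(zeroed, c(0.5, 0, 0, -0.4))
  m <- matrix(v, 1, 4, dimnames = list("T1", paste0("g", 1:4)))
  # idempotence of the tau-zeroing
  z1 <- ifelse(abs(m) <= 0.38, 0, m)
  expect_equal(ifelse(abs(z1) <= 0.38, 0, z1), z1)
})

test_that("de_score handles controls, missing TFs, and time courses", {
  expr <- tiny_expression()
  # the constructor already refuses maps without controls
  expect_error(perturbation_map(colnames(expr), rep("G1", 5),
                                rep("overexpression", 5)), "control")
  # a map whose control rows were edited away downstream still errors
  pm <- tiny_pmap()
  pm$mechanism[pm$mechanism == "none"] <- "overexpression"
  pm$perturbed_tf[is.na(pm$perturbed_tf)] <- "G3"
  expect_error(de_score(expr, pm), "control")

  # never-perturbed TF requested in the universe: missing-marker row
  de <- de_score(expr, tiny_pmap(), tfs = c("G1", "G2", "G9"))
  expect_true(all(is.na(de["G9", ])))

  # multi-timepoint: the max-|LFC| time point wins, sign preserved
  m <- rbind(G1 = c(0, 0, 0, 0), G2 = c(1, 1, 1.6, 0.2))
  colnames(m) <- c("c1", "c2", "t15", "t30")
  pm2 <- perturbation_map(colnames(m), c(NA, NA, "G1", "G1"),
                          c("none", "none", "deletion", "deletion"),
                          c(NA, NA, 15, 30))
  de2 <- de_score(expression_matrix(m), pm2, tau = 0.38)
  expect_equal(de2["G1", "G2"], -0.8)  # t30 LFC -0.8 beats t15 +0.6
})

test_that("lasso_scores recovers a strong linear driver and rejects noise", {
  recovered <- 0; clean <- 0; null_zero <- 0
  for (sd in 1:5) {
    set.seed(200 + sd)
    n <- 20
    tf1 <- rnorm(n); tf2 <- rnorm(n); tf3 <- rnorm(n)
    g <- 2 * tf1
    g_null <- rnorm(n)
    m <- rbind(TF1 = tf1, TF2 = tf2, TF3 = tf3, GX = g, GN = g_null)
    colnames(m) <- sprintf("s%02d", seq_len(n))
    net <- lasso_scores(expression_matrix(m), c("TF1", "TF2", "TF3"),
                        seed = sd)
    if (abs(net["TF1", "GX"] - 2) < 0.2) recovered <- recovered + 1
    if (all(abs(net[c("TF2", "TF3"), "GX"]) < 0.05)) clean <- clean + 1
    if (all(net[, "GN"] == 0)) null_zero <- null_zero + 1
  }
  expect_gte(recovered, 4)
  expect_gte(clean, 4)
  expect_gte(null_zero, 4)  # independent noise: all-zero at CV penalty
})

test_that("constant series yield zero scores with warnings", {
  m <- rbind(TF1 = rep(1, 6), TF2 = rnorm(6), G1 = rnorm(6))
  colnames(m) <- paste0("s", 1:6)
  expr <- expression_matrix(m)
  # the constant series warns both as predictor and as response
  w <- capture_warnings(net <- lasso_scores(expr, c("TF1", "TF2"), seed = 1))
  expect_true(any(grepl("constant", w)))
  expect_true(all(net["TF1", !is.na(net["TF1", ])] == 0))
  expect_warning(sp <- spearman_scores(expr, c("TF1", "TF2")), "zero-variance")
  expect_true(all(sp["TF1", !is.na(sp["TF1", ])] == 0))
})

test_that("tree_ensemble_scores ranks a step-function driver above noise", {
  wins <- 0
  for (sd in 1:10) {
    set.seed(300 + sd)
    n <- 30
    tf1 <- rnorm(n); tf2 <- rnorm(n)
    g <- ifelse(tf1 > 0, 2, -2) + rnorm(n, 0, 0.2)
    m <- rbind(TF1 = tf1, TF2 = tf2, GX = g)
    colnames(m) <- sprintf("s%02d", seq_len(n))
    net <- tree_ensemble_scores(expression_matrix(m), c("TF1", "TF2"),
                                seed = sd)
    if (net["TF1", "GX"] > net["TF2", "GX"]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("tree importances are nonnegative and constant input gives zeros", {
  m <- rbind(TF1 = rep(2, 5), TF2 = rep(1, 5), G1 = rep(0, 5))
  colnames(m) <- paste0("s", 1:5)
  net <- tree_ensemble_scores(expression_matrix(m), c("TF1", "TF2"), seed = 1)
  expect_true(all(net[!is.na(net)] == 0))
  b <- ref_bench()$nets$bart
  expect_true(all(b[!is.na(b)] >= 0))
})

test_that("spearman_scores matches the rank formula and its bounds", {
  m <- rbind(TF = c(1, 2, 3, 4), GU = c(10, 20, 30, 40),
             GD = c(8, 6, 4, 2), GM = c(2, 1, 4, 3))
  colnames(m) <- paste0("s", 1:4)
  sp <- spearman_scores(expression_matrix(m), "TF")
  expect_equal(sp["TF", "GU"], 1.0)
  expect_equal(sp["TF", "GD"], -1.0)
  # hand rank formula: 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0,?): ranks of
  # (2,1,4,3) against (1,2,3,4) give sum(d^2)=4 -> 1 - 24/60 = 0.6
  expect_equal(sp["TF", "GM"], 0.6)
})

test_that("evidence scores are invariant to sample order", {
  set.seed(77)
  m <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("G", 1:8), paste0("s", 1:12)))
  expr <- expression_matrix(m)
  perm <- expression_matrix(m[, sample(ncol(m))])
  tfs <- c("G1", "G2", "G3")
  expect_equal(unclass(lasso_scores(expr, tfs, seed = 5)),
               unclass(lasso_scores(perm, tfs, seed = 5)))
  expect_equal(unclass(tree_ensemble_scores(expr, tfs, seed = 5)),
               unclass(tree_ensemble_scores(perm, tfs, seed = 5)))
  expect_equal(unclass(spearman_scores(expr, tfs)),
               unclass(spearman_scores(perm, tfs)))
  pmap <- perturbation_map(colnames(m), c(NA, NA, NA, rep("G1", 9)),
                           c(rep("none", 3), rep("deletion", 9)))
  expect_equal(unclass(de_score(expr, pmap)), unclass(de_score(perm, pmap)))
})

test_that("assemble_features builds the edge x evidence table", {
  tfs <- c("A", "B"); genes <- c("g1", "g2", "g3")
  nets <- list(de = toy_network(1:6, tfs, genes),
               lasso = toy_network(seq(0.1, 0.6, by = 0.1), tfs, genes),
               bart = toy_network(rep(1, 6), tfs, genes),
               pwm = toy_network(rep(2, 6), tfs, genes))
  ft <- assemble_features(nets)
  expect_equal(nrow(ft), 6L)                  # 2 TFs x 3 genes, no self-edges
  expect_equal(feature_names(ft), c("de", "lasso", "bart", "pwm"))

  # eight features (two-dataset variant)
  nets8 <- c(nets, stats::setNames(nets, paste0(names(nets), "_2")))
  expect_length(feature_names(assemble_features(nets8)), 8L)

  # an edge covered by one network only gets missing markers elsewhere
  ft2 <- assemble_features(list(
    de = toy_network(1:2, "A", c("g1", "g2")),
    lasso = toy_network(5, "A", "g9")))
  row <- ft2[ft2$gene == "g9", ]
  expect_true(is.na(row$de) && row$lasso == 5)

  # labels attach only to labeled TFs
  lab <- toy_binary(c(1, 0, 1), "A", genes)
  ft3 <- assemble_features(nets["de"], lab)
  expect_equal(ft3$label[ft3$tf == "A" & ft3$gene == "g1"], 1)
  expect_true(all(is.na(ft3$label[ft3$tf == "B"])))

  expect_error(assemble_features(list(toy_network(1, "A", "g1"))), "name")

  # self-edges never appear
  self_net <- toy_network(1:4, c("g1", "g2"), c("g1", "g2"))
  ft4 <- assemble_features(list(de = self_net))
  expect_false(any(ft4$tf == ft4$gene))
})

test_that("feature tables round-trip through TSV", {
  ft <- ref_bench()$features[1:50, ]
  attr(ft, "feature_names") <- feature_names(ref_bench()$features)
  class(ft) <- c("feature_table", "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(ft, path)
  back <- load_features(path)
  expect_equal(feature_names(back), feature_names(ft))
  expect_equal(back$label, ft$label)
  expect_equal(back$de, ft$de, tolerance = 1e-5)  # 6 significant digits
})
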