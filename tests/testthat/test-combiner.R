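test_that("make_folds partitions TFs, stratified and balanced", {
  genes <- paste0("g", 1:40)
  lab <- matrix(0, 10, 40, dimnames = list(paste0("T", 1:10), genes))
  lab[, 1:5] <- 1
  folds <- make_folds(binary_network(lab), k = 10L, seed = 3L)
  expect_setequal(names(folds), paste0("T", 1:10))
  expect_equal(sort(unname(folds)), 1:10)  # one TF per fold

  # 10 low-positive + 10 high-positive TFs into 10 folds: one of each
  lab2 <- matrix(0, 20, 40, dimnames = list(paste0("T", 1:20), genes))
  lab2[1:10, 1] <- 1          # low stratum: 1 positive
  lab2[11:20, 1:30] <- 1      # high stratum: 30 positives
  folds2 <- make_folds(binary_network(lab2), k = 10L, seed = 7L)
  for (f in 1:10) {
    members <- names(folds2)[folds2 == f]
    expect_length(members, 2L)
    expect_length(intersect(members, paste0("T", 1:10)), 1L)
    expect_length(intersect(members, paste0("T", 11:20)), 1L)
  }

  # determinism and the too-many-folds error
  expect_identical(folds2, make_folds(binary_network(lab2), 10L, seed = 7L))
  expect_error(make_folds(binary_network(lab), k = 11L), "folds")
})

test_that("hyperparameter tuning honors grid order and degenerate labels", {
  ft <- ref_bench()$features
  g1 <- default_hyper_grid()[1L, ]
  expect_identical(tune_hyperparameters(ft, g1), g1)  # size-1 grid: no CV

  bad <- ft
  bad$label[!is.na(bad$label)] <- 1
  expect_error(tune_hyperparameters(bad, test_grid()), "degenerate")

  # a stump-depth model loses to a deeper one on an interaction (XOR) toy
  set.seed(31)
  n_tf <- 20; n_g <- 30
  tfs <- sprintf("T%02d", 1:n_tf)
  rows <- expand.grid(tf = tfs, gene = sprintf("g%02d", 1:n_g),
                      stringsAsFactors = FALSE)
  a <- runif(nrow(rows)); b <- runif(nrow(rows))
  lab <- as.numeric(xor(a > 0.5, b > 0.5))
  toy <- data.frame(tf = rows$tf, gene = rows$gene, label = lab,
                    f1 = a, f2 = b)
  toy <- structure(toy, feature_names = c("f1", "f2"),
                   class = c("feature_table", "data.frame"))
  grid <- data.frame(max_depth = c(1L, 4L), eta = 0.3,
                     nrounds = c(20L, 100L), min_child_weight = 1,
                     subsample = 1)
  best <- tune_hyperparameters(toy, grid, inner_k = 3L, seed = 2L)
  expect_equal(best$max_depth, 4L)
})

test_that("the combiner overfits a separable toy and stays within [0,1]", {
  tfs <- sprintf("T%02d", 1:6)
  rows <- expand.grid(tf = tfs, gene = sprintf("g%02d", 1:20),
                      stringsAsFactors = FALSE)
  lab <- rep(c(1, 0), length.out = nrow(rows))
  toy <- structure(
    data.frame(tf = rows$tf, gene = rows$gene, label = lab,
               de = lab, noise = runif(nrow(rows))),
    feature_names = c("de", "noise"), class = c("feature_table", "data.frame"))
  model <- train_combiner(toy, overfit_profile(), seed = 1L)
  p <- predict(model, toy)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auroc(p, toy$label), 1.0)  # training AUROC on separable toy

  # all-one-class refuses to train
  toy$label <- 1
  expect_error(train_combiner(toy, overfit_profile()), "positive")

  # feature-name mismatch is rejected with the offending names
  toy2 <- toy
  attr(toy2, "feature_names") <- c("de", "other")
  names(toy2)[names(toy2) == "noise"] <- "other"
  expect_error(predict(model, toy2), "other")
})

test_that("tree predictions are invariant to positive feature rescaling", {
  ft <- ref_bench()$features[1:2000, ]
  attr(ft, "feature_names") <- c("de", "lasso", "bart")
  class(ft) <- c("feature_table", "data.frame")
  keep <- !is.na(ft$label)
  model <- train_combiner(ft, default_hyper_grid()[2L, ], seed = 5L)
  scaled <- ft
  scaled$de <- scaled$de * 1000
  model2 <- local({
    f <- scaled
    train_combiner(f, default_hyper_grid()[2L, ], seed = 5L)
  })
  expect_equal(predict(model2, scaled), predict(model, ft), tolerance = 1e-6)
})

test_that("generalization mode never predicts a TF with its own labels", {
  gen <- ref_generalization()
  for (a in gen$audit) {
    for (f in seq_along(a$training_tfs)) {
      held_out <- names(a$fold_plan)[a$fold_plan == f]
      expect_length(intersect(held_out, a$training_tfs[[f]]), 0L)
    }
  }
  m <- unclass(gen$mean)
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  # seed-mean equals the average of per-seed networks
  stack <- simplify2array(lapply(gen$per_seed, unclass))
  expect_equal(m, apply(stack, c(1, 2), mean))
})

test_that("integration mode reduces to one full-table model at group_size all", {
  ft <- ref_bench()$features[ref_bench()$features$tf %in%
                               sprintf("G%04d", 1:8), ]
  attr(ft, "feature_names") <- c("de", "lasso", "bart")
  class(ft) <- c("feature_table", "data.frame")
  int_all <- run_integration(ft, group_size = "all", seed = 9L)
  # group "all" trains one model on every labeled edge
  manual <- train_combiner(ft, overfit_profile(),
                           seed = tfmapr:::derive_seed(9L, 1L))
  pred <- predict(manual, ft)
  expect_equal(unname(int_all[cbind(ft$tf, ft$gene)]), unname(pred),
               tolerance = 1e-7)

  # unlabeled TF directs the user to generalization mode
  ft2 <- ft
  ft2$label[ft2$tf == "G0001"] <- NA
  expect_error(run_integration(ft2, 1L), "generalization")
})

test_that("integration with the overfit profile drives training log-loss below a tuned fit", {
  ft <- ref_bench()$features
  keep <- !is.na(ft$label)
  over <- train_combiner(ft, overfit_profile(), seed = 2L)
  mild <- train_combiner(ft, test_grid()[1L, ], seed = 2L)
  logloss <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  p_over <- predict(over, ft)[keep]
  p_mild <- predict(mild, ft)[keep]
  y <- ft$label[keep]
  expect_lt(logloss(p_over, y), logloss(p_mild, y))
})

test_that("cross-trained mode aligns columns and matches the all-group reduction", {
  ft <- ref_bench()$features
  hp <- test_grid()[2L, ]
  net_ab <- run_cross_trained(ft, ft, hyperparameters = hp, seed = 6L)
  model <- train_combiner(ft, hp, seed = 6L)
  expect_equal(unname(net_ab[cbind(ft$tf, ft$gene)]),
               unname(predict(model, ft)), tolerance = 1e-7)

  # mismatched feature roles are rejected, naming the offender
  ft_b <- ft
  names(ft_b)[names(ft_b) == "bart"] <- "trees"
  attr(ft_b, "feature_names") <- c("de", "lasso", "trees")
  expect_error(run_cross_trained(ft, ft_b), "trees")

  # a TF absent from A's labels still gets predictions over B
  ft_unlab <- ft
  ft_unlab$label[ft_unlab$tf == "G0001"] <- NA
  net <- run_cross_trained(ft_unlab, ft, hyperparameters = hp, seed = 6L)
  expect_true(all(!is.na(net["G0001", setdiff(colnames(net), "G0001")])))
})

test_that("a saved combiner reloads and predicts identically", {
  ft <- ref_bench()$features
  model <- train_combiner(ft, test_grid()[1L, ], seed = 11L)
  dir <- withr::local_tempdir()
  save_combiner(model, dir)
  back <- load_combiner(dir)
  expect_identical(back$feature_names, model$feature_names)
  expect_equal(predict(back, ft), predict(model, ft), tolerance = 1e-7)
})

test_that("constrained ranking keeps only positively labeled edges", {
  tfs <- c("A", "B"); genes <- c("g1", "g2", "g3")
  pred <- toy_network(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), tfs, genes)
  all1 <- toy_binary(rep(1, 6), tfs, genes)
  expect_equal(unclass(constrained_ranking(pred, all1)), unclass(pred))
  all0 <- toy_binary(rep(0, 6), tfs, genes)
  expect_true(all(unclass(constrained_ranking(pred, all0)) == 0, na.rm = TRUE))
  mixed <- toy_binary(c(1, 0, 1, 0, 1, 0), tfs, genes)
  cr <- constrained_ranking(pred, mixed)
  nz <- which(unclass(cr) != 0)
  expect_true(all(unclass(mixed)[nz] == 1))   # nonzero => labeled
})

test_that("calibration curves report expected and observed support", {
  tfs <- "A"; genes <- paste0("g", 1:2)
  pred <- toy_network(c(1.0, 0.0), tfs, genes)
  lab <- toy_binary(c(1, 0), tfs, genes)
  cc <- calibration_curve(pred, lab, n_grid = 1L)
  expect_equal(cc$expected, 100)
  expect_equal(cc$observed, 100)

  set.seed(12)
  genes <- paste0("g", 1:400)
  lab2 <- toy_binary(rbinom(400, 1, 0.5), "A", genes)
  pred2 <- toy_network(rep(0.5, 400), "A", genes)
  cc2 <- calibration_curve(pred2, lab2, n_grid = 400L)
  expect_equal(cc2$expected, 50)
  expect_lt(abs(cc2$observed - 50), 8)   # sampling error at n=400
})

test_that("training-TF subsampling is seeded and bounded", {
  lab <- ref_bench()$bm$labels
  sets <- subsample_training_tfs(lab, n_tfs = 10L, repeats = 5L, seed = 8L)
  expect_length(sets, 5L)
  expect_true(all(vapply(sets, length, 0L) == 10L))
  expect_identical(sets, subsample_training_tfs(lab, 10L, 5L, seed = 8L))
  full <- subsample_training_tfs(lab, n_tfs = nrow(lab), repeats = 2L)
  expect_true(all(vapply(full, identical, logical(1), sort(rownames(lab)))))
  expect_error(subsample_training_tfs(lab, nrow(lab) + 1L), "exceeds")
})

test_that("out-of-fold performance sits at the base rate when labels are permuted", {
  set.seed(60)
  tfs <- sprintf("T%02d", 1:15)
  rows <- expand.grid(tf = tfs, gene = sprintf("g%02d", 1:30),
                      stringsAsFactors = FALSE)
  ft <- structure(
    data.frame(tf = rows$tf, gene = rows$gene,
               label = rbinom(nrow(rows), 1, 0.2),
               f1 = rnorm(nrow(rows)), f2 = rnorm(nrow(rows))),
    feature_names = c("f1", "f2"), class = c("feature_table", "data.frame"))
  gen <- run_generalization(ft, k = 5L, seeds = 1:10,
                            grid = default_hyper_grid()[2L, ], inner_k = 2L)
  lab_net <- binary_network(
    local({
      m <- matrix(NA_real_, 15, 30, dimnames = list(tfs, sprintf("g%02d", 1:30)))
      m[cbind(ft$tf, ft$gene)] <- ft$label
      m
    }))
  aps <- vapply(gen$per_seed, function(net) auprc(net, lab_net), 0)
  expect_lt(abs(mean(aps) - 0.2), 0.05)
})
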