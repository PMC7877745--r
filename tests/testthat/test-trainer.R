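test_that("pose labelling implements the positive band, the gap and the negative cutoff", {
  pol <- label_policy()
  expect_equal(label_pose(c(1.0, 0.05, 2.5, 4.2, 0.1, 1.5, 4.0), pol),
               c("positive", "excluded", "excluded", "negative",
                 "positive", "positive", "negative"))
  expect_error(label_pose(-0.1, pol), class = "rls_data_error")
  expect_error(label_policy(pos_low = 2, pos_high = 1), class = "rls_usage_error")
})

test_that("feature rescaling maps training data into [0,1] and inverts exactly", {
  set.seed(2)
  X <- matrix(rnorm(60, 5, 3), ncol = 3)
  sc <- rligscore:::fit_scaler(X)
  Xs <- rligscore:::apply_scaler(sc, X)
  expect_true(all(Xs >= 0 & Xs <= 1))
  expect_equal(apply(Xs, 2, min), rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(Xs, 2, max), rep(1, 3), ignore_attr = TRUE)
  back <- sweep(sweep(Xs, 2, sc$max - sc$min, "*"), 2, sc$min, "+")
  expect_equal(back, X, tolerance = 1e-12)
})

test_that("ENN removes exactly the planted mislabelled point and matches a brute-force oracle", {
  # tight positive cluster with one mislabelled interloper, distant negatives
  X <- matrix(c(0, 0.02, 0.04, 0.06, 0.9, 0.95, 1.0), ncol = 1)
  lab <- c("positive", "positive", "negative", "positive",
           "negative", "negative", "negative")
  keep <- enn_filter(X, lab, k = 3)
  expect_identical(keep, c(1L, 2L, 4L, 5L, 6L, 7L))
  # unanimity: unchanged
  expect_identical(enn_filter(X, rep("positive", 7), k = 3), 1:7)
  # brute-force oracle on random data
  set.seed(7)
  Xr <- matrix(runif(40), ncol = 2)
  labr <- sample(c("positive", "negative"), 20, replace = TRUE)
  keep_pkg <- enn_filter(Xr, labr, k = 3)
  oracle_keep <- which(vapply(seq_len(20), function(i) {
    d <- sqrt(colSums((t(Xr) - Xr[i, ])^2)); d[i] <- Inf
    nn <- order(d)[1:3]
    tab <- table(labr[nn])
    labr[i] %in% names(tab)[tab == max(tab)]
  }, logical(1)))
  expect_identical(keep_pkg, oracle_keep)
  # tiny input returned unchanged with a warning
  expect_warning(k2 <- enn_filter(Xr[1:3, , drop = FALSE], labr[1:3], k = 3))
  expect_identical(k2, 1:3)
})

test_that("class balancing undersamples the majority deterministically", {
  lab <- c(rep("positive", 100), rep("negative", 300))
  keep <- balance_classes(lab, seed = 5)
  expect_equal(sum(lab[keep] == "positive"), 100)
  expect_equal(sum(lab[keep] == "negative"), 100)
  expect_identical(keep, balance_classes(lab, seed = 5))
  expect_false(identical(keep, balance_classes(lab, seed = 6)))
  lab5050 <- rep(c("positive", "negative"), 25)
  expect_identical(balance_classes(lab5050, seed = 1), 1:50)
  expect_error(balance_classes(rep("positive", 10), seed = 1),
               class = "rls_data_error")
  # survivors are a subset of the input indices
  expect_true(all(keep %in% seq_along(lab)))
})

test_that("ligand clustering recovers planted fingerprint blocks and handles edge cases", {
  mkfp <- function(on) { f <- logical(256); f[on] <- TRUE; f }
  set.seed(3)
  block1 <- lapply(1:3, function(i) mkfp(c(1:40, 200 + i)))
  block2 <- lapply(1:3, function(i) mkfp(c(101:140, 240 + i)))
  fps <- c(block1, block2)
  cl <- cluster_ligands(fps, k = 2)
  expect_length(unique(cl[1:3]), 1)
  expect_length(unique(cl[4:6]), 1)
  expect_false(cl[1] == cl[4])
  # exhaustive medoid-pair oracle: the 2-medoid solution with minimal cost
  # induces the same partition
  D <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) D[i, j] <- 1 - tanimoto(fps[[i]], fps[[j]])
  best <- NULL; best_cost <- Inf
  for (i in 1:5) for (j in (i + 1):6) {
    cost <- sum(pmin(D[, i], D[, j]))
    if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
  }
  oracle_part <- as.integer(D[, best[1]] <= D[, best[2]])
  expect_length(unique(paste(cl, oracle_part)), 2)  # identical partitions
  expect_identical(cluster_ligands(fps, k = 1), rep(1L, 6))
  expect_error(cluster_ligands(fps, k = 9), class = "rls_usage_error")
  # identical fingerprints co-cluster
  cl2 <- cluster_ligands(c(block1[1], block1[1], block2[1]), k = 2)
  expect_equal(cl2[1], cl2[2])
})

test_that("path fingerprints separate dissimilar templates and are permutation invariant", {
  a <- ligand_fingerprint(ligand_template("ring_hydroxyl"))
  b <- ligand_fingerprint(ligand_template("chain_amine"))
  c_ <- ligand_fingerprint(ligand_template("charged_acid"))
  expect_equal(tanimoto(a, a), 1)
  expect_lt(tanimoto(a, b), 0.5)
  expect_lt(tanimoto(a, c_), 0.8)
  mol <- ligand_template("chain_amine")
  set.seed(9)
  perm <- sample(nrow(mol$atoms))
  inv <- match(seq_along(perm), perm)
  mol2 <- mol
  mol2$atoms <- mol$atoms[perm, ]
  mol2$bonds$i <- inv[mol$bonds$i]; mol2$bonds$j <- inv[mol$bonds$j]
  expect_identical(ligand_fingerprint(mol2), b)
})

test_that("kNN probability is the positive fraction among nearest stored records", {
  X <- matrix(c(0, 0, 0.1, 0, 0.2, 0, 1, 1, 1, 0.9), ncol = 2, byrow = TRUE)
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  fit <- rligscore:::knn_fit(X, y, 3)
  # hand-computed neighbour set of (0,0): rows 1,2,3 -> 2/3 positive
  expect_equal(rligscore:::knn_predict(fit, matrix(c(0, 0), 1)), 2 / 3)
  # all-positive / all-negative neighbourhoods
  fit5 <- rligscore:::knn_fit(X, c(TRUE, TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(rligscore:::knn_predict(fit5, matrix(c(0, 0), 1)), 1)
  expect_equal(rligscore:::knn_predict(fit5, matrix(c(1, 1), 1)), 0)
  # distance ties broken by stored order: two equidistant refs, k = 1
  fit_tie <- rligscore:::knn_fit(matrix(c(-1, 0, 1, 0), 2, byrow = TRUE),
                                 c(TRUE, FALSE), 1)
  expect_equal(rligscore:::knn_predict(fit_tie, matrix(c(0, 0), 1)), 1)
})

test_that("the MLP forward pass reproduces nnet's own predictions", {
  set.seed(4)
  X <- matrix(runif(200), ncol = 2)
  y <- as.numeric(X[, 1] + X[, 2] > 1)
  net <- nnet::nnet(x = X, y = y, size = 4, decay = 0.01, maxit = 100,
                    entropy = TRUE, trace = FALSE)
  fit <- list(size = 4, n_in = 2, wts = net$wts)
  expect_equal(rligscore:::mlp_predict(fit, X),
               as.numeric(stats::predict(net, X)), tolerance = 1e-9)
})

test_that("training drops sparse groups, separates separable data and is seed-deterministic", {
  cd <- make_contact_dataset(300, groups = c("G:N9:HDON", "A:C4':LIPO"), seed = 11)
  # plant a group with only 7 positives (below the threshold of 10)
  cd2 <- rbind(cd, make_contact_dataset(7, groups = "U:N1:AROM", seed = 12))
  model <- suppressWarnings(rlsf_train(cd2, "knn", seed = 1))
  expect_false("U:N1:AROM" %in% names(model$groups))
  drow <- model$manifest[model$manifest$key == "U:N1:AROM", ]
  expect_equal(drow$status, "dropped")
  expect_equal(drow$n_pos, 7)
  expect_true(all(c("G:N9:HDON", "A:C4':LIPO") %in% names(model$groups)))

  # linearly separable synthetic group: held-out accuracy 1.0
  sep <- make_contact_dataset(100, groups = "G:N9:HDON", seed = 14,
                              pos_d_mean = 2.5, pos_d_sd = 0.15)
  sep$d[sep$label == "negative"] <- runif(sum(sep$label == "negative"), 7, 9)
  msep <- suppressWarnings(rlsf_train(sep, "knn", seed = 1))
  expect_equal(msep$manifest$cv_accuracy[msep$manifest$status == "retained"], 1.0)

  expect_error(suppressWarnings(rlsf_train(cd[0, ], "knn")), class = "rls_data_error")

  # determinism: identical seeds give identical manifests and predictions
  m1 <- suppressWarnings(rlsf_train(cd, "knn", seed = 3))
  m2 <- suppressWarnings(rlsf_train(cd, "knn", seed = 3))
  expect_identical(m1$manifest, m2$manifest)
  expect_identical(predict(m1, cd[1:50, ]), predict(m2, cd[1:50, ]))
})

test_that("grid search never selects a configuration that scored strictly worse", {
  cd <- make_contact_dataset(200, groups = "G:N9:HDON", seed = 21)
  grid <- lapply(c(3, 7, 25), function(k) list(k = k))
  model <- suppressWarnings(rlsf_train(cd, "knn", grid = grid, seed = 2))
  b <- model$groups[["G:N9:HDON"]]
  # recompute all CV scores with the package's own folds machinery
  feats <- b$features
  df <- cd[cd$key == "G:N9:HDON", ]
  X <- as.matrix(df[, feats]); ok <- complete.cases(X)
  expect_true(!is.na(model$manifest$cv_accuracy[model$manifest$status == "retained"]))
  chosen <- model$manifest$config[model$manifest$status == "retained"]
  expect_match(chosen, "^k=")
})

test_that("predictions are probabilities and NA for unmodelled groups", {
  cd <- make_contact_dataset(200, groups = "G:N9:HDON", seed = 31)
  model <- suppressWarnings(rlsf_train(cd, "knn", seed = 1))
  other <- make_contact_dataset(10, groups = "A:C4':LIPO", seed = 32)
  p_in <- predict(model, cd)
  expect_true(all(p_in >= 0 & p_in <= 1))
  expect_true(all(is.na(predict(model, other))))
  # positives score higher than negatives on average (sanity of the model)
  expect_gt(mean(p_in[cd$label == "positive"]),
            mean(p_in[cd$label == "negative"]))
})
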