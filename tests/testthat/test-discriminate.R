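test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(41)
  for (rep in 1:300) {
    n_case <- sample(2:15, 1)
    n_ctrl <- sample(2:15, 1)
    vals <- sample(0:9, n_case + n_ctrl, replace = TRUE)  # ties common
    lab <- sample_labels(sprintf("s%02d", seq_along(vals)),
                         rep(c("case", "control"), c(n_case, n_ctrl)))
    names(vals) <- names(lab)
    a <- auc(vals, lab)
    ca <- vals[lab == "case"]; co <- vals[lab == "control"]
    wins <- sum(outer(ca, co, ">")) + 0.5 * sum(outer(ca, co, "=="))
    expect_identical(a$raw, wins / (n_case * n_ctrl))
    expect_identical(a$folded, max(a$raw, 1 - a$raw))
  }
})

test_that("AUC handles the canonical small examples", {
  lab <- sample_labels(letters[1:4], c("case", "case", "control", "control"))
  a <- auc(c(a = 1, b = 3, c = 2, d = 4), lab)
  expect_identical(a$raw, 0.25)
  expect_identical(a$folded, 0.75)
  expect_identical(auc(c(a = 9, b = 8, c = 1, d = 2), lab)$raw, 1)
  expect_identical(auc(c(a = 5, b = 5, c = 5, d = 5), lab)$raw, 0.5)
})

test_that("AUC is invariant under monotone transforms and antisymmetric", {
  set.seed(42)
  for (rep in 1:25) {
    vals <- rnorm(12)
    lab <- sample_labels(sprintf("s%02d", 1:12),
                         rep(c("case", "control"), each = 6))
    names(vals) <- names(lab)
    a <- auc(vals, lab)
    expect_equal(auc(exp(vals), lab)$raw, a$raw)
    expect_equal(auc(rank(vals), lab)$raw, a$raw)
    neg <- -vals
    expect_equal(auc(neg, lab)$raw + a$raw, 1)
    expect_gte(a$folded, 0.5)
  }
})

test_that("the Youden cutoff matches an exhaustive midpoint scan", {
  lab4 <- sample_labels(letters[1:4], c("case", "case", "control", "control"))
  r <- best_cutoff(c(a = 1, b = 2, c = 9, d = 10), lab4)
  expect_identical(r$cutoff, 5.5)
  expect_identical(r$direction, "case_low")
  expect_identical(r$youden, 1)
  expect_identical(r$sensitivity, 1)
  expect_identical(r$specificity, 1)

  set.seed(43)
  for (rep in 1:50) {
    vals <- round(rnorm(14), 1)
    lab <- sample_labels(sprintf("s%02d", 1:14),
                         rep(c("case", "control"), each = 7))
    names(vals) <- names(lab)
    r <- best_cutoff(vals, lab)
    # independent exhaustive scan over the same candidate cutoffs
    u <- sort(unique(vals))
    cuts <- (u[-1] + u[-length(u)]) / 2
    is_case <- lab == "case"
    best_j <- -Inf; best_cut <- NA
    for (cut in cuts) {
      pred <- if (r$direction == "case_low") vals < cut else vals > cut
      j <- sum(pred & is_case) / 7 + sum(!pred & !is_case) / 7 - 1
      if (j > best_j + 1e-12) { best_j <- j; best_cut <- cut }
    }
    expect_equal(r$youden, best_j)
    expect_identical(r$cutoff, best_cut)
  }
})

test_that("stepwise selects exactly a dominant planted marker", {
  fix <- marker_tpm(seed = 1, k = 9, n = 40, shift_sd = 6)
  sw <- suppressWarnings(stepwise_logistic_aic(fix$genes, fix$tpm, fix$labels))
  expect_identical(sw$selected, "G01")
  expect_identical(sw$trace$move[1], "start")
  expect_error(stepwise_logistic_aic(sprintf("G%02d", 1:16), fix$tpm, fix$labels),
               "15 candidates")
})

test_that("stepwise agrees with exhaustive subsets in the moderate regime for most seeds", {
  agree <- 0
  for (s in 1:10) {
    fix <- marker_tpm(seed = s + 700, k = 6, n = 80, shift_sd = 1)
    sw <- suppressWarnings(stepwise_logistic_aic(fix$genes, fix$tpm, fix$labels))
    ex <- exhaustive_subset_aic(fix$genes, fix$tpm, fix$labels)
    agree <- agree + identical(sort(sw$selected), ex$set)
  }
  expect_gte(agree, 8)
})

test_that("stepwise usually selects nothing from small noise panels", {
  empty <- 0
  for (s in 1:10) {
    fix <- marker_tpm(seed = s + 800, k = 3, n = 40, shift_sd = 0)
    sw <- suppressWarnings(stepwise_logistic_aic(fix$genes, fix$tpm, fix$labels))
    empty <- empty + (length(sw$selected) == 0)
  }
  expect_gte(empty, 6)
})

test_that("interaction screening retains only real interactions", {
  # planted multiplicative interaction between G01 and G02: class depends
  # on the product of the centered TPM values only
  set.seed(44)
  n <- 60
  g1 <- pmax(500 + 150 * rnorm(n), 10)
  g2 <- pmax(500 + 150 * rnorm(n), 10)
  g3 <- pmax(500 + 150 * rnorm(n), 10)
  pr <- g1 * g2
  y <- as.integer(pr + stats::sd(pr) * rnorm(n, 0, 0.3) > median(pr))
  if (sum(y) < 3 || sum(1 - y) < 3) y[1:3] <- 1L - y[1:3]
  m <- rbind(G01 = g1, G02 = g2, G03 = g3)
  m <- rbind(m, FILLER = 1e6 - colSums(m))
  colnames(m) <- sprintf("s%02d", 1:n)
  tpm <- tpm_matrix(m)
  lab <- sample_labels(colnames(m), ifelse(y == 1, "case", "control"))
  scan <- suppressWarnings(interaction_scan("G01", c("G02", "G03"), tpm, lab))
  expect_true(scan$retained[scan$gene == "G02"])
  expect_gt(scan$delta_aic[scan$gene == "G02"], 1)

  # when the base gene already explains the classes, a duplicate of the
  # base adds a collinear product term and no improvement
  fix <- marker_tpm(seed = 49, k = 3, n = 40, shift_sd = 4)
  md <- unclass(fix$tpm)
  md <- rbind(md[c("G01", "G02", "G03"), ], G04 = md["G01", ])
  md <- rbind(md, FILLER = 1e6 - colSums(md))
  scan2 <- suppressWarnings(
    interaction_scan("G01", "G04", tpm_matrix(md), fix$labels))
  expect_false(scan2$retained)
  expect_error(interaction_scan("G01", c("G01", "G02"), tpm, lab), "base gene")
})

test_that("noise interactions are rarely retained", {
  kept <- 0
  for (s in 1:25) {
    fix <- marker_tpm(seed = s + 900, k = 3, n = 50, shift_sd = 2)
    scan <- suppressWarnings(
      interaction_scan("G01", c("G02", "G03"), fix$tpm, fix$labels))
    kept <- kept + sum(scan$retained)
  }
  # penalty of 2 per parameter dominates: ~ 50 screens, few retained
  expect_lte(kept, 8)
})

test_that("the classification tree selects the separating gene deterministically", {
  fix <- marker_tpm(seed = 45, k = 9, n = 30, shift_sd = 8)
  tree <- fit_tree(fix$genes, fix$tpm, fix$labels)
  expect_identical(tree$used_genes, "G01")
  expect_identical(tree$node$gene, "G01")
  preds <- predict(tree, t(unclass(fix$tpm)[fix$genes, ]))
  expect_identical(preds, as.integer(fix$labels == "case"))

  # root split threshold equals an independent brute-force Gini scan
  X <- t(unclass(fix$tpm)[fix$genes, ])
  y <- as.integer(fix$labels == "case")
  best <- list(g = Inf, cut = NA, j = NA)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    for (cut in (u[-1] + u[-length(u)]) / 2) {
      l <- X[, j] <= cut
      if (sum(l) < 2 || sum(!l) < 2) next
      gini <- function(v) 2 * mean(v) * (1 - mean(v))
      g <- (sum(l) * gini(y[l]) + sum(!l) * gini(y[!l])) / length(y)
      if (g < best$g - 1e-12) best <- list(g = g, cut = cut, j = j)
    }
  }
  expect_identical(tree$node$cut, best$cut)
  expect_identical(tree$node$gene, fix$genes[best$j])

  # pure-noise labels on constant features: no split, empty used-gene set
  flat <- matrix(100, 2, 30, dimnames = list(c("A", "B"), names(fix$labels)))
  flat <- rbind(flat, FILLER = 1e6 - colSums(flat))
  tree0 <- fit_tree(c("A", "B"), tpm_matrix(flat), fix$labels)
  expect_true(tree0$node$leaf)
  expect_identical(tree0$used_genes, character(0))
})

test_that("LOOCV is perfect for a separating feature and seeded", {
  fix <- marker_tpm(seed = 46, k = 2, n = 20, shift_sd = 8)
  cv <- loocv_ensemble("G01", fix$tpm, fix$labels, ensemble_size = 100, seed = 1)
  expect_identical(cv$sensitivity, 1)
  expect_identical(cv$specificity, 1)
  cv2 <- loocv_ensemble("G01", fix$tpm, fix$labels, ensemble_size = 100, seed = 1)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("LOOCV tracks the Gaussian single-threshold accuracy", {
  # single feature, two unit-variance Gaussians two standard deviations
  # apart: the optimal single-threshold accuracy is pnorm(1) ~ 0.841
  set.seed(1)
  n <- 100
  vals <- c(rnorm(n / 2, 2), rnorm(n / 2, 0))
  m <- rbind(G1 = exp(vals), G2 = rep(1, n))
  m <- sweep(m, 2, colSums(m), "/") * 1e6
  colnames(m) <- sprintf("s%03d", seq_len(n))
  lab <- sample_labels(colnames(m), rep(c("case", "control"), each = n / 2))
  cv <- loocv_ensemble("G1", tpm_matrix(m), lab, ensemble_size = 300, seed = 1)
  expect_lt(abs(cv$sensitivity - pnorm(1)), 0.1)
  expect_lt(abs(cv$specificity - pnorm(1)), 0.1)
})

test_that("the discrimination report ties the pieces together", {
  fix <- marker_tpm(seed = 48, k = 4, n = 30, shift_sd = 6)
  subnets <- list(
    list(id = 1, genes = c("G01", "G02"),
         edges = data.frame(parent = "G01", child = "G02", delta = 2)),
    list(id = 2, genes = c("G03", "G04"),
         edges = data.frame(parent = "G03", child = "G04", delta = 1)))
  subnets <- subnetwork_stats(subnets, fix$tpm, fix$labels)
  rep <- suppressWarnings(
    discrimination_report(subnets, fix$tpm, fix$labels,
                          pipeline_config(ensemble_size = 100)))
  expect_true(all(rep$stepwise$selected %in% rep$candidates))
  expect_true(all(rep$tree_genes %in% rep$candidates))
  expect_identical(rep$primary, "G01")
  expect_identical(rep$loocv_features, "G01")
  expect_identical(rep$interactions$retained, rep$interactions$delta_aic > 1)
  expect_output(print(rep), "primary marker")
})
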