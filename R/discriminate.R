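#' Area under the ROC curve by pair counting
#'
#' Raw AUC is the probability that a random case sample outranks a random
#' control sample, computed exactly as
#' `(wins + 0.5 * ties) / (n_case * n_control)` over all case/control
#' pairs. The folded AUC is `max(raw, 1 - raw)`, so markers that are lower
#' in cases score the same as markers that are higher in cases.
#'
#' @param values Per-sample marker values (named or in label order).
#' @param labels A [sample_labels()] factor.
#' @return List with `raw` and `folded`.
#' @export
#' @examples
#' lab <- sample_labels(c("a", "b", "c", "d"), c("case", "case", "control", "control"))
#' auc(c(a = 1, b = 3, c = 2, d = 4), lab)   # raw 0.25, folded 0.75
auc <- function(values, labels) {
  if (!is.null(names(values))) values <- values[names(labels)]
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ca <- values[is_case]; co <- values[!is_case]
  # rank-sum form of exact pair counting (ties averaged)
  r <- rank(c(ca, co), ties.method = "average")
  raw <- (sum(r[seq_along(ca)]) - length(ca) * (length(ca) + 1) / 2) /
    (length(ca) * length(co))
  list(raw = raw, folded = max(raw, 1 - raw))
}

#' Best discrimination cutoff by the Youden index
#'
#' The marker direction (case-low vs case-high) is fixed by the folded AUC,
#' then all midpoints between adjacent sorted unique values are scanned and
#' the cutoff maximizing Youden's `J = sensitivity + specificity - 1` is
#' returned (ties: the smallest cutoff). Cases are called below the cutoff
#' for a case-low marker and above it for a case-high marker.
#'
#' @inheritParams auc
#' @param gene Optional gene ID recorded in the result.
#' @return Object of class `roc_result`: `gene`, `auc_raw`, `auc_folded`,
#'   `cutoff`, `sensitivity`, `specificity`, `direction`
#'   (`"case_low"`/`"case_high"`), `youden`.
#' @export
best_cutoff <- function(values, labels, gene = NA_character_) {
  if (!is.null(names(values))) values <- values[names(labels)]
  a <- auc(values, labels)
  direction <- if (a$raw < 0.5) "case_low" else "case_high"
  is_case <- labels == "case"
  u <- sort(unique(values))
  cuts <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else u
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred_case <- if (direction == "case_low") values < cuts[i] else values > cuts[i]
    sens[i] <- sum(pred_case & is_case) / sum(is_case)
    spec[i] <- sum(!pred_case & !is_case) / sum(!is_case)
  }
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1]   # cuts ascending -> smallest wins ties
  structure(list(gene = gene, auc_raw = a$raw, auc_folded = a$folded,
                 cutoff = cuts[best], sensitivity = sens[best],
                 specificity = spec[best], direction = direction,
                 youden = J[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("%s: folded AUC %.3f, cutoff %.4g (%s), sens %.2f / spec %.2f\n",
              if (is.na(x$gene)) "marker" else x$gene,
              x$auc_folded, x$cutoff, x$direction, x$sensitivity, x$specificity))
  invisible(x)
}

# --- logistic fitting with separation handling ----------------------------

# Fit case ~ X by ML logistic regression; when the fit separates
# (diverging coefficients), refit with a small ridge penalty and report the
# AIC of the unpenalized log-likelihood at the penalized coefficients.
fit_logistic <- function(X, y, ridge = 1e-6) {
  df <- as.data.frame(X)
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  eps <- 1e-8
  separated <- !fit$converged || anyNA(stats::coef(fit)) ||
    any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  if (!separated) {
    return(list(aic = fit$aic, coef = stats::coef(fit), separated = FALSE))
  }
  warning("separation detected in logistic fit: applying ridge penalty", call. = FALSE)
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  # standardize columns so the ridge is scale-equivariant and Newton is
  # well conditioned; coefficients are mapped back afterwards
  ctr <- c(0, colMeans(Xm[, -1, drop = FALSE]))
  scl <- c(1, pmax(apply(Xm[, -1, drop = FALSE], 2, stats::sd), 1e-12))
  Xs <- sweep(sweep(Xm, 2, ctr), 2, scl, "/")
  p <- ncol(Xs)
  pen_obj <- function(beta) {
    eta <- drop(Xs %*% beta)
    -sum(y * eta - log1p(exp(eta))) + ridge / 2 * sum(beta^2)
  }
  beta <- rep(0, p)
  obj <- pen_obj(beta)
  converged <- FALSE
  for (it in seq_len(200)) {
    eta <- drop(Xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xs, Xs * w) + diag(ridge, p)
    g <- crossprod(Xs, y - mu) - ridge * beta
    step <- drop(solve(H, g))
    # step halving on the penalized objective
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (pen_obj(cand) <= obj + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta_new <- beta + lam * step
    obj_new <- pen_obj(beta_new)
    done <- max(abs(beta_new - beta)) < 1e-8 || abs(obj - obj_new) < 1e-12
    beta <- beta_new
    obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) stop("logistic fit failed to converge", call. = FALSE)
  eta <- drop(Xs %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  beta_orig <- beta / scl
  beta_orig[1] <- beta[1] - sum(beta[-1] * ctr[-1] / scl[-1])
  list(aic = -2 * ll + 2 * p,
       coef = stats::setNames(beta_orig, colnames(Xm)), separated = TRUE)
}

#' Bidirectional stepwise logistic regression by AIC
#'
#' Starting from the intercept-only model, repeatedly applies the single
#' add-or-drop move that most decreases `AIC = -2 logLik + 2k`, stopping
#' when no move strictly decreases it. Genes with complete separation are
#' handled with a small ridge penalty.
#'
#' @param candidates Character vector of candidate gene IDs (<= 15).
#' @param tpm A [tpm_matrix()] (markers are used on the TPM scale).
#' @param labels A [sample_labels()] factor.
#' @return List with `selected` (gene IDs, possibly empty), `aic` of the
#'   final model, and `trace` (data.frame of accepted moves).
#' @export
stepwise_logistic_aic <- function(candidates, tpm, labels) {
  if (length(candidates) > 15) stop("at most 15 candidates supported", call. = FALSE)
  labels <- align_labels(labels, colnames(tpm))
  if (sum(labels == "case") < 3 || sum(labels == "control") < 3) {
    stop("both groups need at least 3 samples", call. = FALSE)
  }
  y <- as.integer(labels == "case")
  X_all <- t(unclass(tpm)[candidates, , drop = FALSE])
  aic_of <- function(set) {
    if (length(set) == 0) {
      mu <- mean(y)
      ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
      return(-2 * ll + 2)
    }
    fit_logistic(X_all[, set, drop = FALSE], y)$aic
  }
  current <- character(0)
  current_aic <- aic_of(current)
  trace <- data.frame(move = "start", gene = NA_character_, aic = current_aic,
                      stringsAsFactors = FALSE)
  repeat {
    moves <- rbind(
      if (length(current) < length(candidates))
        data.frame(move = "add", gene = setdiff(candidates, current),
                   stringsAsFactors = FALSE),
      if (length(current) > 0)
        data.frame(move = "drop", gene = current, stringsAsFactors = FALSE)
    )
    if (is.null(moves) || nrow(moves) == 0) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      set <- if (moves$move[i] == "add") c(current, moves$gene[i])
             else setdiff(current, moves$gene[i])
      aic_of(set)
    }, 0)
    best <- order(moves$aic, moves$gene)[1]
    if (moves$aic[best] >= current_aic - 1e-8) break
    current <- if (moves$move[best] == "add") c(current, moves$gene[best])
               else setdiff(current, moves$gene[best])
    current_aic <- moves$aic[best]
    trace <- rbind(trace, moves[best, c("move", "gene", "aic")])
  }
  rownames(trace) <- NULL
  list(selected = sort(current), aic = current_aic, trace = trace)
}

#' Screen pairwise interactions with a base marker by AIC
#'
#' For each other gene `g`, compares the base logistic model
#' (`case ~ base`) with the model adding the product term `base * g`.
#' `delta_aic = AIC_base - AIC_interaction`; the interaction is retained
#' only when the improvement exceeds 1.
#'
#' @param base Gene ID of the base marker.
#' @param others Character vector of genes to screen (must not contain
#'   `base`).
#' @inheritParams stepwise_logistic_aic
#' @return data.frame with `gene`, `delta_aic`, `retained`.
#' @export
interaction_scan <- function(base, others, tpm, labels) {
  if (base %in% others) stop("base gene must not appear in others", call. = FALSE)
  labels <- align_labels(labels, colnames(tpm))
  y <- as.integer(labels == "case")
  xb <- unclass(tpm)[base, ]
  base_aic <- fit_logistic(matrix(xb, ncol = 1, dimnames = list(NULL, base)), y)$aic
  rows <- lapply(others, function(g) {
    X <- cbind(xb, xb * unclass(tpm)[g, ])
    colnames(X) <- c(base, paste0(base, ":", g))
    d <- base_aic - fit_logistic(X, y)$aic
    data.frame(gene = g, delta_aic = d, retained = d > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- Gini classification tree ---------------------------------------------

gini_impurity <- function(y) {
  if (length(y) == 0) return(0)
  p <- mean(y)
  2 * p * (1 - p)
}

# Exhaustive best split over the given features: minimal weighted Gini;
# ties broken by lower feature index, then smaller threshold.
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    cuts <- (u[-1] + u[-length(u)]) / 2
    for (cut in cuts) {
      left <- X[, j] <= cut
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      g <- (nl * gini_impurity(y[left]) + (n - nl) * gini_impurity(y[!left])) / n
      if (is.null(best) || g < best$gini - 1e-12) {
        best <- list(feature = j, cut = cut, gini = g)
      }
    }
  }
  best
}

#' Greedy Gini classification tree
#'
#' A small deterministic CART: binary splits chosen by exhaustive threshold
#' scan minimizing weighted Gini impurity, maximum depth 3, minimum leaf
#' size 2, ties broken by lower gene index then smaller threshold. Used for
#' variable selection: the set of genes appearing in splits is returned
#' alongside the tree.
#'
#' @param candidates Character vector of candidate gene IDs.
#' @param tpm A [tpm_matrix()].
#' @param labels A [sample_labels()] factor.
#' @param max_depth Maximum tree depth (root split = depth 1).
#' @param min_leaf Minimum samples per leaf.
#' @return Object of class `gini_tree`: list with `node` (nested tree) and
#'   `used_genes`.
#' @export
fit_tree <- function(candidates, tpm, labels, max_depth = 3L, min_leaf = 2L) {
  labels <- align_labels(labels, colnames(tpm))
  X <- t(unclass(tpm)[candidates, , drop = FALSE])
  y <- as.integer(labels == "case")
  used <- character(0)

  grow <- function(idx, depth) {
    ysub <- y[idx]
    leaf <- list(leaf = TRUE, n = length(idx),
                 pred = if (mean(ysub) > 0.5) 1L else 0L)
    if (depth > max_depth || length(unique(ysub)) == 1 ||
        length(idx) < 2 * min_leaf) {
      return(leaf)
    }
    sp <- best_split(X[idx, , drop = FALSE], ysub, min_leaf)
    if (is.null(sp) || sp$gini >= gini_impurity(ysub) - 1e-12) return(leaf)
    used <<- union(used, candidates[sp$feature])
    left <- idx[X[idx, sp$feature] <= sp$cut]
    right <- setdiff(idx, left)
    list(leaf = FALSE, gene = candidates[sp$feature], cut = sp$cut,
         n = length(idx),
         left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  node <- grow(seq_along(y), 1L)
  structure(list(node = node, used_genes = sort(used), candidates = candidates),
            class = "gini_tree")
}

#' Predict case/control from a fitted Gini tree
#'
#' @param object A `gini_tree`.
#' @param newdata Samples-by-genes matrix or data.frame containing the
#'   candidate genes used by the tree.
#' @param ... Unused.
#' @return Integer vector (1 = case, 0 = control).
#' @export
predict.gini_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[[node$gene]] <= node$cut) node$left else node$right
    }
    node$pred
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object$node, newdata[i, ]), 0L)
}

#' @export
print.gini_tree <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%sleaf: predict %s (n=%d)\n", pad,
                  if (node$pred == 1) "case" else "control", node$n))
    } else {
      cat(sprintf("%s%s <= %.4g (n=%d)\n", pad, node$gene, node$cut, node$n))
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$node, 0)
  invisible(x)
}

#' Leave-one-out cross-validated bagged-tree classification
#'
#' Each sample is held out in turn; a bagged ensemble of depth-limited
#' trees (bootstrap rows, random feature subset per split when more than
#' one feature is supplied) is fitted on the remaining samples via the
#' randomForest package and the held-out sample is predicted by majority
#' vote. Pooled held-out predictions give sensitivity (`TP / (TP + FN)`,
#' case = positive) and specificity (`TN / (TN + FP)`). Fully seeded: every
#' fold's RNG stream derives from `seed`.
#'
#' @param genes Feature gene IDs (typically the single best representative).
#' @param tpm A [tpm_matrix()].
#' @param labels A [sample_labels()] factor.
#' @param ensemble_size Trees per fold.
#' @param seed Master seed.
#' @return List with `sensitivity`, `specificity`, `confusion` (2x2 table),
#'   `predictions` (named factor).
#' @export
loocv_ensemble <- function(genes, tpm, labels, ensemble_size = 500L, seed = 1L) {
  labels <- align_labels(labels, colnames(tpm))
  n <- length(labels)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  X <- t(unclass(tpm)[genes, , drop = FALSE])
  colnames(X) <- genes
  y <- factor(as.character(labels), levels = c("control", "case"))
  preds <- factor(rep(NA_character_, n), levels = c("control", "case"))
  names(preds) <- names(labels)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) == 1) {
      warning("degenerate training fold with one class: predicting majority",
              call. = FALSE)
      preds[i] <- as.character(ytr[1])
      next
    }
    set.seed(stage_seed(seed, "loocv", i))
    fit <- randomForest::randomForest(
      x = as.data.frame(X[-i, , drop = FALSE]), y = ytr,
      ntree = ensemble_size, nodesize = 2)
    preds[i] <- as.character(stats::predict(fit,
      newdata = as.data.frame(X[i, , drop = FALSE])))
  }
  tp <- sum(preds == "case" & y == "case")
  fn <- sum(preds == "control" & y == "case")
  tn <- sum(preds == "control" & y == "control")
  fp <- sum(preds == "case" & y == "control")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(predicted = c("control", "case"),
                                          truth = c("control", "case"))),
       predictions = preds)
}

#' Assemble the marker discrimination report
#'
#' Runs the full discrimination analysis on the subnetwork representatives:
#' per-gene ROC results, stepwise-AIC logistic selection, Gini-tree
#' selection, the pairwise interaction screen around the primary marker,
#' and LOOCV of the primary marker with the bagged ensemble. The primary
#' marker is the first stepwise-selected gene (falling back to the best
#' folded-AUC representative when the stepwise selection is empty).
#'
#' @param subnets Completed subnetworks from [subnetwork_stats()].
#' @param tpm A [tpm_matrix()].
#' @param labels A [sample_labels()] factor.
#' @param config A [pipeline_config()].
#' @param loocv_all_representatives Use all representatives (rather than the
#'   single primary marker) as LOOCV features.
#' @return Object of class `discrimination_report`.
#' @export
discrimination_report <- function(subnets, tpm, labels,
                                  config = pipeline_config(),
                                  loocv_all_representatives = FALSE) {
  labels <- align_labels(labels, colnames(tpm))
  reps <- vapply(subnets, function(s) s$representative, "")
  reps <- unique(reps)
  roc <- lapply(reps, function(g) best_cutoff(unclass(tpm)[g, ], labels, gene = g))
  names(roc) <- reps
  sw <- stepwise_logistic_aic(reps, tpm, labels)
  tree <- fit_tree(reps, tpm, labels)
  folded <- vapply(roc, function(r) r$auc_folded, 0)
  primary <- if (length(sw$selected) > 0) sw$selected[[1]] else
    reps[order(-folded, reps)][1]
  inter <- if (length(reps) > 1) {
    interaction_scan(primary, setdiff(reps, primary), tpm, labels)
  } else {
    data.frame(gene = character(0), delta_aic = numeric(0), retained = logical(0))
  }
  feats <- if (loocv_all_representatives) reps else primary
  cv <- loocv_ensemble(feats, tpm, labels,
                       ensemble_size = config$ensemble_size, seed = config$seed)
  structure(list(candidates = reps, roc = roc, stepwise = sw,
                 tree_genes = tree$used_genes, tree = tree,
                 primary = primary, interactions = inter,
                 loocv_features = feats, loocv = cv,
                 ensemble_size = config$ensemble_size, seed = config$seed),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Marker discrimination report\n")
  cat("  candidates:        ", paste(x$candidates, collapse = ", "), "\n")
  cat("  stepwise selected: ",
      if (length(x$stepwise$selected) == 0) "(none)" else
        paste(x$stepwise$selected, collapse = ", "),
      sprintf(" (AIC %.2f)\n", x$stepwise$aic))
  cat("  tree selected:     ",
      if (length(x$tree_genes) == 0) "(none)" else
        paste(x$tree_genes, collapse = ", "), "\n")
  cat("  primary marker:    ", x$primary, "\n")
  cat(sprintf("  LOOCV (features: %s): sensitivity %.2f, specificity %.2f\n",
              paste(x$loocv_features, collapse = ","),
              x$loocv$sensitivity, x$loocv$specificity))
  invisible(x)
}
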