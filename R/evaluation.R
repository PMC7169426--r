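#' External cross-validated classification error of selected features
#'
#' Assesses a feature-selection configuration without selection bias: in
#' each of `folds` stratified folds, feature ranking is performed ONLY on
#' the training part, the top-s features are taken for every requested
#' signature size, an RBF-kernel SVM is (optionally grid-tuned and) trained
#' on the training part restricted to those features, and the
#' misclassification fraction is scored on the held-out part. Held-out
#' samples never influence selection or tuning.
#'
#' Setting `protocol = "naive"` deliberately runs the ranking once on the
#' full data before cross-validation — the biased protocol whose
#' optimistic error the external protocol exists to avoid — so the
#' selection-bias effect can be demonstrated side by side.
#'
#' @param X Features x samples matrix.
#' @param y Labels.
#' @param sizes Integer vector of signature sizes to sweep (< number of
#'   features).
#' @param folds Number of CV folds (default 10); `folds = ncol(X)` gives
#'   leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @param mode,elim_percent,cost Selector configuration, passed to
#'   [recursive_eliminate()].
#' @param tune_costs,tune_gammas Optional RBF grids; when both are given
#'   each fold's classifier is tuned by inner cross-validation on the
#'   training part via [tune_rbf_grid()]; otherwise the classifier uses
#'   `eval_cost` and gamma = 1/s.
#' @param inner_folds Inner CV folds for tuning (default 3).
#' @param eval_cost RBF cost when not tuning (default 1).
#' @param protocol `"external"` (default) or `"naive"` (selection on the
#'   full data before CV; biased, for demonstration only).
#' @return Object of class `cv_result`: list with `per_size_errors` (named
#'   mean error per size), `fold_errors` (folds x sizes matrix),
#'   `mean_error` (over the last size swept), `sizes`, `folds`, `seed`,
#'   `protocol`.
#' @export
external_cv_error <- function(X, y, sizes, folds = 10, seed = 1L,
                              mode = c("significant", "literal", "rfe"),
                              elim_percent = 1, cost = 10,
                              tune_costs = NULL, tune_gammas = NULL,
                              inner_folds = 3, eval_cost = 1,
                              protocol = c("external", "naive")) {
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  yv <- as_pm1(y, n = ncol(X))
  d <- nrow(X); M <- ncol(X)
  sizes <- as.integer(sizes)
  if (any(sizes >= d) || any(sizes < 1L)) {
    stop("every signature size must be in [1, number of features)")
  }
  if (folds < 2L || folds > M) stop("folds must be in [2, number of samples]")
  fold_id <- stratified_folds(yv, folds, seed)

  tune <- !is.null(tune_costs) && !is.null(tune_gammas)
  naive_rank <- if (protocol == "naive") {
    recursive_eliminate(X, yv, mode = mode, elim_percent = elim_percent,
                        cost = cost)
  } else NULL

  fold_err <- matrix(NA_real_, nrow = folds, ncol = length(sizes),
                     dimnames = list(NULL, paste0("s", sizes)))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- setdiff(seq_len(M), test_idx)
    y_tr <- yv[train_idx]
    if (length(unique(y_tr)) < 2L) {
      stop("fold ", f, " leaves a single-class training part; reduce folds")
    }
    rl <- if (protocol == "naive") naive_rank else {
      recursive_eliminate(X[, train_idx, drop = FALSE], y_tr, mode = mode,
                          elim_percent = elim_percent, cost = cost)
    }
    for (si in seq_along(sizes)) {
      s <- sizes[si]
      feat <- rl$order[seq_len(s)]
      Xtr <- t(X[feat, train_idx, drop = FALSE])
      Xte <- t(X[feat, test_idx, drop = FALSE])
      if (tune) {
        tg <- tune_rbf_grid(X[feat, train_idx, drop = FALSE], y_tr,
                            costs = tune_costs, gammas = tune_gammas,
                            inner_folds = inner_folds, seed = seed + f)
        cc <- tg$best["cost"]; gg <- tg$best["gamma"]
      } else {
        cc <- eval_cost; gg <- 1 / s
      }
      fit <- e1071::svm(Xtr, factor(y_tr, levels = c(-1L, 1L)),
                        kernel = "radial", cost = cc, gamma = gg,
                        scale = FALSE)
      pred <- stats::predict(fit, Xte)
      fold_err[f, si] <- mean(as.integer(as.character(pred)) != yv[test_idx])
    }
  }
  per_size <- colMeans(fold_err)
  structure(list(per_size_errors = stats::setNames(per_size, sizes),
                 fold_errors = fold_err,
                 mean_error = unname(per_size[length(per_size)]),
                 sizes = sizes, folds = folds, seed = seed,
                 protocol = protocol, mode = mode),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$protocol, " protocol, ", x$folds, "-fold, mode = ",
      x$mode, "):\n", sep = "")
  print(round(x$per_size_errors, 4))
  invisible(x)
}

# Stratified fold assignment: shuffles each class separately under the
# seed, then deals fold labels round-robin so folds cover all samples
# disjointly and preserve class balance.
stratified_folds <- function(yv, folds, seed) {
  folds <- as.integer(folds)
  fold_id <- integer(length(yv))
  with_seed(seed, {
    offset <- 0L
    for (cls in c(-1L, 1L)) {
      idx <- sample(which(yv == cls))
      fold_id[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold_id
}

#' Grid search for RBF-SVM cost and gamma
#'
#' Exhaustive evaluation of a (cost, gamma) grid by stratified inner
#' cross-validated accuracy on the training data only. Ties are broken
#' toward the smaller cost, then the smaller gamma (the simpler model).
#'
#' @param X_train Features x samples training matrix.
#' @param y_train Labels for the training samples.
#' @param costs,gammas Positive grids (defaults: `2^seq(-5, 15, 2)` and
#'   `2^seq(-15, 3, 2)`).
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Seed for the inner folds.
#' @return Object of class `tuning_grid`: list with `scores`
#'   (costs x gammas accuracy matrix), `costs`, `gammas`, `best` (named
#'   vector: cost, gamma, score).
#' @export
tune_rbf_grid <- function(X_train, y_train,
                          costs = 2^seq(-5, 15, 2),
                          gammas = 2^seq(-15, 3, 2),
                          inner_folds = 5, seed = 1L) {
  if (!length(costs) || !length(gammas)) stop("grids must be non-empty")
  yv <- as_pm1(y_train, n = ncol(X_train))
  inner_folds <- min(inner_folds, min(table(yv)))
  if (inner_folds < 2L) stop("too few samples per class for inner folds")
  fold_id <- stratified_folds(yv, inner_folds, seed)
  Xt <- t(X_train)
  scores <- matrix(NA_real_, nrow = length(costs), ncol = length(gammas),
                   dimnames = list(paste0("C", costs), paste0("g", gammas)))
  for (ci in seq_along(costs)) for (gi in seq_along(gammas)) {
    acc <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold_id != f; te <- !tr
      if (length(unique(yv[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(Xt[tr, , drop = FALSE],
                        factor(yv[tr], levels = c(-1L, 1L)),
                        kernel = "radial", cost = costs[ci],
                        gamma = gammas[gi], scale = FALSE)
      pred <- stats::predict(fit, Xt[te, , drop = FALSE])
      mean(as.integer(as.character(pred)) == yv[te])
    }, numeric(1L))
    scores[ci, gi] <- mean(acc, na.rm = TRUE)
  }
  best_flat <- which(scores == max(scores), arr.ind = TRUE)
  # ties: smaller cost first, then smaller gamma
  best_flat <- best_flat[order(best_flat[, 1L], best_flat[, 2L]), , drop = FALSE]
  bi <- best_flat[1L, ]
  structure(list(scores = scores, costs = costs, gammas = gammas,
                 best = c(cost = costs[bi[1L]], gamma = gammas[bi[2L]],
                          score = scores[bi[1L], bi[2L]])),
            class = "tuning_grid")
}

#' @export
print.tuning_grid <- function(x, ...) {
  cat("tuning_grid:", length(x$costs), "x", length(x$gammas),
      "grid; best cost =", x$best["cost"], ", gamma =", x$best["gamma"],
      ", accuracy =", round(x$best["score"], 4), "\n")
  invisible(x)
}

#' Mean unadjusted p-value by rank position
#'
#' For each rank position j up to `top_n`, averages over the supplied
#' ranked lists the unadjusted two-sided t-test p-value of the feature that
#' occupies position j in each list. The p-values are computed once on the
#' full data (Welch test per feature). With a single list the profile is
#' simply that list's features' p-values in rank order.
#'
#' @param rank_lists List of `ranked_list` objects (e.g. per-bootstrap
#'   rankings) over the features of `X`.
#' @param X Features x samples matrix.
#' @param y Labels.
#' @param top_n How many leading rank positions to profile (default 1000,
#'   clamped to the feature count).
#' @return Numeric vector of length `top_n`; entry j is the mean p-value
#'   at rank position j.
#' @export
rank_position_pvalues <- function(rank_lists, X, y, top_n = 1000) {
  if (!length(rank_lists)) stop("need at least one ranked list")
  N <- nrow(X)
  top_n <- min(as.integer(top_n), N)
  if (top_n < 1L) stop("top_n must be >= 1")
  p <- row_welch_p(X, y)
  mat <- vapply(rank_lists, function(rl) {
    if (length(rl$order) != N) stop("ranked list does not match the matrix features")
    p[rl$order[seq_len(top_n)]]
  }, numeric(top_n))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = top_n)
  rowMeans(mat)
}
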