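#' Train a soft-margin linear SVM
#'
#' Thin wrapper around [e1071::svm()] (libsvm) with a linear kernel and no
#' internal feature scaling, returning the primal weight vector
#' reconstructed from the dual solution, `w = sum_k alpha_k y_k x_k`, with
#' the sign oriented so that a positive decision value
#' `f(x) = sum_j w_j x_j + b` predicts the +1 class.
#'
#' @param X Features x samples numeric matrix (active features only).
#' @param y Labels: a `class_labels` object or a +1/-1 vector, one entry
#'   per sample, both classes present.
#' @param cost Positive regularization parameter C (default 10).
#' @return Object of class `linear_svm`: list with `weights`, `bias`,
#'   `dual_coef` (alpha_k * y_k for the support vectors), `support`
#'   (support-sample column indices), `cost`.
#' @export
train_linear_svm <- function(X, y, cost = 10) {
  stopifnot(is.matrix(X), is.numeric(X))
  yv <- as_pm1(y, n = ncol(X))
  if (ncol(X) < 2L) stop("need at least 2 samples")
  if (!is.finite(cost) || cost <= 0) stop("cost must be a positive scalar")
  fit <- e1071::svm(x = t(X), y = factor(yv, levels = c(-1L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's decision value is positive for the class listed first in
  # fit$labels; flip so positive means class +1
  first_level <- fit$levels[fit$labels[1L]]
  if (first_level == "-1") {
    w <- -w
    b <- -b
    dual <- -drop(fit$coefs)
  } else {
    dual <- drop(fit$coefs)
  }
  names(w) <- rownames(X)
  structure(list(weights = w, bias = b, dual_coef = dual,
                 support = fit$index, cost = cost),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("linear_svm:", length(x$weights), "features,",
      length(x$support), "support vectors, cost =", x$cost, "\n")
  invisible(x)
}

#' Decision values of a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Features x samples matrix with the same features.
#' @param ... Unused.
#' @return Numeric vector `w'x + b` per sample.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  drop(crossprod(newdata, object$weights)) + object$bias
}

#' Two-sample Welch t-test with one-sample fallback
#'
#' For two groups with at least two observations each this is the Welch
#' unequal-variance t statistic with Satterthwaite degrees of freedom. When
#' one group is a singleton, the larger group is tested against a reference
#' mean `mu` (by default the singleton's observed value) with a one-sample
#' t; the sign convention is kept so that a positive statistic always means
#' the +1 group mean exceeds the -1 group mean. The two-sided p-value is
#' the tail probability `P[t(v) < -|u| or t(v) > |u|]`.
#'
#' Degenerate variances never crash: if both groups are constant and equal
#' the result is t = 0, p = 1; if constant but different, p is set to the
#' machine epsilon (maximal significance).
#'
#' @param x_plus,x_minus Numeric value vectors for the +1 and -1 groups.
#' @param reference_mean Optional scalar mu for the singleton fallback.
#' @return Object of class `t_test_result`: list with `t_statistic`, `dof`,
#'   `p_two_sided`, `mean_plus`, `mean_minus`, `sd_plus`, `sd_minus`,
#'   `n_plus`, `n_minus`.
#' @export
welch_t <- function(x_plus, x_minus, reference_mean = NULL) {
  np <- length(x_plus); nm <- length(x_minus)
  if (np < 1L || nm < 1L) stop("both groups must be non-empty")
  if (np < 2L && nm < 2L) stop("at least one group needs n >= 2")
  mp <- mean(x_plus); mm <- mean(x_minus)
  sp <- if (np > 1L) stats::sd(x_plus) else NA_real_
  sm <- if (nm > 1L) stats::sd(x_minus) else NA_real_

  if (np >= 2L && nm >= 2L) {
    vp <- sp^2 / np; vm <- sm^2 / nm
    se2 <- vp + vm
    if (se2 == 0) {
      if (mp == mm) {
        t <- 0; v <- np + nm - 2; p <- 1
      } else {
        t <- sign(mp - mm) * Inf; v <- np + nm - 2; p <- .Machine$double.eps
      }
    } else {
      t <- (mp - mm) / sqrt(se2)
      v <- se2^2 / (vp^2 / (np - 1L) + vm^2 / (nm - 1L))
      p <- 2 * stats::pt(-abs(t), df = v)
    }
  } else {
    # one-sample fallback: test the larger group against mu
    if (np == 1L) {
      mu <- if (is.null(reference_mean)) x_plus else reference_mean
      if (sm == 0) {
        if (mm == mu) { t <- 0; p <- 1 } else { t <- sign(mp - mm) * Inf; p <- .Machine$double.eps }
        v <- nm - 1L
      } else {
        t <- -(mm - mu) / (sm / sqrt(nm))  # positive when plus mean exceeds minus mean
        v <- nm - 1L
        p <- 2 * stats::pt(-abs(t), df = v)
      }
    } else {
      mu <- if (is.null(reference_mean)) x_minus else reference_mean
      if (sp == 0) {
        if (mp == mu) { t <- 0; p <- 1 } else { t <- sign(mp - mm) * Inf; p <- .Machine$double.eps }
        v <- np - 1L
      } else {
        t <- (mp - mu) / (sp / sqrt(np))
        v <- np - 1L
        p <- 2 * stats::pt(-abs(t), df = v)
      }
    }
  }
  structure(list(t_statistic = t, dof = v, p_two_sided = p,
                 mean_plus = mp, mean_minus = mm,
                 sd_plus = sp, sd_minus = sm,
                 n_plus = np, n_minus = nm),
            class = "t_test_result")
}

# Vectorized per-row Welch p-values for a features x samples matrix.
# Same formulas and degenerate-variance policy as welch_t(); used inside
# the elimination loop and for the rank-position p-value profile.
row_welch_p <- function(X, y, reference_mean = NULL) {
  yv <- as_pm1(y, n = ncol(X))
  Xp <- X[, yv == 1L, drop = FALSE]
  Xm <- X[, yv == -1L, drop = FALSE]
  np <- ncol(Xp); nm <- ncol(Xm)
  mp <- rowMeans(Xp); mm <- rowMeans(Xm)
  if (np >= 2L && nm >= 2L) {
    vp <- apply(Xp, 1L, stats::var) / np
    vm <- apply(Xm, 1L, stats::var) / nm
    se2 <- vp + vm
    t <- ifelse(se2 > 0, (mp - mm) / sqrt(se2), 0)
    v <- ifelse(se2 > 0,
                se2^2 / (vp^2 / (np - 1L) + vm^2 / (nm - 1L)),
                np + nm - 2)
    p <- 2 * stats::pt(-abs(t), df = v)
    deg <- se2 == 0 & mp != mm
    p[deg] <- .Machine$double.eps
    p[se2 == 0 & mp == mm] <- 1
  } else {
    p <- vapply(seq_len(nrow(X)), function(i) {
      welch_t(Xp[i, ], Xm[i, ], reference_mean = reference_mean)$p_two_sided
    }, numeric(1L))
  }
  unname(p)
}

#' Per-feature ranking criteria
#'
#' Combines the linear-SVM weight of each surviving feature with its
#' two-sided t-test p-value into the elimination criterion. The feature
#' with the smallest criterion is the next elimination candidate.
#'
#' Modes:
#' \describe{
#'   \item{`significant`}{(default) `c_i = w_i^2 * (1 - p_i)` — monotone in
#'     both the weight magnitude and the significance, so small-weight or
#'     non-significant features are eliminated first.}
#'   \item{`literal`}{`c_i = w_i * p_i`, the raw product of weight and tail
#'     probability.}
#'   \item{`rfe`}{`c_i = w_i^2`, the classical weight-only SVM-RFE
#'     criterion.}
#' }
#'
#' @param weights Numeric weight vector (or a `linear_svm`).
#' @param pvalues Two-sided p-values aligned to `weights`; ignored for
#'   `mode = "rfe"` (may be `NULL` in that case).
#' @param mode One of `"significant"`, `"literal"`, `"rfe"`.
#' @return Object of class `ranking_scores`: list with `criterion`,
#'   `weight_component`, `pvalue_component`, `mode`.
#' @export
ranking_criteria <- function(weights, pvalues = NULL,
                             mode = c("significant", "literal", "rfe")) {
  mode <- match.arg(mode)
  if (inherits(weights, "linear_svm")) weights <- weights$weights
  w <- as.numeric(weights)
  if (mode != "rfe") {
    if (is.null(pvalues)) stop("pvalues required for mode '", mode, "'")
    p <- as.numeric(pvalues)
    if (length(p) != length(w)) {
      stop("length mismatch: ", length(w), " weights vs ", length(p), " p-values")
    }
  } else {
    p <- rep(NA_real_, length(w))
  }
  crit <- switch(mode,
                 rfe = w^2,
                 literal = w * p,
                 significant = w^2 * (1 - p))
  structure(list(criterion = crit, weight_component = w,
                 pvalue_component = p, mode = mode),
            class = "ranking_scores")
}

#' Recursive feature elimination with a significance-weighted criterion
#'
#' Backward elimination over all features: at each iteration a linear SVM
#' is retrained on the surviving features, the per-feature criterion
#' (see [ranking_criteria()]) is computed, and the
#' `max(1, ceiling(elim_percent/100 * n_surviving))` lowest-criterion
#' features are removed and pushed onto the ranked list (worst criterion
#' receives the worst remaining rank). Iteration continues until no feature
#' survives, producing a full permutation with rank 1 = the feature removed
#' last.
#'
#' Ties in the criterion are broken by eliminating the smaller feature
#' index first, so results are deterministic.
#'
#' @param X Features x samples numeric matrix.
#' @param y Labels (`class_labels` or +1/-1 vector).
#' @param mode Ranking criterion mode, see [ranking_criteria()].
#' @param elim_percent Percentage E in (0, 100] of surviving features to
#'   remove per iteration (default 1; 100 reduces to a single-pass sort of
#'   the first-iteration criteria).
#' @param cost SVM cost parameter.
#' @param reference_mean Passed to the t-test's one-sample fallback.
#' @return Object of class `ranked_list`: list with `order` (feature
#'   indices, position 1 = best), `feature_ids` (identifiers in rank
#'   order), `criterion_at_removal` (criterion value each feature had when
#'   eliminated, rank order), `elimination_trace` (data.frame: iteration,
#'   n_surviving, n_removed), `mode`, `elim_percent`, `cost`.
#' @export
recursive_eliminate <- function(X, y,
                                mode = c("significant", "literal", "rfe"),
                                elim_percent = 1, cost = 10,
                                reference_mean = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), is.numeric(X))
  d <- nrow(X)
  if (d < 1L) stop("need at least one feature")
  if (!is.finite(elim_percent) || elim_percent <= 0 || elim_percent > 100) {
    stop("elim_percent must be in (0, 100]")
  }
  yv <- as_pm1(y, n = ncol(X))
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(d))

  s <- seq_len(d)                    # surviving feature indices
  ord <- integer(d)                  # ord[rank position] = feature index
  crit_at_removal <- numeric(d)
  next_worst <- d
  trace <- list()
  iter <- 0L

  while (length(s) > 0L) {
    iter <- iter + 1L
    Xs <- X[s, , drop = FALSE]
    if (length(s) == 1L) {
      # a single survivor needs no retraining to be ranked
      ord[1L] <- s
      crit_at_removal[1L] <- NA_real_
      trace[[iter]] <- data.frame(iteration = iter, n_surviving = 1L,
                                  n_removed = 1L)
      s <- integer(0L)
      break
    }
    fit <- train_linear_svm(Xs, yv, cost = cost)
    pv <- if (mode == "rfe") NULL else row_welch_p(Xs, yv, reference_mean)
    sc <- ranking_criteria(fit$weights, pv, mode = mode)
    m <- max(1L, ceiling(elim_percent / 100 * length(s)))
    m <- min(m, length(s))
    elim_pos <- order(sc$criterion, seq_along(s))[seq_len(m)]  # worst first
    for (j in seq_len(m)) {
      ord[next_worst - j + 1L] <- s[elim_pos[j]]
      crit_at_removal[next_worst - j + 1L] <- sc$criterion[elim_pos[j]]
    }
    next_worst <- next_worst - m
    trace[[iter]] <- data.frame(iteration = iter, n_surviving = length(s),
                                n_removed = m)
    s <- s[-elim_pos]
  }

  structure(list(order = ord,
                 feature_ids = ids[ord],
                 criterion_at_removal = crit_at_removal,
                 elimination_trace = do.call(rbind, trace),
                 mode = mode, elim_percent = elim_percent, cost = cost),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("ranked_list:", length(x$order), "features, mode =", x$mode,
      ", E =", x$elim_percent, "%\n")
  cat("top:", paste(utils::head(x$feature_ids, 5L), collapse = ", "), "...\n")
  invisible(x)
}

#' Classical weight-only SVM-RFE
#'
#' Delegates to [recursive_eliminate()] with `mode = "rfe"`
#' (criterion `w_i^2`).
#'
#' @inheritParams recursive_eliminate
#' @return A `ranked_list`.
#' @export
svm_rfe <- function(X, y, elim_percent = 1, cost = 10) {
  recursive_eliminate(X, y, mode = "rfe", elim_percent = elim_percent,
                      cost = cost)
}

# ranks[feature index] = rank position of that feature in rl
ranks_of <- function(rl) {
  r <- integer(length(rl$order))
  r[rl$order] <- seq_along(rl$order)
  r
}
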