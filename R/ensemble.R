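#' Plan stratified bootstrap subsamples
#'
#' Draws `k` subsample index sets of size `ceiling(fraction * M)` with
#' replacement (the default), stratified so every set preserves the class
#' proportions (rounded) and contains at least two samples of each class.
#' Per-bootstrap seeds are derived from the master seed by the documented
#' scheme `seed_i = master_seed + i`, recorded in the plan so any single
#' bootstrap can be reproduced in isolation.
#'
#' @param labels `class_labels` or +1/-1 vector (length M); each class
#'   must have at least two samples.
#' @param k Number of bootstraps (default 40).
#' @param fraction Subsample fraction in (0, 1] (default 0.9).
#' @param master_seed Integer master seed.
#' @param with_replacement Sample with replacement (default `TRUE`).
#' @return Object of class `bootstrap_plan`: list with `index_sets` (list
#'   of k integer vectors), `seeds`, `k`, `fraction`, `with_replacement`,
#'   `size`, `seed_scheme`.
#' @export
make_bootstrap_plan <- function(labels, k = 40, fraction = 0.9,
                                master_seed = 1L, with_replacement = TRUE) {
  yv <- as_pm1(labels)
  M <- length(yv)
  if (M < 4L) stop("need at least 4 samples")
  np <- sum(yv == 1L); nm <- sum(yv == -1L)
  if (np < 2L || nm < 2L) stop("each class needs >= 2 samples (have ",
                               np, " / ", nm, ")")
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  size <- ceiling(fraction * M)
  if (size < 4L) stop("subsample size ", size, " too small to stratify")
  n_pos <- round(size * np / M)
  n_pos <- min(max(n_pos, 2L), size - 2L)
  n_neg <- size - n_pos
  if (!with_replacement && (n_pos > np || n_neg > nm)) {
    stop("without replacement the strata cannot supply ", n_pos, "+", n_neg,
         " samples")
  }
  pos_idx <- which(yv == 1L); neg_idx <- which(yv == -1L)
  seeds <- as.integer(master_seed) + seq_len(k)
  index_sets <- lapply(seeds, function(sd) {
    with_seed(sd, {
      c(sample(pos_idx, n_pos, replace = with_replacement),
        sample(neg_idx, n_neg, replace = with_replacement))
    })
  })
  structure(list(index_sets = index_sets, seeds = seeds, k = as.integer(k),
                 fraction = fraction, with_replacement = with_replacement,
                 size = size, n_pos = n_pos, n_neg = n_neg,
                 seed_scheme = "seed_i = master_seed + i"),
            class = "bootstrap_plan")
}

#' @export
print.bootstrap_plan <- function(x, ...) {
  cat("bootstrap_plan:", x$k, "sets of", x$size, "samples (",
      x$n_pos, "+ /", x$n_neg, "- ), fraction =", x$fraction,
      if (x$with_replacement) "with" else "without", "replacement\n")
  invisible(x)
}

#' Rank features on every bootstrap subsample
#'
#' Runs [recursive_eliminate()] independently on each planned subsample,
#' returning one full ranked list per bootstrap.
#'
#' @param X Features x samples matrix.
#' @param y Labels.
#' @param plan A `bootstrap_plan` whose indices are valid for `X`.
#' @inheritParams recursive_eliminate
#' @return List of `k` `ranked_list` objects.
#' @export
rank_all_bootstraps <- function(X, y, plan,
                                mode = c("significant", "literal", "rfe"),
                                elim_percent = 1, cost = 10) {
  mode <- match.arg(mode)
  yv <- as_pm1(y, n = ncol(X))
  lapply(seq_along(plan$index_sets), function(i) {
    idx <- plan$index_sets[[i]]
    if (any(idx < 1L | idx > ncol(X))) {
      stop("bootstrap ", i, " has indices outside the sample range")
    }
    yb <- yv[idx]
    if (length(unique(yb)) < 2L) {
      stop("bootstrap ", i, " collapsed to a single class")
    }
    recursive_eliminate(X[, idx, drop = FALSE], yb, mode = mode,
                        elim_percent = elim_percent, cost = cost)
  })
}

#' Complete linear aggregation (CLA) of bootstrap rankings
#'
#' Sums each feature's rank position over all bootstrap ranked lists
#' (optionally weighted per bootstrap); since rank 1 is best, the features
#' with the smallest weighted rank sum form the consensus top of the
#' ensemble ranking. Ties are broken by smaller feature index.
#'
#' @param rank_lists List of `ranked_list` objects over the same features.
#' @param bootstrap_weights Optional numeric weights, one per list
#'   (default all 1).
#' @return Object of class `ensemble_ranking`: list with `aggregated`
#'   (per-feature weighted rank sum, feature order of the input matrix),
#'   `per_bootstrap_ranks` (k x N matrix), `bootstrap_weights`,
#'   `final_order` (feature indices, position 1 = best), `feature_ids`.
#' @export
aggregate_cla <- function(rank_lists, bootstrap_weights = NULL) {
  k <- length(rank_lists)
  if (k < 1L) stop("need at least one ranked list")
  N <- length(rank_lists[[1L]]$order)
  ids <- character(N)
  ids[rank_lists[[1L]]$order] <- rank_lists[[1L]]$feature_ids
  rank_mat <- matrix(NA_integer_, nrow = k, ncol = N)
  for (i in seq_len(k)) {
    rl <- rank_lists[[i]]
    if (length(rl$order) != N) stop("list ", i, " ranks a different feature count")
    this_ids <- character(N)
    this_ids[rl$order] <- rl$feature_ids
    if (!identical(this_ids, ids)) {
      stop("list ", i, " ranks a different feature universe")
    }
    rank_mat[i, ] <- ranks_of(rl)
  }
  if (is.null(bootstrap_weights)) bootstrap_weights <- rep(1, k)
  if (length(bootstrap_weights) != k) stop("need one weight per ranked list")
  aggregated <- drop(crossprod(rank_mat, bootstrap_weights))
  final_order <- order(aggregated, seq_len(N))
  structure(list(aggregated = aggregated,
                 per_bootstrap_ranks = rank_mat,
                 bootstrap_weights = bootstrap_weights,
                 final_order = final_order,
                 feature_ids = ids),
            class = "ensemble_ranking")
}

#' @export
print.ensemble_ranking <- function(x, ...) {
  cat("ensemble_ranking:", length(x$aggregated), "features over",
      nrow(x$per_bootstrap_ranks), "bootstraps\n")
  cat("top:", paste(x$feature_ids[utils::head(x$final_order, 5L)],
                    collapse = ", "), "...\n")
  invisible(x)
}

#' Extract a fixed-size signature
#'
#' The first `s` features of an ensemble (or single) ranking. `s` may be a
#' count or a percentage string such as `"10%"`, resolved as
#' `ceiling(percent * N / 100)`.
#'
#' @param ranking An `ensemble_ranking` or `ranked_list`.
#' @param s Signature size: integer count in (0, N) or `"<pct>%"`.
#' @return Object of class `signature_set`: list with `feature_ids` (size
#'   s, best first), `indices`, `size`, `universe_size`, `source`.
#' @export
extract_signature <- function(ranking, s) {
  if (inherits(ranking, "ensemble_ranking")) {
    ord <- ranking$final_order
    ids <- ranking$feature_ids
    src <- "ensemble"
  } else if (inherits(ranking, "ranked_list")) {
    ord <- ranking$order
    ids <- character(length(ord)); ids[ord] <- ranking$feature_ids
    src <- "single"
  } else stop("ranking must be an ensemble_ranking or ranked_list")
  N <- length(ord)
  if (is.character(s)) {
    pct <- suppressWarnings(as.numeric(sub("%$", "", s)))
    if (is.na(pct)) stop("cannot parse signature size '", s, "'")
    s <- ceiling(pct * N / 100)
  }
  s <- as.integer(s)
  if (is.na(s) || s <= 0L || s >= N) {
    stop("signature size must satisfy 0 < s < N (requested ", s,
         " of ", N, ")")
  }
  idx <- ord[seq_len(s)]
  structure(list(feature_ids = ids[idx], indices = idx, size = s,
                 universe_size = N, source = src),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", x$size, "of", x$universe_size, "features (",
      x$source, ")\n")
  invisible(x)
}

# Run RNG-consuming code under a fixed seed, restoring the caller's
# random state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
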