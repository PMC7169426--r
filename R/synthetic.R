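#' Simulate a two-class expression matrix with planted differential features
#'
#' Emulates the quantile-normalized log-intensity microarray regime: many
#' features, few (possibly unbalanced) samples. Each feature gets a
#' baseline mean drawn once from a wide uniform range (default log2 scale
#' 4-10) and within-class Gaussian noise with standard deviation `sigma`;
#' a chosen subset of "informative" features is additionally shifted by
#' `+delta * sigma` in the +1 class. Optional equicorrelation `rho` among
#' the informative features (single block, shared-factor construction) and
#' a heavy-tailed Student-t noise option are available for robustness
#' studies.
#'
#' @param n_plus,n_minus Samples per class (each >= 2).
#' @param d Number of features.
#' @param n_informative Number of planted differential features (0..d).
#' @param delta Between-class mean shift in units of `sigma` (default 2).
#' @param sigma Within-class standard deviation (default 1).
#' @param rho Equicorrelation among informative features in [0, 1)
#'   (default 0).
#' @param seed Integer seed; the data set is fully reproducible from it.
#' @param baseline_range Range for the per-feature baseline means.
#' @param noise `"gaussian"` (default) or `"t"` (Student t scaled to
#'   standard deviation `sigma`).
#' @param t_df Degrees of freedom for `noise = "t"` (default 3, must be
#'   > 2 so the variance exists).
#' @return Object of class `synthetic_dataset`: list with `matrix`
#'   (features x samples, dimnames set), `labels` (`class_labels`),
#'   `informative_ids`, `delta`, `sigma`, `rho`, `seed`.
#' @export
simulate_two_class <- function(n_plus, n_minus, d, n_informative,
                               delta = 2, sigma = 1, rho = 0, seed = 1L,
                               baseline_range = c(4, 10),
                               noise = c("gaussian", "t"), t_df = 3) {
  noise <- match.arg(noise)
  if (n_plus < 2L || n_minus < 2L) stop("each class needs >= 2 samples")
  if (d < 1L) stop("d must be >= 1")
  if (n_informative < 0L || n_informative > d) {
    stop("n_informative must be in [0, d]")
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (noise == "t" && t_df <= 2) stop("t_df must exceed 2")
  M <- n_plus + n_minus

  out <- with_seed(seed, {
    mu <- stats::runif(d, baseline_range[1L], baseline_range[2L])
    eps <- if (noise == "gaussian") {
      matrix(stats::rnorm(d * M), nrow = d)
    } else {
      matrix(stats::rt(d * M, df = t_df) / sqrt(t_df / (t_df - 2)), nrow = d)
    }
    informative <- if (n_informative > 0L) sort(sample.int(d, n_informative)) else integer(0L)
    if (rho > 0 && n_informative > 1L && noise == "gaussian") {
      shared <- stats::rnorm(M)
      eps[informative, ] <- sqrt(rho) * matrix(shared, nrow = n_informative,
                                               ncol = M, byrow = TRUE) +
        sqrt(1 - rho) * eps[informative, , drop = FALSE]
    }
    X <- mu + sigma * eps
    if (n_informative > 0L) {
      X[informative, seq_len(n_plus)] <- X[informative, seq_len(n_plus)] +
        delta * sigma
    }
    list(X = X, informative = informative)
  })

  width <- max(4L, nchar(d))
  fids <- sprintf(paste0("g%0", width, "d"), seq_len(d))
  sids <- sprintf("s%03d", seq_len(M))
  dimnames(out$X) <- list(fids, sids)
  lab <- class_labels(
    stats::setNames(rep(c("case", "control"), c(n_plus, n_minus)), sids),
    positive_label = "case")
  structure(list(matrix = out$X, labels = lab,
                 informative_ids = fids[out$informative],
                 delta = delta, sigma = sigma, rho = rho, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$matrix), "features x", ncol(x$matrix),
      "samples;", length(x$informative_ids), "informative, delta =",
      x$delta, ", sigma =", x$sigma, ", rho =", x$rho, "\n")
  invisible(x)
}

#' Fraction of planted features recovered in the top of a ranking
#'
#' `|top_k of the ranking intersect informative set| /
#'  min(top_k, n_informative)`. A `top_k` beyond the feature count is
#' clamped to it.
#'
#' @param ranking A `ranked_list`, `ensemble_ranking`, or `signature_set`.
#' @param truth A `synthetic_dataset` (or a character vector of true
#'   informative identifiers).
#' @param top_k How many leading features to examine (default: the size of
#'   the truth set).
#' @return Scalar in [0, 1].
#' @export
recovery_fraction <- function(ranking, truth, top_k = NULL) {
  truth_ids <- if (inherits(truth, "synthetic_dataset")) {
    truth$informative_ids
  } else as.character(truth)
  if (!length(truth_ids)) stop("truth set is empty")
  ids <- if (inherits(ranking, "ensemble_ranking")) {
    ranking$feature_ids[ranking$final_order]
  } else if (inherits(ranking, "ranked_list")) {
    ranking$feature_ids
  } else if (inherits(ranking, "signature_set")) {
    ranking$feature_ids
  } else stop("unsupported ranking object")
  if (is.null(top_k)) top_k <- length(truth_ids)
  if (top_k < 1L) stop("top_k must be >= 1")
  top_k <- min(as.integer(top_k), length(ids))
  top <- ids[seq_len(top_k)]
  length(intersect(top, truth_ids)) / min(top_k, length(truth_ids))
}
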