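#' Kuncheva index between two equal-size signatures
#'
#' Chance-corrected overlap `KI = (r - s^2/N) / (s - s^2/N)` where
#' `r = |a intersect b|` and `s` is the common signature size out of a
#' universe of `N` features. Bounded in (-1, 1], equal to 1 iff the
#' signatures coincide, and 0 in expectation for signatures drawn uniformly
#' at random (the `s^2/N` term removes the chance overlap).
#'
#' @param sig_a,sig_b Signatures: `signature_set` objects or vectors of
#'   feature identifiers; equal sizes, `0 < s < N`.
#' @param N Universe size (total feature count).
#' @return Scalar Kuncheva index.
#' @export
kuncheva_index <- function(sig_a, sig_b, N) {
  a <- signature_ids(sig_a)
  b <- signature_ids(sig_b)
  s <- length(a)
  if (length(b) != s) stop("signatures have unequal sizes (", s, " vs ",
                           length(b), ")")
  if (anyDuplicated(a) || anyDuplicated(b)) stop("signatures must not contain duplicates")
  if (s == 0L) stop("empty signature")
  if (s >= N) stop("signature size must be < universe size N")
  r <- length(intersect(a, b))
  (r - s^2 / N) / (s - s^2 / N)
}

signature_ids <- function(x) {
  if (inherits(x, "signature_set")) x$feature_ids else as.vector(x)
}

#' Total stability of a set of signatures
#'
#' The mean Kuncheva index over all `k(k-1)/2` unordered pairs of
#' signatures, together with the full pairwise matrix.
#'
#' @param signatures List of k >= 2 equal-size signatures
#'   (`signature_set` objects or identifier vectors).
#' @param N Universe size.
#' @return Object of class `stability_report`: list with `pairwise`
#'   (k x k symmetric matrix, unit diagonal), `s_tot`, `k`, `s`
#'   (signature size), `N`, `reference_mode = "all_pairs"`.
#' @export
total_stability <- function(signatures, N) {
  k <- length(signatures)
  if (k < 2L) stop("need at least 2 signatures")
  sizes <- vapply(signatures, function(x) length(signature_ids(x)), integer(1L))
  if (length(unique(sizes)) != 1L) stop("all signatures must have the same size")
  pw <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      pw[i, j] <- pw[j, i] <- kuncheva_index(signatures[[i]], signatures[[j]], N)
    }
  }
  s_tot <- mean(pw[upper.tri(pw)])
  structure(list(pairwise = pw, s_tot = s_tot, k = k, s = sizes[1L], N = N,
                 reference_mode = "all_pairs", reference_index = NA_integer_),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report: k =", x$k, ", s =", x$s, ", N =", x$N,
      ", S_tot =", format(x$s_tot, digits = 4), "\n")
  invisible(x)
}

#' Pairwise stability against a reference signature
#'
#' Kuncheva index of every non-reference signature against a chosen
#' reference list, the quantity histogrammed in pairwise-stability plots.
#'
#' @inheritParams total_stability
#' @param reference_index Which signature serves as the reference
#'   (default 1, the first bootstrap's signature).
#' @return Numeric vector of k-1 Kuncheva indices.
#' @export
reference_pairwise_stability <- function(signatures, N, reference_index = 1L) {
  k <- length(signatures)
  if (k < 2L) stop("need at least 2 signatures")
  if (reference_index < 1L || reference_index > k) {
    stop("reference_index out of range")
  }
  ref <- signatures[[reference_index]]
  vapply(signatures[-reference_index], kuncheva_index, numeric(1L),
         sig_b = ref, N = N)
}

#' Serialize a stability report to JSON
#'
#' @param report A `stability_report`.
#' @param path Output path.
#' @export
write_stability_report <- function(report, path) {
  jsonlite::write_json(
    list(schema_version = "1.0",
         kind = "stability_report",
         k = report$k, s = report$s, N = report$N,
         reference_mode = report$reference_mode,
         s_tot = report$s_tot,
         pairwise = report$pairwise),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
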