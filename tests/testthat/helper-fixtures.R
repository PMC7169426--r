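# Small in-code fixtures shared across test files.

# A tiny deterministic two-class data set with a strong planted signal.
tiny_dataset <- function(seed = 7, d = 30, n_informative = 5, delta = 3,
                         n_plus = 12, n_minus = 12) {
  simulate_two_class(n_plus, n_minus, d, n_informative,
                     delta = delta, seed = seed)
}

# Write a features x samples matrix and matching labels to temp files;
# returns their paths.
write_fixture_pair <- function(X, labels_chr,
                               dir = local({
                                 d <- tempfile("fix"); dir.create(d); d
                               })) {
  mpath <- file.path(dir, "expr.tsv")
  lpath <- file.path(dir, "labels.tsv")
  write_expression_table(X, mpath)
  writeLines(paste(colnames(X), labels_chr, sep = "\t"), lpath)
  list(matrix = mpath, labels = lpath)
}
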