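# In-code fixtures shared across test files.

# Two well-separated Gaussian blobs in `d` dimensions.
make_blobs <- function(n_per_class = 10, d = 2, sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, mean = 0, sd = sd), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep, sd = sd), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  feature_matrix(x, rep(c(-1L, 1L), each = n_per_class))
}

# Pure-noise features with balanced labels.
make_noise_fm <- function(n_per_class = 20, d = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * d), ncol = d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  feature_matrix(x, rep(c(-1L, 1L), each = n_per_class))
}

# A small valid protein dataset with both classes.
make_tiny_dataset <- function(n_per_class = 6, len = 25, seed = 1) {
  set.seed(seed)
  labeled_dataset(
    paste0("s", seq_len(2 * n_per_class)),
    vapply(rep(len, 2 * n_per_class), random_protein, character(1)),
    rep(c(1L, -1L), each = n_per_class)
  )
}

write_tmp_fasta <- function(entries, width = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(names(entries), function(id) {
    s <- entries[[id]]
    body <- if (is.null(width)) s
            else substring(s, seq(1, nchar(s), width),
                           pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}
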