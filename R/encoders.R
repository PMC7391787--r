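# Feature encoders: g-gap dipeptide composition over the full 20-letter
# alphabet, and n-peptide composition over a reduced (clustered) alphabet.
# All vectors are frequencies summing to 1, in fixed lexicographic order over
# the relevant alphabet, so feature names are stable across train and predict.

#' Encoder specifications
#'
#' An encoder spec names one member of the two feature families:
#' `ggap_spec(g)` — the 400-dimensional g-gap dipeptide composition, counting
#' ordered residue pairs separated by exactly `g` intervening residues
#' (`g = 0` means adjacent); `raac_spec(profile, n)` — the `k^n`-dimensional
#' overlapping n-peptide composition over the `k`-letter reduced alphabet of a
#' cluster profile.
#'
#' @param g Gap size, an integer in \[0, 9\] (larger values only with
#'   `override = TRUE`).
#' @param override Allow `g > 9`.
#' @param profile A [cluster_profile()] or profile name.
#' @param n Peptide order; defaults to the profile's optimal order.
#' @return An object of class `encoder_spec`.
#' @examples
#' ggap_spec(3)
#' raac_spec("Op5")        # n defaults to 3
#' @export
ggap_spec <- function(g, override = FALSE) {
  g <- as.integer(g)
  if (g < 0L || (g > 9L && !override))
    stop("g must be an integer in [0, 9]", call. = FALSE)
  structure(list(type = "ggap", g = g), class = "encoder_spec")
}

#' @rdname ggap_spec
#' @export
raac_spec <- function(profile, n = NULL) {
  if (!inherits(profile, "cluster_profile")) profile <- cluster_profile(profile)
  n <- if (is.null(n)) profile$optimal_n else as.integer(n)
  if (n < 1L) stop("n must be a positive integer", call. = FALSE)
  structure(list(type = "raac", profile = profile, n = n),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(encoder_label(x), " (", length(encoder_feature_names(x)),
      " features)\n", sep = "")
  invisible(x)
}

encoder_label <- function(spec) {
  if (spec$type == "ggap") paste0("g", spec$g)
  else paste0(spec$profile$name, ".n", spec$n)
}

# Minimum sequence length the encoder can process.
encoder_min_length <- function(spec) {
  if (spec$type == "ggap") spec$g + 2L else spec$n
}

# Fixed lexicographic feature names for an encoder.
encoder_feature_names <- function(spec) {
  if (spec$type == "ggap") {
    paste0(rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, 20L), "|g", spec$g)
  } else {
    reps <- sort(spec$profile$representative)
    mers <- Reduce(function(acc, .) as.vector(t(outer(acc, reps, paste0))),
                   seq_len(spec$n - 1L), init = reps)
    paste0(mers, "|", spec$profile$name)
  }
}

#' g-gap dipeptide composition
#'
#' Encodes a protein sequence as the frequencies of the 400 ordered amino-acid
#' pairs `(a, b)` whose positions differ by `g + 1` (i.e. separated by exactly
#' `g` residues). Each frequency is `count / (L - g - 1)` where `L` is the
#' sequence length, so the vector sums to 1 whenever `L > g + 1`.
#'
#' @param seq An amino-acid sequence string over the 20-letter alphabet.
#' @param g Gap size in \[0, 9\], or a `ggap_spec`.
#' @param id Optional record id for error messages.
#' @return A named numeric vector of length 400 (names `"AC|g0"` style, pairs
#'   in lexicographic order) with the raw pair counts in attribute `"counts"`.
#' @examples
#' v <- ggap_composition("ACDE", 0)
#' v[v > 0]   # AC, CD, DE each 1/3
#' @export
ggap_composition <- function(seq, g, id = NULL) {
  spec <- if (inherits(g, "encoder_spec")) g else ggap_spec(g)
  idx <- aa_indices(seq, id)
  L <- length(idx)
  g <- spec$g
  if (L <= g + 1L)
    stop("sequence", if (!is.null(id)) paste0(" ", id), " of length ", L,
         " too short for g = ", g, " (needs length > ", g + 1L, ")",
         call. = FALSE)
  a <- idx[1:(L - g - 1L)]
  b <- idx[(g + 2L):L]
  counts <- tabulate((a - 1L) * 20L + b, nbins = 400L)
  out <- counts / (L - g - 1L)
  names(out) <- encoder_feature_names(spec)
  attr(out, "counts") <- counts
  out
}

#' Reduce a sequence to a cluster-profile alphabet
#'
#' Replaces each residue by the representative letter of its cluster group.
#' The output has the same length as the input and is a fixed point of further
#' reduction under the same profile.
#'
#' @param seq Amino-acid sequence string.
#' @param profile A [cluster_profile()] or profile name.
#' @return The reduced sequence string.
#' @examples
#' reduce_sequence("GIVA", "Op5")  # "GIIA"
#' @export
reduce_sequence <- function(seq, profile) {
  if (!inherits(profile, "cluster_profile")) profile <- cluster_profile(profile)
  idx <- aa_indices(seq)
  paste(profile$map[idx], collapse = "")
}

#' Reduced amino-acid n-peptide composition
#'
#' Reduces the sequence with [reduce_sequence()], then counts the overlapping
#' n-peptides over the `k`-letter reduced alphabet. Each of the `k^n`
#' frequencies equals `count / (L - n + 1)`, so the vector sums to 1 whenever
#' `L >= n`. Dimensions at the built-in profiles' optimal orders: 125 (Op5,
#' n = 3), 64 (Op8), 81 (Op9), 121 (Op11), 169 (Op13); Op5 dipeptides (n = 2)
#' give 25.
#'
#' @param seq Amino-acid sequence string.
#' @param profile A [cluster_profile()] or profile name (ignored when a full
#'   `raac_spec` is passed instead).
#' @param n Peptide order; defaults to the profile's optimal order.
#' @param id Optional record id for error messages.
#' @return A named numeric vector of length `k^n` (names like `"GII|Op5"`,
#'   n-mers of representative letters in lexicographic order), counts in
#'   attribute `"counts"`.
#' @export
raac_composition <- function(seq, profile, n = NULL, id = NULL) {
  spec <- if (inherits(profile, "encoder_spec")) profile
          else raac_spec(profile, n)
  prof <- spec$profile
  n <- spec$n
  idx <- aa_indices(seq, id)
  L <- length(idx)
  if (L < n)
    stop("sequence", if (!is.null(id)) paste0(" ", id), " of length ", L,
         " too short for n = ", n, call. = FALSE)
  reps_sorted <- sort(prof$representative)
  # group index of each residue, in the sorted-representative order that
  # matches the lexicographic feature names
  gi <- match(prof$map[idx], reps_sorted)
  k <- prof$k
  m <- L - n + 1L
  code <- rep(0L, m)
  for (j in seq_len(n)) code <- code * k + (gi[j:(j + m - 1L)] - 1L)
  counts <- tabulate(code + 1L, nbins = k^n)
  out <- counts / m
  names(out) <- encoder_feature_names(spec)
  attr(out, "counts") <- counts
  out
}

# Map a sequence string to indices in AA_ALPHABET, validating residues.
aa_indices <- function(seq, id = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx))
    stop("invalid residue(s) ", paste(unique(chars[is.na(idx)]), collapse = ", "),
         if (!is.null(id)) paste0(" in record ", id), call. = FALSE)
  idx
}

#' Encode a labeled dataset as a feature matrix
#'
#' Applies one encoder to every record. All records must satisfy the encoder's
#' minimum-length precondition; violations abort with the offending ids (no
#' silent dropping).
#'
#' @param data A `labeled_dataset`.
#' @param spec An `encoder_spec` from [ggap_spec()] or [raac_spec()].
#' @return A `feature_matrix`: list with `x` (numeric matrix, rows = records,
#'   columns = features), `labels` (+1/-1), `ids`, and `encoder`.
#' @export
encode_dataset <- function(data, spec) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(spec, "encoder_spec"))
  min_len <- encoder_min_length(spec)
  too_short <- nchar(data$sequence) < min_len
  if (any(too_short))
    stop("record(s) too short for encoder ", encoder_label(spec),
         " (need length >= ", min_len, "): ",
         paste(data$id[too_short], collapse = ", "), call. = FALSE)
  enc1 <- function(s, id) {
    if (spec$type == "ggap") as.numeric(ggap_composition(s, spec, id = id))
    else as.numeric(raac_composition(s, spec, id = id))
  }
  x <- t(mapply(enc1, data$sequence, data$id, USE.NAMES = FALSE))
  colnames(x) <- encoder_feature_names(spec)
  rownames(x) <- data$id
  feature_matrix(x, data$label, data$id, encoder = spec)
}

#' Construct a feature matrix
#'
#' @param x Numeric matrix (rows = samples, named columns = features).
#' @param labels Integer vector over \{+1, -1\} (or `NA` for unlabeled data).
#' @param ids Record identifiers; defaults to rownames of `x`.
#' @param encoder Optional `encoder_spec` provenance.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, labels, ids = rownames(x), encoder = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0L)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("labels length must match rows of x", call. = FALSE)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  structure(list(x = x, labels = labels, ids = as.character(ids),
                 encoder = encoder),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$x), " x ", ncol(x$x),
      if (!is.null(x$encoder)) paste0(" [", encoder_label(x$encoder), "]"),
      " (", sum(x$labels == 1L, na.rm = TRUE), " positive / ",
      sum(x$labels == -1L, na.rm = TRUE), " negative)\n", sep = "")
  invisible(x)
}

#' Subset a feature matrix
#'
#' `subset_features` keeps the named columns (in the given order);
#' `subset_samples` keeps the indexed rows. Labels, ids and encoder
#' provenance are carried through.
#'
#' @param fm A `feature_matrix`.
#' @param features Character vector of feature names.
#' @param i Row index vector.
#' @return A `feature_matrix`.
#' @export
subset_features <- function(fm, features) {
  missing <- setdiff(features, colnames(fm$x))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  feature_matrix(fm$x[, features, drop = FALSE], fm$labels, fm$ids, fm$encoder)
}

#' @rdname subset_features
#' @export
subset_samples <- function(fm, i) {
  feature_matrix(fm$x[i, , drop = FALSE], fm$labels[i], fm$ids[i], fm$encoder)
}

#' Write a feature matrix as TSV
#'
#' First two columns are `id` and `label`, then one column per feature.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = fm$ids, label = fm$labels, fm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
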