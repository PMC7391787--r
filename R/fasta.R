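# Dataset assembly: FASTA in/out, residue cleaning, stratified splitting.
# A labeled dataset is a data.frame with columns id, sequence, label (+1/-1),
# class "labeled_dataset"; +1 marks the positive (antioxidant) class.

#' Clean a raw amino-acid sequence
#'
#' Uppercases the sequence and handles characters outside the 20-letter
#' alphabet `ACDEFGHIKLMNPQRSTVWY`. Under `"strict"` any such character is an
#' error; under `"drop_nonstandard"` (the default elsewhere in the package)
#' non-standard residues (B, J, O, U, X, Z), gaps and `*` are removed before
#' any counting, and the sequence length is that of the cleaned string.
#'
#' @param raw A single non-empty character string.
#' @param policy `"strict"` or `"drop_nonstandard"`.
#' @param id Optional record identifier used in error messages.
#' @return The cleaned sequence string.
#' @examples
#' clean_sequence("ACXDE", "drop_nonstandard")  # "ACDE"
#' @export
clean_sequence <- function(raw, policy = c("drop_nonstandard", "strict"),
                           id = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("empty sequence", call. = FALSE)
  s <- toupper(gsub("[[:space:]]", "", raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (policy == "strict") {
      stop("invalid residue(s) ", paste(unique(chars[bad]), collapse = ", "),
           if (!is.null(id)) paste0(" in record ", id),
           " (strict policy)", call. = FALSE)
    }
    chars <- chars[!bad]
  }
  if (length(chars) == 0L) {
    stop("sequence", if (!is.null(id)) paste0(" ", id),
         " empty after cleaning", call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Construct a labeled protein dataset
#'
#' @param ids Character vector of unique record identifiers.
#' @param sequences Character vector of amino-acid sequences (already clean;
#'   use [clean_sequence()] or [read_fasta()] otherwise).
#' @param labels Integer vector over \{+1, -1\}; +1 = positive class.
#' @return A `labeled_dataset`: a data.frame with columns `id`, `sequence`,
#'   `label`.
#' @export
labeled_dataset <- function(ids, sequences, labels) {
  ids <- as.character(ids)
  sequences <- as.character(sequences)
  labels <- as.integer(labels)
  if (length(ids) != length(sequences) || length(ids) != length(labels))
    stop("ids, sequences and labels must have equal length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!all(labels %in% c(-1L, 1L) | is.na(labels)))
    stop("labels must be +1 or -1 (or NA for unlabeled records)", call. = FALSE)
  structure(
    data.frame(id = ids, sequence = sequences, label = labels,
               stringsAsFactors = FALSE),
    class = c("labeled_dataset", "data.frame")
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled protein dataset: ", nrow(x), " records (",
      sum(x$label == 1L), " positive, ", sum(x$label == -1L), " negative), ",
      "lengths ", min(nchar(x$sequence)), "-", max(nchar(x$sequence)),
      "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a labeled dataset. The id of each record is the
#' header up to the first whitespace; sequences are uppercased and cleaned
#' per `policy`.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param label Class label, `+1` or `-1`, applied to every record; or `NULL`
#'   to attach labels later (stored as `NA`).
#' @param policy Residue cleaning policy, see [clean_sequence()]. Dropping
#'   non-standard residues emits one summary warning.
#' @return A `labeled_dataset`.
#' @export
read_fasta <- function(path, label = NULL,
                       policy = c("drop_nonstandard", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  raw <- as.character(set)
  dropped <- 0L
  sequences <- mapply(function(s, id) {
    cleaned <- clean_sequence(s, policy, id = id)
    dropped <<- dropped + (nchar(gsub("[[:space:]]", "", s)) - nchar(cleaned))
    cleaned
  }, raw, ids, USE.NAMES = FALSE)
  if (dropped > 0L)
    warning("dropped ", dropped, " non-standard residue(s) while reading ",
            path, call. = FALSE)
  labels <- if (is.null(label)) rep(NA_integer_, length(ids))
            else rep(as.integer(label), length(ids))
  out <- data.frame(id = ids, sequence = sequences, label = labels,
                    stringsAsFactors = FALSE)
  if (is.null(label)) {
    class(out) <- c("labeled_dataset", "data.frame")
    out
  } else {
    labeled_dataset(out$id, out$sequence, out$label)
  }
}

#' Write a dataset to FASTA
#'
#' @param data A `labeled_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  set <- Biostrings::BStringSet(data$sequence)
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Attach labels from a two-column table
#'
#' Joins a TSV of `(id, label)` onto a dataset read from a single mixed FASTA.
#'
#' @param data A `labeled_dataset` (labels possibly `NA`).
#' @param path Path to a two-column TSV (id, label), labels in \{+1, -1\}.
#' @return A fully labeled `labeled_dataset`.
#' @export
read_labels <- function(data, path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("id", "label"),
                           stringsAsFactors = FALSE)
  idx <- match(data$id, tab$id)
  if (anyNA(idx))
    stop("no label for record(s): ",
         paste(data$id[is.na(idx)], collapse = ", "), call. = FALSE)
  labeled_dataset(data$id, data$sequence, tab$label[idx])
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into training and testing parts, stratified by
#' class: each class contributes `round(fraction * n_class)` records to the
#' training part (within one record of the requested fraction). The split is
#' reproducible from `seed` and leaves the caller's RNG state untouched.
#'
#' @param data A `labeled_dataset` with both classes present.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed; default 42.
#' @return A `dataset_split`: list with `train`, `test` (both
#'   `labeled_dataset`), `fraction`, `seed`.
#' @examples
#' d <- labeled_dataset(paste0("s", 1:20),
#'                      rep(c("ACDEFGHIKLMNP", "MKVLANQRSTVWY"), 10),
#'                      rep(c(1, -1), each = 10))
#' sp <- split_dataset(d, 0.8, seed = 1)
#' nrow(sp$train)  # 16
#' @export
split_dataset <- function(data, fraction = 0.8, seed = 42L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)", call. = FALSE)
  if (anyNA(data$label)) stop("dataset has unlabeled records", call. = FALSE)
  counts <- table(factor(data$label, levels = c(-1L, 1L)))
  if (any(counts < 2L))
    stop("each class needs at least 2 records to stratify", call. = FALSE)
  train_idx <- with_seed(as.integer(seed), {
    unlist(lapply(c(-1L, 1L), function(cls) {
      idx <- which(data$label == cls)
      n_train <- max(1L, min(length(idx) - 1L,
                             as.integer(round(fraction * length(idx)))))
      sample(idx, n_train)
    }))
  })
  train_idx <- sort(train_idx)
  mk <- function(i) labeled_dataset(data$id[i], data$sequence[i], data$label[i])
  structure(
    list(train = mk(train_idx), test = mk(setdiff(seq_len(nrow(data)), train_idx)),
         fraction = fraction, seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Train/test split (fraction ", x$fraction, ", seed ", x$seed, ")\n",
      sep = "")
  cat("  train: "); print(x$train)
  cat("  test:  "); print(x$test)
  invisible(x)
}

#' Write a split manifest
#'
#' Records subset membership as TSV (id, subset, label) so a split can be
#' audited and re-applied.
#'
#' @param split A `dataset_split`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  man <- rbind(
    data.frame(id = split$train$id, subset = "train", label = split$train$label),
    data.frame(id = split$test$id, subset = "test", label = split$test$label)
  )
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
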