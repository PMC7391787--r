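# The 20-letter amino-acid alphabet, fixed order used for all feature naming.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Cluster profiles: partitions of the 20 standard amino acids into k
# physicochemical groups, written in their canonical group order. The
# representative letter of a group is its first letter as written here.
.PROFILE_GROUPS <- list(
  Op5  = c("G", "IVFYW", "ALMEQRK", "P", "NDHSTC"),
  Op8  = c("G", "IV", "FYW", "ALM", "EQRK", "P", "ND", "HSTC"),
  Op9  = c("G", "IV", "FYW", "ALM", "EQRK", "P", "ND", "HS", "TC"),
  Op11 = c("G", "IV", "FYW", "A", "LM", "EQRK", "P", "ND", "HS", "T", "C"),
  Op13 = c("G", "IV", "FYW", "A", "L", "M", "E", "QRK", "P", "ND", "HS", "T", "C")
)

# Peptide order n that performed best for each profile in the source study.
.PROFILE_OPTIMAL_N <- c(Op5 = 3L, Op8 = 2L, Op9 = 2L, Op11 = 2L, Op13 = 2L)

#' Amino-acid cluster profiles for alphabet reduction
#'
#' A cluster profile partitions the 20 standard amino acids into `k` groups of
#' physicochemically similar residues. Reducing a sequence replaces every
#' residue by its group's representative letter (the first letter of the group),
#' shrinking the alphabet from 20 to `k` and thereby the n-peptide feature
#' space from `20^n` to `k^n`.
#'
#' Five profiles are built in: `Op5`, `Op8`, `Op9`, `Op11` and `Op13`, with 5,
#' 8, 9, 11 and 13 groups respectively. Each carries the peptide order `n`
#' found optimal for it (3 for `Op5`, 2 for the others), used as the default by
#' [raac_composition()].
#'
#' @param name Profile name, one of `"Op5"`, `"Op8"`, `"Op9"`, `"Op11"`,
#'   `"Op13"`, or a list of custom group strings (each group a string of
#'   amino-acid letters; the groups must partition the 20-letter alphabet).
#' @param optimal_n Peptide order to attach when `name` is a custom group list.
#'
#' @return An object of class `cluster_profile`: a list with elements
#'   `name`, `groups` (character vector of group strings), `representative`
#'   (one letter per group), `k` (number of groups), `optimal_n`, and `map`
#'   (named character vector mapping each of the 20 residues to its
#'   representative letter).
#'
#' @examples
#' p <- cluster_profile("Op5")
#' p$k            # 5 groups
#' p$optimal_n    # 3
#' p$map[["V"]]   # "I": V belongs to the IVFYW group
#' @export
cluster_profile <- function(name, optimal_n = 2L) {
  if (is.character(name) && length(name) == 1L) {
    if (!name %in% names(.PROFILE_GROUPS)) {
      stop("unknown cluster profile '", name, "'; available: ",
           paste(names(.PROFILE_GROUPS), collapse = ", "), call. = FALSE)
    }
    groups <- .PROFILE_GROUPS[[name]]
    optimal_n <- .PROFILE_OPTIMAL_N[[name]]
  } else if (is.list(name) || (is.character(name) && length(name) > 1L)) {
    groups <- unlist(name, use.names = FALSE)
    name <- paste0("custom", length(groups))
  } else {
    stop("'name' must be a profile name or a list of group strings", call. = FALSE)
  }
  letters_by_group <- strsplit(groups, "", fixed = TRUE)
  all_letters <- unlist(letters_by_group)
  if (anyDuplicated(all_letters) || !setequal(all_letters, AA_ALPHABET)) {
    stop("groups must partition the 20-letter amino-acid alphabet exactly",
         call. = FALSE)
  }
  representative <- vapply(letters_by_group, `[`, character(1), 1L)
  map <- structure(rep(representative, lengths(letters_by_group)),
                   names = all_letters)
  map <- map[AA_ALPHABET]
  structure(
    list(name = name, groups = groups, representative = representative,
         k = length(groups), optimal_n = as.integer(optimal_n), map = map),
    class = "cluster_profile"
  )
}

#' @rdname cluster_profile
#' @export
list_cluster_profiles <- function() names(.PROFILE_GROUPS)

#' @export
print.cluster_profile <- function(x, ...) {
  cat("Cluster profile ", x$name, ": ", x$k, " groups {",
      paste(x$groups, collapse = "; "), "}, optimal n = ", x$optimal_n,
      "\n", sep = "")
  invisible(x)
}
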