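# Independent brute-force oracles, deliberately naive: explicit double loops
# over positions and residue pairs, sharing no code with the package's
# vectorized encoders.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# g-gap dipeptide frequencies by position-by-position enumeration.
naive_ggap <- function(seq, g) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  counts <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  for (p in seq_len(L - g - 1)) {
    a <- chars[p]; b <- chars[p + g + 1]
    counts[a, b] <- counts[a, b] + 1L
  }
  freqs <- numeric(400)
  nm <- character(400)
  i <- 0
  for (a in AA20) for (b in AA20) {
    i <- i + 1
    freqs[i] <- counts[a, b] / (L - g - 1)
    nm[i] <- paste0(a, b, "|g", g)
  }
  names(freqs) <- nm
  freqs
}

# Profile group tables written out directly from the cluster definitions.
PROFILE_TABLES <- list(
  Op5  = c("G", "IVFYW", "ALMEQRK", "P", "NDHSTC"),
  Op8  = c("G", "IV", "FYW", "ALM", "EQRK", "P", "ND", "HSTC"),
  Op9  = c("G", "IV", "FYW", "ALM", "EQRK", "P", "ND", "HS", "TC"),
  Op11 = c("G", "IV", "FYW", "A", "LM", "EQRK", "P", "ND", "HS", "T", "C"),
  Op13 = c("G", "IV", "FYW", "A", "L", "M", "E", "QRK", "P", "ND", "HS", "T", "C")
)

naive_reduce <- function(seq, profile_name) {
  groups <- PROFILE_TABLES[[profile_name]]
  chars <- strsplit(seq, "")[[1]]
  out <- character(length(chars))
  for (i in seq_along(chars)) {
    for (grp in groups) {
      if (grepl(chars[i], grp, fixed = TRUE)) {
        out[i] <- substr(grp, 1, 1)
        break
      }
    }
  }
  paste(out, collapse = "")
}

# Reduced n-peptide frequencies by sliding-window enumeration over every
# possible n-mer of representative letters.
naive_raac <- function(seq, profile_name, n) {
  reduced <- naive_reduce(seq, profile_name)
  chars <- strsplit(reduced, "")[[1]]
  L <- length(chars)
  reps <- sort(substr(PROFILE_TABLES[[profile_name]], 1, 1))
  mers <- reps
  if (n > 1) for (i in 2:n) {
    mers <- unlist(lapply(mers, function(m) paste0(m, reps)))
  }
  counts <- setNames(integer(length(mers)), mers)
  for (p in seq_len(L - n + 1)) {
    w <- paste(chars[p:(p + n - 1)], collapse = "")
    counts[w] <- counts[w] + 1L
  }
  out <- counts / (L - n + 1)
  names(out) <- paste0(mers, "|", profile_name)
  out
}
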