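# Synthetic labeled protein datasets with a plantable compositional signal.
# Negatives are i.i.d. residues from a background table; positives carry a
# first-order dependence at a chosen lag (or between reduced-alphabet
# groups): whenever the residue d positions back matches the first member of
# a planted ordered pair, the emission probability of the second member is
# multiplied by (1 + effect) and the distribution renormalized. The planted
# pairs therefore map one-to-one onto features of the encoding under test.

# Approximate natural amino-acid abundances (per-mille order of magnitude),
# for users wanting a non-uniform null; the default background is uniform.
.NATURAL_FREQ <- c(A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039,
                   G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.097,
                   M = 0.024, N = 0.041, P = 0.047, Q = 0.039, R = 0.055,
                   S = 0.066, T = 0.053, V = 0.069, W = 0.011, Y = 0.029)

#' Synthetic dataset configuration
#'
#' Defines a two-class generative process shaped like the antioxidant
#' benchmark (253 positive / 1,552 negative by default). `effect = 0` makes
#' the two classes draws from the identical process; increasing `effect`
#' strengthens the planted compositional divergence, carried by
#' `n_signal_features` ordered pairs in the feature family named by
#' `signal_channel`.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Sequence length bounds (uniform); the lower bound must
#'   exceed 10 so every encoder up to g = 9 applies.
#' @param effect Signal strength >= 0: planted pairs are emitted with
#'   probability multiplied by `1 + effect` (before renormalization).
#' @param signal_channel An `encoder_spec` naming the feature family that
#'   carries the signal: `ggap_spec(g)` plants residue pairs at lag `g + 1`;
#'   `raac_spec(profile)` plants reduced-group pairs at lag 1.
#' @param n_signal_features Number of planted ordered pairs.
#' @param background `"uniform"` (1/20 each, the default null) or
#'   `"natural"` (approximate database abundances).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_pos = 253L, n_neg = 1552L,
                         length_range = c(30L, 500L), effect = 2,
                         signal_channel = ggap_spec(1),
                         n_signal_features = 10L,
                         background = c("uniform", "natural"), seed = 42L) {
  background <- match.arg(background)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("length_range must be an increasing integer pair", call. = FALSE)
  if (length_range[1] <= 10L)
    stop("length_range lower bound must exceed 10 so all encoders ",
         "(up to g = 9) apply", call. = FALSE)
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (n_pos < 1L || n_neg < 1L) stop("class sizes must be positive", call. = FALSE)
  stopifnot(inherits(signal_channel, "encoder_spec"))
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         length_range = length_range, effect = effect,
         signal_channel = signal_channel,
         n_signal_features = as.integer(n_signal_features),
         background = background, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic labeled dataset
#'
#' Draws `n_neg` background sequences (class -1) and `n_pos` signal-bearing
#' sequences (class +1) per the configuration. The planted feature names
#' (in the signal channel's encoding) are recorded in attribute
#' `"signal_features"` and the configuration in attribute `"config"`.
#'
#' @param config A [synth_config()].
#' @return A `labeled_dataset`, positives first.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  bg <- if (config$background == "uniform") rep(1 / 20, 20)
        else unname(.NATURAL_FREQ[AA_ALPHABET] / sum(.NATURAL_FREQ))
  spec <- config$signal_channel
  with_seed(config$seed, {
    if (spec$type == "ggap") {
      lag <- spec$g + 1L
      pair_idx <- sample(400L, config$n_signal_features)
      pa <- (pair_idx - 1L) %/% 20L + 1L   # first residue of each pair
      pb <- (pair_idx - 1L) %% 20L + 1L    # second residue
      signal_features <- paste0(AA_ALPHABET[pa], AA_ALPHABET[pb], "|g", spec$g)
      # per conditioning residue, the multiplicative boost profile
      boost <- matrix(1, 20, 20)
      boost[cbind(pa, pb)] <- 1 + config$effect
    } else {
      prof <- spec$profile
      lag <- 1L
      k <- prof$k
      reps_sorted <- sort(prof$representative)
      pair_idx <- sample(k * k, min(config$n_signal_features, k * k))
      pa <- (pair_idx - 1L) %/% k + 1L
      pb <- (pair_idx - 1L) %% k + 1L
      signal_features <- paste0(reps_sorted[pa], reps_sorted[pb],
                                "|", prof$name)
      boost <- matrix(1, k, 20)
      group_of <- match(prof$map[AA_ALPHABET], reps_sorted)
      for (i in seq_along(pa))
        boost[pa[i], group_of == pb[i]] <- 1 + config$effect
      emit_group <- group_of
    }
    lens <- sample(config$length_range[1]:config$length_range[2],
                   config$n_pos + config$n_neg, replace = TRUE)
    gen_background <- function(L)
      paste(AA_ALPHABET[sample.int(20L, L, replace = TRUE, prob = bg)],
            collapse = "")
    gen_signal <- function(L) {
      s <- integer(L)
      for (t in seq_len(L)) {
        if (t <= lag || config$effect == 0) {
          p <- bg
        } else {
          cond <- if (spec$type == "ggap") s[t - lag]
                  else emit_group[s[t - lag]]
          p <- bg * boost[cond, ]
          p <- p / sum(p)
        }
        s[t] <- sample.int(20L, 1L, prob = p)
      }
      paste(AA_ALPHABET[s], collapse = "")
    }
    pos_seqs <- vapply(lens[seq_len(config$n_pos)], gen_signal, character(1))
    neg_seqs <- vapply(lens[config$n_pos + seq_len(config$n_neg)],
                       gen_background, character(1))
    out <- labeled_dataset(
      c(sprintf("pos%04d", seq_len(config$n_pos)),
        sprintf("neg%04d", seq_len(config$n_neg))),
      c(pos_seqs, neg_seqs),
      c(rep(1L, config$n_pos), rep(-1L, config$n_neg))
    )
    attr(out, "signal_features") <- signal_features
    attr(out, "config") <- config
    out
  })
}

#' Write a synthetic dataset with its manifest
#'
#' Writes one FASTA per class plus a JSON manifest recording the
#' configuration and the planted signal features.
#'
#' @param data A dataset from [generate_synthetic()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(split_like(data, which(data$label == 1L)),
              file.path(dir, "positive.fasta"))
  write_fasta(split_like(data, which(data$label == -1L)),
              file.path(dir, "negative.fasta"))
  cfg <- attr(data, "config")
  manifest <- list(
    n_pos = cfg$n_pos, n_neg = cfg$n_neg,
    length_range = cfg$length_range, effect = cfg$effect,
    signal_channel = encoder_label(cfg$signal_channel),
    signal_features = attr(data, "signal_features"),
    background = cfg$background, seed = cfg$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
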