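# SwissProt-like background residue frequencies (percent), alphabetical
# order; normalized to a probability vector at use.
BACKGROUND_FREQ <- c(
  A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
  G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
  M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
  S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
)

# Residues up-weighted in the positive class. Frozen so tests are stable.
SIGNAL_RESIDUES <- c("K", "R", "E", "P")

#' Class residue-composition distributions
#'
#' The negative class draws residues from a database-background
#' composition; the positive class up-weights the fixed residue subset
#' K, R, E, P by a factor `(1 + effect)` and renormalizes. `effect = 0`
#' makes the two classes identically distributed; `effect = 1` doubles the
#' weight of the signal residues.
#'
#' @param effect Class-separation strength in `[0, 1]`.
#' @return A list with probability vectors `positive` and `negative` (length
#'   20, alphabetical residue order).
#' @export
synthetic_composition <- function(effect) {
  stopifnot(effect >= 0, effect <= 1)
  base <- BACKGROUND_FREQ / sum(BACKGROUND_FREQ)
  pos <- base
  pos[SIGNAL_RESIDUES] <- pos[SIGNAL_RESIDUES] * (1 + effect)
  list(positive = pos / sum(pos), negative = base)
}

#' Simulate a labeled two-class sequence dataset
#'
#' Generates i.i.d. protein sequences for two classes that differ only in
#' residue composition (see [synthetic_composition()]), emulating the
#' statistical structure of a curated inhibitor/non-inhibitor training set:
#' a small positive class against a larger random-background negative class.
#' Lengths are uniform over `length_range`. Output is a pure function of the
#' arguments: the same call gives byte-identical sequences.
#'
#' @param n_pos,n_neg Class sizes; the defaults mirror a 56-positive /
#'   300-negative training design.
#' @param length_range Integer `(min, max)` sequence lengths; `min` must be
#'   at least 3 so every encoding applies.
#' @param effect Class-separation strength in `[0, 1]`; 0 yields
#'   indistinguishable classes.
#' @param seed Integer seed.
#' @return A labeled tibble (`id`, `description`, `residues`, `length`,
#'   `label`), positives first.
#' @export
simulate_sequences <- function(n_pos = 56L, n_neg = 300L,
                               length_range = c(50L, 250L),
                               effect = 0.9, seed = 42L) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2,
            length_range[1] >= 3, length_range[1] <= length_range[2])
  comp <- synthetic_composition(effect)
  with_local_seed(seed, {
    draw <- function(n, prefix, prob, what) {
      lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
      tibble(
        id = sprintf("%s_%03d", prefix, seq_len(n)),
        description = rep(what, n),
        residues = vapply(lens, function(L) {
          paste(sample(AMINO_ACIDS, L, replace = TRUE, prob = prob), collapse = "")
        }, character(1)),
        length = lens
      )
    }
    dplyr::bind_rows(
      dplyr::mutate(draw(n_pos, "pos", comp$positive, "synthetic positive"), label = TRUE),
      dplyr::mutate(draw(n_neg, "neg", comp$negative, "synthetic negative"), label = FALSE)
    )
  })
}

#' Simulate matched PSSM profiles for a dataset
#'
#' Builds one synthetic profile per sequence with [synthesize_profile()],
#' seeding each from the dataset seed plus the row index so the collection
#' is reproducible. Profiles are consistent with the query residues, so the
#' planted composition signal carries through the PSSM encoding.
#'
#' @param data A sequence tibble (columns `id`, `residues`).
#' @param self_score,off_score,noise_sd Passed to [synthesize_profile()].
#' @param seed Base integer seed.
#' @return A named list of raw [pssm_profile] objects, keyed by sequence id.
#' @export
simulate_profiles <- function(data, self_score = 5L, off_score = -2L,
                              noise_sd = 1, seed = 42L) {
  stopifnot(is.data.frame(data), all(c("id", "residues") %in% names(data)))
  profiles <- purrr::map(seq_len(nrow(data)), function(i) {
    synthesize_profile(data$residues[i], sequence_id = data$id[i],
                       self_score = self_score, off_score = off_score,
                       noise_sd = noise_sd, seed = seed + i)
  })
  setNames(profiles, data$id)
}
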