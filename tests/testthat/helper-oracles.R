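# Independent naive counting oracles for the encoders, written as plain
# per-position loops so they share no code path with the implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAIR400 <- paste0(rep(AA20, each = 20), AA20)

oracle_aac <- function(s) {
  chars <- strsplit(s, "")[[1]]
  counts <- setNames(numeric(20), AA20)
  for (ch in chars) counts[ch] <- counts[ch] + 1
  counts / length(chars)
}

oracle_saac <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  k <- n %/% 3
  parts <- list(chars[1:k], chars[(k + 1):(2 * k)], chars[(2 * k + 1):n])
  out <- numeric(0)
  for (p in parts) {
    counts <- setNames(numeric(20), AA20)
    for (ch in p) counts[ch] <- counts[ch] + 1
    out <- c(out, counts / length(p))
  }
  out
}

oracle_gapped <- function(s, gap) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  counts <- setNames(numeric(400), PAIR400)
  for (p in 1:(n - gap - 1)) {
    key <- paste0(chars[p], chars[p + gap + 1])
    counts[key] <- counts[key] + 1
  }
  counts / (n - gap - 1)
}

# Triple-loop pooling oracle for the PSSM-400 composition (length-normalized).
oracle_pssm400 <- function(norm_scores, s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  acc <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (a in AA20) {
    for (b in seq_len(20)) {
      total <- 0
      for (p in seq_len(n)) {
        if (chars[p] == a) total <- total + norm_scores[p, b]
      }
      acc[a, b] <- total / n
    }
  }
  as.numeric(t(acc))
}

# Random canonical sequence from a given composition (uniform by default).
random_seq <- function(len, prob = NULL) {
  paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = "")
}

# Small labeled toy dataset of composition-biased sequences.
toy_dataset <- function(n_pos = 6, n_neg = 6, len = 60, seed = 7) {
  withr::with_seed(seed, {
    pos_prob <- rep(1, 20); pos_prob[c(9, 15)] <- 6  # K, R heavy
    tibble::tibble(
      id = sprintf("t%02d", seq_len(n_pos + n_neg)),
      residues = c(
        vapply(seq_len(n_pos), function(i) random_seq(len, pos_prob / sum(pos_prob)), ""),
        vapply(seq_len(n_neg), function(i) random_seq(len), "")
      ),
      label = rep(c(TRUE, FALSE), c(n_pos, n_neg))
    )
  })
}

# Linearly separable 2-d point clouds for classifier contract tests.
cloud_fixture <- function(n_per_class = 15, sep = 3, seed = 11) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per_class, sep), ncol = 2),
               matrix(rnorm(2 * n_per_class, -sep), ncol = 2))
    colnames(x) <- c("f1", "f2")
    list(x = x, labels = rep(c(TRUE, FALSE), each = n_per_class))
  })
}
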