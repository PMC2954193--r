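#' PSSM profile objects
#'
#' A `pssm_profile` holds the per-position substitution scores for one query
#' sequence: an `N x 20` matrix (position by substituted residue) whose
#' columns follow the package's alphabetical residue order, together with the
#' query residues. Raw profiles carry integer log-odds scores; after
#' [logistic_normalize()] the entries lie strictly between 0 and 1.
#'
#' @param sequence_id Sequence identifier.
#' @param residues Query residue string of length `N`.
#' @param scores `N x 20` numeric matrix, columns in alphabetical residue
#'   order.
#' @param normalized Logical; `TRUE` once entries are logistic-normalized.
#' @param source Provenance note (a file path, or `"synthetic"`).
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(sequence_id, residues, scores,
                         normalized = FALSE, source = "constructed") {
  stopifnot(is.matrix(scores), ncol(scores) == 20)
  chars <- strsplit(residues, "")[[1]]
  if (nrow(scores) != length(chars)) {
    abort("profile row count must equal query sequence length")
  }
  if (!normalized) {
    if (any(scores != round(scores)) || any(abs(scores) > 20)) {
      abort("raw PSSM scores must be integers with |score| <= 20")
    }
  }
  colnames(scores) <- AMINO_ACIDS
  structure(
    list(sequence_id = sequence_id, residues = residues,
         scores = scores, normalized = normalized, source = source),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 residues (%s, %s)\n",
              x$sequence_id, nrow(x$scores),
              if (x$normalized) "normalized" else "raw log-odds", x$source))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard ASCII matrix layout written by PSI-BLAST
#' (`-out_ascii_pssm`): header lines, a column-label line of 40 residue
#' letters, then one line per position holding the position index, the query
#' residue, 20 integer log-odds scores and 20 weighted-percentage columns.
#' Only the log-odds block is retained, and the file's column order
#' (A R N D C Q E G H I L K M F P S T W Y V) is remapped onto the package's
#' alphabetical residue order. Scores must be integers with absolute value at
#' most 20.
#'
#' @param path Path to an ASCII PSSM file.
#' @param sequence_id Identifier to attach; defaults to the file name.
#' @return A raw [pssm_profile].
#' @export
read_psiblast_pssm <- function(path, sequence_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  parse_psiblast_pssm(lines, sequence_id = sequence_id %||%
                        sub("\\.[^.]*$", "", basename(path)),
                      source = path)
}

#' @rdname read_psiblast_pssm
#' @param lines Character vector of file lines (alternative to `path`).
#' @param source Provenance note stored on the profile.
#' @export
parse_psiblast_pssm <- function(lines, sequence_id = "query", source = "text") {
  tokens <- lapply(lines, function(l) strsplit(stringr::str_trim(l), "\\s+")[[1]])
  is_label <- vapply(tokens, function(tk) {
    length(tk) == 40 && all(tk %in% AMINO_ACIDS)
  }, logical(1))
  if (!any(is_label)) {
    abort("not a PSSM file: missing 40-letter residue column-label line")
  }
  label_at <- which(is_label)[1]
  file_order <- tokens[[label_at]][1:20]
  if (!setequal(file_order, AMINO_ACIDS)) {
    abort("not a PSSM file: column labels are not the 20 standard residues")
  }

  residues <- character(0)
  rows <- list()
  for (i in seq((label_at + 1), length(tokens))) {
    tk <- tokens[[i]]
    if (length(tk) == 0) {
      if (length(rows) > 0) break else next
    }
    if (is.na(suppressWarnings(as.integer(tk[1])))) {
      if (length(rows) > 0) break
      abort(paste0("PSSM parse error at line ", i, ": expected a position row"))
    }
    if (length(tk) < 22) {
      abort(paste0("PSSM parse error at line ", i, ": truncated row (",
                   length(tk) - 2, " score columns, need 20)"))
    }
    pos <- as.integer(tk[1])
    if (pos != length(rows) + 1L) {
      abort(paste0("PSSM parse error at line ", i, ": position indices not consecutive (",
                   "got ", pos, ", expected ", length(rows) + 1L, ")"))
    }
    res <- tk[2]
    vals <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(vals) || any(vals != round(vals))) {
      abort(paste0("PSSM parse error at line ", i, ": non-integer log-odds score"))
    }
    if (any(abs(vals) > 20)) {
      abort(paste0("PSSM parse error at line ", i, ": score outside accepted band |x| <= 20"))
    }
    residues <- c(residues, res)
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0) {
    abort("not a PSSM file: no position rows found")
  }
  raw <- do.call(rbind, rows)
  # remap file column order onto alphabetical order
  scores <- raw[, match(AMINO_ACIDS, file_order), drop = FALSE]
  pssm_profile(sequence_id, paste(residues, collapse = ""), scores,
               normalized = FALSE, source = source)
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Writes the header, the 40-letter column-label line, and one row per
#' position with the log-odds block in PSI-BLAST column order followed by a
#' zero-filled percentage block. `read_psiblast_pssm()` on the output
#' reproduces the score matrix exactly.
#'
#' @param profile A raw [pssm_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (profile$normalized) {
    abort("only raw (integer log-odds) profiles can be written as ASCII PSSM")
  }
  scores <- profile$scores[, match(PSIBLAST_ORDER, AMINO_ACIDS), drop = FALSE]
  chars <- strsplit(profile$residues, "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(PSIBLAST_ORDER, PSIBLAST_ORDER)), collapse = " "))
  )
  body <- vapply(seq_along(chars), function(p) {
    paste0(sprintf("%5d %s ", p, chars[p]),
           paste(sprintf("%3d", as.integer(scores[p, ])), collapse = " "),
           "  ",
           paste(sprintf("%3d", integer(20)), collapse = " "),
           sprintf("  %4.2f %4.2f", 0, 0))
  }, character(1))
  footer <- c("", "                      K         Lambda")
  writeLines(c(header, body, footer), path)
  invisible(path)
}

#' Logistic normalization of a PSSM
#'
#' Maps every raw log-odds score `x` to `g(x) = 1 / (1 + exp(-x))`, so all
#' entries lie strictly between 0 and 1 with `g(0) = 0.5`, and scores keep
#' their order (`g` is strictly increasing). This puts profiles from
#' different searches on a common bounded scale before composition pooling.
#'
#' @param profile A raw [pssm_profile].
#' @return A normalized [pssm_profile].
#' @export
logistic_normalize <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (profile$normalized) {
    return(profile)
  }
  out <- profile
  out$scores <- 1 / (1 + exp(-profile$scores))
  out$normalized <- TRUE
  out
}

#' PSSM-400 evolutionary composition vector
#'
#' Collapses a normalized profile into a fixed 400-dimension vector: for each
#' query-residue type `a` and substitution column `b`, the component at index
#' `20 * idx(a) + idx(b)` pools the normalized scores `g(x)[p, b]` over all
#' positions `p` whose query residue is `a`. With the default
#' length-normalized aggregation the pooled sum is divided by the sequence
#' length `N`, so vectors from proteins of different lengths are comparable;
#' residue types absent from the sequence contribute a block of 20 zeros.
#'
#' @param profile A normalized [pssm_profile] (see [logistic_normalize()]).
#' @param residues The query residue string; must equal the profile's.
#' @param aggregate Pooling statistic: `"length-normalized"` (sum over
#'   matching positions divided by `N`, the default), `"sum"` (raw sum), or
#'   `"mean"` (mean over the positions of that residue type).
#' @return Named numeric vector of length 400 (names `PSSM_AA` ... `PSSM_YY`).
#' @export
pssm400 <- function(profile, residues,
                    aggregate = c("length-normalized", "sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(profile, "pssm_profile"))
  if (!profile$normalized) {
    abort("pssm400() expects a normalized profile; call logistic_normalize() first")
  }
  if (!identical(profile$residues, residues)) {
    abort(paste0("profile/sequence mismatch for '", profile$sequence_id, "'"))
  }
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  out <- matrix(0, nrow = 20, ncol = 20, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
  for (a in AMINO_ACIDS) {
    idx <- which(chars == a)
    if (length(idx) == 0) next
    block <- colSums(profile$scores[idx, , drop = FALSE])
    out[a, ] <- switch(aggregate,
      "length-normalized" = block / n,
      "sum" = block,
      "mean" = block / length(idx)
    )
  }
  setNames(as.numeric(t(out)),
           paste0("PSSM_", rep(AMINO_ACIDS, each = 20L), AMINO_ACIDS))
}

#' Synthesize a PSSM profile for a sequence
#'
#' Builds a deterministic stand-in for an iterative-search profile: at each
#' position the column matching the query residue receives `self_score` and
#' every other column `off_score`, optionally perturbed by integer-rounded
#' Gaussian noise. Scores are clamped to the parser's accepted band
#' (`|x| <= 20`). Useful for testing the full PSSM pipeline without running
#' any database search; the output round-trips exactly through
#' [write_pssm_ascii()] and [read_psiblast_pssm()].
#'
#' @param residues Query residue string.
#' @param sequence_id Identifier for the profile.
#' @param self_score Integer score for the query residue's own column; must
#'   exceed `off_score`.
#' @param off_score Integer score for all other columns.
#' @param noise_sd Standard deviation of the Gaussian noise added before
#'   rounding; 0 gives the noise-free template.
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A raw [pssm_profile] with `source = "synthetic"`.
#' @export
synthesize_profile <- function(residues, sequence_id = "synthetic",
                               self_score = 5L, off_score = -2L,
                               noise_sd = 0, seed = 42L) {
  stopifnot(self_score > off_score, noise_sd >= 0)
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  scores <- matrix(as.numeric(off_score), nrow = n, ncol = 20,
                   dimnames = list(NULL, AMINO_ACIDS))
  scores[cbind(seq_len(n), match(chars, AMINO_ACIDS))] <- as.numeric(self_score)
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, matrix(round(rnorm(n * 20, sd = noise_sd)), nrow = n))
    scores <- scores + noise
  }
  scores <- pmin(pmax(scores, -20), 20)
  pssm_profile(sequence_id, residues, scores, normalized = FALSE, source = "synthetic")
}
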