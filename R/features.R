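#' Amino-acid composition (AAC)
#'
#' Fraction of each of the 20 standard amino acids in the sequence: component
#' `i` is `count(residue_i) / N`, with residues in alphabetical one-letter
#' order (A, C, D, ..., Y). The vector has 20 components and sums to 1.
#'
#' @param residues A single canonical residue string (see
#'   [sanitize_residues()]).
#' @return Named numeric vector of length 20 (names `AAC_A` ... `AAC_Y`).
#' @examples
#' aac("ACDE")
#' @export
aac <- function(residues) {
  chars <- residue_chars(residues, min_length = 1L, op = "AAC")
  counts <- table(factor(chars, levels = AMINO_ACIDS))
  setNames(as.numeric(counts) / length(chars), paste0("AAC_", AMINO_ACIDS))
}

#' Split amino-acid composition (SAAC)
#'
#' The sequence is partitioned into three contiguous parts and [aac()] is
#' computed on each part separately; the result is the 60-component
#' concatenation. When `N` is not divisible by 3 the parts have lengths
#' `floor(N/3)`, `floor(N/3)`, and `N - 2*floor(N/3)` (the remainder goes to
#' the final part). Each 20-component block sums to 1.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 60 (names `SAAC1_A` ... `SAAC3_Y`).
#' @export
saac <- function(residues) {
  chars <- residue_chars(residues, min_length = 3L, op = "SAAC",
                         too_short = "sequence too short for SAAC (need N >= 3)")
  n <- length(chars)
  k <- n %/% 3L
  parts <- list(chars[seq_len(k)], chars[(k + 1L):(2L * k)], chars[(2L * k + 1L):n])
  out <- unlist(lapply(parts, function(p) {
    as.numeric(table(factor(p, levels = AMINO_ACIDS))) / length(p)
  }))
  setNames(out, paste0("SAAC", rep(1:3, each = 20L), "_", rep(AMINO_ACIDS, 3L)))
}

#' Dipeptide composition (DPC)
#'
#' Fraction of each of the 400 ordered adjacent residue pairs: the component
#' for pair (a, b) is the number of positions where `a` is immediately
#' followed by `b`, divided by `N - 1` (the number of adjacent pairs), so the
#' vector sums to 1. Pair order is `20 * idx(a) + idx(b)` over the
#' alphabetical residue order.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400 (names `DPC_AA` ... `DPC_YY`).
#' @export
dpc <- function(residues) {
  gapped_dpc(residues, gap = 0L, prefix = "DPC")
}

#' Gapped dipeptide composition
#'
#' Fraction of ordered residue pairs separated by exactly `gap` intervening
#' residues: the component for (a, b) counts positions `p` with
#' `residue(p) == a` and `residue(p + gap + 1) == b`, divided by
#' `N - gap - 1` (the number of valid gapped pairs). `gap = 1` is the
#' one-gap ("2-gram") encoding; `gap = 0` reduces exactly to [dpc()].
#'
#' @inheritParams aac
#' @param gap Non-negative integer number of intervening residues.
#' @param prefix Name prefix for the output components.
#' @return Named numeric vector of length 400.
#' @export
gapped_dpc <- function(residues, gap = 1L, prefix = paste0("GAP", gap)) {
  stopifnot(length(gap) == 1, gap >= 0, gap == as.integer(gap))
  gap <- as.integer(gap)
  chars <- residue_chars(residues, min_length = gap + 2L, op = prefix,
                         too_short = paste0("sequence too short for gap-", gap,
                                            " dipeptides (need N >= ", gap + 2L, ")"))
  n <- length(chars)
  first <- chars[seq_len(n - gap - 1L)]
  second <- chars[(gap + 2L):n]
  pair <- factor(paste0(first, second),
                 levels = paste0(rep(AMINO_ACIDS, each = 20L), AMINO_ACIDS))
  counts <- table(pair)
  setNames(as.numeric(counts) / (n - gap - 1L), paste0(prefix, "_", levels(pair)))
}

# Internal: split a residue string, checking alphabet and length.
residue_chars <- function(residues, min_length, op, too_short = NULL) {
  stopifnot(is.character(residues), length(residues) == 1, !is.na(residues))
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) < min_length) {
    abort(too_short %||% paste0(op, " requires a sequence of length >= ", min_length))
  }
  bad <- setdiff(unique(chars), AMINO_ACIDS)
  if (length(bad) > 0) {
    abort(paste0(op, ": non-canonical residue(s) ", paste(bad, collapse = ", "),
                 "; run sanitize_residues() first"))
  }
  chars
}

#' Encode a sequence table into a feature matrix
#'
#' Applies one of the five encodings to every sequence in a tibble and
#' returns one row per sequence with named feature columns, ready for
#' [train_svm()], [train_ann()] or [loocv()].
#'
#' Encodings and dimensions: `"AAC"` (20), `"SAAC"` (60), `"DPC"` (400),
#' `"GAP1"` (one-gap dipeptides, 400), `"PSSM400"` (logistic-normalized PSSM
#' composition, 400; requires `profiles`).
#'
#' @param data A tibble with columns `id` and `residues` (e.g. from
#'   [read_fasta()]). Only `id` is carried into the output, so the result
#'   joins cleanly back onto `data`.
#' @param encoding One of `"AAC"`, `"SAAC"`, `"DPC"`, `"GAP1"`, `"PSSM400"`.
#' @param gap Gap width used when `encoding = "GAP1"`; the default 1
#'   reproduces the one-gap encoding.
#' @param profiles For `"PSSM400"`: a named list of [pssm_profile] objects,
#'   one per sequence id.
#' @return A tibble with column `id` followed by the feature columns.
#' @export
encode_features <- function(data,
                            encoding = c("AAC", "SAAC", "DPC", "GAP1", "PSSM400"),
                            gap = 1L,
                            profiles = NULL) {
  stopifnot(is.data.frame(data), all(c("id", "residues") %in% names(data)))
  if (length(encoding) == 1 && !encoding %in% c("AAC", "SAAC", "DPC", "GAP1", "PSSM400")) {
    abort(paste0("unknown encoding: '", encoding, "'"))
  }
  encoding <- match.arg(encoding)
  if (encoding == "PSSM400") {
    if (is.null(profiles)) {
      abort("encoding 'PSSM400' requires a named list of PSSM profiles")
    }
    missing <- setdiff(data$id, names(profiles))
    if (length(missing) > 0) {
      abort(paste0("no PSSM profile for sequence(s): ", paste(missing, collapse = ", ")))
    }
  }
  encoder <- switch(encoding,
    AAC = function(row) aac(row$residues),
    SAAC = function(row) saac(row$residues),
    DPC = function(row) dpc(row$residues),
    GAP1 = function(row) gapped_dpc(row$residues, gap = gap),
    PSSM400 = function(row) {
      pssm400(logistic_normalize(profiles[[row$id]]), row$residues)
    }
  )
  rows <- purrr::map(seq_len(nrow(data)), function(i) encoder(data[i, ]))
  mat <- do.call(rbind, rows)
  out <- dplyr::bind_cols(tibble(id = data$id), as_tibble(mat))
  attr(out, "encoding") <- encoding
  out
}

#' Write a feature table as TSV
#'
#' One row per sequence; first column `id`, then one column per feature.
#'
#' @param features A feature tibble from [encode_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write features in sparse classifier-input format
#'
#' One line per sequence: the class label (`+1`/`-1`, or `0` when unknown)
#' followed by `index:value` pairs with 1-based feature indices; zero-valued
#' features are omitted. A trailing `# id` comment carries the sequence id.
#'
#' @param features A feature tibble from [encode_features()].
#' @param path Output path.
#' @param labels Optional logical vector (`TRUE` = positive), recycled to the
#'   number of rows.
#' @return `path`, invisibly.
#' @export
write_sparse_features <- function(features, path, labels = NULL) {
  mat <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  lab <- if (is.null(labels)) rep("0", nrow(mat)) else ifelse(rep(labels, length.out = nrow(mat)), "+1", "-1")
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    nz <- which(mat[i, ] != 0)
    paste0(lab[i], " ",
           paste(sprintf("%d:%.10g", nz, mat[i, nz]), collapse = " "),
           " # ", features$id[i])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
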