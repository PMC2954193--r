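#' Sanitize a raw residue string
#'
#' Normalizes a candidate protein sequence to the canonical 20-letter
#' amino-acid alphabet: letters are uppercased and whitespace, digits, gap and
#' stop characters (`-`, `.`, `*`) are removed. What happens to the remaining
#' non-standard codes (`B`, `Z`, `J`, `X`, `U`, `O`, or anything else) depends
#' on the policy:
#'
#' * `"strict-drop"` (default): non-standard characters are removed and a
#'   single warning reports how many of each were dropped. This keeps every
#'   composition vector on the 20-letter simplex.
#' * `"reject"`: any non-standard character is an error.
#'
#' Sanitization is idempotent: applying it twice gives the same result.
#'
#' @param raw Character vector of candidate residue strings.
#' @param policy `"strict-drop"` or `"reject"`.
#' @return Character vector of canonical residue strings, same length as
#'   `raw`.
#' @examples
#' sanitize_residues("ac de")          # "ACDE"
#' sanitize_residues("ACXDE")          # "ACDE", with a warning
#' @export
sanitize_residues <- function(raw, policy = c("strict-drop", "reject")) {
  if (length(policy) == 1 && !policy %in% c("strict-drop", "reject")) {
    abort(paste0("unknown sanitization policy: '", policy, "'"))
  }
  policy <- match.arg(policy)
  stopifnot(is.character(raw))

  up <- stringr::str_remove_all(toupper(raw), "[\\s[:digit:]\\-\\.\\*]")
  foreign <- stringr::str_remove_all(up, paste0("[", paste(AMINO_ACIDS, collapse = ""), "]"))
  n_foreign <- sum(nchar(foreign))

  if (n_foreign > 0) {
    tab <- sort(table(strsplit(paste(foreign, collapse = ""), "")[[1]]), decreasing = TRUE)
    detail <- paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")
    if (policy == "reject") {
      abort(paste0("non-standard residue characters under policy 'reject': ", detail))
    }
    warn(paste0("dropped ", n_foreign, " non-standard residue character(s): ", detail))
  }

  clean <- stringr::str_remove_all(up, paste0("[^", paste(AMINO_ACIDS, collapse = ""), "]"))
  if (any(!nzchar(clean))) {
    abort("sequence empty after sanitization")
  }
  clean
}

#' Read protein sequences from a FASTA file
#'
#' Returns one row per record, in file order. The record id is the header up
#' to the first whitespace; the remainder of the header is kept as the
#' description. Sequence lines are concatenated with whitespace stripped and
#' passed through [sanitize_residues()]. Any line-ending dialect is accepted.
#'
#' @param path Path to a FASTA file.
#' @param sanitize Sanitization policy passed to [sanitize_residues()], or
#'   `NULL` to keep residues exactly as read (uppercased only).
#' @return A tibble with columns `id`, `description`, `residues`, `length`.
#' @seealso [write_fasta()], [read_labeled_fasta()]
#' @export
read_fasta <- function(path, sanitize = "strict-drop") {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) {
    abort(paste0("no records in FASTA file: ", path))
  }
  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("FASTA record with empty header")
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA ids: ", paste(dups, collapse = ", ")))
  }
  raw <- as.character(set)
  empty <- !nzchar(stringr::str_remove_all(raw, "\\s"))
  if (any(empty)) {
    abort(paste0("empty sequence for record(s): ", paste(ids[empty], collapse = ", ")))
  }
  residues <- if (is.null(sanitize)) {
    stringr::str_remove_all(toupper(raw), "\\s")
  } else {
    vapply(seq_along(raw), function(i) {
      tryCatch(
        sanitize_residues(raw[[i]], policy = sanitize),
        error = function(e) abort(paste0("record '", ids[[i]], "': ", conditionMessage(e)))
      )
    }, character(1))
  }
  tibble(
    id = ids,
    description = desc,
    residues = residues,
    length = nchar(residues)
  )
}

#' Write protein sequences to a FASTA file
#'
#' Writes standard FASTA with sequence lines wrapped at 60 columns.
#' `read_fasta(write_fasta(x, path))` reproduces ids, order and residues
#' exactly.
#'
#' @param seqs A sequence tibble with at least columns `id` and `residues`;
#'   a non-empty `description` column, if present, is appended to the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)), nrow(seqs) > 0)
  headers <- seqs$id
  if ("description" %in% names(seqs)) {
    has_desc <- !is.na(seqs$description) & nzchar(seqs$description)
    headers[has_desc] <- paste(seqs$id[has_desc], seqs$description[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(seqs$residues, headers))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read a labeled two-class sequence dataset
#'
#' Reads a positive-class and a negative-class FASTA file and binds them into
#' one labeled dataset, preserving file order (positives first). Ids must be
#' unique across both files.
#'
#' @param positive,negative Paths to the positive- and negative-class FASTA
#'   files.
#' @inheritParams read_fasta
#' @return A tibble with the [read_fasta()] columns plus a logical `label`
#'   column (`TRUE` = positive class).
#' @export
read_labeled_fasta <- function(positive, negative, sanitize = "strict-drop") {
  pos <- read_fasta(positive, sanitize = sanitize)
  neg <- read_fasta(negative, sanitize = sanitize)
  both <- dplyr::bind_rows(
    dplyr::mutate(pos, label = TRUE),
    dplyr::mutate(neg, label = FALSE)
  )
  if (anyDuplicated(both$id)) {
    dups <- unique(both$id[duplicated(both$id)])
    abort(paste0("ids shared between positive and negative sets: ", paste(dups, collapse = ", ")))
  }
  both
}

# Internal: validate a labeled dataset used for training.
check_labeled_dataset <- function(data, min_per_class = 1L) {
  stopifnot(is.data.frame(data), all(c("id", "residues", "label") %in% names(data)))
  if (!is.logical(data$label) || anyNA(data$label)) {
    abort("`label` must be a logical vector without NA (TRUE = positive class)")
  }
  if (sum(data$label) < min_per_class || sum(!data$label) < min_per_class) {
    abort(paste0("dataset needs at least ", min_per_class, " member(s) of each class"))
  }
  invisible(data)
}
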