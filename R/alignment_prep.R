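# Normalization of raw homeodomain sequences to the 60-column superfamily
# alignment frame. Typical TALE-class homeodomains are 63 residues long
# because of a three-residue insertion in the loop between helices 1 and 2;
# a handful of atypical homeodomains carry other short insertions. These are
# excised (and kept on the record) so that every sequence occupies the same
# 60 columns. Positions are declared by the caller or the catalog; there is
# no automatic insertion inference.

#' Normalize a 63-residue TALE homeodomain to 60 columns
#'
#' Excises raw positions 23-25 (the three-amino-acid loop extension between
#' the first and second alpha-helices) and records the excised tripeptide as
#' an insertion after normalized column 22, so the operation is lossless.
#'
#' @param raw 63-character residue string.
#' @return `list(residues = <60-mer>, insertions = <1-row data.frame>)`.
#' @examples
#' normalize_tale(paste0(strrep("A", 22), "NLA", strrep("A", 38)))
#' @export
normalize_tale <- function(raw) {
  raw <- toupper(raw)
  if (nchar(raw) != 63L) {
    stop("shape error: TALE normalization expects a 63-residue sequence, got ",
         nchar(raw), call. = FALSE)
  }
  excise_insertions(raw, data.frame(after_column = 22L, length = 3L))
}

#' Excise declared insertions from a raw homeodomain sequence
#'
#' Removes declared insertion content from a raw sequence so that exactly 60
#' columns remain. Each declaration gives `after_column` (the last normalized
#' column preceding the insertion, 1-59) and `length` (number of inserted
#' residues). The excised content is preserved in the returned insertion
#' records; [reinsert_insertions()] reconstructs the raw sequence exactly.
#'
#' @param raw residue string of length `60 + sum(declared$length)`.
#' @param declared `data.frame` with columns `after_column` and `length`.
#' @return `list(residues = <60-mer>, insertions = <data.frame>)` with
#'   insertion columns `after_column`, `inserted`.
#' @export
excise_insertions <- function(raw, declared = NULL) {
  raw <- toupper(raw)
  if (is.null(declared) || !nrow(declared)) {
    if (nchar(raw) != 60L) {
      stop("shape error: sequence has ", nchar(raw),
           " residues but no declared insertions", call. = FALSE)
    }
    return(list(residues = raw, insertions = empty_insertions()))
  }
  declared <- declared[order(declared$after_column), , drop = FALSE]
  if (nchar(raw) != 60L + sum(declared$length)) {
    stop("shape error: sequence has ", nchar(raw), " residues but declared ",
         "insertions account for ", sum(declared$length),
         " (expected total ", 60L + sum(declared$length), ")", call. = FALSE)
  }
  if (any(declared$after_column < 1L | declared$after_column > 59L)) {
    stop("insertion after_column must lie in 1..59", call. = FALSE)
  }
  chars <- strsplit(raw, "")[[1]]
  kept <- character(0)
  insertions <- empty_insertions()
  pos <- 1L   # next raw position to consume
  for (k in seq_len(nrow(declared))) {
    ac <- declared$after_column[k]
    len <- declared$length[k]
    n_before <- ac - length(kept)  # normalized columns still owed before this insertion
    if (n_before < 0L) stop("overlapping insertion declarations", call. = FALSE)
    kept <- c(kept, chars[seq.int(pos, length.out = n_before)])
    pos <- pos + n_before
    insertions <- rbind(insertions, data.frame(
      after_column = ac,
      inserted = paste(chars[seq.int(pos, length.out = len)], collapse = ""),
      stringsAsFactors = FALSE))
    pos <- pos + len
  }
  kept <- c(kept, chars[seq.int(pos, length(chars))])
  stopifnot(length(kept) == 60L)
  list(residues = paste(kept, collapse = ""), insertions = insertions)
}

#' Reconstruct the raw sequence from a normalized record
#'
#' Inverse of [excise_insertions()] / [normalize_tale()].
#'
#' @param residues 60-character normalized residue string.
#' @param insertions insertion `data.frame` (`after_column`, `inserted`).
#' @return the raw residue string with all insertions restored.
#' @export
reinsert_insertions <- function(residues, insertions) {
  if (!nrow(insertions)) return(residues)
  insertions <- insertions[order(insertions$after_column), , drop = FALSE]
  chars <- strsplit(residues, "")[[1]]
  out <- character(0)
  prev <- 0L
  for (k in seq_len(nrow(insertions))) {
    ac <- insertions$after_column[k]
    out <- c(out, chars[seq.int(prev + 1L, length.out = ac - prev)],
             strsplit(insertions$inserted[k], "")[[1]])
    prev <- ac
  }
  out <- c(out, if (prev < 60L) chars[(prev + 1L):60L])
  paste(out, collapse = "")
}
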