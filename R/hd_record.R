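#' @importFrom stats setNames aggregate cor rexp runif
#' @importFrom utils read.delim write.table head combn
NULL

# 20-letter amino acid alphabet, alphabetical
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

HD_CLASSES <- c("ANTP", "PRD", "LIM", "POU", "SINE", "TALE",
                "HNF", "CUT", "PROS", "ZF", "CERS", "UNCLASSIFIED")

HD_SUBCLASSES <- c("NKL", "HOXL", "HOXL2", "EXTENDED_HOX",
                   "Q50", "K50", "S50", "HOX", "PARAHOX")

SECONDARY_DOMAINS <- c("POU_SPECIFIC", "SIX", "LIM", "PBC", "MEIS_A",
                       "MEIS_B", "MEIS_D", "OCTAPEPTIDE", "PAIRED")

#' Construct a homeodomain record
#'
#' A homeodomain record holds one 60-column aligned homeodomain together with
#' its annotations: loop/helix insertions that were excised to reach the
#' 60-column frame, secondary protein domains found near the homeodomain,
#' intron positions within the homeobox, and optional genomic coordinates.
#' The first two characters of `id` are the species prefix (e.g. `"Ml"`,
#' `"Hs"`), the convention used throughout for per-species statistics.
#'
#' @param id record identifier; its first two characters are taken as the
#'   species prefix.
#' @param residues 60-character string over the 20 amino acids, `-` (gap) and
#'   `X` (unknown). Lower-case letters are upper-cased; any other character is
#'   mapped to `X` with a warning.
#' @param insertions `data.frame` with columns `after_column` (integer, 1-59)
#'   and `inserted` (residue string): sequence content that sits after the
#'   given alignment column in the raw (un-normalized) sequence.
#' @param secondary_domains character vector of domain labels, a subset of
#'   `r paste(SECONDARY_DOMAINS, collapse = ", ")`.
#' @param octapeptide_seq optional 8-residue string found upstream of the
#'   homeodomain.
#' @param introns `data.frame` as returned by [parse_intron_notation()], or a
#'   notation string which is parsed for you.
#' @param scaffold optional `list(scaffold_id =, start =, end =, strand =)`
#'   giving 0-based half-open genomic coordinates of the homeobox.
#' @param hd_class optional class label (one of
#'   `r paste(HD_CLASSES, collapse = ", ")`).
#' @param accession optional sequence database accession.
#' @param flags character vector of free-text annotation flags.
#' @return an object of class `hd_record`.
#' @examples
#' r <- hd_record("MlANTP19", strrep("A", 60))
#' r$species_prefix
#' @export
hd_record <- function(id, residues, insertions = NULL, secondary_domains = character(),
                      octapeptide_seq = NULL, introns = NULL, scaffold = NULL,
                      hd_class = NULL, accession = NULL, flags = character()) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) >= 2L)
  residues <- normalize_residues(residues, id = id)
  if (nchar(residues) != 60L) {
    stop("record '", id, "': residues must have exactly 60 columns, got ",
         nchar(residues), call. = FALSE)
  }
  if (is.null(insertions)) {
    insertions <- empty_insertions()
  } else {
    insertions <- as.data.frame(insertions, stringsAsFactors = FALSE)
    stopifnot(all(c("after_column", "inserted") %in% names(insertions)))
    insertions$after_column <- as.integer(insertions$after_column)
    insertions$inserted <- toupper(as.character(insertions$inserted))
    if (nrow(insertions) && any(insertions$after_column < 1L | insertions$after_column > 59L)) {
      stop("record '", id, "': insertion after_column must lie in 1..59", call. = FALSE)
    }
  }
  if (length(secondary_domains)) {
    bad <- setdiff(secondary_domains, SECONDARY_DOMAINS)
    if (length(bad)) {
      stop("record '", id, "': unknown secondary domain(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.character(introns) && length(introns) == 1L) introns <- parse_intron_notation(introns)
  if (is.null(introns)) introns <- empty_introns()
  if (!is.null(scaffold)) {
    stopifnot(all(c("scaffold_id", "start", "end", "strand") %in% names(scaffold)))
    scaffold$start <- as.integer(scaffold$start)
    scaffold$end <- as.integer(scaffold$end)
    if (scaffold$start < 0L || scaffold$start >= scaffold$end) {
      stop("record '", id, "': scaffold span requires 0 <= start < end", call. = FALSE)
    }
    if (!scaffold$strand %in% c("+", "-")) {
      stop("record '", id, "': strand must be '+' or '-'", call. = FALSE)
    }
  }
  if (!is.null(hd_class)) hd_class <- match.arg(hd_class, HD_CLASSES)
  structure(list(
    id = id,
    species_prefix = substr(id, 1L, 2L),
    residues = residues,
    insertions = insertions,
    secondary_domains = unique(as.character(secondary_domains)),
    octapeptide_seq = octapeptide_seq,
    introns = introns,
    scaffold = scaffold,
    hd_class = hd_class,
    accession = accession,
    flags = as.character(flags)
  ), class = "hd_record")
}

empty_insertions <- function() {
  data.frame(after_column = integer(), inserted = character(),
             stringsAsFactors = FALSE)
}

empty_introns <- function() {
  data.frame(codon = integer(), placement = character(), flag = character(),
             stringsAsFactors = FALSE)
}

# uppercase, keep AA/-/X, map anything else to X (warn)
normalize_residues <- function(residues, id = "?") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  bad <- !(chars %in% c(AA20, "-", "X"))
  if (any(bad)) {
    warning("record '", id, "': ", sum(bad),
            " unparseable residue character(s) mapped to 'X'", call. = FALSE)
    chars[bad] <- "X"
  }
  paste(chars, collapse = "")
}

#' @export
print.hd_record <- function(x, ...) {
  cat("<hd_record> ", x$id, if (!is.null(x$hd_class)) paste0(" [", x$hd_class, "]"), "\n", sep = "")
  cat("  residues: ", x$residues, "\n", sep = "")
  if (nrow(x$insertions)) {
    cat("  insertions: ",
        paste(sprintf("insert(%s) %d", x$insertions$inserted,
                      x$insertions$after_column + 1L), collapse = "; "), "\n", sep = "")
  }
  if (length(x$secondary_domains)) {
    cat("  domains: ", paste(x$secondary_domains, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$introns)) {
    cat("  introns: ", format_intron_notation(x$introns), "\n", sep = "")
  }
  invisible(x)
}

#' Parse homeobox intron-position notation
#'
#' Intron positions within a homeobox are written as comma-separated tokens:
#' a bare codon number (`"37"`) for an intron interrupting that codon
#' (placement `WITHIN`), or `"47/48"` (equivalently `"47-48"`) for an intron
#' falling on the boundary between consecutive codons (placement
#' `BETWEEN_NEXT`, anchored at the first codon). A trailing `*` on a token is
#' preserved verbatim as an annotation flag. TALE-class homeoboxes are 63
#' codons long, so codon numbers up to 63 are accepted.
#'
#' @param text notation string, e.g. `"2,47/48"`; empty or `NA` means no
#'   introns.
#' @return `data.frame` with columns `codon` (integer), `placement`
#'   (`"WITHIN"` or `"BETWEEN_NEXT"`) and `flag` (`"*"` or `NA`).
#' @examples
#' parse_intron_notation("2,47/48")
#' parse_intron_notation("57*")
#' @export
parse_intron_notation <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(empty_introns())
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  out <- lapply(tokens, function(tok) {
    flag <- NA_character_
    if (grepl("\\*$", tok)) {
      flag <- "*"
      tok <- sub("\\*$", "", tok)
    }
    if (grepl("^[0-9]+$", tok)) {
      data.frame(codon = as.integer(tok), placement = "WITHIN", flag = flag,
                 stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+[/-][0-9]+$", tok)) {
      parts <- as.integer(strsplit(tok, "[/-]")[[1]])
      if (parts[2] != parts[1] + 1L) {
        stop("intron notation '", tok, "': boundary must be between consecutive codons",
             call. = FALSE)
      }
      data.frame(codon = parts[1], placement = "BETWEEN_NEXT", flag = flag,
                 stringsAsFactors = FALSE)
    } else {
      stop("unparseable intron token: '", tok, "'", call. = FALSE)
    }
  })
  res <- do.call(rbind, out)
  if (any(res$codon < 1L | res$codon > 63L)) {
    stop("intron codon out of range 1..63", call. = FALSE)
  }
  res
}

#' Format intron positions back to notation
#'
#' Inverse of [parse_intron_notation()]: renders a parsed intron table as the
#' compact comma-separated notation.
#'
#' @param introns `data.frame` with columns `codon`, `placement`, `flag`.
#' @return a single notation string (empty string for no introns).
#' @export
format_intron_notation <- function(introns) {
  if (!nrow(introns)) return("")
  tok <- ifelse(introns$placement == "BETWEEN_NEXT",
                paste0(introns$codon, "/", introns$codon + 1L),
                as.character(introns$codon))
  tok <- ifelse(!is.na(introns$flag), paste0(tok, introns$flag), tok)
  paste(tok, collapse = ",")
}

#' Residue matrix of a record list
#'
#' @param records list of [hd_record()] objects.
#' @return character matrix (one row per record, 60 columns) with record ids
#'   as row names.
#' @export
residue_matrix <- function(records) {
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, lapply(records, function(r) strsplit(r$residues, "")[[1]]))
  rownames(m) <- ids
  m
}
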