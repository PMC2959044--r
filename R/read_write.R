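# Readers and writers for homeodomain alignments, catalogs and scaffold
# coordinates. FASTA goes through Biostrings, Phylip through phangorn, BED
# through rtracklayer; the Table-1-style catalog TSV is this package's own
# exchange format.

CLASS_SECTION_MAP <- c(
  TALE = "TALE", POU = "POU", LIM = "LIM", SIX = "SINE", SINE = "SINE",
  ANTP = "ANTP", PRD = "PRD", HNF = "HNF", CUT = "CUT", PROS = "PROS",
  ZF = "ZF", CERS = "CERS", UNCLASSIFIED = "UNCLASSIFIED"
)

DOMAIN_TOKEN_MAP <- c(
  Pbx = "PBC", Pou = "POU_SPECIFIC", Lim = "LIM", Six = "SIX",
  MeisA = "MEIS_A", MeisB = "MEIS_B", MeisD = "MEIS_D",
  Octapeptide = "OCTAPEPTIDE", Paired = "PAIRED"
)

#' Read a homeodomain alignment
#'
#' Reads an aligned set of homeodomain sequences from FASTA or Phylip and
#' normalizes every sequence to the 60-column homeodomain frame. Sequences
#' longer than 60 columns must declare their insertions, either in the FASTA
#' description line using the catalog notation `insert(SEQ) N` (the inserted
#' content begins at raw position `N`) or through the `declared_insertions`
#' argument; the declared content is excised with [excise_insertions()] and
#' kept losslessly on the record. Unparseable residue characters are mapped
#' to `X` with a warning.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (sequential or interleaved, relaxed
#'   names).
#' @param declared_insertions optional named list (by record id) of
#'   `data.frame(after_column =, length =)` declaring insertions for sequences
#'   longer than 60 columns.
#' @return list of [hd_record()] objects, in file order.
#' @export
read_hd_alignment <- function(path, format = c("fasta", "phylip"),
                              declared_insertions = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    headers <- names(ss)
    seqs <- as.character(ss)
    ids <- sub("\\s.*$", "", headers)
    descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  } else {
    pd <- phangorn::read.phyDat(path, format = "phylip", type = "AA")
    m <- as.character(pd)
    ids <- rownames(m)
    seqs <- apply(m, 1L, paste, collapse = "")
    descs <- rep("", length(ids))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ins <- parse_insert_tokens(descs[i])
    raw <- toupper(seqs[i])
    if (nchar(raw) > 60L) {
      decl <- NULL
      if (!is.null(declared_insertions) && !is.null(declared_insertions[[ids[i]]])) {
        decl <- declared_insertions[[ids[i]]]
      } else if (nrow(ins)) {
        decl <- data.frame(after_column = ins$after_column,
                           length = nchar(ins$inserted))
      }
      if (is.null(decl)) {
        stop("sequence '", ids[i], "' has ", nchar(raw),
             " columns but no declared insertions", call. = FALSE)
      }
      norm <- excise_insertions(raw, decl)
      records[[i]] <- hd_record(ids[i], norm$residues, insertions = norm$insertions)
    } else if (nchar(raw) == 60L) {
      records[[i]] <- hd_record(ids[i], raw,
                                insertions = if (nrow(ins)) ins else NULL)
    } else {
      stop("alignment shape error: sequence '", ids[i], "' has ", nchar(raw),
           " columns (expected >= 60)", call. = FALSE)
    }
  }
  lens <- vapply(records, function(r) nchar(r$residues), 1L)
  stopifnot(all(lens == 60L))
  records
}

# "insert(NLA) 23" tokens from a FASTA description; the printed position is
# where the inserted content starts in the raw sequence, so after_column is
# one less.
parse_insert_tokens <- function(desc) {
  out <- empty_insertions()
  if (!nzchar(desc)) return(out)
  m <- gregexpr("insert\\(([A-Za-z]+)\\)\\s*([0-9]+)", desc)
  hits <- regmatches(desc, m)[[1]]
  for (h in hits) {
    content <- toupper(sub("insert\\(([A-Za-z]+)\\).*", "\\1", h))
    pos <- as.integer(sub(".*\\)\\s*([0-9]+)$", "\\1", h))
    out <- rbind(out, data.frame(after_column = pos - 1L, inserted = content,
                                 stringsAsFactors = FALSE))
  }
  out
}

format_insert_tokens <- function(insertions) {
  if (!nrow(insertions)) return("")
  paste(sprintf("insert(%s) %d", insertions$inserted,
                insertions$after_column + 1L), collapse = " ")
}

#' Write homeodomain records as FASTA
#'
#' The 60-column normalized residues are written; recorded insertions are
#' rendered as `insert(SEQ) N` tokens on the description line so that
#' [read_hd_alignment()] round-trips ids, residues and insertions exactly.
#'
#' @param records list of [hd_record()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hd_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    desc <- format_insert_tokens(r$insertions)
    header <- if (nzchar(desc)) paste(r$id, desc) else r$id
    c(paste0(">", header), r$residues)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Table-1-style homeodomain catalog
#'
#' The catalog is a TSV with columns `name`, `domain`, `signature`,
#' `intron_codons`, `accession`. Rows whose `name` is a bare class label
#' (`TALE`, `POU`, `LIM`, `SIX`, `ANTP`, `PRD`, `Unclassified`, ...) are
#' section headers: all following gene rows take that class (`SIX` maps to
#' the SINE class). The `domain` column holds comma-separated secondary
#' domain tokens (`Pbx`, `Pou`, `Lim`, `Six`, `MeisA`, `MeisD`,
#' `Octapeptide`, ...); the `signature` column holds diagnostic-signature
#' labels (`NKL`, `HOXL`, `HOXL2`, `PRD`) and/or `insert(SEQ) N` insertion
#' annotations; `intron_codons` uses the notation of
#' [parse_intron_notation()]. A trailing `*` on an accession is preserved as
#' a record flag.
#'
#' Catalog rows carry no sequence, so `residues` is set to 60 `X` columns.
#'
#' @param path TSV file path.
#' @return list of [hd_record()] objects with `hd_class` filled in; signature
#'   labels are kept as `SIG:<label>` flags.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  needed <- c("name", "domain", "signature", "intron_codons", "accession")
  if (!all(needed %in% names(df))) {
    stop("catalog must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  records <- list()
  current_class <- NULL
  for (i in seq_len(nrow(df))) {
    row <- lapply(df[i, needed], trimws)
    if (!nzchar(row$name)) next
    is_section <- !nzchar(row$domain) && !nzchar(row$signature) &&
      !nzchar(row$intron_codons) && !nzchar(row$accession) &&
      !grepl("^Ml|^[A-Z][a-z][A-Z0-9]", row$name)
    key <- toupper(row$name)
    if (key %in% names(CLASS_SECTION_MAP) && is_section) {
      current_class <- CLASS_SECTION_MAP[[key]]
      next
    }
    if (is_section) {
      stop("unknown class section header: '", row$name, "'", call. = FALSE)
    }
    if (is.null(current_class)) {
      stop("catalog row '", row$name, "' appears before any class section header",
           call. = FALSE)
    }
    domains <- character()
    if (nzchar(row$domain)) {
      toks <- trimws(strsplit(row$domain, ",")[[1]])
      unknown <- setdiff(toks, names(DOMAIN_TOKEN_MAP))
      if (length(unknown)) {
        stop("catalog row '", row$name, "': unknown domain token(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      domains <- unname(DOMAIN_TOKEN_MAP[toks])
    }
    flags <- character()
    insertions <- empty_insertions()
    if (nzchar(row$signature)) {
      toks <- trimws(strsplit(row$signature, ",")[[1]])
      for (tok in toks) {
        if (grepl("^insert\\(", tok)) {
          insertions <- rbind(insertions, parse_insert_tokens(tok))
        } else {
          flags <- c(flags, paste0("SIG:", tok))
        }
      }
    }
    accession <- if (nzchar(row$accession)) row$accession else NULL
    if (!is.null(accession) && grepl("\\*$", accession)) {
      flags <- c(flags, "ACCESSION_FLAGGED")
      accession <- sub("\\*$", "", accession)
    }
    records[[length(records) + 1L]] <- hd_record(
      id = row$name,
      residues = strrep("X", 60L),
      insertions = if (nrow(insertions)) insertions else NULL,
      secondary_domains = domains,
      introns = row$intron_codons,
      hd_class = current_class,
      accession = accession,
      flags = flags
    )
  }
  records
}

#' Write records as a Table-1-style catalog TSV
#'
#' Inverse of [read_catalog()] for records that carry a class: rows are
#' grouped into class sections in first-appearance order.
#'
#' @param records list of [hd_record()] objects, all with `hd_class` set.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path) {
  classes <- vapply(records, function(r) r$hd_class %||% "UNCLASSIFIED", "")
  inv_domain <- setNames(names(DOMAIN_TOKEN_MAP), DOMAIN_TOKEN_MAP)
  lines <- c("name\tdomain\tsignature\tintron_codons\taccession")
  for (cl in unique(classes)) {
    section <- if (cl == "SINE") "SIX" else if (cl == "UNCLASSIFIED") "Unclassified" else cl
    lines <- c(lines, paste0(section, "\t\t\t\t"))
    for (r in records[classes == cl]) {
      sig <- c(sub("^SIG:", "", grep("^SIG:", r$flags, value = TRUE)),
               if (nrow(r$insertions)) format_insert_tokens(r$insertions))
      acc <- r$accession %||% ""
      if (nzchar(acc) && "ACCESSION_FLAGGED" %in% r$flags) acc <- paste0(acc, "*")
      lines <- c(lines, paste(
        r$id,
        paste(inv_domain[r$secondary_domains], collapse = ", "),
        paste(sig, collapse = ", "),
        format_intron_notation(r$introns),
        acc, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read homeobox scaffold coordinates from BED
#'
#' Reads a BED file (chrom, start, end, name, score, strand; 0-based
#' half-open) of homeobox spans.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `scaffold_id`, `start`, `end`, `name`,
#'   `strand`.
#' @export
read_scaffold_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    # GRanges is 1-based closed; convert back to BED 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = gr$name,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Attach scaffold coordinates to records
#'
#' @param records list of [hd_record()] objects.
#' @param coords `data.frame` as from [read_scaffold_bed()]; matched to
#'   records by `name`.
#' @return the record list with `scaffold` filled in where matched.
#' @export
attach_scaffolds <- function(records, coords) {
  idx <- match(vapply(records, `[[`, "", "id"), coords$name)
  for (i in seq_along(records)) {
    if (!is.na(idx[i])) {
      j <- idx[i]
      records[[i]]$scaffold <- list(scaffold_id = coords$scaffold_id[j],
                                    start = coords$start[j], end = coords$end[j],
                                    strand = coords$strand[j])
    }
  }
  records
}

#' Tally class assignments
#'
#' Counts records or assignments per homeodomain class; classes absent from
#' the input are reported as zero, so the counts always sum to the input
#' length.
#'
#' @param x a list of [hd_record()] objects with `hd_class` set, a list of
#'   assignments from [assign_class()], or a `data.frame` with an `hd_class`
#'   column.
#' @return named integer vector over all classes.
#' @export
tally_classes <- function(x) {
  if (is.data.frame(x)) {
    classes <- x$hd_class
  } else {
    classes <- vapply(x, function(r) r$hd_class %||% "UNCLASSIFIED", "")
  }
  bad <- setdiff(classes, HD_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(unique(bad), collapse = ", "),
                        call. = FALSE)
  tab <- table(factor(classes, levels = HD_CLASSES))
  setNames(as.integer(tab), names(tab))
}
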