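# Diagnostic-residue signature matching and rule-based class/subclass
# assignment. A signature is a position-anchored run of per-column residue
# constraints on the 60-column homeodomain frame, written in a compact
# bracket notation: "QV" fixes two columns, "[AKST]" allows a set,
# "[^DGHM]" disallows a set. Gaps and unknown residues never satisfy a
# signature column: a signature is a presence claim.

#' Define a diagnostic residue signature
#'
#' @param name signature name (e.g. `"NKL"`).
#' @param start_column 1-based alignment column where the signature starts.
#' @param pattern bracket-notation pattern: a sequence of single residues,
#'   `[SET]` allowed-set and `[^SET]` disallowed-set tokens, one per column.
#' @return object of class `signature_definition` with fields `name`,
#'   `start_column`, `pattern` and `columns` (parsed per-column constraints).
#' @examples
#' nkl <- signature_definition("NKL", 41, "[AKST][DENPS][LAST]QV")
#' signature_width(nkl)
#' @export
signature_definition <- function(name, start_column, pattern) {
  start_column <- as.integer(start_column)
  cols <- parse_signature_pattern(pattern)
  if (start_column < 1L || start_column + length(cols) - 1L > 60L) {
    stop("signature '", name, "': window [", start_column, ", ",
         start_column + length(cols) - 1L, "] must lie within columns 1..60",
         call. = FALSE)
  }
  structure(list(name = name, start_column = start_column,
                 pattern = pattern, columns = cols),
            class = "signature_definition")
}

parse_signature_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  cols <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      negate <- FALSE
      if (j <= length(chars) && chars[j] == "^") {
        negate <- TRUE
        j <- j + 1L
      }
      k <- j
      while (k <= length(chars) && chars[k] != "]") k <- k + 1L
      if (k > length(chars)) stop("unterminated '[' in signature pattern", call. = FALSE)
      set <- chars[j:(k - 1L)]
      if (!length(set) || !all(set %in% AA20)) {
        stop("signature set must be a non-empty subset of the 20 amino acids",
             call. = FALSE)
      }
      cols[[length(cols) + 1L]] <- list(type = if (negate) "disallowed" else "allowed",
                                        residues = set)
      i <- k + 1L
    } else {
      if (!chars[i] %in% AA20) {
        stop("invalid residue '", chars[i], "' in signature pattern", call. = FALSE)
      }
      cols[[length(cols) + 1L]] <- list(type = "allowed", residues = chars[i])
      i <- i + 1L
    }
  }
  cols
}

#' @export
print.signature_definition <- function(x, ...) {
  cat("<signature> ", x$name, ": columns ", x$start_column, "-",
      x$start_column + length(x$columns) - 1L, " ", x$pattern, "\n", sep = "")
  invisible(x)
}

#' Width (number of columns) of a signature
#' @param sig a [signature_definition()].
#' @return integer number of alignment columns the signature spans.
#' @export
signature_width <- function(sig) length(sig$columns)

#' Load the packaged diagnostic signature set
#'
#' The shipped configuration transcribes the diagnostic residue patterns used
#' for homeodomain subclassification: the NKL block at columns 41-45, the
#' HOXL block at 46-58, the HOXL2 block at 16-19, the PRD (paired) block at
#' 16-26, and the SIX1/2 family `ETSY` pattern at columns 3-6.
#'
#' @param path optional TSV with columns `name`, `start_column`, `pattern`;
#'   defaults to the packaged configuration.
#' @return named list of [signature_definition()] objects.
#' @export
load_signatures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signatures.tsv", package = "homeorep",
                        mustWork = TRUE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  sigs <- lapply(seq_len(nrow(df)), function(i) {
    signature_definition(df$name[i], as.integer(df$start_column[i]), df$pattern[i])
  })
  setNames(sigs, df$name)
}

#' Match a signature against a record
#'
#' `TRUE` iff every signature column holds a residue satisfying its
#' allowed/disallowed constraint. A gap (`-`) or unknown (`X`) anywhere in
#' the window fails the match.
#'
#' @param record an [hd_record()] or a plain 60-character residue string.
#' @param sig a [signature_definition()].
#' @return logical scalar.
#' @export
match_signature <- function(record, sig) {
  residues <- if (inherits(record, "hd_record")) record$residues else record
  chars <- strsplit(residues, "")[[1]]
  window <- chars[sig$start_column + seq_along(sig$columns) - 1L]
  if (any(window %in% c("-", "X"))) return(FALSE)
  for (i in seq_along(sig$columns)) {
    col <- sig$columns[[i]]
    hit <- window[i] %in% col$residues
    if (col$type == "allowed" && !hit) return(FALSE)
    if (col$type == "disallowed" && hit) return(FALSE)
  }
  TRUE
}

#' Number of k-mers matching a signature
#'
#' Counts the strings over the 20-residue alphabet, of the signature's width,
#' that satisfy every column constraint: the product of per-column admissible
#' set sizes (a disallowed set of size s admits 20 - s residues).
#'
#' @param sig a [signature_definition()].
#' @return numeric count.
#' @export
signature_match_count <- function(sig) {
  prod(vapply(sig$columns, function(col) {
    if (col$type == "allowed") length(col$residues) else 20L - length(col$residues)
  }, 1L))
}

#' Call the residue at homeodomain position 50
#'
#' Position 50 is the homeodomain DNA-binding specificity residue: Q50, K50
#' and S50 define the PRD subclasses, K50 is characteristic of the SINE
#' class, and G50 of the Pbx family within TALE.
#'
#' @param record an [hd_record()] or 60-character residue string.
#' @return one of `"Q"`, `"K"`, `"S"`, `"G"`, `"OTHER"`, or `"UNKNOWN"` when
#'   column 50 is a gap or `X`.
#' @export
call_position50 <- function(record) {
  residues <- if (inherits(record, "hd_record")) record$residues else record
  r <- substr(residues, 50L, 50L)
  if (r %in% c("-", "X")) return("UNKNOWN")
  if (r %in% c("Q", "K", "S", "G")) return(r)
  "OTHER"
}

# structural windows on the 60-column frame (after_column coordinates):
# the loop between helices 1 and 2, and helix 3
LOOP_WINDOW <- 20:25
HELIX3_WINDOW <- 31:45

#' Classify a record's homeodomain insertion
#'
#' TALE-class homeodomains carry a characteristic three-residue insertion in
#' the loop between the first and second alpha-helices. Other insertions in
#' that loop are atypical; insertions falling in the third helix form a
#' separate category.
#'
#' @param record an [hd_record()].
#' @return `"TALE_TYPICAL"` (exactly one 3-residue insertion in the loop
#'   window), `"ATYPICAL_LOOP"`, `"HELIX3"`, or `"NONE"`.
#' @export
classify_insertion <- function(record) {
  ins <- record$insertions
  if (!nrow(ins)) return("NONE")
  in_loop <- ins$after_column %in% LOOP_WINDOW
  if (nrow(ins) == 1L && in_loop[1] && nchar(ins$inserted[1]) == 3L) {
    return("TALE_TYPICAL")
  }
  if (any(in_loop)) return("ATYPICAL_LOOP")
  if (any(ins$after_column %in% HELIX3_WINDOW)) return("HELIX3")
  "NONE"
}

#' Scan an upstream peptide for an octapeptide motif
#'
#' A short conserved eight-residue motif upstream of the homeodomain is a
#' hallmark of a subset of PRD-class genes. The printed examples give no
#' formal rule, so this scanner applies a documented stand-in score against
#' the consensus `x-x-I-x-x-L-L-x`: a window is a candidate when positions
#' 5-8 contain at least two residues from \{L, I, V\} and position 6 or 7 is
#' an L; its score is the number of positions among \{3, 6, 7\} holding a
#' residue from \{L, I, V\}. Score 3 is `CLEAR`, score 2 `POSSIBLE`. The
#' best-scoring (leftmost on ties) window is reported.
#'
#' @param upstream_peptide residue string upstream of the homeodomain.
#' @return `list(seq = <8-mer or NA>, confidence = "CLEAR"|"POSSIBLE"|"NONE")`.
#' @examples
#' detect_octapeptide("SSISSLLS")$confidence  # "CLEAR"
#' @export
detect_octapeptide <- function(upstream_peptide) {
  pep <- toupper(upstream_peptide)
  n <- nchar(pep)
  if (n < 8L) return(list(seq = NA_character_, confidence = "NONE"))
  hydro <- c("L", "I", "V")
  best <- list(seq = NA_character_, score = 0L, start = NA_integer_)
  for (s in seq_len(n - 7L)) {
    w <- strsplit(substr(pep, s, s + 7L), "")[[1]]
    gate <- sum(w[5:8] %in% hydro) >= 2L && any(w[6:7] == "L")
    if (!gate) next
    score <- sum(w[c(3L, 6L, 7L)] %in% hydro)
    if (score > best$score) best <- list(seq = paste(w, collapse = ""),
                                         score = score, start = s)
  }
  conf <- if (best$score >= 3L) "CLEAR" else if (best$score == 2L) "POSSIBLE" else "NONE"
  list(seq = if (conf == "NONE") NA_character_ else best$seq, confidence = conf)
}

# class implied by each evidence item
DOMAIN_CLASS_MAP <- c(POU_SPECIFIC = "POU", SIX = "SINE", LIM = "LIM",
                      PBC = "TALE", MEIS_A = "TALE", MEIS_B = "TALE",
                      MEIS_D = "TALE", OCTAPEPTIDE = "PRD", PAIRED = "PRD")
SIGNATURE_CLASS_MAP <- c(NKL = "ANTP", HOXL = "ANTP", HOXL2 = "ANTP",
                         PRD = "PRD", SINE_ETSY = "SINE")
EVIDENCE_PRECEDENCE <- c("SECONDARY_DOMAIN", "INSERTION", "TREE_PLACEMENT",
                         "SIGNATURE", "INTRON")

#' Assign a homeodomain class and subclass to a record
#'
#' Collects evidence of five kinds and resolves the class by fixed
#' precedence: secondary domains, then a typical TALE loop insertion, then a
#' tree-placement hint, then diagnostic residue signatures, then the
#' PRD-characteristic intron at the codon 46/47 boundary. Precedence mirrors
#' observed practice: an upstream SIX domain overrides an NKL signature, for
#' instance. When evidence kinds disagree on the class the highest-precedence
#' kind wins and `conflict` is set. Subclasses: within ANTP, an NKL signature
#' gives subclass NKL, and HOXL/HOXL2 signatures without NKL mark the record
#' as extended-Hox-related; within PRD the subclass is the position-50 call
#' (Q50/K50/S50). A record with no evidence at all is UNCLASSIFIED.
#'
#' Signature labels recorded on catalog rows (flags `SIG:<name>`) count as
#' signature evidence, so catalog records without sequence still classify.
#'
#' @param record an [hd_record()].
#' @param tree_hint optional class label from tree placement.
#' @param signatures named list of [signature_definition()]s, by default the
#'   packaged set.
#' @return object of class `hd_class_assignment`: `list(record_id, hd_class,
#'   subclass, evidence = data.frame(kind, detail), conflict)`.
#' @export
assign_class <- function(record, tree_hint = NULL, signatures = load_signatures()) {
  ev <- data.frame(kind = character(), detail = character(), class = character(),
                   stringsAsFactors = FALSE)
  add <- function(kind, detail, class) {
    rbind(ev, data.frame(kind = kind, detail = detail, class = class,
                         stringsAsFactors = FALSE))
  }
  for (d in record$secondary_domains) {
    ev <- add("SECONDARY_DOMAIN", d, unname(DOMAIN_CLASS_MAP[d]))
  }
  ins_type <- classify_insertion(record)
  if (ins_type == "TALE_TYPICAL") {
    ev <- add("INSERTION", "TALE_TYPICAL", "TALE")
  }
  if (!is.null(tree_hint)) {
    tree_hint <- match.arg(tree_hint, HD_CLASSES)
    ev <- add("TREE_PLACEMENT", tree_hint, tree_hint)
  }
  sig_hits <- character()
  for (sig in signatures) {
    if (match_signature(record, sig)) {
      sig_hits <- c(sig_hits, sig$name)
      ev <- add("SIGNATURE", sig$name, unname(SIGNATURE_CLASS_MAP[sig$name]))
    }
  }
  for (f in grep("^SIG:", record$flags, value = TRUE)) {
    lab <- sub("^SIG:", "", f)
    if (lab %in% names(SIGNATURE_CLASS_MAP) && !lab %in% sig_hits) {
      sig_hits <- c(sig_hits, lab)
      ev <- add("SIGNATURE", paste0("catalog:", lab),
                unname(SIGNATURE_CLASS_MAP[lab]))
    }
  }
  if (nrow(record$introns)) {
    prd_intron <- any(record$introns$codon == 46L &
                        record$introns$placement == "BETWEEN_NEXT")
    if (prd_intron) ev <- add("INTRON", "46/47", "PRD")
  }

  if (!nrow(ev)) {
    return(structure(list(record_id = record$id, hd_class = "UNCLASSIFIED",
                          subclass = NA_character_,
                          evidence = ev[, c("kind", "detail")], conflict = FALSE),
                     class = "hd_class_assignment"))
  }
  ev$kind <- factor(ev$kind, levels = EVIDENCE_PRECEDENCE)
  ev <- ev[order(ev$kind), , drop = FALSE]
  ev$kind <- as.character(ev$kind)
  hd_class <- ev$class[!is.na(ev$class)][1]
  conflict <- length(unique(ev$class[!is.na(ev$class)])) > 1L

  subclass <- NA_character_
  if (hd_class == "ANTP") {
    if ("NKL" %in% sig_hits) {
      subclass <- "NKL"
    } else if (any(c("HOXL", "HOXL2") %in% sig_hits)) {
      subclass <- "EXTENDED_HOX"
    }
  } else if (hd_class == "PRD") {
    p50 <- call_position50(record)
    if (p50 %in% c("Q", "K", "S")) subclass <- paste0(p50, "50")
  }
  structure(list(record_id = record$id, hd_class = hd_class, subclass = subclass,
                 evidence = ev[, c("kind", "detail")], conflict = conflict),
            class = "hd_class_assignment")
}

#' @export
print.hd_class_assignment <- function(x, ...) {
  cat("<assignment> ", x$record_id, " -> ", x$hd_class,
      if (!is.na(x$subclass)) paste0(" / ", x$subclass),
      if (x$conflict) "  (conflicting evidence)", "\n", sep = "")
  if (nrow(x$evidence)) {
    cat(paste0("  ", x$evidence$kind, ": ", x$evidence$detail, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Classify a list of records
#'
#' @param records list of [hd_record()] objects.
#' @param tree_hints optional named character vector of class hints by record
#'   id.
#' @param signatures signature set (see [load_signatures()]).
#' @return list of `hd_class_assignment` objects.
#' @export
classify_records <- function(records, tree_hints = NULL,
                             signatures = load_signatures()) {
  lapply(records, function(r) {
    hint <- if (!is.null(tree_hints) && r$id %in% names(tree_hints)) {
      tree_hints[[r$id]]
    }
    assign_class(r, tree_hint = hint, signatures = signatures)
  })
}

#' Tabulate class assignments
#'
#' @param assignments list of `hd_class_assignment` objects.
#' @return `data.frame` with columns `record_id`, `species`, `hd_class`,
#'   `subclass`, `conflict`.
#' @export
assignments_table <- function(assignments) {
  data.frame(
    record_id = vapply(assignments, `[[`, "", "record_id"),
    species = substr(vapply(assignments, `[[`, "", "record_id"), 1L, 2L),
    hd_class = vapply(assignments, `[[`, "", "hd_class"),
    subclass = vapply(assignments, `[[`, NA_character_, "subclass"),
    conflict = vapply(assignments, `[[`, NA, "conflict"),
    stringsAsFactors = FALSE
  )
}
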