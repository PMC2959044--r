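# Genomic linkage scanning: homeoboxes that share a scaffold are reported as
# linked pairs with the gap between their nearest span ends and their strand
# orientation. Coordinates are 0-based half-open throughout.

#' Find pairs of homeoboxes co-located on a scaffold
#'
#' Every unordered pair of records sharing a `scaffold_id` is reported. The
#' distance is the nearest-end gap, `max(0, later.start - earlier.end)`, which
#' is strand-independent; orientation is derived from the strand combination
#' in scaffold order: same strands give `SAME_STRAND`, `+` then `-` gives
#' `CONVERGENT` (the genes point at each other) and `-` then `+` gives
#' `DIVERGENT`. Overlapping spans on one scaffold are an error.
#'
#' @param records list of [hd_record()] objects; records without scaffold
#'   coordinates are ignored.
#' @return `data.frame` with columns `id_a`, `id_b` (lexicographically
#'   ordered within each pair), `scaffold_id`, `gap_bp`, `orientation`,
#'   sorted by scaffold then gap.
#' @export
find_linked_pairs <- function(records) {
  has_coord <- vapply(records, function(r) !is.null(r$scaffold), NA)
  recs <- records[has_coord]
  empty <- data.frame(id_a = character(), id_b = character(),
                      scaffold_id = character(), gap_bp = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (length(recs) < 2L) return(empty)
  tab <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    scaffold_id = vapply(recs, function(r) r$scaffold$scaffold_id, ""),
    start = vapply(recs, function(r) as.numeric(r$scaffold$start), 1),
    end = vapply(recs, function(r) as.numeric(r$scaffold$end), 1),
    strand = vapply(recs, function(r) r$scaffold$strand, ""),
    stringsAsFactors = FALSE
  )
  out <- empty
  for (sc in unique(tab$scaffold_id)) {
    sub <- tab[tab$scaffold_id == sc, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$start), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        if (sub$start[j] < sub$end[i]) {
          stop("overlap error: '", sub$id[i], "' and '", sub$id[j],
               "' overlap on scaffold ", sc, call. = FALSE)
        }
        gap <- max(0L, sub$start[j] - sub$end[i])
        orientation <- if (sub$strand[i] == sub$strand[j]) {
          "SAME_STRAND"
        } else if (sub$strand[i] == "+") "CONVERGENT" else "DIVERGENT"
        pair <- sort(c(sub$id[i], sub$id[j]))
        out <- rbind(out, data.frame(
          id_a = pair[1], id_b = pair[2], scaffold_id = sc, gap_bp = gap,
          orientation = orientation, stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$scaffold_id, out$gap_bp), , drop = FALSE]
}

#' Format a base-pair gap in kilobases
#'
#' @param gap_bp integer gap in base pairs.
#' @return character, e.g. `"4.7 KB"` (one decimal).
#' @export
format_kb <- function(gap_bp) sprintf("%.1f KB", gap_bp / 1000)

#' Render a linkage report
#'
#' One line per linked pair, with the gap formatted in kilobases to one
#' decimal and the orientation drawn with arrowheads (`>` / `<`) matching the
#' strand of each partner in scaffold order.
#'
#' @param pairs `data.frame` from [find_linked_pairs()].
#' @return character vector of report lines (header first).
#' @export
render_linkage_report <- function(pairs) {
  header <- "id_a\tid_b\tscaffold\tdistance\torientation"
  if (!nrow(pairs)) return(header)
  arrows <- c(SAME_STRAND = ">--->", CONVERGENT = ">---<", DIVERGENT = "<--->")
  c(header, sprintf("%s\t%s\t%s\t%s\t%s", pairs$id_a, pairs$id_b,
                    pairs$scaffold_id, format_kb(pairs$gap_bp),
                    arrows[pairs$orientation]))
}
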