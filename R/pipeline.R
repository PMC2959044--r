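# End-to-end orchestration: classify -> NJ -> midpoint root -> clade stats ->
# linkage -> presence/absence matrix, writing every intermediate plus a run
# manifest. Also the class/subclass presence matrix builder.

PRESENCE_ROWS <- data.frame(
  hd_class = c("ANTP", "ANTP", "ANTP", "ANTP", "ANTP",
               "PRD", "PRD", "PRD", "PRD",
               "LIM", "POU", "SINE", "TALE", "HNF", "CUT", "PROS", "ZF", "CERS"),
  subclass = c(NA, "HOX", "PARAHOX", "EXTENDED_HOX", "NKL",
               NA, "Q50", "S50", "K50",
               NA, NA, NA, NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE
)

#' Build a class/subclass presence-absence matrix
#'
#' One row per class or subclass in the conventional reporting order (ANTP
#' with Hox, ParaHox, Extended Hox and NKL subclass rows; PRD with Q50, S50
#' and K50 rows; then the remaining classes); one column per species. A cell
#' is PRESENT iff the species has at least one assignment of that class (for
#' class rows) or of that class and subclass (for subclass rows) — so a K50
#' call in a SINE-class gene never switches the PRD K50 row. A class row with
#' any PRESENT subclass row is itself PRESENT.
#'
#' @param assignments `data.frame` with columns `species`, `hd_class`,
#'   `subclass` ([assignments_table()] output, possibly combined over
#'   species), or a list of `hd_class_assignment` objects for a single
#'   species (then `species` must name it).
#' @param species optional character vector fixing the column order; defaults
#'   to the species present in `assignments`.
#' @return `data.frame` with columns `hd_class`, `subclass`, then one
#'   `"PRESENT"`/`"ABSENT"` column per species.
#' @export
build_presence_matrix <- function(assignments, species = NULL) {
  if (!is.data.frame(assignments)) assignments <- assignments_table(assignments)
  stopifnot(all(c("species", "hd_class", "subclass") %in% names(assignments)))
  if (is.null(species)) species <- unique(assignments$species)
  out <- PRESENCE_ROWS
  for (sp in species) {
    sub <- assignments[assignments$species == sp, , drop = FALSE]
    cells <- character(nrow(out))
    for (i in seq_len(nrow(out))) {
      cl <- out$hd_class[i]; sc <- out$subclass[i]
      hit <- if (is.na(sc)) {
        any(sub$hd_class == cl)
      } else {
        any(sub$hd_class == cl & !is.na(sub$subclass) & sub$subclass == sc)
      }
      cells[i] <- if (hit) "PRESENT" else "ABSENT"
    }
    # a class with any PRESENT subclass is itself PRESENT
    for (cl in unique(out$hd_class)) {
      rows <- out$hd_class == cl
      if (any(cells[rows & !is.na(out$subclass)] == "PRESENT")) {
        cells[rows & is.na(out$subclass)] <- "PRESENT"
      }
    }
    out[[sp]] <- cells
  }
  out
}

#' Run the full repertoire analysis pipeline
#'
#' Stages, in order: load or simulate records; classify every record; build
#' the NJ tree from the 60-column alignment and midpoint-root it; compute the
#' per-species clade/branch-length report; scan scaffold linkage; build the
#' presence matrix. All intermediates are written to `out_dir` together with
#' a JSON manifest recording package version, seed and stage decisions. A
#' stage failure aborts with the stage name.
#'
#' @param config a list with either `alignment` (FASTA path; optional
#'   `catalog` TSV, `bed` scaffold BED, `tree_hints` named class hints) or
#'   `simulation` (a [simulation_config()]); optional `min_clade_size`
#'   (default 2) and `distance_model` (default `"poisson"`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the computed objects and output paths:
#'   `assignments`, `tree`, `clade_report`, `linkage`, `presence`, `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  min_size <- config$min_clade_size %||% 2L
  model <- config$distance_model %||% "poisson"
  seed <- NA_integer_
  tree_hints <- config$tree_hints

  records <- stage("input", {
    if (!is.null(config$simulation)) {
      seed <- config$simulation$seed
      simulate_repertoire(config$simulation)$records
    } else if (!is.null(config$alignment)) {
      recs <- read_hd_alignment(config$alignment)
      if (!is.null(config$catalog)) {
        cat_recs <- read_catalog(config$catalog)
        cat_ids <- vapply(cat_recs, `[[`, "", "id")
        recs <- lapply(recs, function(r) {
          k <- match(r$id, cat_ids)
          if (!is.na(k)) {
            cr <- cat_recs[[k]]
            r$secondary_domains <- cr$secondary_domains
            r$introns <- cr$introns
            r$hd_class <- cr$hd_class
            r$flags <- union(r$flags, cr$flags)
            if (!nrow(r$insertions)) r$insertions <- cr$insertions
          }
          r
        })
      }
      if (!is.null(config$bed)) {
        recs <- attach_scaffolds(recs, read_scaffold_bed(config$bed))
      }
      recs
    } else {
      stop("config needs either 'alignment' or 'simulation'")
    }
  })

  assignments <- stage("classify", {
    assignments_table(classify_records(records, tree_hints = tree_hints))
  })
  tree <- stage("nj", nj_from_records(records, model = model))
  rooted <- stage("midpoint-root", midpoint_root(tree))
  report <- stage("cladestats", build_clade_report(rooted, records,
                                                  min_size = min_size))
  linkage <- stage("linkage", find_linked_pairs(records))
  presence <- stage("presence", build_presence_matrix(assignments))

  paths <- list(
    assignments = file.path(out_dir, "assignments.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    clade_report = file.path(out_dir, "cladereport.tsv"),
    linkage = file.path(out_dir, "linkage.tsv"),
    presence = file.path(out_dir, "presence.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write.table(assignments, paths$assignments, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(rooted, paths$tree)
  write.table(report, paths$clade_report, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(render_linkage_report(linkage), paths$linkage)
  write.table(presence, paths$presence, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  manifest <- list(
    package = "homeorep",
    version = as.character(utils::packageVersion("homeorep")),
    seed = seed,
    distance_model = model,
    min_clade_size = min_size,
    n_records = length(records),
    n_clamped_branches = attr(tree, "n_clamped") %||% 0L,
    stages = c("classify", "nj", "midpoint-root", "cladestats", "linkage",
               "presence")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(assignments = assignments, tree = rooted,
                 clade_report = report, linkage = linkage, presence = presence,
                 paths = paths))
}
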