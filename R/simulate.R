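# Synthetic multi-species homeodomain repertoires with known ground truth.
# Gene families evolve along a fixed species tree under a birth-death copy
# process (duplications anywhere; losses only of duplicated copies, so each
# family keeps one surviving ortholog per species); sequences evolve down the
# resulting gene trees by per-site Poisson substitution with uniform
# replacement over the 19 alternative residues. Diagnostic signature motifs
# can be planted into designated families. Every stage of the analysis
# pipeline can then be checked against the recorded truth: the true gene
# tree, true root-to-tip depths, and the species-specific clade counts
# implied by the recorded duplication history.

#' Build a repertoire simulation configuration
#'
#' Defaults describe a small three-species world of deep divergences: two
#' sister lineages with terminal branches of 8 and 5 time units plus an
#' outgroup at depth 9, eight gene families, and a substitution rate of 0.05
#' per site per unit time — so sister species are separated by 0.5-0.8
#' expected substitutions per site, the divergence scale of real homeodomain
#' repertoires, while staying clearly below saturation. Duplication (0.0015)
#' and loss (0.00075) rates per lineage per unit time make lineage-specific
#' duplications rare discrete events (about 0.3 surviving duplications per
#' repertoire), the regime in which a 60-column alignment still lets
#' tree reconstruction recover the planted clades reliably.
#'
#' @param species_tree newick string or [ape::phylo]; tip labels are the
#'   two-character species prefixes.
#' @param n_families number of independent gene families.
#' @param duplication_rate duplication events per lineage per unit time.
#' @param loss_rate loss events per lineage per unit time; losses affect only
#'   duplicated copies, never the original lineage copy.
#' @param substitution_rate expected substitutions per site per unit time.
#' @param seq_length alignment length (default 60, the homeodomain frame).
#' @param planted_signatures named list of [signature_definition()]s planted
#'   one-per-family into the first families; `NULL` (default) plants the
#'   packaged NKL and PRD signatures; use `list()` to plant none.
#' @param family_stem stem branch length joining each family subtree to the
#'   repertoire root.
#' @param family_divergence expected substitutions per site separating each
#'   family's root sequence from the common repertoire ancestor (default
#'   0.25: families are divergent but alignable; combined with the stems this
#'   keeps every pairwise p-distance clearly below saturation, where the
#'   Poisson correction diverges). Deliberately independent of
#'   `substitution_rate`, which governs evolution within the simulated
#'   species set.
#' @param seed integer random seed (mandatory: simulations are reproducible
#'   by construction).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(species_tree = "((Ml:8,Aq:5):1,Nv:9);",
                              n_families = 8L, duplication_rate = 0.0015,
                              loss_rate = 0.00075, substitution_rate = 0.05,
                              seq_length = 60L, planted_signatures = NULL,
                              family_stem = 2.0, family_divergence = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  stopifnot(inherits(species_tree, "phylo"),
            all(nchar(species_tree$tip.label) == 2L),
            duplication_rate >= 0, loss_rate >= 0, substitution_rate >= 0,
            n_families >= 1L)
  if (is.null(planted_signatures)) {
    planted_signatures <- load_signatures()[c("NKL", "PRD")]
  }
  if (length(planted_signatures)) {
    max_end <- max(vapply(planted_signatures, function(s) {
      s$start_column + signature_width(s) - 1L
    }, 1L))
    if (seq_length < max_end) {
      stop("seq_length must cover every planted signature window", call. = FALSE)
    }
  }
  structure(list(species_tree = species_tree, n_families = as.integer(n_families),
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 substitution_rate = substitution_rate,
                 seq_length = as.integer(seq_length),
                 planted_signatures = planted_signatures,
                 family_stem = family_stem, family_divergence = family_divergence,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# one gene family along the species tree; returns a newick fragment (no stem)
# rooted at the species-tree root, with leaf labels <prefix>f<fam>n<k>.
# env carries: total (global leaf cap), counter per prefix.
sim_family_tree <- function(stree, fam, dup_rate, loss_rate, env) {
  fmt <- function(x) sprintf("%.17g", x)
  ntip <- ape::Ntip(stree)
  kids_of <- split(seq_len(nrow(stree$edge)), stree$edge[, 1])

  emit_leaf <- function(tip) {
    pfx <- stree$tip.label[tip]
    env$total <- env$total + 1L
    if (env$total > 10000L) {
      stop("runaway simulation: more than 10000 gene copies", call. = FALSE)
    }
    key <- paste0(pfx, fam)
    env$counter[[key]] <- (env$counter[[key]] %||% 0L) + 1L
    sprintf("%sf%02dn%02d", pfx, fam, env$counter[[key]])
  }

  # lineage at a species-tree node: returns list(frag, stem) or NULL
  at_node <- function(node) {
    if (node <= ntip) return(list(frag = emit_leaf(node), stem = 0))
    parts <- list()
    for (e in kids_of[[as.character(node)]]) {
      res <- on_edge(stree$edge[e, 2], stree$edge.length[e], is_original = TRUE)
      parts[[length(parts) + 1L]] <- res
    }
    combine(parts, 0)
  }

  # lineage travelling an edge towards `child` with `T_rem` time left
  on_edge <- function(child, T_rem, is_original) {
    t_dup <- if (dup_rate > 0) rexp(1L, dup_rate) else Inf
    t_loss <- if (!is_original && loss_rate > 0) rexp(1L, loss_rate) else Inf
    t <- min(t_dup, t_loss)
    if (t >= T_rem) {
      res <- descend(child, is_original)
      if (is.null(res)) return(NULL)
      return(list(frag = res$frag, stem = res$stem + T_rem))
    }
    if (t_loss < t_dup) return(NULL)
    a <- on_edge(child, T_rem - t, is_original)
    b <- on_edge(child, T_rem - t, FALSE)
    res <- combine(list(a, b), t)
    res
  }

  # lineage arriving at species-tree node `node` (speciation or tip)
  descend <- function(node, is_original) {
    if (node <= ntip) return(list(frag = emit_leaf(node), stem = 0))
    parts <- list()
    for (e in kids_of[[as.character(node)]]) {
      parts[[length(parts) + 1L]] <-
        on_edge(stree$edge[e, 2], stree$edge.length[e], is_original)
    }
    combine(parts, 0)
  }

  # merge surviving sublineages below a point `stem_used` into one fragment;
  # a single survivor collapses the would-be unifurcation
  combine <- function(parts, stem_used) {
    parts <- parts[!vapply(parts, is.null, NA)]
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) {
      return(list(frag = parts[[1]]$frag, stem = parts[[1]]$stem + stem_used))
    }
    inner <- vapply(parts, function(p) paste0(p$frag, ":", fmt(p$stem)), "")
    list(frag = paste0("(", paste(inner, collapse = ","), ")"), stem = stem_used)
  }

  at_node(ntip + 1L)
}

# evolve a root sequence down a gene (sub)tree; returns named leaf sequences
evolve_sequences <- function(tree, root_seq, rate) {
  ntip <- ape::Ntip(tree)
  L <- length(root_seq)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  for (k in rev(ape::postorder(tree))) {
    par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    s <- seqs[[par]]
    nsub <- stats::rpois(1L, rate * tree$edge.length[k] * L)
    if (nsub > 0L) {
      sites <- sample.int(L, nsub, replace = TRUE)
      for (site in sites) {
        s[site] <- sample(AA20[AA20 != s[site]], 1L)
      }
    }
    seqs[[ch]] <- s
  }
  out <- lapply(seq_len(ntip), function(i) seqs[[i]])
  names(out) <- tree$tip.label
  out
}

#' Simulate a multi-species homeodomain repertoire
#'
#' Runs the birth-death copy process of `config` for each gene family, builds
#' the joint gene tree (family subtrees joined at a common repertoire root by
#' stem branches), evolves sequences down it, and records the full truth.
#' Species-specific clade truth is computed directly from the true gene tree
#' with [count_species_specific_clades()], which by construction equals the
#' planted duplication history (duplications in terminal lineages whose
#' copies survive).
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_repertoire`: `list(records,
#'   true_gene_tree, truth, true_root_tip, planted_classes, config)` where
#'   `truth` is the per-prefix clade-count table and `planted_classes` maps
#'   family index to the planted signature name (or NA).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  env <- new.env()
  env$total <- 0L
  env$counter <- list()
  fmt <- function(x) sprintf("%.17g", x)

  frags <- character(config$n_families)
  for (f in seq_len(config$n_families)) {
    res <- sim_family_tree(config$species_tree, f, config$duplication_rate,
                           config$loss_rate, env)
    # stem accumulated above the family root is absorbed into the family stem
    frags[f] <- paste0(res$frag, ":", fmt(config$family_stem + res$stem))
  }
  txt <- if (config$n_families == 1L) {
    sub(":[0-9eE.+-]+$", ";", frags[1])
  } else {
    paste0("(", paste(frags, collapse = ","), ");")
  }
  true_tree <- ape::read.tree(text = txt)
  # rooted by construction (the repertoire root), even when multifurcating
  true_tree <- flag_rooted(true_tree)

  planted <- rep(NA_character_, config$n_families)
  sig_names <- names(config$planted_signatures)
  if (length(sig_names)) {
    planted[seq_len(min(length(sig_names), config$n_families))] <-
      sig_names[seq_len(min(length(sig_names), config$n_families))]
  }

  # family roots descend from one repertoire ancestor: divergent but
  # alignable, so cross-family distances never saturate
  ancestor <- sample(AA20, config$seq_length, replace = TRUE)
  mutate <- function(s, n_expected) {
    nsub <- stats::rpois(1L, n_expected)
    if (nsub > 0L) {
      sites <- sample.int(length(s), nsub, replace = TRUE)
      for (site in sites) s[site] <- sample(AA20[AA20 != s[site]], 1L)
    }
    s
  }
  all_seqs <- list()
  for (f in seq_len(config$n_families)) {
    root_seq <- mutate(ancestor, config$family_divergence * config$seq_length)
    if (!is.na(planted[f])) {
      sig <- config$planted_signatures[[planted[f]]]
      for (i in seq_along(sig$columns)) {
        col <- sig$columns[[i]]
        pool <- if (col$type == "allowed") col$residues else setdiff(AA20, col$residues)
        root_seq[sig$start_column + i - 1L] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
    }
    fam_tips <- grep(sprintf("^..f%02dn", f), true_tree$tip.label, value = TRUE)
    if (length(fam_tips) == 1L) {
      all_seqs[[fam_tips]] <-   # single-copy family: stem only
        mutate(root_seq, config$substitution_rate * config$family_stem *
                 config$seq_length)
    } else {
      fam_tree <- ape::keep.tip(true_tree, fam_tips)
      fam_seqs <- evolve_sequences(fam_tree, root_seq, config$substitution_rate)
      all_seqs[names(fam_seqs)] <- fam_seqs
    }
  }

  records <- lapply(true_tree$tip.label, function(id) {
    f <- as.integer(sub("^..f([0-9]+)n.*$", "\\1", id))
    flags <- if (!is.na(planted[f])) paste0("PLANTED:", planted[f]) else character()
    hd_record(id, paste(all_seqs[[id]], collapse = ""), flags = flags)
  })
  truth <- count_species_specific_clades(true_tree)
  truth$n_records <- as.integer(table(substr(true_tree$tip.label, 1, 2))[truth$prefix])
  structure(list(records = records, true_gene_tree = true_tree, truth = truth,
                 true_root_tip = root_tip_lengths(true_tree),
                 planted_classes = planted, config = config),
            class = "simulated_repertoire")
}

#' @export
print.simulated_repertoire <- function(x, ...) {
  cat("<simulated_repertoire> ", length(x$records), " records, ",
      x$config$n_families, " families, seed ", x$config$seed, "\n", sep = "")
  print(x$truth)
  invisible(x)
}

#' Feasibility study: branch-length recovery from 60-residue alignments
#'
#' For each replicate: simulate a repertoire with a known gene tree, rebuild
#' the tree from the simulated sequences ([compute_distances()] +
#' [neighbor_joining()]), midpoint-root it, and compare per-prefix mean
#' root-to-tip lengths with the truth. A zero substitution rate produces an
#' all-zero distance matrix; the replicate is then flagged degenerate and the
#' estimates are NA.
#'
#' @param config a [simulation_config()]; replicate `r` runs with seed
#'   `config$seed + r - 1`.
#' @param n_replicates number of replicates (>= 1).
#' @return `data.frame` with columns `replicate`, `prefix`,
#'   `true_mean_root_tip`, `estimated_mean_root_tip`, `degenerate`; the
#'   attributes `bias` (mean estimated minus true) and `spearman` (rank
#'   correlation over non-degenerate rows) summarize recovery.
#' @export
simulate_branchlength_study <- function(config, n_replicates) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 1L)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    rep_sim <- simulate_repertoire(cfg)
    # true depths are in time units; rescale to expected substitutions per
    # site so bias is on the estimated scale (family-root divergence, which
    # is not part of the gene-tree clock, still inflates the estimates)
    true_avg <- average_root_tip_by_prefix(rep_sim$true_gene_tree) *
      config$substitution_rate
    est_avg <- rep(NA_real_, length(true_avg))
    names(est_avg) <- names(true_avg)
    degenerate <- FALSE
    est <- tryCatch({
      midpoint_root(nj_from_records(rep_sim$records))
    }, error = function(e) {
      if (grepl("degenerate metric", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(est)) degenerate <- TRUE else {
      ea <- average_root_tip_by_prefix(est)
      est_avg[names(ea)] <- ea
    }
    rows[[r]] <- data.frame(replicate = r, prefix = names(true_avg),
                            true_mean_root_tip = unname(true_avg),
                            estimated_mean_root_tip = unname(est_avg),
                            degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !out$degenerate & !is.na(out$estimated_mean_root_tip)
  attr(out, "bias") <- if (any(ok)) {
    mean(out$estimated_mean_root_tip[ok] - out$true_mean_root_tip[ok])
  } else NA_real_
  attr(out, "spearman") <- if (sum(ok) > 2L) {
    cor(out$true_mean_root_tip[ok], out$estimated_mean_root_tip[ok],
        method = "spearman")
  } else NA_real_
  out
}

#' Place records on synthetic scaffolds with given gaps
#'
#' The first `length(spacing_bp) + 1` records are placed consecutively on one
#' synthetic scaffold with exactly the requested inter-span gaps (each
#' homeobox span is 180 bp, the length of a 60-codon homeobox) and seeded
#' random strands; any remaining records go one-per-scaffold.
#'
#' @param records list of [hd_record()] objects.
#' @param spacing_bp integer vector of gaps (bp) between consecutive spans.
#' @param seed integer seed for strand assignment.
#' @return the record list with `scaffold` coordinates filled in.
#' @export
generate_toy_scaffolds <- function(records, spacing_bp, seed) {
  stopifnot(all(spacing_bp >= 0))
  if (!length(records)) return(records)
  set.seed(seed)
  span <- 180L
  k <- min(length(records), length(spacing_bp) + 1L)
  pos <- 100L
  for (i in seq_len(k)) {
    records[[i]]$scaffold <- list(scaffold_id = "scaffold_synth_1",
                                  start = pos, end = pos + span,
                                  strand = sample(c("+", "-"), 1L))
    if (i <= length(spacing_bp)) pos <- pos + span + as.integer(spacing_bp[i])
  }
  if (k < length(records)) {
    for (i in (k + 1L):length(records)) {
      records[[i]]$scaffold <- list(
        scaffold_id = sprintf("scaffold_synth_%d", i - k + 1L),
        start = 100L, end = 100L + span, strand = sample(c("+", "-"), 1L))
    }
  }
  records
}
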