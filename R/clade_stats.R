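# Paralog-retention and branch-length statistics on gene trees: midpoint
# rooting, root-to-tip path lengths, per-species averages over the two-letter
# leaf prefixes, and counting of maximal species-specific (prefix-
# homogeneous) clades. The clade count of a species proxies the number of
# lineage-specific duplications retained since that species diverged from its
# closest relative in the tree.

# undirected adjacency list of a phylo tree: for each node, data.frame of
# (neighbor, length)
tree_adjacency <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  adj
}

# rebuild a rooted phylo from an undirected adjacency, rooted at `root`.
# `extra` optionally injects a new node (id 0) splitting edge (a, b) at
# distance x from a.
build_rooted <- function(tree, root, adj) {
  tips <- ape::Ntip(tree)
  frag <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (node <= tips && nrow(kids) == 0L) {
      return(tree$tip.label[node])
    }
    inner <- apply(kids, 1L, function(kw) {
      paste0(frag(kw[1], node), ":", sprintf("%.17g", kw[2]))
    })
    paste0("(", paste(inner, collapse = ","), ")")
  }
  txt <- paste0(frag(root, -1L), ";")
  ape::read.tree(text = txt)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the tree's diameter (the longest
#' leaf-to-leaf path), so the two diameter endpoints are equidistant from the
#' root. If the midpoint falls exactly on a node, that node becomes the root.
#' Ties in the diameter pair are broken by the lexicographically smallest
#' leaf-label pair, making the result deterministic.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return a rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tree) {
  if (!inherits(tree, "phylo")) stop("need a 'phylo' tree", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (all(tree$edge.length == 0)) {
    stop("degenerate metric: all branch lengths are zero", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("need at least 2 leaves", call. = FALSE)
  dn <- ape::dist.nodes(tree)
  dl <- dn[seq_len(ntip), seq_len(ntip), drop = FALSE]
  L <- max(dl)
  cand <- which(dl >= L - 1e-12 & upper.tri(dl), arr.ind = TRUE)
  keys <- apply(cand, 1L, function(ij) {
    paste(sort(tree$tip.label[ij]), collapse = "\r")
  })
  pick <- cand[order(keys)[1L], ]
  u <- pick[1]; v <- pick[2]

  # node path u -> v by parent pointers over the undirected tree
  adj <- tree_adjacency(tree)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  seen <- rep(FALSE, nnode)
  queue <- u; seen[u] <- TRUE
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(adj[[node]]))) {
      nb <- adj[[node]][r, 1]
      if (!seen[nb]) {
        seen[nb] <- TRUE; parent[nb] <- node; queue <- c(queue, nb)
      }
    }
  }
  path <- v
  while (path[1] != u) path <- c(parent[path[1]], path)

  # cumulative distance from u along the path; find where it crosses L/2
  cum <- c(0, cumsum(dn[cbind(path[-length(path)], path[-1])]))
  half <- L / 2
  k <- max(which(cum <= half + 1e-12))
  x <- half - cum[k]
  a <- path[k]
  if (abs(x) <= 1e-12) {
    return(flag_rooted(build_rooted(tree, a, adj)))
  }
  b <- path[k + 1]
  edge_len <- dn[a, b]
  if (abs(x - edge_len) <= 1e-12) {
    return(flag_rooted(build_rooted(tree, b, adj)))
  }
  # split edge (a, b): new root node at distance x from a
  newnode <- nnode + 1L
  strip <- function(mat, drop_to) mat[mat[, 1] != drop_to, , drop = FALSE]
  adj[[a]] <- rbind(strip(adj[[a]], b), c(newnode, x))
  adj[[b]] <- rbind(strip(adj[[b]], a), c(newnode, edge_len - x))
  adj[[newnode]] <- rbind(c(a, x), c(b, edge_len - x))
  flag_rooted(build_rooted(tree, newnode, adj))
}

# a midpoint root may sit on a node of degree 3, which ape::is.rooted()
# reports as unrooted; carry an explicit flag for downstream checks
flag_rooted <- function(tree) {
  attr(tree, "midpoint_rooted") <- TRUE
  tree
}

is_rooted_tree <- function(tree) {
  ape::is.rooted(tree) || isTRUE(attr(tree, "midpoint_rooted"))
}

#' Root-to-tip path lengths
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return named numeric vector: for each leaf, the sum of branch lengths on
#'   its root-to-leaf path.
#' @export
root_tip_lengths <- function(tree) {
  if (!inherits(tree, "phylo")) stop("need a 'phylo' tree", call. = FALSE)
  if (!is_rooted_tree(tree)) {
    stop("rooting required: midpoint_root() the tree first", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  depth <- numeric(ntip + tree$Nnode)
  ord <- rev(ape::postorder(tree))    # parents before children
  for (k in ord) {
    depth[tree$edge[k, 2]] <- depth[tree$edge[k, 1]] + tree$edge.length[k]
  }
  setNames(depth[seq_len(ntip)], tree$tip.label)
}

#' Mean root-to-tip length per species prefix
#'
#' The per-species "average branch length": the arithmetic mean of
#' root-to-tip path lengths over all leaves sharing a two-letter species
#' prefix. Prefixes with a single leaf are still reported.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @return named numeric vector by species prefix, sorted by prefix.
#' @export
average_root_tip_by_prefix <- function(tree) {
  rtl <- root_tip_lengths(tree)
  pref <- substr(names(rtl), 1L, 2L)
  out <- tapply(rtl, pref, mean)
  out[order(names(out))]
}

#' Count species-specific clades
#'
#' A species-specific clade is a maximal monophyletic group whose leaves all
#' carry the same two-letter species prefix: an internal node whose leaf set
#' is prefix-homogeneous while its parent's is not. Nested homogeneous clades
#' are never double-counted. Only clades with at least `min_size` leaves
#' count (default 2: clades of more than one homeodomain).
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param min_size minimum number of leaves for a clade to count.
#' @return `data.frame` with one row per species prefix present in the tree:
#'   `prefix`, `n_clades`, `n_leaves` (total leaves inside counted clades).
#' @export
count_species_specific_clades <- function(tree, min_size = 2L) {
  if (!inherits(tree, "phylo")) stop("need a 'phylo' tree", call. = FALSE)
  if (!is_rooted_tree(tree)) {
    stop("rooting required: midpoint_root() the tree first", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  pref <- substr(tree$tip.label, 1L, 2L)
  # postorder sweep: per node, its prefix if homogeneous (NA otherwise) and
  # its leaf count
  node_pref <- c(pref, rep(NA_character_, tree$Nnode))
  homog <- c(rep(TRUE, ntip), rep(NA, tree$Nnode))
  nleaf <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  ord <- ape::postorder(tree)
  for (k in ord) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    nleaf[p] <- nleaf[p] + nleaf[ch]
    if (is.na(homog[p])) {
      homog[p] <- homog[ch]
      node_pref[p] <- node_pref[ch]
    } else if (isTRUE(homog[p])) {
      if (!isTRUE(homog[ch]) || !identical(node_pref[p], node_pref[ch])) {
        homog[p] <- FALSE
        node_pref[p] <- NA_character_
      }
    }
  }
  root <- ntip + 1L
  parent_of <- rep(NA_integer_, nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  counts <- setNames(integer(length(unique(pref))), sort(unique(pref)))
  leaves <- counts
  for (node in seq_len(nnode)) {
    if (!isTRUE(homog[node]) || nleaf[node] < min_size) next
    par <- parent_of[node]
    maximal <- is.na(par) || !isTRUE(homog[par])
    if (maximal) {
      pfx <- node_pref[node]
      counts[pfx] <- counts[pfx] + 1L
      leaves[pfx] <- leaves[pfx] + nleaf[node]
    }
  }
  data.frame(prefix = names(counts), n_clades = as.integer(counts),
             n_leaves = as.integer(leaves), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Relabel the species prefix of a subset of leaves
#'
#' Supports subset branch-length comparisons: reassigning part of one
#' species' leaves to an unused pseudo-prefix (e.g. `"Zz"`) makes
#' [average_root_tip_by_prefix()] and [count_species_specific_clades()]
#' report the subset separately.
#'
#' @param tree an [ape::phylo] tree.
#' @param leaf_ids character vector of leaf labels to relabel.
#' @param new_prefix two-character prefix not used by any other leaf.
#' @return the tree with relabelled leaves; topology and lengths untouched.
#' @export
relabel_subset <- function(tree, leaf_ids, new_prefix) {
  stopifnot(nchar(new_prefix) == 2L)
  missing_ids <- setdiff(leaf_ids, tree$tip.label)
  if (length(missing_ids)) {
    stop("leaf id(s) not in tree: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  others <- setdiff(tree$tip.label, leaf_ids)
  if (any(substr(others, 1L, 2L) == new_prefix)) {
    stop("prefix collision: '", new_prefix, "' already used by other leaves",
         call. = FALSE)
  }
  sel <- tree$tip.label %in% leaf_ids
  tree$tip.label[sel] <- paste0(new_prefix, substr(tree$tip.label[sel], 3L,
                                                   nchar(tree$tip.label[sel])))
  tree
}

#' Assemble the per-species clade/branch-length report
#'
#' Combines, per species prefix: the number of homeodomains, the number
#' sitting in species-specific clades, the number of such clades, and the
#' mean root-to-tip length; plus a grand-mean row (arithmetic mean of each
#' per-species column).
#'
#' @param tree a rooted [ape::phylo] tree (midpoint-root it first if it came
#'   straight from [neighbor_joining()]).
#' @param records optional list of [hd_record()] objects; when given, every
#'   tree leaf must have a matching record id (a reconciliation error lists
#'   orphans otherwise).
#' @param min_size minimum clade size, passed to
#'   [count_species_specific_clades()].
#' @return `data.frame` with columns `species`, `n_records`,
#'   `n_in_species_specific_clades`, `n_species_specific_clades`,
#'   `average_root_tip`; the final row (`species == "Average"`) holds the
#'   grand means.
#' @export
build_clade_report <- function(tree, records = NULL, min_size = 2L) {
  if (!is.null(records)) {
    ids <- vapply(records, `[[`, "", "id")
    orphans <- setdiff(tree$tip.label, ids)
    if (length(orphans)) {
      stop("reconciliation error: tree leaves without records: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
  }
  cl <- count_species_specific_clades(tree, min_size = min_size)
  avg <- average_root_tip_by_prefix(tree)
  n_rec <- table(substr(tree$tip.label, 1L, 2L))
  out <- data.frame(
    species = cl$prefix,
    n_records = as.numeric(n_rec[cl$prefix]),
    n_in_species_specific_clades = as.numeric(cl$n_leaves),
    n_species_specific_clades = as.numeric(cl$n_clades),
    average_root_tip = unname(avg[cl$prefix]),
    stringsAsFactors = FALSE
  )
  grand <- data.frame(species = "Average", t(colMeans(out[, -1])),
                      stringsAsFactors = FALSE)
  rbind(out, grand)
}
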