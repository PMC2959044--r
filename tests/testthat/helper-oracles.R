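# Independent oracles and generators used across the suite. Each oracle is a
# deliberately different implementation path from the code it checks.

# random rooted binary tree with two-letter species prefixes on the tips
rand_prefixed_tree <- function(n, prefixes = c("Ml", "Aq", "Nv", "Hs")) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0(sample(prefixes, n, replace = TRUE),
                         sprintf("x%02d", seq_len(n)))
  tr
}

# brute-force root-to-tip oracle: independent path walk via ape::nodepath
oracle_root_tip <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  out <- vapply(seq_len(ntip), function(tip) {
    path <- ape::nodepath(tree, root, tip)
    sum(vapply(seq_len(length(path) - 1L), function(k) {
      e <- which(tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1])
      tree$edge.length[e]
    }, 1))
  }, 1)
  setNames(out, tree$tip.label)
}

# brute-force midpoint oracle: minimum over all edges and discretized
# positions of the maximum distance to any leaf
oracle_min_max_roottip <- function(tree, npoints = 41L) {
  dn <- ape::dist.nodes(tree)
  ntip <- ape::Ntip(tree)
  best <- Inf
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; len <- tree$edge.length[k]
    for (x in seq(0, len, length.out = npoints)) {
      maxd <- max(pmin(dn[a, seq_len(ntip)] + x,
                       dn[b, seq_len(ntip)] + len - x))
      if (maxd < best) best <- maxd
    }
  }
  best
}

# exhaustive clade-count oracle: every node via phangorn::Descendants with an
# explicit maximality filter
oracle_clade_counts <- function(tree, min_size = 2L) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tip_pref <- substr(tree$tip.label, 1L, 2L)
  desc <- phangorn::Descendants(tree, seq_len(nnode), "tips")
  parent_of <- rep(NA_integer_, nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  prefs <- sort(unique(tip_pref))
  counts <- setNames(integer(length(prefs)), prefs)
  leaves <- counts
  homog_pref <- function(node) {
    u <- unique(tip_pref[desc[[node]]])
    if (length(u) == 1L) u else NA_character_
  }
  for (node in seq_len(nnode)) {
    p <- homog_pref(node)
    if (is.na(p) || length(desc[[node]]) < min_size) next
    par <- parent_of[node]
    if (is.na(par) || is.na(homog_pref(par))) {
      counts[p] <- counts[p] + 1L
      leaves[p] <- leaves[p] + length(desc[[node]])
    }
  }
  data.frame(prefix = prefs, n_clades = as.integer(counts),
             n_leaves = as.integer(leaves), row.names = NULL,
             stringsAsFactors = FALSE)
}

# regex oracle for signature matching: R's own regex engine on the window
oracle_signature_regex <- function(window, sig) {
  grepl(paste0("^", sig$pattern, "$"), window)
}

random_window <- function(width) {
  paste(sample(AA20_test, width, replace = TRUE), collapse = "")
}
AA20_test <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# exhaustive k-mer enumeration of a signature window (only for width <= 5)
enumerate_signature_matches <- function(sig, columns = seq_along(sig$columns)) {
  stopifnot(length(columns) <= 5L)
  grids <- rep(list(seq_len(20L)), length(columns))
  g <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  keep <- rep(TRUE, nrow(g))
  for (j in seq_along(columns)) {
    col <- sig$columns[[columns[j]]]
    inset <- AA20_test[g[, j]] %in% col$residues
    keep <- keep & if (col$type == "allowed") inset else !inset
  }
  sum(keep)
}

# product of admissible set sizes restricted to some columns
admissible_product <- function(sig, columns = seq_along(sig$columns)) {
  prod(vapply(sig$columns[columns], function(col) {
    if (col$type == "allowed") length(col$residues) else 20L - length(col$residues)
  }, 1L))
}
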