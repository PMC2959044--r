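# SYNTHETIC stand-in for the published seven-species NJ gene tree (which is
# only available as a supplementary download): a programmatically built
# 740-leaf tree that plants, for each species, the published number of
# homeodomains, of species-specific clades and of leaves inside them, with
# every leaf at exactly that species' published mean root-to-tip depth. The
# deepest species has leaves on both sides of the root, so the tree is its
# own midpoint root. Reading the per-species targets from the packaged
# printed-table fixture keeps this helper free of magic numbers.

synthetic_reference_tree <- function() {
  tab <- read.delim(system.file("extdata", "table2_species_stats.tsv",
                                package = "homeorep"),
                    stringsAsFactors = FALSE)
  delta <- 0.002  # tiny within-clade edge
  eps <- 0.01     # root half-edges
  units <- character(0)   # newick fragments, each hung directly below A or B
  counter <- 0L
  for (i in seq_len(nrow(tab))) {
    pfx <- tab$prefix[i]
    n <- tab$n_records[i]
    nc <- tab$n_species_specific_clades[i]
    nl <- tab$n_in_species_specific_clades[i]
    depth <- tab$average_root_tip[i]
    sizes <- if (nc > 0) c(nl - 2L * (nc - 1L), rep(2L, nc - 1L)) else integer()
    tip <- function() {
      counter <<- counter + 1L
      sprintf("%s%04d", pfx, counter)
    }
    for (k in sizes) {
      leaves <- vapply(seq_len(k), function(j) sprintf("%s:%g", tip(), delta), "")
      units <- c(units, sprintf("(%s):%.10f", paste(leaves, collapse = ","),
                                depth - delta - eps))
    }
    for (j in seq_len(n - nl)) {
      units <- c(units, sprintf("%s:%.10f", tip(), depth - eps))
    }
  }
  a <- units[seq_along(units) %% 2L == 1L]
  b <- units[seq_along(units) %% 2L == 0L]
  txt <- sprintf("((%s):%g,(%s):%g);", paste(a, collapse = ","), eps,
                 paste(b, collapse = ","), eps)
  ape::read.tree(text = txt)
}

reference_species_table <- function() {
  read.delim(system.file("extdata", "table2_species_stats.tsv",
                         package = "homeorep"), stringsAsFactors = FALSE)
}
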