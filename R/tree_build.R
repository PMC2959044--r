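# Protein distances and neighbor-joining over normalized 60-column
# homeodomain alignments. The distance model is a Poisson-corrected
# p-distance with pairwise deletion (uncorrected p-distance available):
# deliberately simple and deterministic, since the downstream statistics
# (clade counts, relative root-to-tip lengths) depend on tree shape rather
# than on empirical exchangeabilities.

#' Pairwise protein distances between homeodomain records
#'
#' Uses pairwise deletion: alignment columns where either sequence of a pair
#' has `-` or `X` are excluded from both numerator and denominator. With
#' `p = mismatches / compared`, the `"poisson"` model reports
#' `d = -ln(1 - p)` and the `"p"` model reports `p` itself. A saturated pair
#' (`p == 1`) yields an infinite Poisson distance and a warning; a pair with
#' zero comparable columns is an error naming the pair.
#'
#' @param records list of [hd_record()] objects (all 60 columns).
#' @param model `"poisson"` (default) or `"p"`.
#' @return symmetric numeric matrix (substitutions per site) with record ids
#'   as dimnames and zero diagonal.
#' @export
compute_distances <- function(records, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- residue_matrix(records)
  n <- nrow(m)
  ok <- !(m == "-" | m == "X")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(D)
  saturated <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        stop("incomparable pair: '", rownames(m)[i], "' and '", rownames(m)[j],
             "' share no gap-free columns", call. = FALSE)
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d <- if (model == "poisson") {
        if (p >= 1) { saturated <- saturated + 1L; Inf } else -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  if (saturated > 0L) {
    warning(saturated, " saturated pair(s) (p = 1) have infinite Poisson distance",
            call. = FALSE)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion and two-point
#' branch-length formulas. Ties on the minimal Q value are broken by picking
#' the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest leaf), so the result is deterministic. Negative
#' estimated branch lengths are clamped to zero; the number of clamped edges
#' is reported as attribute `n_clamped` and via a message. The returned tree
#' is unrooted (stored with the conventional trifurcation at the last three
#' clusters); for `n = 2` the two leaves are joined by a total path of length
#' `D[1, 2]`.
#'
#' @param D symmetric distance matrix with unique labels as dimnames.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("distance matrix needs unique row/column labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)) ||
      any(!is.finite(D)) || any(D < 0) || any(diag(D) != 0)) {
    stop("matrix-validity error: need a finite symmetric non-negative matrix ",
         "with zero diagonal", call. = FALSE)
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  n_clamped <- 0L
  clamp <- function(x) {
    neg <- x < 0
    n_clamped <<- n_clamped + sum(neg)
    x[neg] <- 0
    x
  }
  fmt <- function(x) sprintf("%.17g", x)
  newick <- labels          # newick fragment per active cluster
  clab <- labels            # cluster label = smallest leaf label within

  if (n == 2L) {
    tr <- ape::read.tree(text = paste0("(", newick[1], ":", fmt(D[1, 2] / 2),
                                       ",", newick[2], ":", fmt(D[1, 2] / 2), ");"))
    attr(tr, "n_clamped") <- 0L
    return(tr)
  }

  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    # deterministic tie-break: lexicographically smallest (sorted) label pair
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(clab[ij]), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- min(pick); j <- max(pick)
    dij <- D[i, j]
    li <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (nn - 2)))
    lj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (nn - 2))))
    new_frag <- paste0("(", newick[i], ":", fmt(li), ",", newick[j], ":", fmt(lj), ")")
    new_lab <- min(clab[c(i, j)])
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    dnew <- dnew[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    newick <- c(newick[-c(i, j)], new_frag)
    clab <- c(clab[-c(i, j)], new_lab)
  }

  # closing trifurcation: star branch lengths from the three-point formulas
  a <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  c3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- paste0("(", newick[1], ":", fmt(a), ",", newick[2], ":", fmt(b),
                ",", newick[3], ":", fmt(c3), ");")
  tr <- ape::read.tree(text = txt)
  if (n_clamped > 0L) {
    message("neighbor_joining: clamped ", n_clamped, " negative branch length(s) to 0")
  }
  attr(tr, "n_clamped") <- n_clamped
  tr
}

#' Build an NJ tree straight from records
#'
#' Convenience wrapper: [compute_distances()] then [neighbor_joining()].
#'
#' @inheritParams compute_distances
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_from_records <- function(records, model = c("poisson", "p")) {
  neighbor_joining(compute_distances(records, model = match.arg(model)))
}
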