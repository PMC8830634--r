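#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-matrix joins) on a labelled symmetric
#' distance matrix. Labels are put in alphabetical order before joining so
#' the result is invariant to input ordering; negative branch lengths are
#' clamped to zero.
#'
#' @param D symmetric labelled distance matrix (>= 3 labels, finite,
#'   zero diagonal)
#' @return an unrooted `phylo`
#' @export
neighbor_joining <- function(D) {
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 labels")
  if (!all(is.finite(D))) stop("non-finite distances")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# canonical bipartition keys for the internal edges of an (unrooted) tree:
# the side of each internal edge not containing the alphabetically first
# leaf, as a comma-joined sorted label string. Returns a character vector
# named by internal node id (the child end of each internal edge).
bipartition_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- min(phy$tip.label)
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  keys <- character(0)
  for (i in seq_along(parts)) {
    node <- ntip + i
    if (node == ntip + 1L) next                  # root: trivial split
    side <- labs[parts[[i]]]
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    keys[as.character(node)] <- paste(sort(side), collapse = ",")
  }
  keys
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Builds the NJ tree from Poisson-corrected MSA distances, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree,
#' and labels every internal edge of the main tree with the percentage of
#' replicates containing the same (unrooted) bipartition. Rows are put in
#' a canonical order first, so the resampling stream depends only on the
#' seed and column count, not on input row order.
#'
#' @param x an [msa()]
#' @param n_reps bootstrap replicates (default 1000)
#' @param rng_seed integer seed for reproducibility
#' @param d_max distance cap passed to [msa_distances()]
#' @return an unrooted `phylo`; `node.label` carries supports in [0, 100]
#' @export
bootstrap_supports <- function(x, n_reps = 1000, rng_seed = NULL,
                               d_max = 10) {
  stopifnot(n_reps >= 1)
  ord <- order(x$ids)
  x <- msa(x$ids[ord], x$seqs[ord])
  m <- msa_matrix(x)
  L <- ncol(m)
  p_cap <- 1 - exp(-d_max)
  dist_from <- function(cols) {
    p <- cpp_pdist(m, cols)
    d <- ifelse(is.na(p) | p >= p_cap, d_max, -log(1 - p))
    diag(d) <- 0
    dimnames(d) <- list(rownames(m), rownames(m))
    d
  }
  main <- neighbor_joining(dist_from(seq_len(L)))
  keys <- bipartition_keys(main)
  counts <- setNames(numeric(length(keys)), keys)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    tr <- neighbor_joining(dist_from(cols))
    hit <- keys %in% bipartition_keys(tr)
    counts[hit] <- counts[hit] + 1
  }
  ntip <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  for (node_chr in names(keys)) {
    node <- as.integer(node_chr)
    labels[node - ntip] <- sprintf("%.10g", 100 * counts[[keys[node_chr]]] /
                                     n_reps)
  }
  main$node.label <- labels
  main
}

#' Per-family gene tree: align, trim, NJ, bootstrap
#'
#' Convenience wrapper chaining [progressive_msa()],
#' [trim_poor_columns()], [msa_distances()] and [bootstrap_supports()].
#'
#' @param prot proteome rows of one family (>= 3 records)
#' @param scheme a [scoring_scheme()]
#' @param n_reps bootstrap replicates
#' @param rng_seed seed for the bootstrap
#' @param max_gap_fraction column-trimming threshold
#' @return list with elements `msa` (trimmed) and `tree` (`phylo` with
#'   supports)
#' @export
build_gene_tree <- function(prot, scheme = scoring_scheme(),
                            n_reps = 1000, rng_seed = NULL,
                            max_gap_fraction = 0.5) {
  al <- progressive_msa(prot, scheme)
  al <- trim_poor_columns(al, max_gap_fraction)
  tree <- bootstrap_supports(al, n_reps = n_reps, rng_seed = rng_seed)
  list(msa = al, tree = tree)
}
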