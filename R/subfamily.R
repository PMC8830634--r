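#' Assign genes to subfamilies by clading with labelled reference genes
#'
#' Each unlabelled leaf receives the label of the smallest clade
#' containing it whose labelled reference members are unanimous;
#' otherwise `"unassigned"`. Clades are evaluated as bipartition sides
#' (plus the full leaf set), so the assignment is invariant under
#' re-rooting of the gene tree. Reference leaves keep their own label.
#'
#' @param gene_tree a `phylo`
#' @param reference_labels named character vector: reference gene leaf
#'   label -> subfamily
#' @return named character vector over all leaves
#' @export
classify_subfamilies <- function(gene_tree, reference_labels) {
  tips <- gene_tree$tip.label
  refs <- intersect(names(reference_labels), tips)
  if (length(refs) == 0L) {
    stop("no labelled reference leaf is present in the tree")
  }
  ntip <- length(tips)
  sides <- list(tips)
  if (ntip > 2L && gene_tree$Nnode > 1L) {
    parts <- ape::prop.part(gene_tree)
    labs <- attr(parts, "labels")
    for (i in seq_along(parts)) {
      if (i == 1L) next                       # root: full set already there
      side <- labs[parts[[i]]]
      sides <- c(sides, list(side), list(setdiff(tips, side)))
    }
  }
  out <- setNames(rep("unassigned", ntip), tips)
  out[refs] <- reference_labels[refs]
  for (x in setdiff(tips, refs)) {
    best_size <- Inf; best_labels <- character(0)
    for (side in sides) {
      if (!(x %in% side)) next
      r <- intersect(side, refs)
      if (length(r) == 0L) next
      lab <- unique(reference_labels[r])
      if (length(lab) != 1L) next
      if (length(side) < best_size) {
        best_size <- length(side); best_labels <- lab
      } else if (length(side) == best_size) {
        best_labels <- union(best_labels, lab)
      }
    }
    if (length(best_labels) == 1L) out[x] <- best_labels
  }
  out
}
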