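#' Read a single-tree newick file
#'
#' Numeric internal-node labels are interpreted downstream as bootstrap
#' supports in [0, 100]. Unbalanced parentheses, trailing top-level
#' garbage and duplicate leaf labels raise parse errors (with the
#' offending character position where applicable).
#'
#' @param path file path, or a literal newick string containing `;`
#' @return an `ape` `phylo` object
#' @export
read_newick <- function(path) {
  text <- if (grepl(";", path, fixed = TRUE)) path else {
    if (!file.exists(path)) stop("no such file: ", path)
    paste(readLines(path), collapse = "")
  }
  text <- trimws(text)
  validate_newick_text(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("newick parse error: unparsable tree text")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label: '",
         phy$tip.label[duplicated(phy$tip.label)][1], "'")
  }
  phy
}

validate_newick_text <- function(text) {
  chars <- strsplit(text, "")[[1]]
  if (length(chars) == 0L || chars[length(chars)] != ";") {
    stop("newick parse error: tree text must end with ';'")
  }
  depth <- 0L
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "(") depth <- depth + 1L
    if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error: unbalanced ')' at position ", i)
    }
    if (c == "," && depth == 0L) {
      stop("newick parse error: top-level ',' at position ", i)
    }
    if (c == ";" && i < length(chars)) {
      stop("newick parse error: text after ';' at position ", i)
    }
  }
  if (depth != 0L) stop("newick parse error: ", depth, " unclosed '('")
  invisible(TRUE)
}

#' Write a tree as newick
#'
#' Branch lengths and internal-node labels (supports) are preserved;
#' round-tripping canonical output through [read_newick()] is lossless.
#'
#' @param tree a `phylo`
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

# ---- nested-list tree representation (internal) ---------------------------
# node := list(label, len, support, kids = list(...)); leaves have no kids.

as_rtree <- function(phy) {
  ntip <- length(phy$tip.label)
  has_len <- !is.null(phy$edge.length)
  labs <- phy$node.label
  kids_of <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  build <- function(node, len) {
    if (node <= ntip) {
      return(list(label = phy$tip.label[node], len = len,
                  support = NA_real_, kids = list()))
    }
    lab <- if (!is.null(labs)) labs[node - ntip] else ""
    sup <- suppressWarnings(as.numeric(lab))
    rows <- kids_of[[as.character(node)]]
    kids <- lapply(rows, function(i) {
      build(phy$edge[i, 2], if (has_len) phy$edge.length[i] else NA_real_)
    })
    list(label = if (is.na(sup)) lab else "", len = len, support = sup,
         kids = kids)
  }
  build(ntip + 1L, NA_real_)
}

rtree_newick <- function(node) {
  render <- function(nd) {
    lenstr <- if (is.na(nd$len)) "" else sprintf(":%.10g", nd$len)
    if (length(nd$kids) == 0L) return(paste0(nd$label, lenstr))
    lab <- if (!is.na(nd$support)) sprintf("%.10g", nd$support) else nd$label
    paste0("(", paste(vapply(nd$kids, render, ""), collapse = ","),
           ")", lab, lenstr)
  }
  paste0(render(node), ";")
}

rtree_to_phylo <- function(node) {
  phy <- ape::read.tree(text = rtree_newick(node))
  if (!is.null(phy$edge.length)) {
    if (all(is.na(phy$edge.length))) phy$edge.length <- NULL else
      phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  phy
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose bootstrap support is below
#' `threshold` (edges with support >= threshold, and edges without a
#' numeric support label, are kept), producing a condensed, possibly
#' multifurcating tree for reconciliation. Leaves are never touched.
#'
#' @param tree a `phylo` with numeric internal-node labels as supports
#' @param threshold support threshold in [0, 100]; default 70
#' @return a `phylo`, possibly multifurcating
#' @export
collapse_low_support <- function(tree, threshold = 70) {
  rt <- as_rtree(tree)
  contract <- function(nd) {
    if (length(nd$kids) == 0L) return(nd)
    nd$kids <- lapply(nd$kids, contract)
    new_kids <- list()
    for (k in nd$kids) {
      drop <- length(k$kids) > 0L && !is.na(k$support) && k$support < threshold
      if (drop) new_kids <- c(new_kids, k$kids) else
        new_kids <- c(new_kids, list(k))
    }
    nd$kids <- new_kids
    nd
  }
  rtree_to_phylo(contract(rt))
}

# number of internal edges (edges whose child is an internal node)
n_internal_edges <- function(phy) {
  ntip <- length(phy$tip.label)
  sum(phy$edge[, 2] > ntip)
}

# ---- unrooted adjacency and rooting on an edge ----------------------------

# Edge table with per-edge supports (the support of an internal edge is the
# node label of its child in the stored orientation).
tree_adjacency <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  sup <- rep(NA_real_, nrow(phy$edge))
  if (!is.null(phy$node.label)) {
    child <- phy$edge[, 2]
    int <- child > ntip
    sup[int] <- suppressWarnings(as.numeric(phy$node.label[child[int] - ntip]))
  }
  len <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge)) else
    phy$edge.length
  nbr <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    nbr[[a]] <- c(nbr[[a]], i)
    nbr[[b]] <- c(nbr[[b]], i)
  }
  list(phy = phy, ntip = ntip, edges = phy$edge, support = sup, len = len,
       nbr = nbr)
}

# Root the (unrooted) adjacency on edge `e`; returns a nested rtree whose
# root has the two edge endpoints as children.
root_at_edge <- function(adj, e) {
  ends <- adj$edges[e, ]
  build <- function(v, from_edge, len, support) {
    if (v <= adj$ntip) {
      return(list(label = adj$phy$tip.label[v], len = len,
                  support = NA_real_, kids = list()))
    }
    out_edges <- setdiff(adj$nbr[[v]], from_edge)
    kids <- lapply(out_edges, function(i) {
      w <- setdiff(adj$edges[i, ], v)
      build(w, i, adj$len[i], adj$support[i])
    })
    list(label = "", len = len, support = support, kids = kids)
  }
  half <- if (is.na(adj$len[e])) c(NA_real_, NA_real_) else
    rep(adj$len[e] / 2, 2)
  list(label = "", len = NA_real_, support = NA_real_,
       kids = list(build(ends[1], e, half[1], NA_real_),
                   build(ends[2], e, half[2], NA_real_)))
}

# sorted leaf labels under a nested node
rtree_leaves <- function(nd) {
  if (length(nd$kids) == 0L) return(nd$label)
  sort(unlist(lapply(nd$kids, rtree_leaves)))
}

#' Species-of-leaf map from "species|gene" labels
#'
#' @param labels gene-tree leaf labels
#' @return named character vector mapping label to species
#' @export
leaf_species_map <- function(labels) {
  setNames(sub("\\|.*$", "", labels), labels)
}
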