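# Duplication-loss parsimony reconciliation of gene trees with a species
# tree: LCA mapping, event counting per species-tree branch, minimum-cost
# resolution of polytomies in condensed (support-collapsed) trees, and
# cost-minimising rooting. Unit event weights throughout. The reported
# cost includes the "stem" losses from the species root down to the
# species-tree image of the gene root, so a family observed only in one
# subtree of the species tree is charged one loss at the stem of each
# bypassed subtree (and none deeper inside an empty subtree).

# ---- species-tree arrays --------------------------------------------------

species_arrays <- function(S) {
  if (!ape::is.binary(S) || !ape::is.rooted(S)) {
    stop("the species tree must be rooted and binary")
  }
  ntip <- length(S$tip.label)
  nn <- ntip + S$Nnode
  parent <- integer(nn)
  children <- matrix(0L, nn, 2)
  for (i in seq_len(nrow(S$edge))) {
    a <- S$edge[i, 1]; b <- S$edge[i, 2]
    parent[b] <- a
    children[a, if (children[a, 1] == 0L) 1L else 2L] <- b
  }
  root <- ntip + 1L
  depth <- integer(nn)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ord <- c(ord, v)
    if (children[v, 1] > 0L) {
      depth[children[v, ]] <- depth[v] + 1L
      stack <- c(stack, children[v, ])
    }
  }
  anc <- matrix(FALSE, nn, nn)
  for (v in seq_len(nn)) {
    u <- v
    while (u != 0L) { anc[u, v] <- TRUE; u <- parent[u] }
  }
  lca <- matrix(0L, nn, nn)
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    u <- a
    while (!anc[u, b]) u <- parent[u]
    lca[a, b] <- u
  }
  nlab <- S$node.label
  names <- c(S$tip.label,
             vapply(seq_len(S$Nnode), function(i) {
               if (!is.null(nlab) && nzchar(nlab[i])) nlab[i] else
                 paste0("N", ntip + i)
             }, ""))
  list(tree = S, ntip = ntip, nn = nn, root = root, parent = parent,
       children = children, depth = depth, anc = anc, lca = lca,
       names = names, tip_id = setNames(seq_len(ntip), S$tip.label))
}

lca_set <- function(sa, ids) Reduce(function(a, b) sa$lca[a, b], ids)

# species nodes on the path a -> b (top-down, inclusive); a must be an
# ancestor of (or equal to) b
path_down <- function(sa, a, b) {
  p <- b
  out <- integer(0)
  while (p != a) {
    out <- c(p, out)
    p <- sa$parent[p]
    if (p == 0L) stop("internal error: not an ancestor")
  }
  c(a, out)
}

sibling_of <- function(sa, v) {
  p <- sa$parent[v]
  setdiff(sa$children[p, ], v)
}

# ---- gene-tree arrays -----------------------------------------------------

# nested rtree -> children table + per-leaf species ids + labels
rtree_arrays <- function(nd, species_ids) {
  kids <- list(); gs <- integer(0); labs <- character(0)
  add <- function(n) {
    if (length(n$kids) == 0L) {
      sp <- species_ids[[n$label]]
      if (is.null(sp) || is.na(sp)) {
        stop("gene leaf '", n$label, "' maps to no species-tree leaf")
      }
      kids[[length(kids) + 1L]] <<- c(0L, 0L)
      gs[length(gs) + 1L] <<- sp
      labs[length(labs) + 1L] <<- n$label
      return(length(kids))
    }
    ids <- vapply(n$kids, add, 0L)
    if (length(ids) != 2L) stop("gene tree is not binary")
    kids[[length(kids) + 1L]] <<- ids
    gs[length(gs) + 1L] <<- 0L
    labs[length(labs) + 1L] <<- ""
    length(kids)
  }
  root <- add(nd)
  list(kids = do.call(rbind, kids), species = gs, root = root, labels = labs)
}

# leaf-label -> species-node-id lookup from a leaf map (label -> species)
species_id_lookup <- function(sa, leaf_map) {
  unknown <- setdiff(unique(leaf_map), names(sa$tip_id))
  if (length(unknown)) {
    stop("species not present in the species tree: ",
         paste(unknown, collapse = ", "))
  }
  as.list(setNames(sa$tip_id[leaf_map], names(leaf_map)))
}

# ---- LCA reconciliation ---------------------------------------------------

reconcile_core <- function(ga, sa) {
  n <- nrow(ga$kids)
  M <- integer(n)
  is_dup <- logical(n)
  gains <- integer(sa$nn)
  losses <- integer(sa$nn)
  charge_path <- function(a, b, from_top) {
    # loss at the sibling of every path node s_j, j = start..k (top-down)
    if (a == b) return(invisible())
    p <- path_down(sa, a, b)
    start <- if (from_top) 2L else 3L
    if (length(p) < start) return(invisible())
    for (j in start:length(p)) {
      sib <- sibling_of(sa, p[j])
      losses[sib] <<- losses[sib] + 1L
    }
    invisible()
  }
  walk <- function(v) {
    if (ga$kids[v, 1] == 0L) { M[v] <<- ga$species[v]; return(M[v]) }
    m1 <- walk(ga$kids[v, 1])
    m2 <- walk(ga$kids[v, 2])
    mu <- sa$lca[m1, m2]
    dup <- (m1 == mu) || (m2 == mu)
    M[v] <<- mu
    is_dup[v] <<- dup
    if (dup) gains[mu] <<- gains[mu] + 1L
    # losses along each child edge: sibling of s_2..s_k for a speciation,
    # sibling of s_1..s_k for a duplication
    charge_path(mu, m1, from_top = dup)
    charge_path(mu, m2, from_top = dup)
    mu
  }
  mroot <- walk(ga$root)
  # stem: one surviving lineage travels from the species root to M(root)
  charge_path(sa$root, mroot, from_top = TRUE)
  total <- sum(gains) + sum(losses)
  # ancestral copies: root copies = 1 + duplications mapped at the root;
  # then copies(child) = copies(parent) + gains - losses on the branch
  copies <- integer(sa$nn)
  copies[sa$root] <- 1L + gains[sa$root]
  for (v in setdiff(seq_len(sa$nn), sa$root)[order(sa$depth[setdiff(seq_len(sa$nn), sa$root)])]) {
    copies[v] <- copies[sa$parent[v]] + gains[v] - losses[v]
  }
  extant <- tabulate(ga$species[ga$species > 0L], nbins = sa$nn)
  if (!all(copies[seq_len(sa$ntip)] == extant[seq_len(sa$ntip)])) {
    stop("internal consistency error: leaf copy numbers do not match ",
         "extant gene counts (reconciliation bookkeeping bug)")
  }
  list(M = M, is_dup = is_dup, gains = gains, losses = losses,
       copies = copies, total = total)
}

#' Duplication-loss reconciliation of a rooted binary gene tree
#'
#' Computes the LCA mapping of every gene-tree node onto the species tree,
#' labels internal nodes as speciations or duplications (a node is a
#' duplication iff it maps to the same species node as one of its
#' children), counts the implied gene losses along every species-tree
#' branch, and propagates ancestral copy numbers from the root tipward.
#' The LCA mapping minimises the total duplication + loss cost.
#'
#' @param G rooted binary gene tree (`phylo`); leaf labels are
#'   `"species|gene"` unless `leaf_map` is given
#' @param S rooted binary species tree (`phylo`)
#' @param leaf_map named character vector mapping gene leaves to species
#'   names; defaults to parsing `"species|gene"` labels
#' @return an object of class `reconciliation`: a list with
#'   `node_events` (data.frame: gene node, event, mapped species),
#'   `gains_per_branch` and `losses_per_branch` (named integer vectors
#'   indexed by the species node at the bottom of each branch; the entry
#'   for the species root holds pre-root duplications),
#'   `ancestral_copies` (named integer vector over species-tree nodes)
#'   and `total_cost`
#' @export
lca_reconcile <- function(G, S, leaf_map = NULL) {
  if (!ape::is.binary(G) || !ape::is.rooted(G)) {
    stop("the gene tree must be rooted and binary; ",
         "use resolve_polytomies_min_cost() first")
  }
  sa <- species_arrays(S)
  if (is.null(leaf_map)) leaf_map <- leaf_species_map(G$tip.label)
  ids <- species_id_lookup(sa, leaf_map)
  ga <- rtree_arrays(as_rtree(G), ids)
  core <- reconcile_core(ga, sa)
  internal <- which(ga$species == 0L)
  node_events <- data.frame(
    node = vapply(internal, function(v) {
      paste(sort(ga$labels[gene_leaves_under(ga, v)])[1:2], collapse = "+")
    }, ""),
    event = ifelse(core$is_dup[internal], "duplication", "speciation"),
    species = sa$names[core$M[internal]],
    stringsAsFactors = FALSE)
  structure(
    list(node_events = node_events,
         gains_per_branch = setNames(core$gains, sa$names),
         losses_per_branch = setNames(core$losses, sa$names),
         ancestral_copies = setNames(core$copies, sa$names),
         total_cost = core$total,
         species_arrays = sa, gene_arrays = ga),
    class = "reconciliation")
}

gene_leaves_under <- function(ga, v) {
  if (ga$kids[v, 1] == 0L) return(v)
  c(gene_leaves_under(ga, ga$kids[v, 1]),
    gene_leaves_under(ga, ga$kids[v, 2]))
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation: %d duplications, %d losses, cost %d>\n",
              sum(x$gains_per_branch), sum(x$losses_per_branch),
              x$total_cost))
  invisible(x)
}

#' Ancestral copy numbers from a reconciliation
#'
#' Recomputes root-to-tip propagation `copies(child) = copies(parent) +
#' gains(branch) - losses(branch)` from the per-branch event counts and
#' verifies that every leaf equals the observed extant gene count (an
#' internal-consistency check of the event bookkeeping).
#'
#' @param res a `reconciliation` from [lca_reconcile()]
#' @return named integer vector over species-tree nodes
#' @export
ancestral_copy_numbers <- function(res) {
  sa <- res$species_arrays
  gains <- unname(res$gains_per_branch)
  losses <- unname(res$losses_per_branch)
  copies <- integer(sa$nn)
  copies[sa$root] <- 1L + gains[sa$root]
  rest <- setdiff(seq_len(sa$nn), sa$root)
  for (v in rest[order(sa$depth[rest])]) {
    copies[v] <- copies[sa$parent[v]] + gains[v] - losses[v]
  }
  extant <- tabulate(res$gene_arrays$species[res$gene_arrays$species > 0L],
                     nbins = sa$nn)
  if (!all(copies[seq_len(sa$ntip)] == extant[seq_len(sa$ntip)])) {
    stop("internal consistency error: leaf copies != extant counts")
  }
  setNames(copies, sa$names)
}

# ---- minimum-cost polytomy resolution -------------------------------------

# Exact dynamic programme over the species tree for one polytomy: given
# child subtrees ("items") with fixed species-tree mappings, finds a binary
# resolution minimising local duplication + loss cost. g[s][j] is the
# minimum cost inside the species subtree at s given j gene lineages
# present at s, each required to lead to at least one item. Works for any
# polytomy degree; because the LCA image of the polytomy root is invariant
# under resolution, polytomies can be resolved independently.
resolve_polytomy_dp <- function(items, m_ids, sa) {
  rho <- lca_set(sa, m_ids)
  sig <- vapply(items, function(it) paste(rtree_leaves(it), collapse = ","), "")
  ord <- order(sig)
  items <- items[ord]; m_ids <- m_ids[ord]
  join2 <- function(u, v) list(label = "", len = 0, support = NA_real_,
                               kids = list(u, v))
  chain <- function(nodes, j) {
    while (length(nodes) > j) {
      k <- length(nodes)
      nodes <- c(nodes[seq_len(k - 2L)],
                 list(join2(nodes[[k - 1L]], nodes[[k]])))
    }
    nodes
  }
  in_sub <- function(s) which(vapply(m_ids, function(m) sa$anc[s, m], TRUE))
  if (sa$children[rho, 1] == 0L) {          # all items on one species leaf
    return(chain(items, 1L)[[1L]])
  }
  g <- vector("list", sa$nn)       # g[[s]][j + 1] over j = 0..n_sub(s)
  choice_d <- vector("list", sa$nn)
  choice_ab <- vector("list", sa$nn)
  # postorder over the species subtree of rho
  sub_nodes <- which(sa$anc[rho, ])
  sub_nodes <- sub_nodes[order(-sa$depth[sub_nodes])]
  for (s in sub_nodes) {
    cs <- sum(m_ids == s)
    ns <- length(in_sub(s))
    if (sa$children[s, 1] == 0L) {
      gv <- rep(Inf, ns + 1L)
      gv[1L] <- if (cs == 0L) 0 else Inf
      if (cs > 0L) gv[1L + seq_len(cs)] <- cs - seq_len(cs)
      g[[s]] <- gv
      next
    }
    l <- sa$children[s, 1]; r <- sa$children[s, 2]
    gl <- g[[l]]; gr <- g[[r]]
    nl <- length(gl) - 1L; nr <- length(gr) - 1L
    H <- rep(Inf, nl + nr + 1L)            # H[d + 1]
    Hab <- vector("list", nl + nr + 1L)
    if (is.finite(gl[1L]) && is.finite(gr[1L])) {
      H[1L] <- gl[1L] + gr[1L]
      Hab[[1L]] <- c(0L, 0L)
    }
    for (a in 0:nl) {
      if (!is.finite(gl[a + 1L])) next
      for (b in 0:nr) {
        if (!is.finite(gr[b + 1L])) next
        if (a + b == 0L) next
        for (d in max(a, b, 1L):(a + b)) {
          cand <- 2 * d - a - b + gl[a + 1L] + gr[b + 1L]
          if (cand < H[d + 1L]) {
            H[d + 1L] <- cand
            Hab[[d + 1L]] <- c(a, b)
          }
        }
      }
    }
    gv <- rep(Inf, ns + 1L)
    dv <- rep(NA_integer_, ns + 1L)
    gv[1L] <- if (ns == 0L) 0 else Inf
    if (ns > 0L) {
      for (j in 1:ns) {
        for (d in max(0L, j - cs):(length(H) - 1L)) {
          if (!is.finite(H[d + 1L])) next
          k <- d + cs
          if (k < j) next
          cand <- (k - j) + H[d + 1L]
          if (cand < gv[j + 1L]) { gv[j + 1L] <- cand; dv[j + 1L] <- d }
        }
      }
    }
    g[[s]] <- gv
    choice_d[[s]] <- dv
    choice_ab[[s]] <- Hab
  }
  if (!is.finite(g[[rho]][2L])) stop("internal error: infeasible polytomy DP")
  build <- function(s, j) {
    if (j == 0L) return(list())
    here <- items[m_ids == s]
    if (sa$children[s, 1] == 0L) return(chain(here, j))
    d <- choice_d[[s]][j + 1L]
    if (d == 0L) { A <- list(); B <- list(); a <- 0L; b <- 0L }
    else {
      ab <- choice_ab[[s]][[d + 1L]]
      a <- ab[1]; b <- ab[2]
      A <- build(sa$children[s, 1], a)
      B <- build(sa$children[s, 2], b)
    }
    x <- a + b - d
    spec <- if (x > 0L) lapply(seq_len(x), function(i) join2(A[[i]], B[[i]]))
      else list()
    below <- c(spec,
               if (a > x) A[(x + 1L):a] else list(),
               if (b > x) B[(x + 1L):b] else list())
    chain(c(here, below), j)
  }
  build(rho, 1L)[[1L]]
}

resolve_rtree <- function(nd, ids, sa) {
  if (length(nd$kids) == 0L) return(nd)
  kids <- lapply(nd$kids, resolve_rtree, ids = ids, sa = sa)
  if (length(kids) == 1L) {                 # splice degree-2 node
    k <- kids[[1L]]
    k$len <- sum(c(k$len, nd$len), na.rm = TRUE)
    return(k)
  }
  if (length(kids) == 2L) { nd$kids <- kids; return(nd) }
  m_ids <- vapply(kids, function(k) {
    lca_set(sa, unlist(ids[rtree_leaves(k)], use.names = FALSE))
  }, 0L)
  res <- resolve_polytomy_dp(kids, m_ids, sa)
  res$label <- nd$label; res$len <- nd$len; res$support <- nd$support
  res
}

#' Resolve polytomies of a condensed gene tree at minimum DL cost
#'
#' Each multifurcation of a rooted gene tree (typically produced by
#' [collapse_low_support()]) is replaced by the rooted binary resolution
#' that minimises duplication + loss cost against the species tree, via an
#' exact dynamic programme over the species tree (optimal for any
#' polytomy degree). An already binary tree is returned unchanged.
#'
#' @inheritParams lca_reconcile
#' @param G rooted gene tree, possibly multifurcating (`phylo`)
#' @return a rooted binary `phylo`
#' @export
resolve_polytomies_min_cost <- function(G, S, leaf_map = NULL) {
  sa <- species_arrays(S)
  if (is.null(leaf_map)) leaf_map <- leaf_species_map(G$tip.label)
  ids <- species_id_lookup(sa, leaf_map)
  rt <- resolve_rtree(as_rtree(G), ids, sa)
  rtree_to_phylo(rt)
}

# ---- rooting --------------------------------------------------------------

#' Root a gene tree where the DL reconciliation cost is minimal
#'
#' Tries every edge of the (unrooted) gene tree as a root position,
#' resolves any polytomies at minimum cost, and returns the rooted binary
#' tree with the smallest total duplication + loss cost. Ties are broken
#' by the lexicographically smallest sorted-leaf-label signature of the
#' root bipartition, so the result is deterministic.
#'
#' @inheritParams lca_reconcile
#' @param G gene tree (`phylo`), unrooted or rooted, possibly
#'   multifurcating
#' @return rooted binary `phylo`
#' @export
root_for_min_cost <- function(G, S, leaf_map = NULL) {
  sa <- species_arrays(S)
  if (is.null(leaf_map)) leaf_map <- leaf_species_map(G$tip.label)
  ids <- species_id_lookup(sa, leaf_map)
  if (length(G$tip.label) <= 2L) {
    rt <- resolve_rtree(as_rtree(G), ids, sa)
    return(rtree_to_phylo(rt))
  }
  adj <- tree_adjacency(G)
  best <- NULL; best_cost <- Inf; best_sig <- NULL
  for (e in seq_len(nrow(adj$edges))) {
    rt <- root_at_edge(adj, e)
    rt <- resolve_rtree(rt, ids, sa)
    ga <- rtree_arrays(rt, ids)
    cost <- cpp_dl_cost(ga$kids, ga$species, ga$root, sa$lca, sa$depth)
    sides <- sort(vapply(rt$kids,
                         function(k) paste(rtree_leaves(k), collapse = ","),
                         ""))
    sig <- paste(sides, collapse = "|")
    if (cost < best_cost || (cost == best_cost && sig < best_sig)) {
      best <- rt; best_cost <- cost; best_sig <- sig
    }
  }
  rtree_to_phylo(best)
}

# ---- exhaustive reference oracles (validation) ----------------------------

#' Brute-force minimum DL cost over all reconciliation mappings
#'
#' Exhaustively enumerates every valid mapping of internal gene-tree nodes
#' onto the species tree and returns the minimum duplication + loss cost.
#' Exponential in tree size; a reference implementation used to validate
#' [lca_reconcile()] on small trees.
#'
#' @inheritParams lca_reconcile
#' @return integer minimum cost
#' @export
brute_force_dl_cost <- function(G, S, leaf_map = NULL) {
  sa <- species_arrays(S)
  if (is.null(leaf_map)) leaf_map <- leaf_species_map(G$tip.label)
  ids <- species_id_lookup(sa, leaf_map)
  ga <- rtree_arrays(as_rtree(G), ids)
  cpp_brute_min_cost(ga$kids, ga$species, ga$root, sa$lca, sa$depth, sa$anc)
}

#' Exhaustive minimum DL cost over all binary refinements
#'
#' Enumerates every rooted binary resolution of every polytomy of a
#' multifurcating gene tree (Cartesian product across polytomies) and
#' returns the minimum LCA reconciliation cost. A reference oracle for
#' [resolve_polytomies_min_cost()] on small trees.
#'
#' @inheritParams lca_reconcile
#' @param G rooted, possibly multifurcating gene tree
#' @return integer minimum cost
#' @export
exhaustive_resolution_cost <- function(G, S, leaf_map = NULL) {
  sa <- species_arrays(S)
  if (is.null(leaf_map)) leaf_map <- leaf_species_map(G$tip.label)
  ids <- species_id_lookup(sa, leaf_map)
  rt <- as_rtree(G)
  kids_list <- list(); gs <- integer(0)
  add <- function(n) {
    if (length(n$kids) == 0L) {
      kids_list[[length(kids_list) + 1L]] <<- integer(0)
      gs[length(gs) + 1L] <<- ids[[n$label]]
      return(length(kids_list))
    }
    idx <- vapply(n$kids, add, 0L)
    kids_list[[length(kids_list) + 1L]] <<- idx
    gs[length(gs) + 1L] <<- 0L
    length(kids_list)
  }
  root <- add(rt)
  cpp_min_resolution_cost(kids_list, gs, root, sa$lca, sa$depth)
}

#' Condense, root and reconcile a gene tree in one call
#'
#' Collapses internal edges below the support threshold, finds the
#' minimum-cost rooting (resolving polytomies exactly), and reconciles the
#' result: the standard path from a bootstrapped gene tree to per-branch
#' gain/loss counts.
#'
#' @inheritParams lca_reconcile
#' @param G gene tree with bootstrap supports (`phylo`)
#' @param collapse_threshold support threshold for [collapse_low_support()]
#' @return a `reconciliation` (see [lca_reconcile()])
#' @export
reconcile_gene_tree <- function(G, S, leaf_map = NULL,
                                collapse_threshold = 70) {
  cond <- collapse_low_support(G, collapse_threshold)
  rooted <- root_for_min_cost(cond, S, leaf_map)
  lca_reconcile(rooted, S, leaf_map)
}
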