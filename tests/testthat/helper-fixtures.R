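# Shared fixture builders. Everything is generated in code under fixed
# seeds; the default study bundle is cached per session because several
# test files use it.

.fixture_cache <- new.env(parent = emptyenv())

cached_default_study <- function(seed = 1L) {
  key <- paste0("study", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_study(default_sim_config(seed = seed))
  }
  .fixture_cache[[key]]
}

cached_default_fixture_dir <- function(seed = 1L) {
  key <- paste0("dir", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- file.path(tempdir(), paste0("famevol_fixture_", seed))
    unlink(d, recursive = TRUE)
    make_fixture(default_sim_config(seed = seed), d)
    .fixture_cache[[key]] <- d
  }
  .fixture_cache[[key]]
}

random_protein <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA_RESIDUES, L, replace = TRUE), collapse = "")
}

tiny_proteome <- function(..., species = "sp") {
  seqs <- c(...)
  proteome(paste0("g", seq_along(seqs)), rep(species, length(seqs)), seqs)
}

# point-mutate a fraction of positions (new residue always different)
mutate_seq <- function(seq, frac, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), round(frac * length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(AA_RESIDUES, ch[i]), 1)
  paste(ch, collapse = "")
}

# all rooted binary tree shapes over n leaves labelled from `species`,
# up to isomorphism, as nested kid-lists of species names (memoised)
enumerate_gene_trees <- function(n, species = c("A", "B", "C")) {
  key <- paste0("trees", n, paste(species, collapse = ""))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  canon <- function(t) {
    if (is.character(t)) return(t)
    sub <- sort(vapply(t, canon, ""))
    paste0("(", sub[1], ",", sub[2], ")")
  }
  gen <- function(k) {
    gkey <- paste0("g", k, paste(species, collapse = ""))
    if (!is.null(.fixture_cache[[gkey]])) return(.fixture_cache[[gkey]])
    out <- if (k == 1L) as.list(species) else {
      seen <- character(0)
      acc <- list()
      for (i in seq_len(k %/% 2)) {
        for (a in gen(i)) for (b in gen(k - i)) {
          t <- list(a, b)
          cs <- canon(t)
          if (!(cs %in% seen)) {
            seen <- c(seen, cs)
            acc[[length(acc) + 1L]] <- t
          }
        }
      }
      acc
    }
    .fixture_cache[[gkey]] <- out
    out
  }
  out <- gen(n)
  .fixture_cache[[key]] <- out
  out
}

# nested species-name tree -> arrays for the reconciliation kernels,
# with unique "species|gN" leaf labels
nested_to_gene_arrays <- function(t, sa) {
  kids <- list(); gs <- integer(0)
  cnt <- 0L
  add <- function(x) {
    if (is.character(x)) {
      kids[[length(kids) + 1L]] <<- c(0L, 0L)
      gs[length(gs) + 1L] <<- sa$tip_id[[x]]
      return(length(kids))
    }
    ids <- vapply(x, add, 0L)
    kids[[length(kids) + 1L]] <<- ids
    gs[length(gs) + 1L] <<- 0L
    length(kids)
  }
  root <- add(t)
  list(kids = do.call(rbind, kids), species = gs, root = root)
}

# nested species-name tree -> newick with unique gene leaf labels
nested_to_newick <- function(t) {
  cnt <- 0L
  render <- function(x) {
    if (is.character(x)) {
      cnt <<- cnt + 1L
      return(paste0(x, "|g", cnt))
    }
    paste0("(", paste(vapply(x, render, ""), collapse = ","), ")")
  }
  paste0(render(t), ";")
}

# random rooted multifurcating gene tree (newick) over `species`, made by
# contracting random internal edges of a random binary shape
random_multifurcating_tree <- function(n_leaves, species = c("A", "B", "C"),
                                       contract_p = 0.5) {
  nodes <- as.list(sample(species, n_leaves, replace = TRUE))
  while (length(nodes) > 1L) {
    i <- sample(length(nodes), 2)
    nodes <- c(nodes[-i], list(nodes[i]))
  }
  # contract: each internal child is merged into its parent with prob p
  contract <- function(t) {
    if (is.character(t)) return(t)
    kids <- lapply(t, contract)
    out <- list()
    for (k in kids) {
      if (!is.character(k) && runif(1) < contract_p) out <- c(out, k) else
        out <- c(out, list(k))
    }
    out
  }
  t <- contract(nodes[[1]])
  cnt <- 0L
  render <- function(x) {
    if (is.character(x)) {
      cnt <<- cnt + 1L
      return(paste0(x, "|g", cnt))
    }
    paste0("(", paste(vapply(x, render, ""), collapse = ","), ")")
  }
  paste0(render(t), ";")
}
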