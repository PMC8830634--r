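#' Parameters for the seeded family search
#'
#' @param e_threshold E-value cutoff (default 1e-5)
#' @param scheme a [scoring_scheme()]
#' @param min_alignment_columns minimum alignment length for a hit to
#'   count (default 30), guarding against spurious micro-alignments
#' @return an object of class `search_params`
#' @export
search_params <- function(e_threshold = 1e-5, scheme = scoring_scheme(),
                          min_alignment_columns = 30L) {
  stopifnot(e_threshold > 0)
  structure(list(e_threshold = e_threshold, scheme = scheme,
                 min_alignment_columns = as.integer(min_alignment_columns)),
            class = "search_params")
}

#' Seeded local-alignment search of a proteome
#'
#' Aligns every seed against every protein of the target proteome
#' (best local alignment per ordered pair) and keeps hits with
#' `E <= e_threshold` and at least `min_alignment_columns` aligned
#' columns. The database size for the E-value is the total residue count
#' of the target proteome.
#'
#' @param seeds proteome `data.frame` of seed proteins (non-empty)
#' @param target proteome `data.frame` to search
#' @param params a [search_params()]
#' @return a twelve-column hit table (see [write_hit_table()]), one row
#'   per passing seed-target pair
#' @export
seed_search <- function(seeds, target, params = search_params()) {
  stopifnot(nrow(seeds) > 0L)
  if (nrow(target) == 0L) {
    warning("empty target proteome: no hits")
    return(empty_hit_table())
  }
  n_db <- sum(nchar(target$sequence))
  qids <- full_id(seeds)
  m <- nchar(seeds$sequence)
  out <- vector("list", nrow(target))
  for (j in seq_len(nrow(target))) {
    res <- align_many(seeds$sequence, target$sequence[j], params$scheme)
    hits <- hits_from_alignments(res, qids, full_id(target)[j], m, n_db,
                                 params$scheme)
    keep <- !res$no_hit & hits$evalue <= params$e_threshold &
      hits$length >= params$min_alignment_columns
    out[[j]] <- hits[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reciprocal seed-exchange expansion of a family candidate set
#'
#' The proteins hit in the first search round become seeds themselves and
#' are searched back against the original seed species' proteome; any
#' seed-species genes recovered that were not among the original seeds
#' join the candidate set with `round_found = 2`. Round-1 members are
#' never removed, and re-applying the expansion adds nothing (fixed
#' point).
#'
#' @param seed_proteome proteome of the seed species
#' @param target_proteome proteome searched in round 1
#' @param round1_hits hit table from [seed_search()]
#' @param params a [search_params()]
#' @return data.frame with columns `species`, `gene_id`, `round_found`
#' @export
reciprocal_expand <- function(seed_proteome, target_proteome, round1_hits,
                              params = search_params()) {
  empty <- data.frame(species = character(), gene_id = character(),
                      round_found = integer(), stringsAsFactors = FALSE)
  if (nrow(round1_hits) == 0L) return(empty)
  t_ids <- full_id(target_proteome)
  hit_rows <- target_proteome[t_ids %in% unique(round1_hits$sseqid), ,
                              drop = FALSE]
  cand <- data.frame(species = hit_rows$species, gene_id = hit_rows$gene_id,
                     round_found = 1L, stringsAsFactors = FALSE)
  back <- seed_search(hit_rows, seed_proteome, params)
  if (nrow(back)) {
    s_ids <- full_id(seed_proteome)
    recovered <- seed_proteome[s_ids %in% unique(back$sseqid), , drop = FALSE]
    new <- !(full_id(recovered) %in% unique(round1_hits$qseqid))
    recovered <- recovered[new, , drop = FALSE]
    if (nrow(recovered)) {
      cand <- rbind(cand, data.frame(species = recovered$species,
                                     gene_id = recovered$gene_id,
                                     round_found = 2L,
                                     stringsAsFactors = FALSE))
    }
  }
  cand[!duplicated(cand[, c("species", "gene_id")]), , drop = FALSE]
}

#' Read a domain-annotation table
#'
#' Two tab-separated columns: fully qualified gene label
#' (`"species|gene_id"`) and a comma-separated list of domain accessions
#' (stand-in for an InterProScan summary).
#'
#' @param path TSV file
#' @return named list: gene label -> character vector of accessions
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("line ", bad[1], ": expected 2 tab-separated fields")
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate gene id in domain table: ",
                               ids[duplicated(ids)][1])
  setNames(lapply(fields, function(f) strsplit(f[2], ",", fixed = TRUE)[[1]]),
           ids)
}

write_domain_table <- function(domains, path) {
  lines <- vapply(names(domains), function(id) {
    paste0(id, "\t", paste(domains[[id]], collapse = ","))
  }, "")
  writeLines(unname(lines), path)
  invisible(path)
}

#' Filter family candidates by required domains
#'
#' Keeps only candidates whose annotated domain set intersects the
#' required accessions; genes absent from the domain table are removed
#' (with a message listing how many).
#'
#' @param candidates data.frame with `species`, `gene_id` (and optionally
#'   more columns)
#' @param domains a domain table from [read_domain_table()]
#' @param required non-empty character vector of accepted accessions
#' @return the filtered candidates (subset of the input rows)
#' @export
domain_filter <- function(candidates, domains, required) {
  stopifnot(length(required) > 0L)
  if (nrow(candidates) == 0L) return(candidates)
  labels <- paste(candidates$species, candidates$gene_id, sep = "|")
  known <- labels %in% names(domains)
  if (any(!known)) {
    message(sum(!known), " candidate(s) absent from the domain table ",
            "were removed")
  }
  has_dom <- vapply(labels, function(l) {
    !is.null(domains[[l]]) && length(intersect(domains[[l]], required)) > 0L
  }, TRUE)
  candidates[known & has_dom, , drop = FALSE]
}

#' Annotate gene families across a set of proteomes
#'
#' For each family: the seed proteins are searched against every other
#' species' proteome (round 1); round-1 hits are exchanged with the seeds
#' and searched back against each seed species' proteome, recovering
#' additional seed-species genes (round 2); the union is then filtered by
#' the family's required domains (filter after union). Seed proteins are
#' members by definition but must also pass the domain filter.
#'
#' @param proteomes named list of proteome `data.frame`s (names =
#'   species)
#' @param seed_sets named list: family -> proteome `data.frame` of seeds
#'   (may contain several seed species)
#' @param domains a domain table from [read_domain_table()]
#' @param required_domains named list: family -> accession vector
#' @param params a [search_params()]
#' @return data.frame with columns `family`, `species`, `gene_id`,
#'   `round_found` (1 = seed or first pass, 2 = reciprocal pass)
#' @export
annotate_families <- function(proteomes, seed_sets, domains,
                              required_domains, params = search_params()) {
  out <- list()
  for (fam in names(seed_sets)) {
    seeds <- seed_sets[[fam]]
    seed_species <- unique(seeds$species)
    cand <- data.frame(species = seeds$species, gene_id = seeds$gene_id,
                       round_found = 1L, stringsAsFactors = FALSE)
    for (sp in setdiff(names(proteomes), seed_species)) {
      r1 <- seed_search(seeds, proteomes[[sp]], params)
      for (ss in seed_species) {
        expanded <- reciprocal_expand(proteomes[[ss]], proteomes[[sp]], r1,
                                      params)
        cand <- rbind(cand, expanded)
      }
    }
    cand <- cand[!duplicated(cand[, c("species", "gene_id")]), , drop = FALSE]
    cand <- domain_filter(cand, domains, required_domains[[fam]])
    if (nrow(cand)) {
      cand$family <- fam
      out[[fam]] <- cand[, c("family", "species", "gene_id", "round_found")]
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(family = character(), species = character(),
                      gene_id = character(), round_found = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Per-species family count table
#'
#' Integer gene counts per species and family; missing combinations are
#' zero. Species rows follow the supplied order (typically the species
#' tree's tip order).
#'
#' @param assignments data.frame with `family`, `species`, `gene_id`
#'   (e.g. from [annotate_families()])
#' @param species_order character vector of species defining row order;
#'   defaults to sorted species present
#' @param families column order; defaults to sorted families present
#' @return data.frame: first column `species`, one integer column per
#'   family
#' @export
family_count_table <- function(assignments, species_order = NULL,
                               families = NULL) {
  if (is.null(species_order)) {
    species_order <- sort(unique(assignments$species))
  }
  if (is.null(families)) families <- sort(unique(assignments$family))
  counts <- matrix(0L, length(species_order), length(families),
                   dimnames = list(species_order, families))
  if (nrow(assignments)) {
    tab <- table(assignments$species, assignments$family)
    for (sp in intersect(rownames(tab), species_order)) {
      for (fam in intersect(colnames(tab), families)) {
        counts[sp, fam] <- tab[sp, fam]
      }
    }
  }
  data.frame(species = species_order, counts, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}
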