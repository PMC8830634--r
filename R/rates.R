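# Relative evolutionary rates from pairwise amino-acid identity: for each
# group (a family or subfamily), all-vs-all best local alignments yield
# within-species samples of n(n-1)/2 identities per species and an
# among-species sample of all cross-species pairs; higher identity means a
# lower evolutionary rate. Pairs are unordered (one value per pair) and
# self-hits are excluded. Pairs with no significant local alignment
# (E above the search threshold) are excluded from the sample rather
# than scored 0, exactly as a database search reports no row for them.

# All unordered-pair identities among `records`. A pair contributes one
# value only if its best local alignment is significant (E <= e_threshold
# against the group's total residue count); insignificant pairs are
# excluded with a warning, mirroring the fact that a database search
# reports no row at all for them.
pairwise_identities <- function(records, scheme = scoring_scheme(),
                                e_threshold = 1e-5) {
  n <- nrow(records)
  if (n < 2L) {
    return(data.frame(id1 = character(), id2 = character(),
                      sp1 = character(), sp2 = character(),
                      pident = numeric(), stringsAsFactors = FALSE))
  }
  ids <- full_id(records)
  n_db <- sum(nchar(records$sequence))
  out <- vector("list", n - 1L)
  dropped <- 0L
  for (j in 2:n) {
    res <- align_many(records$sequence[seq_len(j - 1L)],
                      records$sequence[j], scheme)
    ev <- e_value(res$score, nchar(records$sequence[seq_len(j - 1L)]),
                  n_db, scheme)
    ok <- !res$no_hit & ev <= e_threshold
    dropped <- dropped + sum(!ok)
    out[[j - 1L]] <- data.frame(
      id1 = ids[seq_len(j - 1L)][ok], id2 = rep(ids[j], sum(ok)),
      sp1 = records$species[seq_len(j - 1L)][ok],
      sp2 = rep(records$species[j], sum(ok)),
      pident = 100 * res$identities[ok] / res$columns[ok],
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(dropped, " pair(s) with no significant local alignment were ",
            "excluded from the identity sample")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-species identity sample of a group
#'
#' Every pair of the group's members inside one species contributes one
#' percent-identity value (best local alignment per unordered pair), so a
#' species with n members yields n(n-1)/2 values when all pairs align.
#'
#' @param members proteome `data.frame` of the group's members (all
#'   species)
#' @param species the species to sample
#' @param scheme a [scoring_scheme()]
#' @param e_threshold pairs whose best alignment has a larger E-value are
#'   excluded from the sample (default 1e-5)
#' @return list with `scope`, `values`
#' @export
within_species_identities <- function(members, species,
                                      scheme = scoring_scheme(),
                                      e_threshold = 1e-5) {
  rec <- members[members$species == species, , drop = FALSE]
  pw <- pairwise_identities(rec, scheme, e_threshold)
  list(scope = paste0("within:", species), values = pw$pident)
}

#' Among-species identity sample of a group
#'
#' All cross-species unordered pairs of the group's members; the
#' within-species pairs are removed (the deduplication rule), so with
#' N total members of which species s has n_s,
#' `|among| = N(N-1)/2 - sum_s n_s(n_s-1)/2` when all pairs align.
#'
#' @param members proteome `data.frame` of the group's members
#' @param scheme a [scoring_scheme()]
#' @param e_threshold pairs whose best alignment has a larger E-value are
#'   excluded from the sample (default 1e-5)
#' @return list with `scope = "among"`, `values`
#' @export
among_species_identities <- function(members, scheme = scoring_scheme(),
                                     e_threshold = 1e-5) {
  if (length(unique(members$species)) < 2L) {
    message("group present in fewer than 2 species: empty among sample")
    return(list(scope = "among", values = numeric(0)))
  }
  pw <- pairwise_identities(members, scheme, e_threshold)
  list(scope = "among", values = pw$pident[pw$sp1 != pw$sp2])
}

#' Pooled within-species identity sample
#'
#' Concatenates the within-species samples of every species with at least
#' two members (used for the within-scope ranking).
#'
#' @inheritParams among_species_identities
#' @return list with `scope = "within"`, `values`
#' @export
within_all_identities <- function(members, scheme = scoring_scheme(),
                                  e_threshold = 1e-5) {
  pw <- pairwise_identities(members, scheme, e_threshold)
  list(scope = "within", values = pw$pident[pw$sp1 == pw$sp2])
}

#' Summary statistics of an identity sample
#'
#' Mean, population standard deviation and quartiles by the linear
#' interpolation convention (R quantile type 7).
#'
#' @param sample list with a `values` vector (>= 1 value)
#' @return data.frame with `mean`, `sd`, `lower_quartile`, `median`,
#'   `upper_quartile`, `count`
#' @export
summarize_identities <- function(sample) {
  v <- sample$values
  if (length(v) < 1L) stop("cannot summarize an empty identity sample")
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  data.frame(mean = mean(v),
             sd = sqrt(mean((v - mean(v))^2)),
             lower_quartile = q[1], median = q[2], upper_quartile = q[3],
             count = length(v), stringsAsFactors = FALSE)
}

#' Rank groups from fastest- to slowest-evolving
#'
#' Ascending mean identity corresponds to descending evolutionary rate
#' (the lower the identity, the faster the group evolves). A group whose
#' mean is `NA` because none of its pairs had a significant alignment is
#' ranked fastest of all: no detectable similarity places its identity
#' below the detection floor of every measurable group. Ties are broken
#' alphabetically by group name.
#'
#' @param summaries data.frame with columns `group` and `mean` (one row
#'   per group, >= 2 groups; `mean` may be `NA` for below-detection
#'   groups)
#' @return the input rows reordered, fastest-evolving first
#' @export
rank_by_identity <- function(summaries) {
  stopifnot(nrow(summaries) >= 2L, all(c("group", "mean") %in%
                                         names(summaries)))
  ord <- order(!is.na(summaries$mean), summaries$mean, summaries$group,
               na.last = FALSE)
  out <- summaries[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare within- and among-species rate rankings
#'
#' Emits both rank orders (fastest first) and every pair of groups whose
#' relative order differs between the two scopes (the Kendall inversion
#' set; an identical ranking has zero inversions).
#'
#' @param within_summaries,among_summaries data.frames with `group` and
#'   `mean` columns covering the same groups
#' @return list with `within_order`, `among_order`, `inversions`
#'   (data.frame of group pairs) and `n_inversions`
#' @export
compare_within_vs_among <- function(within_summaries, among_summaries) {
  stopifnot(setequal(within_summaries$group, among_summaries$group))
  wo <- rank_by_identity(within_summaries)$group
  ao <- rank_by_identity(among_summaries)$group
  pairs <- utils::combn(sort(wo), 2)
  inv <- apply(pairs, 2, function(p) {
    (match(p[1], wo) < match(p[2], wo)) !=
      (match(p[1], ao) < match(p[2], ao))
  })
  list(within_order = wo, among_order = ao,
       inversions = data.frame(group1 = pairs[1, inv],
                               group2 = pairs[2, inv],
                               stringsAsFactors = FALSE),
       n_inversions = sum(inv))
}
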