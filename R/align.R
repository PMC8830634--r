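#' Smith-Waterman local alignment of two proteins
#'
#' Maximum-scoring local alignment under the scheme's substitution matrix
#' and affine gap penalties (the pairwise engine used by the seeded family
#' search and the identity statistics; dynamic programming via
#' `Biostrings::pairwiseAlignment`). If no residue pair scores positively
#' the result is an empty alignment flagged `no_hit` with score 0.
#'
#' @param a,b proteome rows (single-row `data.frame`s) or plain sequences;
#'   plain sequences get ids `"a"` and `"b"`
#' @param scheme a [scoring_scheme()]
#' @return an object of class `alignment`: a list with `query_id`,
#'   `subject_id`, `aligned_query`, `aligned_subject`, `score`,
#'   `identities`, `columns`, 1-based inclusive coordinates
#'   `q_start`, `q_end`, `s_start`, `s_end`, and flag `no_hit`
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  a <- as_protein_record(a, "a")
  b <- as_protein_record(b, "b")
  res <- align_many(a$sequence, b$sequence, scheme, with_strings = TRUE)
  row_to_alignment(res, 1L, full_id(a), full_id(b))
}

as_protein_record <- function(x, default_id) {
  if (is.character(x) && length(x) == 1L) {
    x <- proteome(default_id, default_id, x)
  }
  stopifnot(is.data.frame(x), nrow(x) == 1L)
  x
}

row_to_alignment <- function(res, i, query_id, subject_id) {
  structure(
    list(query_id = query_id, subject_id = subject_id,
         aligned_query = res$aligned_query[i],
         aligned_subject = res$aligned_subject[i],
         score = res$score[i], identities = res$identities[i],
         columns = res$columns[i],
         q_start = res$q_start[i], q_end = res$q_end[i],
         s_start = res$s_start[i], s_end = res$s_end[i],
         no_hit = res$no_hit[i]),
    class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  if (x$no_hit) {
    cat("<alignment: no hit>\n")
  } else {
    cat(sprintf("<alignment %s x %s: score %g, %d/%d identities (%.1f%%)>\n",
                x$query_id, x$subject_id, x$score, x$identities, x$columns,
                percent_identity(x)))
  }
  invisible(x)
}

# Vectorised local alignment of many query sequences against one subject.
# Returns one row per query with scores, identity counts, gap statistics
# and coordinates; `no_hit` marks alignments with score <= 0, which are
# zeroed out. Aligned strings (needed only for single-pair inspection)
# are extracted when `with_strings = TRUE`.
align_many <- function(queries, subject, scheme = scoring_scheme(),
                       with_strings = FALSE) {
  stopifnot(length(subject) == 1L, nchar(subject) > 0L,
            all(nchar(queries) > 0L))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = abs(scheme$gap_open),
    gapExtension = abs(scheme$gap_extend))
  score <- Biostrings::score(pa)
  ins <- Biostrings::insertion(Biostrings::nindel(pa))
  del <- Biostrings::deletion(Biostrings::nindel(pa))
  res <- data.frame(
    score = score,
    identities = Biostrings::nmatch(pa),
    columns = Biostrings::nchar(pa),
    gap_opens = ins[, "Length"] + del[, "Length"],
    gap_columns = ins[, "WidthSum"] + del[, "WidthSum"],
    q_start = BiocGenerics::start(Biostrings::pattern(pa)),
    q_end = BiocGenerics::end(Biostrings::pattern(pa)),
    s_start = BiocGenerics::start(Biostrings::subject(pa)),
    s_end = BiocGenerics::end(Biostrings::subject(pa)),
    no_hit = score <= 0,
    stringsAsFactors = FALSE)
  if (with_strings) {
    res$aligned_query <- unname(as.character(Biostrings::alignedPattern(pa)))
    res$aligned_subject <-
      unname(as.character(Biostrings::alignedSubject(pa)))
  } else {
    res$aligned_query <- res$aligned_subject <- NA_character_
  }
  zero <- res$no_hit
  if (any(zero)) {
    res$score[zero] <- 0
    res$identities[zero] <- 0L
    res$columns[zero] <- 0L
    res$gap_opens[zero] <- res$gap_columns[zero] <- 0L
    res$q_start[zero] <- res$q_end[zero] <- 0L
    res$s_start[zero] <- res$s_end[zero] <- 0L
    res$aligned_query[zero] <- res$aligned_subject[zero] <- ""
  }
  res
}

#' Percent identity of an alignment
#'
#' `100 * identities / columns`, where gap columns count in the
#' denominator (the BLAST `pident` convention over the aligned region).
#'
#' @param al an `alignment` from [local_align()]
#' @return a value in [0, 100]
#' @export
percent_identity <- function(al) {
  if (isTRUE(al$no_hit) || al$columns < 1L) {
    stop("percent identity is undefined for an empty (no hit) alignment")
  }
  100 * al$identities / al$columns
}

# Global (Needleman-Wunsch) percent identity over all alignment columns;
# used for guide-tree distances in the progressive aligner.
global_identity <- function(queries, subject, scheme = scoring_scheme()) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "global",
    substitutionMatrix = scheme$matrix,
    gapOpening = abs(scheme$gap_open),
    gapExtension = abs(scheme$gap_extend))
  Biostrings::nmatch(pa) / Biostrings::nchar(pa) * 100
}
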