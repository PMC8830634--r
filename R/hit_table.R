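HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Build hit-table rows from vectorised alignment results
#'
#' Produces the classical twelve-column tabular layout (query id, subject
#' id, percent identity, alignment length, mismatches, gap openings,
#' query/subject coordinates, E-value, bit score).
#'
#' @param res result of an internal vectorised alignment
#' @param query_ids,subject_id full `"species|gene_id"` labels
#' @param m query lengths; `n` database residue count for the E-value
#' @param scheme a [scoring_scheme()]
#' @keywords internal
hits_from_alignments <- function(res, query_ids, subject_id, m, n,
                                 scheme = scoring_scheme()) {
  data.frame(
    qseqid = query_ids,
    sseqid = rep(subject_id, nrow(res)),
    pident = ifelse(res$columns > 0L, 100 * res$identities / res$columns, 0),
    length = res$columns,
    mismatch = res$columns - res$identities - res$gap_columns,
    gapopen = res$gap_opens,
    qstart = res$q_start, qend = res$q_end,
    sstart = res$s_start, send = res$s_end,
    evalue = e_value(res$score, m, n, scheme),
    bitscore = bit_score(res$score, scheme),
    stringsAsFactors = FALSE)
}

#' Write / read a twelve-column hit table
#'
#' Tab-separated, no header, one row per hit; identities are printed to 3
#' decimals, E-values in scientific notation with 2 significant digits and
#' bit scores to 1 decimal, so serialisation is stable and diffs are
#' reproducible. `read_hit_table` raises an error naming the line number
#' when a row does not have exactly 12 fields.
#'
#' @param hits a data.frame with the twelve hit columns
#' @param path file path
#' @return `read_hit_table` returns a data.frame with the 12 columns
#'   (zero rows for an empty file)
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(identical(names(hits), HIT_COLUMNS))
  out <- hits
  out$pident <- sprintf("%.3f", hits$pident)
  out$evalue <- formatC(hits$evalue, format = "e", digits = 1)
  out$bitscore <- sprintf("%.1f", hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_hit_table <- function() {
  data.frame(qseqid = character(), sseqid = character(),
             pident = numeric(), length = integer(),
             mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- empty_hit_table()
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("line ", bad[1], ": expected 12 tab-separated fields, found ",
         lengths(fields)[bad[1]])
  }
  m <- do.call(rbind, fields)
  df <- empty[seq_len(nrow(m)), ]
  df$qseqid <- m[, 1]; df$sseqid <- m[, 2]
  df$pident <- as.numeric(m[, 3]); df$length <- as.integer(m[, 4])
  df$mismatch <- as.integer(m[, 5]); df$gapopen <- as.integer(m[, 6])
  df$qstart <- as.integer(m[, 7]); df$qend <- as.integer(m[, 8])
  df$sstart <- as.integer(m[, 9]); df$send <- as.integer(m[, 10])
  df$evalue <- as.numeric(m[, 11]); df$bitscore <- as.numeric(m[, 12])
  rownames(df) <- NULL
  df
}
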