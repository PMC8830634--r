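# Progressive multiple alignment: UPGMA guide tree on pairwise global
# identity distances, then profile-profile global alignment with a linear
# per-column gap cost and the once-a-gap-always-a-gap rule. Deterministic.

#' Construct / validate a multiple sequence alignment object
#'
#' An `msa` holds equal-length aligned sequences (residues + `-`) with
#' their gene ids. At least two rows are required and no row may be all
#' gaps.
#'
#' @param ids character vector of sequence ids
#' @param seqs aligned sequences, equal lengths
#' @return an object of class `msa`
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2L) stop("an MSA needs at least 2 rows")
  if (length(unique(nchar(seqs))) != 1L) stop("unequal row lengths")
  if (any(gsub("-", "", seqs, fixed = TRUE) == "")) stop("all-gap row")
  structure(list(ids = ids, seqs = seqs), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d sequences x %d columns>\n", length(x$ids),
              nchar(x$seqs[1])))
  invisible(x)
}

# integer-coded alignment matrix: rows = sequences, 0 = gap, 1..21 residues
msa_matrix <- function(x) {
  chars <- strsplit(x$seqs, "")
  m <- do.call(rbind, lapply(chars, function(s) {
    i <- match(s, AA_ALPHABET_X)
    i[is.na(i)] <- 0L
    i
  }))
  rownames(m) <- x$ids
  m
}

matrix_to_msa <- function(m) {
  code <- c("-", AA_ALPHABET_X)
  seqs <- apply(m, 1, function(r) paste(code[r + 1L], collapse = ""))
  msa(rownames(m), unname(seqs))
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from pairwise global-alignment identity
#' distances, then merges profiles leaf-to-root by global profile-profile
#' alignment (mean-of-pairs substitution score, linear per-column gap cost,
#' gaps once introduced are never removed). Fully deterministic.
#'
#' @param prot a proteome `data.frame` with >= 2 rows
#' @param scheme a [scoring_scheme()]
#' @param gap_col per-column gap-versus-residue score used in profile
#'   alignment (default -8)
#' @return an [msa()] in the input row order, ids from [full_id()]
#' @export
progressive_msa <- function(prot, scheme = scoring_scheme(), gap_col = -8) {
  n <- nrow(prot)
  if (n < 2L) stop("progressive_msa needs at least 2 records")
  ids <- full_id(prot)
  seqs <- prot$sequence
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in 2:n) {
    pid <- global_identity(seqs[seq_len(j - 1L)], seqs[j], scheme)
    D[seq_len(j - 1L), j] <- D[j, seq_len(j - 1L)] <- 1 - pid / 100
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(match(strsplit(seqs[i], "")[[1]], AA_ALPHABET_X), 1)
    rownames(m) <- ids[i]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  get_prof <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    merged[[s]] <- align_profiles(get_prof(hc$merge[s, 1]),
                                  get_prof(hc$merge[s, 2]),
                                  scheme, gap_col)
  }
  out <- merged[[length(merged)]]
  matrix_to_msa(out[ids, , drop = FALSE])
}

# Global alignment of two profiles (integer matrices, 0 = gap). Column
# score = mean over all residue pairs of the substitution matrix, with
# residue-vs-gap scoring `gap_col` and gap-vs-gap 0. Linear gap model;
# tie-break diagonal > up > left.
align_profiles <- function(A, B, scheme, gap_col) {
  M <- scheme$matrix[AA_ALPHABET_X, AA_ALPHABET_X]
  nA <- nrow(A); nB <- nrow(B)
  LA <- ncol(A); LB <- ncol(B)
  count21 <- function(P) {
    out <- apply(P, 2, function(col) tabulate(col[col > 0L], nbins = 21L))
    matrix(out, nrow = 21L)
  }
  CA <- count21(A); CB <- count21(B)          # 21 x L
  resA <- colSums(CA); resB <- colSums(CB)
  gapA <- nA - resA; gapB <- nB - resB
  S <- (t(CA) %*% M %*% CB +
          gap_col * (outer(resA, gapB) + outer(gapA, resB))) / (nA * nB)
  gA <- gap_col * resB / nB                    # all-gap column in A vs B col
  gB <- gap_col * resA / nA
  GA <- cumsum(gA)
  dp <- matrix(0, LA + 1L, LB + 1L)
  dp[1L, ] <- c(0, GA)
  dp[, 1L] <- c(0, cumsum(gB))
  for (i in seq_len(LA)) {
    V <- pmax(dp[i, seq_len(LB)] + S[i, ], dp[i, -1L] + gB[i])
    P <- cummax(c(dp[i + 1L, 1L], V - GA))
    dp[i + 1L, -1L] <- P[-1L] + GA
  }
  eps <- 1e-9
  i <- LA; j <- LB
  pathA <- integer(0); pathB <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(dp[i + 1L, j + 1L] - (dp[i, j] + S[i, j])) < eps) {
      pathA <- c(i, pathA); pathB <- c(j, pathB); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(dp[i + 1L, j + 1L] - (dp[i, j + 1L] + gB[i])) < eps) {
      pathA <- c(i, pathA); pathB <- c(0L, pathB); i <- i - 1L
    } else {
      pathA <- c(0L, pathA); pathB <- c(j, pathB); j <- j - 1L
    }
  }
  ncols <- length(pathA)
  out <- matrix(0L, nA + nB, ncols)
  out[seq_len(nA), pathA > 0L] <- A[, pathA[pathA > 0L], drop = FALSE]
  out[nA + seq_len(nB), pathB > 0L] <- B[, pathB[pathB > 0L], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Remove poorly aligned (gap-rich) columns
#'
#' Drops every column whose gap fraction exceeds `max_gap_fraction`
#' (an automated stand-in for manual removal of badly aligned blocks).
#' Row order is preserved; removing all columns is an error.
#'
#' @param x an [msa()]
#' @param max_gap_fraction columns with a strictly greater gap fraction
#'   are removed (default 0.5; 1.0 removes nothing)
#' @return an [msa()]
#' @export
trim_poor_columns <- function(x, max_gap_fraction = 0.5) {
  m <- msa_matrix(x)
  gap_frac <- colMeans(m == 0L)
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("trimming would remove every column")
  matrix_to_msa(m[, keep, drop = FALSE])
}

#' Poisson-corrected pairwise distances from an MSA
#'
#' p is the fraction of differing sites over columns where both rows are
#' non-gap; the distance is the Poisson correction `d = -ln(1 - p)`,
#' capped at `d_max` (also used when two rows share no columns).
#'
#' @param x an [msa()]
#' @param d_max distance cap (default 10)
#' @return symmetric labelled distance matrix with zero diagonal
#' @export
msa_distances <- function(x, d_max = 10) {
  m <- msa_matrix(x)
  p <- cpp_pdist(m, seq_len(ncol(m)))
  p_cap <- 1 - exp(-d_max)
  d <- ifelse(is.na(p) | p >= p_cap, d_max, -log(1 - p))
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
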