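#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues plus 'X' for unknown.
#' @export
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname AA_RESIDUES
#' @export
AA_ALPHABET_X <- c(AA_RESIDUES, "X")

#' Scoring scheme for protein local alignment
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' constants for E-value computation. The default matrix is BLOSUM62
#' restricted to the 20 standard residues plus 'X', with 'X' scoring 0
#' against everything. Gap penalties follow the BLAST convention: a gap of
#' length k costs `|gap_open| + k * |gap_extend|`.
#'
#' @param gap_open gap opening penalty, negative integer (default -11)
#' @param gap_extend gap extension penalty, negative integer (default -1);
#'   must satisfy `gap_open <= gap_extend < 0`
#' @param ka_lambda,ka_K Karlin-Altschul constants for the E-value
#'   `E = K * m * n * exp(-lambda * S)`. Defaults are the classical
#'   ungapped BLOSUM62 estimates (lambda = 0.267, K = 0.041).
#' @param matrix optional symmetric integer substitution matrix with
#'   dimnames covering [AA_ALPHABET_X]; if `NULL` the default is built.
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(gap_open = -11L, gap_extend = -1L,
                           ka_lambda = 0.267, ka_K = 0.041,
                           matrix = NULL) {
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    stop("gap penalties must satisfy gap_open <= gap_extend < 0")
  }
  if (!(ka_lambda > 0 && ka_K > 0)) {
    stop("Karlin-Altschul constants must be positive")
  }
  if (is.null(matrix)) {
    matrix <- default_substitution_matrix()
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric")
  }
  if (!all(AA_ALPHABET_X %in% rownames(matrix))) {
    stop("substitution matrix must cover the 20 residues plus 'X'")
  }
  structure(
    list(matrix = matrix, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend),
         ka_lambda = ka_lambda, ka_K = ka_K),
    class = "scoring_scheme")
}

default_substitution_matrix <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  m <- data_env$BLOSUM62[AA_ALPHABET_X, AA_ALPHABET_X]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a raw alignment score `S`, query
#' length `m` and database residue count `n`.
#'
#' @param score raw alignment score(s)
#' @param m query length (>= 1)
#' @param n total residue count of the searched database (>= 1)
#' @param scheme a [scoring_scheme()]
#' @return non-negative E-value(s)
#' @export
e_value <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$ka_K * m * n * exp(-scheme$ka_lambda * score)
}

#' Bit score from a raw score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams e_value
#' @export
bit_score <- function(score, scheme = scoring_scheme()) {
  (scheme$ka_lambda * score - log(scheme$ka_K)) / log(2)
}
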