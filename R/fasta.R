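#' Construct a proteome table
#'
#' A proteome is a plain `data.frame` with one row per protein and columns
#' `gene_id`, `species`, `sequence` and optional `family` / `subfamily`
#' labels. Sequences must be non-empty, uppercase and drawn from the 20
#' standard residues plus 'X'; `gene_id` must be unique within a species.
#'
#' @param gene_id,species,sequence character vectors of equal length
#' @param family,subfamily optional character labels (NA when unknown)
#' @return a validated proteome `data.frame`
#' @export
proteome <- function(gene_id, species, sequence,
                     family = NA_character_, subfamily = NA_character_) {
  n <- length(gene_id)
  df <- data.frame(gene_id = as.character(gene_id),
                   species = as.character(species),
                   sequence = as.character(sequence),
                   family = rep_len(family, n),
                   subfamily = rep_len(subfamily, n),
                   stringsAsFactors = FALSE)
  validate_proteome(df)
  df
}

validate_proteome <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET_X, collapse = "")),
                df$sequence)
  if (any(bad)) {
    stop("illegal residue or empty sequence in record '",
         df$gene_id[which(bad)[1]], "'")
  }
  dup <- duplicated(df[, c("species", "gene_id")])
  if (any(dup)) {
    stop("duplicate gene_id within a proteome: '", df$gene_id[which(dup)[1]],
         "' (", df$species[which(dup)[1]], ")")
  }
  invisible(df)
}

#' Fully qualified gene labels
#'
#' Gene-tree leaves and cross-species tables use `"species|gene_id"` labels.
#'
#' @param df a proteome or any data.frame with `species` and `gene_id`
#' @return character vector of labels
#' @export
full_id <- function(df) paste(df$species, df$gene_id, sep = "|")

#' Read a protein FASTA file into a proteome table
#'
#' Headers follow the `"species|gene_id"` convention; alternatively a
#' single `species` can be supplied and headers are taken as bare gene ids.
#' Record order is preserved. Malformed headers or illegal residues raise
#' an error naming the offending record.
#'
#' @param path FASTA file
#' @param species optional species name overriding header parsing
#' @return a proteome `data.frame` (zero rows for an empty file)
#' @export
read_fasta <- function(path, species = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  # pre-validate raw sequence lines (the FASTA reader silently drops
  # invalid codes), so the offending record can be named
  raw <- readLines(path)
  current <- "<no header>"
  ok <- sprintf("^[%s]*$", paste(AA_ALPHABET_X, collapse = ""))
  for (line in raw) {
    if (startsWith(line, ">")) current <- sub("^>", "", line) else
      if (!grepl(ok, toupper(trimws(line)))) {
        stop("illegal residue in record '", current, "'")
      }
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(proteome(character(), character(), character()))
  }
  headers <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (is.null(species)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    np <- lengths(parts)
    if (any(np != 2L)) {
      stop("malformed header (expected 'species|gene_id'): '",
           headers[which(np != 2L)[1]], "'")
    }
    sp <- vapply(parts, `[`, "", 1L)
    id <- vapply(parts, `[`, "", 2L)
  } else {
    sp <- rep(species, length(headers))
    id <- sub("^.*\\|", "", headers)
  }
  proteome(id, sp, seqs)
}

#' Write a proteome table as FASTA
#'
#' Headers are written as `"species|gene_id"`; [read_fasta()] reparses the
#' output to identical records.
#'
#' @param df a proteome `data.frame`
#' @param path output file
#' @export
write_fasta <- function(df, path) {
  validate_proteome(df)
  set <- Biostrings::AAStringSet(df$sequence)
  names(set) <- full_id(df)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
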