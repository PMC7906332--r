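# Amino-acid trigram encoding.  A sequence of length L yields L-2 overlapping
# trigrams (overlap 2); each trigram gets a base-20 positional code in
# 1..8000, and index 0 is reserved for padding.  The one-hot-times-embedding
# product of the model is realised as an index lookup, which is the same map
# without materialising 8000-dimensional vectors.

#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AMBIGUOUS_AA <- c("B", "J", "O", "U", "X", "Z")

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return `data.frame` with columns `id` (first whitespace-delimited header
#'   token) and `sequence`, in input order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  if (any(Biostrings::width(set) == 0L))
    stop("FASTA record with empty sequence: ",
         names(set)[Biostrings::width(set) == 0L][1])
  data.frame(id = sub("\\s.*$", "", names(set)),
             sequence = toupper(as.character(set)),
             row.names = NULL)
}

#' Filter sequences by length and alphabet
#'
#' Drops sequences longer than `max_len` and sequences containing any
#' character outside the 20-letter standard amino-acid alphabet (the
#' ambiguity codes B, J, O, U, X, Z and anything else).
#'
#' @param records `data.frame` as returned by [read_fasta()].
#' @param max_len maximum sequence length kept (default 1002).
#' @return List with `kept` (records data frame) and `dropped` (records plus
#'   a `reason` column, one of `"too long"` / `"ambiguous"`).
#' @export
filter_sequences <- function(records, max_len = 1002L) {
  if (max_len < 3L) stop("max_len must be >= 3")
  too_long <- nchar(records$sequence) > max_len
  clean <- grepl(sprintf("^[%s]*$", paste(AA_ALPHABET, collapse = "")),
                 records$sequence)
  reason <- ifelse(too_long, "too long", ifelse(!clean, "ambiguous", NA))
  dropped <- records[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!is.na(reason)]
  else dropped$reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Trigram code
#'
#' Base-20 positional code of a 3-letter amino-acid word, alphabetical letter
#' order, plus one: `"AAA"` is 1, `"YYY"` is 8000.  Bijective over the 8000
#' possible trigrams; 0 is reserved for padding.
#'
#' @param trigram character vector of 3-letter strings.
#' @return Integer vector in `[1, 8000]`.
#' @export
trigram_index <- function(trigram) {
  if (any(nchar(trigram) != 3L)) stop("trigrams must have exactly 3 letters")
  l1 <- match(substr(trigram, 1, 1), AA_ALPHABET)
  l2 <- match(substr(trigram, 2, 2), AA_ALPHABET)
  l3 <- match(substr(trigram, 3, 3), AA_ALPHABET)
  if (anyNA(l1) || anyNA(l2) || anyNA(l3))
    stop("trigram contains a letter outside the 20-letter alphabet")
  (l1 - 1L) * 400L + (l2 - 1L) * 20L + l3
}

#' Encode sequences as padded trigram index vectors
#'
#' Position `i` of the encoding holds the trigram code of `seq[i..i+2]`;
#' positions past `L - 2` hold the padding code 0.  The padding row of the
#' embedding table is fixed at zero, so model output does not depend on
#' `max_positions` beyond the sequence's own trigrams.
#'
#' @param records `data.frame` with `id` and `sequence` columns, already
#'   passed through [filter_sequences()].
#' @param max_positions number of trigram positions (default 1000, matching a
#'   maximum sequence length of 1002).
#' @return Object of class `trigram_encoding`: list with `indices` (integer
#'   matrix, `max_positions` x n), `lengths` (number of real trigrams per
#'   sequence) and `ids`.
#' @export
encode_sequences <- function(records, max_positions = 1000L) {
  n <- nrow(records)
  L <- nchar(records$sequence)
  if (any(L < 3L))
    stop("sequence shorter than 3 residues: ", records$id[L < 3L][1])
  if (any(L - 2L > max_positions))
    stop("sequence has more than max_positions trigrams: ",
         records$id[L - 2L > max_positions][1])
  idx <- matrix(0L, max_positions, n)
  for (s in seq_len(n)) {
    ntri <- L[s] - 2L
    tris <- substring(records$sequence[s], 1:ntri, 3:L[s])
    idx[seq_len(ntri), s] <- trigram_index(tris)
  }
  structure(list(indices = idx, lengths = L - 2L, ids = records$id),
            class = "trigram_encoding")
}

#' @export
print.trigram_encoding <- function(x, ...) {
  cat("trigram_encoding:", length(x$ids), "sequences,",
      nrow(x$indices), "positions\n")
  invisible(x)
}

#' Decode a trigram encoding back to sequences
#'
#' Inverse of [encode_sequences()]: successive overlapping trigrams determine
#' the sequence (first letter of each trigram plus the tail of the last one).
#'
#' @param enc a `trigram_encoding`.
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(enc) {
  vapply(seq_along(enc$ids), function(s) {
    codes <- enc$indices[seq_len(enc$lengths[s]), s] - 1L
    l1 <- codes %/% 400L
    l2 <- (codes %/% 20L) %% 20L
    l3 <- codes %% 20L
    last <- length(codes)
    paste(c(AA_ALPHABET[l1 + 1L],
            AA_ALPHABET[l2[last] + 1L], AA_ALPHABET[l3[last] + 1L]),
          collapse = "")
  }, "")
}

#' Read a numeric feature table
#'
#' TSV with a protein id column followed by `d` numeric feature columns
#' (dataset-2 style hand-crafted features; 258 in the FFPred encoding).
#'
#' @param path TSV path with a header row; first column is the id.
#' @return List with `ids` and `features` (n x d numeric matrix).
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("feature table needs an id column plus features")
  feat <- df[, -1, drop = FALSE]
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric value in feature table at row ", bad,
           ", column ", colnames(feat)[j])
    }
    if (anyNA(v))
      stop("missing value in feature table at row ", which(is.na(v))[1],
           ", column ", colnames(feat)[j])
  }
  m <- as.matrix(feat)
  rownames(m) <- as.character(df[[1]])
  list(ids = as.character(df[[1]]), features = m)
}

#' Read protein-term annotation pairs
#'
#' @param path TSV with header columns `protein_id` and `term_id`.
#' @return `data.frame` of pairs.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("protein_id", "term_id") %in% colnames(df)))
    stop("annotation TSV needs protein_id and term_id columns")
  df[, c("protein_id", "term_id")]
}

#' Build a binary annotation matrix from pairs
#'
#' @param pairs `data.frame` with `protein_id` and `term_id`.
#' @param protein_ids row universe (order preserved).
#' @param terms column universe (order preserved).
#' @return Binary matrix proteins x terms.
#' @export
annotation_matrix <- function(pairs, protein_ids, terms) {
  M <- matrix(0, length(protein_ids), length(terms),
              dimnames = list(protein_ids, terms))
  keep <- pairs$protein_id %in% protein_ids & pairs$term_id %in% terms
  p <- pairs[keep, , drop = FALSE]
  M[cbind(match(p$protein_id, protein_ids), match(p$term_id, terms))] <- 1
  M
}

#' Write annotation pairs as TSV
#'
#' @param M binary annotation matrix (proteins x terms, dimnames set).
#' @param path output TSV.
#' @export
write_annotations <- function(M, path) {
  idx <- which(M == 1, arr.ind = TRUE)
  df <- data.frame(protein_id = rownames(M)[idx[, 1]],
                   term_id = colnames(M)[idx[, 2]])
  df <- df[order(df$protein_id, df$term_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param records `data.frame` with `id` and `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
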