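IUPAC_DNA <- "ACGTURYSWKMBDHVN"
IUPAC_PROTEIN <- "ACDEFGHIKLMNPQRSTVWYBJZXUO"
AMBIG_DNA <- "URYSWKMBDHVNX"    # ambiguity codes always score as mismatch
AMBIG_PROTEIN <- "BJZX"

alphabet_chars <- function(alphabet) {
  switch(alphabet, dna = IUPAC_DNA, protein = IUPAC_PROTEIN,
         stop("unknown alphabet: ", alphabet))
}

ambiguous_chars <- function(alphabet) {
  switch(alphabet, dna = AMBIG_DNA, protein = AMBIG_PROTEIN, "")
}

validate_residues <- function(residues, alphabet, ids) {
  ok <- alphabet_chars(alphabet)
  bad <- regexpr(sprintf("[^%s]", ok), residues)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf(
      "record '%s': non-IUPAC %s character '%s' at position %d",
      ids[i], alphabet, substr(residues[i], bad[i], bad[i]), bad[i]))
  }
  invisible(TRUE)
}

#' Construct a set of named sequences
#'
#' A `seq_set` is the package's container for FASTA-style records: a
#' data frame with columns `id`, `description` and `residues` plus an
#' `alphabet` attribute (`"dna"` or `"protein"`). Residues are uppercased
#' and validated against the IUPAC alphabet of the declared type
#' (ambiguity codes permitted).
#'
#' @param id character vector of unique, non-empty record ids.
#' @param residues character vector of non-empty sequences.
#' @param description optional free-text descriptions (default `""`).
#' @param alphabet `"dna"` or `"protein"`.
#' @return A data frame of class `seq_set`.
#' @export
seq_set <- function(id, residues, description = "",
                    alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: '", dup[1L], "'")
  if (any(!nzchar(residues)))
    stop("record '", id[which(!nzchar(residues))[1L]], "': empty sequence")
  validate_residues(residues, alphabet, id)
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    residues = residues,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d %s sequence(s)\n", nrow(x), attr(x, "alphabet")))
  n <- min(nrow(x), 6L)
  for (i in seq_len(n)) {
    r <- x$residues[i]
    cat(sprintf("  %s (%d) %s%s\n", x$id[i], nchar(r),
                substr(r, 1, 40), if (nchar(r) > 40) "..." else ""))
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

# Coerce a single sequence (seq_set row, record list, or bare character)
# to list(id, description, residues, alphabet).
as_seq_record <- function(x, alphabet = NULL) {
  if (inherits(x, "seq_set")) {
    if (nrow(x) != 1L) stop("expected a single sequence, got ", nrow(x))
    return(list(id = x$id, description = x$description,
                residues = x$residues, alphabet = attr(x, "alphabet")))
  }
  if (is.list(x) && !is.null(x$residues)) {
    return(list(id = x$id %||% "seq", description = x$description %||% "",
                residues = toupper(x$residues),
                alphabet = x$alphabet %||% alphabet %||%
                  guess_alphabet(x$residues)))
  }
  if (is.character(x) && length(x) == 1L) {
    res <- toupper(x)
    return(list(id = names(x) %||% "seq", description = "", residues = res,
                alphabet = alphabet %||% guess_alphabet(res)))
  }
  stop("cannot interpret object of class '", class(x)[1L], "' as a sequence")
}

guess_alphabet <- function(residues) {
  if (grepl("^[ACGTUN]*$", toupper(residues))) "dna" else "protein"
}

#' Read a FASTA file
#'
#' Headers start with `>`; the first whitespace-delimited token is the id,
#' the remainder the description. Wrapped sequence lines are merged and
#' residues uppercased (soft-masking discarded). Record order is preserved.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @param alphabet declared alphabet of the records, `"dna"` or `"protein"`.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq_set(id = id, residues = as.character(set),
          description = description, alphabet = alphabet)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 60 columns; descriptions, when present, follow
#' the id on the header line.
#'
#' @param x a [seq_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- ifelse(nzchar(x$description),
                       paste(x$id, x$description), x$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Total length of a genome given as FASTA records
#'
#' Sums residue counts over all records (replicons/contigs), so the result
#' is invariant to record order.
#'
#' @param records a [seq_set] (or list of records with `residues`).
#' @return Total length in residues (bp for DNA).
#' @export
genome_length <- function(records) {
  if (inherits(records, "seq_set")) {
    if (nrow(records) == 0L) stop("no records")
    return(sum(nchar(records$residues)))
  }
  if (is.list(records) && length(records)) {
    res <- vapply(records, function(r) as_seq_record(r)$residues, "")
    return(sum(nchar(res)))
  }
  stop("no records")
}
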