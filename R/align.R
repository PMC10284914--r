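#' Affine-gap scoring scheme
#'
#' The default values are the nucleotide scheme used throughout the
#' package: match 5, mismatch -4, gap open 16, gap extension 4. A gap run
#' of length L costs `gap_open + (L - 1) * gap_extend`, i.e. the opening
#' column carries the whole opening penalty. The same scheme is reused for
#' protein identity screening, where the statistic of interest
#' (matches / (matches + mismatches)) does not depend on a substitution
#' matrix.
#'
#' @param match score for an identical, unambiguous residue pair.
#' @param mismatch score for any other residue pair (negative).
#' @param gap_open positive penalty for the first column of a gap run.
#' @param gap_extend positive penalty for each further gap column.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4,
                           gap_open = 16, gap_extend = 4) {
  if (!(match > mismatch)) stop("match score must exceed mismatch score")
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop("require gap_open >= gap_extend > 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: match %g, mismatch %g, gap open %g, gap extend %g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch (Gotoh) alignment of two sequences of the same
#' alphabet. In `"global"` mode both sequences are aligned end to end. In
#' `"semiglobal"` mode the terminal overhangs of the longer sequence are
#' free, which recruits a short read inside a longer reference fragment.
#' Ambiguity codes (N and friends) always score as mismatch. Traceback
#' ties are broken diagonal > vertical > horizontal, so results are
#' deterministic.
#'
#' @param a,b sequences: [seq_set] rows, record lists or bare strings.
#' @param scheme a [scoring_scheme].
#' @param mode `"global"` or `"semiglobal"`.
#' @return An object of class `pairwise_alignment` with elements
#'   `gapped_a`, `gapped_b`, `score`, `n_match`, `n_mismatch`,
#'   `n_gap_cols`, plus the input ids and mode.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(),
                         mode = c("global", "semiglobal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "scoring_scheme"))
  ra <- as_seq_record(a)
  rb <- as_seq_record(b, alphabet = ra$alphabet)
  if (!nzchar(ra$residues) || !nzchar(rb$residues))
    stop("cannot align an empty sequence")
  if (!identical(ra$alphabet, rb$alphabet))
    stop("alphabet mismatch: ", ra$alphabet, " vs ", rb$alphabet)
  amb <- ambiguous_chars(ra$alphabet)
  free_a <- free_b <- FALSE
  if (mode == "semiglobal") {
    if (nchar(rb$residues) >= nchar(ra$residues)) free_b <- TRUE else free_a <- TRUE
  }
  core <- .gotoh_core(ra$residues, rb$residues,
                      scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend,
                      amb, free_a, free_b)
  build_alignment(core$gapped_a, core$gapped_b, core$score,
                  id_a = ra$id, id_b = rb$id,
                  alphabet = ra$alphabet, mode = mode)
}

build_alignment <- function(gapped_a, gapped_b, score, id_a = "a", id_b = "b",
                            alphabet = "dna", mode = "global") {
  ba <- charToRaw(gapped_a); bb <- charToRaw(gapped_b)
  if (length(ba) != length(bb)) stop("gapped strings differ in length")
  gap <- as.raw(45L)
  is_gap <- ba == gap | bb == gap
  if (any(ba == gap & bb == gap)) stop("all-gap alignment column")
  amb <- charToRaw(ambiguous_chars(alphabet))
  eq <- !is_gap & ba == bb & !(ba %in% amb)
  n_match <- sum(eq)
  n_mismatch <- sum(!is_gap & !eq)
  structure(list(gapped_a = gapped_a, gapped_b = gapped_b,
                 score = score,
                 n_match = n_match, n_mismatch = n_mismatch,
                 n_gap_cols = sum(is_gap),
                 id_a = id_a, id_b = id_b,
                 alphabet = alphabet, mode = mode),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("pairwise_alignment (%s, %s): score %g, %d match / %d mismatch / %d gap cols\n",
              x$mode, x$alphabet, x$score, x$n_match, x$n_mismatch, x$n_gap_cols))
  len <- nchar(x$gapped_a)
  for (s in seq(1L, len, by = width)) {
    e <- min(s + width - 1L, len)
    cat(" ", substr(x$gapped_a, s, e), "\n ", substr(x$gapped_b, s, e), "\n")
  }
  invisible(x)
}

#' Gap-excluded percent identity
#'
#' The identity of an alignment is the number of matches divided by the
#' sum of matches and mismatches; gap columns enter neither numerator nor
#' denominator.
#'
#' @param aln a [pairwise_alignment].
#' @return Identity as a fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  denom <- aln$n_match + aln$n_mismatch
  if (denom == 0L)
    stop("identity undefined: alignment has no aligned residue pairs")
  aln$n_match / denom
}

#' Map an anchor interval onto the aligned target
#'
#' Given an alignment whose first row is the anchor, returns the smallest
#' target interval whose alignment columns span anchor positions
#' `[start, end]` (1-based, inclusive, in ungapped anchor coordinates).
#' Returns `NULL` when the spanned columns contain no target residue
#' (region deleted in the target).
#'
#' @param anchor_aln a [pairwise_alignment]; the anchor is row `a`.
#' @param start,end anchor coordinates, `1 <= start <= end <= length(anchor)`.
#' @return Integer vector `c(start, end)` in target coordinates, or `NULL`.
#' @export
map_region <- function(anchor_aln, start, end) {
  stopifnot(inherits(anchor_aln, "pairwise_alignment"))
  ba <- charToRaw(anchor_aln$gapped_a)
  bb <- charToRaw(anchor_aln$gapped_b)
  gap <- as.raw(45L)
  apos <- cumsum(ba != gap)
  bpos <- cumsum(bb != gap)
  alen <- apos[length(apos)]
  if (start < 1L || end < start || end > alen)
    stop(sprintf("region (%s, %s) outside anchor of length %d",
                 start, end, alen))
  cols <- which(ba != gap & apos >= start & apos <= end)
  span <- seq.int(min(cols), max(cols))
  tcols <- span[bb[span] != gap]
  if (!length(tcols)) return(NULL)
  c(bpos[min(tcols)], bpos[max(tcols)])
}
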