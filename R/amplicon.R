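#' Trim a full-length 16S gene to the amplified window
#'
#' Aligns the full-length reference against an anchor 16S sequence
#' (E. coli numbering convention) and extracts the region mapped from
#' anchor positions `[start, end]` (1-based inclusive; the default
#' 515--938 window spans 424 anchor positions).
#'
#' @param full16s full-length 16S rRNA gene of the organism of interest.
#' @param anchor16s anchor 16S sequence defining the coordinate system;
#'   ungapped length must reach `end`.
#' @param start,end anchor coordinates of the amplified window.
#' @param scheme [scoring_scheme] for the anchoring alignment.
#' @return An object of class `reference_fragment` with fields
#'   `source_id`, `residues` and `anchor_interval`.
#' @export
trim_reference <- function(full16s, anchor16s, start = 515L, end = 938L,
                           scheme = scoring_scheme()) {
  full <- as_seq_record(full16s, alphabet = "dna")
  anchor <- as_seq_record(anchor16s, alphabet = "dna")
  if (!identical(full$alphabet, "dna") || !identical(anchor$alphabet, "dna"))
    stop("16S sequences must be dna")
  if (nchar(anchor$residues) < end)
    stop("anchor (", nchar(anchor$residues),
         " nt) shorter than window end ", end)
  aln <- global_align(anchor, full, scheme = scheme, mode = "global")
  reg <- map_region(aln, start, end)
  if (is.null(reg) || reg[2L] < reg[1L])
    stop("window maps to a zero-length fragment in '", full$id, "'")
  structure(list(source_id = full$id,
                 residues = substr(full$residues, reg[1L], reg[2L]),
                 anchor_interval = c(start = as.integer(start),
                                     end = as.integer(end))),
            class = "reference_fragment")
}

#' @export
print.reference_fragment <- function(x, ...) {
  cat(sprintf("reference_fragment %s: %d nt (anchor %d-%d)\n", x$source_id,
              nchar(x$residues), x$anchor_interval[1L], x$anchor_interval[2L]))
  invisible(x)
}

# Normalise a fragment collection (list of reference_fragment, or a
# seq_set) to a named character vector of residues, sorted by id so that
# identity ties resolve lexicographically.
fragment_residues <- function(fragments) {
  if (inherits(fragments, "seq_set")) {
    res <- setNames(fragments$residues, fragments$id)
  } else if (is.character(fragments) && length(fragments) &&
             !is.null(names(fragments))) {
    res <- toupper(fragments)
  } else if (is.list(fragments) && length(fragments)) {
    res <- vapply(fragments, function(f) {
      if (inherits(f, "reference_fragment")) f$residues
      else as_seq_record(f, alphabet = "dna")$residues
    }, "")
    names(res) <- vapply(fragments, function(f) {
      if (inherits(f, "reference_fragment")) f$source_id
      else as_seq_record(f)$id
    }, "")
  } else stop("empty fragment list")
  if (!length(res)) stop("empty fragment list")
  if (anyDuplicated(names(res))) stop("duplicate fragment id")
  res[order(names(res))]
}

#' Recruit a read against reference fragments
#'
#' Computes the semiglobal (free terminal overhangs of the longer
#' sequence) alignment identity of the read against every fragment and
#' returns the id of the best fragment when that identity reaches
#' `min_identity`, else `NA`. Ties go to the lexicographically smallest
#' fragment id. Reads shorter than `min_read_length` are rejected with a
#' warning.
#'
#' @param read a DNA sequence (record or string).
#' @param fragments reference fragments (list of `reference_fragment` or a
#'   [seq_set]).
#' @param min_identity identity threshold (default 0.98).
#' @param scheme [scoring_scheme].
#' @param min_read_length minimum read length considered (default 50 nt).
#' @return Best reference id (`NA_character_` for no match), with the best
#'   identity attached as attribute `"identity"`.
#' @export
recruit_read <- function(read, fragments, min_identity = 0.98,
                         scheme = scoring_scheme(), min_read_length = 50L) {
  r <- as_seq_record(read, alphabet = "dna")
  frags <- fragment_residues(fragments)
  if (!nzchar(r$residues)) stop("empty read")
  if (nchar(r$residues) < min_read_length) {
    warning("read '", r$id, "' shorter than ", min_read_length,
            " nt; rejected")
    return(structure(NA_character_, identity = NA_real_))
  }
  best_id <- NA_character_
  best_ident <- -Inf
  for (fid in names(frags)) {
    aln <- global_align(r$residues, frags[[fid]], scheme = scheme,
                        mode = "semiglobal")
    ident <- percent_identity(aln)
    if (ident > best_ident) {       # first id wins ties (names sorted)
      best_ident <- ident
      best_id <- fid
    }
  }
  if (is.finite(best_ident) && best_ident >= min_identity)
    structure(best_id, identity = best_ident)
  else
    structure(NA_character_, identity = best_ident)
}

#' Relative-abundance profiles across an amplicon survey
#'
#' Recruits every read of every sample and reports, per (sample,
#' reference) pair, the matched-read count and the relative abundance
#' `n_matched / n_total`, where `n_total` counts all reads searched in the
#' sample (matched or not). Rows are joined to the sample metadata and
#' sorted by season (winter < spring < summer), depth, size fraction and
#' reference id.
#'
#' @param reads named list, `sample_id -> seq_set` of reads.
#' @param fragments reference fragments (see [recruit_read]).
#' @param metadata sample metadata data frame ([read_sample_metadata]).
#' @param min_identity identity threshold (default 0.98).
#' @param scheme [scoring_scheme].
#' @return A data frame with columns sample_id, station, depth_label,
#'   season, size_fraction, reference_id, n_matched, n_total,
#'   rel_abundance.
#' @export
profile_samples <- function(reads, fragments, metadata,
                            min_identity = 0.98, scheme = scoring_scheme()) {
  metadata <- validate_sample_metadata(metadata)
  frags <- fragment_residues(fragments)
  unknown <- setdiff(names(reads), metadata$sample_id)
  if (length(unknown)) stop("unknown sample_id: ", unknown[1L])
  rows <- list()
  for (sid in names(reads)) {
    rs <- reads[[sid]]
    n_total <- if (inherits(rs, "seq_set")) nrow(rs) else length(rs)
    hits <- character(0)
    if (n_total > 0L) {
      res <- if (inherits(rs, "seq_set")) rs$residues else
        vapply(rs, function(x) as_seq_record(x)$residues, "")
      hits <- vapply(res, function(rr)
        as.character(recruit_read(rr, fragments, min_identity = min_identity,
                                  scheme = scheme)), "", USE.NAMES = FALSE)
    }
    counts <- table(factor(hits[!is.na(hits)], levels = names(frags)))
    md <- metadata[metadata$sample_id == sid, , drop = FALSE]
    rows[[sid]] <- data.frame(
      sample_id = sid, station = md$station, depth_label = md$depth_label,
      season = md$season, size_fraction = md$size_fraction,
      reference_id = names(frags),
      n_matched = as.integer(counts),
      n_total = n_total,
      rel_abundance = if (n_total > 0L) as.integer(counts) / n_total else 0,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  season_f <- factor(out$season, levels = SEASONS)
  depth_f <- factor(out$depth_label,
                    levels = c(DEPTH_ORDER,
                               sort(setdiff(unique(out$depth_label),
                                            DEPTH_ORDER))))
  out <- out[order(season_f, depth_f, out$size_fraction, out$reference_id,
                   out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
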