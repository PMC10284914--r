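#' Construct a curated rhodopsin reference set
#'
#' Each reference carries a subfamily label (PR, XR, P4, P5, NQ, outgroup
#' labels, ...), the 1-based position of the retinal-binding lysine and
#' the 1-based interval of transmembrane helix 7. The residue at
#' `retinal_k_pos` must be K and must lie inside the helix-7 interval.
#'
#' @param id,subfamily,residues per-reference vectors.
#' @param retinal_k_pos 1-based position of the retinal-binding lysine.
#' @param helix7_start,helix7_end 1-based helix-7 interval.
#' @return A data frame of class `rhodopsin_refs`.
#' @export
rhodopsin_refs <- function(id, subfamily, residues, retinal_k_pos,
                           helix7_start, helix7_end) {
  residues <- toupper(as.character(residues))
  d <- data.frame(id = as.character(id), subfamily = as.character(subfamily),
                  residues = residues,
                  retinal_k_pos = as.integer(retinal_k_pos),
                  helix7_start = as.integer(helix7_start),
                  helix7_end = as.integer(helix7_end),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$id)) stop("duplicate reference id")
  validate_residues(d$residues, "protein", d$id)
  for (i in seq_len(nrow(d))) {
    if (substr(d$residues[i], d$retinal_k_pos[i], d$retinal_k_pos[i]) != "K")
      stop("reference '", d$id[i], "': residue at retinal_k_pos is not K")
    if (d$retinal_k_pos[i] < d$helix7_start[i] ||
        d$retinal_k_pos[i] > d$helix7_end[i])
      stop("reference '", d$id[i], "': retinal lysine outside helix 7")
  }
  class(d) <- c("rhodopsin_refs", "data.frame")
  d
}

#' Read a rhodopsin reference set from FASTA + annotation TSV
#'
#' @param fasta_path protein FASTA of reference sequences.
#' @param tsv_path TSV with columns id, subfamily, retinal_k_pos,
#'   helix7_start, helix7_end.
#' @return A [rhodopsin_refs] object.
#' @export
read_rhodopsin_refs <- function(fasta_path, tsv_path) {
  seqs <- read_fasta(fasta_path, alphabet = "protein")
  ann <- read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "subfamily", "retinal_k_pos", "helix7_start", "helix7_end")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("reference TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(seqs$id, ann$id)
  if (length(miss)) stop("no annotation for reference ", miss[1L])
  ann <- ann[match(seqs$id, ann$id), ]
  rhodopsin_refs(seqs$id, ann$subfamily, seqs$residues,
                 ann$retinal_k_pos, ann$helix7_start, ann$helix7_end)
}

#' Assign a query to a rhodopsin subfamily by best reference hit
#'
#' The best hit maximises the gap-excluded identity under global
#' alignment; ties are broken by longer alignment, then lexicographic
#' reference id.
#'
#' @param query a protein sequence (record or string).
#' @param refs a [rhodopsin_refs] object.
#' @param scheme [scoring_scheme].
#' @return List with `subfamily`, `best_identity`, `best_ref_id`.
#' @export
classify_subfamily <- function(query, refs, scheme = scoring_scheme()) {
  stopifnot(inherits(refs, "rhodopsin_refs"))
  if (nrow(refs) == 0L) stop("empty reference set")
  q <- as_seq_record(query, alphabet = "protein")
  ord <- order(refs$id)
  best <- NULL
  for (i in ord) {
    aln <- global_align(q$residues, refs$residues[i], scheme = scheme,
                        mode = "global")
    ident <- percent_identity(aln)
    alen <- nchar(aln$gapped_a)
    if (is.null(best) || ident > best$ident ||
        (ident == best$ident && alen > best$alen)) {
      best <- list(i = i, ident = ident, alen = alen)
    }
  }
  list(subfamily = refs$subfamily[best$i],
       best_identity = best$ident,
       best_ref_id = refs$id[best$i])
}

#' Check the retinal-binding lysine in helix 7
#'
#' Aligns the query globally to its best reference, maps the reference's
#' retinal-lysine position onto the query, and reports `"present"` when
#' the mapped residue is K and lies within the query region aligned to
#' the reference's helix-7 interval, `"absent"` when a different residue
#' is mapped, and `"unalignable"` when the position maps into a gap
#' (e.g. helix 7 deleted).
#'
#' @param query a protein sequence (record or string).
#' @param best_ref single-row [rhodopsin_refs] slice (the query's best
#'   hit).
#' @param scheme [scoring_scheme].
#' @return `"present"`, `"absent"` or `"unalignable"`.
#' @export
check_retinal_lysine <- function(query, best_ref, scheme = scoring_scheme()) {
  if (is.data.frame(best_ref)) {
    stopifnot(nrow(best_ref) == 1L)
    ref <- as.list(best_ref)
  } else ref <- best_ref
  q <- as_seq_record(query, alphabet = "protein")
  aln <- global_align(ref$residues, q$residues, scheme = scheme,
                      mode = "global")
  kq <- map_region(aln, ref$retinal_k_pos, ref$retinal_k_pos)
  if (is.null(kq)) return("unalignable")
  qres <- substr(q$residues, kq[1L], kq[1L])
  h7 <- map_region(aln, ref$helix7_start, ref$helix7_end)
  in_h7 <- !is.null(h7) && kq[1L] >= h7[1L] && kq[1L] <= h7[2L]
  if (qres == "K" && in_h7) "present" else "absent"
}

#' Greedy identity clustering at one level
#'
#' Sequences are processed longest-first (ties by id); each sequence
#' joins the existing representative with the highest identity when that
#' identity reaches `level` (ties by lexicographic representative id),
#' else founds a new cluster. Deterministic.
#'
#' @param seqs a protein [seq_set].
#' @param level identity level in `(0, 1]`.
#' @param scheme [scoring_scheme].
#' @return Data frame with columns level, representative_id, member_id.
#' @export
greedy_cluster <- function(seqs, level, scheme = scoring_scheme()) {
  stopifnot(inherits(seqs, "seq_set"), level > 0, level <= 1)
  if (nrow(seqs) == 0L) stop("no sequences to cluster")
  ord <- order(-nchar(seqs$residues), seqs$id)
  reps <- character(0)
  assign <- character(nrow(seqs))
  names(assign) <- seqs$id
  res <- setNames(seqs$residues, seqs$id)
  for (i in ord) {
    sid <- seqs$id[i]
    best_rep <- NA_character_; best_ident <- -Inf
    for (rid in sort(reps)) {
      aln <- global_align(res[[sid]], res[[rid]], scheme = scheme,
                          mode = "global")
      ident <- tryCatch(percent_identity(aln), error = function(e) 0)
      if (ident > best_ident) { best_ident <- ident; best_rep <- rid }
    }
    if (is.finite(best_ident) && best_ident >= level) {
      assign[sid] <- best_rep
    } else {
      reps <- c(reps, sid)
      assign[sid] <- sid
    }
  }
  out <- data.frame(level = level,
                    representative_id = unname(assign[seqs$id]),
                    member_id = seqs$id, stringsAsFactors = FALSE)
  out[order(out$representative_id, out$member_id), , drop = FALSE]
}

#' Sequential greedy clustering at decreasing identity levels
#'
#' Clusters the input at the first level, then clusters the surviving
#' representatives at each subsequent (strictly lower) level; the
#' recorded lineage maps every original sequence to its cluster at every
#' level.
#'
#' @param seqs a protein [seq_set].
#' @param levels strictly decreasing identity levels (default
#'   `c(0.9, 0.8, 0.7, 0.6)`).
#' @param scheme [scoring_scheme].
#' @return List with `levels`, `clusters` (one membership data frame per
#'   level) and `lineage` (member_id plus one representative column per
#'   level).
#' @export
sequential_cluster <- function(seqs, levels = c(0.9, 0.8, 0.7, 0.6),
                               scheme = scoring_scheme()) {
  stopifnot(inherits(seqs, "seq_set"))
  lineage <- data.frame(member_id = seqs$id, stringsAsFactors = FALSE)
  if (length(levels) == 0L) {
    return(list(levels = numeric(0), clusters = list(), lineage = lineage))
  }
  if (any(diff(levels) >= 0)) stop("levels must be strictly decreasing")
  clusters <- vector("list", length(levels))
  names(clusters) <- sprintf("level_%d", round(levels * 100))
  current <- seqs
  carried <- setNames(seqs$id, seqs$id)  # original -> current representative
  for (k in seq_along(levels)) {
    cl <- greedy_cluster(current, levels[k], scheme = scheme)
    clusters[[k]] <- cl
    rep_of <- setNames(cl$representative_id, cl$member_id)
    carried <- setNames(unname(rep_of[unname(carried)]), names(carried))
    lineage[[names(clusters)[k]]] <- unname(carried[lineage$member_id])
    keep <- unique(cl$representative_id)
    current <- seqs[seqs$id %in% keep, , drop = FALSE]
    class(current) <- c("seq_set", "data.frame")
    attr(current, "alphabet") <- attr(seqs, "alphabet")
  }
  list(levels = levels, clusters = clusters, lineage = lineage)
}

#' Flag likely and potential contamination in a rhodopsin cohort
#'
#' Cohort-level rules: a subfamily represented in fewer than three
#' distinct assemblies has all its calls flagged `"likely"`; otherwise a
#' retained call whose 60%-identity cluster contains exactly one distinct
#' assembly is flagged `"potential"`; all other retained calls are
#' `"none"`. Non-retained calls keep `NA`.
#'
#' @param calls data frame of rhodopsin calls (query_id, assembly_id,
#'   subfamily, retained, ...).
#' @param clusters60 membership data frame at the 60% level
#'   (representative_id, member_id) covering every retained query.
#' @return `calls` with a `contamination` column.
#' @export
flag_contamination <- function(calls, clusters60) {
  ret <- calls[calls$retained, , drop = FALSE]
  miss <- setdiff(ret$query_id, clusters60$member_id)
  if (length(miss)) stop("query missing from clustering: ", miss[1L])
  n_asm <- tapply(ret$assembly_id, ret$subfamily,
                  function(a) length(unique(a)))
  cl_of <- setNames(clusters60$representative_id, clusters60$member_id)
  asm_of <- setNames(ret$assembly_id, ret$query_id)
  cl_asm <- tapply(asm_of[clusters60$member_id],
                   clusters60$representative_id,
                   function(a) length(unique(a[!is.na(a)])))
  contamination <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!calls$retained[i]) next
    fam <- calls$subfamily[i]
    if (!is.na(fam) && n_asm[[fam]] < 3L) {
      contamination[i] <- "likely"
    } else {
      cl <- cl_of[[calls$query_id[i]]]
      contamination[i] <- if (cl_asm[[cl]] == 1L) "potential" else "none"
    }
  }
  calls$contamination <- contamination
  calls
}

#' Full rhodopsin screen: classify, filter, cluster, flag
#'
#' Runs best-hit subfamily classification, the retinal-lysine filter,
#' 100%-identity deduplication followed by sequential clustering at the
#' given levels, and cohort-level contamination flagging. Queries whose
#' best reference identity falls below `min_hit_identity` are rejected as
#' having no confident hit. Query ids must encode the source assembly as
#' `"assembly|protein"`.
#'
#' @param queries protein [seq_set] of candidate rhodopsins.
#' @param refs a [rhodopsin_refs] object.
#' @param min_hit_identity confident-hit threshold (default 0.25).
#' @param levels sequential clustering levels (default
#'   `c(0.9, 0.8, 0.7, 0.6)`).
#' @param scheme [scoring_scheme].
#' @return List with `calls` (one row per query), `clusters` (per-level
#'   membership including the 100% level), `lineage`, and `clusters60`
#'   (original queries mapped to their cluster at the lowest level).
#' @export
screen_rhodopsins <- function(queries, refs, min_hit_identity = 0.25,
                              levels = c(0.9, 0.8, 0.7, 0.6),
                              scheme = scoring_scheme()) {
  stopifnot(inherits(queries, "seq_set"))
  asm <- sub("\\|.*$", "", queries$id)
  asm[!grepl("\\|", queries$id)] <- NA_character_
  calls <- data.frame(query_id = queries$id, assembly_id = asm,
                      subfamily = NA_character_, best_identity = NA_real_,
                      retinal_k = NA_character_, retained = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(queries))) {
    hit <- classify_subfamily(queries$residues[i], refs, scheme = scheme)
    calls$subfamily[i] <- hit$subfamily
    calls$best_identity[i] <- hit$best_identity
    if (hit$best_identity >= min_hit_identity) {
      ref <- refs[refs$id == hit$best_ref_id, , drop = FALSE]
      calls$retinal_k[i] <- check_retinal_lysine(queries$residues[i], ref,
                                                 scheme = scheme)
      calls$retained[i] <- calls$retinal_k[i] == "present"
    }
  }
  kept <- queries[calls$retained[match(queries$id, calls$query_id)], ,
                  drop = FALSE]
  class(kept) <- c("seq_set", "data.frame")
  attr(kept, "alphabet") <- attr(queries, "alphabet")
  clusters <- list(); lineage <- NULL; clusters60 <- NULL
  if (nrow(kept)) {
    dedup <- greedy_cluster(kept, 1.0, scheme = scheme)
    rep100 <- setNames(dedup$representative_id, dedup$member_id)
    uniq <- kept[kept$id %in% unique(dedup$representative_id), , drop = FALSE]
    class(uniq) <- c("seq_set", "data.frame")
    attr(uniq, "alphabet") <- attr(kept, "alphabet")
    sq <- sequential_cluster(uniq, levels = levels, scheme = scheme)
    clusters <- c(list(level_100 = dedup), sq$clusters)
    # compose: original -> 100% rep -> lowest-level rep
    low_col <- if (length(levels)) sprintf("level_%d",
                                           round(levels[length(levels)] * 100))
               else NULL
    low_of <- if (!is.null(low_col))
      setNames(sq$lineage[[low_col]], sq$lineage$member_id)
    else setNames(sq$lineage$member_id, sq$lineage$member_id)
    lineage <- data.frame(member_id = kept$id,
                          rep_100 = unname(rep100[kept$id]),
                          stringsAsFactors = FALSE)
    for (cn in setdiff(names(sq$lineage), "member_id"))
      lineage[[cn]] <- unname(setNames(sq$lineage[[cn]],
                                       sq$lineage$member_id)[lineage$rep_100])
    clusters60 <- data.frame(
      representative_id = unname(low_of[unname(rep100[kept$id])]),
      member_id = kept$id, stringsAsFactors = FALSE)
  }
  calls <- flag_contamination(calls,
                              clusters60 %||%
                                data.frame(representative_id = character(0),
                                           member_id = character(0)))
  list(calls = calls, clusters = clusters, lineage = lineage,
       clusters60 = clusters60)
}
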