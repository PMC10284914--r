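#' Default single-copy marker orthogroups
#'
#' The 20 COG orthogroups used by default for marker-based taxon
#' abundance, shipped with the package.
#'
#' @return Character vector of COG ids.
#' @export
default_marker_cogs <- function() {
  path <- system.file("extdata", "marker_cogs.txt", package = "photohet")
  readLines(path, warn = FALSE)
}

#' Recruit catalog records to a target pangenome
#'
#' A catalog protein is recruited when its best-identity hit (global
#' alignment, gap-excluded identity) over all supplied proteins (targets
#' plus optional competitors) is a target protein and that identity is at
#' least `min_identity`.
#'
#' @param catalog_proteins [seq_set] of catalog protein records.
#' @param target_proteins [seq_set] of the target taxon's proteins.
#' @param og_map gene-to-orthogroup map: a named character vector
#'   (`gene_id -> orthogroup_id`) or data frame with columns `gene_id`,
#'   `orthogroup_id`; must cover all catalog ids.
#' @param min_identity recruitment threshold (default 0.95).
#' @param competitors optional [seq_set] of non-target reference proteins
#'   competing for best hit.
#' @param scheme [scoring_scheme].
#' @return Data frame with columns gene_id, orthogroup_id, best_hit,
#'   best_identity, best_hit_target, recruited.
#' @export
recruit_records <- function(catalog_proteins, target_proteins, og_map,
                            min_identity = 0.95, competitors = NULL,
                            scheme = scoring_scheme()) {
  stopifnot(inherits(catalog_proteins, "seq_set"),
            inherits(target_proteins, "seq_set"))
  if (nrow(target_proteins) == 0L) stop("empty target protein set")
  if (is.data.frame(og_map))
    og_map <- setNames(og_map$orthogroup_id, og_map$gene_id)
  miss <- setdiff(catalog_proteins$id, names(og_map))
  if (length(miss)) stop("og_map does not cover gene: ", miss[1L])
  refs <- setNames(target_proteins$residues, target_proteins$id)
  is_target <- rep(TRUE, length(refs))
  if (!is.null(competitors) && nrow(competitors) > 0L) {
    refs <- c(refs, setNames(competitors$residues, competitors$id))
    is_target <- c(is_target, rep(FALSE, nrow(competitors)))
  }
  ord <- order(names(refs))
  refs <- refs[ord]; is_target <- is_target[ord]
  out <- lapply(seq_len(nrow(catalog_proteins)), function(i) {
    q <- catalog_proteins$residues[i]
    best_ident <- -Inf; best_k <- NA_integer_
    for (k in seq_along(refs)) {
      aln <- global_align(q, refs[[k]], scheme = scheme, mode = "global")
      ident <- percent_identity(aln)
      if (ident > best_ident) { best_ident <- ident; best_k <- k }
    }
    data.frame(gene_id = catalog_proteins$id[i],
               orthogroup_id = unname(og_map[catalog_proteins$id[i]]),
               best_hit = names(refs)[best_k],
               best_identity = best_ident,
               best_hit_target = is_target[best_k],
               recruited = is_target[best_k] && best_ident >= min_identity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sum recruited per-gene coverage into an orthogroup x sample matrix.
# Orthogroups with no contributing gene get an all-zero row.
og_coverage <- function(cov, ogs, gene_ids = NULL) {
  stopifnot(inherits(cov, "coverage_matrix"))
  keep <- if (is.null(gene_ids)) rep(TRUE, length(cov$gene_ids)) else
    cov$gene_ids %in% gene_ids
  m <- matrix(0, nrow = length(ogs), ncol = length(cov$sample_ids),
              dimnames = list(ogs, cov$sample_ids))
  for (g in which(keep & cov$orthogroup_ids %in% ogs)) {
    og <- cov$orthogroup_ids[g]
    m[og, ] <- m[og, ] + cov$values[g, ]
  }
  m
}

#' Select reliable marker orthogroups
#'
#' Concrete mutual-correlation / outlier-detection rule: per-orthogroup
#' coverage is the sum over its (recruited) genes; orthogroups whose total
#' coverage is a high outlier (> median + `mad_k` * MAD of per-orthogroup
#' totals; multi-copy or contaminated markers) are dropped, then the
#' orthogroup with the lowest median Spearman correlation of
#' `log(coverage + pseudocount)` to the others is iteratively dropped
#' while that median falls below the overall median minus `mad_k` * MAD
#' of the median-correlation vector. Deterministic given its input.
#'
#' @param cov [coverage_matrix] restricted to recruited marker genes.
#' @param candidates candidate orthogroup ids (character vector or a list
#'   with element `candidate_ogs`).
#' @param pseudocount added before the log (default 1e-6).
#' @param mad_k MAD multiplier (default 3).
#' @return A `marker_set`: list with `candidate_ogs`, `selected_ogs` and a
#'   data frame `dropped` (orthogroup, reason).
#' @export
select_markers <- function(cov, candidates, pseudocount = 1e-6, mad_k = 3) {
  if (is.list(candidates) && !is.null(candidates$candidate_ogs))
    candidates <- candidates$candidate_ogs
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < 3L) stop("need at least 3 candidate orthogroups")
  if (length(cov$sample_ids) < 5L) stop("need at least 5 samples")
  m <- og_coverage(cov, candidates)
  dropped <- data.frame(orthogroup_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  # high-coverage outliers (multi-copy / contaminant markers)
  tot <- rowSums(m)
  hi <- tot > median(tot) + mad_k * mad(tot)
  if (any(hi)) {
    dropped <- rbind(dropped, data.frame(orthogroup_id = names(tot)[hi],
                                         reason = "coverage_outlier"))
    m <- m[!hi, , drop = FALSE]
  }
  # iterative mutual-correlation pruning
  repeat {
    if (nrow(m) < 3L) stop("marker selection collapsed")
    lc <- log(m + pseudocount)
    cc <- suppressWarnings(cor(t(lc), method = "spearman"))
    cc[is.na(cc)] <- 0          # constant (e.g. all-zero) markers
    diag(cc) <- NA
    med <- apply(cc, 1L, median, na.rm = TRUE)
    cutoff <- median(med) - mad_k * mad(med)
    worst <- which.min(med)     # ties: first in sorted orthogroup order
    if (med[worst] < cutoff) {
      if (nrow(m) - 1L < 3L) stop("marker selection collapsed")
      dropped <- rbind(dropped,
                       data.frame(orthogroup_id = rownames(m)[worst],
                                  reason = "low_mutual_correlation"))
      m <- m[-worst, , drop = FALSE]
    } else break
  }
  structure(list(candidate_ogs = candidates,
                 selected_ogs = rownames(m),
                 dropped = dropped),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d / %d orthogroups selected\n",
              length(x$selected_ogs), length(x$candidate_ogs)))
  if (nrow(x$dropped))
    cat("  dropped:", paste(x$dropped$orthogroup_id, collapse = ", "), "\n")
  invisible(x)
}

as_marker_set <- function(markers) {
  if (inherits(markers, "marker_set")) return(markers)
  markers <- sort(unique(as.character(markers)))
  structure(list(candidate_ogs = markers, selected_ogs = markers,
                 dropped = data.frame(orthogroup_id = character(0),
                                      reason = character(0))),
            class = "marker_set")
}

#' Marker-based taxon abundance per sample
#'
#' Taxon abundance is the arithmetic mean, over the selected marker
#' orthogroups, of recruited per-orthogroup coverage; zeros are included,
#' so a sample lacking the taxon scores ~0 rather than NaN. The detection
#' fraction is the share of selected orthogroups with coverage above zero.
#'
#' @param cov [coverage_matrix] restricted to recruited marker genes.
#' @param markers a `marker_set` (see [select_markers]) or character
#'   vector of selected orthogroups.
#' @return Data frame with columns sample_id, taxon_abundance,
#'   detection_fraction.
#' @export
taxon_abundance <- function(cov, markers) {
  markers <- as_marker_set(markers)
  if (!length(markers$selected_ogs)) stop("no selected marker orthogroups")
  m <- og_coverage(cov, markers$selected_ogs)
  data.frame(sample_id = cov$sample_ids,
             taxon_abundance = colMeans(m),
             detection_fraction = colMeans(m > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Taxon fraction of the whole microbial community
#'
#' Divides the taxon marker abundance by the mean, over the selected
#' orthogroups, of total community marker coverage in the same sample.
#' Fractions above 1 are reported as-is but flagged (`exceeds_one`) with a
#' warning; a zero denominator yields an undefined (NA) fraction.
#'
#' @param taxon_ab output of [taxon_abundance].
#' @param total_marker_cov matrix of total community coverage, selected
#'   orthogroups x samples.
#' @return `taxon_ab` with columns community_fraction and exceeds_one
#'   appended.
#' @export
community_fraction <- function(taxon_ab, total_marker_cov) {
  total_marker_cov <- as.matrix(total_marker_cov)
  if (!all(taxon_ab$sample_id %in% colnames(total_marker_cov)))
    stop("total marker coverage missing sample(s)")
  denom <- colMeans(total_marker_cov[, taxon_ab$sample_id, drop = FALSE])
  frac <- ifelse(denom > 0, taxon_ab$taxon_abundance / denom, NA_real_)
  if (any(frac > 1, na.rm = TRUE))
    warning("community fraction exceeds 1 in ",
            sum(frac > 1, na.rm = TRUE), " sample(s)")
  taxon_ab$community_fraction <- frac
  taxon_ab$exceeds_one <- !is.na(frac) & frac > 1
  taxon_ab
}

#' Accessory-gene copies per target genome
#'
#' Copy number is the accessory gene's coverage divided by the
#' marker-based taxon abundance, defined only in samples where at least
#' `min_detect` of the selected markers have coverage above zero.
#'
#' @param gene_cov named numeric vector of the gene's per-sample coverage
#'   (names = sample ids), or a single-row slice of a coverage matrix.
#' @param taxon_ab output of [taxon_abundance].
#' @param gene_id label for the output rows.
#' @param min_detect detection-fraction gate (default 0.9).
#' @return Data frame with columns sample_id, gene_id, copies_per_genome,
#'   defined.
#' @export
gene_copy_number <- function(gene_cov, taxon_ab, gene_id = "gene",
                             min_detect = 0.9) {
  if (is.matrix(gene_cov)) gene_cov <- gene_cov[1L, ]
  if (is.null(names(gene_cov)))
    stop("gene_cov must be named by sample id")
  miss <- setdiff(taxon_ab$sample_id, names(gene_cov))
  if (length(miss)) stop("gene coverage missing for sample ", miss[1L])
  gv <- gene_cov[taxon_ab$sample_id]
  if (any(gv < 0)) stop("negative gene coverage")
  defined <- taxon_ab$detection_fraction >= min_detect
  if (any(defined & taxon_ab$taxon_abundance <= 0))
    stop("invariant violated: detected sample with zero taxon abundance")
  data.frame(sample_id = taxon_ab$sample_id,
             gene_id = gene_id,
             copies_per_genome = ifelse(defined,
                                        gv / taxon_ab$taxon_abundance,
                                        NA_real_),
             defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average copy number of a two-gene operon
#'
#' The operon estimate per sample is the arithmetic mean of the two
#' per-gene copy numbers, defined only where both are defined.
#'
#' @param cn_pr,cn_blh outputs of [gene_copy_number] for the two genes,
#'   over the same samples.
#' @param gene_id label for the combined estimate.
#' @return Data frame in the [gene_copy_number] layout.
#' @export
operon_copy_number <- function(cn_pr, cn_blh, gene_id = "pr-blh") {
  if (!identical(cn_pr$sample_id, cn_blh$sample_id))
    stop("sample mismatch between the two copy-number tables")
  defined <- cn_pr$defined & cn_blh$defined
  data.frame(sample_id = cn_pr$sample_id,
             gene_id = gene_id,
             copies_per_genome = ifelse(defined,
                                        (cn_pr$copies_per_genome +
                                           cn_blh$copies_per_genome) / 2,
                                        NA_real_),
             defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}
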