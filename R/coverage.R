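#' Construct a coverage matrix
#'
#' Per-base read coverage of catalog genes across samples, with one
#' orthogroup annotation per gene (may be blank for accessory genes).
#'
#' @param values numeric matrix, genes x samples, all entries `>= 0`.
#' @param gene_ids,sample_ids row/column identifiers.
#' @param orthogroup_ids orthogroup per gene (`""` when unannotated).
#' @return An object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(values, gene_ids, orthogroup_ids, sample_ids) {
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("coverage dimensions inconsistent with gene/sample ids")
  if (length(orthogroup_ids) != length(gene_ids))
    stop("one orthogroup id per gene required")
  if (anyNA(values)) stop("coverage values must not be NA")
  if (any(values < 0)) stop("negative coverage value")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 orthogroup_ids = as.character(orthogroup_ids),
                 sample_ids = as.character(sample_ids)),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d genes x %d samples (%d orthogroup-annotated)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(nzchar(x$orthogroup_ids))))
  invisible(x)
}

#' Read a gene-by-sample coverage table
#'
#' Tab-delimited, UTF-8; first two columns `gene_id` and `orthogroup_id`,
#' remaining columns one per sample. Empty cells and `"."` are read as 0.
#'
#' @param path path to the TSV file.
#' @return A [coverage_matrix].
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", blank.lines.skip = TRUE)
  if (length(unique(nf)) != 1L)
    stop("ragged coverage table: rows have ", paste(unique(nf), collapse = "/"),
         " fields")
  d <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                  colClasses = "character", na.strings = NULL)
  if (ncol(d) < 3L || !identical(names(d)[1:2], c("gene_id", "orthogroup_id")))
    stop("coverage table must start with columns gene_id, orthogroup_id")
  vals <- as.matrix(d[, -(1:2), drop = FALSE])
  vals[vals == "" | vals == "."] <- "0"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) stop("non-numeric coverage cell")
  if (any(num < 0)) stop("negative coverage value in ", path)
  coverage_matrix(num, gene_ids = d$gene_id,
                  orthogroup_ids = d$orthogroup_id,
                  sample_ids = colnames(d)[-(1:2)])
}

#' Write a coverage matrix as TSV
#'
#' Rows are written sorted by `gene_id` so output is deterministic.
#'
#' @param cov a [coverage_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_matrix"))
  ord <- order(cov$gene_ids)
  d <- data.frame(gene_id = cov$gene_ids[ord],
                  orthogroup_id = cov$orthogroup_ids[ord],
                  cov$values[ord, , drop = FALSE],
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_result_table(d, path, sort_by = NULL)
}

SEASONS <- c("winter", "spring", "summer")
SIZE_FRACTIONS <- c("FL", "PA")
DEPTH_ORDER <- c("10m", "half-DCM", "DCM")

#' Read sample metadata
#'
#' Tab-delimited with columns `sample_id`, `station`, `depth_label`,
#' `season`, `size_fraction`, `year`. Seasons come from the closed
#' vocabulary winter/spring/summer and size fractions from FL
#' (free-living, 0.22--5 um) / PA (particle-associated, >11 um).
#'
#' @param path path to the TSV file.
#' @return A data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "station", "depth_label", "season",
            "size_fraction", "year")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_sample_metadata(d)
}

validate_sample_metadata <- function(d) {
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in metadata: ",
         d$sample_id[duplicated(d$sample_id)][1L])
  bad <- setdiff(unique(d$season), SEASONS)
  if (length(bad)) stop("unknown season: ", bad[1L])
  bad <- setdiff(unique(d$size_fraction), SIZE_FRACTIONS)
  if (length(bad)) stop("unknown size_fraction: ", bad[1L])
  d
}

# Deterministic result-table writer: header row, tab-separated, rows sorted
# by the given key columns.
write_result_table <- function(d, path, sort_by = names(d)[1L]) {
  if (!is.null(sort_by) && length(sort_by))
    d <- d[do.call(order, unname(d[sort_by])), , drop = FALSE]
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
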