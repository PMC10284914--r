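# Pipeline configuration and the three end-to-end analyses. Defaults
# reproduce the thresholds used throughout: nucleotide scoring 5/-4/16/4,
# 98% read identity, 95% protein recruitment identity, 90% detection
# gate, sequential clustering at 90/80/70/60%.

#' Default pipeline configuration
#'
#' @param ... named overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scoring = list(match = 5, mismatch = -4, gap_open = 16, gap_extend = 4),
    window_start = 515L, window_end = 938L,
    read_min_identity = 0.98,
    recruit_min_identity = 0.95,
    min_detect = 0.9,
    marker_pseudocount = 1e-6,
    marker_mad_k = 3,
    min_hit_identity = 0.25,
    cluster_levels = c(0.9, 0.8, 0.7, 0.6),
    accessory_genes = c("pr", "blh"),
    seed = 1L,
    quiet = FALSE,
    paths = list()
  )
  cfg <- utils::modifyList(cfg, list(...))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (f in c("read_min_identity", "recruit_min_identity", "min_detect",
              "min_hit_identity"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop(f, " must lie in (0, 1]")
  if (any(cfg$cluster_levels <= 0 | cfg$cluster_levels > 1))
    stop("cluster levels must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of [pipeline_config];
#' all other defaults are kept.
#'
#' @param path YAML file.
#' @param ... further overrides applied after the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, utils::modifyList(y %||% list(), list(...)))
}

cfg_scheme <- function(cfg) {
  do.call(scoring_scheme, cfg$scoring)
}

plog <- function(cfg, ...) {
  if (!isTRUE(cfg$quiet)) message("[photohet] ", ...)
}

need_path <- function(cfg, key) {
  p <- cfg$paths[[key]]
  if (is.null(p)) stop("config is missing path '", key, "'")
  if (!file.exists(p)) stop("missing input for '", key, "': ", p)
  p
}

# Machine-readable run manifest: config hash plus per-input checksums.
# Deliberately timestamp-free so identical runs write identical manifests.
write_manifest <- function(cfg, inputs, outputs, path) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  cfgs <- cfg
  cfgs$paths <- NULL; cfgs$quiet <- NULL
  yaml::write_yaml(unclass(cfgs), tmp)
  manifest <- list(
    package_version = as.character(packageVersion("photohet")),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    inputs = lapply(inputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, basename))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the 16S amplicon survey analysis
#'
#' Trims the full-length references to the amplified window, recruits
#' every read at the configured identity threshold, and writes the
#' relative-abundance table. Required config paths: `references` (full
#' 16S FASTA), `anchor` (anchor 16S FASTA, one record), `reads_manifest`
#' (TSV: sample_id, fasta), `metadata` (sample metadata TSV), `out_dir`.
#'
#' @param config a `pipeline_config`.
#' @return Path of the abundance TSV, invisibly; the profile data frame
#'   as attribute `"profile"`.
#' @export
run_amplicon_survey <- function(config = pipeline_config()) {
  cfg <- validate_config(config)
  refs <- read_fasta(need_path(cfg, "references"), "dna")
  anchor <- read_fasta(need_path(cfg, "anchor"), "dna")
  manifest_tsv <- need_path(cfg, "reads_manifest")
  metadata <- read_sample_metadata(need_path(cfg, "metadata"))
  out_dir <- cfg$paths$out_dir %||% stop("config is missing path 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- cfg_scheme(cfg)

  plog(cfg, "trimming ", nrow(refs), " reference(s) to anchor window ",
       cfg$window_start, "-", cfg$window_end)
  anchor_rec <- list(id = anchor$id[1L], residues = anchor$residues[1L],
                     alphabet = "dna")
  fragments <- lapply(seq_len(nrow(refs)), function(i)
    trim_reference(list(id = refs$id[i], residues = refs$residues[i],
                        alphabet = "dna"),
                   anchor_rec,
                   start = cfg$window_start, end = cfg$window_end,
                   scheme = scheme))

  man <- read.delim(manifest_tsv, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "fasta") %in% names(man)))
    stop("reads manifest needs columns sample_id, fasta")
  if (nrow(man) == 0L) stop("reads manifest is empty")
  base <- dirname(manifest_tsv)
  reads <- list()
  for (i in seq_len(nrow(man))) {
    p <- man$fasta[i]
    if (!file.exists(p)) p <- file.path(base, man$fasta[i])
    if (!file.exists(p)) stop("missing reads FASTA: ", man$fasta[i])
    reads[[man$sample_id[i]]] <- read_fasta(p, "dna")
  }
  plog(cfg, "recruiting reads from ", length(reads), " sample(s) at >= ",
       cfg$read_min_identity * 100, "% identity")
  prof <- profile_samples(reads, fragments, metadata,
                          min_identity = cfg$read_min_identity,
                          scheme = scheme)
  plog(cfg, sum(prof$n_matched), " / ",
       sum(prof$n_total[!duplicated(prof$sample_id)]), " reads matched")
  out <- file.path(out_dir, "amplicon_abundance.tsv")
  write_result_table(prof, out, sort_by = NULL)  # already sorted
  write_manifest(cfg, cfg$paths[c("references", "anchor", "reads_manifest",
                                  "metadata")],
                 list(abundance = out),
                 file.path(out_dir, "amplicon_manifest.json"))
  invisible(structure(out, profile = prof))
}

#' Run the marker-gene prevalence and copy-number analysis
#'
#' Selects reliable markers from the candidate set, estimates taxon
#' abundance, community fraction, per-gene accessory copy numbers and the
#' operon average. Required config paths: `coverage` (coverage TSV),
#' `totals` (community totals TSV: orthogroup x samples), `out_dir`.
#' Optional: `catalog_proteins`, `target_proteins`, `og_map` to run
#' protein recruitment and restrict the coverage matrix first;
#' `marker_list` (one orthogroup id per line; defaults to the shipped 20
#' COGs).
#'
#' @param config a `pipeline_config`.
#' @return Path of the abundance TSV, invisibly; results attached as
#'   attributes `"abundance"` and `"copy_numbers"`.
#' @export
run_prevalence <- function(config = pipeline_config()) {
  cfg <- validate_config(config)
  cov <- read_coverage_table(need_path(cfg, "coverage"))
  totals_d <- read_coverage_table(need_path(cfg, "totals"))
  out_dir <- cfg$paths$out_dir %||% stop("config is missing path 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  candidates <- if (!is.null(cfg$paths$marker_list))
    readLines(need_path(cfg, "marker_list"), warn = FALSE)
  else default_marker_cogs()

  inputs <- cfg$paths[c("coverage", "totals")]
  if (!is.null(cfg$paths$catalog_proteins)) {
    catalog <- read_fasta(need_path(cfg, "catalog_proteins"), "protein")
    target <- read_fasta(need_path(cfg, "target_proteins"), "protein")
    ogm <- read.delim(need_path(cfg, "og_map"), sep = "\t",
                      stringsAsFactors = FALSE)
    plog(cfg, "recruiting ", nrow(catalog), " catalog protein(s) at >= ",
         cfg$recruit_min_identity * 100, "% identity")
    rec <- recruit_records(catalog, target, ogm,
                           min_identity = cfg$recruit_min_identity,
                           scheme = cfg_scheme(cfg))
    keep <- cov$gene_ids %in% c(rec$gene_id[rec$recruited],
                                cfg$accessory_genes)
    cov <- coverage_matrix(cov$values[keep, , drop = FALSE],
                           cov$gene_ids[keep], cov$orthogroup_ids[keep],
                           cov$sample_ids)
    inputs <- c(inputs, cfg$paths[c("catalog_proteins", "target_proteins",
                                    "og_map")])
    plog(cfg, sum(rec$recruited), " record(s) recruited")
  }

  markers <- select_markers(cov, candidates,
                            pseudocount = cfg$marker_pseudocount,
                            mad_k = cfg$marker_mad_k)
  plog(cfg, length(markers$selected_ogs), " / ",
       length(markers$candidate_ogs), " markers selected")
  ab <- taxon_abundance(cov, markers)
  tot <- totals_d$values[markers$selected_ogs, , drop = FALSE]
  ab <- community_fraction(ab, tot)

  cns <- list()
  for (g in intersect(cfg$accessory_genes, cov$gene_ids)) {
    gv <- cov$values[match(g, cov$gene_ids), ]
    cns[[g]] <- gene_copy_number(gv, ab, gene_id = g,
                                 min_detect = cfg$min_detect)
  }
  if (length(cns) == 2L)
    cns$operon <- operon_copy_number(cns[[1L]], cns[[2L]],
                                     gene_id = paste(names(cns)[1:2],
                                                     collapse = "-"))
  cn <- if (length(cns))
    do.call(rbind, c(unname(cns), list(make.row.names = FALSE))) else NULL
  if (!is.null(cn))
    plog(cfg, sum(cn$defined), " / ", nrow(cn),
         " copy-number estimates defined (gate ", cfg$min_detect, ")")

  out_ab <- file.path(out_dir, "prevalence_abundance.tsv")
  write_result_table(ab, out_ab, sort_by = "sample_id")
  out_cn <- file.path(out_dir, "copy_numbers.tsv")
  if (!is.null(cn)) write_result_table(cn, out_cn,
                                       sort_by = c("gene_id", "sample_id"))
  write_manifest(cfg, inputs,
                 list(abundance = out_ab,
                      copy_numbers = if (!is.null(cn)) out_cn else NULL),
                 file.path(out_dir, "prevalence_manifest.json"))
  invisible(structure(out_ab, abundance = ab, copy_numbers = cn,
                      markers = markers))
}

#' Run the rhodopsin classification and clustering screen
#'
#' Classifies candidate proteins by best reference hit, applies the
#' retinal-lysine filter, clusters retained sequences sequentially and
#' flags contamination. Required config paths: `queries` (protein FASTA
#' with `assembly|protein` ids), `ref_fasta`, `ref_tsv`, `out_dir`.
#'
#' @param config a `pipeline_config`.
#' @return Path of the calls TSV, invisibly; the full screen attached as
#'   attribute `"screen"`.
#' @export
run_rhodopsin_screen <- function(config = pipeline_config()) {
  cfg <- validate_config(config)
  queries <- read_fasta(need_path(cfg, "queries"), "protein")
  refs <- read_rhodopsin_refs(need_path(cfg, "ref_fasta"),
                              need_path(cfg, "ref_tsv"))
  out_dir <- cfg$paths$out_dir %||% stop("config is missing path 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plog(cfg, "screening ", nrow(queries), " query protein(s) against ",
       nrow(refs), " reference(s)")
  sc <- screen_rhodopsins(queries, refs,
                          min_hit_identity = cfg$min_hit_identity,
                          levels = cfg$cluster_levels,
                          scheme = cfg_scheme(cfg))
  plog(cfg, sum(sc$calls$retained), " / ", nrow(sc$calls),
       " queries retained after the retinal-lysine filter")
  out_calls <- file.path(out_dir, "rhodopsin_calls.tsv")
  write_result_table(sc$calls, out_calls, sort_by = "query_id")
  out_cl <- file.path(out_dir, "rhodopsin_clusters.tsv")
  cl <- do.call(rbind, c(lapply(names(sc$clusters), function(nm) {
    d <- sc$clusters[[nm]]
    if (!"level" %in% names(d))
      d$level <- as.numeric(sub("level_", "", nm)) / 100
    d[, c("level", "representative_id", "member_id")]
  }), list(make.row.names = FALSE)))
  if (is.null(cl))
    cl <- data.frame(level = numeric(0), representative_id = character(0),
                     member_id = character(0))
  write_result_table(cl, out_cl,
                     sort_by = c("level", "representative_id", "member_id"))
  write_manifest(cfg, cfg$paths[c("queries", "ref_fasta", "ref_tsv")],
                 list(calls = out_calls, clusters = out_cl),
                 file.path(out_dir, "rhodopsin_manifest.json"))
  invisible(structure(out_calls, screen = sc))
}
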