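# Seeded generators producing inputs with the statistical structure the
# analysis stages assume, plus ground-truth tables for recovery tests.
# One integer seed fans out to independent substreams, so adding draws to
# one block does not perturb the others.

substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a marker/accessory coverage matrix with known truth
#'
#' Emulates the structure of a gene-catalog coverage matrix: a latent
#' per-sample taxon abundance (lognormal, with a stated fraction of
#' samples where the taxon is absent), marker coverage proportional to it
#' under multiplicative lognormal noise, a few corrupted markers whose
#' coverage is independent of the taxon, accessory genes with coverage
#' `copies x abundance x noise`, and total community coverage
#' `abundance / community_share x noise` per marker orthogroup.
#'
#' @param n_samples number of samples (default 30).
#' @param n_markers number of candidate marker orthogroups (default 20;
#'   the first 20 use the shipped COG ids).
#' @param noise_sd sd of the multiplicative lognormal noise on the log
#'   scale (default 0.2; 0 gives the noiseless limit).
#' @param n_corrupt number of corrupted markers (default 2).
#' @param community_share true taxon fraction of the community (default
#'   0.02).
#' @param copy_numbers named integer vector, accessory gene -> true copies
#'   per genome in `{0, 1, 2}` (default `c(pr = 1, blh = 1)`).
#' @param frac_absent fraction of samples with the taxon absent (default
#'   0.1).
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of the
#'   latent abundance (defaults `log(5)` and 1).
#' @param seed integer seed.
#' @return List with `coverage` (a [coverage_matrix] of marker +
#'   accessory genes), `totals` (community coverage matrix, marker
#'   orthogroups x samples), `markers` (candidate orthogroup ids) and
#'   `truth` (latent abundance, corrupted markers, absent samples, true
#'   share and copy numbers).
#' @export
simulate_coverage <- function(n_samples = 30L, n_markers = 20L,
                              noise_sd = 0.2, n_corrupt = 2L,
                              community_share = 0.02,
                              copy_numbers = c(pr = 1L, blh = 1L),
                              frac_absent = 0.1,
                              abundance_meanlog = log(5),
                              abundance_sdlog = 1,
                              seed = 1L) {
  if (n_markers < 3L) stop("need at least 3 markers")
  if (n_samples < 5L) stop("need at least 5 samples")
  if (n_corrupt < 0L || n_corrupt >= n_markers)
    stop("n_corrupt must be in [0, n_markers)")
  if (!all(copy_numbers %in% 0:2))
    stop("copy numbers must be 0, 1 or 2")
  if (community_share <= 0 || community_share > 1)
    stop("community_share must be in (0, 1]")
  ss <- substream_seeds(seed, 5L)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  cogs <- default_marker_cogs()
  ogs <- if (n_markers <= length(cogs)) cogs[seq_len(n_markers)] else
    c(cogs, sprintf("OGX%04d", seq_len(n_markers - length(cogs))))

  set.seed(ss[1L])
  a <- rlnorm(n_samples, abundance_meanlog, abundance_sdlog)
  n_absent <- floor(frac_absent * n_samples)
  absent <- if (n_absent > 0) sort(sample.int(n_samples, n_absent)) else integer(0)
  a[absent] <- 0

  set.seed(ss[2L])
  corrupted <- if (n_corrupt > 0) sort(sample(ogs, n_corrupt)) else character(0)

  noise <- function(n) if (noise_sd > 0) rlnorm(n, 0, noise_sd) else rep(1, n)

  set.seed(ss[3L])
  mk <- matrix(0, n_markers, n_samples, dimnames = list(ogs, sample_ids))
  for (g in seq_len(n_markers)) {
    if (ogs[g] %in% corrupted) {
      mk[g, ] <- rlnorm(n_samples, abundance_meanlog, abundance_sdlog) *
        noise(n_samples)
    } else {
      mk[g, ] <- a * noise(n_samples)
    }
  }

  set.seed(ss[4L])
  acc <- matrix(0, length(copy_numbers), n_samples,
                dimnames = list(names(copy_numbers), sample_ids))
  for (g in seq_along(copy_numbers))
    acc[g, ] <- copy_numbers[g] * a * noise(n_samples)

  set.seed(ss[5L])
  totals <- matrix(0, n_markers, n_samples, dimnames = list(ogs, sample_ids))
  for (g in seq_len(n_markers))
    totals[g, ] <- (a / community_share) * noise(n_samples)

  cov <- coverage_matrix(rbind(mk, acc),
                         gene_ids = c(paste0("gene_", ogs),
                                      names(copy_numbers)),
                         orthogroup_ids = c(ogs,
                                            rep("", length(copy_numbers))),
                         sample_ids = sample_ids)
  list(coverage = cov, totals = totals, markers = ogs,
       truth = list(seed = seed, abundance = setNames(a, sample_ids),
                    community_share = community_share,
                    copy_numbers = copy_numbers,
                    corrupted_markers = corrupted,
                    absent_samples = sample_ids[absent]))
}

#' Simulate amplicon reads from reference fragments
#'
#' Each read is a uniformly placed window of its source fragment with
#' i.i.d. substitutions (never back to the original base) at the
#' fragment's substitution rate. The truth table records the realised
#' substitution count per read.
#'
#' @param fragments reference fragments (list of `reference_fragment`, a
#'   [seq_set], or a named character vector of sequences).
#' @param plan data frame with columns `sample_id`, `reference_id`, `n`:
#'   how many reads to draw from each fragment in each sample.
#' @param substitution_rate per-fragment substitution rate in `[0, 0.5)`;
#'   a scalar or a vector named by fragment id.
#' @param read_length read length (default 200; must not exceed any used
#'   fragment's length).
#' @param seed integer seed.
#' @return List with `reads` (named list, sample_id -> [seq_set]) and
#'   `truth` (read_id, sample_id, source_reference, start, n_subs).
#' @export
simulate_reads <- function(fragments, plan, substitution_rate = 0.005,
                           read_length = 200L, seed = 1L) {
  frags <- if (is.character(fragments) && !is.null(names(fragments)))
    fragments[order(names(fragments))] else fragment_residues(fragments)
  if (!all(c("sample_id", "reference_id", "n") %in% names(plan)))
    stop("plan needs columns sample_id, reference_id, n")
  if (!all(plan$reference_id %in% names(frags)))
    stop("plan references unknown fragment")
  rate <- if (length(substitution_rate) == 1L && is.null(names(substitution_rate)))
    setNames(rep(substitution_rate, length(frags)), names(frags))
  else substitution_rate[names(frags)]
  if (anyNA(rate)) stop("substitution_rate missing for some fragment")
  if (any(rate < 0 | rate >= 0.5))
    stop("substitution rates must lie in [0, 0.5)")
  if (any(read_length > nchar(frags[unique(plan$reference_id)])))
    stop("read_length exceeds a fragment length")
  bases <- c("A", "C", "G", "T")
  set.seed(substream_seeds(seed, 1L))
  reads <- list(); truth <- list()
  for (sid in unique(plan$sample_id)) {
    sub <- plan[plan$sample_id == sid, , drop = FALSE]
    ids <- character(0); seqsv <- character(0)
    t_src <- character(0); t_start <- integer(0); t_sub <- integer(0)
    serial <- 0L
    for (r in seq_len(nrow(sub))) {
      fid <- sub$reference_id[r]
      fres <- frags[[fid]]
      L <- nchar(fres)
      for (k in seq_len(sub$n[r])) {
        serial <- serial + 1L
        start <- sample.int(L - read_length + 1L, 1L)
        rd <- strsplit(substr(fres, start, start + read_length - 1L), "")[[1L]]
        mut <- which(runif(read_length) < rate[[fid]])
        for (m in mut)
          rd[m] <- sample(setdiff(bases, rd[m]), 1L)
        ids <- c(ids, sprintf("%s_read%05d", sid, serial))
        seqsv <- c(seqsv, paste(rd, collapse = ""))
        t_src <- c(t_src, fid); t_start <- c(t_start, start)
        t_sub <- c(t_sub, length(mut))
      }
    }
    reads[[sid]] <- seq_set(ids, seqsv, alphabet = "dna")
    truth[[sid]] <- data.frame(read_id = ids, sample_id = sid,
                               source_reference = t_src, start = t_start,
                               n_subs = t_sub, stringsAsFactors = FALSE)
  }
  list(reads = reads,
       truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))))
}

#' Generate random rhodopsin-like subfamily consensus references
#'
#' Random protein consensi (one per subfamily label) with a lysine fixed
#' at `retinal_k_pos` inside the helix-7 interval. Random sequences of
#' this length have pairwise identity far below 50%, which the function
#' asserts.
#'
#' @param families subfamily labels (default PR, XR, P4, P5).
#' @param length consensus length in residues (default 240).
#' @param retinal_k_pos retinal lysine position (default 215).
#' @param helix7 helix-7 interval (default `c(200, 230)`).
#' @param seed integer seed.
#' @return A [rhodopsin_refs] object with one consensus per family.
#' @export
random_rhodopsin_consensi <- function(families = c("PR", "XR", "P4", "P5"),
                                      length = 240L, retinal_k_pos = 215L,
                                      helix7 = c(200L, 230L), seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  set.seed(substream_seeds(seed, 1L))
  res <- vapply(families, function(f) {
    s <- sample(aa, length, replace = TRUE)
    s[retinal_k_pos] <- "K"
    paste(s, collapse = "")
  }, "")
  refs <- rhodopsin_refs(id = paste0("ref_", families), subfamily = families,
                         residues = unname(res),
                         retinal_k_pos = retinal_k_pos,
                         helix7_start = helix7[1L], helix7_end = helix7[2L])
  for (i in seq_len(nrow(refs) - 1L)) for (j in seq(i + 1L, nrow(refs))) {
    aln <- global_align(refs$residues[i], refs$residues[j])
    if (percent_identity(aln) > 0.5)
      stop("consensus pair exceeds 50% identity; choose a longer length")
  }
  refs
}

#' Simulate a rhodopsin query cohort from subfamily consensi
#'
#' Queries are derived from their family consensus by i.i.d.
#' substitutions (never at the retinal lysine unless the lesion is a
#' K-knockout, and never back to the original residue). Lesions:
#' `"none"`, `"K-knockout"` (retinal lysine replaced by a non-K residue)
#' or `"helix7-deletion"` (the helix-7 interval excised). Query ids
#' encode the assembly as `"assembly|protein"`.
#'
#' @param consensi a [rhodopsin_refs] object (e.g.
#'   [random_rhodopsin_consensi]); pairwise identity must not exceed 0.5.
#' @param mutation_rate per-residue substitution rate (must be `<= 0.3`,
#'   above which labels would be unreliable).
#' @param n_per_family queries per family: scalar or vector named by
#'   subfamily.
#' @param n_assemblies assemblies per family (queries are spread
#'   round-robin): scalar or vector named by subfamily.
#' @param lesion_plan optional data frame with columns `subfamily`,
#'   `index`, `lesion` assigning lesions to the index-th query of a
#'   family (default: no lesions).
#' @param seed integer seed.
#' @return List with `queries` (protein [seq_set]), `references`
#'   (the consensi) and `truth` (query_id, subfamily, assembly, lesion,
#'   n_mutations).
#' @export
simulate_rhodopsins <- function(consensi = random_rhodopsin_consensi(),
                                mutation_rate = 0.10, n_per_family = 15L,
                                n_assemblies = 8L, lesion_plan = NULL,
                                seed = 1L) {
  stopifnot(inherits(consensi, "rhodopsin_refs"))
  if (mutation_rate > 0.3) stop("mutation_rate above 0.3: labels unreliable")
  fams <- consensi$subfamily
  nq <- if (length(n_per_family) == 1L)
    setNames(rep(n_per_family, length(fams)), fams) else n_per_family[fams]
  nasm <- if (length(n_assemblies) == 1L)
    setNames(rep(n_assemblies, length(fams)), fams) else n_assemblies[fams]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  set.seed(substream_seeds(seed, 1L))
  ids <- res <- t_fam <- t_asm <- t_les <- character(0)
  t_mut <- integer(0)
  for (fi in seq_along(fams)) {
    fam <- fams[fi]
    cons <- strsplit(consensi$residues[fi], "")[[1L]]
    kpos <- consensi$retinal_k_pos[fi]
    h7 <- c(consensi$helix7_start[fi], consensi$helix7_end[fi])
    for (q in seq_len(nq[[fam]])) {
      lesion <- "none"
      if (!is.null(lesion_plan)) {
        hit <- lesion_plan$subfamily == fam & lesion_plan$index == q
        if (any(hit)) lesion <- lesion_plan$lesion[which(hit)[1L]]
      }
      s <- cons
      mut <- which(runif(length(s)) < mutation_rate)
      if (lesion != "K-knockout") mut <- setdiff(mut, kpos)
      for (m in mut) s[m] <- sample(setdiff(aa, s[m]), 1L)
      if (lesion == "K-knockout")
        s[kpos] <- sample(setdiff(aa, "K"), 1L)
      if (lesion == "helix7-deletion")
        s <- s[-seq.int(h7[1L], h7[2L])]
      asm <- sprintf("%s_asm%02d", fam, ((q - 1L) %% nasm[[fam]]) + 1L)
      qid <- sprintf("%s|%s_q%02d", asm, fam, q)
      ids <- c(ids, qid); res <- c(res, paste(s, collapse = ""))
      t_fam <- c(t_fam, fam); t_asm <- c(t_asm, asm)
      t_les <- c(t_les, lesion)
      t_mut <- c(t_mut, length(setdiff(mut, kpos)))
    }
  }
  list(queries = seq_set(ids, res, alphabet = "protein"),
       references = consensi,
       truth = data.frame(query_id = ids, subfamily = t_fam,
                          assembly = t_asm, lesion = t_les,
                          n_mutations = t_mut, stringsAsFactors = FALSE))
}
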