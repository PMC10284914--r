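# Small helper: coverage matrix straight from a plain matrix whose rows
# are marker orthogroups (one gene per orthogroup).
cov_from_matrix <- function(m, ogs = rownames(m)) {
  coverage_matrix(m, gene_ids = paste0("gene_", ogs),
                  orthogroup_ids = ogs,
                  sample_ids = colnames(m) %||% sprintf("S%02d", seq_len(ncol(m))))
}

test_that("recruit_records keeps >=95% best hits against the target", {
  set.seed(71)
  target <- rand_protein(100)
  catalog <- seq_set(c("exact", "sub7", "near_decoy"),
                     c(target,
                       mutate_at(target, sample(100, 7), AA20),
                       mutate_at(target, sample(100, 4), AA20)),
                     alphabet = "protein")
  targets <- seq_set("tgt1", target, alphabet = "protein")
  # decoy closer to 'near_decoy' than the target is
  decoy <- seq_set("decoy1", catalog$residues[3], alphabet = "protein")
  ogm <- setNames(rep("COG0012", 3), catalog$id)
  rec <- recruit_records(catalog, targets, ogm, competitors = decoy)
  expect_true(rec$recruited[rec$gene_id == "exact"])
  expect_equal(rec$best_identity[rec$gene_id == "exact"], 1.0)
  # identity 93/100 < 0.95 -> not recruited
  expect_false(rec$recruited[rec$gene_id == "sub7"])
  expect_equal(rec$best_identity[rec$gene_id == "sub7"], 0.93)
  # best hit is the decoy (identity 1) although the target is at 0.96
  expect_false(rec$recruited[rec$gene_id == "near_decoy"])
  expect_identical(rec$best_hit[rec$gene_id == "near_decoy"], "decoy1")
  expect_error(recruit_records(catalog, targets[0, ], ogm), "empty target")
})

test_that("perfectly proportional markers are all selected", {
  set.seed(81)
  a <- rlnorm(12, log(5), 1)
  m <- outer(rep(1, 20), a)
  rownames(m) <- default_marker_cogs()
  ms <- select_markers(cov_from_matrix(m), rownames(m))
  expect_setequal(ms$selected_ogs, rownames(m))
  expect_equal(nrow(ms$dropped), 0L)
})

test_that("an uncorrelated marker is identified and dropped", {
  sim <- simulate_coverage(n_samples = 30, n_markers = 20, n_corrupt = 1,
                           noise_sd = 0.2, seed = 91)
  ms <- select_markers(sim$coverage, sim$markers)
  expect_identical(ms$dropped$orthogroup_id, sim$truth$corrupted_markers)
  # brute-force check: the dropped marker minimises the median rank
  # correlation of log coverage to the other candidates
  m <- log(sapply(sim$markers, function(og) {
    g <- which(sim$coverage$orthogroup_ids == og)
    colSums(sim$coverage$values[g, , drop = FALSE])
  }) + 1e-6)
  cc <- cor(m, method = "spearman"); diag(cc) <- NA
  med <- apply(cc, 2, median, na.rm = TRUE)
  expect_identical(names(which.min(med)), sim$truth$corrupted_markers)
})

test_that("marker selection enforces its preconditions", {
  m <- matrix(1:10, nrow = 2, dimnames = list(c("A", "B"), NULL))
  expect_error(select_markers(cov_from_matrix(m), c("A", "B")),
               "at least 3")
  m <- matrix(1:12, nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
  expect_error(select_markers(cov_from_matrix(m), c("A", "B", "C")),
               "at least 5 samples")
})

test_that("taxon abundance is the zero-inclusive marker mean", {
  m <- rbind(c(2, 3), c(2, 1), c(2, 0), c(2, 0))
  rownames(m) <- c("A", "B", "C", "D")
  colnames(m) <- c("s1", "s2")
  ab <- taxon_abundance(cov_from_matrix(m), c("A", "B", "C", "D"))
  expect_equal(ab$taxon_abundance, c(2.0, 1.0))
  expect_equal(ab$detection_fraction, c(1.0, 0.5))
})

test_that("community fraction divides by mean total marker coverage", {
  m <- matrix(1, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  ab <- taxon_abundance(cov_from_matrix(m), rownames(m))
  totals <- matrix(10, 4, 2, dimnames = dimnames(m))
  cf <- community_fraction(ab, totals)
  expect_equal(cf$community_fraction, c(0.1, 0.1))
  # zero taxon coverage -> fraction 0; zero denominator -> NA
  m0 <- m; m0[, 2] <- 0
  ab0 <- taxon_abundance(cov_from_matrix(m0), rownames(m))
  totals0 <- totals; totals0[, 2] <- 0
  cf0 <- community_fraction(ab0, totals0)
  expect_equal(cf0$community_fraction[1], 0.1)
  expect_true(is.na(cf0$community_fraction[2]))
  # fractions above one are flagged, not silently clipped
  expect_warning(cfx <- community_fraction(ab, totals / 200), "exceeds 1")
  expect_true(all(cfx$exceeds_one))
})

test_that("copy numbers apply the 90% detection gate", {
  ab <- data.frame(sample_id = c("s1", "s2"),
                   taxon_abundance = c(2.0, 2.0),
                   detection_fraction = c(1.0, 0.85))
  cn <- gene_copy_number(c(s1 = 2.0, s2 = 2.0), ab, "pr")
  expect_equal(cn$copies_per_genome[1], 1.0)
  expect_true(cn$defined[1])
  expect_false(cn$defined[2])          # detection 0.85 < 0.9
  expect_true(is.na(cn$copies_per_genome[2]))
})

test_that("operon copy number averages pr and blh where both defined", {
  ab <- data.frame(sample_id = c("s1", "s2"),
                   taxon_abundance = c(1, 1),
                   detection_fraction = c(1, 1))
  pr <- gene_copy_number(c(s1 = 1.0, s2 = 1.0), ab, "pr")
  blh <- gene_copy_number(c(s1 = 1.2, s2 = 1.4), ab, "blh")
  op <- operon_copy_number(pr, blh)
  expect_equal(op$copies_per_genome, c(1.1, 1.2))
  blh$defined[2] <- FALSE; blh$copies_per_genome[2] <- NA
  op <- operon_copy_number(pr, blh)
  expect_true(is.na(op$copies_per_genome[2]))
  expect_false(op$defined[2])
  blh2 <- blh[2:1, ]
  expect_error(operon_copy_number(pr, blh2), "sample mismatch")
})

test_that("copy-number estimates are invariant to per-sample scaling", {
  sim <- simulate_coverage(n_samples = 10, n_markers = 12, n_corrupt = 0,
                           seed = 13)
  ms <- sim$markers
  ab <- taxon_abundance(sim$coverage, ms)
  cn <- gene_copy_number(sim$coverage$values["pr", ], ab, "pr")
  k <- runif(length(sim$coverage$sample_ids), 0.5, 8)
  scaled <- coverage_matrix(sweep(sim$coverage$values, 2, k, `*`),
                            sim$coverage$gene_ids,
                            sim$coverage$orthogroup_ids,
                            sim$coverage$sample_ids)
  ab2 <- taxon_abundance(scaled, ms)
  cn2 <- gene_copy_number(scaled$values["pr", ], ab2, "pr")
  expect_equal(cn2$copies_per_genome, cn$copies_per_genome, tolerance = 1e-12)
  expect_identical(cn2$defined, cn$defined)
})

test_that("no copy number is ever defined below the detection gate", {
  sim <- simulate_coverage(n_samples = 30, frac_absent = 0.2, seed = 17)
  ms <- select_markers(sim$coverage, sim$markers)
  ab <- taxon_abundance(sim$coverage, ms)
  cn <- rbind(gene_copy_number(sim$coverage$values["pr", ], ab, "pr"),
              gene_copy_number(sim$coverage$values["blh", ], ab, "blh"))
  det <- ab$detection_fraction[match(cn$sample_id, ab$sample_id)]
  expect_true(all(!cn$defined[det < 0.9]))
  expect_true(all(is.na(cn$copies_per_genome[!cn$defined])))
})
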