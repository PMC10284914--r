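ref_cohort <- function(seed = 5) random_rhodopsin_consensi(seed = seed)

test_that("reference construction validates the retinal lysine", {
  expect_error(rhodopsin_refs("r1", "PR", strrep("A", 240), 215, 200, 230),
               "not K")
  s <- strrep("A", 240); substr(s, 215, 215) <- "K"
  expect_error(rhodopsin_refs("r1", "PR", s, 215, 220, 230),
               "outside helix 7")
  refs <- rhodopsin_refs("r1", "PR", s, 215, 200, 230)
  expect_s3_class(refs, "rhodopsin_refs")
})

test_that("classification returns the best-identity subfamily", {
  refs <- ref_cohort()
  hit <- classify_subfamily(refs$residues[refs$subfamily == "PR"], refs)
  expect_identical(hit$subfamily, "PR")
  expect_equal(hit$best_identity, 1.0)
  # a 15%-mutated XR query stays XR with identity near 0.85
  set.seed(7)
  xr <- refs$residues[refs$subfamily == "XR"]
  pos <- setdiff(sample(240, 36), 215)
  q <- mutate_at(xr, pos, AA20)
  hit <- classify_subfamily(q, refs)
  expect_identical(hit$subfamily, "XR")
  expect_equal(hit$best_identity, 1 - length(pos) / 240, tolerance = 0.03)
  expect_error(classify_subfamily(q, refs[0, ]), "empty reference")
})

test_that("equidistant same-subfamily references resolve deterministically", {
  set.seed(3)
  base <- rand_protein(120)
  refs <- rhodopsin_refs(c("refB", "refA"), c("PR", "PR"),
                         c(mutate_at(paste0(substr(base, 1, 59), "K",
                                            substr(base, 61, 120)), 10, AA20),
                           mutate_at(paste0(substr(base, 1, 59), "K",
                                            substr(base, 61, 120)), 100, AA20)),
                         60, 50, 70)
  q <- paste0(substr(base, 1, 59), "K", substr(base, 61, 120))
  hit <- classify_subfamily(q, refs)
  expect_identical(hit$subfamily, "PR")
  expect_identical(hit$best_ref_id, "refA")   # lexicographic tie-break
})

test_that("the retinal-lysine check distinguishes present/absent/unalignable", {
  refs <- ref_cohort()
  pr <- refs[refs$subfamily == "PR", ]
  expect_identical(check_retinal_lysine(pr$residues, pr), "present")
  # K -> A at the lysine position
  ko <- pr$residues
  substr(ko, pr$retinal_k_pos, pr$retinal_k_pos) <- "A"
  expect_identical(check_retinal_lysine(ko, pr), "absent")
  # helix 7 deleted entirely: the position maps into a gap
  del <- paste0(substr(pr$residues, 1, pr$helix7_start - 1),
                substr(pr$residues, pr$helix7_end + 1, nchar(pr$residues)))
  expect_identical(check_retinal_lysine(del, pr), "unalignable")
})

test_that("greedy clustering respects the identity level", {
  s <- seq_set(c("a", "b"), rep(strrep("MKTL", 25), 2), alphabet = "protein")
  cl <- greedy_cluster(s, 1.0)
  expect_equal(length(unique(cl$representative_id)), 1L)
  expect_setequal(cl$member_id, c("a", "b"))
  # pair at identity 0.75 stays apart at level 0.8
  set.seed(19)
  x <- rand_protein(100)
  y <- mutate_at(x, sample(100, 25), AA20)
  s2 <- seq_set(c("x", "y"), c(x, y), alphabet = "protein")
  expect_equal(percent_identity(global_align(x, y)), 0.75)
  cl2 <- greedy_cluster(s2, 0.8)
  expect_equal(length(unique(cl2$representative_id)), 2L)
  cl3 <- greedy_cluster(s2, 0.7)
  expect_equal(length(unique(cl3$representative_id)), 1L)
})

test_that("every member reaches its representative's identity level", {
  set.seed(23)
  base <- rand_protein(120)
  res <- c(base, vapply(1:11, function(i)
    mutate_at(base, sample(120, sample(5:50, 1)), AA20), ""))
  s <- seq_set(sprintf("q%02d", seq_along(res)), res, alphabet = "protein")
  for (level in c(0.9, 0.7, 0.5)) {
    cl <- greedy_cluster(s, level)
    res_of <- setNames(s$residues, s$id)
    for (i in seq_len(nrow(cl))) {
      if (cl$member_id[i] == cl$representative_id[i]) next
      ident <- percent_identity(global_align(res_of[[cl$member_id[i]]],
                                             res_of[[cl$representative_id[i]]]))
      expect_gte(ident, level)
    }
  }
})

test_that("sequential clustering keeps families apart and records lineage", {
  sim <- simulate_rhodopsins(mutation_rate = 0.12, n_per_family = 6, seed = 29)
  sq <- sequential_cluster(sim$queries)
  expect_named(sq$clusters, c("level_90", "level_80", "level_70", "level_60"))
  fam_of <- setNames(sim$truth$subfamily, sim$truth$query_id)
  mix <- tapply(fam_of[sq$lineage$member_id], sq$lineage$level_60,
                function(f) length(unique(f)))
  expect_true(all(mix == 1))
  expect_error(sequential_cluster(sim$queries, c(0.9, 0.9)),
               "strictly decreasing")
  # empty level list: every sequence is its own representative
  sq0 <- sequential_cluster(sim$queries, numeric(0))
  expect_identical(sq0$lineage$member_id, sim$queries$id)
  expect_length(sq0$clusters, 0L)
})

test_that("clustering output is byte-identical across repeated runs", {
  sim <- simulate_rhodopsins(mutation_rate = 0.1, n_per_family = 5, seed = 31)
  a <- sequential_cluster(sim$queries)
  b <- sequential_cluster(sim$queries)
  expect_identical(a, b)
})

test_that("contamination flags follow the cohort rules", {
  calls <- data.frame(
    query_id = sprintf("q%02d", 1:8),
    assembly_id = c("a1", "a2", "a1", "a2", "a3", "a4", "a5", "a6"),
    subfamily = c("XR", "XR", rep("PR", 6)),
    retained = TRUE, stringsAsFactors = FALSE)
  clusters60 <- data.frame(
    representative_id = c("q01", "q01", "q03", "q03", "q03", "q03", "q03",
                          "q08"),
    member_id = sprintf("q%02d", 1:8), stringsAsFactors = FALSE)
  out <- flag_contamination(calls, clusters60)
  # XR in 2 assemblies -> likely for all its calls
  expect_true(all(out$contamination[out$subfamily == "XR"] == "likely"))
  # PR in 6 assemblies; q08 sits alone in its 60% cluster -> potential
  expect_identical(out$contamination[out$query_id == "q08"], "potential")
  expect_true(all(out$contamination[out$query_id %in%
                                      sprintf("q%02d", 3:7)] == "none"))
  # exactly 3 assemblies is not contamination
  calls3 <- calls[3:8, ]
  calls3$assembly_id <- c("a1", "a1", "a2", "a2", "a3", "a3")
  cl3 <- data.frame(representative_id = "q03",
                    member_id = sprintf("q%02d", 3:8))
  out3 <- flag_contamination(calls3, cl3)
  expect_true(all(out3$contamination == "none"))
  expect_error(flag_contamination(calls, clusters60[-8, ]),
               "missing from clustering")
})

test_that("screen_rhodopsins retains only lysine-bearing confident hits", {
  plan <- data.frame(subfamily = c("PR", "XR"), index = c(1, 2),
                     lesion = c("K-knockout", "helix7-deletion"))
  sim <- simulate_rhodopsins(mutation_rate = 0.1, n_per_family = 6,
                             lesion_plan = plan, seed = 37)
  sc <- screen_rhodopsins(sim$queries, sim$references)
  m <- merge(sc$calls, sim$truth, by = "query_id")
  expect_true(all(m$subfamily.x == m$subfamily.y))
  expect_identical(sort(m$query_id[!m$retained]),
                   sort(m$query_id[m$lesion != "none"]))
  expect_setequal(m$retinal_k[m$lesion == "K-knockout"], "absent")
  expect_setequal(m$retinal_k[m$lesion == "helix7-deletion"], "unalignable")
  expect_true(all(m$retinal_k[m$retained] == "present"))
})
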