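make_anchor <- function(seed = 9, len = 1540) {
  set.seed(seed)
  rand_dna(len)
}

test_that("trim_reference extracts the 515-938 window (424 nt)", {
  anchor <- make_anchor()
  # reference identical to the anchor: identity mapping of the window
  frag <- trim_reference(list(id = "iso", residues = anchor,
                              alphabet = "dna"), anchor)
  expect_s3_class(frag, "reference_fragment")
  expect_identical(frag$residues, substr(anchor, 515, 938))
  expect_equal(nchar(frag$residues), 424L)
})

test_that("trim_reference tracks indels inside the window", {
  anchor <- make_anchor()
  # one deletion inside the window -> fragment one residue shorter
  del <- paste0(substr(anchor, 1, 699), substr(anchor, 701, nchar(anchor)))
  frag <- trim_reference(list(id = "del", residues = del,
                              alphabet = "dna"), anchor)
  expect_equal(nchar(frag$residues), 423L)
  # one insertion inside the window -> one residue longer
  ins <- paste0(substr(anchor, 1, 700), "A", substr(anchor, 701, nchar(anchor)))
  frag <- trim_reference(list(id = "ins", residues = ins,
                              alphabet = "dna"), anchor)
  expect_equal(nchar(frag$residues), 425L)
})

test_that("trim_reference rejects anchors shorter than the window", {
  short <- substr(make_anchor(), 1, 900)
  expect_error(trim_reference(short, short), "shorter than")
})

test_that("recruit_read applies the 98% identity threshold exactly", {
  set.seed(21)
  frags <- c(refA = rand_dna(424), decoy = rand_dna(424))
  read <- substr(frags[["refA"]], 100, 299)
  hit <- recruit_read(read, frags)
  expect_identical(as.character(hit), "refA")
  expect_equal(attr(hit, "identity"), 1.0)
  # 5 substitutions over 200 nt: identity 0.975 < 0.98 -> none
  read5 <- mutate_at(read, c(7, 53, 99, 140, 188))
  miss <- recruit_read(read5, frags)
  expect_true(is.na(miss))
  expect_equal(attr(miss, "identity"), 0.975)
  # 3 substitutions: identity 0.985 >= 0.98 -> matched
  read3 <- mutate_at(read, c(7, 53, 99))
  expect_identical(as.character(recruit_read(read3, frags)), "refA")
  expect_error(recruit_read(read, list()), "empty fragment list")
})

test_that("short reads are rejected with a warning", {
  set.seed(2)
  frags <- c(refA = rand_dna(424))
  expect_warning(hit <- recruit_read(substr(frags[["refA"]], 1, 30), frags),
                 "shorter than")
  expect_true(is.na(hit))
})

test_that("profile_samples computes matched/total per reference", {
  set.seed(31)
  frags <- c(refA = rand_dna(424), refB = rand_dna(424))
  reads <- seq_set(sprintf("r%02d", 1:10),
                   c(vapply(1:4, function(i)
                       substr(frags[["refA"]], 10 * i, 10 * i + 199), ""),
                     vapply(1:6, function(i) rand_dna(200), "")),
                   alphabet = "dna")
  md <- data.frame(sample_id = "s1", station = "N1200", depth_label = "DCM",
                   season = "winter", size_fraction = "FL", year = 2015)
  prof <- profile_samples(list(s1 = reads), frags, md)
  expect_equal(prof$rel_abundance[prof$reference_id == "refA"], 0.4)
  expect_equal(prof$rel_abundance[prof$reference_id == "refB"], 0.0)
  expect_equal(unique(prof$n_total), 10L)
  expect_error(profile_samples(list(bad = reads), frags, md),
               "unknown sample_id")
})

test_that("season-restricted reads give zero summer abundance", {
  set.seed(41)
  anchor <- rand_dna(1540)
  frag <- trim_reference(list(id = "isoA", residues = anchor,
                              alphabet = "dna"), anchor)
  plan <- data.frame(sample_id = c("w1", "sp1", "sm1", "sm2"),
                     reference_id = "isoA",
                     n = c(25, 15, 0, 0))
  rs <- simulate_reads(list(frag), plan[plan$n > 0, ],
                       substitution_rate = 0.005, seed = 42)
  # summer samples exist but received no target reads
  reads <- c(rs$reads, list(sm1 = seq_set("x1", rand_dna(200)),
                            sm2 = seq_set("x2", rand_dna(200))))
  md <- data.frame(sample_id = c("w1", "sp1", "sm1", "sm2"),
                   station = "N1200", depth_label = "DCM",
                   season = c("winter", "spring", "summer", "summer"),
                   size_fraction = "FL", year = 2015)
  prof <- profile_samples(reads, list(frag), md)
  summer <- prof$season == "summer"
  expect_true(all(prof$rel_abundance[summer] == 0))
  expect_true(all(prof$rel_abundance[prof$season == "winter"] > 0.9))
  # sorted winter < spring < summer
  expect_identical(unique(prof$season), c("winter", "spring", "summer"))
})

test_that("raising the threshold never recruits more reads", {
  set.seed(51)
  frags <- c(refA = rand_dna(424), refB = rand_dna(424))
  plan <- data.frame(sample_id = "s1", reference_id = c("refA", "refB"),
                     n = c(40, 40))
  rs <- simulate_reads(frags, plan, substitution_rate = 0.02, seed = 6)
  idents <- vapply(rs$reads$s1$residues, function(r)
    attr(recruit_read(r, frags, min_identity = 0), "identity"), 0,
    USE.NAMES = FALSE)
  counts <- vapply(c(0.90, 0.95, 0.98, 0.99, 1.0), function(t)
    sum(idents >= t), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("per-sample relative abundances never sum above one", {
  set.seed(61)
  frags <- c(refA = rand_dna(424), refB = rand_dna(424))
  plan <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     reference_id = rep(c("refA", "refB"), 2),
                     n = c(10, 5, 3, 12))
  rs <- simulate_reads(frags, plan, substitution_rate = 0.01, seed = 8)
  md <- data.frame(sample_id = c("s1", "s2"), station = "st",
                   depth_label = "DCM", season = "winter",
                   size_fraction = c("FL", "PA"), year = 2014)
  prof <- profile_samples(rs$reads, frags, md)
  sums <- tapply(prof$rel_abundance, prof$sample_id, sum)
  expect_true(all(sums <= 1 + 1e-12))
})
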