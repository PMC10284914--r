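# Independent alignment oracle: exhaustive enumeration of every gapped
# alignment (move sequences), scoring gap runs affinely as they are
# emitted. No dynamic-programming reuse, so it cross-checks the Gotoh
# implementation rather than mirroring it.
brute_force_score <- function(a, b, match = 5, mismatch = -4,
                              gap_open = 16, gap_extend = 4) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  best <- -Inf
  rec <- function(i, j, last, cur) {
    if (i == n && j == m) {
      if (cur > best) best <<- cur
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1L, j + 1L, "D",
          cur + if (A[i + 1L] == B[j + 1L]) match else mismatch)
    if (i < n) rec(i + 1L, j, "V",
                   cur - if (last == "V") gap_extend else gap_open)
    if (j < m) rec(i, j + 1L, "H",
                   cur - if (last == "H") gap_extend else gap_open)
  }
  rec(0L, 0L, "S", 0)
  best
}

DNA4 <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

rand_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")
rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# substitute k positions, never to the original residue
mutate_at <- function(seq, positions, alphabet = DNA4) {
  s <- strsplit(seq, "")[[1L]]
  for (p in positions) s[p] <- sample(setdiff(alphabet, s[p]), 1L)
  paste(s, collapse = "")
}

write_tmp_fasta <- function(lines, ext = ".fasta") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
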