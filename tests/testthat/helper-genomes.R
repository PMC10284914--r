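# Locate (or fetch) the deposited genome FASTA for an accession. Looks for
# a local copy under inst/extdata/genomes/ or tests/testthat/genomes/
# first (the files are ~5 Mb and are not shipped with the package), then
# falls back to NCBI efetch.
fetch_genome_fasta <- function(accession) {
  candidates <- c(
    system.file("extdata", "genomes", paste0(accession, ".fasta"),
                package = "photohet"),
    testthat::test_path("genomes", paste0(accession, ".fasta")))
  for (p in candidates) if (nzchar(p) && file.exists(p)) return(p)
  dest <- file.path(tempdir(), paste0(accession, ".fasta"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession,
                "&rettype=fasta&retmode=text")
  old <- getOption("timeout"); on.exit(options(timeout = old))
  options(timeout = 60)
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) < 1e6) {
    unlink(dest)
    stop("genome FASTA for ", accession, " unavailable: no local copy ",
         "under extdata/genomes/ and the NCBI fetch failed")
  }
  dest
}
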