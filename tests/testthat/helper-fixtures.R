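# Shared fixtures and independent oracles for the test suite.

RE1 <- "AAGCTT"   # HindIII-like, cut offset 1
RE2 <- "CCGG"     # MspI-like, cut offset 1

# deterministic background sequence free of RE1/RE2 (period-5 repeat of a
# motif-free word, so no junction can spell a 4/6-mer cutter site)
bg_seq <- function(len) {
  word <- "ACTGA"
  paste(rep(word, ceiling(len / nchar(word))), collapse = "") |>
    substr(1, len)
}

# plant motifs at given 0-based positions into a background string
plant_at <- function(len, positions, motif) {
  s <- bg_seq(len)
  for (p0 in positions) substr(s, p0 + 1, p0 + nchar(motif)) <- motif
  s
}

# small fully annotated two-chromosome fragment table for event tests:
# RE1 cut sites at fixed positions, RE2 sites well inside every fragment
toy_genome <- function() {
  chr1 <- plant_at(6000, c(1000, 2500, 4200), RE1)
  for (q in c(300, 700, 1600, 3000, 3600, 5000))
    substr(chr1, q + 1, q + nchar(RE2)) <- RE2
  chr2 <- plant_at(4000, c(1200, 2600), RE1)
  for (q in c(400, 1800, 3200)) substr(chr2, q + 1, q + nchar(RE2)) <- RE2
  Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
}

toy_frags <- function() build_fragment_table(toy_genome(), RE1, RE2,
                                             mappability = FALSE)

# a well-behaved mid-sized simulated dataset reused across test files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 20260901,
                        chrom_lengths = c(chrA = 150000L, chrB = 150000L,
                                          chrC = 150000L))
      cache <<- c(list(config = cfg), simulate_dataset(cfg, 50000))
    }
    cache
  }
})

# independent SCN oracle: naive loops, run to a tight tolerance
scn_oracle <- function(m, tol = 1e-12, max_iter = 5000) {
  for (it in seq_len(max_iter)) {
    for (j in seq_len(ncol(m))) m[, j] <- m[, j] / sqrt(sum(m[, j]^2))
    for (i in seq_len(nrow(m))) m[i, ] <- m[i, ] / sqrt(sum(m[i, ]^2))
    rn <- apply(m, 1, function(x) sqrt(sum(x^2)))
    cn <- apply(m, 2, function(x) sqrt(sum(x^2)))
    if (max(abs(c(rn, cn) - 1)) < tol && max(abs(m - t(m))) < tol) break
  }
  m
}

# build a ContactMatrix directly from a dense matrix (single chromosome by
# default; midpoints 1 kb apart)
cm_from_matrix <- function(v, chrom = NULL) {
  n <- nrow(v)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  contact_matrix(v, data.frame(fragment_id = seq_len(n), chrom = chrom,
                               start = (seq_len(n) - 1) * 1000,
                               end = seq_len(n) * 1000,
                               mid = (seq_len(n) - 0.5) * 1000),
                 scope = "all")
}
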