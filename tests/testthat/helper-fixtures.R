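# Shared fixtures and independent oracles, built in code at test time.

library(data.table)

# random genome string
rand_genome <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

build_indexes <- function(ref, sa_spacing = 4L, occ_spacing = 64L) {
  list(C_LESS = build_converted_index(ref, "C_LESS", sa_spacing, occ_spacing),
       G_LESS = build_converted_index(ref, "G_LESS", sa_spacing, occ_spacing))
}

# one small aligned simulation, cached per test session
.small_aligned <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(genome_length = 8000, depth = 15, rng_seed = 101)
    sim <- run_simulation(cfg)
    packed <- pack_reference(sim$ref)
    idx <- build_indexes(sim$ref)
    recs <- align_pairs_table(sim$reads$r1, sim$reads$r2, idx, packed)
    cache <<- list(sim = sim, packed = packed, idx = idx, recs = recs)
    cache
  }
})

# Build alignment records directly from simulator truth (bypassing the
# aligner) - used to test the pileup/QC/epiBED modules in isolation.
truth_records <- function(sim) {
  rl <- sim$config$read_length
  tr <- copy(sim$reads$truth)
  seqs <- rbind(
    data.table(name = sim$reads$r1$name, mate = 1L, seq = sim$reads$r1$seq,
               qual = sim$reads$r1$qual),
    data.table(name = sim$reads$r2$name, mate = 2L, seq = sim$reads$r2$seq,
               qual = sim$reads$r2$qual))
  tr <- merge(tr, seqs, by = c("name", "mate"), sort = FALSE)
  minus <- tr$strand == "-"
  flag <- 1L + ifelse(tr$mate == 1L, 64L, 128L) + ifelse(minus, 16L, 0L)
  oseq <- tr$seq
  oseq[minus] <- vapply(tr$seq[minus], methsuite::revcomp, character(1),
                        USE.NAMES = FALSE)
  data.table(qname = tr$name, flag = flag, rname = tr$contig, pos = tr$pos,
             mapq = 60L, cigar = paste0(rl, "M"), rnext = "=", pnext = 0L,
             tlen = 0L, seq = oseq, qual = tr$qual, nm = 0L, as_score = rl,
             xs = 0L, zs = NA_character_, xa = NA_character_, xb = 0L,
             zc = 0L, tag = tr$bs_tag,
             cls = ifelse(tr$bs_tag %in% c("OT", "CTOT"), "C2T", "G2A"),
             ambiguous = FALSE, ref_end = tr$pos + rl - 1L,
             dup = tr$duplicate)
}

# Exhaustive affine-gap local alignment oracle (plain dynamic programming,
# no band, gap of length k costs open + k*ext); returns the optimal score.
sw_oracle <- function(ref_chars, read_chars, cls, match = 1, mismatch = 4,
                      gap_open = 6, gap_ext = 1) {
  w <- length(ref_chars); m <- length(read_chars)
  NEG <- -1e9
  H <- matrix(0, m + 1, w + 1)
  E <- matrix(NEG, m + 1, w + 1)
  F <- matrix(NEG, m + 1, w + 1)
  best <- 0
  sub <- function(r, q) {
    if (r == "N" || q == "N") return(0)
    if (r == q) return(match)
    if (cls == "C2T" && r == "C" && q == "T") return(match)
    if (cls == "G2A" && r == "G" && q == "A") return(match)
    -mismatch
  }
  for (i in 1:m) {
    for (j in 1:w) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext,
                             E[i, j + 1] - gap_ext)
      F[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext,
                             F[i + 1, j] - gap_ext)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + sub(ref_chars[j], read_chars[i]),
                             E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# two-sided Fisher exact p-value by direct hypergeometric enumeration
fisher_oracle <- function(m1, u1, m2, u2) {
  k <- m1 + m2; n1 <- m1 + u1; n2 <- m2 + u2
  x <- max(0, k - n2):min(k, n1)
  probs <- dhyper(x, n1, n2, k)
  p_obs <- dhyper(m1, n1, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# overlapping occurrence count of a pattern in a text (Biostrings; BString
# admits the sentinel characters)
count_occurrences <- function(pattern, text) {
  Biostrings::countPattern(pattern, Biostrings::BString(text))
}
occurrence_starts <- function(pattern, text) {
  Biostrings::start(Biostrings::matchPattern(pattern, Biostrings::BString(text)))
}

# the converted forward!reverse text of an index, as a character string
index_text_string <- function(ref, kind) {
  joined <- paste(unclass(ref), collapse = "X")
  conv <- function(s) if (kind == "C_LESS") chartr("C", "T", s) else
    chartr("G", "A", s)
  paste0(conv(joined), "!", conv(methsuite::revcomp(joined)))
}

# The full-scale end-to-end run (100 kb genome, 30x, directional WGBS),
# cached for the test session; used by the recovery checks.
.e2e <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(rng_seed = 20260101)   # defaults ARE the study design
    sim <- run_simulation(cfg)
    packed <- pack_reference(sim$ref)
    idx <- build_indexes(sim$ref)
    recs <- align_pairs_table(sim$reads$r1, sim$reads$r2, idx, packed)
    recs <- mark_duplicates(recs)
    cache <<- list(sim = sim, packed = packed, idx = idx, recs = recs)
    cache
  }
})
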