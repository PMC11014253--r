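test_that("read conversion hypotheses follow library chemistry", {
  r1 <- bs_read("r", "ACCT", mate = 1L)
  hyp <- convert_read(r1, "directional")
  expect_length(hyp, 1)
  expect_equal(hyp[[1]]$converted, "ATTT")
  expect_equal(hyp[[1]]$kind, "C_LESS")
  r2 <- bs_read("r", "ACCT", mate = 2L)
  hyp2 <- convert_read(r2, "directional")
  expect_equal(hyp2[[1]]$converted, "ACCT")  # no G present
  expect_equal(hyp2[[1]]$kind, "G_LESS")
  expect_length(convert_read(r1, "non_directional"), 2)
})

test_that("seeding finds unique loci, duplicated loci and respects length", {
  g <- rand_genome(3000, seed = 201)
  dup <- substr(g, 501, 900)
  g2 <- paste0(g, dup)                      # duplicated 400 bp block
  ref <- reference(c(chr1 = g2))
  idx <- build_indexes(ref)
  params <- scoring_params()

  readseq <- chartr("C", "T", substr(g, 1501, 1550))
  seeds <- generate_seeds(bs_read("u", readseq), idx, params)
  expect_gte(nrow(seeds), 1)
  best <- seeds[which.max(length)]
  expect_equal(best$ref_start, 1501L)
  expect_gte(best$length, 45)

  dupread <- chartr("C", "T", substr(g, 601, 660))
  ds <- generate_seeds(bs_read("d", dupread), idx, params)
  expect_setequal(intersect(ds$ref_start, c(601L, 3101L)), c(601L, 3101L))

  short <- bs_read("s", "ACGTACGT")        # shorter than min_seed_len
  expect_equal(nrow(generate_seeds(short, idx, params)), 0)
  allN <- bs_read("n", strrep("N", 40))
  expect_equal(nrow(generate_seeds(allN, idx, params)), 0)
})

test_that("4-base compatibility enforces strand-specific asymmetry", {
  packed <- pack_reference(reference(c(chr1 = "TCGA")))
  seed <- function(tag) {
    list(read_offset = 0L, length = 4L, contig = "chr1", ref_start = 1L,
         strand = "+", tag = tag)
  }
  # ref TCGA / read TTGA on OT: C->T tolerated
  expect_true(check_four_base_compatibility(seed("OT"), packed,
                                            bs_read("a", "TTGA")))
  # read C over ref T is never tolerated
  packed2 <- pack_reference(reference(c(chr1 = "TTGA")))
  expect_false(check_four_base_compatibility(seed("OT"), packed2,
                                             bs_read("b", "TCGA")))
  # G->A is not allowed on the OT strand ...
  expect_false(check_four_base_compatibility(seed("OT"), packed,
                                             bs_read("c", "TCAA")))
  # ... but is on OB
  expect_true(check_four_base_compatibility(seed("OB"), packed,
                                            bs_read("d", "TCAA")))
})

test_that("chaining merges colinear seeds and splits contigs", {
  params <- scoring_params(max_chain_gap = 50L)
  two <- data.table::data.table(
    read_offset = c(0L, 25L), length = c(20L, 20L),
    contig = c("chr1", "chr1"), ref_start = c(100L, 125L),
    strand = "+", tag = "OT", cls = "C2T")
  ch <- chain_seeds(two, params)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$score, 40L)
  expect_equal(ch$n_seeds, 2L)

  split2 <- data.table::copy(two)[2, contig := "chr2"]
  expect_equal(nrow(chain_seeds(split2, params,
                                contig_order = c("chr1", "chr2"))), 2)

  # overlapping seeds are trimmed: score <= sum of lengths
  ovl <- data.table::data.table(
    read_offset = c(0L, 10L), length = c(20L, 20L), contig = "chr1",
    ref_start = c(100L, 110L), strand = "+", tag = "OT", cls = "C2T")
  expect_lte(chain_seeds(ovl, params)$score, 40L)
  expect_equal(chain_seeds(ovl, params)$score, 30L)
})

test_that("asymmetric substitution score follows the conversion rules", {
  p <- scoring_params(match = 1L, mismatch = 4L)
  expect_equal(asymmetric_score("C", "T", "OT", p), 1L)
  expect_equal(asymmetric_score("T", "C", "OT", p), -4L)
  expect_equal(asymmetric_score("G", "A", "OB", p), 1L)
  expect_equal(asymmetric_score("A", "G", "OB", p), -4L)
  expect_equal(asymmetric_score("C", "T", "OB", p), -4L)   # wrong strand
  expect_equal(asymmetric_score("G", "A", "CTOB", p), 1L)
  expect_equal(asymmetric_score("A", "A", "OT", p), 1L)
  expect_equal(asymmetric_score("N", "A", "OT", p), 0L)
  expect_equal(asymmetric_score("A", "N", "OB", p), 0L)
})

test_that("extension: perfect reads, planted deletions, conversion parity", {
  g <- rand_genome(2000, seed = 210)
  ref <- reference(c(chr1 = g))
  packed <- pack_reference(ref)
  p <- scoring_params()
  chain <- list(tag = "OT", contig = "chr1", strand = "+",
                anchor_ref = 501L, anchor_off = 0L)

  plain <- substr(g, 501, 600)
  conv <- chartr("C", "T", plain)
  ext_conv <- extend_alignment(chain, packed, bs_read("a", conv), p)
  expect_equal(ext_conv$cigar, "100M")
  expect_equal(ext_conv$score, 100L)
  expect_equal(ext_conv$nm, 0L)
  # fully converted read scores identically to the unconverted read
  ext_plain <- extend_alignment(chain, packed, bs_read("b", plain), p)
  expect_equal(ext_plain$score, ext_conv$score)

  # planted 2 bp deletion
  del <- paste0(substr(plain, 1, 50), substr(g, 553, 602))
  ext_del <- extend_alignment(chain, packed, bs_read("c", del), p)
  expect_match(ext_del$cigar, "2D")
  expect_equal(ext_del$score, 100L * p$match - p$gap_open - 2L * p$gap_extend)

  # a non-conversion mismatch never increases the score (monotonicity)
  mm <- plain
  substr(mm, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                substr(plain, 30, 30))[1]
  ext_mm <- extend_alignment(chain, packed, bs_read("d", mm), p)
  expect_lt(ext_mm$score, ext_plain$score)
})

test_that("banded extension agrees with the exhaustive DP oracle", {
  set.seed(321)
  p <- scoring_params(band_width = 100L)
  for (i in 1:40) {
    w <- sample(60:80, 1)
    refc <- sample(c("A", "C", "G", "T"), w, TRUE)
    m <- sample(30:60, 1)
    start <- sample(seq_len(w - m), 1)
    readc <- refc[start:(start + m - 1)]
    cls <- sample(c("C2T", "G2A"), 1)
    # conversions, mutations, and a 1-3 bp indel
    if (cls == "C2T") readc[readc == "C" & runif(m) < 0.5] <- "T"
    else readc[readc == "G" & runif(m) < 0.5] <- "A"
    nmut <- sample(0:2, 1)
    if (nmut) {
      at <- sample(m, nmut)
      readc[at] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
    }
    if (i %% 2 == 0) {
      gl <- sample(1:3, 1)
      at <- sample(3:(m - gl - 3), 1)
      readc <- if (i %% 4 == 0) readc[-(at:(at + gl - 1))] else
        append(readc, sample(c("A", "C", "G", "T"), gl, TRUE), after = at)
    }
    ref <- reference(c(w1 = paste(refc, collapse = "")))
    packed <- pack_reference(ref)
    chain <- list(tag = if (cls == "C2T") "OT" else "CTOB", contig = "w1",
                  strand = "+", anchor_ref = start, anchor_off = 0L)
    got <- extend_alignment(chain, packed,
                            bs_read("x", paste(readc, collapse = "")), p)
    want <- sw_oracle(refc, readc, cls)
    expect_equal(got$score, want, info = paste("window", i))
  }
})

test_that("MAPQ formula: ties give 0, unique hits 60, gaps interpolate", {
  expect_equal(compute_mapq(100L, 100L, 2L), 0L)
  expect_equal(compute_mapq(100L, NA, 1L), 60L)
  expect_equal(compute_mapq(100L, 50L, 1L), 30L)
  expect_equal(compute_mapq(0L, NA, 1L), 0L)
  expect_equal(compute_mapq(100L, -5L, 1L), 60L)
})

test_that("conversion strand is reassessed from alignment evidence", {
  g <- "AACGTTACGTTTACGAA"
  packed <- pack_reference(reference(c(chr1 = g)))
  p <- scoring_params(min_seed_len = 10L)
  # read with all three Cs converted: C->T evidence only
  conv <- chartr("C", "T", g)
  aln <- extend_alignment(list(tag = "OT", contig = "chr1", strand = "+",
                               anchor_ref = 1L, anchor_off = 0L),
                          packed, bs_read("a", conv), p)
  re <- reassess_conversion_strand(aln, bs_read("a", conv), packed)
  expect_equal(re$cls, "C2T")
  expect_false(re$ambiguous)
  # identical read (no conversions at all): no evidence -> ambiguous
  aln2 <- extend_alignment(list(tag = "OT", contig = "chr1", strand = "+",
                                anchor_ref = 1L, anchor_off = 0L),
                           packed, bs_read("b", g), p)
  re2 <- reassess_conversion_strand(aln2, bs_read("b", g), packed)
  expect_true(re2$ambiguous)
})

test_that("a read from a duplicated locus gets MAPQ 0 with alternates", {
  base <- rand_genome(4000, seed = 230)
  seg <- substr(base, 1001, 1800)
  ref <- reference(c(chr1 = paste0(base, seg)))
  packed <- pack_reference(ref)
  idx <- build_indexes(ref)
  readseq <- chartr("C", "T", substr(base, 1201, 1300))
  rec <- align_read(bs_read("dup", readseq), idx, packed)
  expect_equal(rec$mapq, 0L)
  expect_equal(rec$xb, 1L)
  expect_match(rec$xa, "chr1,\\+(4201|1201),100M")
  expect_setequal(c(rec$pos, as.integer(sub(".*\\+(\\d+),.*", "\\1", rec$xa))),
                  c(1201L, 4201L))
})

test_that("unalignable reads come back as unmapped records", {
  ref <- reference(c(chr1 = rand_genome(1000, 240)))
  idx <- build_indexes(ref)
  packed <- pack_reference(ref)
  rec <- align_read(bs_read("junk", strrep("AGCT", 25)), idx, packed)
  # either no seeds at all or no positive-score candidate; flag 4 either way
  if (bitwAnd(rec$flag, 4L)) {
    expect_equal(rec$rname, "*")
    expect_equal(rec$cigar, "*")
  } else succeed()
})

test_that("pairs get SAM-consistent flags, mate fields and TLEN", {
  al <- .small_aligned()
  recs <- al$recs
  sub <- recs[!bitwAnd(flag, 4L)]
  both <- sub[, .N, by = qname][N == 2]$qname
  pair <- sub[qname == both[1]]
  expect_equal(nrow(pair), 2)
  expect_true(all(bitwAnd(pair$flag, 1L) > 0))
  expect_equal(sum(bitwAnd(pair$flag, 64L) > 0), 1)
  expect_equal(sum(bitwAnd(pair$flag, 128L) > 0), 1)
  expect_equal(pair$tlen[1], -pair$tlen[2])
  expect_equal(pair$pnext[1], pair$pos[2])
  expect_equal(pair$pnext[2], pair$pos[1])
  # proper pairs are FR with sane insert
  proper <- recs[bitwAnd(flag, 2L) > 0]
  expect_gt(nrow(proper), 0)
  expect_true(all(abs(proper$tlen) <= 300 + 4 * 30 + 1))
  # strands within a proper pair are opposite
  ps <- proper[, .(n_strand = data.table::uniqueN(bitwAnd(flag, 16L))),
               by = qname]
  expect_true(all(ps$n_strand == 2))
})

test_that("chimeric mates are not forced into a pair", {
  cfg <- sim_config(genome_length = 6000, depth = 4, rng_seed = 314,
                    chimera_rate = 1)
  sim <- run_simulation(cfg)
  packed <- pack_reference(sim$ref)
  idx <- build_indexes(sim$ref)
  recs <- align_pairs_table(sim$reads$r1[1:20], sim$reads$r2[1:20],
                            idx, packed)
  tr <- sim$reads$truth[name %in% sim$reads$r1$name[1:20]]
  # chimeric inserts: mates still map to their own true loci
  m <- merge(recs[!bitwAnd(flag, 4L),
                  .(qname, mate = ifelse(bitwAnd(flag, 64L) > 0, 1L, 2L),
                    pos, flag)],
             tr, by.x = c("qname", "mate"), by.y = c("name", "mate"))
  expect_gt(m[, mean(abs(pos.x - pos.y) <= 5)], 0.9)
  # the far-apart ones must not carry the proper-pair flag
  far <- m[, .(spread = max(abs(diff(pos.y)))), by = qname][spread > 500]
  farrec <- recs[qname %in% far$qname]
  expect_true(all(bitwAnd(farrec$flag, 2L) == 0))
})

test_that("duplicate marking is conversion-aware and coordinate-based", {
  al <- .small_aligned()
  recs <- data.table::copy(al$recs)
  # fabricate a duplicate of the first mapped pair with a DIFFERENT
  # methylation pattern (base content must not split the group)
  qn <- recs[!bitwAnd(flag, 4L) & bitwAnd(flag, 2L) > 0, qname][1]
  pair <- recs[qname == qn]
  dup <- data.table::copy(pair)
  dup[, qname := paste0(qn, "_copy")]
  dup[, seq := chartr("C", "T", seq)]      # extra conversions
  dup[, qual := strrep("5", nchar(seq[1]))] # lower base quality
  marked <- mark_duplicates(rbind(recs, dup))
  expect_true(all(marked[qname == paste0(qn, "_copy"), dup]))
  expect_false(any(marked[qname == qn, dup]))
  # same position, opposite bisulfite class: not duplicates
  flip <- data.table::copy(pair)
  flip[, qname := paste0(qn, "_flip")]
  flip[, cls := ifelse(cls == "C2T", "G2A", "C2T")]
  marked2 <- mark_duplicates(rbind(pair, flip))
  expect_false(any(marked2$dup))
  # singletons are never flagged
  single <- mark_duplicates(pair)
  expect_false(any(single$dup))
})

test_that("SAM output round-trips through the parser", {
  al <- .small_aligned()
  recs <- sort_records(al$recs[1:50], al$packed$contigs)
  path <- tempfile(fileext = ".sam")
  write_sam(recs, path, al$packed)
  back <- read_sam(path)
  expect_equal(nrow(back), 50)
  for (col in c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
                "qual", "nm", "as_score", "zs", "xb"))
    expect_equal(back[[col]], recs[[col]], info = col)
  # FLAG/POS/CIGAR consistency: reconstructed ref_end matches
  expect_equal(back$ref_end, recs$ref_end)
})
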