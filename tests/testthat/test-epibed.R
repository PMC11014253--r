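test_that("RLE encoding round-trips and follows the documented form", {
  expect_equal(encode_rle(c("x", "x", "M", "x", "x", "x")), "2x1M3x")
  expect_equal(decode_rle("2x1M3x"), c("x", "x", "M", "x", "x", "x"))
  expect_equal(decode_rle(encode_rle(c("M"))), "M")
  set.seed(11)
  for (i in 1:200) {
    st <- sample(c("M", "U", "F", "x", "D"), sample(1:60, 1), TRUE)
    expect_identical(decode_rle(encode_rle(st)), st)
  }
  expect_error(decode_rle("2x1"), "malformed")
})

test_that("encode_read reports CpG states, variants and deletions", {
  #      1234567890
  g <- "AAACGTACGA"
  packed <- pack_reference(reference(c(chr1 = g)))
  rec <- data.table::data.table(
    qname = "r1", flag = 0L, rname = "chr1", pos = 1L, mapq = 60L,
    cigar = "10M", rnext = "*", pnext = 0L, tlen = 0L,
    seq = "AAACGTATGA",       # CpG at 4 retained; CpG at 8 converted
    qual = strrep("F", 10), nm = 0L, as_score = 10L, xs = 0L,
    zs = "++", xa = NA_character_, xb = 0L, zc = 1L, tag = "OT",
    cls = "C2T", ambiguous = FALSE, ref_end = 10L, dup = FALSE)
  eb <- encode_read(rec, packed)
  expect_equal(decode_rle(eb$rle_meth),
               c("x", "x", "x", "M", "x", "x", "x", "U", "x", "x"))
  expect_equal(eb$start, 0L)
  expect_equal(eb$end, 10L)

  # a G/C SNP covered by a G->A-strand read showing A reports R
  rec2 <- data.table::copy(rec)
  rec2[, `:=`(seq = "AAACATACGA", cls = "G2A", tag = "CTOB", zs = "--")]
  sites <- data.table::data.table(contig = "chr1", pos = 5L)
  eb2 <- encode_read(rec2, packed, variant_sites = sites)
  expect_equal(decode_rle(eb2$rle_var)[5], "R")
  # the same SNP site on a C->T read showing T reports Y
  rec3 <- data.table::copy(rec)
  rec3[, seq := "AAACTTACGA"]
  sites3 <- data.table::data.table(contig = "chr1", pos = 5L)
  eb3 <- encode_read(rec3, packed, variant_sites = sites3)
  expect_equal(decode_rle(eb3$rle_var)[5], "Y")

  # deletions appear as D in both channels; insertions in the side field
  rec4 <- data.table::copy(rec)
  rec4[, `:=`(cigar = "4M2D4M2I", seq = "AAACTACGAA",
              ref_end = 10L)]
  eb4 <- encode_read(rec4, packed, variant_sites = sites)
  expect_equal(decode_rle(eb4$rle_meth)[5:6], c("D", "D"))
  expect_match(eb4$ins, "^11:")

  # low-quality bases are filtered to F
  rec5 <- data.table::copy(rec)
  q <- strsplit(rec5$qual, "")[[1]]; q[4] <- "#"
  rec5[, qual := paste(q, collapse = "")]
  eb5 <- encode_read(rec5, packed)
  expect_equal(decode_rle(eb5$rle_meth)[4], "F")
})

test_that("encode/decode is the identity on simulated reads", {
  al <- .small_aligned()
  rec <- al$recs[!bitwAnd(flag, 4L) & mapq >= 40][1:400]
  for (i in seq_len(nrow(rec))) {
    eb <- encode_read(rec[i], al$packed)
    dec <- decode_epibed(eb)
    expect_equal(length(dec$meth), eb$end - eb$start)
    expect_identical(encode_rle(dec$meth), eb$rle_meth)
  }
})

test_that("mate merging is overlap-aware, conflict-filtered, commutative", {
  g <- paste(rep("ACGT", 10), collapse = "")
  packed <- pack_reference(reference(c(chr1 = g)))
  mk <- function(name, pos, seq, flag) data.table::data.table(
    qname = name, flag = flag, rname = "chr1", pos = pos, mapq = 60L,
    cigar = paste0(nchar(seq), "M"), rnext = "=", pnext = 0L, tlen = 0L,
    seq = seq, qual = strrep("F", nchar(seq)), nm = 0L,
    as_score = nchar(seq), xs = 0L, zs = "++", xa = NA_character_,
    xb = 0L, zc = 0L, tag = "OT", cls = "C2T", ambiguous = FALSE,
    ref_end = pos + nchar(seq) - 1L, dup = FALSE)
  # overlapping mates: both retain the CpG at 10 -> kept once
  r1 <- encode_read(mk("m", 6L, substr(g, 6, 17), 64L + 1L), packed)
  r2 <- encode_read(mk("m", 10L, substr(g, 10, 21), 128L + 1L), packed)
  merged <- merge_mates(r1, r2)
  expect_equal(merged$start, 5L)
  expect_equal(merged$end, 21L)
  st <- decode_epibed(merged)$meth
  expect_equal(sum(st == "M"), length(unique(c(
    which(decode_epibed(r1)$meth == "M") + r1$start,
    which(decode_epibed(r2)$meth == "M") + r2$start))))
  # commutative
  expect_identical(merge_mates(r2, r1)[, -"mate"], merged[, -"mate"])
  # conflicting M/U -> F
  rec_conv <- mk("m", 10L, chartr("C", "T", substr(g, 10, 21)), 128L + 1L)
  r2c <- encode_read(rec_conv, packed)
  conflicted <- merge_mates(r1, r2c)
  stc <- decode_epibed(conflicted)$meth
  overlap_cpg <- which(decode_epibed(r1)$meth == "M") + r1$start
  overlap_cpg <- overlap_cpg[overlap_cpg > r2c$start & overlap_cpg <= r2c$end]
  expect_true(all(stc[overlap_cpg - conflicted$start] == "F"))
  # disjoint mates: concatenated with an x gap
  r3 <- encode_read(mk("m", 25L, substr(g, 25, 32), 128L + 1L), packed)
  dis <- merge_mates(r1, r3)
  gap <- decode_epibed(dis)$meth[(r1$end - dis$start + 1L):(r3$start - dis$start)]
  expect_true(all(gap == "x"))
})

test_that("epiBED files round-trip losslessly", {
  al <- .small_aligned()
  eb <- epibed_from_records(al$recs[1:60], al$packed)
  path <- tempfile(fileext = ".epibed")
  write_epibed(eb, path)
  back <- read_epibed(path)
  data.table::setorder(eb, chrom, start, read)
  expect_equal(back$rle_meth, eb$rle_meth)
  expect_equal(back$start, eb$start)
  expect_equal(back$read, eb$read)
  # gzip round trip
  pgz <- tempfile(fileext = ".epibed.gz")
  write_epibed(eb, pgz)
  expect_equal(read_epibed(pgz)$rle_meth, eb$rle_meth)
})

test_that("matrix column betas agree with the pileup (no double counting)", {
  al <- .small_aligned()
  recs <- al$recs[!bitwAnd(flag, 4L)]
  eb <- epibed_from_records(recs, al$packed, merge = TRUE)
  L <- al$packed$lengths[[1]]
  mat <- to_matrix(eb, "chr1", 1L, L)
  obs <- pileup(recs, al$packed, min_baseq = 20L)
  mt <- meth_table(obs, al$packed)
  checked <- 0L
  for (j in seq_along(mat$positions)) {
    target <- mat$positions[j]
    st <- mat$meth[, j]
    if (any(st == "F", na.rm = TRUE)) next  # mate-conflict-filtered columns
    m <- sum(st == "M", na.rm = TRUE); u <- sum(st == "U", na.rm = TRUE)
    row <- mt[pos == target]
    if (nrow(row) == 1 && m + u > 0) {
      expect_equal(m, row$M, info = paste("pos", target))
      expect_equal(u, row$U, info = paste("pos", target))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50)
})

test_that("the ASM Fisher test matches the exact hypergeometric", {
  # 10 reads allele G all U, 10 reads allele C all M at one CpG
  snp <- matrix(c(rep("G", 10), rep("C", 10)), ncol = 1,
                dimnames = list(NULL, "50"))
  meth <- matrix(c(rep("U", 10), rep("M", 10)), ncol = 1,
                 dimnames = list(NULL, "60"))
  mat <- structure(list(meth = meth, snp = snp, positions = 60L,
                        snp_positions = 50L), class = "read_state_matrix")
  res <- asm_test(mat, 50L, min_reads_per_allele = 3L)
  expect_true(res$tested)
  expect_equal(sort(c(res$beta1, res$beta2)), c(0, 1))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value, fisher_oracle(res$m1, res$u1, res$m2, res$u2),
               tolerance = 1e-9)
  # identical methylation -> p = 1
  meth2 <- matrix(rep("M", 20), ncol = 1, dimnames = list(NULL, "60"))
  mat2 <- structure(list(meth = meth2, snp = snp, positions = 60L,
                         snp_positions = 50L), class = "read_state_matrix")
  expect_equal(asm_test(mat2, 50L)$p_value, 1)
  # below min_reads_per_allele -> untested
  snp3 <- matrix(c(rep("G", 2), rep("C", 18)), ncol = 1,
                 dimnames = list(NULL, "50"))
  mat3 <- structure(list(meth = meth, snp = snp3, positions = 60L,
                         snp_positions = 50L), class = "read_state_matrix")
  expect_false(asm_test(mat3, 50L)$tested)
})

test_that("allele-specific methylation is recovered end to end", {
  # construct a locus where the C allele is methylated and the T allele not
  set.seed(500)
  g <- rand_genome(900, seed = 501)
  # ensure a CpG near position 450 and a SNP site at 470
  substr(g, 450, 451) <- "CG"
  substr(g, 470, 470) <- "A"
  packed <- pack_reference(reference(c(chr1 = g)))
  idx <- build_indexes(reference(c(chr1 = g)))
  reads <- list()
  for (i in 1:12) {
    frag <- substr(g, 421, 520)
    if (i <= 6) {        # allele A (ref), unmethylated: CpG converted
      s <- chartr("C", "T", frag)
    } else {             # allele G at 470, methylated CpG retained
      substr(frag, 50, 50) <- "G"
      conv <- chartr("C", "T", frag)
      substr(conv, 30, 30) <- "C"   # keep the CpG C at 450
      substr(conv, 50, 50) <- "G"
      s <- conv
    }
    reads[[i]] <- data.table::data.table(name = paste0("rd", i), seq = s,
                                         qual = strrep("F", 100))
  }
  tbl <- data.table::rbindlist(reads)
  recs <- align_reads_table(tbl, idx, packed)
  expect_true(all(!bitwAnd(recs$flag, 4L)))
  eb <- epibed_from_records(recs, packed, merge = FALSE,
                            variant_sites = data.table::data.table(
                              contig = "chr1", pos = 470L))
  mat <- to_matrix(eb, "chr1", 400L, 520L, include_snps = TRUE)
  res <- asm_test(mat, 470L)
  row <- res[pos == 450L]
  expect_true(row$tested)
  expect_lt(row$p_value, 0.01)
  expect_equal(abs(row$beta1 - row$beta2), 1)
})
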