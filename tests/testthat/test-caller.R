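obs_row <- function(base, cls, pos = 10L, qname = paste0("r", seq_along(base)),
                    qual = 37L) {
  data.table::data.table(qname = qname, mate = 1L, contig = "chr1",
                         pos = pos, base = base, qual = qual,
                         cls = cls, tag = ifelse(cls == "C2T", "OT", "OB"),
                         cycle = 1L)
}

test_that("six-letter support maps converted-strand reads to Y and R", {
  col <- obs_row(c("T", "A", "T", "C", "G"),
                 c("C2T", "G2A", "G2A", "C2T", "C2T"))
  sup <- sixletter_support(col)
  expect_equal(sup[["Y"]], 1L)  # T on a C->T strand is ambiguous
  expect_equal(sup[["R"]], 1L)  # A on a G->A strand is ambiguous
  expect_equal(sup[["T"]], 1L)  # T on a G->A strand is unambiguous
  expect_equal(sup[["C"]], 1L)
  expect_equal(sup[["G"]], 1L)
  expect_equal(sup[["A"]], 0L)
})

test_that("the four Y-reduction rules hold (and R mirror-wise)", {
  # rule 1: unambiguous evidence for exactly one of C/T
  expect_equal(reduce_support(c(Y = 5, C = 3, T = 0), "C"),
               c(A = 0L, C = 8L, G = 0L, T = 0L))
  expect_equal(reduce_support(c(Y = 5, C = 0, T = 2), "A"),
               c(A = 0L, C = 0L, G = 0L, T = 7L))
  # rule 2: evidence for both -> Y ignored
  expect_equal(reduce_support(c(Y = 5, C = 3, T = 2), "C"),
               c(A = 0L, C = 3L, G = 0L, T = 2L))
  # rule 3: no evidence, ref not C/T -> Y ignored
  expect_equal(reduce_support(c(Y = 5), "A"),
               c(A = 0L, C = 0L, G = 0L, T = 0L))
  # rule 4: no evidence, ref C or T -> Y goes to the reference
  expect_equal(reduce_support(c(Y = 5), "T"),
               c(A = 0L, C = 0L, G = 0L, T = 5L))
  expect_equal(reduce_support(c(Y = 5), "C"),
               c(A = 0L, C = 5L, G = 0L, T = 0L))
  # R mirrors over A/G
  expect_equal(reduce_support(c(R = 4, G = 2), "T"),
               c(A = 0L, C = 0L, G = 6L, T = 0L))
  expect_equal(reduce_support(c(R = 4, A = 1, G = 2), "G"),
               c(A = 1L, C = 0L, G = 2L, T = 0L))
  expect_equal(reduce_support(c(R = 4), "C"),
               c(A = 0L, C = 0L, G = 0L, T = 0L))
  expect_equal(reduce_support(c(R = 4), "A"),
               c(A = 4L, C = 0L, G = 0L, T = 0L))
})

test_that("reduction conserves mass over random supports", {
  set.seed(404)
  for (i in 1:2000) {
    sup <- setNames(as.integer(rpois(6, 3)), c("A", "C", "G", "T", "R", "Y"))
    ref <- sample(c("A", "C", "G", "T"), 1)
    red <- reduce_support(sup, ref)
    base_total <- sum(sup[c("A", "C", "G", "T")])
    expect_gte(sum(red), base_total)
    expect_lte(sum(red), sum(sup))
    # A and G unchanged by Y handling, C and T unchanged by R handling
    supY <- sup; supY[["R"]] <- 0L
    redY <- reduce_support(supY, ref)
    expect_equal(redY[["A"]], sup[["A"]])
    expect_equal(redY[["G"]], sup[["G"]])
  }
})

test_that("genotype model calls obvious sites and normalizes posteriors", {
  p <- genotype_params(error_rate = 0.01, contamination = 0,
                       theta = 1e-3)
  hom <- genotype_call(c(A = 20), "A", p)
  expect_equal(hom$genotype, "A/A")
  expect_gt(hom$gq, 30)
  expect_equal(sum(hom$posterior), 1, tolerance = 1e-9)

  het <- genotype_call(c(A = 10, G = 10), "A", p)
  expect_equal(het$genotype, "A/G")

  none <- genotype_call(c(A = 0), "A", p)
  expect_true(is.na(none$genotype))

  # posterior is invariant to observation order by construction (counts);
  # argmax matches a direct numeric evaluation of all 10 posteriors
  counts <- c(A = 7, C = 0, G = 3, T = 0)
  gts <- list(c("A","A"), c("A","C"), c("A","G"), c("A","T"), c("C","C"),
              c("C","G"), c("C","T"), c("G","G"), c("G","T"), c("T","T"))
  e <- 0.01; th <- 1e-3
  pba <- function(b, a) ifelse(b == a, 1 - e, e / 3)
  ll <- vapply(gts, function(g) {
    sum(vapply(names(counts), function(b)
      counts[[b]] * log(0.5 * pba(b, g[1]) + 0.5 * pba(b, g[2])),
      numeric(1)))
  }, numeric(1))
  prior <- rep(th / 6, 10); prior[1] <- 1 - 1.5 * th
  post <- exp(ll + log(prior)); post <- post / sum(post)
  oracle_gt <- paste(gts[[which.max(post)]], collapse = "/")
  got <- genotype_call(counts, "A", p)
  expect_equal(got$genotype, oracle_gt)
  expect_equal(unname(got$posterior[got$genotype]), max(post),
               tolerance = 1e-9)
})

test_that("pileup excludes duplicates/low-MAPQ and dedups mate overlap", {
  cfg <- sim_config(genome_length = 3000, depth = 8, rng_seed = 777,
                    insert_mean = 150, insert_sd = 5)  # overlapping mates
  sim <- run_simulation(cfg)
  packed <- pack_reference(sim$ref)
  recs <- truth_records(sim)
  obs <- pileup(recs, packed)
  # overlapping mates contribute at most one observation per position
  expect_equal(anyDuplicated(obs[, .(qname, contig, pos)]), 0)
  # duplicate-flagged and low-MAPQ records are excluded
  recs2 <- data.table::copy(recs)
  recs2[1, `:=`(dup = TRUE, flag = flag + 1024L)]   # mate 1 duplicate
  recs2[2, mapq := 10L]                             # its mate low MAPQ
  obs2 <- pileup(recs2, packed)
  expect_equal(obs2[qname == recs2$qname[1], .N], 0)
  # 8x simulated locus: mean depth close to nominal
  depth <- obs[, .N, by = .(contig, pos)]
  expect_gt(mean(depth$N), 8 * 0.6)
  expect_lt(mean(depth$N), 8 * 1.2)
})

test_that("methylation calls recover context, counts and beta", {
  # ...ACGT...: one CpG with 3 retained + 1 converted observation
  g <- "AAAAACGTTTTT"
  packed <- pack_reference(reference(c(chr1 = g)))
  col <- obs_row(c("C", "C", "C", "T"), "C2T", pos = 6L)
  call <- call_methylation(col, packed, "WGBS")
  expect_equal(call$context, "CpG")
  expect_equal(call$M, 3L)
  expect_equal(call$U, 1L)
  expect_equal(call$beta, 0.75)
  expect_equal(call$strand, "+")
  # the G of the same CpG on the minus strand, informed by G2A reads
  colm <- obs_row(c("G", "A"), "G2A", pos = 7L)
  callm <- call_methylation(colm, packed, "WGBS")
  expect_equal(callm$context, "CpG")
  expect_equal(callm$strand, "-")
  expect_equal(callm$beta, 0.5)
  # CpH contexts are split
  colh <- obs_row("C", "C2T", pos = 5L)  # AC -> next base C? g[5]=A
  # g = A A A A A C G T T T T T ; pos 5 is A -> not a cytosine, no call
  expect_null(call_methylation(colh, packed, "WGBS"))
})

test_that("NOMe mode excludes GCG, flags CCG, and splits channels", {
  #        123456789012345
  g <- "AAGCGAAGCAACCGAA"
  # GCG at 3-5 (C at 4, excluded); GCH at 8-10 (C at 9, accessibility);
  # CCG at 12-14 (C at 13, HCG with CCG flag)
  packed <- pack_reference(reference(c(chr1 = g)))
  obs <- rbind(obs_row("C", "C2T", pos = 4L, qname = "a"),
               obs_row("C", "C2T", pos = 9L, qname = "b"),
               obs_row("C", "C2T", pos = 13L, qname = "c"))
  mt <- meth_table(obs, packed, assay = "NOMe")
  expect_false(4L %in% mt$pos)              # GCG excluded
  expect_equal(mt[pos == 9L, context], "GCH")
  expect_equal(mt[pos == 13L, context], "HCG")
  expect_equal(mt[pos == 13L, flag], "CCG") # retained but flagged
})

test_that("VCF and BED emission follow the documented dialects", {
  al <- .small_aligned()
  obs <- pileup(al$recs, al$packed)
  gt <- call_genotypes(obs, al$packed)
  mt <- meth_table(obs, al$packed)
  calls <- pileup_calls(gt, mt, al$packed)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_gt(length(body), 0)
  back <- read_vcf(vcf)
  # genotypes survive the round trip at cytosine/variant sites
  common <- merge(back$gt, gt, by = c("contig", "pos"))
  expect_gt(nrow(common), 0)
  expect_equal(common$gt.x, common$gt.y)
  expect_equal(common$dp.x, common$dp.y)

  bed <- vcf2bed(calls, "cg", min_depth = 1)
  expect_equal(names(bed), c("chrom", "start", "end", "beta", "depth"))
  expect_true(all(bed$end == bed$start + 1L))          # 0-based half-open
  cg <- mt[context == "CpG"][order(contig, pos)]
  expect_equal(nrow(bed), nrow(cg))
  expect_equal(bed$depth, cg[, M + U])
  # depth filter drops shallow rows
  expect_true(all(vcf2bed(calls, "cg", min_depth = 5)$depth >= 5))
  # snp channel emits only non-hom-ref calls
  snp <- vcf2bed(calls, "snp")
  expect_true(all(snp$gt != "0/0"))
})

test_that("vcf2bed single-site example emits the documented row", {
  packed <- pack_reference(reference(c(chr1 = strrep("A", 99))))
  calls <- pileup_calls(
    data.table::data.table(contig = character(), pos = integer(),
                           ref = character(), gt = character(),
                           gq = numeric(), dp = integer(), sp = character()),
    data.table::data.table(contig = "chr1", pos = 101L, strand = "+",
                           context = "CpG", flag = "", M = 3L, U = 1L,
                           beta = 0.75),
    packed)
  row <- vcf2bed(calls, "cg")
  expect_equal(unname(unlist(row[1, .(chrom, start, end, beta, depth)])),
               c("chr1", "100", "101", "0.75", "4"))
  expect_equal(nrow(vcf2bed(calls, "cg", min_depth = 5)), 0)
})

test_that("two-tier GQ filter applies the common-SNP prior rules", {
  gt <- data.table::data.table(
    contig = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", gt = c("A/G", "A/G", "G/G", "A/A", "A/G"),
    gq = c(20, 20, 70, 99, 4), dp = 30L, sp = "")
  common <- GenomicRanges::GRanges("chr1", IRanges::IRanges(95, 105),
                                   score = 0.1)
  excl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(295, 305))
  kept <- filter_variants(gt, common, excl)
  # pos 100: GQ 20 in common track (MAF 0.1) -> kept
  expect_true(100L %in% kept$pos)
  # pos 200: GQ 20, not common -> needs >= 60 -> dropped
  expect_false(200L %in% kept$pos)
  # pos 300: GQ 70 but inside exclusion -> dropped
  expect_false(300L %in% kept$pos)
  # pos 400: hom-ref -> dropped; pos 500: below hard floor -> dropped
  expect_false(400L %in% kept$pos)
  expect_false(500L %in% kept$pos)
  # MAF below the floor disqualifies the common tier
  rare <- GenomicRanges::GRanges("chr1", IRanges::IRanges(95, 105),
                                 score = 0.01)
  expect_false(100L %in% filter_variants(gt, rare, excl)$pos)
  # canonical-contig restriction
  gt2 <- data.table::copy(gt)[1, contig := "chrUn"]
  expect_false("chrUn" %in%
                 filter_variants(gt2, common, excl,
                                 canonical_contigs = "chr1")$contig)
})
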