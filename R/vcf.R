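# VCF 4.2 / BED emission and the two-tier genotype-quality variant filter.

#' Bundle pileup calls for serialization
#'
#' @param gt genotype table from [call_genotypes()].
#' @param meth methylation table from [meth_table()] (may be empty).
#' @param packed packed reference.
#' @param assay assay label recorded in the header.
#' @return a list of class `pileup_calls`.
#' @export
pileup_calls <- function(gt, meth, packed, assay = "WGBS") {
  structure(list(gt = gt, meth = meth, contigs = packed$contigs,
                 contig_lengths = packed$lengths, assay = assay),
            class = "pileup_calls")
}

.gt_vcf_fields <- function(ref, gt) {
  a1 <- sub("/.*", "", gt); a2 <- sub(".*/", "", gt)
  alt <- character(length(gt)); gtf <- character(length(gt))
  for (i in seq_along(gt)) {
    alleles <- unique(c(a1[i], a2[i]))
    alts <- setdiff(alleles, ref[i])
    alt[i] <- if (length(alts)) paste(alts, collapse = ",") else "."
    idx <- match(c(a1[i], a2[i]), c(ref[i], alts)) - 1L
    gtf[i] <- paste(sort(idx), collapse = "/")
  }
  list(alt = alt, gt = gtf)
}

#' Write pileup calls as VCF 4.2
#'
#' Variant records carry FORMAT `GT:GQ:DP:SP` (SP is the six-letter support
#' "A:C:G:T:R:Y"); cytosine records additionally carry INFO `CX` (context)
#' and FORMAT fields `RT`/`CV` (retained/converted counts). Output is plain
#' text, bgzip-compatible.
#'
#' @param calls a [pileup_calls()] object.
#' @param path output path.
#' @param sample sample name for the header.
#' @param all_sites emit genotype records for every covered site (default:
#'   variant and cytosine sites only).
#' @export
write_vcf <- function(calls, path, sample = "sample1", all_sites = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=methsuite-0.1.0",
           paste0("##contig=<ID=", calls$contigs, ",length=",
                  calls$contig_lengths[calls$contigs], ">"),
           "##INFO=<ID=CX,Number=1,Type=String,Description=\"Cytosine context\">",
           "##INFO=<ID=N5,Number=0,Type=Flag,Description=\"NOMe CCG off-target context\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth after reduction\">",
           "##FORMAT=<ID=SP,Number=1,Type=String,Description=\"Six-letter support A:C:G:T:R:Y\">",
           "##FORMAT=<ID=RT,Number=1,Type=Integer,Description=\"Retained cytosines\">",
           "##FORMAT=<ID=CV,Number=1,Type=Integer,Description=\"Converted cytosines\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  gt <- calls$gt[!is.na(gt)]
  if (!all_sites) {
    hom_ref <- gt$gt == paste(gt$ref, gt$ref, sep = "/")
    cyt_key <- unique(calls$meth[, paste0(contig, ":", pos)])
    gt <- gt[!hom_ref | paste0(contig, ":", pos) %in% cyt_key]
  }
  meth_key <- calls$meth[, .(key = paste0(contig, ":", pos), context, flag,
                             M, U, strand)]
  lines <- character(0)
  if (nrow(gt)) {
    vf <- .gt_vcf_fields(gt$ref, gt$gt)
    key <- paste0(gt$contig, ":", gt$pos)
    mi <- match(key, meth_key$key)
    info <- ifelse(is.na(mi), ".",
                   paste0("CX=", meth_key$context[mi],
                          ifelse(meth_key$flag[mi] == "CCG", ";N5", "")))
    fmt <- ifelse(is.na(mi), "GT:GQ:DP:SP", "GT:GQ:DP:SP:RT:CV")
    val <- paste(vf$gt, round(gt$gq), gt$dp, gt$sp, sep = ":")
    val <- ifelse(is.na(mi), val,
                  paste(val, meth_key$M[mi], meth_key$U[mi], sep = ":"))
    lines <- paste(gt$contig, gt$pos, ".", gt$ref, vf$alt, ".", "PASS",
                   info, fmt, val, sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Convert pileup calls to BED
#'
#' Methylation channels emit `chrom start0 end beta depth`; the `snp`
#' channel emits `chrom start0 end ref alt GT GQ` for non-hom-ref calls.
#' Coordinates become 0-based half-open here, at serialization.
#'
#' @param calls a [pileup_calls()] object.
#' @param channel one of `cg`, `ch`, `gch`, `hcg`, `snp`.
#' @param min_depth rows below this depth are dropped.
#' @param path optional output path (TSV without header).
#' @param keep_ccg for NOMe channels, keep CCG-flagged rows (default TRUE;
#'   set FALSE for post-hoc filtering of the off-target context).
#' @return the BED rows as a `data.table` (invisibly written when `path`
#'   is given).
#' @export
vcf2bed <- function(calls, channel = c("cg", "ch", "gch", "hcg", "snp"),
                    min_depth = 1L, path = NULL, keep_ccg = TRUE) {
  channel <- match.arg(channel)
  if (channel == "snp") {
    gt <- calls$gt[!is.na(gt) & gt != paste(ref, ref, sep = "/")]
    vf <- .gt_vcf_fields(gt$ref, gt$gt)
    out <- data.table(chrom = gt$contig, start = gt$pos - 1L, end = gt$pos,
                      ref = gt$ref, alt = vf$alt, gt = vf$gt,
                      gq = round(gt$gq))
  } else {
    m <- calls$meth
    m <- switch(channel,
                cg = m[context == "CpG"],
                ch = m[context %in% c("CpA", "CpC", "CpT")],
                gch = m[context == "GCH"],
                hcg = m[context == "HCG"])
    if (!keep_ccg) m <- m[flag != "CCG"]
    m <- m[M + U >= min_depth]
    out <- data.table(chrom = m$contig, start = m$pos - 1L, end = m$pos,
                      beta = round(m$M / (m$M + m$U), 4), depth = m$M + m$U)
  }
  setorder(out, chrom, start)
  if (!is.null(path)) fwrite(out, path, sep = "\t", col.names = FALSE)
  out[]
}

#' Read a BED interval file
#'
#' Three required columns (chrom, 0-based start, end); a numeric fourth
#' column, when present, is interpreted as a score (e.g. minor allele
#' frequency for a common-SNP track).
#'
#' @param path BED path (plain or gzipped).
#' @return a `GRanges` with optional `score` metadata column.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1]],
    ranges = IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]))
  if (ncol(dt) >= 4 && is.numeric(dt[[4]])) S4Vectors::mcols(gr)$score <- dt[[4]]
  gr
}

.as_granges_track <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1) return(read_bed(x))
  stop("interval track must be a GRanges or a BED path")
}

#' Two-tier genotype-quality variant filter with a common-SNP prior
#'
#' Applies the post-hoc SNV filter: drop calls with GQ at or below the hard
#' floor, hom-ref calls and calls on non-canonical contigs; drop calls
#' inside the exclusion track; then keep a call if it intersects a
#' common-SNP interval with minor allele frequency at least `maf_floor`
#' and has GQ >= `gq_common`, or otherwise has GQ >= `gq_other`.
#'
#' @param gt genotype table ([call_genotypes()] output).
#' @param common_snps common-SNP track: `GRanges` (optional `score` = MAF)
#'   or a BED path with MAF in column 4.
#' @param exclusion exclusion-list track (`GRanges` or BED path), or NULL.
#' @param gq_common GQ threshold for calls backed by a common SNP.
#' @param gq_other GQ threshold for all other calls.
#' @param maf_floor minimum MAF for the common-SNP tier.
#' @param gq_hard_floor calls with GQ <= this are always dropped.
#' @param canonical_contigs contigs to keep (NULL keeps all).
#' @return the filtered genotype table.
#' @export
filter_variants <- function(gt, common_snps = NULL, exclusion = NULL,
                            gq_common = 15, gq_other = 60, maf_floor = 0.05,
                            gq_hard_floor = 5, canonical_contigs = NULL) {
  v <- gt[!is.na(gt) & gt != paste(ref, ref, sep = "/") & gq > gq_hard_floor]
  if (!is.null(canonical_contigs)) v <- v[contig %in% canonical_contigs]
  if (!nrow(v)) return(v)
  vr <- GenomicRanges::GRanges(v$contig, IRanges::IRanges(v$pos, v$pos))
  excl <- .as_granges_track(exclusion)
  if (length(excl)) {
    v <- v[!IRanges::overlapsAny(vr, excl)]
    vr <- vr[!IRanges::overlapsAny(vr, excl)]
  }
  common <- .as_granges_track(common_snps)
  if (length(common) && !is.null(S4Vectors::mcols(common)$score))
    common <- common[S4Vectors::mcols(common)$score >= maf_floor]
  in_common <- IRanges::overlapsAny(vr, common)
  v[(in_common & gq >= gq_common) | (!in_common & gq >= gq_other)]
}

#' Read a VCF written by [write_vcf()] back into call tables
#'
#' Light parser for this toolkit's own pileup VCF dialect.
#'
#' @param path VCF path.
#' @return a list of class `pileup_calls` with `gt` and `meth` tables
#'   (methylation rows only for records carrying RT/CV fields; strand is
#'   not stored in the VCF and is returned as NA).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  contig_lines <- lines[startsWith(lines, "##contig")]
  contigs <- sub(".*ID=([^,>]+).*", "\\1", contig_lines)
  clen <- as.integer(sub(".*length=([0-9]+).*", "\\1", contig_lines))
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    gt <- data.table(contig = character(), pos = integer(),
                     ref = character(), gt = character(), gq = numeric(),
                     dp = integer(), sp = character())
    meth <- data.table(contig = character(), pos = integer(),
                       strand = character(), context = character(),
                       flag = character(), M = integer(), U = integer(),
                       beta = numeric())
    return(structure(list(gt = gt, meth = meth, contigs = contigs,
                          contig_lengths = setNames(clen, contigs),
                          assay = "unknown"), class = "pileup_calls"))
  }
  p <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(p, `[[`, character(1), i)
  chrom <- getf(1); pos <- as.integer(getf(2)); ref <- getf(4)
  alt <- getf(5); info <- getf(8); fmt <- getf(9); val <- getf(10)
  vparts <- strsplit(val, ":", fixed = TRUE)
  fparts <- strsplit(fmt, ":", fixed = TRUE)
  pull <- function(key) {
    mapply(function(f, v) {
      i <- match(key, f)
      if (is.na(i)) NA_character_ else v[i]
    }, fparts, vparts, USE.NAMES = FALSE)
  }
  gtf <- pull("GT"); gq <- as.numeric(pull("GQ")); dp <- as.integer(pull("DP"))
  sp <- pull("SP")
  rt <- suppressWarnings(as.integer(pull("RT")))
  cv <- suppressWarnings(as.integer(pull("CV")))
  # decode numeric GT back to allele letters
  alleles <- mapply(function(r, a, g) {
    all <- c(r, strsplit(a, ",", fixed = TRUE)[[1]])
    idx <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]]) + 1L
    paste(sort(all[idx]), collapse = "/")
  }, ref, alt, gtf, USE.NAMES = FALSE)
  gt <- data.table(contig = chrom, pos = pos, ref = ref, gt = alleles,
                   gq = gq, dp = dp, sp = sp)
  has_meth <- !is.na(rt)
  cx <- rep(NA_character_, length(pos))
  hit <- grepl("CX=", info)
  cx[hit] <- sub(".*CX=([^;]+).*", "\\1", info[hit])
  meth <- data.table(contig = chrom[has_meth], pos = pos[has_meth],
                     strand = NA_character_, context = cx[has_meth],
                     flag = ifelse(grepl("(^|;)N5($|;)", info[has_meth]),
                                   "CCG", ""),
                     M = rt[has_meth], U = cv[has_meth])
  meth[, beta := ifelse(M + U > 0, M / (M + U), NA_real_)]
  structure(list(gt = gt, meth = meth, contigs = contigs,
                 contig_lengths = setNames(clen, contigs),
                 assay = "unknown"), class = "pileup_calls")
}
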