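# Bisulfite-aware seed-and-extend aligner.
#
# Reads are in-silico converted (C->T and/or G->A), seeded by maximal exact
# matches against the corresponding 3-base FM-index, filtered for 4-base
# reference compatibility, chained by genomic proximity, and extended
# against the packed 4-base reference with a conversion-asymmetric
# substitution score: a read T may align to a reference C (C->T strands)
# and a read A to a reference G (G->A strands) penalty-free, never the
# reverse.
#
# The per-read pipeline works on plain vectors (the `.x_core` helpers);
# data.tables are only assembled at the API boundary.

#' Alignment scoring and seeding parameters
#'
#' BWA-MEM-style defaults; every knob is user-settable.
#'
#' @param match match score (positive).
#' @param mismatch mismatch penalty (positive; subtracted).
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param band_width band half-width for the banded extension DP.
#' @param min_seed_len minimum seed (maximal exact match) length; at least 10.
#' @param max_top_chains number of best-scoring chains visited for extension.
#' @param max_total_chains upper bound on chains considered when few pass
#'   the 4-base compatibility filter.
#' @param max_xa_hits alternate alignments are listed in the XA tag only
#'   when their count does not exceed this; the count always goes to XB.
#' @param max_chain_gap maximum reference/read gap between chained seeds.
#' @param max_seed_hits per-seed cap on located occurrences.
#' @param pair_bonus score bonus for a properly oriented pair within the
#'   insert model.
#' @return a list of class `scoring_params`.
#' @export
scoring_params <- function(match = 1L, mismatch = 4L, gap_open = 6L,
                           gap_extend = 1L, band_width = 100L,
                           min_seed_len = 19L, max_top_chains = 50L,
                           max_total_chains = 100L, max_xa_hits = 5L,
                           max_chain_gap = 100L, max_seed_hits = 64L,
                           pair_bonus = 10L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0,
            min_seed_len >= 10, band_width >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 band_width = as.integer(band_width),
                 min_seed_len = as.integer(min_seed_len),
                 max_top_chains = as.integer(max_top_chains),
                 max_total_chains = as.integer(max_total_chains),
                 max_xa_hits = as.integer(max_xa_hits),
                 max_chain_gap = as.integer(max_chain_gap),
                 max_seed_hits = as.integer(max_seed_hits),
                 pair_bonus = as.integer(pair_bonus)),
            class = "scoring_params")
}

#' A sequencing read
#'
#' @param name read name.
#' @param seq base sequence over A/C/G/T/N.
#' @param qual per-base Phred qualities as a SAM quality string; defaults to
#'   constant Phred 37.
#' @param mate 1, 2 or 0 (unpaired).
#' @return a list of class `bs_read`.
#' @export
bs_read <- function(name, seq, qual = NULL, mate = 0L) {
  seq <- toupper(seq)
  if (nchar(seq) < 1) stop("read length must be >= 1")
  if (is.null(qual)) qual <- strrep("F", nchar(seq))
  if (nchar(qual) != nchar(seq)) stop("|qualities| must equal |sequence|")
  structure(list(name = name, seq = seq, qual = qual, mate = as.integer(mate)),
            class = "bs_read")
}

#' In-silico conversion hypotheses for a read
#'
#' Directional libraries constrain mate 1 to original strands (searched
#' C->T in the C-less index, covering OT and OB) and mate 2 to their PCR
#' complements (searched G->A in the G-less index, covering CTOT and CTOB);
#' non-directional mode searches both conversions for every mate.
#'
#' @param read a [bs_read()].
#' @param mode `"directional"` or `"non_directional"`.
#' @return a list of hypotheses, each with `converted` (sequence) and
#'   `kind` (target index).
#' @export
convert_read <- function(read, mode = c("directional", "non_directional")) {
  mode <- match.arg(mode)
  hyp <- list(
    list(converted = convert_seq(read$seq, "C_LESS"), kind = "C_LESS"),
    list(converted = convert_seq(read$seq, "G_LESS"), kind = "G_LESS"))
  if (mode == "directional") {
    hyp <- if (identical(read$mate, 2L)) hyp[2] else hyp[1]
  }
  hyp
}

.tag_for_hit <- function(kind, strand) {
  ifelse(kind == "C_LESS" & strand == "+", "OT",
  ifelse(kind == "C_LESS", "OB",
  ifelse(strand == "+", "CTOB", "CTOT")))
}

# oriented read codes for a strand
oriented_codes <- function(read, strand) {
  if (strand == "+") read_to_codes(read$seq) else
    read_to_codes(revcomp(read$seq))
}

# seeds as plain vectors (oriented read coordinates)
.seeds_core <- function(read, indexes, params, mode) {
  m <- nchar(read$seq)
  off <- integer(0); len <- integer(0); contig <- character(0)
  rstart <- integer(0); strand <- character(0); tag <- character(0)
  for (h in convert_read(read, mode)) {
    idx <- indexes[[h$kind]]
    pat <- read_to_codes(h$converted)
    res <- fm_seeds_cpp(idx$bwt, idx$occ, idx$C, idx$occ_spacing,
                        idx$sa_sample, pat, params$min_seed_len,
                        params$max_seed_hits)
    if (!length(res$read_offset)) next
    gm <- text_span_to_genome(idx, res$text_pos, res$length)
    keep <- !is.na(gm$contig)
    if (!any(keep)) next
    st <- gm$strand[keep]
    o <- res$read_offset[keep]; l <- res$length[keep]
    off <- c(off, ifelse(st == "+", o, m - o - l))
    len <- c(len, l)
    contig <- c(contig, gm$contig[keep])
    rstart <- c(rstart, gm$start[keep])
    strand <- c(strand, st)
    tag <- c(tag, .tag_for_hit(h$kind, st))
  }
  dupkey <- paste(off, len, contig, rstart, tag)
  keep <- !duplicated(dupkey)
  list(read_offset = off[keep], length = len[keep], contig = contig[keep],
       ref_start = rstart[keep], strand = strand[keep], tag = tag[keep],
       cls = tag_class(tag[keep]))
}

#' Generate seeds for a read
#'
#' Maximal exact matches of length at least `min_seed_len` between each
#' converted copy of the read and its converted index, located to genomic
#' coordinates. Seed coordinates are reported in *oriented* read
#' coordinates (the read as it would be written on the forward reference
#' strand: reverse-complemented for minus-strand hits).
#'
#' @param read a [bs_read()].
#' @param indexes named list with elements `C_LESS` and `G_LESS`.
#' @param params a [scoring_params()].
#' @param mode library mode, see [convert_read()].
#' @return a `data.table` with columns `read_offset` (0-based, oriented),
#'   `length`, `contig`, `ref_start` (1-based leftmost), `strand`, `tag`,
#'   `cls`.
#' @export
generate_seeds <- function(read, indexes, params = scoring_params(),
                           mode = "directional") {
  as.data.table(.seeds_core(read, indexes, params, mode))
}

# vectorized 4-base filter over a seed vector-list; oc = list("+"=codes,"-"=codes)
# returns the pass/fail indicator vector
.seed_compat_core <- function(s, packed, oc) {
  n <- length(s$read_offset)
  ok <- logical(n)
  for (i in seq_len(n)) {
    q <- oc[[s$strand[i]]][(s$read_offset[i] + 1L):
                             (s$read_offset[i] + s$length[i])]
    r <- ref_slice_codes(packed, s$contig[i], s$ref_start[i],
                         s$ref_start[i] + s$length[i] - 1L)
    hit <- r == q | r >= 6L | q >= 6L
    if (s$cls[i] == "C2T") hit <- hit | (r == 3L & q == 5L)
    else hit <- hit | (r == 4L & q == 2L)
    ok[i] <- all(hit)
  }
  ok
}

#' Check a seed against the 4-base reference
#'
#' A seeded region is accepted only if every position satisfies conversion
#' asymmetry for the seed's bisulfite strand: read base equals reference
#' base, or (C->T strands) reference C with read T, or (G->A strands)
#' reference G with read A. Any other difference rejects the seed.
#'
#' @param seed a list or one-row data.table with `read_offset`, `length`,
#'   `contig`, `ref_start`, `strand`, `tag`.
#' @param packed a [pack_reference()] object.
#' @param read the [bs_read()] the seed came from.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
check_four_base_compatibility <- function(seed, packed, read) {
  oc <- list("+" = oriented_codes(read, "+"), "-" = oriented_codes(read, "-"))
  s <- list(read_offset = seed$read_offset, length = seed$length,
            contig = seed$contig, ref_start = seed$ref_start,
            strand = seed$strand, tag = seed$tag,
            cls = tag_class(seed$tag))
  .seed_compat_core(s, packed, oc)[1]
}

# greedy chaining on plain vectors
.chain_core <- function(s, params, contig_order) {
  n <- length(s$read_offset)
  out <- list(tag = character(0), contig = character(0),
              strand = character(0), anchor_ref = integer(0),
              anchor_off = integer(0), score = integer(0),
              n_seeds = integer(0))
  if (!n) return(out)
  ord <- order(s$tag, s$contig, s$read_offset, s$ref_start)
  # chain state vectors
  c_tag <- character(0); c_contig <- character(0); c_strand <- character(0)
  c_aref <- integer(0); c_aoff <- integer(0); c_score <- integer(0)
  c_n <- integer(0); c_loff <- integer(0); c_llen <- integer(0)
  c_lref <- integer(0)
  for (i in ord) {
    attached <- FALSE
    for (ci in seq_along(c_tag)) {
      if (c_tag[ci] != s$tag[i] || c_contig[ci] != s$contig[i]) next
      read_gap <- s$read_offset[i] - (c_loff[ci] + c_llen[ci])
      ref_gap <- s$ref_start[i] - (c_lref[ci] + c_llen[ci])
      trimmed <- s$length[i] - max(0L, -read_gap, -ref_gap)
      if (s$ref_start[i] >= c_lref[ci] &&
          read_gap <= params$max_chain_gap &&
          ref_gap <= params$max_chain_gap &&
          abs(ref_gap - read_gap) <= params$band_width &&
          trimmed > 0L) {
        c_loff[ci] <- s$read_offset[i]; c_llen[ci] <- s$length[i]
        c_lref[ci] <- s$ref_start[i]
        c_score[ci] <- c_score[ci] + trimmed
        c_n[ci] <- c_n[ci] + 1L
        attached <- TRUE
        break
      }
    }
    if (!attached) {
      c_tag <- c(c_tag, s$tag[i]); c_contig <- c(c_contig, s$contig[i])
      c_strand <- c(c_strand, s$strand[i])
      c_aref <- c(c_aref, s$ref_start[i])
      c_aoff <- c(c_aoff, s$read_offset[i])
      c_score <- c(c_score, s$length[i]); c_n <- c(c_n, 1L)
      c_loff <- c(c_loff, s$read_offset[i])
      c_llen <- c(c_llen, s$length[i]); c_lref <- c(c_lref, s$ref_start[i])
    }
  }
  o <- order(-c_score, match(c_contig, contig_order), c_aref, c_tag)
  list(tag = c_tag[o], contig = c_contig[o], strand = c_strand[o],
       anchor_ref = c_aref[o], anchor_off = c_aoff[o], score = c_score[o],
       n_seeds = c_n[o])
}

#' Chain compatible seeds
#'
#' Colinear seeds sharing a bisulfite strand, contig and orientation are
#' merged greedily when their read and reference gaps stay within
#' `max_chain_gap` and on a consistent diagonal. The chain score is the sum
#' of seed lengths after trimming read/reference overlap.
#'
#' @param seeds a seed table from [generate_seeds()].
#' @param params a [scoring_params()].
#' @param contig_order contig names in reference order (for deterministic
#'   sorting); defaults to order of appearance.
#' @return a `data.table`, one row per chain, sorted by (score desc, contig,
#'   position, tag): columns `tag`, `cls`, `contig`, `strand`, `anchor_ref`,
#'   `anchor_off`, `score`, `n_seeds`.
#' @export
chain_seeds <- function(seeds, params = scoring_params(),
                        contig_order = NULL) {
  if (is.null(contig_order)) contig_order <- unique(seeds$contig)
  ch <- .chain_core(as.list(seeds), params, contig_order)
  dt <- as.data.table(ch)
  dt[, cls := tag_class(tag)]
  data.table::setcolorder(dt, c("tag", "cls", "contig", "strand",
                                "anchor_ref", "anchor_off", "score",
                                "n_seeds"))
  dt[]
}

#' Conversion-asymmetric substitution score
#'
#' @param ref_base,read_base single bases in A/C/G/T/N.
#' @param bs_strand one of OT, OB, CTOT, CTOB (OT/CTOT tolerate reference C
#'   over read T; OB/CTOB tolerate reference G over read A).
#' @param params a [scoring_params()].
#' @return the score contribution: `+match` for a match or a
#'   strand-appropriate converted pair, `0` if either base is N,
#'   `-mismatch` otherwise.
#' @export
asymmetric_score <- function(ref_base, read_base, bs_strand,
                             params = scoring_params()) {
  cls <- tag_class(bs_strand)
  ifelse(ref_base == "N" | read_base == "N", 0L,
  ifelse(ref_base == read_base, params$match,
  ifelse(cls == "C2T" & ref_base == "C" & read_base == "T", params$match,
  ifelse(cls == "G2A" & ref_base == "G" & read_base == "A", params$match,
         -params$mismatch))))
}

# vectorized over integer codes; cls is "C2T"/"G2A"
.score_codes <- function(r, q, cls, params) {
  s <- rep(-params$mismatch, length(r))
  s[r == q] <- params$match
  if (cls == "C2T") s[r == 3L & q == 5L] <- params$match
  else s[r == 4L & q == 2L] <- params$match
  s[r >= 6L | q >= 6L] <- 0L
  s
}

# core extension; chain is a plain list for one chain, q the oriented codes
.extend_core <- function(chain, packed, q, params) {
  cls <- chain$cls
  m <- length(q)
  clen <- packed$lengths[[chain$contig]]
  anchor <- chain$anchor_ref - chain$anchor_off
  if (anchor >= 1L && anchor + m - 1L <= clen) {
    r <- ref_slice_codes(packed, chain$contig, anchor, anchor + m - 1L)
    s <- .score_codes(r, q, cls, params)
    if (all(s == params$match)) {
      return(list(contig = chain$contig, pos = anchor,
                  strand = chain$strand, tag = chain$tag, cls = cls,
                  cigar = paste0(m, "M"), score = m * params$match,
                  nm = 0L, zc = sum(r != q & q <= 5L & r <= 5L),
                  ref_end = anchor + m - 1L, aligned = TRUE))
    }
  }
  pad <- params$band_width + 8L
  wstart <- max(1L, anchor - pad)
  wend <- min(clen, anchor + m - 1L + pad)
  if (wstart > wend) return(list(aligned = FALSE, score = 0L))
  rwin <- ref_slice_codes(packed, chain$contig, wstart, wend)
  diag0 <- anchor - wstart
  res <- banded_sw_cpp(rwin, q, if (cls == "C2T") 0L else 1L,
                       params$match, params$mismatch, params$gap_open,
                       params$gap_extend, params$band_width, diag0)
  if (!isTRUE(res$aligned)) return(list(aligned = FALSE, score = 0L))
  lens <- res$lens
  ops <- res$ops
  head_clip <- res$read_start
  tail_clip <- m - res$read_end
  if (head_clip > 0L) { ops <- c("S", ops); lens <- c(head_clip, lens) }
  if (tail_clip > 0L) { ops <- c(ops, "S"); lens <- c(lens, tail_clip) }
  list(contig = chain$contig, pos = wstart + res$ref_start,
       strand = chain$strand, tag = chain$tag, cls = cls,
       cigar = paste0(lens, ops, collapse = ""),
       score = res$score, nm = res$n_mismatch + res$n_indel,
       zc = res$n_conversion,
       ref_end = wstart + res$ref_end - 1L, aligned = TRUE)
}

#' Extend a seed chain into a full alignment
#'
#' Gap-free extension along the chain diagonal is attempted first; if any
#' position scores below a match (mismatch or indel evidence), a banded
#' affine-gap Smith-Waterman under the asymmetric substitution score is
#' run over the chain window. Unaligned read ends are soft-clipped.
#'
#' @param chain one chain row from [chain_seeds()] (list or 1-row table).
#' @param packed packed reference.
#' @param read a [bs_read()].
#' @param params a [scoring_params()].
#' @return a list: `contig`, `pos` (1-based leftmost), `strand`, `tag`,
#'   `cls`, `cigar`, `score`, `nm` (conversion-aware edit distance), `zc`
#'   (count of asymmetry-consistent conversions), `ref_end`, `aligned`.
#' @export
extend_alignment <- function(chain, packed, read, params = scoring_params()) {
  ch <- as.list(chain)
  ch$cls <- tag_class(ch$tag)
  .extend_core(ch, packed, oriented_codes(read, ch$strand), params)
}

#' Mapping quality from candidate scores
#'
#' Reports 0 whenever two or more candidates share the optimal score;
#' otherwise `round(60 * (best - suboptimal) / best)` clamped to 0..60,
#' with suboptimal taken as 0 when the hit is unique.
#'
#' @param best_score score of the primary alignment.
#' @param second_score best score among the other candidates (NA if none).
#' @param n_equal_best number of candidates attaining `best_score`.
#' @return an integer MAPQ in 0..60.
#' @export
compute_mapq <- function(best_score, second_score = NA, n_equal_best = 1L) {
  if (n_equal_best >= 2L) return(0L)
  if (best_score <= 0L) return(0L)
  second <- if (is.na(second_score)) 0 else max(0, second_score)
  as.integer(max(0L, min(60L, round(60 * (best_score - second) / best_score))))
}

# parse a cigar into op/length vectors
cigar_ops <- function(cigar) {
  if (cigar == "*" || !nzchar(cigar)) {
    return(list(op = character(), len = integer()))
  }
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDSH]", cigar))[[1]]
  list(op = op, len = len)
}

cigar_ref_span <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "D")])
}

# Walk an alignment and return aligned (ref_pos, read_pos) pairs for M ops;
# read_pos is 1-based in the oriented read.
aligned_pairs <- function(pos, cigar) {
  co <- cigar_ops(cigar)
  rp <- pos; qp <- 1L
  refs <- integer(0); quer <- integer(0)
  for (i in seq_along(co$op)) {
    op <- co$op[i]; l <- co$len[i]
    if (op == "M") {
      refs <- c(refs, rp:(rp + l - 1L))
      quer <- c(quer, qp:(qp + l - 1L))
      rp <- rp + l; qp <- qp + l
    } else if (op == "D") rp <- rp + l
    else if (op %in% c("I", "S")) qp <- qp + l
  }
  list(ref = refs, query = quer)
}

#' Reassess the conversion strand of an alignment
#'
#' Counts reference-C/read-T and reference-G/read-A pairs within the
#' alignment and assigns the strand class with strictly more evidence; ties
#' (including zero evidence) keep the seeding tag but are flagged
#' ambiguous.
#'
#' @param aln an extension result from [extend_alignment()].
#' @param read the [bs_read()].
#' @param packed packed reference.
#' @return a list `tag`, `cls`, `ambiguous`.
#' @export
reassess_conversion_strand <- function(aln, read, packed) {
  q <- oriented_codes(read, aln$strand)
  ap <- aligned_pairs(aln$pos, aln$cigar)
  r <- ref_slice_codes(packed, aln$contig, aln$pos, aln$ref_end)
  rb <- r[ap$ref - aln$pos + 1L]
  qb <- q[ap$query]
  ct <- sum(rb == 3L & qb == 5L)
  ga <- sum(rb == 4L & qb == 2L)
  if (ct > ga) cls <- "C2T"
  else if (ga > ct) cls <- "G2A"
  else return(list(tag = aln$tag, cls = aln$cls, ambiguous = TRUE))
  list(tag = strand_class_tag(aln$strand, cls), cls = cls, ambiguous = FALSE)
}

# all extended candidates for one read as field vectors, deduplicated by
# placement and sorted (score desc, contig order, pos, tag)
.candidates_core <- function(read, indexes, packed, params, mode) {
  oc <- list("+" = oriented_codes(read, "+"),
             "-" = oriented_codes(read, "-"))
  s <- .seeds_core(read, indexes, params, mode)
  ok <- .seed_compat_core(s, packed, oc)
  ch <- .chain_core(lapply(s, `[`, ok), params, packed$contigs)
  n_chain <- length(ch$tag)
  n_visit <- min(n_chain, params$max_top_chains)
  # too few chains pass the 4-base filter: keep visiting chains built from
  # the non-conforming seeds, up to the max_total_chains bound, so that a
  # single anti-asymmetric base (e.g. a sequencing-error C) inside an
  # otherwise clean seed cannot strand the read - the extension DP decides
  chf <- NULL
  if (n_visit < params$max_top_chains && any(!ok)) {
    chf <- .chain_core(lapply(s, `[`, !ok), params, packed$contigs)
    n_extra <- min(length(chf$tag),
                   params$max_total_chains - n_visit)
    chf <- lapply(chf, `[`, seq_len(n_extra))
    ch <- Map(c, ch, chf)
    n_visit <- n_visit + n_extra
  }
  cand <- list(contig = character(0), pos = integer(0),
               strand = character(0), tag = character(0), cls = character(0),
               cigar = character(0), score = integer(0), nm = integer(0),
               zc = integer(0), ref_end = integer(0))
  for (i in seq_len(n_visit)) {
    chain_i <- list(tag = ch$tag[i], cls = tag_class(ch$tag[i]),
                    contig = ch$contig[i], strand = ch$strand[i],
                    anchor_ref = ch$anchor_ref[i],
                    anchor_off = ch$anchor_off[i])
    ext <- .extend_core(chain_i, packed, oc[[chain_i$strand]], params)
    if (!isTRUE(ext$aligned) || ext$score <= 0L) next
    cand$contig <- c(cand$contig, ext$contig)
    cand$pos <- c(cand$pos, ext$pos)
    cand$strand <- c(cand$strand, ext$strand)
    cand$tag <- c(cand$tag, ext$tag)
    cand$cls <- c(cand$cls, ext$cls)
    cand$cigar <- c(cand$cigar, ext$cigar)
    cand$score <- c(cand$score, ext$score)
    cand$nm <- c(cand$nm, ext$nm)
    cand$zc <- c(cand$zc, ext$zc)
    cand$ref_end <- c(cand$ref_end, ext$ref_end)
  }
  if (!length(cand$pos)) return(cand)
  o <- order(-cand$score, match(cand$contig, packed$contigs), cand$pos,
             cand$tag)
  cand <- lapply(cand, `[`, o)
  # one candidate per placement; the strand tag is reassessed afterwards
  keep <- !duplicated(paste(cand$contig, cand$pos, cand$strand))
  lapply(cand, `[`, keep)
}

.unmapped_row <- function(read, flag_extra = 0L) {
  list(qname = read$name, flag = 4L + flag_extra, rname = "*",
       pos = 0L, mapq = 0L, cigar = "*", rnext = "*", pnext = 0L,
       tlen = 0L, seq = read$seq, qual = read$qual, nm = NA_integer_,
       as_score = NA_integer_, xs = NA_integer_, zs = NA_character_,
       xa = NA_character_, xb = NA_integer_, zc = NA_integer_,
       tag = NA_character_, cls = NA_character_, ambiguous = NA,
       ref_end = NA_integer_, dup = FALSE)
}

.sam_empty <- function() {
  rbindlist(list(.unmapped_row(bs_read("x", "A"))))[0]
}

.revqual <- function(qual) {
  vapply(qual, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# one SAM-ready row (plain list) from the candidate vectors
.record_row <- function(read, cand, packed, params, primary = 1L) {
  n <- length(cand$pos)
  sc <- cand$score
  n_eq <- sum(sc == max(sc))
  second <- if (n > 1L) max(sc[-primary]) else NA
  mapq <- compute_mapq(sc[primary], second, n_eq)
  prim <- lapply(cand, `[`, primary)
  re <- reassess_conversion_strand(prim, read, packed)
  xa <- NA_character_
  if (n > 1L && (n - 1L) <= params$max_xa_hits) {
    oth <- lapply(cand, `[`, -primary)
    xa <- paste0(oth$contig, ",", oth$strand, oth$pos, ",", oth$cigar, ",",
                 oth$nm, ";", collapse = "")
  }
  minus <- prim$strand == "-"
  list(qname = read$name, flag = if (minus) 16L else 0L,
       rname = prim$contig, pos = prim$pos, mapq = mapq,
       cigar = prim$cigar, rnext = "*", pnext = 0L, tlen = 0L,
       seq = if (minus) revcomp(read$seq) else read$seq,
       qual = if (minus) .revqual(read$qual) else read$qual,
       nm = prim$nm, as_score = prim$score,
       xs = if (is.na(second)) 0L else as.integer(max(0, second)),
       zs = tag_zs(re$tag), xa = xa, xb = n - 1L,
       zc = prim$zc, tag = re$tag, cls = re$cls,
       ambiguous = re$ambiguous, ref_end = prim$ref_end, dup = FALSE)
}

#' Align a single read
#'
#' Runs the full convert/seed/filter/chain/extend pipeline and reports the
#' primary alignment (ties broken by contig order, then coordinate), with
#' alternate hits in the XA tag when few enough and their count in XB.
#' Unalignable reads yield an unmapped record (FLAG 4).
#'
#' @param read a [bs_read()].
#' @param indexes named list with `C_LESS` and `G_LESS` indexes.
#' @param packed packed reference.
#' @param params a [scoring_params()].
#' @param mode `"directional"` or `"non_directional"`.
#' @return a one-row `data.table` of SAM fields and tags.
#' @export
align_read <- function(read, indexes, packed, params = scoring_params(),
                       mode = "directional") {
  cand <- .candidates_core(read, indexes, packed, params, mode)
  row <- if (!length(cand$pos)) .unmapped_row(read) else
    .record_row(read, cand, packed, params)
  rbindlist(list(row))
}

# pair search over candidate vectors; returns list(pick1, pick2, proper)
.pair_pick <- function(c1, c2, params, insert_mean, insert_sd) {
  n1 <- min(length(c1$pos), 20L); n2 <- min(length(c2$pos), 20L)
  best <- -Inf; pick1 <- 1L; pick2 <- 1L; proper <- FALSE
  lim_lo <- max(1, insert_mean - 4 * insert_sd)
  lim_hi <- insert_mean + 4 * insert_sd
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (c1$contig[i] != c2$contig[j] || c1$strand[i] == c2$strand[j]) next
    if (c1$strand[i] == "+") {
      fpos <- c1$pos[i]; rpos <- c2$pos[j]; rend <- c2$ref_end[j]
    } else {
      fpos <- c2$pos[j]; rpos <- c1$pos[i]; rend <- c1$ref_end[i]
    }
    tl <- rend - fpos + 1L
    if (fpos > rpos || tl < lim_lo || tl > lim_hi) next
    sc <- c1$score[i] + c2$score[j] + params$pair_bonus
    if (sc > best) { best <- sc; pick1 <- i; pick2 <- j; proper <- TRUE }
  }
  list(pick1 = pick1, pick2 = pick2, proper = proper)
}

#' Align a read pair
#'
#' Candidate placements of the two mates are combined; a properly oriented
#' (forward/reverse, mates facing) combination whose implied insert size
#' lies within `insert_mean +- 4 * insert_sd` receives a pairing bonus.
#' Mates are rescued independently: if no consistent combination exists
#' (e.g. a chimeric insert), both mates are reported at their own best
#' placements with the proper-pair flag unset. Pairing is never forced.
#'
#' @param read1,read2 [bs_read()] objects (mates 1 and 2).
#' @param indexes,packed,params,mode as in [align_read()].
#' @param insert_mean,insert_sd insert-size model for proper pairs.
#' @return a two-row `data.table` (mate 1 then mate 2).
#' @export
align_pair <- function(read1, read2, indexes, packed,
                       params = scoring_params(), mode = "directional",
                       insert_mean = 300, insert_sd = 30) {
  read1$mate <- 1L; read2$mate <- 2L
  c1 <- .candidates_core(read1, indexes, packed, params, mode)
  c2 <- .candidates_core(read2, indexes, packed, params, mode)
  has1 <- length(c1$pos) > 0L; has2 <- length(c2$pos) > 0L
  proper <- FALSE; pick1 <- 1L; pick2 <- 1L
  if (has1 && has2) {
    pp <- .pair_pick(c1, c2, params, insert_mean, insert_sd)
    pick1 <- pp$pick1; pick2 <- pp$pick2; proper <- pp$proper
  }
  r1 <- if (!has1) .unmapped_row(read1) else
    .record_row(read1, c1, packed, params, pick1)
  r2 <- if (!has2) .unmapped_row(read2) else
    .record_row(read2, c2, packed, params, pick2)
  f1 <- r1$flag + 1L + 64L; f2 <- r2$flag + 1L + 128L
  if (bitwAnd(r2$flag, 4L)) f1 <- f1 + 8L
  if (bitwAnd(r1$flag, 4L)) f2 <- f2 + 8L
  if (!bitwAnd(r2$flag, 4L) && bitwAnd(r2$flag, 16L)) f1 <- f1 + 32L
  if (!bitwAnd(r1$flag, 4L) && bitwAnd(r1$flag, 16L)) f2 <- f2 + 32L
  if (proper) { f1 <- f1 + 2L; f2 <- f2 + 2L }
  r1$flag <- f1; r2$flag <- f2
  if (!bitwAnd(f1, 4L) && !bitwAnd(f2, 4L)) {
    r1$rnext <- r2$rname; r1$pnext <- r2$pos
    r2$rnext <- r1$rname; r2$pnext <- r1$pos
    if (r1$rname == r2$rname) {
      r1$rnext <- "="; r2$rnext <- "="
      lo <- min(r1$pos, r2$pos)
      hi <- max(r1$ref_end, r2$ref_end)
      span <- hi - lo + 1L
      r1$tlen <- if (r1$pos <= r2$pos) span else -span
      r2$tlen <- -r1$tlen
    }
  }
  rbindlist(list(r1, r2))
}

# unclipped 5' position of a record (orientation-aware)
.unclipped5 <- function(records) {
  co <- lapply(records$cigar, cigar_ops)
  lead <- vapply(co, function(x)
    if (length(x$op) && x$op[1] == "S") x$len[1] else 0L, integer(1))
  trail <- vapply(co, function(x) {
    n <- length(x$op)
    if (n && x$op[n] == "S") x$len[n] else 0L
  }, integer(1))
  ifelse(bitwAnd(records$flag, 16L) > 0L,
         records$ref_end + trail, records$pos - lead)
}

.mean_qual <- function(qual) {
  vapply(qual, function(s) mean(utf8ToInt(s)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Conversion-aware duplicate marking
#'
#' Fragments sharing a coordinate signature - contig, unclipped 5' position
#' of each mate, orientation and bisulfite-strand class - are grouped and
#' all but the highest total-base-quality fragment flagged as duplicates.
#' Signatures are computed on coordinates only, never on base content, so
#' differing conversion (methylation) patterns cannot split a duplicate
#' group.
#'
#' @param records an alignment record table.
#' @return the records with the duplicate flag (0x400) set and the `dup`
#'   column updated.
#' @export
mark_duplicates <- function(records) {
  rec <- copy(records)
  rec[, dup := FALSE]
  rec[, flag := bitwAnd(flag, bitwNot(1024L))]
  mapped <- which(!bitwAnd(rec$flag, 4L))
  if (!length(mapped)) return(rec)
  sub <- rec[mapped]
  sub[, `:=`(p5 = .unclipped5(sub),
             orient = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mq = .mean_qual(qual) * nchar(seq))]
  sub[, key := paste0(rname, ":", p5, ":", orient, ":", cls)]
  sig <- sub[, .(sig = paste(sort(key), collapse = "|"),
                 qsum = sum(mq)), by = qname]
  sig[, rank := frank(-qsum, ties.method = "first"), by = sig]
  dup_q <- sig[rank > 1L, qname]
  rec[qname %in% dup_q & !bitwAnd(flag, 4L),
      `:=`(dup = TRUE, flag = flag + 1024L)]
  rec
}
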