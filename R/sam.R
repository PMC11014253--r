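# SAM (v1.6) serialization of alignment record tables.
#
# Records live in memory as a data.table (one row per read) with the eleven
# mandatory fields plus the toolkit's tags:
#   NM:i conversion-aware edit distance, AS:i alignment score,
#   XS:i suboptimal score, ZS:Z bisulfite strand ("++"/"+-"/"-+"/"--"
#   for OT/CTOT/OB/CTOB), ZC:i count of asymmetry-consistent conversions,
#   XA:Z alternate hits "chr,(+|-)pos,CIGAR,NM;", XB:i alternate-hit count.

#' Write alignment records as SAM
#'
#' @param records an alignment record table ([align_read()] rows).
#' @param path output path (plain text).
#' @param packed packed reference for the @SQ header lines.
#' @export
write_sam <- function(records, path, packed) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", packed$contigs, "\tLN:",
                  packed$lengths[packed$contigs]),
           "@PG\tID:methsuite\tPN:methsuite\tVN:0.1.0")
  tagf <- function(val, tag, type) {
    ifelse(is.na(val), NA_character_, paste0(tag, ":", type, ":", val))
  }
  tagmat <- cbind(tagf(records$nm, "NM", "i"),
                  tagf(records$as_score, "AS", "i"),
                  tagf(records$xs, "XS", "i"),
                  tagf(records$zs, "ZS", "Z"),
                  tagf(records$zc, "ZC", "i"),
                  tagf(records$xa, "XA", "Z"),
                  tagf(records$xb, "XB", "i"))
  tags <- apply(tagmat, 1L, function(x) paste(x[!is.na(x)], collapse = "\t"))
  body <- paste(records$qname, records$flag, records$rname, records$pos,
                records$mapq, records$cigar, records$rnext, records$pnext,
                records$tlen, records$seq, records$qual, sep = "\t")
  body <- ifelse(nzchar(tags), paste(body, tags, sep = "\t"), body)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment record table
#'
#' Parses the mandatory fields and this toolkit's auxiliary tags back into
#' the in-memory record layout (derived columns `tag`, `cls` and `ref_end`
#' are reconstructed from ZS/FLAG/CIGAR).
#'
#' @param path path to a SAM file.
#' @return an alignment record `data.table`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(.sam_empty())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  getf <- function(i) vapply(parts, `[[`, character(1), i)
  tagval <- function(prefix) {
    vapply(parts, function(p) {
      hit <- p[startsWith(p, prefix)]
      if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  rec <- data.table(
    qname = getf(1), flag = as.integer(getf(2)), rname = getf(3),
    pos = as.integer(getf(4)), mapq = as.integer(getf(5)),
    cigar = getf(6), rnext = getf(7), pnext = as.integer(getf(8)),
    tlen = as.integer(getf(9)), seq = getf(10), qual = getf(11),
    nm = as.integer(tagval("NM:i:")), as_score = as.integer(tagval("AS:i:")),
    xs = as.integer(tagval("XS:i:")), zs = tagval("ZS:Z:"),
    xa = tagval("XA:Z:"), xb = as.integer(tagval("XB:i:")),
    zc = as.integer(tagval("ZC:i:")))
  zs_tag <- setNames(names(.TAG_ZS), unname(.TAG_ZS))
  rec[, tag := zs_tag[zs]]
  rec[, cls := tag_class(tag)]
  rec[, ambiguous := NA]
  span <- vapply(rec$cigar, cigar_ref_span, numeric(1), USE.NAMES = FALSE)
  rec[, ref_end := ifelse(bitwAnd(flag, 4L) > 0L, NA_integer_,
                          as.integer(pos + span - 1L))]
  rec[, dup := bitwAnd(flag, 1024L) > 0L]
  rec[]
}

#' Coordinate-sort an alignment record table
#'
#' @param records record table.
#' @param contig_order contigs in reference order.
#' @return sorted copy (unmapped records last).
#' @export
sort_records <- function(records, contig_order = NULL) {
  rec <- copy(records)
  if (is.null(contig_order)) contig_order <- unique(rec$rname)
  rec[, ci := match(rname, contig_order)]
  rec[is.na(ci), ci := .Machine$integer.max]
  setorder(rec, ci, pos, qname)
  rec[, ci := NULL]
  rec[]
}
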