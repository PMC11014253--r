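# epiBED: BED-compliant read-level run-length-encoded methylation +
# variant states.
#
# Dialect (version 1.0), one row per read (or merged mate pair):
#   1 chrom  2 start (0-based)  3 end (half-open)  4 read_name
#   5 mate (1, 2 or M for merged)  6 bs_strand tag (OT/OB/CTOT/CTOB)
#   7 rle_meth   8 rle_var   9 rle_acc (NOMe accessibility; "." for WGBS)
#   10 insertions ("refpos:seq" ;-separated, "." if none)
# RLE strings are count+symbol runs ("2x1M3x"); decoded length equals
# end - start. Methylation alphabet: M retained, U converted, F filtered
# (low quality or mate conflict), D deletion, x not informative. Variant
# alphabet: A/C/G/T observed base at a supplied variant site, with Y (on
# C->T strands) and R (on G->A strands) where conversion makes the base
# call ambiguous, plus F/D/x as above.

EPIBED_DIALECT_VERSION <- "1.0"

#' Run-length encode a state string
#'
#' @param states character vector of single-character states.
#' @return the RLE string, e.g. `"2x1M3x"`.
#' @export
encode_rle <- function(states) {
  r <- rle(states)
  paste0(r$lengths, r$values, collapse = "")
}

#' Decode a run-length-encoded state string
#'
#' @param s an RLE string from [encode_rle()].
#' @return character vector of per-position states.
#' @export
decode_rle <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(character(0))
  lens <- as.integer(regmatches(s, gregexpr("[0-9]+", s))[[1]])
  vals <- regmatches(s, gregexpr("[^0-9]", s))[[1]]
  if (length(lens) != length(vals)) stop("malformed RLE string: ", s)
  rep(vals, lens)
}

# channel cytosine predicate: positions (1-based) informative for a read
# of conversion class cls, restricted to the channel context
.channel_sites <- function(packed, contig, positions, cls, assay,
                           channel = c("meth", "acc")) {
  channel <- match.arg(channel)
  if (!length(positions)) return(logical(0))
  refb <- ref_base_at(packed, contig, positions)
  informative <- if (cls == "C2T") refb == "C" else refb == "G"
  strand <- if (cls == "C2T") "+" else "-"
  out <- rep(FALSE, length(positions))
  idx <- which(informative)
  if (!length(idx)) return(out)
  ctx <- .meth_context(packed, rep(contig, length(idx)), positions[idx],
                       rep(strand, length(idx)),
                       if (assay == "WGBS") "WGBS" else "NOMe")
  ok <- if (assay == "WGBS") {
    if (channel == "meth") !is.na(ctx$context) & ctx$context == "CpG"
    else rep(FALSE, length(idx))
  } else {
    if (channel == "meth") !is.na(ctx$context) & ctx$context == "HCG"
    else !is.na(ctx$context) & ctx$context == "GCH"
  }
  out[idx[ok]] <- TRUE
  out
}

#' Encode one aligned read as an epiBED record
#'
#' Walks the alignment and emits one state per covered reference position:
#' M (retained channel cytosine), U (converted), F (base quality below
#' `min_baseq`), D (deletion), x otherwise; observed bases at supplied
#' variant sites go to the variant channel, as Y/R when conversion on the
#' read's strand makes the call ambiguous. Insertions are kept in a side
#' field. The literal strings are run-length compressed.
#'
#' @param record a one-row alignment record table.
#' @param packed packed reference.
#' @param variant_sites optional `data.table`/data.frame with `contig`,
#'   `pos` (1-based) of SNP sites to report in the variant channel.
#' @param min_baseq adaptive base-quality filter.
#' @param assay `"WGBS"` or `"NOMe"` (NOMe adds the accessibility channel).
#' @return a one-row `data.table` epiBED record.
#' @export
encode_read <- function(record, packed, variant_sites = NULL,
                        min_baseq = 20L, assay = c("WGBS", "NOMe")) {
  assay <- match.arg(assay)
  stopifnot(nrow(record) == 1L, !bitwAnd(record$flag, 4L))
  span <- record$ref_end - record$pos + 1L
  meth <- rep("x", span); var <- rep("x", span)
  acc <- if (assay == "NOMe") rep("x", span) else NULL
  co <- cigar_ops(record$cigar)
  rp <- record$pos; qp <- 1L
  qchars <- strsplit(record$seq, "", fixed = TRUE)[[1]]
  quals <- utf8ToInt(record$qual) - 33L
  ins <- character(0)
  vkeys <- if (!is.null(variant_sites))
    variant_sites$pos[variant_sites$contig == record$rname] else integer(0)
  cls <- record$cls
  for (k in seq_along(co$op)) {
    op <- co$op[k]; l <- co$len[k]
    if (op == "M") {
      refpos <- rp:(rp + l - 1L)
      qpos <- qp:(qp + l - 1L)
      off <- refpos - record$pos + 1L
      lowq <- quals[qpos] < min_baseq
      for (ch in c("meth", if (assay == "NOMe") "acc")) {
        sites <- .channel_sites(packed, record$rname, refpos, cls, assay, ch)
        st <- rep("x", l)
        retained_base <- if (cls == "C2T") "C" else "G"
        converted_base <- if (cls == "C2T") "T" else "A"
        st[sites & qchars[qpos] == retained_base] <- "M"
        st[sites & qchars[qpos] == converted_base] <- "U"
        st[sites & lowq] <- "F"
        if (ch == "meth") meth[off] <- st else acc[off] <- st
      }
      vi <- which(refpos %in% vkeys)
      if (length(vi)) {
        b <- qchars[qpos[vi]]
        b[cls == "C2T" & b == "T"] <- "Y"
        b[cls == "G2A" & b == "A"] <- "R"
        b[lowq[vi]] <- "F"
        var[off[vi]] <- b
      }
      rp <- rp + l; qp <- qp + l
    } else if (op == "D") {
      off <- (rp:(rp + l - 1L)) - record$pos + 1L
      meth[off] <- "D"; var[off] <- "D"
      if (!is.null(acc)) acc[off] <- "D"
      rp <- rp + l
    } else if (op == "I") {
      ins <- c(ins, paste0(rp, ":", paste(qchars[qp:(qp + l - 1L)],
                                          collapse = "")))
      qp <- qp + l
    } else if (op == "S") qp <- qp + l
  }
  mate <- if (bitwAnd(record$flag, 64L)) "1" else
    if (bitwAnd(record$flag, 128L)) "2" else "1"
  data.table(chrom = record$rname, start = record$pos - 1L,
             end = record$ref_end, read = record$qname, mate = mate,
             bs = record$tag,
             rle_meth = encode_rle(meth), rle_var = encode_rle(var),
             rle_acc = if (is.null(acc)) "." else encode_rle(acc),
             ins = if (length(ins)) paste(ins, collapse = ";") else ".")
}

#' Decode an epiBED record to per-position states
#'
#' Exact inverse of the run-length encoding; lengths are checked against
#' the record span.
#'
#' @param record a one-row epiBED record.
#' @return a list of state vectors `meth`, `var` and (if present) `acc`,
#'   each of length `end - start`.
#' @export
decode_epibed <- function(record) {
  span <- record$end - record$start
  out <- list(meth = decode_rle(record$rle_meth),
              var = decode_rle(record$rle_var))
  if (!is.null(record$rle_acc) && !is.na(record$rle_acc) &&
      record$rle_acc != ".")
    out$acc <- decode_rle(record$rle_acc)
  for (nm in names(out))
    if (length(out[[nm]]) != span)
      stop("decoded ", nm, " length ", length(out[[nm]]),
           " != span ", span, " for read ", record$read)
  out
}

.merge_states <- function(a, b) {
  out <- a
  out[a == "x"] <- b[a == "x"]
  conflict <- a != "x" & b != "x" & a != b
  out[conflict] <- "F"
  out
}

#' Merge the two mates of a molecule into one epiBED row
#'
#' Spans are united (the gap between disjoint mates filled with x); in the
#' overlap, agreeing states are kept once (no double counting) and
#' disagreeing methylation states are conflict-filtered to F. Commutative
#' in its arguments.
#'
#' @param r1,r2 one-row epiBED records with the same read name and chrom.
#' @return a merged one-row record with mate "M".
#' @export
merge_mates <- function(r1, r2) {
  stopifnot(r1$read == r2$read, r1$chrom == r2$chrom)
  s <- min(r1$start, r2$start); e <- max(r1$end, r2$end)
  span <- e - s
  has_acc <- r1$rle_acc != "." || r2$rle_acc != "."
  chans <- c("meth", "var", if (has_acc) "acc")
  states <- lapply(chans, function(ch) rep("x", span))
  names(states) <- chans
  place <- function(rec) {
    dec <- decode_epibed(rec)
    off <- (rec$start - s + 1L):(rec$end - s)
    for (ch in chans) {
      if (!is.null(dec[[ch]]))
        states[[ch]][off] <<- .merge_states(states[[ch]][off], dec[[ch]])
    }
  }
  # deterministic, order-independent: place the lower-start record first
  first <- if (r1$start <= r2$start) r1 else r2
  second <- if (r1$start <= r2$start) r2 else r1
  place(first); place(second)
  ins <- setdiff(unique(c(strsplit(r1$ins, ";")[[1]],
                          strsplit(r2$ins, ";")[[1]])), ".")
  data.table(chrom = r1$chrom, start = s, end = e, read = r1$read,
             mate = "M", bs = first$bs,
             rle_meth = encode_rle(states$meth),
             rle_var = encode_rle(states$var),
             rle_acc = if (has_acc) encode_rle(states$acc) else ".",
             ins = if (length(ins)) paste(ins, collapse = ";") else ".")
}

#' Encode a full record table as epiBED
#'
#' Encodes every mapped, non-duplicate record and optionally merges mates
#' into single molecule rows.
#'
#' @param records alignment record table.
#' @param packed packed reference.
#' @param variant_sites,min_baseq,assay see [encode_read()].
#' @param merge merge mate pairs into molecule rows (default TRUE).
#' @param min_mapq MAPQ filter.
#' @return coordinate-sorted epiBED `data.table`.
#' @export
epibed_from_records <- function(records, packed, variant_sites = NULL,
                                min_baseq = 20L, assay = "WGBS",
                                merge = TRUE, min_mapq = 40L) {
  rec <- records[!bitwAnd(flag, 4L) & !dup & mapq >= min_mapq]
  rows <- lapply(seq_len(nrow(rec)), function(i)
    encode_read(rec[i], packed, variant_sites, min_baseq, assay))
  eb <- rbindlist(rows)
  if (merge && nrow(eb)) {
    merged <- eb[, {
      if (.N == 2L && chrom[1] == chrom[2]) {
        grp <- copy(.SD)[, read := .BY$read]
        merge_mates(grp[1], grp[2])[, !"read"]
      } else .SD
    }, by = read]
    eb <- merged[, names(eb), with = FALSE]
  }
  setorder(eb, chrom, start, read)
  eb[]
}

#' Write epiBED records
#'
#' Tab-separated, coordinate-sorted, BED-compliant; gzip-compatible via a
#' `.gz` suffix.
#'
#' @param records epiBED record table.
#' @param path output path.
#' @export
write_epibed <- function(records, path) {
  rec <- copy(records)
  setorder(rec, chrom, start, read)
  fwrite(rec, path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read an epiBED file
#'
#' Validates that every RLE string decodes to the record span.
#'
#' @param path epiBED path.
#' @return epiBED record table.
#' @export
read_epibed <- function(path) {
  cn <- c("chrom", "start", "end", "read", "mate", "bs",
          "rle_meth", "rle_var", "rle_acc", "ins")
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    fread(text = readLines(con), header = FALSE, col.names = cn)
  } else {
    fread(path, header = FALSE, col.names = cn)
  }
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            mate = as.character(mate))]
  for (i in seq_len(nrow(dt))) decode_epibed(dt[i])
  dt[]
}

#' Build a read-by-position state matrix from epiBED records
#'
#' One row per molecule (mates merged beforehand by
#' [epibed_from_records()]), one column per position carrying an M/U/F
#' state in any record within the region; optional SNP columns carry the
#' observed base letters.
#'
#' @param records epiBED record table.
#' @param chrom,start,end region (1-based inclusive `start`, `end`).
#' @param include_snps add columns for variant-channel positions.
#' @param complete_only keep only rows covering every requested column.
#' @param sort_rows sort rows by mean methylation (descending).
#' @return a list of class `read_state_matrix`: `meth` (character matrix,
#'   NA where uncovered), `snp` (or NULL), `positions`, `snp_positions`.
#' @export
to_matrix <- function(records, chrom, start, end, include_snps = FALSE,
                      complete_only = FALSE, sort_rows = FALSE) {
  sel <- records[records$chrom == chrom & records$end > start - 1L &
                   records$start < end]
  decs <- lapply(seq_len(nrow(sel)), function(i) decode_epibed(sel[i]))
  # columns: positions with an M/U/F state in any overlapping record
  cols <- sort(unique(unlist(lapply(seq_len(nrow(sel)), function(i) {
    st <- decs[[i]]$meth
    pos <- (sel$start[i] + 1L):sel$end[i]
    pos[st %in% c("M", "U", "F")]
  }))))
  cols <- cols[cols >= start & cols <= end]
  snp_cols <- integer(0)
  if (include_snps) {
    snp_cols <- sort(unique(unlist(lapply(seq_len(nrow(sel)), function(i) {
      st <- decs[[i]]$var
      pos <- (sel$start[i] + 1L):sel$end[i]
      pos[st %in% c("A", "C", "G", "T", "R", "Y")]
    }))))
    snp_cols <- snp_cols[snp_cols >= start & snp_cols <= end]
  }
  fill <- function(channel, columns) {
    m <- matrix(NA_character_, nrow = nrow(sel), ncol = length(columns),
                dimnames = list(sel$read, as.character(columns)))
    for (i in seq_len(nrow(sel))) {
      pos <- (sel$start[i] + 1L):sel$end[i]
      hit <- columns %in% pos
      if (any(hit))
        m[i, hit] <- decs[[i]][[channel]][match(columns[hit], pos)]
    }
    m
  }
  meth <- fill("meth", cols)
  snp <- if (include_snps) fill("var", snp_cols) else NULL
  if (complete_only && ncol(meth)) {
    covered <- rowSums(is.na(meth) | meth == "x") == 0
    if (include_snps && length(snp_cols))
      covered <- covered & rowSums(is.na(snp) | snp == "x") == 0
    meth <- meth[covered, , drop = FALSE]
    if (!is.null(snp)) snp <- snp[covered, , drop = FALSE]
  }
  if (sort_rows && nrow(meth)) {
    mm <- rowMeans(meth == "M", na.rm = TRUE)
    ord <- order(-ifelse(is.nan(mm), -1, mm))
    meth <- meth[ord, , drop = FALSE]
    if (!is.null(snp)) snp <- snp[ord, , drop = FALSE]
  }
  structure(list(meth = meth, snp = snp, positions = cols,
                 snp_positions = snp_cols),
            class = "read_state_matrix")
}

#' Allele-specific methylation test
#'
#' For the two most frequent alleles at a SNP column, tests each CpG
#' column with a two-sided Fisher exact test on the 2x2 allele-by-M/U
#' table and reports per-allele mean beta. No multiple-testing correction
#' is applied unless `bh = TRUE`, in which case a BH-adjusted column is
#' added (flagged in the result).
#'
#' @param mat a [to_matrix()] result built with `include_snps = TRUE`.
#' @param snp_pos the SNP column position.
#' @param min_reads_per_allele minimum informative reads per allele; CpGs
#'   (or alleles) below it are reported untested.
#' @param bh add a Benjamini-Hochberg adjusted p-value column.
#' @return a `data.table`: `pos`, `allele1`, `allele2`, `m1`, `u1`, `m2`,
#'   `u2`, `beta1`, `beta2`, `p_value`, `tested` (+ `p_bh` if requested);
#'   attribute `alleles` gives the allele counts.
#' @export
asm_test <- function(mat, snp_pos, min_reads_per_allele = 3L, bh = FALSE) {
  stopifnot(!is.null(mat$snp))
  sc <- match(as.character(snp_pos), colnames(mat$snp))
  if (is.na(sc)) stop("snp position ", snp_pos, " not in matrix")
  alleles <- mat$snp[, sc]
  ok <- alleles %in% c("A", "C", "G", "T", "R", "Y")
  tab <- sort(table(alleles[ok]), decreasing = TRUE)
  out <- data.table(pos = as.integer(colnames(mat$meth)))
  if (length(tab) < 2L) {
    out[, `:=`(allele1 = NA_character_, allele2 = NA_character_,
               m1 = NA_integer_, u1 = NA_integer_, m2 = NA_integer_,
               u2 = NA_integer_, beta1 = NA_real_, beta2 = NA_real_,
               p_value = NA_real_, tested = FALSE)]
    attr(out, "alleles") <- tab
    return(out)
  }
  a1 <- names(tab)[1]; a2 <- names(tab)[2]
  res <- lapply(seq_len(ncol(mat$meth)), function(j) {
    st <- mat$meth[, j]
    g1 <- st[ok & alleles == a1]; g2 <- st[ok & alleles == a2]
    m1 <- sum(g1 == "M", na.rm = TRUE); u1 <- sum(g1 == "U", na.rm = TRUE)
    m2 <- sum(g2 == "M", na.rm = TRUE); u2 <- sum(g2 == "U", na.rm = TRUE)
    tested <- (m1 + u1) >= min_reads_per_allele &&
      (m2 + u2) >= min_reads_per_allele
    p <- if (tested)
      fisher.test(matrix(c(m1, u1, m2, u2), nrow = 2))$p.value else NA_real_
    data.table(allele1 = a1, allele2 = a2, m1 = m1, u1 = u1, m2 = m2,
               u2 = u2,
               beta1 = if (m1 + u1 > 0) m1 / (m1 + u1) else NA_real_,
               beta2 = if (m2 + u2 > 0) m2 / (m2 + u2) else NA_real_,
               p_value = p, tested = tested)
  })
  out <- cbind(out, rbindlist(res))
  if (bh) out[, p_bh := p.adjust(p_value, "BH")]
  attr(out, "alleles") <- tab
  attr(out, "bh_applied") <- bh
  out[]
}
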