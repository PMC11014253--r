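# Conversion and bias diagnostics.
#
# Retention (a cytosine read as C rather than T on its informative strand)
# is split by dinucleotide context. CpH contexts are reported separately as
# CpA, CpC and CpT: genuine non-CpG methylation occurs preferentially at
# CpA, so the CpC/CpT pool estimates the background non-conversion rate
# while an elevated CpA level flags real CpA methylation.

# per-read cytosine observations with context annotations (no mate-overlap
# dedup: QC is a per-read diagnostic, and the M-bias arrays must conserve
# the context totals)
.qc_cytosine_obs <- function(records, packed, min_mapq = 40L,
                             min_baseq = 20L) {
  rec <- records[!bitwAnd(flag, 4L) & mapq >= min_mapq]
  obs <- expand_alignments(rec)
  obs <- obs[qual >= min_baseq]
  if (!nrow(obs)) return(obs[, `:=`(context = character(0),
                                    retained = logical(0),
                                    strand = character(0))])
  obs[, ref := ref_base_at(packed, contig, pos)]
  plus <- obs[ref == "C" & cls == "C2T" & base %in% c("C", "T")]
  minus <- obs[ref == "G" & cls == "G2A" & base %in% c("G", "A")]
  plus[, `:=`(strand = "+", retained = base == "C")]
  minus[, `:=`(strand = "-", retained = base == "G")]
  cyt <- rbindlist(list(plus, minus))
  if (!nrow(cyt)) return(cyt)
  ctx <- .meth_context(packed, cyt$contig, cyt$pos, cyt$strand, "WGBS")
  cyt[, context := ctx$context]
  cyt[!is.na(context)]
}

#' Cytosine retention split by context, with M-bias arrays
#'
#' Every aligned cytosine observation on its informative strand is
#' classified by dinucleotide context (CpG, CpA, CpC, CpT) and
#' retained/converted status, indexed by position within the read (M-bias)
#' separately for mates 1 and 2.
#'
#' @param records alignment record table (duplicates are excluded).
#' @param packed packed reference.
#' @param min_mapq,min_baseq quality filters.
#' @return a list of class `retention_profile`: `by_context`
#'   (context, retained, total, retention) and `mbias`
#'   (mate, cycle, context, retained, total).
#' @export
retention_by_context <- function(records, packed, min_mapq = 40L,
                                 min_baseq = 20L) {
  cyt <- .qc_cytosine_obs(records[records$dup == FALSE], packed, min_mapq,
                          min_baseq)
  ctx_levels <- c("CpG", "CpA", "CpC", "CpT")
  if (!nrow(cyt)) {
    by_context <- data.table(context = ctx_levels, retained = 0L,
                             total = 0L, retention = NA_real_)
    mbias <- data.table(mate = integer(), cycle = integer(),
                        context = character(), retained = integer(),
                        total = integer())
    return(structure(list(by_context = by_context, mbias = mbias),
                     class = "retention_profile"))
  }
  by_context <- cyt[, .(retained = sum(retained), total = .N),
                    by = context][order(match(context, ctx_levels))]
  missing <- setdiff(ctx_levels, by_context$context)
  if (length(missing))
    by_context <- rbind(by_context,
                        data.table(context = missing, retained = 0L,
                                   total = 0L))[order(match(context,
                                                            ctx_levels))]
  by_context[, retention := ifelse(total > 0, retained / total, NA_real_)]
  mbias <- cyt[, .(retained = sum(retained), total = .N),
               by = .(mate, cycle, context)]
  setorder(mbias, mate, cycle, context)
  structure(list(by_context = by_context, mbias = mbias),
            class = "retention_profile")
}

#' Infer the background non-conversion rate from CpH retention
#'
#' The background is the pooled CpC + CpT retention with a binomial
#' confidence interval. Genuine CpA methylation is flagged when CpA
#' retention exceeds the background by more than chance for both binomial
#' errors (one-sided two-proportion z-test at `alpha`); the small `alpha`
#' default targets high specificity, since a raised flag typically
#' triggers manual review.
#'
#' @param profile a [retention_by_context()] result.
#' @param conf_level confidence level of the background interval.
#' @param alpha one-sided significance level for the CpA-methylation flag.
#' @return a list of class `conversion_background`: `rate`, `ci` (length
#'   2), `n`, `cpa_retention`, `cpa_flag`, `cpa_z`.
#' @export
infer_conversion_background <- function(profile, conf_level = 0.95,
                                        alpha = 1e-4) {
  bc <- profile$by_context
  k <- bc[context %in% c("CpC", "CpT"), sum(retained)]
  n <- bc[context %in% c("CpC", "CpT"), sum(total)]
  if (n == 0) {
    return(structure(list(rate = NA_real_, ci = c(NA_real_, NA_real_),
                          n = 0L, cpa_retention = NA_real_,
                          cpa_flag = FALSE, cpa_z = NA_real_),
                     class = "conversion_background"))
  }
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  rate <- k / n
  ka <- bc[context == "CpA", sum(retained)]
  na <- bc[context == "CpA", sum(total)]
  if (na > 0) {
    pa <- ka / na
    se <- sqrt(rate * (1 - rate) / n + pa * (1 - pa) / na)
    z <- if (se > 0) (pa - rate) / se else if (pa > rate) Inf else 0
    flag <- z > qnorm(1 - alpha)
  } else {
    pa <- NA_real_; z <- NA_real_; flag <- FALSE
  }
  structure(list(rate = rate, ci = as.numeric(bt$conf.int), n = n,
                 cpa_retention = pa, cpa_flag = flag, cpa_z = z),
            class = "conversion_background")
}

#' Remove reads with extensive conversion failure
#'
#' A read carrying at least `min_cph_seen` CpH cytosines of which more than
#' `max_cph_retained` are retained is removed; reads with too little CpH
#' evidence are kept.
#'
#' @param records alignment record table.
#' @param packed packed reference.
#' @param max_cph_retained maximum tolerated retained CpH cytosines.
#' @param min_cph_seen minimum CpH cytosines required to judge a read.
#' @param min_baseq base-quality floor for counted cytosines.
#' @return a list with `kept` and `removed` record tables.
#' @export
filter_failed_conversion_reads <- function(records, packed,
                                           max_cph_retained = 2L,
                                           min_cph_seen = 3L,
                                           min_baseq = 20L) {
  cyt <- .qc_cytosine_obs(records, packed, min_mapq = 0L,
                          min_baseq = min_baseq)
  if (!nrow(cyt)) return(list(kept = records, removed = records[0]))
  per <- cyt[context %in% c("CpA", "CpC", "CpT"),
             .(seen = .N, ret = sum(retained)), by = .(qname, mate)]
  bad <- per[seen >= min_cph_seen & ret > max_cph_retained]
  key_rec <- paste0(records$qname, "/",
                    ifelse(bitwAnd(records$flag, 64L) > 0L, 1L,
                           ifelse(bitwAnd(records$flag, 128L) > 0L, 2L, 0L)))
  key_bad <- paste0(bad$qname, "/", bad$mate)
  drop <- key_rec %in% key_bad
  list(kept = records[!drop], removed = records[drop])
}

#' Assemble and serialize a machine-readable QC report
#'
#' Writes `<prefix>.qc.txt` (flat `key: value` metrics) and
#' `<prefix>.mbias.tsv` (per-cycle retention by context and mate).
#'
#' @param records alignment record table.
#' @param packed packed reference.
#' @param prefix output path prefix (NULL skips writing).
#' @param min_mapq MAPQ threshold defining optimally mapped reads.
#' @return a list of class `qc_report` with `counts`, `profile`,
#'   `background`, `failed_conversion_reads`.
#' @export
qc_report <- function(records, packed, prefix = NULL, min_mapq = 40L) {
  mapped <- !bitwAnd(records$flag, 4L)
  counts <- list(
    total_reads = nrow(records),
    mapped_reads = sum(mapped),
    optimally_mapped_reads = sum(mapped & records$mapq >= min_mapq),
    duplicate_reads = sum(records$dup))
  profile <- retention_by_context(records, packed, min_mapq = min_mapq)
  background <- infer_conversion_background(profile)
  failed <- filter_failed_conversion_reads(records, packed)
  counts$failed_conversion_reads <- nrow(failed$removed)
  rep <- structure(list(counts = counts, profile = profile,
                        background = background,
                        failed_conversion_reads = nrow(failed$removed)),
                   class = "qc_report")
  if (!is.null(prefix)) {
    lines <- c(
      paste0("total_reads: ", counts$total_reads),
      paste0("mapped_reads: ", counts$mapped_reads),
      paste0("optimally_mapped_reads: ", counts$optimally_mapped_reads),
      paste0("duplicate_reads: ", counts$duplicate_reads),
      paste0("failed_conversion_reads: ", counts$failed_conversion_reads),
      paste0("background_nonconversion_rate: ",
             signif(background$rate, 6)),
      paste0("background_ci_low: ", signif(background$ci[1], 6)),
      paste0("background_ci_high: ", signif(background$ci[2], 6)),
      paste0("cpa_retention: ", signif(background$cpa_retention, 6)),
      paste0("cpa_methylation_flag: ", background$cpa_flag),
      paste0("retention_", profile$by_context$context, ": ",
             signif(profile$by_context$retention, 6)))
    writeLines(lines, paste0(prefix, ".qc.txt"))
    fwrite(profile$mbias, paste0(prefix, ".mbias.tsv"), sep = "\t")
  }
  rep
}
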