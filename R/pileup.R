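# Pileup-based joint extraction of genotypes and cytosine methylation.
#
# The pileup is represented as a long observation table (one row per
# retained base observation); per-site aggregation yields the six-letter
# allele support {A,C,G,T,R,Y} where Y is a read T seen on a C->T-converted
# strand (could be a true C) and R a read A seen on a G->A-converted strand
# (could be a true G).

#' Build the pileup observation stream from alignment records
#'
#' Excludes unmapped, duplicate-flagged and low-MAPQ records and low-quality
#' bases, and resolves mate overlap so that overlapping mates contribute at
#' most one observation per position (the higher base quality wins, ties to
#' mate 1) - double counting from the same molecule is prevented.
#'
#' @param records alignment record table (coordinate order not required).
#' @param packed packed reference (used by downstream per-site calls).
#' @param min_mapq minimum mapping quality (default 40, the "optimally
#'   mapped" notion used for QC).
#' @param min_baseq minimum base quality (default 20).
#' @return a `data.table` of class `pileup_obs` with columns `qname`,
#'   `mate`, `contig`, `pos`, `base`, `qual` (Phred), `cls` (conversion
#'   class of the read), `tag`, `cycle` (position within the original
#'   read).
#' @export
pileup <- function(records, packed, min_mapq = 40L, min_baseq = 20L) {
  rec <- records[!bitwAnd(flag, 4L) & !dup & mapq >= min_mapq]
  obs <- expand_alignments(rec)
  obs <- obs[qual >= min_baseq]
  setorder(obs, contig, pos, -qual, mate)
  obs <- obs[!duplicated(obs[, .(qname, contig, pos)])]
  setattr(obs, "class", c("pileup_obs", class(obs)))
  obs[]
}

# Expand M-blocks of all records into per-base observations (no filters).
expand_alignments <- function(rec) {
  if (!nrow(rec)) {
    return(data.table(qname = character(), mate = integer(),
                      contig = character(), pos = integer(),
                      base = character(), qual = integer(),
                      cls = character(), tag = character(),
                      cycle = integer()))
  }
  co <- lapply(rec$cigar, cigar_ops)
  opdt <- rbindlist(lapply(co, function(x) data.table(op = x$op, len = x$len)),
                    idcol = "ri")
  opdt[, `:=`(qoff = cumsum(c(0L, head(len * (op %in% c("M", "I", "S")), -1L))),
              roff = cumsum(c(0L, head(len * (op %in% c("M", "D")), -1L)))),
       by = ri]
  mblk <- opdt[op == "M"]
  n <- mblk[, sum(len)]
  ri <- rep(mblk$ri, mblk$len)
  within <- sequence(mblk$len) - 1L
  qpos <- rep(mblk$qoff, mblk$len) + within + 1L
  rpos <- rep(rep(rec$pos, vapply(co, function(x) sum(x$op == "M"), 1L))[
    seq_len(nrow(mblk))], mblk$len) + rep(mblk$roff, mblk$len) + within
  # base and quality characters via one concatenated string
  seqcat <- paste(rec$seq, collapse = "")
  qualcat <- paste(rec$qual, collapse = "")
  offs <- cumsum(c(0L, head(nchar(rec$seq), -1L)))
  allb <- strsplit(seqcat, "", fixed = TRUE)[[1]]
  allq <- utf8ToInt(qualcat) - 33L
  glob <- offs[ri] + qpos
  rl <- nchar(rec$seq)
  minus <- bitwAnd(rec$flag, 16L) > 0L
  mate <- ifelse(bitwAnd(rec$flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(rec$flag, 128L) > 0L, 2L, 0L))
  data.table(qname = rec$qname[ri], mate = mate[ri], contig = rec$rname[ri],
             pos = rpos, base = allb[glob], qual = allq[glob],
             cls = rec$cls[ri], tag = rec$tag[ri],
             cycle = ifelse(minus[ri], rl[ri] - qpos + 1L, qpos))
}

#' Six-letter allele support of one pileup column
#'
#' A read T on a C->T-converted strand becomes Y; a read A on a
#' G->A-converted strand becomes R; every other observation keeps its base.
#'
#' @param column observation rows of a single site (subset of [pileup()]).
#' @return named integer vector with counts over A, C, G, T, R, Y.
#' @export
sixletter_support <- function(column) {
  letter <- sixletter_of(column$base, column$cls)
  counts <- table(factor(letter, levels = c("A", "C", "G", "T", "R", "Y")))
  setNames(as.integer(counts), names(counts))
}

sixletter_of <- function(base, cls) {
  letter <- base
  letter[base == "T" & cls == "C2T"] <- "Y"
  letter[base == "A" & cls == "G2A"] <- "R"
  letter
}

# genome-wide six-letter support counts, one row per covered site
support_table <- function(obs) {
  o <- copy(obs)[base %in% c("A", "C", "G", "T")]
  o[, letter := sixletter_of(base, cls)]
  tab <- o[, .N, by = .(contig, pos, letter)]
  wide <- data.table::dcast(tab, contig + pos ~ letter, value.var = "N",
                            fill = 0L)
  for (l in c("A", "C", "G", "T", "R", "Y"))
    if (is.null(wide[[l]])) wide[, (l) := 0L]
  setorder(wide, contig, pos)
  wide[]
}

#' Reduce six-letter support to the four-letter alphabet
#'
#' The ambiguous Y support is redistributed by four rules (R is handled
#' mirror-wise over A/G): (1) unambiguous evidence for exactly one of C or
#' T adds Y to that base; (2) evidence for both ignores Y; (3) no evidence
#' and the reference is neither C nor T ignores Y; (4) no evidence and the
#' reference is C or T adds Y to the reference allele.
#'
#' @param support named counts over A, C, G, T, R, Y.
#' @param ref_base the reference base at the site.
#' @param unamb_min minimal count that constitutes unambiguous evidence
#'   (default 1 read).
#' @return named counts over A, C, G, T.
#' @export
reduce_support <- function(support, ref_base, unamb_min = 1L) {
  g <- function(x) if (is.na(support[x])) 0L else as.integer(support[x])
  out <- c(A = g("A"), C = g("C"), G = g("G"), T = g("T"))
  y <- g("Y"); r <- g("R")
  if (y > 0L) {
    hasC <- out[["C"]] >= unamb_min; hasT <- out[["T"]] >= unamb_min
    if (hasC && !hasT) out[["C"]] <- out[["C"]] + y
    else if (hasT && !hasC) out[["T"]] <- out[["T"]] + y
    else if (!hasC && !hasT && ref_base %in% c("C", "T"))
      out[[ref_base]] <- out[[ref_base]] + y
  }
  if (r > 0L) {
    hasA <- out[["A"]] >= unamb_min; hasG <- out[["G"]] >= unamb_min
    if (hasA && !hasG) out[["A"]] <- out[["A"]] + r
    else if (hasG && !hasA) out[["G"]] <- out[["G"]] + r
    else if (!hasA && !hasG && ref_base %in% c("A", "G"))
      out[[ref_base]] <- out[[ref_base]] + r
  }
  out
}

#' Genotyping model parameters
#'
#' @param error_rate per-base sequencing error rate e.
#' @param contamination contamination rate c: the probability that an
#'   observation derives from reference-like contaminating material.
#' @param theta empirical polymorphism rate; the heterozygosity prior is
#'   derived from it (hom-ref prior `1 - 3*theta/2`, total het mass
#'   `theta`, total hom-alt mass `theta/2`).
#' @return a list of class `genotype_params`.
#' @export
genotype_params <- function(error_rate = 0.005, contamination = 0.01,
                            theta = 1e-3) {
  stopifnot(error_rate >= 0, error_rate < 1, contamination >= 0,
            contamination < 1, theta >= 0, theta < 1)
  structure(list(error_rate = error_rate, contamination = contamination,
                 theta = theta), class = "genotype_params")
}

.GENOTYPES <- c("A/A", "A/C", "A/G", "A/T", "C/C", "C/G", "C/T",
                "G/G", "G/T", "T/T")
.GT_ALLELES <- matrix(c("A","A", "A","C", "A","G", "A","T", "C","C",
                        "C","G", "C","T", "G","G", "G","T", "T","T"),
                      ncol = 2, byrow = TRUE)

# log P(observed base b | genotype g, ref) for the 4 bases x 10 genotypes
.gt_loglik_matrix <- function(ref_base, params) {
  e <- params$error_rate; cc <- params$contamination
  bases <- c("A", "C", "G", "T")
  pba <- function(b, a) ifelse(b == a, 1 - e, e / 3)
  L <- matrix(0, nrow = 4, ncol = 10, dimnames = list(bases, .GENOTYPES))
  for (gi in 1:10) {
    a1 <- .GT_ALLELES[gi, 1]; a2 <- .GT_ALLELES[gi, 2]
    mix <- 0.5 * pba(bases, a1) + 0.5 * pba(bases, a2)
    L[, gi] <- log((1 - cc) * mix + cc * pba(bases, ref_base))
  }
  L
}

.gt_log_prior <- function(ref_base, params) {
  th <- params$theta
  prior <- rep(th / 6, 10)                    # 6 hets share theta ...
  homs <- which(.GT_ALLELES[, 1] == .GT_ALLELES[, 2])
  prior[homs] <- th / 6                       # ... 3 hom-alts share theta/2
  ref_hom <- which(.GENOTYPES == paste(ref_base, ref_base, sep = "/"))
  prior[ref_hom] <- 1 - 1.5 * th
  log(prior)
}

#' Call a genotype from reduced allele support
#'
#' Bayesian model over the 10 diploid genotypes: per-read likelihood is a
#' contamination-weighted mixture of the genotype allele mixture and the
#' reference allele, both with symmetric sequencing error; the prior puts
#' mass `1 - 3*theta/2` on hom-ref, `theta` on heterozygotes and `theta/2`
#' on hom-alts.
#'
#' @param reduced named four-letter counts from [reduce_support()].
#' @param ref_base reference base.
#' @param params a [genotype_params()].
#' @return a list of class `genotype_call`: `genotype` (e.g. "A/G", NA when
#'   depth is zero), `gq` (Phred of 1 - posterior, capped at 99),
#'   `posterior` (named, sums to 1), `loglik`.
#' @export
genotype_call <- function(reduced, ref_base, params = genotype_params()) {
  counts <- setNames(numeric(4), c("A", "C", "G", "T"))
  counts[names(reduced)] <- reduced
  if (sum(counts) == 0) {
    return(structure(list(genotype = NA_character_, gq = NA_real_,
                          posterior = NULL, loglik = NULL),
                     class = "genotype_call"))
  }
  L <- .gt_loglik_matrix(ref_base, params)
  ll <- drop(counts %*% L) + .gt_log_prior(ref_base, params)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  best <- which.max(post)
  gq <- min(99, -10 * log10(max(1 - post[best], 1e-10)))
  structure(list(genotype = .GENOTYPES[best], gq = gq,
                 posterior = setNames(post, .GENOTYPES),
                 loglik = setNames(ll, .GENOTYPES)),
            class = "genotype_call")
}

# decoded character vector of a whole contig, memoised on the packed object
.contig_chars <- function(packed, cn) {
  env <- packed$chars_env
  if (!is.null(env) && !is.null(env[[cn]])) return(env[[cn]])
  chars <- strsplit(ref_slice(packed, cn, 1L, packed$lengths[[cn]]),
                    "", fixed = TRUE)[[1]]
  if (!is.null(env)) env[[cn]] <- chars
  chars
}

# reference base character vector for sites (contig/pos vectors)
ref_base_at <- function(packed, contig, pos) {
  out <- character(length(pos))
  for (cn in unique(contig)) {
    i <- contig == cn
    out[i] <- .contig_chars(packed, cn)[pos[i]]
  }
  out
}

#' Genome-wide genotype calls from a pileup
#'
#' Aggregates the observation stream into six-letter support, applies the
#' reduction rules and the Bayesian genotype model at every covered site.
#'
#' @param obs a [pileup()] observation table.
#' @param packed packed reference.
#' @param params a [genotype_params()].
#' @param unamb_min see [reduce_support()].
#' @return a `data.table`: `contig`, `pos`, `ref`, `gt`, `gq`, `dp`
#'   (post-reduction depth), `sp` (six-letter support "A:C:G:T:R:Y").
#' @export
call_genotypes <- function(obs, packed, params = genotype_params(),
                           unamb_min = 1L) {
  sup <- support_table(obs)
  if (!nrow(sup)) {
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), gt = character(), gq = numeric(),
                      dp = integer(), sp = character()))
  }
  sup[, ref := ref_base_at(packed, contig, pos)]
  sup <- sup[ref %in% c("A", "C", "G", "T")]
  # vectorized reduction
  red <- as.matrix(sup[, .(A, C, G, T)])
  Yv <- sup$Y; Rv <- sup$R
  hasC <- red[, "C"] >= unamb_min; hasT <- red[, "T"] >= unamb_min
  red[, "C"] <- red[, "C"] + Yv * (hasC & !hasT)
  red[, "T"] <- red[, "T"] + Yv * ((hasT & !hasC) |
    (!hasC & !hasT & sup$ref == "T"))
  red[, "C"] <- red[, "C"] + Yv * (!hasC & !hasT & sup$ref == "C")
  hasA <- red[, "A"] >= unamb_min; hasG <- red[, "G"] >= unamb_min
  red[, "A"] <- red[, "A"] + Rv * ((hasA & !hasG) |
    (!hasA & !hasG & sup$ref == "A"))
  red[, "G"] <- red[, "G"] + Rv * ((hasG & !hasA) |
    (!hasA & !hasG & sup$ref == "G"))
  gt <- character(nrow(sup)); gq <- numeric(nrow(sup))
  for (rb in c("A", "C", "G", "T")) {
    i <- which(sup$ref == rb)
    if (!length(i)) next
    L <- .gt_loglik_matrix(rb, genotype_params(params$error_rate,
                                               params$contamination,
                                               params$theta))
    ll <- red[i, , drop = FALSE] %*% L
    ll <- sweep(ll, 2L, -.gt_log_prior(rb, params), "-")
    mx <- apply(ll, 1L, max)
    post <- exp(ll - mx)
    post <- post / rowSums(post)
    best <- max.col(post, ties.method = "first")
    gt[i] <- .GENOTYPES[best]
    pb <- post[cbind(seq_along(best), best)]
    gq[i] <- pmin(99, -10 * log10(pmax(1 - pb, 1e-10)))
  }
  out <- data.table(contig = sup$contig, pos = sup$pos, ref = sup$ref,
                    gt = gt, gq = gq, dp = as.integer(rowSums(red)),
                    sp = paste(sup$A, sup$C, sup$G, sup$T, sup$R, sup$Y,
                               sep = ":"))
  out[dp == 0L, `:=`(gt = NA_character_, gq = NA_real_)]
  out[]
}

# -- methylation ---------------------------------------------------------------

# classify cytosine contexts for sites; strand "+" means a reference C,
# strand "-" a reference G (a C on the minus strand)
.meth_context <- function(packed, contig, pos, strand, assay) {
  prev <- ref_base_at(packed, contig, pmax(pos - 1L, 1L))
  nxt_pos <- pmin(pos + 1L, packed$lengths[contig])
  nxt <- ref_base_at(packed, contig, nxt_pos)
  prev[pos - 1L < 1L] <- "N"
  nxt[pos + 1L > packed$lengths[contig]] <- "N"
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # 5' and 3' neighbours in the informative strand's own sense
  five <- ifelse(strand == "+", prev, comp[nxt])
  three <- ifelse(strand == "+", nxt, comp[prev])
  if (assay == "WGBS") {
    ctx <- ifelse(three == "G", "CpG",
           ifelse(three == "A", "CpA",
           ifelse(three == "C", "CpC",
           ifelse(three == "T", "CpT", NA_character_))))
    list(context = ctx, flag = rep("", length(ctx)))
  } else {
    ctx <- rep(NA_character_, length(pos))
    ctx[five == "G" & three == "G"] <- "GCG"    # ambiguous, excluded
    ctx[five == "G" & three != "G" & three != "N"] <- "GCH"
    ctx[five != "G" & five != "N" & three == "G"] <- "HCG"
    flag <- ifelse(five == "C" & three == "G", "CCG", "")
    list(context = ctx, flag = flag)
  }
}

#' Genome-wide cytosine methylation calls
#'
#' Retained (unconverted) and converted counts on the informative strand:
#' C->T-class reads inform reference C positions; G->A-class reads inform
#' reference G positions (cytosines of the minus strand). Contexts are
#' taken from the 4-base reference. For WGBS the CpH contexts are split
#' into CpA, CpC and CpT. For NOMe, HCG sites report endogenous
#' methylation, GCH sites report accessibility, GCG sites are excluded as
#' ambiguous, and CCG sites are retained but flagged for optional post-hoc
#' filtering.
#'
#' @param obs a [pileup()] observation table.
#' @param packed packed reference.
#' @param assay `"WGBS"` or `"NOMe"`.
#' @param min_depth beta is reported only when M + U >= `min_depth`.
#' @return a `data.table`: `contig`, `pos`, `strand`, `context`, `flag`,
#'   `M` (retained), `U` (converted), `beta`.
#' @export
meth_table <- function(obs, packed, assay = c("WGBS", "NOMe"),
                       min_depth = 1L) {
  assay <- match.arg(assay)
  o <- copy(obs)
  o[, ref := ref_base_at(packed, contig, pos)]
  plus <- o[ref == "C" & cls == "C2T" & base %in% c("C", "T")]
  minus <- o[ref == "G" & cls == "G2A" & base %in% c("G", "A")]
  plus[, `:=`(strand = "+", retained = base == "C")]
  minus[, `:=`(strand = "-", retained = base == "G")]
  cyt <- rbindlist(list(plus, minus))
  if (!nrow(cyt)) {
    return(data.table(contig = character(), pos = integer(),
                      strand = character(), context = character(),
                      flag = character(), M = integer(), U = integer(),
                      beta = numeric()))
  }
  agg <- cyt[, .(M = sum(retained), U = sum(!retained)),
             by = .(contig, pos, strand)]
  ctx <- .meth_context(packed, agg$contig, agg$pos, agg$strand, assay)
  agg[, `:=`(context = ctx$context, flag = ctx$flag)]
  agg <- agg[!is.na(context)]
  if (assay == "NOMe") agg <- agg[context != "GCG"]
  agg[, beta := ifelse(M + U >= min_depth, M / (M + U), NA_real_)]
  setorder(agg, contig, pos, strand)
  agg[, .(contig, pos, strand, context, flag, M, U, beta)]
}

#' Methylation/accessibility call at one pileup column
#'
#' Single-site counterpart of [meth_table()]; returns `NULL` for sites
#' that are not an informative cytosine (or are NOMe GCG-excluded).
#'
#' @param column observation rows of one site.
#' @param packed packed reference.
#' @param assay `"WGBS"` or `"NOMe"`.
#' @param min_depth minimum covered depth for a beta value.
#' @return a one-row `data.table` as in [meth_table()], or `NULL`.
#' @export
call_methylation <- function(column, packed, assay = c("WGBS", "NOMe"),
                             min_depth = 1L) {
  res <- meth_table(column, packed, assay, min_depth)
  if (!nrow(res)) return(NULL)
  res
}
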