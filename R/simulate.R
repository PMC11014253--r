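# Synthetic bisulfite-sequencing data with full truth tables: diploid
# genomes with planted SNPs, per-cytosine methylation levels by context,
# strand-specific conversion, paired-end reads with sequencing error, and
# optional chimeric inserts. The simulator is the ground-truth harness for
# the aligner, caller, QC and epiBED modules.

#' Simulation configuration
#'
#' Defaults describe a typical well-converted directional WGBS experiment:
#' CpG methylation is bimodal (Beta with mean 0.7 and low concentration,
#' shared across the two strands of a CpG as maintenance methylation
#' makes CpGs strand-symmetric), CpH methylation is absent, conversion is
#' 98% efficient and sequencing error is 0.1%.
#'
#' @param genome_length total genome length (split over `contig_count`).
#' @param contig_count number of contigs.
#' @param gc_fraction genome GC content.
#' @param snp_rate per-base probability of a planted SNP.
#' @param het_fraction probability a planted SNP is heterozygous.
#' @param meth_cpg,meth_cpa,meth_cpc,meth_cpt mean methylation per context.
#' @param meth_gpc NOMe GpC accessibility mean (NULL for plain WGBS).
#' @param beta_concentration concentration (a+b) of the per-cytosine Beta
#'   distribution; values below 1 give the bimodal methylomes seen in real
#'   tissues.
#' @param conversion_rate probability an unmethylated cytosine converts.
#' @param sequencing_error_rate i.i.d. per-base error probability.
#' @param read_length,insert_mean,insert_sd,depth read geometry.
#' @param mode `"directional"` or `"non_directional"`.
#' @param chimera_rate probability that mate 2 derives from an unrelated
#'   locus (single-cell style chimeric inserts).
#' @param dup_rate probability a finished pair is emitted twice (exact
#'   copy; for duplicate-marking tests).
#' @param rng_seed mandatory random seed; simulation output is
#'   byte-reproducible given the seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e5, contig_count = 1L,
                       gc_fraction = 0.42, snp_rate = 1e-3,
                       het_fraction = 0.5, meth_cpg = 0.7, meth_cpa = 0,
                       meth_cpc = 0, meth_cpt = 0, meth_gpc = NULL,
                       beta_concentration = 0.5, conversion_rate = 0.98,
                       sequencing_error_rate = 0.001, read_length = 100L,
                       insert_mean = 300, insert_sd = 30, depth = 30,
                       mode = c("directional", "non_directional"),
                       chimera_rate = 0, dup_rate = 0, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for reproducibility")
  mode <- match.arg(mode)
  rates <- c(gc_fraction, snp_rate, het_fraction, meth_cpg, meth_cpa,
             meth_cpc, meth_cpt, conversion_rate, sequencing_error_rate,
             chimera_rate, dup_rate)
  stopifnot(all(rates >= 0 & rates <= 1), genome_length >= 1,
            read_length >= 1, depth > 0, rng_seed < 2^31 - 10)
  structure(list(genome_length = as.integer(genome_length),
                 contig_count = as.integer(contig_count),
                 gc_fraction = gc_fraction, snp_rate = snp_rate,
                 het_fraction = het_fraction, meth_cpg = meth_cpg,
                 meth_cpa = meth_cpa, meth_cpc = meth_cpc,
                 meth_cpt = meth_cpt, meth_gpc = meth_gpc,
                 beta_concentration = beta_concentration,
                 conversion_rate = conversion_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 depth = depth, mode = mode, chimera_rate = chimera_rate,
                 dup_rate = dup_rate, rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate a diploid genome with planted SNPs
#'
#' Bases are i.i.d. at the configured GC fraction; SNPs are planted at
#' `snp_rate`, heterozygous with probability `het_fraction`, with the
#' alternate allele uniform over the three non-reference bases.
#' Haplotype 1 carries hom-alt alleles; haplotype 2 additionally carries
#' the het alleles.
#'
#' @param config a [sim_config()]; draws come from a stream seeded with
#'   `rng_seed` (documented draw order; byte-reproducible).
#' @return a list: `ref` (a [reference()]), `snps` truth table (`contig`,
#'   `pos` 1-based, `ref`, `alt`, `genotype` "het"/"hom"), `haplotypes`
#'   (named list of two character vectors of contig sequences).
#' @export
simulate_genome <- function(config) {
  set.seed(config$rng_seed)
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- rep(config$genome_length %/% config$contig_count,
              config$contig_count)
  lens[1] <- lens[1] + config$genome_length %% config$contig_count
  contigs <- paste0("chr", seq_len(config$contig_count))
  seqs <- character(length(lens))
  snp_list <- list()
  hap1 <- hap2 <- character(length(lens))
  for (i in seq_along(lens)) {
    chars <- sample(names(probs), lens[i], replace = TRUE, prob = probs)
    seqs[i] <- paste(chars, collapse = "")
    is_snp <- which(runif(lens[i]) < config$snp_rate)
    h1 <- h2 <- chars
    if (length(is_snp)) {
      alt <- vapply(chars[is_snp], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      het <- runif(length(is_snp)) < config$het_fraction
      h2[is_snp] <- alt
      h1[is_snp[!het]] <- alt[!het]
      snp_list[[i]] <- data.table(contig = contigs[i], pos = is_snp,
                                  ref = chars[is_snp], alt = unname(alt),
                                  genotype = ifelse(het, "het", "hom"))
    }
    hap1[i] <- paste(h1, collapse = "")
    hap2[i] <- paste(h2, collapse = "")
  }
  snps <- if (length(snp_list)) rbindlist(snp_list) else
    data.table(contig = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character())
  list(ref = reference(setNames(seqs, contigs)),
       snps = snps,
       haplotypes = list(hap1 = setNames(hap1, contigs),
                         hap2 = setNames(hap2, contigs)))
}

# draw one beta value given a context mean and concentration
.draw_beta <- function(n, mean, conc) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Assign per-cytosine methylation truth
#'
#' Every cytosine on both strands receives a beta value drawn from a Beta
#' distribution with its context mean. CpG cytosines share one beta across
#' the two strands of the dinucleotide (strand-symmetric maintenance
#' methylation); CpH cytosines are independent. With `meth_gpc` set, GCH
#' cytosines use the accessibility mean and GCG cytosines are assigned
#' like HCG (they are simply excluded at extraction).
#'
#' @param config a [sim_config()]; uses a stream seeded `rng_seed + 1`.
#' @param ref a [reference()] object.
#' @return a `data.table`: `contig`, `pos` (1-based position of the C on
#'   its strand), `strand`, `context`, `beta`.
#' @export
assign_methylation <- function(config, ref) {
  set.seed(config$rng_seed + 1L)
  conc <- config$beta_concentration
  out <- list()
  for (cn in names(ref)) {
    chars <- strsplit(unclass(ref)[[cn]], "", fixed = TRUE)[[1]]
    L <- length(chars)
    mean_of <- function(ctx) switch(ctx, CpG = config$meth_cpg,
                                    CpA = config$meth_cpa,
                                    CpC = config$meth_cpc,
                                    CpT = config$meth_cpt,
                                    GpC = config$meth_gpc)
    # plus-strand cytosines
    cp <- which(chars == "C")
    nxt <- ifelse(cp < L, chars[pmin(cp + 1L, L)], "N")
    ctx_p <- ifelse(nxt == "G", "CpG",
             ifelse(nxt == "N", NA, paste0("Cp", nxt)))
    # minus-strand cytosines (reference G); 3' neighbour on minus strand
    # is the complement of the base to the left
    gp <- which(chars == "G")
    prv <- ifelse(gp > 1L, chars[pmax(gp - 1L, 1L)], "N")
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ctx_m <- ifelse(prv == "C", "CpG",
             ifelse(prv == "N", NA, paste0("Cp", comp[prv])))
    dt <- rbind(data.table(pos = cp, strand = "+", context = ctx_p),
                data.table(pos = gp, strand = "-", context = ctx_m))
    dt <- dt[!is.na(context)]
    # NOMe: GpC cytosines (GCH context) follow the accessibility mean
    if (!is.null(config$meth_gpc)) {
      five_p <- ifelse(cp > 1L, chars[pmax(cp - 1L, 1L)], "N")
      gch_p <- cp[five_p == "G" & nxt != "G" & nxt != "N"]
      five_m <- ifelse(gp < L, chars[pmin(gp + 1L, L)], "N")
      gch_m <- gp[comp[five_m] == "G" & comp[prv] != "G" & prv != "N"]
      dt[strand == "+" & pos %in% gch_p, context := "GpC"]
      dt[strand == "-" & pos %in% gch_m, context := "GpC"]
    }
    setorder(dt, pos, strand)
    dt[, beta := 0]
    # symmetric CpG: one draw per dinucleotide, shared by both strands
    cpg_plus <- dt[context == "CpG" & strand == "+", pos]
    cpg_pair <- cpg_plus[(cpg_plus + 1L) %in% dt[context == "CpG" &
                                                   strand == "-", pos]]
    bcpg <- .draw_beta(length(cpg_pair), config$meth_cpg, conc)
    dt[context == "CpG" & strand == "+" & pos %in% cpg_pair,
       beta := bcpg[match(pos, cpg_pair)]]
    dt[context == "CpG" & strand == "-" & (pos - 1L) %in% cpg_pair,
       beta := bcpg[match(pos - 1L, cpg_pair)]]
    solo <- dt[context == "CpG" &
                 !((strand == "+" & pos %in% cpg_pair) |
                     (strand == "-" & (pos - 1L) %in% cpg_pair))]
    if (nrow(solo)) {
      b <- .draw_beta(nrow(solo), config$meth_cpg, conc)
      dt[solo, on = c("pos", "strand"), beta := b]
    }
    for (ctx in c("CpA", "CpC", "CpT", "GpC")) {
      idx <- which(dt$context == ctx)
      if (length(idx))
        dt[idx, beta := .draw_beta(length(idx), mean_of(ctx), conc)]
    }
    dt[, contig := cn]
    out[[cn]] <- dt[, .(contig, pos, strand, context, beta)]
  }
  rbindlist(out)
}

#' Simulate paired-end bisulfite reads
#'
#' Fragments are drawn uniformly from the two haplotypes and the two
#' original strands; each molecule's cytosines are methylated Bernoulli
#' (beta) and, when unmethylated, converted with probability
#' `conversion_rate` on the molecule's own strand sense. Mate 1 reads the
#' molecule 5' end (original strands OT/OB in directional mode), mate 2
#' the PCR complement (CTOT/CTOB); non-directional mode swaps mate roles
#' with probability 1/2. Sequencing errors are i.i.d.; with probability
#' `chimera_rate` mate 2 is drawn from an unrelated locus. Uses a stream
#' seeded `rng_seed + 2`.
#'
#' @param config a [sim_config()].
#' @param genome result of [simulate_genome()].
#' @param meth methylation truth from [assign_methylation()].
#' @return a list: `r1`, `r2` (`data.table`s with `name`, `seq`, `qual`),
#'   `truth` (per emitted read: `name`, `mate`, `contig`, `pos` 1-based
#'   leftmost alignment position, `strand`, `bs_tag`, `chimeric`,
#'   `duplicate`).
#' @export
simulate_reads <- function(config, genome, meth) {
  set.seed(config$rng_seed + 2L)
  rl <- config$read_length
  contigs <- names(genome$ref)
  lens <- nchar(unclass(genome$ref))
  npair <- round(config$genome_length * config$depth / (2 * rl))
  # per-contig beta lookup vectors
  bplus <- bminus <- list()
  for (cn in contigs) {
    bp <- rep(NA_real_, lens[[cn]]); bm <- rep(NA_real_, lens[[cn]])
    mp <- meth[contig == cn & strand == "+"]
    mm <- meth[contig == cn & strand == "-"]
    bp[mp$pos] <- mp$beta; bm[mm$pos] <- mm$beta
    bplus[[cn]] <- bp; bminus[[cn]] <- bm
  }
  hap_chars <- lapply(genome$haplotypes, function(h)
    lapply(h, function(s) strsplit(s, "", fixed = TRUE)[[1]]))

  draw_fragment <- function() {
    cn <- if (length(contigs) == 1L) contigs else
      sample(contigs, 1L, prob = lens / sum(lens))
    L <- lens[[cn]]
    flen <- max(rl, min(L, round(rnorm(1, config$insert_mean,
                                       config$insert_sd))))
    start <- sample.int(L - flen + 1L, 1L)
    hap <- sample(1:2, 1L)
    top <- runif(1) < 0.5
    list(contig = cn, start = start, flen = flen, hap = hap, top = top)
  }

  convert_fragment <- function(fr) {
    chars <- hap_chars[[fr$hap]][[fr$contig]][fr$start:(fr$start + fr$flen - 1L)]
    if (fr$top) {
      tgt <- which(chars == "C")
      bet <- bplus[[fr$contig]][fr$start + tgt - 1L]
      sub <- "T"
    } else {
      tgt <- which(chars == "G")
      bet <- bminus[[fr$contig]][fr$start + tgt - 1L]
      sub <- "A"
    }
    if (length(tgt)) {
      bet[is.na(bet)] <- 0   # SNP-created cytosines default unmethylated
      methylated <- runif(length(tgt)) < bet
      converted <- !methylated & runif(length(tgt)) < config$conversion_rate
      chars[tgt[converted]] <- sub
    }
    chars
  }

  r1_seq <- character(npair); r2_seq <- character(npair)
  tr <- vector("list", npair)
  for (i in seq_len(npair)) {
    fr <- draw_fragment()
    conv <- convert_fragment(fr)
    fl <- fr$flen
    if (fr$top) {
      m1 <- paste(conv[1:rl], collapse = "")
      m2 <- revcomp(paste(conv[(fl - rl + 1L):fl], collapse = ""))
      p1 <- fr$start; s1 <- "+"; t1 <- "OT"
      p2 <- fr$start + fl - rl; s2 <- "-"; t2 <- "CTOT"
    } else {
      m1 <- revcomp(paste(conv[(fl - rl + 1L):fl], collapse = ""))
      m2 <- paste(conv[1:rl], collapse = "")
      p1 <- fr$start + fl - rl; s1 <- "-"; t1 <- "OB"
      p2 <- fr$start; s2 <- "+"; t2 <- "CTOB"
    }
    chim <- FALSE
    if (config$chimera_rate > 0 && runif(1) < config$chimera_rate) {
      fr2 <- draw_fragment()
      conv2 <- convert_fragment(fr2)
      fl2 <- fr2$flen
      if (fr2$top) {
        m2 <- revcomp(paste(conv2[(fl2 - rl + 1L):fl2], collapse = ""))
        p2 <- fr2$start + fl2 - rl; s2 <- "-"; t2 <- "CTOT"
      } else {
        m2 <- paste(conv2[1:fl2][1:rl], collapse = "")
        p2 <- fr2$start; s2 <- "+"; t2 <- "CTOB"
      }
      chim <- TRUE
      ct2 <- fr2$contig
    } else ct2 <- fr$contig
    if (config$mode == "non_directional" && runif(1) < 0.5) {
      tmp <- m1; m1 <- m2; m2 <- tmp
      tp <- p1; p1 <- p2; p2 <- tp
      ts <- s1; s1 <- s2; s2 <- ts
      tt <- t1; t1 <- t2; t2 <- tt
      tc <- fr$contig; ct1 <- ct2; ct2 <- tc
    } else ct1 <- fr$contig
    r1_seq[i] <- m1; r2_seq[i] <- m2
    tr[[i]] <- data.table(
      name = sprintf("sim_%06d", i), mate = c(1L, 2L),
      contig = c(ct1, ct2), pos = c(p1, p2), strand = c(s1, s2),
      bs_tag = c(t1, t2), chimeric = chim, duplicate = FALSE)
  }
  names_v <- sprintf("sim_%06d", seq_len(npair))
  # i.i.d. sequencing errors over both mate sets
  add_errors <- function(seqs) {
    e <- config$sequencing_error_rate
    if (e <= 0) return(seqs)
    chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < e)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    apply(matrix(chars, nrow = nchar(seqs[1])), 2L, paste, collapse = "")
  }
  r1_seq <- add_errors(r1_seq)
  r2_seq <- add_errors(r2_seq)
  truth <- rbindlist(tr)
  r1 <- data.table(name = names_v, seq = r1_seq, qual = strrep("F", rl))
  r2 <- data.table(name = names_v, seq = r2_seq, qual = strrep("F", rl))
  if (config$dup_rate > 0) {
    dup <- which(runif(npair) < config$dup_rate)
    if (length(dup)) {
      dn <- paste0(names_v[dup], "_dup")
      r1 <- rbind(r1, data.table(name = dn, seq = r1_seq[dup],
                                 qual = strrep("F", rl)))
      r2 <- rbind(r2, data.table(name = dn, seq = r2_seq[dup],
                                 qual = strrep("F", rl)))
      dtr <- truth[name %in% names_v[dup]]
      dtr[, `:=`(name = paste0(name, "_dup"), duplicate = TRUE)]
      truth <- rbind(truth, dtr)
    }
  }
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Run the full simulation
#'
#' Seeds one stream per stage from `rng_seed` and runs
#' [simulate_genome()], [assign_methylation()] and [simulate_reads()].
#'
#' @param config a [sim_config()].
#' @return a list: `config`, `ref`, `snps`, `haplotypes`, `meth`, `reads`.
#' @export
run_simulation <- function(config) {
  genome <- simulate_genome(config)
  meth <- assign_methylation(config, genome$ref)
  reads <- simulate_reads(config, genome, meth)
  list(config = config, ref = genome$ref, snps = genome$snps,
       haplotypes = genome$haplotypes, meth = meth, reads = reads)
}

#' Write simulated reads as FASTQ
#'
#' @param reads `r1` or `r2` table from [simulate_reads()].
#' @param path output path; `.gz` suffix gzips.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$name), reads$seq, "+",
                           reads$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (gzip allowed).
#' @return a `data.table` with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  stopifnot(length(lines) %% 4 == 0)
  data.table(name = sub("^@", "", sub("\\s.*", "", lines[c(TRUE, FALSE, FALSE, FALSE)])),
             seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
             qual = lines[c(FALSE, FALSE, FALSE, TRUE)])
}
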