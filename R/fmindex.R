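# Dual 3-base FM-indexes.
#
# Each index covers the in-silico-converted concatenation of the forward and
# reverse strands of the whole genome:
#
#   text = conv(F) '!' conv(revcomp(F)) '$'
#
# where F joins all contigs with the never-matching junction symbol X, and
# conv is C->T (the "C-less" index) or G->A (the "G-less" index). Applying
# the complement map A<->T, C<->G (X self-paired) after conversion makes the
# two indexed strand sequences exact reverse complements of one another, so
# plain backward search on both indexes covers both search directions.

INDEX_FORMAT_VERSION <- "methsuite-index-v1"

#' Build a converted (3-base) FM-index
#'
#' @param ref a [reference()] object.
#' @param kind `"C_LESS"` (all C converted to T) or `"G_LESS"` (G to A).
#' @param sa_spacing keep every `sa_spacing`-th suffix-array value for
#'   locating (1 keeps all).
#' @param occ_spacing spacing of occurrence-count checkpoints over the BWT.
#' @return an object of class `converted_index`.
#' @export
build_converted_index <- function(ref, kind = c("C_LESS", "G_LESS"),
                                  sa_spacing = 4L, occ_spacing = 64L) {
  kind <- match.arg(kind)
  stopifnot(inherits(ref, "bs_reference"), sa_spacing >= 1L, occ_spacing >= 1L)
  joined <- paste(unclass(ref), collapse = "X")
  fwd <- convert_seq(joined, kind)
  rev <- convert_seq(revcomp(joined), kind)
  text <- paste0(fwd, "!", rev, "$")
  codes <- dna_to_codes(text)
  sa <- build_sa_cpp(codes)                       # 0-based
  n <- length(codes)
  prev <- (sa + n - 1L) %% n
  bwt <- codes[prev + 1L]
  counts <- tabulate(codes + 1L, nbins = 7L)
  Cc <- c(0L, cumsum(counts))[1:7]                # symbols < c
  occ <- occ_build_cpp(bwt, occ_spacing)
  sa_sample <- ifelse(sa %% sa_spacing == 0L, sa, -1L)
  lens <- nchar(unclass(ref))
  structure(list(
    kind = kind,
    text = codes,
    n = n,
    L = nchar(joined),
    bwt = bwt,
    C = Cc,
    occ = occ,
    occ_spacing = as.integer(occ_spacing),
    sa_spacing = as.integer(sa_spacing),
    sa_sample = as.integer(sa_sample),
    contig_names = names(ref),
    contig_lengths = setNames(as.integer(lens), names(ref)),
    # 1-based start of each contig within the joined forward strand
    contig_starts = setNames(
      cumsum(c(1L, head(as.integer(lens), -1L) + 1L)), names(ref)),
    version = INDEX_FORMAT_VERSION
  ), class = "converted_index")
}

#' @export
print.converted_index <- function(x, ...) {
  cat("<converted_index> ", x$kind, ", ", length(x$contig_names),
      " contig(s), indexed length ", x$n, "\n", sep = "")
  invisible(x)
}

#' Backward search over a converted index
#'
#' Finds the suffix-array interval of all exact occurrences of `pattern`
#' in the indexed (converted, double-stranded) text. Patterns containing a
#' symbol absent from the index alphabet (e.g. a C searched in the C-less
#' index, or an N) yield the empty interval.
#'
#' @param index a [build_converted_index()] object.
#' @param pattern a DNA string.
#' @return a list with class `sa_interval`: `lower`, `upper` (half-open row
#'   interval), `matched` (number of pattern symbols consumed before the
#'   interval emptied; equals `nchar(pattern)` on success), and `n_hits`.
#' @export
backward_search <- function(index, pattern) {
  codes <- read_to_codes(pattern)
  res <- backward_search_cpp(index$bwt, index$occ, index$C,
                             index$occ_spacing, codes)
  structure(list(lower = res[1], upper = res[2], matched = res[3],
                 n_hits = max(0L, res[2] - res[1])),
            class = "sa_interval")
}

#' Resolve a suffix-array interval to genomic coordinates
#'
#' Text offsets are recovered by LF-walking to the nearest sampled
#' suffix-array row, then mapped back to (contig, position, strand).
#'
#' @param index a `converted_index`.
#' @param interval an `sa_interval` from [backward_search()].
#' @param max_hits stop after this many hits (truncation is flagged).
#' @return a `data.table` with columns `text_pos` (0-based offset in the
#'   indexed text), `contig`, `pos` (1-based position on the forward genome
#'   of the first matched character) and `strand`; attribute `truncated`.
#' @export
locate_hits <- function(index, interval, max_hits = 100L) {
  if (interval$upper <= interval$lower) {
    out <- data.table(text_pos = integer(), contig = character(),
                      pos = integer(), strand = character())
    attr(out, "truncated") <- FALSE
    return(out)
  }
  res <- locate_cpp(index$bwt, index$occ, index$C, index$occ_spacing,
                    index$sa_sample, interval$lower, interval$upper,
                    as.integer(max_hits))
  tp <- res$positions
  gm <- text_to_genome(index, tp)
  out <- data.table(text_pos = tp, contig = gm$contig, pos = gm$pos,
                    strand = gm$strand)
  attr(out, "truncated") <- res$truncated
  out
}

# Map 0-based text offsets to (contig, 1-based forward position, strand).
# Sentinels and junction symbols map to NA.
text_to_genome <- function(index, text_pos) {
  L <- index$L
  strand <- rep(NA_character_, length(text_pos))
  joinpos <- rep(NA_integer_, length(text_pos))
  f <- text_pos < L
  strand[f] <- "+"
  joinpos[f] <- text_pos[f] + 1L
  r <- text_pos > L & text_pos < (2L * L + 1L)
  strand[r] <- "-"
  joinpos[r] <- L - (text_pos[r] - L - 1L)
  starts <- index$contig_starts
  lens <- index$contig_lengths
  idx <- findInterval(joinpos, starts)
  ok <- !is.na(joinpos) & idx >= 1L &
    joinpos <= (starts[pmax(idx, 1L)] + lens[pmax(idx, 1L)] - 1L)
  contig <- ifelse(ok, index$contig_names[idx], NA_character_)
  pos <- ifelse(ok, joinpos - starts[pmax(idx, 1L)] + 1L, NA_integer_)
  strand[!ok] <- NA_character_
  list(contig = contig, pos = as.integer(pos), strand = strand)
}

# Map a match of `len` characters starting at 0-based text offset to the
# genomic span it covers: (contig, 1-based leftmost forward position,
# strand). Returns NAs if the span leaves a contig (cannot happen for real
# matches, which never cross sentinels or junctions).
text_span_to_genome <- function(index, text_pos, len) {
  first <- text_to_genome(index, text_pos)
  last <- text_to_genome(index, text_pos + len - 1L)
  ok <- !is.na(first$contig) & !is.na(last$contig) &
    first$contig == last$contig
  start <- ifelse(first$strand == "+", first$pos, last$pos)
  list(contig = ifelse(ok, first$contig, NA_character_),
       start = as.integer(ifelse(ok, start, NA_integer_)),
       strand = ifelse(ok, first$strand, NA_character_))
}

#' Persist a converted index to a directory
#'
#' Writes a documented plain-text single-directory layout with a version
#' stamp: `meta.json` (parameters and contig table), `text.txt`,
#' `bwt.txt` (one encoded symbol stream each) and `sa.txt` (sampled
#' suffix-array values, -1 where unsampled). Occurrence checkpoints are
#' recomputed on load.
#'
#' @param index a `converted_index`.
#' @param dir output directory (created if needed); one subdirectory per
#'   conversion kind is conventional, see [save_index_pair()].
#' @export
save_index <- function(index, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(version = index$version, kind = index$kind, n = index$n,
               L = index$L, sa_spacing = index$sa_spacing,
               occ_spacing = index$occ_spacing,
               contig_names = index$contig_names,
               contig_lengths = unname(index$contig_lengths),
               C = index$C)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  fwrite(list(index$text), file.path(dir, "text.txt"), col.names = FALSE)
  fwrite(list(index$bwt), file.path(dir, "bwt.txt"), col.names = FALSE)
  fwrite(list(index$sa_sample), file.path(dir, "sa.txt"), col.names = FALSE)
  invisible(dir)
}

#' Load a converted index saved by [save_index()]
#'
#' @param dir directory written by [save_index()].
#' @return a `converted_index` answering every query identically to the
#'   saved object.
#' @export
load_index <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not an index directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$version, INDEX_FORMAT_VERSION))
    stop("unsupported index version: ", meta$version)
  text <- fread(file.path(dir, "text.txt"), header = FALSE)[[1]]
  bwt <- fread(file.path(dir, "bwt.txt"), header = FALSE)[[1]]
  sa_sample <- fread(file.path(dir, "sa.txt"), header = FALSE)[[1]]
  lens <- setNames(as.integer(meta$contig_lengths), meta$contig_names)
  structure(list(
    kind = meta$kind, text = as.integer(text), n = as.integer(meta$n),
    L = as.integer(meta$L), bwt = as.integer(bwt),
    C = as.integer(meta$C),
    occ = occ_build_cpp(as.integer(bwt), as.integer(meta$occ_spacing)),
    occ_spacing = as.integer(meta$occ_spacing),
    sa_spacing = as.integer(meta$sa_spacing),
    sa_sample = as.integer(sa_sample),
    contig_names = meta$contig_names,
    contig_lengths = lens,
    contig_starts = setNames(
      cumsum(c(1L, head(as.integer(lens), -1L) + 1L)), meta$contig_names),
    version = meta$version
  ), class = "converted_index")
}

#' Build and persist both conversion indexes plus the packed reference
#'
#' Convenience wrapper used by the `index` command-line subcommand: builds
#' the C-less and G-less indexes and stores them under `dir/c_less` and
#' `dir/g_less`, together with the reference FASTA needed for 4-base
#' scoring.
#'
#' @param ref a [reference()] object.
#' @param dir output directory.
#' @param sa_spacing,occ_spacing see [build_converted_index()].
#' @return `dir`, invisibly.
#' @export
save_index_pair <- function(ref, dir, sa_spacing = 4L, occ_spacing = 64L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_index(build_converted_index(ref, "C_LESS", sa_spacing, occ_spacing),
             file.path(dir, "c_less"))
  save_index(build_converted_index(ref, "G_LESS", sa_spacing, occ_spacing),
             file.path(dir, "g_less"))
  write_fasta(ref, file.path(dir, "reference.fa"))
  invisible(dir)
}

#' Load an index pair written by [save_index_pair()]
#'
#' @param dir directory written by [save_index_pair()].
#' @return a list with `indexes` (named list `C_LESS`, `G_LESS`), `packed`
#'   (the packed reference) and `ref`.
#' @export
load_index_pair <- function(dir) {
  ref <- read_fasta(file.path(dir, "reference.fa"))
  list(indexes = list(C_LESS = load_index(file.path(dir, "c_less")),
                      G_LESS = load_index(file.path(dir, "g_less"))),
       packed = pack_reference(ref),
       ref = ref)
}
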