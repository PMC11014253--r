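# Reference genome container and the 2-bit packed representation used during
# alignment. The packed form keeps bases in 2 bits each (A=0, C=1, G=2, T=3)
# with an explicit N mask, so unpacking reproduces the input exactly.

#' Construct a reference genome object
#'
#' @param sequences named character vector of contig sequences (A/C/G/T/N).
#'   Names are contig names; they must be unique and nonempty.
#' @return an object of class `bs_reference`.
#' @examples
#' ref <- reference(c(chr1 = "ACGTNACGT"))
#' @export
reference <- function(sequences) {
  if (length(sequences) < 1) stop("at least one contig is required")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("contig names must be nonempty")
  if (anyDuplicated(nm)) stop("contig names must be unique")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0)) stop("empty contig sequence")
  bad <- regexpr("[^ACGTN]", sequences)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-ACGTN character in contig '", nm[i], "' at position ", bad[i])
  }
  structure(as.character(sequences) |> setNames(nm), class = "bs_reference")
}

#' Read a reference genome from FASTA
#'
#' Accepts multi-contig, wrapped or unwrapped FASTA, optionally gzipped.
#'
#' @param path path to a FASTA file.
#' @return a [reference()] object.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  reference(setNames(as.character(ss), nm))
}

#' Write a reference genome to FASTA
#'
#' @param ref a [reference()] object.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(ss, path, width = width)
}

#' Pack a reference into 2-bit form
#'
#' Bases are stored four to a byte with an N-position mask per contig;
#' [unpack_reference()] restores the original sequences exactly.
#'
#' @param ref a [reference()] object.
#' @return an object of class `packed_reference` with per-contig packed
#'   bytes, N masks, cumulative offsets and total length.
#' @export
pack_reference <- function(ref) {
  stopifnot(inherits(ref, "bs_reference"))
  contigs <- names(ref)
  lens <- nchar(unclass(ref))
  packed <- vector("list", length(ref))
  nmask <- vector("list", length(ref))
  for (i in seq_along(ref)) {
    chars <- strsplit(ref[[i]], "", fixed = TRUE)[[1]]
    code <- match(chars, c("A", "C", "G", "T")) - 1L
    nmask[[i]] <- which(is.na(code))
    code[is.na(code)] <- 0L
    pad <- (4L - length(code) %% 4L) %% 4L
    code <- c(code, integer(pad))
    m <- matrix(code, nrow = 4L)
    packed[[i]] <- as.raw(m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ])
  }
  names(packed) <- names(nmask) <- contigs
  structure(list(
    contigs = contigs,
    lengths = setNames(as.integer(lens), contigs),
    offsets = setNames(cumsum(c(0L, as.integer(lens)[-length(lens)])), contigs),
    packed = packed,
    nmask = nmask,
    total_length = sum(as.integer(lens)),
    # decode cache (environment: shared by reference across copies)
    chars_env = new.env(parent = emptyenv())
  ), class = "packed_reference")
}

#' Unpack a packed reference
#'
#' @param packed a [pack_reference()] object.
#' @return the original [reference()] object, byte-identical round trip.
#' @export
unpack_reference <- function(packed) {
  stopifnot(inherits(packed, "packed_reference"))
  seqs <- vapply(packed$contigs, function(cn) {
    ref_slice(packed, cn, 1L, packed$lengths[[cn]])
  }, character(1))
  reference(setNames(seqs, packed$contigs))
}

#' Random-access slice of a packed reference
#'
#' @param packed a `packed_reference`.
#' @param contig contig name.
#' @param start,end 1-based inclusive positions.
#' @return the sequence as a character string (with Ns restored).
#' @export
ref_slice <- function(packed, contig, start, end) {
  codes <- ref_slice_codes(packed, contig, start, end)
  chars <- c("A", "C", "G", "T", "N")[codes - 1L]
  paste(chars, collapse = "")
}

# integer-code slice (2..5 bases, 6 for N); 1-based inclusive coordinates
ref_slice_codes <- function(packed, contig, start, end) {
  len <- unname(packed$lengths[contig])
  if (is.na(len)) stop("unknown contig: ", contig)
  if (start < 1L || end > len || start > end)
    stop("slice out of range for contig ", contig)
  b0 <- (start - 1L) %/% 4L           # first byte index (0-based)
  b1 <- (end - 1L) %/% 4L
  bytes <- as.integer(packed$packed[[contig]][(b0 + 1L):(b1 + 1L)])
  quads <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  flat <- as.integer(quads)           # bases b0*4+1 .. (b1+1)*4
  lead <- (start - 1L) %% 4L
  codes <- flat[(lead + 1L):(lead + (end - start + 1L))] + 2L
  nm <- packed$nmask[[contig]]
  if (length(nm)) {
    hit <- nm[nm >= start & nm <= end]
    if (length(hit)) codes[hit - start + 1L] <- 6L
  }
  codes
}

#' @export
print.bs_reference <- function(x, ...) {
  cat("<bs_reference> ", length(x), " contig(s), ",
      sum(nchar(unclass(x))), " bp total\n", sep = "")
  invisible(x)
}

#' @export
print.packed_reference <- function(x, ...) {
  cat("<packed_reference> ", length(x$contigs), " contig(s), ",
      x$total_length, " bp total (2-bit packed)\n", sep = "")
  invisible(x)
}
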