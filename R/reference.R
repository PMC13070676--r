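#' Reference genome accessors
#'
#' All sequence lookups in the package go through a small accessor layer so
#' that code is agnostic to whether the reference lives in an indexed FASTA
#' on disk (\code{FastaReference}) or in memory (\code{MemoryReference}, used
#' for per-locus prefetched context and for fixtures).
#'
#' @name ReferenceAccessor
#' @aliases ReferenceAccessor-class FastaReference-class MemoryReference-class
NULL

#' @exportClass ReferenceAccessor
setClass("ReferenceAccessor", representation("VIRTUAL"))

#' @importClassesFrom Rsamtools FaFile
#' @importFrom Biostrings width subseq
#' @exportClass FastaReference
setClass("FastaReference", contains = "ReferenceAccessor",
         representation(fafile = "FaFile"))

#' @exportClass MemoryReference
setClass("MemoryReference", contains = "ReferenceAccessor",
         representation(seqs = "character", offsets = "integer"))

#' Open an indexed reference FASTA
#'
#' Wraps the FASTA in a \code{FastaReference}. A missing \code{.fai} index is
#' created on the fly (the FASTA's directory must then be writable).
#'
#' @param path path to a FASTA file.
#' @return a \code{FastaReference}.
#' @importFrom Rsamtools FaFile indexFa
#' @export
openReference <- function(path) {
  if (is(path, "ReferenceAccessor")) return(path)
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  fai <- paste0(path, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(path)
  new("FastaReference", fafile = Rsamtools::FaFile(path))
}

#' In-memory reference
#'
#' Builds a \code{MemoryReference} from named sequences. \code{offsets} allows
#' a sequence to represent a window of a larger contig: the stored sequence is
#' taken to start at 1-based genomic position \code{offset}.
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param offsets 1-based genomic start of each stored sequence (default 1).
#' @return a \code{MemoryReference}.
#' @importFrom Biostrings DNAStringSet
#' @export
memoryReference <- function(seqs, offsets = NULL) {
  if (!is.character(seqs))
    seqs <- as.character(seqs)                 # e.g. from a DNAStringSet
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by contig")
  nm <- names(seqs)
  seqs <- toupper(seqs)
  names(seqs) <- nm
  if (!all(grepl("^[ACGTN]*$", seqs)))
    stop("sequences must be DNA over ACGTN")
  if (is.null(offsets)) offsets <- rep(1L, length(seqs))
  offsets <- as.integer(offsets)
  names(offsets) <- nm
  new("MemoryReference", seqs = seqs, offsets = offsets)
}

#' @rdname ReferenceAccessor
#' @param ref a \code{ReferenceAccessor}.
#' @param chrom contig name.
#' @param start,end 1-based closed coordinates.
#' @return \code{getRefSeq}: uppercase character string of reference bases.
#' @export
setGeneric("getRefSeq", function(ref, chrom, start, end)
  standardGeneric("getRefSeq"))

#' @rdname ReferenceAccessor
#' @return \code{contigLength}: integer length of the contig.
#' @export
setGeneric("contigLength", function(ref, chrom)
  standardGeneric("contigLength"))

#' @rdname ReferenceAccessor
#' @return \code{contigNames}: character vector of contig names.
#' @export
setGeneric("contigNames", function(ref) standardGeneric("contigNames"))

.checkSpan <- function(chrom, start, end, len) {
  if (start < 1L || end > len || start > end)
    stop(sprintf("reference span %s:%d-%d outside contig bounds [1, %d]",
                 chrom, start, end, len))
}

#' @importFrom Rsamtools scanFa scanFaIndex
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
setMethod("getRefSeq", "FastaReference", function(ref, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  .checkSpan(chrom, start, end, contigLength(ref, chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  toupper(as.character(Rsamtools::scanFa(ref@fafile, gr)[[1L]]))
})

setMethod("getRefSeq", "MemoryReference", function(ref, chrom, start, end) {
  seq <- ref@seqs[[chrom]]
  if (is.null(seq) || is.na(seq))
    stop("contig not in reference: ", chrom)
  off <- ref@offsets[[chrom]]
  s <- start - off + 1L; e <- end - off + 1L
  if (s < 1L || e > nchar(seq) || s > e)
    stop(sprintf(
      "reference span %s:%d-%d outside the stored window [%d, %d]",
      chrom, start, end, off, off + nchar(seq) - 1L))
  substr(seq, s, e)
})

setMethod("contigLength", "FastaReference", function(ref, chrom) {
  idx <- Rsamtools::scanFaIndex(ref@fafile)
  i <- match(chrom, as.character(GenomicRanges::seqnames(idx)))
  if (is.na(i))
    stop("contig not in reference: ", chrom, " (contigs: ",
         paste(as.character(GenomicRanges::seqnames(idx)), collapse = ", "),
         ")")
  IRanges::width(GenomicRanges::ranges(idx))[i]
})

setMethod("contigLength", "MemoryReference", function(ref, chrom) {
  if (!chrom %in% names(ref@seqs))
    stop("contig not in reference: ", chrom)
  tl <- attr(ref, "trueContigLength")
  if (!is.null(tl)) return(as.integer(tl))
  ## a windowed MemoryReference reports the end of its stored window; for
  ## offset 1 this is the true contig length
  ref@offsets[[chrom]] + nchar(ref@seqs[[chrom]]) - 1L
})

setMethod("contigNames", "FastaReference", function(ref)
  as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(ref@fafile))))

setMethod("contigNames", "MemoryReference", function(ref) names(ref@seqs))

## prefetch a window of the on-disk reference into memory for tight loops;
## clamps to contig bounds. Positions outside the window raise, which is the
## guard against undersized prefetch.
.prefetchReference <- function(ref, chrom, start, end) {
  len <- contigLength(ref, chrom)
  start <- max(1L, as.integer(start)); end <- min(len, as.integer(end))
  seqs <- structure(getRefSeq(ref, chrom, start, end), names = chrom)
  mr <- new("MemoryReference", seqs = seqs,
            offsets = structure(start, names = chrom))
  attr(mr, "trueContigLength") <- len
  mr
}

## reverse complement of a plain DNA string (hot path: no XString objects)
.revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}
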