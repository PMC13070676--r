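## Mutation input parsing and harmonization.
##
## Mutations arrive as VCF, as a headered TSV (chrom/pos/ref/alt) or as
## "chr:pos:ref:alt" strings, in one-based or zero-based coordinates, with or
## without VCF anchor bases. Everything is funnelled through RawVariant ->
## resolveAlleles() -> normalizeMutation() into a single canonical form:
## 1-based, anchor-based, left-aligned, parsimonious.

.BLANK_ALLELES <- c("", "-", ".")
.isBlankAllele <- function(a) a %in% .BLANK_ALLELES

#' Parse mutations from any supported representation
#'
#' Accepts a VCF file (plain or bgzipped), a TSV file with header columns
#' \code{chrom,pos,ref,alt}, or a character vector of \code{"chr:pos:ref:alt"}
#' strings. Multi-allelic VCF rows are split into one record per ALT allele;
#' input order is preserved.
#'
#' @param source file path or character vector of colon strings.
#' @param formatHint optional; one of \code{"vcf"}, \code{"tsv"},
#'   \code{"colon_string"}. Guessed from the file extension / input shape when
#'   \code{NULL}.
#' @param coordinateBase \code{"one_based"} (default) or \code{"zero_based"};
#'   applies to TSV and colon-string inputs. VCF is 1-based by standard.
#' @return list of \linkS4class{RawVariant}, in input order.
#' @examples
#' parseVariants("chr7:55242465:GGAATTAAGAGAAGC:-")
#' @export
parseVariants <- function(source, formatHint = NULL,
                          coordinateBase = c("one_based", "zero_based")) {
  coordinateBase <- match.arg(coordinateBase)
  if (length(source) == 0L) stop("empty mutation input")
  fmt <- formatHint
  if (is.null(fmt)) {
    if (length(source) == 1L && file.exists(source)) {
      fmt <- if (grepl("\\.vcf(\\.b?gz)?$", source, ignore.case = TRUE))
        "vcf" else "tsv"
    } else fmt <- "colon_string"
  }
  fmt <- match.arg(fmt, c("vcf", "tsv", "colon_string"))
  switch(fmt,
         vcf = .parseVcf(source),
         tsv = .parseTsv(source, coordinateBase),
         colon_string = .parseColonStrings(source, coordinateBase))
}

.parseColonStrings <- function(strings, coordinateBase) {
  out <- vector("list", length(strings))
  for (i in seq_along(strings)) {
    fields <- strsplit(strings[[i]], ":", fixed = TRUE)[[1L]]
    if (length(fields) != 4L)
      stop("malformed mutation string (need chrom:pos:ref:alt): '",
           strings[[i]], "'")
    pos <- suppressWarnings(as.integer(fields[2L]))
    if (is.na(pos))
      stop("malformed mutation string (non-integer position): '",
           strings[[i]], "'")
    out[[i]] <- RawVariant(fields[1L], pos, fields[3L], fields[4L],
                           sourceFormat = "colon_string",
                           coordinateBase = coordinateBase)
  }
  out
}

.parseTsv <- function(path, coordinateBase) {
  if (!file.exists(path)) stop("mutation TSV not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, comment.char = "")
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(tab)))
    stop("mutation TSV must have header columns chrom, pos, ref, alt; ",
         "found: ", paste(names(tab), collapse = ", "))
  if (nrow(tab) == 0L) stop("empty mutation input: ", path)
  lapply(seq_len(nrow(tab)), function(i)
    RawVariant(tab$chrom[i], as.integer(tab$pos[i]), tab$ref[i], tab$alt[i],
               sourceFormat = "tsv", coordinateBase = coordinateBase))
}

#' @importFrom VariantAnnotation readVcf ref alt
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges seqnames start
#' @importFrom S4Vectors elementNROWS
.parseVcf <- function(path) {
  if (!file.exists(path)) stop("mutation VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (nrow(vcf) == 0L) stop("empty mutation input: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)           # CharacterList/DNAStringSetList
  out <- list()
  for (i in seq_along(chrom)) {
    aa <- as.character(alts[[i]])
    if (length(aa) == 0L) aa <- "."
    for (a in aa)                               # split multi-allelic rows
      out[[length(out) + 1L]] <-
        RawVariant(chrom[i], pos[i], refs[i], a,
                   sourceFormat = "vcf", coordinateBase = "one_based")
  }
  out
}

#' Resolve missing alleles and coordinate conventions
#'
#' Converts a \linkS4class{RawVariant} to an (unnormalized)
#' \linkS4class{Mutation}: zero-based positions are shifted to one-based;
#' absent alleles (\code{"-"}, \code{"."} or empty) are rewritten to the VCF
#' anchor-base representation by prepending the reference base immediately
#' left of the event and decrementing \code{pos}; alleles are uppercased and
#' the mutation class assigned from allele lengths. A non-blank REF allele is
#' checked against the reference and a mismatch is an error.
#'
#' For anchorless insertions (\code{ref} blank) \code{pos} is interpreted as
#' the base immediately left of the inserted sequence; for anchorless
#' deletions (\code{alt} blank) \code{pos} is the first deleted base.
#'
#' @param v a \linkS4class{RawVariant}.
#' @param reference a \linkS4class{ReferenceAccessor} (or FASTA path).
#' @return an unnormalized \linkS4class{Mutation}.
#' @export
resolveAlleles <- function(v, reference) {
  reference <- openReference(reference)
  pos <- v@pos
  if (v@coordinateBase == "zero_based") pos <- pos + 1L
  ref <- v@ref; alt <- v@alt
  refBlank <- .isBlankAllele(ref); altBlank <- .isBlankAllele(alt)
  if (refBlank && altBlank)
    stop("both alleles absent for ", v@chrom, ":", v@pos)
  if (!refBlank && !grepl("^[ACGTN]+$", ref))
    stop("unsupported REF allele '", ref, "' at ", v@chrom, ":", pos,
         " (symbolic/complex alleles are not supported)")
  if (!altBlank && !grepl("^[ACGTN]+$", alt))
    stop("unsupported ALT allele '", alt, "' at ", v@chrom, ":", pos,
         " (symbolic/complex alleles are not supported)")
  if (refBlank) {
    ## insertion without anchor: pos is the base left of the insertion
    if (pos < 1L)
      stop("anchorless insertion before contig start at ", v@chrom, ":", pos)
    anchor <- getRefSeq(reference, v@chrom, pos, pos)
    ref <- anchor
    alt <- paste0(anchor, alt)
  } else if (altBlank) {
    ## deletion without anchor: pos is the first deleted base
    if (pos <= 1L)
      stop("cannot anchor deletion at position 1 of contig ", v@chrom,
           ": no base to the left (unrepresentable)")
    obs <- getRefSeq(reference, v@chrom, pos, pos + nchar(ref) - 1L)
    if (obs != ref)
      stop("REF allele mismatch at ", v@chrom, ":", pos, ": input '", ref,
           "' but reference has '", obs, "'")
    anchor <- getRefSeq(reference, v@chrom, pos - 1L, pos - 1L)
    alt <- anchor
    ref <- paste0(anchor, ref)
    pos <- pos - 1L
  } else {
    obs <- getRefSeq(reference, v@chrom, pos, pos + nchar(ref) - 1L)
    if (obs != ref)
      stop("REF allele mismatch at ", v@chrom, ":", pos, ": input '", ref,
           "' but reference has '", obs, "'")
  }
  Mutation(v@chrom, pos, ref, alt, normalized = FALSE)
}

#' Normalize a mutation (left-align and trim)
#'
#' Applies the standard small-variant normalization for biallelic records:
#' shared suffix bases are trimmed (extending left with the reference base
#' when an allele would empty, which shifts indels leftward through repeat
#' tracts), then shared prefix bases are trimmed while both alleles keep at
#' least one base. The result is the unique left-aligned parsimonious
#' representation; the operation is idempotent. Shifting never runs past
#' position 1 of the contig.
#'
#' Alleles that still differ in length with both longer than one base after
#' trimming have no anchor-based small-variant form and are rejected as
#' COMPLEX.
#'
#' @param m a \linkS4class{Mutation}.
#' @param reference a \linkS4class{ReferenceAccessor} (or FASTA path).
#' @return a normalized \linkS4class{Mutation}.
#' @examples
#' ref <- memoryReference(c(chr1 = "GGTCAAAAGTT"))
#' normalizeMutation(Mutation("chr1", 6, "AA", "A"), ref)  # shifts to pos 4
#' @export
normalizeMutation <- function(m, reference) {
  reference <- openReference(reference)
  chrom <- m@chrom; pos <- m@pos
  ref <- m@ref; alt <- m@alt
  lastChar <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 1L && na >= 1L && (nr > 1L || na > 1L) &&
        lastChar(ref) == lastChar(alt)) {
      if ((nr == 1L || na == 1L) && pos <= 1L)
        break                      # cannot extend left of the contig start
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        b <- getRefSeq(reference, chrom, pos - 1L, pos - 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  ## trim shared prefix, keeping at least one base per allele
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (identical(ref, alt))
    stop("alleles are identical after trimming at ", chrom, ":", pos,
         ": not a variant")
  nr <- nchar(ref); na <- nchar(alt)
  mtype <- if (nr == na) {
    if (nr == 1L) "SNV" else "MNV"
  } else if (min(nr, na) == 1L &&
             substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    if (na > nr) "INS" else "DEL"
  } else "COMPLEX"
  if (mtype == "COMPLEX")
    stop("complex variant at ", chrom, ":", pos, " (", ref, ">", alt,
         "): length-changing substitutions are not supported")
  Mutation(chrom, pos, ref, alt, mtype = mtype, normalized = TRUE)
}

#' Parse, resolve and normalize mutations in one step
#'
#' Convenience wrapper: \code{\link{parseVariants}} then
#' \code{\link{resolveAlleles}} then \code{\link{normalizeMutation}} per
#' record.
#'
#' @inheritParams parseVariants
#' @param reference a \linkS4class{ReferenceAccessor} or FASTA path.
#' @return list of normalized \linkS4class{Mutation}.
#' @export
readMutations <- function(source, reference, formatHint = NULL,
                          coordinateBase = c("one_based", "zero_based")) {
  reference <- openReference(reference)
  raw <- parseVariants(source, formatHint, coordinateBase)
  lapply(raw, function(v)
    normalizeMutation(resolveAlleles(v, reference), reference))
}

#' Apply a mutation to a reference sequence window
#'
#' Returns the haplotype obtained by editing the reference over
#' \code{[start, end]} with the mutation. Used by the normalization
#' equivalence oracle and the simulator; the mutation must lie fully inside
#' the window.
#'
#' @param m a \linkS4class{Mutation}.
#' @param reference a \linkS4class{ReferenceAccessor}.
#' @param start,end 1-based closed window on \code{m}'s contig.
#' @return character string: the edited sequence.
#' @export
applyMutation <- function(m, reference, start, end) {
  reference <- openReference(reference)
  refLen <- nchar(m@ref)
  if (m@pos < start || m@pos + refLen - 1L > end)
    stop("mutation does not lie inside the window")
  ctx <- getRefSeq(reference, m@chrom, start, end)
  i <- m@pos - start + 1L
  paste0(substr(ctx, 1L, i - 1L), m@alt,
         substr(ctx, i + refLen, nchar(ctx)))
}
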