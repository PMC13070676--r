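#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
NULL

.VALID_MTYPES <- c("SNV", "MNV", "INS", "DEL", "COMPLEX")

#' Mutation: a small variant in VCF-style anchor representation
#'
#' A single small mutation (SNV, MNV, insertion or deletion) on a reference
#' contig. Coordinates are 1-based and fully closed throughout the package;
#' \code{pos} is the position of the first REF base. Indels carry a shared
#' anchor base (\code{ref[1] == alt[1]}) as in VCF. Objects with
#' \code{normalized = TRUE} are guaranteed left-aligned and parsimonious
#' (see \code{\link{normalizeMutation}}).
#'
#' @slot chrom contig name.
#' @slot pos 1-based position of the first REF base.
#' @slot ref,alt non-empty uppercase DNA strings over ACGTN.
#' @slot mtype one of \code{"SNV"}, \code{"MNV"}, \code{"INS"}, \code{"DEL"},
#'   \code{"COMPLEX"}.
#' @slot normalized logical; whether the representation is the left-aligned
#'   parsimonious fixed point.
#' @exportClass Mutation
setClass("Mutation",
  representation(chrom = "character", pos = "integer",
                 ref = "character", alt = "character",
                 mtype = "character", normalized = "logical"))

setValidity("Mutation", function(object) {
  msg <- character(0)
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "chrom must be a single non-empty string")
  if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
    msg <- c(msg, "pos must be a single integer >= 1")
  if (!grepl("^[ACGTN]+$", object@ref) || !grepl("^[ACGTN]+$", object@alt))
    msg <- c(msg, "ref and alt must be non-empty strings over ACGTN")
  if (identical(object@ref, object@alt))
    msg <- c(msg, "ref must differ from alt")
  if (!object@mtype %in% .VALID_MTYPES)
    msg <- c(msg, "unknown mtype")
  ## the full anchor-form invariants only hold once normalized
  if (isTRUE(object@normalized)) {
    nr <- nchar(object@ref); na <- nchar(object@alt)
    if (object@mtype %in% c("INS", "DEL")) {
      if (substr(object@ref, 1L, 1L) != substr(object@alt, 1L, 1L))
        msg <- c(msg, "normalized indel must share its anchor base")
      if (min(nr, na) != 1L)
        msg <- c(msg, "normalized indel must have a 1-base short allele")
    }
    if (object@mtype == "SNV" && (nr != 1L || na != 1L))
      msg <- c(msg, "SNV alleles must be single bases")
    if (object@mtype == "MNV") {
      if (nr != na || nr < 2L)
        msg <- c(msg, "MNV alleles must be equal length > 1")
      if (substr(object@ref, 1L, 1L) == substr(object@alt, 1L, 1L) ||
          substr(object@ref, nr, nr) == substr(object@alt, na, na))
        msg <- c(msg, "normalized MNV must not share a prefix or suffix base")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Mutation object
#'
#' @param chrom contig name.
#' @param pos 1-based position of the first REF base.
#' @param ref,alt allele strings (uppercased internally).
#' @param mtype mutation class; inferred from allele lengths when missing.
#' @param normalized whether the representation is already the normalization
#'   fixed point (default \code{FALSE}).
#' @return a \linkS4class{Mutation}.
#' @examples
#' Mutation("chr1", 100, "A", "T")
#' @export
Mutation <- function(chrom, pos, ref, alt, mtype = NULL, normalized = FALSE) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (is.null(mtype)) mtype <- .classifyAlleles(ref, alt)
  new("Mutation", chrom = as.character(chrom), pos = as.integer(pos),
      ref = ref, alt = alt, mtype = mtype, normalized = isTRUE(normalized))
}

## provisional classification by allele length; COMPLEX is only final after
## normalization has trimmed shared prefix/suffix bases
.classifyAlleles <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    if (nr == 1L) "SNV" else "MNV"
  } else if (na > nr) "INS" else "DEL"
}

#' @describeIn Mutation accessor for the contig name.
#' @param x a \code{Mutation}.
#' @export
mutationChrom <- function(x) x@chrom
#' @describeIn Mutation accessor for the 1-based position.
#' @export
mutationPos <- function(x) x@pos
#' @describeIn Mutation accessor for the REF allele.
#' @export
mutationRef <- function(x) x@ref
#' @describeIn Mutation accessor for the ALT allele.
#' @export
mutationAlt <- function(x) x@alt
#' @describeIn Mutation accessor for the mutation class.
#' @export
mutationType <- function(x) x@mtype
#' @describeIn Mutation is the representation normalized?
#' @export
isNormalized <- function(x) x@normalized

#' Canonical "chrom:pos:ref:alt" identifier of a Mutation
#' @param m a \linkS4class{Mutation}.
#' @return single string.
#' @export
mutationId <- function(m) paste(m@chrom, m@pos, m@ref, m@alt, sep = ":")

setMethod("show", "Mutation", function(object) {
  cat(sprintf("Mutation %s:%d %s>%s [%s%s]\n", object@chrom, object@pos,
              object@ref, object@alt, object@mtype,
              if (object@normalized) ", normalized" else ""))
})

#' RawVariant: a mutation as parsed from its source, before harmonization
#'
#' Holds exactly what the input said: alleles may be absent (\code{"-"},
#' \code{"."} or empty) and the coordinate convention is whatever the source
#' declared. \code{\link{resolveAlleles}} turns it into a
#' \linkS4class{Mutation}.
#'
#' @slot chrom contig name.
#' @slot pos integer position in the source's convention.
#' @slot ref,alt allele strings as given (possibly "-", "." or "").
#' @slot sourceFormat one of \code{"vcf"}, \code{"tsv"}, \code{"colon_string"}.
#' @slot coordinateBase \code{"one_based"} or \code{"zero_based"}.
#' @exportClass RawVariant
setClass("RawVariant",
  representation(chrom = "character", pos = "integer",
                 ref = "character", alt = "character",
                 sourceFormat = "character", coordinateBase = "character"))

setValidity("RawVariant", function(object) {
  msg <- character(0)
  if (!nzchar(object@chrom)) msg <- c(msg, "chrom must be non-empty")
  if (is.na(object@pos) || object@pos < 0L) msg <- c(msg, "pos must be >= 0")
  blank <- function(a) a %in% c("", "-", ".")
  if (blank(object@ref) && blank(object@alt))
    msg <- c(msg, "at least one of ref/alt must be non-empty")
  if (!object@sourceFormat %in% c("vcf", "tsv", "colon_string"))
    msg <- c(msg, "unknown sourceFormat")
  if (!object@coordinateBase %in% c("one_based", "zero_based"))
    msg <- c(msg, "unknown coordinateBase")
  if (length(msg)) msg else TRUE
})

#' Construct a RawVariant
#' @param chrom,pos,ref,alt fields as parsed from the source.
#' @param sourceFormat "vcf", "tsv" or "colon_string".
#' @param coordinateBase "one_based" or "zero_based".
#' @return a \linkS4class{RawVariant}.
#' @export
RawVariant <- function(chrom, pos, ref, alt, sourceFormat = "colon_string",
                       coordinateBase = "one_based") {
  new("RawVariant", chrom = as.character(chrom), pos = as.integer(pos),
      ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
      sourceFormat = sourceFormat, coordinateBase = coordinateBase)
}

setMethod("show", "RawVariant", function(object) {
  cat(sprintf("RawVariant %s:%d %s>%s (%s, %s)\n", object@chrom, object@pos,
              object@ref, object@alt, object@sourceFormat,
              object@coordinateBase))
})

#' Fragment: a sequenced cfDNA template reconstructed from a mate pair
#'
#' A fragment pairs the two primary alignments sharing a query name (or one,
#' when the mate is missing or unusable). Reads are stored as plain lists with
#' fields \code{qname, flag, chrom, refStart, refEnd, mapq, cigar, ops, lens,
#' seq, qual, tlen, isReverse, isRead1}; coordinates are 1-based closed.
#'
#' @slot fragmentId the query name.
#' @slot leftRead read with the smaller \code{refStart}.
#' @slot rightRead mate, or empty list when absent.
#' @slot outerStart,outerEnd outermost aligned reference coordinates.
#' @slot properPair logical, from the BAM flag.
#' @slot flags character vector of diagnostic tokens (e.g.
#'   \code{"mate_missing"}, \code{"orientation_discordant"}).
#' @exportClass Fragment
setClass("Fragment",
  representation(fragmentId = "character", leftRead = "list",
                 rightRead = "list", outerStart = "integer",
                 outerEnd = "integer", properPair = "logical",
                 flags = "character"))

setValidity("Fragment", function(object) {
  msg <- character(0)
  if (!nzchar(object@fragmentId)) msg <- c(msg, "fragmentId must be non-empty")
  if (object@outerEnd < object@outerStart)
    msg <- c(msg, "outerEnd must be >= outerStart")
  if (length(object@rightRead)) {
    if (!identical(object@leftRead$qname, object@rightRead$qname))
      msg <- c(msg, "paired reads must share a qname")
    if (!identical(object@leftRead$chrom, object@rightRead$chrom))
      msg <- c(msg, "paired reads must share a contig")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Fragment does the fragment have both mates?
#' @param x a \code{Fragment}.
#' @export
hasBothReads <- function(x) length(x@rightRead) > 0L
#' @describeIn Fragment the left (smaller refStart) read, as a list.
#' @export
leftRead <- function(x) x@leftRead
#' @describeIn Fragment the right read, or NULL for single-read fragments.
#' @export
rightRead <- function(x) if (length(x@rightRead)) x@rightRead else NULL
#' @describeIn Fragment outermost aligned span as c(start, end).
#' @export
outerSpan <- function(x) c(x@outerStart, x@outerEnd)
#' @describeIn Fragment the query name.
#' @export
fragmentId <- function(x) x@fragmentId
#' @describeIn Fragment diagnostic flag tokens.
#' @export
fragmentFlags <- function(x) x@flags

setMethod("show", "Fragment", function(object) {
  cat(sprintf("Fragment %s %s:%d-%d (%s%s)\n", object@fragmentId,
              object@leftRead$chrom, object@outerStart, object@outerEnd,
              if (hasBothReads(object)) "paired" else "single-read",
              if (length(object@flags))
                paste0("; ", paste(object@flags, collapse = ";")) else ""))
})

#' FragmentTable: one row per (fragment x mutation)
#'
#' The primary output of \code{\link{runFragtyper}}: a
#' \code{\link[S4Vectors]{DataFrame}} of per-fragment features and genotype
#' calls, plus per-locus variant-allele-fraction summaries and a per-locus
#' processing status.
#'
#' @slot data the per-fragment table.
#' @slot vaf one row per mutation: n_mut, n_wt, n_oth, n_ni, vaf.
#' @slot locusStatus one row per mutation: "ok" or the captured error message.
#' @exportClass FragmentTable
setClass("FragmentTable",
  representation(data = "DataFrame", vaf = "DataFrame",
                 locusStatus = "DataFrame"))

#' @describeIn FragmentTable the per-fragment \code{DataFrame}.
#' @param x a \code{FragmentTable}.
#' @export
fragmentData <- function(x) x@data
#' @describeIn FragmentTable per-locus VAF summary \code{DataFrame}.
#' @export
vafSummary <- function(x) x@vaf
#' @describeIn FragmentTable per-locus processing status \code{DataFrame}.
#' @export
locusStatus <- function(x) x@locusStatus

#' @export
setMethod("dim", "FragmentTable", function(x) dim(x@data))

#' @export
setMethod("as.data.frame", "FragmentTable",
          function(x, ...) as.data.frame(x@data))

setMethod("show", "FragmentTable", function(object) {
  cat(sprintf("FragmentTable: %d fragments x %d columns, %d mutation(s)\n",
              nrow(object@data), ncol(object@data), nrow(object@vaf)))
  if (nrow(object@vaf)) {
    cat("VAF summary:\n")
    show(object@vaf)
  }
})
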