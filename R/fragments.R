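## BAM read selection and fragment reconstruction.
##
## Reads overlapping a mutation window are fetched through the BAM index,
## filtered on flags and mapping quality, and paired by query name into
## Fragment objects. Coordinates are converted to the package-wide 1-based
## closed convention at read time (Rsamtools already reports 1-based POS).

.FLAG_PAIRED <- 0x1L
.FLAG_PROPER <- 0x2L
.FLAG_UNMAPPED <- 0x4L
.FLAG_MATE_UNMAPPED <- 0x8L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_READ1 <- 0x40L
.FLAG_READ2 <- 0x80L
.FLAG_SECONDARY <- 0x100L
.FLAG_QCFAIL <- 0x200L
.FLAG_DUP <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

#' Selection configuration for fragment recovery
#'
#' Controls which reads around a mutation are retained before pairing.
#' Defaults are deliberately permissive: unmapped, secondary, supplementary
#' and QC-fail reads are always unusable for fragment reconstruction and are
#' dropped; duplicates are dropped by default; no MAPQ or proper-pair
#' requirement. \code{requiredFlags}/\code{forbiddenFlags} are raw SAM flag
#' bitmasks applied on top.
#'
#' @param windowBp half-width of the recovery window around the mutation
#'   (default 600 bp).
#' @param minMapq minimum mapping quality (default 0).
#' @param dropDuplicates drop reads with the duplicate flag (default TRUE).
#' @param dropSecondary,dropSupplementary,dropQcfail drop the corresponding
#'   flag classes (default TRUE).
#' @param requireProperPair require the proper-pair flag (default FALSE).
#' @param requiredFlags,forbiddenFlags extra SAM flag bitmasks that must be
#'   all set / all clear (default 0).
#' @return a named list of class \code{"SelectionConfig"}.
#' @export
selectionConfig <- function(windowBp = 600L, minMapq = 0L,
                            dropDuplicates = TRUE, dropSecondary = TRUE,
                            dropSupplementary = TRUE, dropQcfail = TRUE,
                            requireProperPair = FALSE,
                            requiredFlags = 0L, forbiddenFlags = 0L) {
  windowBp <- as.integer(windowBp)
  stopifnot(windowBp >= 0L, minMapq >= 0L)
  structure(list(windowBp = windowBp, minMapq = as.integer(minMapq),
                 dropDuplicates = isTRUE(dropDuplicates),
                 dropSecondary = isTRUE(dropSecondary),
                 dropSupplementary = isTRUE(dropSupplementary),
                 dropQcfail = isTRUE(dropQcfail),
                 requireProperPair = isTRUE(requireProperPair),
                 requiredFlags = as.integer(requiredFlags),
                 forbiddenFlags = as.integer(forbiddenFlags)),
            class = "SelectionConfig")
}

.hasFlag <- function(flag, bit) bitwAnd(flag, bit) != 0L

## reference/query-consuming CIGAR operation sets (SAM spec)
.REF_OPS <- c("M", "D", "N", "=", "X")
.QRY_OPS <- c("M", "I", "S", "=", "X")

#' Reference span consumed by a CIGAR
#' @param ops,lens exploded CIGAR operations and lengths.
#' @return integer number of reference bases consumed.
#' @keywords internal
.cigarRefWidth <- function(ops, lens) sum(lens[ops %in% .REF_OPS])

.cigarQryWidth <- function(ops, lens) sum(lens[ops %in% .QRY_OPS])

## build the plain-list read record used throughout the package
.makeRead <- function(qname, flag, chrom, pos, mapq, cigar, ops, lens,
                      seq, qual, tlen, mchrom = NA_character_,
                      mpos = NA_integer_) {
  qw <- .cigarQryWidth(ops, lens)
  if (qw != nchar(seq))
    stop("malformed record '", qname, "': CIGAR consumes ", qw,
         " query bases but SEQ has ", nchar(seq))
  list(qname = qname, flag = as.integer(flag), chrom = chrom,
       refStart = as.integer(pos),
       refEnd = as.integer(pos) + .cigarRefWidth(ops, lens) - 1L,
       mapq = as.integer(mapq), cigar = cigar, ops = ops, lens = lens,
       seq = seq, qual = qual, tlen = as.integer(tlen),
       mchrom = mchrom, mpos = as.integer(mpos),
       isReverse = .hasFlag(flag, .FLAG_REVERSE),
       isRead1 = .hasFlag(flag, .FLAG_READ1))
}

#' Select fragments overlapping a mutation window
#'
#' Fetches reads around the mutation through the BAM index, applies the
#' flag/MAPQ filters of \code{cfg}, pairs primary alignments by query name
#' and keeps every fragment whose outer span (outermost aligned coordinates
#' of the pair) intersects
#' \code{[pos - windowBp, pos + nchar(ref) - 1 + windowBp]}. Overlap is
#' assessed on the pair's outer span, so a fragment whose two reads flank the
#' mutation without covering it is still recovered (it will genotype as
#' non-informative). Reads whose mate is missing, unmapped, filtered out, on
#' another contig, in the same orientation, or beyond \code{scanMargin} are
#' kept as flagged single-read fragments.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param m a normalized \linkS4class{Mutation}.
#' @param cfg a \code{\link{selectionConfig}}.
#' @param scanMargin how far beyond the window reads are scanned so that
#'   outer-span overlap can be established from both mates (default 5000 bp,
#'   comfortably above human cfDNA fragment lengths).
#' @return list of \linkS4class{Fragment}, ordered by (outerStart, qname).
#' @importFrom Rsamtools BamFile ScanBamParam scanBam scanBamHeader
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomicAlignments explodeCigarOps explodeCigarOpLengths
#' @export
selectFragments <- function(bam, m, cfg = selectionConfig(),
                            scanMargin = 5000L) {
  stopifnot(is(m, "Mutation"))
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(idx)))
    stop("BAM index not found for '", bam,
         "'; index the file first (e.g. Rsamtools::indexBam)")
  bf <- Rsamtools::BamFile(bam)
  header <- Rsamtools::scanBamHeader(bf)
  targets <- header$targets
  if (!m@chrom %in% names(targets))
    stop("contig '", m@chrom, "' absent from BAM header (contigs: ",
         paste(names(targets), collapse = ", "), ")")
  wStart <- max(1L, m@pos - cfg$windowBp)
  wEnd <- min(unname(targets[[m@chrom]]),
              m@pos + nchar(m@ref) - 1L + cfg$windowBp)
  scanStart <- max(1L, wStart - as.integer(scanMargin))
  scanEnd <- min(unname(targets[[m@chrom]]), wEnd + as.integer(scanMargin))
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(m@chrom,
                                   IRanges::IRanges(scanStart, scanEnd)),
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual", "mrnm", "mpos", "isize"))
  rec <- Rsamtools::scanBam(bf, param = param)[[1L]]
  n <- length(rec$qname)
  if (n == 0L) return(list())

  flag <- as.integer(rec$flag)
  keep <- !.hasFlag(flag, .FLAG_UNMAPPED)
  if (cfg$dropSecondary) keep <- keep & !.hasFlag(flag, .FLAG_SECONDARY)
  if (cfg$dropSupplementary)
    keep <- keep & !.hasFlag(flag, .FLAG_SUPPLEMENTARY)
  if (cfg$dropQcfail) keep <- keep & !.hasFlag(flag, .FLAG_QCFAIL)
  if (cfg$dropDuplicates) keep <- keep & !.hasFlag(flag, .FLAG_DUP)
  if (cfg$requireProperPair) keep <- keep & .hasFlag(flag, .FLAG_PROPER)
  if (cfg$requiredFlags != 0L)
    keep <- keep & (bitwAnd(flag, cfg$requiredFlags) == cfg$requiredFlags)
  if (cfg$forbiddenFlags != 0L)
    keep <- keep & !.hasFlag(flag, cfg$forbiddenFlags)
  keep <- keep & !is.na(rec$pos) & !is.na(rec$mapq) &
    rec$mapq >= cfg$minMapq & !is.na(rec$cigar)
  if (!any(keep)) return(list())

  exOps <- GenomicAlignments::explodeCigarOps(rec$cigar[keep])
  exLens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar[keep])
  kidx <- which(keep)
  reads <- vector("list", length(kidx))
  seqs <- as.character(rec$seq[kidx])
  quals <- as(rec$qual[kidx], "IntegerList")
  for (j in seq_along(kidx)) {
    i <- kidx[j]
    reads[[j]] <- .makeRead(
      rec$qname[i], flag[i], as.character(rec$rname[i]), rec$pos[i],
      rec$mapq[i], rec$cigar[i], exOps[[j]], exLens[[j]], seqs[j],
      as.integer(quals[[j]]), rec$isize[i],
      mchrom = as.character(rec$mrnm[i]), mpos = rec$mpos[i])
  }

  frags <- .pairReads(reads)
  ## fragment-level window overlap on the outer span
  frags <- Filter(function(f)
    f@outerStart <= wEnd && f@outerEnd >= wStart, frags)
  ord <- order(vapply(frags, function(f) f@outerStart, integer(1)),
               vapply(frags, function(f) f@fragmentId, character(1)))
  frags[ord]
}

## pair retained primary alignments by qname; every retained read ends up in
## exactly one Fragment
.pairReads <- function(reads) {
  qnames <- vapply(reads, `[[`, character(1), "qname")
  groups <- split(seq_along(reads), qnames)
  frags <- vector("list", length(groups))
  k <- 0L
  for (g in groups) {
    rs <- reads[g]
    flags <- character(0)
    if (length(rs) > 2L) {
      ## should not happen once secondary/supplementary are dropped; keep the
      ## two highest-MAPQ records and note it
      ord <- order(-vapply(rs, `[[`, integer(1), "mapq"),
                   vapply(rs, `[[`, integer(1), "refStart"))
      rs <- rs[ord[1:2]]
      flags <- c(flags, "extra_alignments_dropped")
    }
    if (length(rs) == 2L) {
      ord <- order(vapply(rs, `[[`, integer(1), "refStart"))
      rs <- rs[ord]
      if (identical(rs[[1L]]$isReverse, rs[[2L]]$isReverse)) {
        ## same-orientation pair: keep one read, flagged
        pick <- if (rs[[2L]]$mapq > rs[[1L]]$mapq) 2L else 1L
        rs <- rs[pick]
        flags <- c(flags, "orientation_discordant")
      }
    }
    if (length(rs) == 2L) {
      f <- new("Fragment", fragmentId = rs[[1L]]$qname,
               leftRead = rs[[1L]], rightRead = rs[[2L]],
               outerStart = min(rs[[1L]]$refStart, rs[[2L]]$refStart),
               outerEnd = max(rs[[1L]]$refEnd, rs[[2L]]$refEnd),
               properPair = .hasFlag(rs[[1L]]$flag, .FLAG_PROPER),
               flags = flags)
    } else {
      r <- rs[[1L]]
      mateGone <- if (.hasFlag(r$flag, .FLAG_MATE_UNMAPPED))
        "mate_unmapped"
      else if (!is.na(r$mchrom) && nzchar(r$mchrom) &&
               !identical(r$mchrom, r$chrom) && r$mchrom != "*")
        "mate_other_contig"
      else "mate_missing"
      if (!"orientation_discordant" %in% flags)
        flags <- c(flags, mateGone)
      f <- new("Fragment", fragmentId = r$qname,
               leftRead = r, rightRead = list(),
               outerStart = r$refStart, outerEnd = r$refEnd,
               properPair = .hasFlag(r$flag, .FLAG_PROPER),
               flags = flags)
    }
    k <- k + 1L
    frags[[k]] <- f
  }
  frags[seq_len(k)]
}

#' Per-base alignment profile of a read
#'
#' Walks the CIGAR once and returns the read's reference/query
#' correspondence: one entry per alignment column. M/=/X columns carry both a
#' reference position and a query index; I and S columns carry only a query
#' index (reference gap); D and N columns carry only a reference position
#' (query gap). H and P consume nothing and emit nothing. \code{anchor} is,
#' for every column, the last reference position at or before it (the
#' insertion anchor; \code{refStart - 1} for leading clips).
#'
#' @param r a read record (list, as stored in a \linkS4class{Fragment}).
#' @return list with integer vectors \code{refpos}, \code{qidx},
#'   \code{anchor} (NA where gapped) and character vector \code{op}.
#' @export
alignmentProfile <- function(r) {
  ops <- r$ops; lens <- r$lens
  drop <- ops %in% c("H", "P")
  if (any(drop)) { ops <- ops[!drop]; lens <- lens[!drop] }
  if (length(ops) == 0L)
    stop("malformed record '", r$qname, "': empty CIGAR")
  qw <- .cigarQryWidth(ops, lens)
  if (qw != nchar(r$seq))
    stop("malformed record '", r$qname, "': CIGAR/SEQ length mismatch")
  colop <- rep(ops, lens)
  refCons <- colop %in% .REF_OPS
  qryCons <- colop %in% .QRY_OPS
  refpos <- rep(NA_integer_, length(colop))
  refpos[refCons] <- r$refStart - 1L + seq_len(sum(refCons))
  qidx <- rep(NA_integer_, length(colop))
  qidx[qryCons] <- seq_len(sum(qryCons))
  ## last reference position at or before each column
  filled <- refpos
  filled[is.na(filled)] <- 0L
  anchor <- cummax(filled)
  anchor[anchor == 0L] <- r$refStart - 1L
  list(refpos = refpos, qidx = qidx, anchor = as.integer(anchor), op = colop)
}
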