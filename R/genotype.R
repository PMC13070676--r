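## Read- and fragment-level genotyping.
##
## Each read overlapping a mutation is compared, over a type-specific
## reference window, to the wild-type haplotype (reference bases) and the
## mutated haplotype (reference with the mutation applied). For indels the
## CIGAR is scanned for the expected left-aligned event and takes precedence
## over the sequence comparison. Read calls aggregate to fragment calls;
## non-informative fragments are excluded from the locus VAF.

.READ_STATUSES <- c("WT", "MUT", "OTH", "AMBIGUOUS")
.FRAG_STATUSES <- c("MUT", "WT", "OTH", "NI")

#' Build the genotyping window for a mutation
#'
#' SNV/MNV: the window covers the substituted bases
#' (\code{[pos, pos + nchar(ref) - 1]}); an extended interval of one flanking
#' base on each side is used only to flag potentially larger events. Indels:
#' the window starts at the anchor base (\code{pos}), covers the varying
#' bases, the base following the indel, and extends rightward through any
#' (possibly partial) perfect repeats of the indel unit plus one terminating
#' non-repeat base, so that a read must reach unambiguous sequence before it
#' can be called. Windows are clipped at contig edges and marked
#' edge-truncated.
#'
#' @param m a normalized \linkS4class{Mutation}.
#' @param reference a \linkS4class{ReferenceAccessor} or FASTA path.
#' @return a list of class \code{"WindowSpec"}: \code{chrom},
#'   \code{wStart}, \code{wEnd}, \code{refHap}, \code{altHap},
#'   \code{extStart}, \code{extEnd}, \code{edgeTruncated}.
#' @export
buildWindow <- function(m, reference) {
  stopifnot(is(m, "Mutation"), isTRUE(m@normalized))
  reference <- openReference(reference)
  len <- contigLength(reference, m@chrom)
  edgeTruncated <- FALSE
  if (m@mtype %in% c("SNV", "MNV")) {
    wStart <- m@pos
    wEnd <- m@pos + nchar(m@ref) - 1L
    if (wEnd > len) stop("mutation extends past contig end")
    extStart <- max(1L, wStart - 1L)
    extEnd <- min(len, wEnd + 1L)
    if (extStart == wStart || extEnd == wEnd) edgeTruncated <- TRUE
  } else {
    unit <- if (m@mtype == "DEL") substr(m@ref, 2L, nchar(m@ref))
            else substr(m@alt, 2L, nchar(m@alt))
    d <- nchar(unit)
    ## first reference base after the indel event
    q <- if (m@mtype == "DEL") m@pos + d + 1L else m@pos + 1L
    ## extend through (partial) perfect repeats of the unit, then one
    ## terminating non-repeat base
    j <- 0L
    while (q <= len &&
           getRefSeq(reference, m@chrom, q, q) ==
           substr(unit, j %% d + 1L, j %% d + 1L)) {
      q <- q + 1L
      j <- j + 1L
    }
    if (q > len) {
      wEnd <- len
      edgeTruncated <- TRUE
    } else {
      wEnd <- q
    }
    wStart <- m@pos
    extStart <- wStart; extEnd <- wEnd
  }
  refHap <- getRefSeq(reference, m@chrom, wStart, wEnd)
  altHap <- {
    i <- m@pos - wStart + 1L
    paste0(substr(refHap, 1L, i - 1L), m@alt,
           substr(refHap, i + nchar(m@ref), nchar(refHap)))
  }
  if (identical(refHap, altHap))
    stop("degenerate window: haplotypes identical at ", mutationId(m))
  structure(list(chrom = m@chrom, wStart = wStart, wEnd = wEnd,
                 refHap = refHap, altHap = altHap,
                 extStart = extStart, extEnd = extEnd,
                 edgeTruncated = edgeTruncated),
            class = "WindowSpec")
}

#' Read bases over a genotyping window
#'
#' Maps the read's query bases onto the window's reference interval via the
#' alignment profile: aligned (M/=/X) bases at reference positions inside
#' \code{[wStart, wEnd]} plus inserted bases anchored inside
#' \code{[wStart, wEnd - 1]}, in query order. Soft-clipped bases are never
#' included (they are unaligned). Deleted reference positions contribute
#' nothing, so a deletion shortens the observed string.
#'
#' @param r a read record (list).
#' @param w a \code{\link{buildWindow}} result.
#' @return list: \code{observed} (string), \code{truncatedLeft},
#'   \code{truncatedRight}, \code{noCoverage} (logicals), \code{qidx}
#'   (query indices of the observed bases, for quality checks).
#' @export
readWindowSequence <- function(r, w) {
  if (r$refStart > w$wEnd || r$refEnd < w$wStart)
    return(list(observed = "", truncatedLeft = TRUE, truncatedRight = TRUE,
                noCoverage = TRUE, qidx = integer(0)))
  prof <- alignmentProfile(r)
  aligned <- prof$op %in% c("M", "=", "X") &
    !is.na(prof$refpos) & prof$refpos >= w$wStart & prof$refpos <= w$wEnd
  inserted <- prof$op == "I" &
    prof$anchor >= w$wStart & prof$anchor <= (w$wEnd - 1L)
  keep <- aligned | inserted
  qidx <- prof$qidx[keep]
  qidx <- qidx[!is.na(qidx)]
  observed <- if (length(qidx))
    paste(strsplit(r$seq, "", fixed = TRUE)[[1L]][qidx], collapse = "")
  else ""
  list(observed = observed,
       truncatedLeft = r$refStart > w$wStart,
       truncatedRight = r$refEnd < w$wEnd,
       noCoverage = FALSE,
       qidx = qidx)
}

#' Scan a read's CIGAR for the expected indel
#'
#' Each I/D operation is converted to an anchor-based event and normalized
#' with the same left-align-and-trim algorithm as the input mutations; the
#' scan reports \code{"expected_indel"} when an event normalizes to exactly
#' the queried mutation (type, left-aligned anchor and allele strings all
#' equal), \code{"other_indel"} when a different I/D event overlaps the
#' genotyping window, and \code{"none"} otherwise. Exact-length matching
#' after left-alignment means near-miss lengths count as other events.
#'
#' @param r a read record (list).
#' @param m a normalized indel \linkS4class{Mutation}.
#' @param w the mutation's \code{\link{buildWindow}} result.
#' @param reference a \linkS4class{ReferenceAccessor} or FASTA path.
#' @return one of \code{"none"}, \code{"expected_indel"},
#'   \code{"other_indel"}.
#' @export
cigarIndelScan <- function(r, m, w, reference) {
  stopifnot(m@mtype %in% c("INS", "DEL"))
  reference <- openReference(reference)
  ev <- .readIndelEvents(r)
  ev <- .evSubset(ev, ev$op %in% c("I", "D"))
  if (length(ev$op) == 0L) return("none")
  expected <- FALSE; other <- FALSE
  for (i in seq_along(ev$op)) {
    op <- ev$op[i]; p <- ev$refpos[i]; L <- ev$len[i]
    cand <- NULL
    if (op == "I") {
      if (p >= 1L)
        cand <- Mutation(m@chrom, p,
                         getRefSeq(reference, m@chrom, p, p),
                         paste0(getRefSeq(reference, m@chrom, p, p),
                                ev$seq[i]))
    } else {
      if (p >= 2L)
        cand <- Mutation(m@chrom, p - 1L,
                         getRefSeq(reference, m@chrom, p - 1L, p + L - 1L),
                         getRefSeq(reference, m@chrom, p - 1L, p - 1L))
    }
    matches <- FALSE
    if (!is.null(cand)) {
      norm <- tryCatch(normalizeMutation(cand, reference),
                       error = function(e) NULL)
      matches <- !is.null(norm) && norm@pos == m@pos &&
        norm@ref == m@ref && norm@alt == m@alt
    }
    if (matches) {
      expected <- TRUE
    } else {
      ## does this (different) event touch the genotyping window?
      evStart <- if (op == "I") p else p
      evEnd <- if (op == "I") p + 1L else p + L - 1L
      if (evStart <= w$wEnd && evEnd >= w$wStart) other <- TRUE
    }
  }
  if (expected) "expected_indel" else if (other) "other_indel" else "none"
}

## is `observed` consistent with haplotype `hap`, given which window sides
## the read failed to reach? Untruncated sides anchor the comparison.
.consistentWithHap <- function(observed, hap, truncLeft, truncRight) {
  if (!truncLeft && !truncRight) return(identical(observed, hap))
  if (!truncLeft) return(startsWith(hap, observed))
  if (!truncRight) return(endsWith(hap, observed))
  grepl(observed, hap, fixed = TRUE)
}

#' Genotype a single read
#'
#' SNV/MNV: the observed window bases are compared to the wild-type and
#' mutated haplotypes (with truncation-aware anchoring); matching exactly one
#' haplotype gives WT or MUT, matching neither gives OTH, and a truncated
#' window compatible with both haplotypes (or no coverage) gives AMBIGUOUS.
#' A MUT/WT call whose one-base extended flanks mismatch the reference is
#' flagged \code{possible_larger_event} (the flag never changes the status).
#' Indels: a CIGAR carrying the expected left-aligned event forces MUT
#' (CIGAR precedence), with \code{cigar_seq_discordant} flagged when the
#' sequence comparison disagrees; otherwise the sequence comparison decides,
#' with \code{other_indel_present} flagged when a different indel overlaps
#' the window. Any observed window base below \code{minBaseq} makes the read
#' AMBIGUOUS with flag \code{low_baseq}.
#'
#' @param r a read record (list).
#' @param m a normalized \linkS4class{Mutation}.
#' @param w the mutation's \code{\link{buildWindow}} result.
#' @param reference a \linkS4class{ReferenceAccessor} or FASTA path.
#' @param minBaseq minimum base quality inside the window (default 0 = off).
#' @return a list of class \code{"ReadCall"}: \code{status}, \code{flags}
#'   (character vector), \code{cigarEvidence}.
#' @export
genotypeRead <- function(r, m, w, reference, minBaseq = 0L) {
  reference <- openReference(reference)
  flags <- character(0)
  rw <- readWindowSequence(r, w)
  if (rw$noCoverage)
    return(structure(list(status = "AMBIGUOUS", flags = "no_coverage",
                          cigarEvidence = "none"), class = "ReadCall"))
  if (w$edgeTruncated) flags <- c(flags, "truncated_window")
  if (minBaseq > 0L && length(rw$qidx) &&
      any(r$qual[rw$qidx] < minBaseq, na.rm = TRUE))
    return(structure(list(status = "AMBIGUOUS",
                          flags = unique(c(flags, "low_baseq")),
                          cigarEvidence = "none"), class = "ReadCall"))

  consRef <- .consistentWithHap(rw$observed, w$refHap,
                                rw$truncatedLeft, rw$truncatedRight)
  consAlt <- .consistentWithHap(rw$observed, w$altHap,
                                rw$truncatedLeft, rw$truncatedRight)
  seqStatus <- if (consRef && consAlt) "AMBIGUOUS"
  else if (consAlt) "MUT"
  else if (consRef) "WT"
  else "OTH"
  if ((rw$truncatedLeft || rw$truncatedRight) && seqStatus == "AMBIGUOUS")
    flags <- c(flags, "truncated_window")

  if (m@mtype %in% c("SNV", "MNV")) {
    status <- seqStatus
    if (status %in% c("MUT", "WT")) {
      ## one-base extended flanks: mismatches flag a possibly larger event
      prof <- alignmentProfile(r)
      for (fp in c(w$extStart, w$extEnd)) {
        if (fp >= w$wStart && fp <= w$wEnd) next  # clipped at contig edge
        i <- which(prof$refpos == fp & prof$op %in% c("M", "=", "X"))
        if (length(i) == 1L) {
          base <- substr(r$seq, prof$qidx[i], prof$qidx[i])
          if (base != getRefSeq(reference, m@chrom, fp, fp))
            flags <- c(flags, "possible_larger_event")
        }
      }
    }
    cigarEvidence <- "none"
  } else {
    cigarEvidence <- cigarIndelScan(r, m, w, reference)
    if (cigarEvidence == "expected_indel") {
      status <- "MUT"
      if (seqStatus == "WT" || seqStatus == "OTH")
        flags <- c(flags, "cigar_seq_discordant")
    } else {
      status <- seqStatus
      if (cigarEvidence == "other_indel")
        flags <- c(flags, "other_indel_present")
    }
  }
  structure(list(status = status, flags = unique(flags),
                 cigarEvidence = cigarEvidence), class = "ReadCall")
}

#' Aggregate read calls into a fragment call
#'
#' A lone covering read (absent mate, or mate without coverage) passes its
#' status through (resolution \code{"single_read"}; a lone AMBIGUOUS read
#' yields NI with resolution \code{"ambiguous"}). Equal definite statuses are
#' \code{"concordant"}; one AMBIGUOUS plus one definite resolves to the
#' definite status (\code{"flag_resolved"}); two unequal definite statuses
#' are irreconcilable (\code{"discrepant"} -> NI); two AMBIGUOUS reads are
#' \code{"ambiguous"} -> NI.
#'
#' @param call1 a \code{ReadCall} (see \code{\link{genotypeRead}}).
#' @param call2 a \code{ReadCall}, or NULL for single-read fragments.
#' @return a list of class \code{"FragmentCall"}: \code{status} (MUT, WT,
#'   OTH or NI), \code{resolution}, \code{flags} (union of read flags).
#' @export
genotypeFragment <- function(call1, call2 = NULL) {
  covered <- function(cl) !is.null(cl) && !"no_coverage" %in% cl$flags
  allFlags <- unique(c(call1$flags, if (!is.null(call2)) call2$flags))
  mk <- function(status, resolution)
    structure(list(status = status, resolution = resolution,
                   flags = allFlags), class = "FragmentCall")
  c1 <- covered(call1); c2 <- covered(call2)
  if (!c1 && !c2) return(mk("NI", "ambiguous"))
  if (xor(c1, c2)) {
    cl <- if (c1) call1 else call2
    if (cl$status == "AMBIGUOUS") return(mk("NI", "ambiguous"))
    return(mk(cl$status, "single_read"))
  }
  s1 <- call1$status; s2 <- call2$status
  if (s1 == "AMBIGUOUS" && s2 == "AMBIGUOUS") return(mk("NI", "ambiguous"))
  if (s1 == "AMBIGUOUS") return(mk(s2, "flag_resolved"))
  if (s2 == "AMBIGUOUS") return(mk(s1, "flag_resolved"))
  if (s1 == s2) return(mk(s1, "concordant"))
  mk("NI", "discrepant")
}

#' Fragment-level VAF at a locus
#'
#' Counts fragment statuses and computes the variant allele fraction as
#' mutated over informative (MUT + WT + OTH) fragments; non-informative
#' fragments are excluded from the denominator. The VAF is NA when no
#' fragment is informative.
#'
#' @param calls list of \code{FragmentCall} (or a character vector of
#'   statuses).
#' @return named list: \code{n_mut}, \code{n_wt}, \code{n_oth}, \code{n_ni},
#'   \code{vaf}.
#' @export
locusVaf <- function(calls) {
  statuses <- if (is.character(calls)) calls
  else vapply(calls, `[[`, character(1), "status")
  stopifnot(all(statuses %in% .FRAG_STATUSES))
  nMut <- sum(statuses == "MUT")
  nWt <- sum(statuses == "WT")
  nOth <- sum(statuses == "OTH")
  nNi <- sum(statuses == "NI")
  denom <- nMut + nWt + nOth
  list(n_mut = nMut, n_wt = nWt, n_oth = nOth, n_ni = nNi,
       vaf = if (denom > 0L) nMut / denom else NA_real_)
}
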