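## Fragmentomic feature extraction.
##
## The central quantity is the indel-aware fragment size: the reference span
## of the outer aligned ends, plus inserted bases, minus deleted bases, plus
## (optionally) outer soft-clipped bases. TLEN, by contrast, is blind to both
## indels and clips, which is exactly the discrepancy this feature removes.

#' Soft-clip policy for fragment size
#'
#' @param keepOuterSoftclips count soft-clipped bases at the fragment's outer
#'   ends as part of the molecule (default TRUE). Set FALSE when clips are
#'   assumed technical (adapter read-through and alignment artifacts).
#' @param countNAsDeletion treat reference-skip (N) operations as deleted
#'   bases in the size (default TRUE); fragments containing N are flagged
#'   either way.
#' @return a named list of class \code{"SizePolicy"}.
#' @export
sizePolicy <- function(keepOuterSoftclips = TRUE, countNAsDeletion = TRUE) {
  structure(list(keepOuterSoftclips = isTRUE(keepOuterSoftclips),
                 countNAsDeletion = isTRUE(countNAsDeletion)),
            class = "SizePolicy")
}

## indel events of one read as parallel vectors: op (I/D/N), refpos (first
## reference base of a D/N; reference base left of an I), len, seq (inserted
## bases, "" for D/N)
.noEvents <- list(op = character(0), refpos = integer(0),
                  len = integer(0), seq = character(0))

.readIndelEvents <- function(r) {
  ops <- r$ops; lens <- r$lens
  keepOps <- !(ops %in% c("H", "P"))
  ops <- ops[keepOps]; lens <- lens[keepOps]
  isEvent <- ops %in% c("I", "D", "N")
  if (!any(isEvent)) return(.noEvents)
  refAdvance <- ifelse(ops %in% .REF_OPS, lens, 0L)
  refBefore <- r$refStart + c(0L, cumsum(refAdvance))[seq_along(ops)]
  qryAdvance <- ifelse(ops %in% .QRY_OPS, lens, 0L)
  qryBefore <- 1L + c(0L, cumsum(qryAdvance))[seq_along(ops)]
  idx <- which(isEvent)
  list(
    op = ops[idx],
    refpos = as.integer(ifelse(ops[idx] == "I",
                               refBefore[idx] - 1L, refBefore[idx])),
    len = lens[idx],
    seq = vapply(idx, function(i) {
      if (ops[i] == "I")
        substr(r$seq, qryBefore[i], qryBefore[i] + lens[i] - 1L)
      else ""
    }, character(1)))
}

.eventKeys <- function(ev) {
  if (!length(ev$op)) return(character(0))
  paste(ev$op, ev$refpos, ev$len, ev$seq, sep = "|")
}

.evSubset <- function(ev, keep)
  list(op = ev$op[keep], refpos = ev$refpos[keep], len = ev$len[keep],
       seq = ev$seq[keep])

.evConcat <- function(...) {
  evs <- list(...)
  list(op = unlist(lapply(evs, `[[`, "op"), use.names = FALSE),
       refpos = unlist(lapply(evs, `[[`, "refpos"), use.names = FALSE),
       len = unlist(lapply(evs, `[[`, "len"), use.names = FALSE),
       seq = unlist(lapply(evs, `[[`, "seq"), use.names = FALSE))
}

.evUnique <- function(ev) .evSubset(ev, !duplicated(.eventKeys(ev)))

## reconcile indel events across the two mates: events reported identically
## by both reads inside their aligned overlap count once; conflicting
## overlap evidence falls back to the higher-MAPQ read (tie: left read)
.fragmentIndelEvents <- function(f) {
  evL <- .readIndelEvents(f@leftRead)
  if (!hasBothReads(f))
    return(list(events = evL, discordant = FALSE))
  evR <- .readIndelEvents(f@rightRead)
  if (!length(evL$op) && !length(evR$op))
    return(list(events = evL, discordant = FALSE))
  oStart <- f@rightRead$refStart
  oEnd <- f@leftRead$refEnd
  if (oStart > oEnd)                        # disjoint mates: no shared zone
    return(list(events = .evUnique(.evConcat(evL, evR)),
                discordant = FALSE))
  ## conflict material is only what BOTH reads could have reported: an
  ## insertion anchored at a read's last aligned base, or a deletion
  ## touching an alignment boundary, is invisible to that read
  inO <- function(ev) ifelse(ev$op == "I",
                             ev$refpos >= oStart & ev$refpos <= oEnd - 1L,
                             ev$refpos >= oStart + 1L &
                               ev$refpos + ev$len - 1L <= oEnd - 1L)
  inL <- inO(evL)
  inR <- inO(evR)
  if (setequal(.eventKeys(.evSubset(evL, inL)),
               .eventKeys(.evSubset(evR, inR)))) {
    list(events = .evUnique(.evConcat(evL, evR)), discordant = FALSE)
  } else {
    useLeft <- f@leftRead$mapq >= f@rightRead$mapq
    chosen <- if (useLeft) .evSubset(evL, inL) else .evSubset(evR, inR)
    ev <- .evConcat(chosen, .evSubset(evL, !inL), .evSubset(evR, !inR))
    list(events = .evUnique(ev), discordant = TRUE)
  }
}

## soft-clip classification: a clip adjacent to the fragment's outermost
## aligned coordinate is an outer clip (5' at outerStart, 3' at outerEnd);
## every other clip is inner
.softclipTally <- function(f) {
  out5 <- 0L; out3 <- 0L; inner <- 0L
  reads <- list(f@leftRead, rightRead(f))
  for (r in reads) {
    if (is.null(r)) next
    ops <- r$ops[!(r$ops %in% c("H", "P"))]
    lens <- r$lens[!(r$ops %in% c("H", "P"))]
    nOps <- length(ops)
    if (nOps == 0L) next
    if (ops[1L] == "S") {
      if (r$refStart == f@outerStart) out5 <- out5 + lens[1L]
      else inner <- inner + lens[1L]
    }
    if (nOps > 1L && ops[nOps] == "S") {
      if (r$refEnd == f@outerEnd) out3 <- out3 + lens[nOps]
      else inner <- inner + lens[nOps]
    }
  }
  c(softclip5_out = out5, softclip3_out = out3, softclip_inner = inner)
}

#' Soft-clip counts of a fragment
#'
#' Counts soft-clipped bases at the fragment's 5' and 3' outer ends
#' (S operations adjacent to the outermost aligned coordinates) and the sum
#' of all remaining (inner) soft clips.
#'
#' @param f a \linkS4class{Fragment}.
#' @return named integer vector \code{softclip5_out}, \code{softclip3_out},
#'   \code{softclip_inner}.
#' @export
softclipCounts <- function(f) .softclipTally(f)

#' Inner distance between mates
#'
#' Reference-space gap between the mates' inner aligned ends:
#' \code{rightRead$refStart - leftRead$refEnd - 1}. Negative when the aligned
#' spans overlap.
#'
#' @param f a \linkS4class{Fragment}.
#' @return integer, or NA for single-read fragments.
#' @export
innerDistance <- function(f) {
  if (!hasBothReads(f)) return(NA_integer_)
  f@rightRead$refStart - f@leftRead$refEnd - 1L
}

#' Indel-aware fragment size
#'
#' Computes the physical fragment length as the reference span of the outer
#' aligned ends, plus inserted bases, minus deleted (D, and by default N)
#' bases, plus outer soft-clipped bases when
#' \code{policy$keepOuterSoftclips}. Indel events reported identically by
#' both mates within their overlap count once; conflicting overlap evidence
#' falls back to the higher-MAPQ read (tie: left read) and flags the
#' fragment \code{size_discordant_mates}. Single-read fragments have no
#' defined size.
#'
#' @param f a \linkS4class{Fragment}.
#' @param policy a \code{\link{sizePolicy}}.
#' @return list: \code{size_bp} (int or NA), \code{tlen_abs},
#'   \code{n_insertions_bp}, \code{n_deletions_bp},
#'   \code{softclip5_out}, \code{softclip3_out}, \code{softclip_inner},
#'   \code{flags} (character vector).
#' @export
fragmentSize <- function(f, policy = sizePolicy()) {
  sc <- .softclipTally(f)
  tlen <- abs(f@leftRead$tlen)
  if (is.na(tlen) || tlen == 0L) tlen <- NA_integer_
  if (!hasBothReads(f)) {
    return(list(size_bp = NA_integer_, tlen_abs = tlen,
                n_insertions_bp = NA_integer_, n_deletions_bp = NA_integer_,
                softclip5_out = unname(sc[1L]),
                softclip3_out = unname(sc[2L]),
                softclip_inner = unname(sc[3L]),
                flags = "no_size_single_read"))
  }
  rec <- .fragmentIndelEvents(f)
  ev <- rec$events
  flags <- character(0)
  if (rec$discordant) flags <- c(flags, "size_discordant_mates")
  nIns <- sum(ev$len[ev$op == "I"])
  nDel <- sum(ev$len[ev$op == "D"])
  nSkip <- sum(ev$len[ev$op == "N"])
  if (nSkip > 0L) {
    flags <- c(flags, "ref_skip_present")
    if (policy$countNAsDeletion) nDel <- nDel + nSkip
  }
  size <- (f@outerEnd - f@outerStart + 1L) + nIns - nDel
  if (policy$keepOuterSoftclips) size <- size + sc[[1L]] + sc[[2L]]
  list(size_bp = as.integer(size), tlen_abs = tlen,
       n_insertions_bp = as.integer(nIns), n_deletions_bp = as.integer(nDel),
       softclip5_out = unname(sc[1L]), softclip3_out = unname(sc[2L]),
       softclip_inner = unname(sc[3L]), flags = flags)
}

#' Reference-derived end motifs of a fragment
#'
#' \code{motif5} reads the top strand inward from the fragment's outer start;
#' \code{motif3} is the reverse complement of the top-strand bases reading
#' inward from the outer end, so both motifs read 5'->3' into the fragment
#' from their respective ends (the standard convention in the end-motif
#' literature). The raw top-strand 3' context is returned as
#' \code{motif3_top_strand}. Motifs anchor at the ALIGNED outer ends; when
#' the fragment carries outer soft clips the true end may extend past the
#' anchor and the fragment is flagged. Ends within \code{k - 1} bases of a
#' contig edge yield NA motifs with a flag.
#'
#' @param f a \linkS4class{Fragment}.
#' @param reference a \linkS4class{ReferenceAccessor} or FASTA path.
#' @param k motif length (default 5).
#' @return list: \code{motif5}, \code{motif3}, \code{motif3_top_strand},
#'   \code{flags}.
#' @export
endMotifs <- function(f, reference, k = 5L) {
  reference <- openReference(reference)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  chrom <- f@leftRead$chrom
  len <- contigLength(reference, chrom)
  flags <- character(0)
  sc <- .softclipTally(f)
  if (sc[[1L]] > 0L || sc[[2L]] > 0L)
    flags <- c(flags, "outer_softclip_motif_anchor")
  if (f@outerStart + k - 1L > len || f@outerStart < 1L) {
    m5 <- NA_character_
    flags <- c(flags, "motif5_contig_edge")
  } else {
    m5 <- getRefSeq(reference, chrom, f@outerStart, f@outerStart + k - 1L)
  }
  if (f@outerEnd - k + 1L < 1L || f@outerEnd > len) {
    m3top <- NA_character_
    m3 <- NA_character_
    flags <- c(flags, "motif3_contig_edge")
  } else {
    m3top <- getRefSeq(reference, chrom, f@outerEnd - k + 1L, f@outerEnd)
    m3 <- .revcomp(m3top)
  }
  list(motif5 = m5, motif3 = m3, motif3_top_strand = m3top, flags = flags)
}

#' All fragmentomic features of a fragment
#'
#' Bundles \code{\link{fragmentSize}}, \code{\link{innerDistance}},
#' \code{\link{endMotifs}} and the outer coordinates into one flat list (one
#' row of the output table).
#'
#' @param f a \linkS4class{Fragment}.
#' @param reference a \linkS4class{ReferenceAccessor} or FASTA path.
#' @param k motif length (default 5).
#' @param policy a \code{\link{sizePolicy}}.
#' @return named list of feature values plus a \code{flags} character vector.
#' @export
fragmentFeatures <- function(f, reference, k = 5L, policy = sizePolicy()) {
  sz <- fragmentSize(f, policy)
  mo <- endMotifs(f, reference, k)
  c(list(outer_start = f@outerStart, outer_end = f@outerEnd,
         inner_distance_bp = innerDistance(f)),
    sz[c("size_bp", "tlen_abs", "n_insertions_bp", "n_deletions_bp",
         "softclip5_out", "softclip3_out", "softclip_inner")],
    mo[c("motif5", "motif3", "motif3_top_strand")],
    list(flags = unique(c(f@flags, sz$flags, mo$flags))))
}
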