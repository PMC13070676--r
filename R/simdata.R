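## Synthetic fixture generation.
##
## Generates a random reference contig with planted mutation contexts, then
## paired-end reads by construction (no aligner): CIGARs are derived from the
## known edit operations of each simulated molecule. TLEN is deliberately
## written as the outer reference span (SAM sign convention), ignorant of
## indels and clips -- reproducing exactly the discrepancy the indel-aware
## size computation removes. Every fragment gets a truth record.

#' Describe one planted mutation for the simulator
#'
#' @param type \code{"SNV"}, \code{"MNV"}, \code{"DEL"} or \code{"INS"}.
#' @param len allele length: substituted bases for MNV, net indel length for
#'   DEL/INS (ignored for SNV).
#' @param vaf planted variant allele fraction in [0, 1].
#' @param context \code{"random"} (whatever the random reference provides) or
#'   \code{"homopolymer"} (the indel sits in a planted A-run, exercising
#'   left-alignment and window extension).
#' @return a named list of class \code{"SimMutation"}.
#' @export
simMutation <- function(type = c("SNV", "MNV", "DEL", "INS"), len = 1L,
                        vaf = 0.1, context = c("random", "homopolymer")) {
  type <- match.arg(type); context <- match.arg(context)
  len <- as.integer(len)
  if (type == "SNV") len <- 1L
  if (type == "MNV" && len < 2L) stop("MNV needs len >= 2")
  if (type %in% c("DEL", "INS") && len < 1L) stop("indel needs len >= 1")
  stopifnot(vaf >= 0, vaf <= 1)
  structure(list(type = type, len = len, vaf = vaf, context = context),
            class = "SimMutation")
}

#' Define a simulation scenario
#'
#' The defaults emulate human plasma cfDNA: a fragment-size mixture of a
#' mononucleosomal mode at 167 bp (sd 10, weight 0.8) and a shorter
#' tumor-like mode at 145 bp (sd 8, weight 0.2), 150 bp read pairs, and
#' error-free bases unless requested. One locus is placed per mutation,
#' \code{spacing} bp apart; every fragment's aligned span covers its locus.
#'
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param mutations list of \code{\link{simMutation}}.
#' @param depth fragments simulated per locus.
#' @param sizeMeans,sizeSds,sizeWeights fragment-size normal mixture.
#' @param sizeRange truncation bounds for size draws (default 60-500 bp).
#' @param readLength read length in bp (default 150).
#' @param errorRate per-base substitution error rate (default 0).
#' @param clipProb probability a fragment carries soft clips (default 0).
#' @param clipRange min/max clip length at each end (default 5-20).
#' @param clipLabel \code{"artifact"} (clip bases are technical, not part of
#'   the molecule) or \code{"genuine"} (clip bases are unaligned molecule
#'   sequence, e.g. a non-reference junction).
#' @param contig contig name.
#' @param spacing distance between loci (default 4000 bp).
#' @param margin contig padding before the first and after the last locus.
#' @param shiftIndelCigars encode planted indels in read CIGARs at the
#'   RIGHTMOST equivalent position instead of the left-aligned one,
#'   emulating a non-normalizing aligner (default FALSE).
#' @param shortMutFragments when TRUE, mutated fragments draw their size
#'   from the mixture component with the smallest mean and wild-type
#'   fragments from the one with the largest, emulating the shorter size
#'   distribution of tumor-derived cfDNA (default FALSE: sizes independent
#'   of status).
#' @return a named list of class \code{"SimScenario"}.
#' @export
simScenario <- function(seed = 1L, mutations = list(simMutation("SNV",
                          vaf = 0.2)),
                        depth = 100L, sizeMeans = c(167, 145),
                        sizeSds = c(10, 8), sizeWeights = c(0.8, 0.2),
                        sizeRange = c(60L, 500L), readLength = 150L,
                        errorRate = 0, clipProb = 0,
                        clipRange = c(5L, 20L),
                        clipLabel = c("artifact", "genuine"),
                        contig = "sim1", spacing = 4000L, margin = 2000L,
                        shiftIndelCigars = FALSE,
                        shortMutFragments = FALSE) {
  clipLabel <- match.arg(clipLabel)
  stopifnot(length(mutations) >= 1L,
            all(vapply(mutations, inherits, logical(1), "SimMutation")),
            length(sizeMeans) == length(sizeSds),
            length(sizeMeans) == length(sizeWeights),
            sizeRange[1L] >= 2L, sizeRange[2L] >= sizeRange[1L],
            errorRate >= 0, errorRate < 1, clipProb >= 0, clipProb <= 1)
  structure(list(seed = as.integer(seed), mutations = mutations,
                 depth = as.integer(depth), sizeMeans = sizeMeans,
                 sizeSds = sizeSds,
                 sizeWeights = sizeWeights / sum(sizeWeights),
                 sizeRange = as.integer(sizeRange),
                 readLength = as.integer(readLength),
                 errorRate = errorRate, clipProb = clipProb,
                 clipRange = as.integer(clipRange), clipLabel = clipLabel,
                 contig = contig, spacing = as.integer(spacing),
                 margin = as.integer(margin),
                 shiftIndelCigars = isTRUE(shiftIndelCigars),
                 shortMutFragments = isTRUE(shortMutFragments)),
            class = "SimScenario")
}

.BASES <- c("A", "C", "G", "T")

.otherBase <- function(b) .BASES[(match(b, .BASES)) %% 4L + 1L]

## uniform integers in [lo, hi], safe for lo == hi
.sampleInt <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n,
                                                  replace = TRUE) - 1L

## truncated mixture size draws; `comp` forces the mixture component
.drawSizes <- function(n, scn, comp = NULL) {
  forced <- !is.null(comp)
  if (!forced)
    comp <- sample.int(length(scn$sizeWeights), n, replace = TRUE,
                       prob = scn$sizeWeights)
  s <- as.integer(round(stats::rnorm(n, scn$sizeMeans[comp],
                                     scn$sizeSds[comp])))
  bad <- which(s < scn$sizeRange[1L] | s > scn$sizeRange[2L])
  tries <- 0L
  while (length(bad) && tries < 50L) {
    compBad <- if (forced) comp[bad]
    else sample.int(length(scn$sizeWeights), length(bad), replace = TRUE,
                    prob = scn$sizeWeights)
    s[bad] <- as.integer(round(stats::rnorm(length(bad),
                                            scn$sizeMeans[compBad],
                                            scn$sizeSds[compBad])))
    bad <- which(s < scn$sizeRange[1L] | s > scn$sizeRange[2L])
    tries <- tries + 1L
  }
  pmin(pmax(s, scn$sizeRange[1L]), scn$sizeRange[2L])
}

## alignment segments as parallel vectors: op (M/I/D), len, seq (query bases
## of the segment; "" for D)
.segPrefix <- function(segs, qBudget) {
  ops <- character(0); lens <- integer(0); seqs <- character(0)
  q <- 0L
  for (i in seq_along(segs$op)) {
    op <- segs$op[i]; len <- segs$len[i]
    if (op == "D") {
      ops <- c(ops, "D"); lens <- c(lens, len); seqs <- c(seqs, "")
      next
    }
    take <- min(len, qBudget - q)
    if (take <= 0L) break
    if (op == "I" && take < len) break    # never emit a partial insertion
    ops <- c(ops, op); lens <- c(lens, take)
    seqs <- c(seqs, substr(segs$seq[i], 1L, take))
    q <- q + take
    if (q >= qBudget) break
  }
  while (length(ops) && ops[length(ops)] == "D") {   # no trailing deletion
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
    seqs <- seqs[-length(seqs)]
  }
  list(op = ops, len = lens, seq = seqs)
}

.segSuffix <- function(segs, qBudget) {
  ops <- character(0); lens <- integer(0); seqs <- character(0)
  q <- 0L
  for (i in rev(seq_along(segs$op))) {
    op <- segs$op[i]; len <- segs$len[i]
    if (op == "D") {
      ops <- c(ops, "D"); lens <- c(lens, len); seqs <- c(seqs, "")
      next
    }
    take <- min(len, qBudget - q)
    if (take <= 0L) break
    if (op == "I" && take < len) break
    ops <- c(ops, op); lens <- c(lens, take)
    seqs <- c(seqs, substr(segs$seq[i], len - take + 1L, len))
    q <- q + take
    if (q >= qBudget) break
  }
  while (length(ops) && ops[length(ops)] == "D") {   # no leading deletion
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
    seqs <- seqs[-length(seqs)]
  }
  list(op = rev(ops), len = rev(lens), seq = rev(seqs))
}

.segRefWidth <- function(segs) sum(segs$len[segs$op %in% c("M", "D")])
.segQry <- function(segs) paste(segs$seq, collapse = "")
.segCigar <- function(segs) paste0(segs$len, segs$op, collapse = "")

## query-index -> reference-position map of a read built from segments
.segRefposMap <- function(segs, pos, clip5, clip3) {
  map <- rep(NA_integer_, clip5)
  refcur <- pos
  for (i in seq_along(segs$op)) {
    op <- segs$op[i]; len <- segs$len[i]
    if (op == "M") {
      map <- c(map, refcur:(refcur + len - 1L))
      refcur <- refcur + len
    } else if (op == "I") {
      map <- c(map, rep(NA_integer_, len))
    } else {
      refcur <- refcur + len
    }
  }
  c(map, rep(NA_integer_, clip3))
}

.randomBases <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

## inject substitution errors; returns new sequence + "qidx:refpos" log
.injectErrors <- function(seq, map, rate) {
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  if (!length(hits)) return(list(seq = seq, log = character(0)))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  logs <- character(length(hits))
  for (k in seq_along(hits)) {
    i <- hits[k]
    alts <- setdiff(.BASES, chars[i])
    chars[i] <- alts[sample.int(3L, 1L)]
    logs[k] <- paste0(i, ":", ifelse(is.na(map[i]), "NA", map[i]))
  }
  list(seq = paste(chars, collapse = ""), log = logs)
}

#' Generate a synthetic reference, BAM and truth table
#'
#' Writes \code{ref.fa} (+\code{.fai}), \code{reads.bam} (+\code{.bai}),
#' \code{mutations.tsv} (normalized chrom/pos/ref/alt) and \code{truth.tsv}
#' (one row per simulated fragment) under \code{outDir}. Mutated fragments
#' carry the planted variant in both SEQ and CIGAR; TLEN is the signed outer
#' reference span. A fixed seed makes the outputs byte-identical across
#' runs.
#'
#' @param scn a \code{\link{simScenario}}.
#' @param outDir output directory (created if needed).
#' @return list with paths (\code{fasta}, \code{bam}, \code{truth},
#'   \code{mutationsFile}), the normalized \code{mutations} (list of
#'   \linkS4class{Mutation}) and the \code{truthTable} data.frame.
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @importFrom Rsamtools asBam indexFa
#' @export
simulateReads <- function(scn, outDir) {
  stopifnot(inherits(scn, "SimScenario"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(scn$seed)
  nLoci <- length(scn$mutations)
  contigLen <- 2L * scn$margin + scn$spacing * (nLoci - 1L)
  refChars <- sample(.BASES, contigLen, replace = TRUE)
  loci <- scn$margin + (seq_len(nLoci) - 1L) * scn$spacing

  ## plant contexts, then derive + normalize the mutations
  for (i in seq_len(nLoci)) {
    sm <- scn$mutations[[i]]; P <- loci[i]
    if (sm$context == "homopolymer" && sm$type %in% c("DEL", "INS")) {
      runLen <- sm$len + 3L
      refChars[P] <- "C"
      refChars[(P + 1L):(P + runLen)] <- "A"
      refChars[P + runLen + 1L] <- "G"   # terminating base of the run
    }
  }
  refSeqStr <- paste(refChars, collapse = "")
  ref <- memoryReference(stats::setNames(refSeqStr, scn$contig))

  muts <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    sm <- scn$mutations[[i]]; P <- loci[i]
    m <- switch(sm$type,
      SNV = Mutation(scn$contig, P, refChars[P], .otherBase(refChars[P])),
      MNV = {
        rr <- paste(refChars[P:(P + sm$len - 1L)], collapse = "")
        aa <- paste(vapply(refChars[P:(P + sm$len - 1L)], .otherBase,
                           character(1)), collapse = "")
        Mutation(scn$contig, P, rr, aa)
      },
      DEL = Mutation(scn$contig, P,
                     paste(refChars[P:(P + sm$len)], collapse = ""),
                     refChars[P]),
      INS = {
        ins <- if (sm$context == "homopolymer")
          strrep("A", sm$len) else .randomBases(sm$len)
        Mutation(scn$contig, P, refChars[P], paste0(refChars[P], ins))
      })
    muts[[i]] <- normalizeMutation(m, ref)
  }

  nTot <- nLoci * scn$depth
  samLines <- character(2L * nTot)
  tFragId <- character(nTot); tMutId <- character(nTot)
  tStatus <- character(nTot); tSize <- integer(nTot)
  tSizeKeep <- integer(nTot); tSizeDrop <- integer(nTot)
  tOutS <- integer(nTot); tOutE <- integer(nTot); tTlen <- integer(nTot)
  tClip5 <- integer(nTot); tClip3 <- integer(nTot)
  tErrors <- character(nTot)
  rowIdx <- 0L
  qualFull <- strrep("F", scn$readLength)  # constant Q37; no quality model

  for (i in seq_len(nLoci)) {
    sm <- scn$mutations[[i]]
    m <- muts[[i]]
    P <- m@pos
    d <- abs(nchar(m@ref) - nchar(m@alt))
    mid <- mutationId(m)
    mShift <- m
    if (scn$shiftIndelCigars && m@mtype %in% c("DEL", "INS")) {
      reps <- enumerateEquivalentRepresentations(m, ref)
      anch <- Filter(function(v) !v@ref %in% c("-", ".", "") &&
                       !v@alt %in% c("-", ".", "") &&
                       v@coordinateBase == "one_based", reps)
      poss <- vapply(anch, function(v) v@pos, integer(1))
      vmax <- anch[[which.max(poss)]]
      mShift <- Mutation(m@chrom, vmax@pos, vmax@ref, vmax@alt)
    }

    statuses <- ifelse(stats::runif(scn$depth) < sm$vaf, "MUT", "WT")
    sizes <- if (scn$shortMutFragments) {
      .drawSizes(scn$depth, scn,
                 comp = ifelse(statuses == "MUT",
                               which.min(scn$sizeMeans),
                               which.max(scn$sizeMeans)))
    } else {
      .drawSizes(scn$depth, scn)
    }
    hasClip <- stats::runif(scn$depth) < scn$clipProb
    clip5s <- ifelse(hasClip,
                     .sampleInt(scn$depth, scn$clipRange[1L],
                                scn$clipRange[2L]), 0L)
    clip3s <- ifelse(hasClip,
                     .sampleInt(scn$depth, scn$clipRange[1L],
                                scn$clipRange[2L]), 0L)
    read1Left <- stats::runif(scn$depth) < 0.5
    mrg <- 5L

    for (j in seq_len(scn$depth)) {
      s <- sizes[j]; status <- statuses[j]
      c5 <- clip5s[j]; c3 <- clip3s[j]
      mut <- status == "MUT"
      eventEndRel <- if (!mut) 0L
      else switch(m@mtype, SNV = 0L, MNV = nchar(m@ref) - 1L,
                  DEL = d + 1L, INS = 1L)
      alignedLen <- if (scn$clipLabel == "genuine") s - c5 - c3 else s
      minAligned <- eventEndRel + 2L * mrg + 2L + (if (mut) d else 0L)
      if (alignedLen < minAligned) {       # molecule too short for clips
        c5 <- 0L; c3 <- 0L
        alignedLen <- s
      }
      refspan <- alignedLen +
        (if (mut && m@mtype == "DEL") d
         else if (mut && m@mtype == "INS") -d else 0L)
      offMax <- refspan - 1L - eventEndRel - mrg
      ## place the fragment so that at least one read sequences the locus:
      ## an event in the unsequenced inner gap is unobservable by design,
      ## so truth would be unverifiable
      qLmax <- min(scn$readLength - c5, refspan)
      qRmax <- min(scn$readLength - c3, refspan)
      offLeftMax <- if (!mut) qLmax - 1L
      else switch(m@mtype, SNV = qLmax - 1L,
                  MNV = qLmax - nchar(m@ref),
                  DEL = qLmax - 2L, INS = qLmax - d - 2L)
      offRightMin <- if (!mut) refspan - qRmax
      else switch(m@mtype, SNV = refspan - qRmax,
                  MNV = refspan - qRmax,
                  DEL = refspan - d - qRmax, INS = refspan + d - qRmax)
      cand <- unique(c(
        if (mrg <= min(offMax, offLeftMax))
          mrg:min(offMax, offLeftMax),
        if (max(mrg, offRightMin) <= offMax)
          max(mrg, offRightMin):offMax))
      off <- if (length(cand) == 0L) mrg
             else cand[sample.int(length(cand), 1L)]
      fstart <- P - off
      fend <- fstart + refspan - 1L
      if (fstart < 1L || fend > contigLen)
        stop("fragment outside contig; increase margin")
      refWin <- substr(refSeqStr, fstart, fend)

      me <- if (mut) mShift else m
      segs <- if (!mut) {
        list(op = "M", len = refspan, seq = refWin)
      } else if (m@mtype %in% c("SNV", "MNV")) {
        i0 <- P - fstart + 1L
        qseq <- paste0(substr(refWin, 1L, i0 - 1L), m@alt,
                       substr(refWin, i0 + nchar(m@ref), nchar(refWin)))
        list(op = "M", len = refspan, seq = qseq)
      } else {
        a1 <- me@pos - fstart + 1L   # M bases through the (shifted) anchor
        if (m@mtype == "DEL") {
          list(op = c("M", "D", "M"),
               len = c(a1, d, refspan - a1 - d),
               seq = c(substr(refWin, 1L, a1), "",
                       substr(refWin, a1 + d + 1L, nchar(refWin))))
        } else {
          list(op = c("M", "I", "M"),
               len = c(a1, d, refspan - a1),
               seq = c(substr(refWin, 1L, a1),
                       substr(me@alt, 2L, nchar(me@alt)),
                       substr(refWin, a1 + 1L, nchar(refWin))))
        }
      }
      Qm <- sum(segs$len[segs$op %in% c("M", "I")])
      qL <- min(scn$readLength - c5, Qm)
      qR <- min(scn$readLength - c3, Qm)
      segL <- .segPrefix(segs, qL)
      segR <- .segSuffix(segs, qR)
      posL <- fstart
      posR <- fend - .segRefWidth(segR) + 1L
      junk5 <- .randomBases(c5)
      junk3 <- .randomBases(c3)
      seqL <- paste0(junk5, .segQry(segL))
      seqR <- paste0(.segQry(segR), junk3)
      cigL <- paste0(if (c5 > 0L) paste0(c5, "S") else "", .segCigar(segL))
      cigR <- paste0(.segCigar(segR), if (c3 > 0L) paste0(c3, "S") else "")
      errLog <- character(0)
      if (scn$errorRate > 0) {
        eL <- .injectErrors(seqL, .segRefposMap(segL, posL, c5, 0L),
                            scn$errorRate)
        seqL <- eL$seq
        eR <- .injectErrors(seqR, .segRefposMap(segR, posR, 0L, c3),
                            scn$errorRate)
        seqR <- eR$seq
        errLog <- c(if (length(eL$log)) paste0("L:", eL$log),
                    if (length(eR$log)) paste0("R:", eR$log))
      }
      qname <- sprintf("frag_%02d_%05d", i, j)
      tlen <- fend - fstart + 1L
      flagL <- 0x1L + 0x2L + 0x20L + (if (read1Left[j]) 0x40L else 0x80L)
      flagR <- 0x1L + 0x2L + 0x10L + (if (read1Left[j]) 0x80L else 0x40L)
      rowIdx <- rowIdx + 1L
      samLines[2L * rowIdx - 1L] <-
        paste(qname, flagL, scn$contig, posL, 60L, cigL, "=", posR, tlen,
              seqL, substr(qualFull, 1L, nchar(seqL)), sep = "\t")
      samLines[2L * rowIdx] <-
        paste(qname, flagR, scn$contig, posR, 60L, cigR, "=", posL, -tlen,
              seqR, substr(qualFull, 1L, nchar(seqR)), sep = "\t")
      tFragId[rowIdx] <- qname; tMutId[rowIdx] <- mid
      tStatus[rowIdx] <- status; tSize[rowIdx] <- s
      tSizeKeep[rowIdx] <- if (scn$clipLabel == "genuine")
        alignedLen + c5 + c3 else s + c5 + c3
      tSizeDrop[rowIdx] <- alignedLen
      tOutS[rowIdx] <- fstart; tOutE[rowIdx] <- fend; tTlen[rowIdx] <- tlen
      tClip5[rowIdx] <- c5; tClip3[rowIdx] <- c3
      tErrors[rowIdx] <- paste(errLog, collapse = ";")
    }
  }

  fastaPath <- file.path(outDir, "ref.fa")
  dna <- Biostrings::DNAStringSet(stats::setNames(refSeqStr, scn$contig))
  Biostrings::writeXStringSet(dna, fastaPath)
  Rsamtools::indexFa(fastaPath)

  samPath <- file.path(outDir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", scn$contig, contigLen))
  writeLines(c(header, samLines), samPath)
  bamPath <- Rsamtools::asBam(samPath, file.path(outDir, "reads"),
                              overwrite = TRUE, indexDestination = TRUE)
  unlink(samPath)

  truthTable <- data.frame(
    fragment_id = tFragId, mutation_id = tMutId, true_status = tStatus,
    true_size = tSize, true_size_keep = tSizeKeep,
    true_size_drop = tSizeDrop, outer_start = tOutS, outer_end = tOutE,
    tlen = tTlen, clip5 = tClip5, clip3 = tClip3,
    clip_label = scn$clipLabel, errors = tErrors,
    stringsAsFactors = FALSE)
  truthPath <- file.path(outDir, "truth.tsv")
  utils::write.table(truthTable, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mutPath <- file.path(outDir, "mutations.tsv")
  utils::write.table(
    data.frame(chrom = vapply(muts, mutationChrom, character(1)),
               pos = vapply(muts, mutationPos, integer(1)),
               ref = vapply(muts, mutationRef, character(1)),
               alt = vapply(muts, mutationAlt, character(1))),
    mutPath, sep = "\t", quote = FALSE, row.names = FALSE)

  list(fasta = fastaPath, bam = bamPath, truth = truthPath,
       mutationsFile = mutPath, mutations = muts, truthTable = truthTable)
}

#' Enumerate all equivalent raw representations of a mutation
#'
#' Brute-force oracle for normalization: every (pos, ref, alt) triple --
#' anchored and anchorless, one- and zero-based -- whose application to the
#' reference yields the same edited sequence as \code{m} does. For an indel
#' in a repeat tract this includes every shift position; for an SNV/MNV
#' exactly the one-based and zero-based pair.
#'
#' @param m a normalized \linkS4class{Mutation}.
#' @param reference a \linkS4class{ReferenceAccessor}.
#' @param maxShift how far around the mutation to search (default 100 bp).
#' @return list of \linkS4class{RawVariant}.
#' @export
enumerateEquivalentRepresentations <- function(m, reference,
                                               maxShift = 100L) {
  reference <- openReference(reference)
  len <- contigLength(reference, m@chrom)
  if (m@mtype %in% c("SNV", "MNV")) {
    return(list(
      RawVariant(m@chrom, m@pos, m@ref, m@alt, "tsv", "one_based"),
      RawVariant(m@chrom, m@pos - 1L, m@ref, m@alt, "tsv", "zero_based")))
  }
  d <- abs(nchar(m@ref) - nchar(m@alt))
  ws <- max(1L, m@pos - as.integer(maxShift))
  we <- min(len, m@pos + nchar(m@ref) + as.integer(maxShift))
  ctx <- getRefSeq(reference, m@chrom, ws, we)
  target <- applyMutation(m, reference, ws, we)
  reps <- list()
  add <- function(v) reps[[length(reps) + 1L]] <<- v
  if (m@mtype == "DEL") {
    for (p in ws:(we - d + 1L)) {
      i <- p - ws + 1L
      cand <- paste0(substr(ctx, 1L, i - 1L),
                     substr(ctx, i + d, nchar(ctx)))
      if (cand != target) next
      delBases <- substr(ctx, i, i + d - 1L)
      add(RawVariant(m@chrom, p, delBases, "-", "tsv", "one_based"))
      add(RawVariant(m@chrom, p - 1L, delBases, "-", "tsv", "zero_based"))
      if (p > 1L) {
        anchor <- getRefSeq(reference, m@chrom, p - 1L, p - 1L)
        add(RawVariant(m@chrom, p - 1L, paste0(anchor, delBases), anchor,
                       "tsv", "one_based"))
        add(RawVariant(m@chrom, p - 2L, paste0(anchor, delBases), anchor,
                       "tsv", "zero_based"))
      }
    }
  } else {
    for (p in (ws - 1L):we) {       # insertion after reference position p
      i <- p - ws + 1L              # index of that base within ctx
      ins <- substr(target, i + 1L, i + d)
      if (nchar(ins) < d) next
      cand <- paste0(substr(ctx, 1L, i), ins,
                     substr(ctx, i + 1L, nchar(ctx)))
      if (cand != target) next
      if (p >= 1L) {
        add(RawVariant(m@chrom, p, "-", ins, "tsv", "one_based"))
        add(RawVariant(m@chrom, p - 1L, "-", ins, "tsv", "zero_based"))
        anchor <- getRefSeq(reference, m@chrom, p, p)
        add(RawVariant(m@chrom, p, anchor, paste0(anchor, ins),
                       "tsv", "one_based"))
        add(RawVariant(m@chrom, p - 1L, anchor, paste0(anchor, ins),
                       "tsv", "zero_based"))
      }
    }
  }
  reps
}
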