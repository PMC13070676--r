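## Shared fixtures, built in code. Heavier simulations are memoized per
## session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## a small handcrafted contig: known motifs and a C AAAA G homopolymer run
## around position 104, plus a TGTG repeat at 131
fixtureContig <- function() {
  left <- paste(rep(c("G", "T", "C", "A", "T"), 19), collapse = "")  # 95 bp
  core <- paste0("CCTGA",      # 96-100
                 "TTT",        # 101-103
                 "CAAAAG",     # 104-109: anchor C, A-run, terminator G
                 "TCGATCGATCGGGGCCCAT",  # 110-128
                 "AC",         # 129-130
                 "TGTGT",      # 131-135: TG repeat then partial T
                 "CATTGCA")    # 136-142
  right <- paste(rep(c("A", "C", "G", "T"), 40), collapse = "")      # 160 bp
  paste0(left, core, right)                                          # 302 bp
}

fixtureMemRef <- function()
  memoryReference(c(chr1 = fixtureContig()))

## the same contig written to an indexed FASTA on disk
fixtureFasta <- function() {
  memoFixture("fasta", function() {
    path <- file.path(tempdir(), "fixture_ref.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(chr1 = fixtureContig())), path)
    Rsamtools::indexFa(path)
    path
  })
}

## build a read record (same shape selectFragments produces) from a CIGAR
## string; the test-side CIGAR parser is intentionally independent of the
## package's own
testRead <- function(qname, pos, cigar, seq, flag = 99L, chrom = "chr1",
                     mapq = 60L, qual = NULL, tlen = 0L,
                     mchrom = chrom, mpos = NA_integer_) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  refw <- sum(nums[ops %in% c("M", "D", "N", "=", "X")])
  if (is.null(qual)) qual <- rep(37L, nchar(seq))
  list(qname = qname, flag = as.integer(flag), chrom = chrom,
       refStart = as.integer(pos), refEnd = as.integer(pos) + refw - 1L,
       mapq = as.integer(mapq), cigar = cigar, ops = ops, lens = nums,
       seq = seq, qual = qual, tlen = as.integer(tlen),
       mchrom = mchrom, mpos = as.integer(mpos),
       isReverse = bitwAnd(as.integer(flag), 16L) != 0L,
       isRead1 = bitwAnd(as.integer(flag), 64L) != 0L)
}

testFragment <- function(left, right = NULL, flags = character(0)) {
  if (is.null(right)) {
    new("Fragment", fragmentId = left$qname, leftRead = left,
        rightRead = list(), outerStart = left$refStart,
        outerEnd = left$refEnd, properPair = FALSE, flags = flags)
  } else {
    if (right$refStart < left$refStart) { tmp <- left; left <- right; right <- tmp }
    new("Fragment", fragmentId = left$qname, leftRead = left,
        rightRead = right,
        outerStart = min(left$refStart, right$refStart),
        outerEnd = max(left$refEnd, right$refEnd),
        properPair = TRUE, flags = flags)
  }
}

## write SAM records (list of vectors: qname, flag, pos, mapq, cigar, mpos,
## tlen, seq) to an indexed BAM on the fixture contig
samToBam <- function(records, dir = tempfile("bam"),
                     contig = "chr1", contigLen = 302L) {
  dir.create(dir, showWarnings = FALSE)
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, contigLen))
  for (r in records) {
    lines <- c(lines, paste(
      r$qname, r$flag, contig, r$pos, if (is.null(r$mapq)) 60L else r$mapq,
      r$cigar, "=", r$mpos, r$tlen, r$seq,
      strrep("F", nchar(r$seq)), sep = "\t"))
  }
  sam <- file.path(dir, "t.sam")
  writeLines(lines, sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

## substring of the fixture contig, 1-based closed (test-side oracle)
ctgSub <- function(s, e) substr(fixtureContig(), s, e)

## a paired-end pair with plain M CIGARs covering [s1, s1+len1-1] and
## [s2, s2+len2-1] on the fixture contig
plainPair <- function(qname, s1, len1, s2, len2) {
  tlen <- (s2 + len2 - 1L) - s1 + 1L
  list(list(qname = qname, flag = 99L, pos = s1, cigar = paste0(len1, "M"),
            mpos = s2, tlen = tlen, seq = ctgSub(s1, s1 + len1 - 1L)),
       list(qname = qname, flag = 147L, pos = s2, cigar = paste0(len2, "M"),
            mpos = s1, tlen = -tlen, seq = ctgSub(s2, s2 + len2 - 1L)))
}

## moderately sized multi-type simulation shared by several test files
sharedSim <- function() {
  memoFixture("sharedSim", function() {
    scn <- simScenario(
      seed = 424242, depth = 60,
      mutations = list(
        simMutation("SNV", vaf = 0.4),
        simMutation("DEL", len = 15L, vaf = 0.3),
        simMutation("INS", len = 3L, vaf = 0.3, context = "homopolymer"),
        simMutation("DEL", len = 1L, vaf = 0.3, context = "homopolymer"),
        simMutation("MNV", len = 2L, vaf = 0.3)),
      shortMutFragments = TRUE)
    dir <- file.path(tempdir(), "sharedSim")
    sim <- simulateReads(scn, dir)
    sim$scenario <- scn
    sim
  })
}

sharedRun <- function() {
  memoFixture("sharedRun", function() {
    sim <- sharedSim()
    runFragtyper(sim$bam, sim$mutationsFile, sim$fasta)
  })
}
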