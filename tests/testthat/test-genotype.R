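## Genotyping windows, read calls, CIGAR precedence, fragment aggregation.

test_that("SNV windows cover the substituted base with one-base flanks", {
  ref <- fixtureMemRef()
  m <- normalizeMutation(Mutation("chr1", 100L, "A", "G"), ref)
  w <- buildWindow(m, ref)
  expect_equal(c(w$wStart, w$wEnd), c(100L, 100L))
  expect_equal(c(w$extStart, w$extEnd), c(99L, 101L))
  expect_equal(w$refHap, "A")
  expect_equal(w$altHap, "G")
})

test_that("indel windows extend through repeats to a terminating base", {
  ref <- fixtureMemRef()
  ## 1 bp A-deletion in the C AAAA G run (104-109): window must reach the G
  del <- normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref)
  w <- buildWindow(del, ref)
  expect_equal(c(w$wStart, w$wEnd), c(104L, 109L))
  expect_equal(w$refHap, "CAAAAG")
  expect_equal(w$altHap, "CAAAG")
  ## derived minimality oracle: truncating one base earlier leaves the
  ## haplotype prefixes indistinguishable, the full window distinguishes
  n <- nchar(w$refHap)
  expect_true(startsWith(w$refHap, substr(w$altHap, 1, n - 2)))
  expect_false(startsWith(w$refHap, w$altHap))

  ## TG insertion in front of TGTGT (131-135): window runs through the
  ## partial repeat to the first non-repeat base (136)
  ins <- normalizeMutation(Mutation("chr1", 130L, "C", "CTG"), ref)
  wi <- buildWindow(ins, ref)
  expect_equal(c(wi$wStart, wi$wEnd), c(130L, 136L))
  expect_equal(wi$refHap, ctgSub(130, 136))
  expect_false(startsWith(wi$refHap, wi$altHap) ||
                 startsWith(wi$altHap, wi$refHap))
})

test_that("read window sequences map through M, I and truncation", {
  ref <- fixtureMemRef()
  m <- normalizeMutation(Mutation("chr1", 100L, "A", "G"), ref)
  w <- buildWindow(m, ref)
  ## clean covering read
  r <- testRead("r", 96, "10M", ctgSub(96, 105))
  rw <- readWindowSequence(r, w)
  expect_equal(rw$observed, "A")
  expect_false(rw$truncatedLeft || rw$truncatedRight)

  ## insertion anchored inside the window appears in the observed bases
  ins <- normalizeMutation(Mutation("chr1", 130L, "C", "CTG"), ref)
  wi <- buildWindow(ins, ref)
  seqIns <- paste0(ctgSub(126, 130), "TG", ctgSub(131, 138))
  rIns <- testRead("ri", 126, "5M2I8M", seqIns)
  rwi <- readWindowSequence(rIns, wi)
  expect_equal(rwi$observed, paste0("CTG", ctgSub(131, 136)))
  expect_equal(rwi$observed, wi$altHap)

  ## a read ending mid-window is the covered prefix, flagged truncated
  rT <- testRead("rt", 96, "11M", ctgSub(96, 106))
  del <- normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref)
  wd <- buildWindow(del, ref)
  rwT <- readWindowSequence(rT, wd)
  expect_equal(rwT$observed, ctgSub(104, 106))
  expect_true(rwT$truncatedRight)

  ## no overlap at all
  rN <- testRead("rn", 200, "10M", ctgSub(200, 209))
  expect_true(readWindowSequence(rN, wd)$noCoverage)
})

test_that("CIGAR scan recognizes the expected indel after left-alignment", {
  ref <- fixtureMemRef()
  del <- normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref)
  w <- buildWindow(del, ref)
  ## deletion encoded at the left-aligned anchor
  rL <- testRead("a", 96, "9M1D10M", paste0(ctgSub(96, 104), ctgSub(106, 115)))
  expect_equal(cigarIndelScan(rL, del, w, ref), "expected_indel")
  ## the same molecule with the deletion right-shifted inside the A-run:
  ## normalization must still recognize it
  rR <- testRead("b", 96, "12M1D7M", paste0(ctgSub(96, 107), ctgSub(109, 115)))
  expect_equal(cigarIndelScan(rR, del, w, ref), "expected_indel")
  ## an insertion in the window is a different event
  rO <- testRead("c", 96, "10M1I9M",
                 paste0(ctgSub(96, 105), "T", ctgSub(106, 114)))
  expect_equal(cigarIndelScan(rO, del, w, ref), "other_indel")
  ## wrong deletion length in the window is near-miss, not expected
  rW <- testRead("d", 96, "9M2D9M", paste0(ctgSub(96, 104), ctgSub(107, 115)))
  expect_equal(cigarIndelScan(rW, del, w, ref), "other_indel")
  ## plain match
  rM <- testRead("e", 96, "20M", ctgSub(96, 115))
  expect_equal(cigarIndelScan(rM, del, w, ref), "none")
})

test_that("SNV read calls follow the window comparison", {
  ref <- fixtureMemRef()
  m <- normalizeMutation(Mutation("chr1", 100L, "A", "G"), ref)
  w <- buildWindow(m, ref)
  mkRead <- function(base, flank = ctgSub(99, 99))
    testRead("r", 96, "10M",
             paste0(ctgSub(96, 98), flank, base, ctgSub(101, 105)))
  expect_equal(genotypeRead(mkRead("G"), m, w, ref)$status, "MUT")
  expect_equal(genotypeRead(mkRead("A"), m, w, ref)$status, "WT")
  expect_equal(genotypeRead(mkRead("T"), m, w, ref)$status, "OTH")
  ## clean flanks carry no flags
  expect_length(genotypeRead(mkRead("G"), m, w, ref)$flags, 0L)
  ## a mismatching extended flank flags a possibly larger event but never
  ## changes the status
  cl <- genotypeRead(mkRead("G", flank = "T"), m, w, ref)
  expect_equal(cl$status, "MUT")
  expect_true("possible_larger_event" %in% cl$flags)
  ## no coverage
  far <- testRead("f", 200, "10M", ctgSub(200, 209))
  cf <- genotypeRead(far, m, w, ref)
  expect_equal(cf$status, "AMBIGUOUS")
  expect_true("no_coverage" %in% cf$flags)
})

test_that("low base quality inside the window makes the read ambiguous", {
  ref <- fixtureMemRef()
  m <- normalizeMutation(Mutation("chr1", 100L, "A", "G"), ref)
  w <- buildWindow(m, ref)
  r <- testRead("r", 96, "10M", paste0(ctgSub(96, 99), "G", ctgSub(101, 105)),
                qual = c(rep(37L, 4), 5L, rep(37L, 5)))
  expect_equal(genotypeRead(r, m, w, ref, minBaseq = 0L)$status, "MUT")
  cl <- genotypeRead(r, m, w, ref, minBaseq = 20L)
  expect_equal(cl$status, "AMBIGUOUS")
  expect_true("low_baseq" %in% cl$flags)
})

test_that("reads ending inside a homopolymer run are ambiguous", {
  ref <- fixtureMemRef()
  del <- normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref)
  w <- buildWindow(del, ref)
  ## mutated molecule read stopping before the run's terminating base:
  ## the truncated haplotypes coincide (string-equality oracle)
  rShort <- testRead("s", 96, "11M", paste0(ctgSub(96, 103), "CAA"))
  cl <- genotypeRead(rShort, del, w, ref)
  expect_equal(cl$status, "AMBIGUOUS")
  expect_true("truncated_window" %in% cl$flags)
  ## the same read reaching the terminator is informative
  rFull <- testRead("g", 96, "9M1D10M",
                    paste0(ctgSub(96, 104), ctgSub(106, 115)))
  expect_equal(genotypeRead(rFull, del, w, ref)$status, "MUT")
})

test_that("CIGAR evidence takes precedence over the sequence window", {
  ref <- fixtureMemRef()
  del <- normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref)
  w <- buildWindow(del, ref)
  ## CIGAR reports the expected deletion but the query bases spell the
  ## wild-type window: status follows the CIGAR, discordance flagged
  rConf <- testRead("cf", 96, "9M1D10M",
                    paste0(ctgSub(96, 104), "AAAAG", ctgSub(111, 115)))
  cl <- genotypeRead(rConf, del, w, ref)
  expect_equal(cl$status, "MUT")
  expect_true("cigar_seq_discordant" %in% cl$flags)
  expect_equal(cl$cigarEvidence, "expected_indel")
  ## a different indel elsewhere in the window only flags
  ins <- testRead("oi", 96, "10M1I9M",
                  paste0(ctgSub(96, 105), "T", ctgSub(106, 114)))
  cl2 <- genotypeRead(ins, del, w, ref)
  expect_true("other_indel_present" %in% cl2$flags)
  expect_equal(cl2$cigarEvidence, "other_indel")
})

test_that("fragment calls aggregate read calls per the resolution table", {
  mk <- function(status, flags = character(0))
    structure(list(status = status, flags = flags, cigarEvidence = "none"),
              class = "ReadCall")
  cases <- list(
    list(mk("MUT"), mk("MUT"), "MUT", "concordant"),
    list(mk("WT"), mk("WT"), "WT", "concordant"),
    list(mk("OTH"), mk("OTH"), "OTH", "concordant"),
    list(mk("AMBIGUOUS"), mk("WT"), "WT", "flag_resolved"),
    list(mk("MUT"), mk("AMBIGUOUS"), "MUT", "flag_resolved"),
    list(mk("MUT"), mk("WT"), "NI", "discrepant"),
    list(mk("MUT"), mk("OTH"), "NI", "discrepant"),
    list(mk("WT"), mk("OTH"), "NI", "discrepant"),
    list(mk("AMBIGUOUS"), mk("AMBIGUOUS"), "NI", "ambiguous"),
    list(mk("MUT"), NULL, "MUT", "single_read"),
    list(mk("AMBIGUOUS"), NULL, "NI", "ambiguous"),
    ## a mate with no coverage behaves like an absent mate
    list(mk("WT"), mk("AMBIGUOUS", "no_coverage"), "WT", "single_read"))
  for (cs in cases) {
    fc <- genotypeFragment(cs[[1]], cs[[2]])
    expect_equal(fc$status, cs[[3]])
    expect_equal(fc$resolution, cs[[4]])
    ## the NI iff {discrepant, ambiguous} invariant
    expect_equal(fc$status == "NI",
                 fc$resolution %in% c("discrepant", "ambiguous"))
  }
})

test_that("locus VAF counts mutated over informative fragments", {
  v <- locusVaf(c("MUT", "MUT", "WT", "WT", "NI"))
  expect_equal(v$vaf, 0.5)
  expect_equal(v$n_ni, 1L)
  expect_equal(locusVaf(c("MUT", "WT", "WT", "OTH"))$vaf, 0.25)
  expect_true(is.na(locusVaf(c("NI", "NI"))$vaf))
  expect_true(is.na(locusVaf(character(0))$vaf))
})

test_that("genotyping is invariant to the input representation", {
  sim <- sharedSim()
  fa <- sim$fasta
  ref <- openReference(fa)
  ## the two homopolymer indels have many raw representations; the full
  ## workflow result must not depend on which one the user supplied
  for (m in sim$mutations[c(3, 4)]) {
    reps <- enumerateEquivalentRepresentations(m, ref)
    pick <- reps[c(1L, length(reps))]
    base <- runFragtyper(sim$bam, list(m), fa, windowBp = 300L)
    for (v in pick) {
      alt <- runFragtyper(
        sim$bam,
        paste(v@chrom, v@pos, v@ref, v@alt, sep = ":"), fa,
        windowBp = 300L,
        coordinateBase = v@coordinateBase)
      expect_equal(as.data.frame(alt)[-1], as.data.frame(base)[-1],
                   label = paste("representation", v@pos, v@ref, v@alt))
      expect_equal(as.data.frame(vafSummary(alt))[-1],
                   as.data.frame(vafSummary(base))[-1])
    }
  }
})
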