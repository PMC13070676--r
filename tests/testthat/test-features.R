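## Fragmentomic features: indel-aware size, inner distance, motifs, clips.

test_that("clean pairs have size equal to |TLEN|", {
  ## 75M + 75M spanning 167 bp, no indels or clips
  l <- testRead("f", 100, "75M", strrep("A", 75), flag = 99, tlen = 167)
  r <- testRead("f", 192, "75M", strrep("A", 75), flag = 147, tlen = -167)
  f <- testFragment(l, r)
  sz <- fragmentSize(f)
  expect_equal(sz$size_bp, 167L)
  expect_equal(sz$tlen_abs, 167L)
  expect_equal(sz$n_insertions_bp, 0L)
  expect_equal(sz$n_deletions_bp, 0L)
})

test_that("a 15 bp deletion shifts TLEN-based size by exactly 15", {
  ## outer span 180 bp; one read carries 15D -> molecule is 165 bp
  l <- testRead("f", 100, "30M15D30M", strrep("A", 60), flag = 99,
                tlen = 180)
  r <- testRead("f", 220, "60M", strrep("A", 60), flag = 147, tlen = -180)
  f <- testFragment(l, r)
  sz <- fragmentSize(f)
  expect_equal(sz$size_bp, 165L)
  expect_equal(sz$tlen_abs, 180L)
  expect_equal(sz$tlen_abs - sz$size_bp, 15L)
})

test_that("mates reporting the same indel in their overlap count it once", {
  ## both reads span the event region and both report the same 5D;
  ## outer span 100..169 = 70 bp, the deletion counts once
  l <- testRead("f", 100, "20M5D30M", strrep("A", 50), flag = 99, tlen = 70)
  r <- testRead("f", 110, "10M5D45M", strrep("A", 55), flag = 147,
                tlen = -70)
  f <- testFragment(l, r)
  sz <- fragmentSize(f)
  expect_equal(sz$size_bp, 65L)
  expect_equal(sz$n_deletions_bp, 5L)
  expect_false("size_discordant_mates" %in% sz$flags)
})

test_that("conflicting overlap evidence falls back to the higher-MAPQ read", {
  ## same outer span (100..169) but only the left read reports a deletion
  ## inside the mates' overlap [110, 154]
  l <- testRead("f", 100, "20M5D30M", strrep("A", 50), flag = 99,
                mapq = 60, tlen = 70)
  r <- testRead("f", 110, "60M", strrep("A", 60), flag = 147,
                mapq = 20, tlen = -70)
  f <- testFragment(l, r)
  sz <- fragmentSize(f)
  expect_true("size_discordant_mates" %in% sz$flags)
  expect_equal(sz$size_bp, 65L)          # left read (higher MAPQ) wins

  ## flip the qualities: the clean right read wins
  l2 <- testRead("f", 100, "20M5D30M", strrep("A", 50), flag = 99,
                 mapq = 20, tlen = 70)
  r2 <- testRead("f", 110, "60M", strrep("A", 60), flag = 147,
                 mapq = 60, tlen = -70)
  sz2 <- fragmentSize(testFragment(l2, r2))
  expect_true("size_discordant_mates" %in% sz2$flags)
  expect_equal(sz2$size_bp, 70L)
})

test_that("read-through clips are excluded under the drop policy", {
  ## 60 bp molecule fully read by 75 bp reads: 15 adapter bases clipped at
  ## each fragment end
  l <- testRead("f", 100, "60M15S", strrep("A", 75), flag = 99, tlen = 60)
  r <- testRead("f", 100, "15S60M", strrep("A", 75), flag = 147, tlen = -60)
  f <- testFragment(l, r)
  szDrop <- fragmentSize(f, sizePolicy(keepOuterSoftclips = FALSE))
  expect_equal(szDrop$size_bp, 60L)
  ## keep policy counts the outer clip bases into the size
  szKeep <- fragmentSize(f, sizePolicy(keepOuterSoftclips = TRUE))
  expect_equal(szKeep$size_bp, 60L + szKeep$softclip5_out +
                 szKeep$softclip3_out)
})

test_that("single-read fragments have no size, with a flag", {
  f <- testFragment(testRead("s", 100, "50M", strrep("A", 50), tlen = 0))
  sz <- fragmentSize(f)
  expect_true(is.na(sz$size_bp))
  expect_true("no_size_single_read" %in% sz$flags)
})

test_that("inner distance is the gap between inner aligned ends", {
  mk <- function(s1, e1, s2, e2) {
    testFragment(
      testRead("f", s1, paste0(e1 - s1 + 1, "M"),
               strrep("A", e1 - s1 + 1), flag = 99),
      testRead("f", s2, paste0(e2 - s2 + 1, "M"),
               strrep("A", e2 - s2 + 1), flag = 147))
  }
  expect_equal(innerDistance(mk(100, 174, 200, 274)), 25L)
  expect_equal(innerDistance(mk(100, 174, 150, 224)), -25L)
  expect_equal(innerDistance(mk(100, 174, 100, 174)), -75L)
  expect_true(is.na(innerDistance(
    testFragment(testRead("s", 100, "50M", strrep("A", 50))))))
})

test_that("end motifs come from the reference, 5'->3' into the fragment", {
  ref <- fixtureMemRef()
  ## fragment starting at the CCTGA motif (96) and ending at 140
  f <- testFragment(
    testRead("f", 96, "30M", ctgSub(96, 125), flag = 99),
    testRead("f", 111, "30M", ctgSub(111, 140), flag = 147))
  mo <- endMotifs(f, ref, k = 5L)
  expect_equal(mo$motif5, "CCTGA")
  ## 3' end at 140: top strand 136-140 is CATTG; inward reading is its
  ## reverse complement
  expect_equal(mo$motif3_top_strand, ctgSub(136, 140))
  expect_equal(mo$motif3, "CAATG")
  expect_equal(nchar(mo$motif5), 5L)

  ## k = 1: single terminal bases
  mo1 <- endMotifs(f, ref, k = 1L)
  expect_equal(mo1$motif5, ctgSub(96, 96))
  expect_equal(mo1$motif3, chartr("ACGT", "TGCA", ctgSub(140, 140)))

  ## contig edges: motifs read inward, so they stay defined right up to
  ## the ends...
  revc <- function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  fEdge <- testFragment(
    testRead("e", 1, "20M", ctgSub(1, 20), flag = 99),
    testRead("e", 283, "20M", ctgSub(283, 302), flag = 147))
  moE <- endMotifs(fEdge, ref, k = 5L)
  expect_equal(moE$motif5, ctgSub(1, 5))
  expect_equal(moE$motif3, revc(ctgSub(298, 302)))
  ## ...but a fragment END within k-1 bases of the contig START has no
  ## inward 3' context
  fEdge2 <- testFragment(testRead("e2", 1, "3M", ctgSub(1, 3), flag = 99))
  moE2 <- endMotifs(fEdge2, ref, k = 5L)
  expect_true(is.na(moE2$motif3))
  expect_true("motif3_contig_edge" %in% moE2$flags)
})

test_that("soft clips classify as outer or inner by adjacency", {
  mk <- function(c1, c2) testFragment(
    testRead("f", 100, c1, strrep("A", sum(as.integer(
      regmatches(c1, gregexpr("[0-9]+(?=[MIS])", c1, perl = TRUE))[[1]]))),
      flag = 99),
    testRead("f", 130, c2, strrep("A", sum(as.integer(
      regmatches(c2, gregexpr("[0-9]+(?=[MIS])", c2, perl = TRUE))[[1]]))),
      flag = 147))
  expect_equal(unname(softclipCounts(mk("5S70M", "75M"))), c(5L, 0L, 0L))
  expect_equal(unname(softclipCounts(mk("75M", "70M5S"))), c(0L, 5L, 0L))
  ## clips at the facing (inner) read ends
  expect_equal(unname(softclipCounts(mk("70M5S", "5S70M"))), c(0L, 0L, 10L))
})

test_that("size matches simulator truth for both policies over 300 draws", {
  ## indels 1-8 bp with artifact clips; policy-specific truth from the
  ## generator is the oracle
  scn <- simScenario(
    seed = 99, depth = 50, clipProb = 0.5, clipRange = c(1L, 20L),
    clipLabel = "artifact", sizeRange = c(60L, 500L),
    sizeMeans = c(170, 300), sizeSds = c(30, 80), sizeWeights = c(0.6, 0.4),
    mutations = list(
      simMutation("DEL", len = 1L, vaf = 0.5),
      simMutation("INS", len = 4L, vaf = 0.5),
      simMutation("DEL", len = 8L, vaf = 0.5,  context = "homopolymer"),
      simMutation("INS", len = 6L, vaf = 0.5),
      simMutation("DEL", len = 5L, vaf = 0.5),
      simMutation("INS", len = 2L, vaf = 0.5, context = "homopolymer")))
  sim <- simulateReads(scn, tempfile("sizesim"))
  for (keep in c(TRUE, FALSE)) {
    ft <- runFragtyper(sim$bam, sim$mutationsFile, sim$fasta,
                       keepSoftclips = keep)
    mg <- merge(as.data.frame(ft), sim$truthTable,
                by = c("fragment_id", "mutation_id"))
    expect_equal(nrow(mg), nrow(sim$truthTable))
    truthCol <- if (keep) mg$true_size_keep else mg$true_size_drop
    expect_equal(mean(mg$size_bp == truthCol), 1,
                 label = paste("policy keep =", keep))
  }
})

test_that("TLEN and indel-aware size agree on clip- and indel-free pairs", {
  scn <- simScenario(seed = 100, depth = 150,
                     mutations = list(simMutation("SNV", vaf = 0.5)))
  sim <- simulateReads(scn, tempfile("tlensim"))
  ft <- runFragtyper(sim$bam, sim$mutationsFile, sim$fasta)
  df <- as.data.frame(ft)
  expect_gte(nrow(df), 150L)
  expect_equal(mean(df$size_bp == df$tlen_abs), 1)
})

test_that("feature extraction cost grows linearly in fragment count", {
  ## the per-mutation loop touches each read's CIGAR a bounded number of
  ## times: operation counts (not wall clock) at n and 2n fragments
  countOps <- function(depth) {
    scn <- simScenario(seed = 55, depth = depth,
                       mutations = list(simMutation("DEL", len = 5L,
                                                    vaf = 0.5)))
    sim <- simulateReads(scn, tempfile("complexity"))
    counter <- 0L
    ns <- asNamespace("fragtyper")
    suppressMessages(trace("alignmentProfile", where = ns,
                           tracer = function() counter <<- counter + 1L,
                           print = FALSE))
    on.exit(suppressMessages(untrace("alignmentProfile", where = ns)),
            add = TRUE)
    invisible(runFragtyper(sim$bam, sim$mutationsFile, sim$fasta))
    counter
  }
  n1 <- countOps(60L)
  n2 <- countOps(120L)
  expect_gt(n1, 0L)
  expect_lte(n2, 2.3 * n1)
})
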