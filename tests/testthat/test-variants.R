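## Mutation parsing, allele resolution and normalization.

test_that("colon strings parse field-wise and reject malformed input", {
  v <- parseVariants("chr7:55242465:GGAATTAAGAGAAGC:-")[[1]]
  expect_s4_class(v, "RawVariant")
  expect_equal(v@chrom, "chr7")
  expect_equal(v@pos, 55242465L)
  expect_equal(v@ref, "GGAATTAAGAGAAGC")
  expect_equal(v@alt, "-")

  expect_error(parseVariants("chr1:100:A"), "malformed")
  expect_error(parseVariants("chr1:xx:A:T"), "non-integer")
  expect_error(parseVariants(character(0)), "empty")
})

test_that("TSV input requires the documented header", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t100\tA\tT"), tsv)
  v <- parseVariants(tsv)
  expect_length(v, 1L)
  expect_equal(v[[1]]@sourceFormat, "tsv")
  expect_equal(v[[1]]@pos, 100L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chr\tposition\tr\ta", "chr1\t100\tA\tT"), bad)
  expect_error(parseVariants(bad), "found: chr, position")
})

test_that("VCF rows are 1-based and multi-allelic records split per ALT", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=302>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t.\t.\t.",
    "chr1\t120\t.\tA\tT,G\t.\t.\t."), vcf)
  v <- parseVariants(vcf)
  ## oracle: one RawVariant per comma-separated ALT allele
  expect_length(v, 3L)
  expect_equal(v[[1]]@coordinateBase, "one_based")
  expect_equal(vapply(v, function(x) x@alt, character(1)),
               c("T", "T", "G"))
  expect_equal(vapply(v, function(x) x@pos, integer(1)),
               c(100L, 120L, 120L))
})

test_that("resolveAlleles anchors blank alleles and fixes conventions", {
  ref <- memoryReference(c(chr1 = "GGTCATTAGC"))
  ## deletion given anchorless: pos = first deleted base; reference has A
  ## at 5, T at 6 -> manual anchor-base construction gives (5, AT, A)
  m <- resolveAlleles(RawVariant("chr1", 6L, "T", "-"), ref)
  expect_equal(mutationPos(m), 5L)
  expect_equal(mutationRef(m), "AT")
  expect_equal(mutationAlt(m), "A")
  expect_equal(mutationType(m), "DEL")

  ## complete alleles pass through
  m2 <- resolveAlleles(RawVariant("chr1", 5L, "A", "T"), ref)
  expect_equal(mutationPos(m2), 5L)
  expect_equal(mutationRef(m2), "A")
  expect_equal(mutationType(m2), "SNV")

  ## zero-based input shifts by one
  m3 <- resolveAlleles(
    RawVariant("chr1", 4L, "A", "T", coordinateBase = "zero_based"), ref)
  expect_equal(mutationPos(m3), 5L)

  ## anchorless insertion: pos is the base left of the insertion
  m4 <- resolveAlleles(RawVariant("chr1", 5L, "-", "GG"), ref)
  expect_equal(mutationPos(m4), 5L)
  expect_equal(mutationRef(m4), "A")
  expect_equal(mutationAlt(m4), "AGG")

  expect_error(resolveAlleles(RawVariant("chr1", 5L, "C", "T"), ref),
               "mismatch.*'C'.*'A'")
  expect_error(resolveAlleles(RawVariant("chr1", 1L, "G", "-"), ref),
               "unrepresentable")
  expect_error(resolveAlleles(RawVariant("chr1", 5L, "<DEL>", "A"), ref),
               "unsupported")
})

test_that("normalization trims and left-aligns to a fixed point", {
  ref <- memoryReference(c(chr1 = "GGTCAAAAGTTATGCA"))
  ## SNVs are fixed points
  snv <- normalizeMutation(Mutation("chr1", 2L, "G", "A"), ref)
  expect_equal(mutationPos(snv), 2L)
  expect_true(isNormalized(snv))

  ## shared prefix/suffix trims an MNV-shaped record down to the SNV core
  ## (ATG -> AGG differs only at its middle base)
  tr <- normalizeMutation(Mutation("chr1", 11L, "ATG", "AGG"), ref)
  expect_equal(mutationPos(tr), 12L)
  expect_equal(mutationRef(tr), "T")
  expect_equal(mutationAlt(tr), "G")
  expect_equal(mutationType(tr), "SNV")

  ## deletion inside the A-homopolymer (positions 5-8) left-aligns to the
  ## C anchor at 4
  del <- normalizeMutation(Mutation("chr1", 6L, "AA", "A"), ref)
  expect_equal(mutationPos(del), 4L)
  expect_equal(mutationRef(del), "CA")
  expect_equal(mutationAlt(del), "C")

  ## complex (length-changing substitution after trim) is rejected
  expect_error(normalizeMutation(Mutation("chr1", 10L, "TTA", "GC"), ref),
               "complex")
})

test_that("all equivalent representations collapse to one canonical form", {
  ref <- fixtureMemRef()
  ## brute-force oracle on the fixture contig
  cases <- list(
    normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref),  # 1bp del in run
    normalizeMutation(Mutation("chr1", 104L, "C", "CA"), ref),  # 1bp ins in run
    normalizeMutation(Mutation("chr1", 130L, "C", "CTG"), ref), # TG-repeat ins
    normalizeMutation(Mutation("chr1", 110L, "TCGAT", "T"), ref))
  for (m in cases) {
    reps <- enumerateEquivalentRepresentations(m, ref)
    expect_gte(length(reps), 4L)
    for (v in reps) {
      norm <- normalizeMutation(resolveAlleles(v, ref), ref)
      expect_equal(mutationId(norm), mutationId(m), label = mutationId(m))
    }
  }
  ## a 1 bp deletion in the AAAA run: >= 4 shift positions x anchored and
  ## anchorless x coordinate conventions
  reps <- enumerateEquivalentRepresentations(
    normalizeMutation(Mutation("chr1", 104L, "CA", "C"), ref), ref)
  expect_gte(length(reps), 16L)
  ## an SNV has exactly the one-based and zero-based pair
  snvReps <- enumerateEquivalentRepresentations(
    normalizeMutation(Mutation("chr1", 104L, "C", "T"), ref), ref)
  expect_length(snvReps, 2L)
})

test_that("normalization is idempotent and round-trips via apply-and-diff", {
  ref <- fixtureMemRef()
  muts <- list(
    Mutation("chr1", 104L, "CA", "C"),
    Mutation("chr1", 104L, "C", "CA"),
    Mutation("chr1", 130L, "C", "CTG"),
    Mutation("chr1", 96L, "CC", "TT"),
    Mutation("chr1", 100L, "A", "G"))
  for (m0 in muts) {
    m1 <- normalizeMutation(m0, ref)
    m2 <- normalizeMutation(m1, ref)
    expect_equal(mutationId(m1), mutationId(m2))
    ## applying m1 and re-deriving the difference finds m1 again: the
    ## canonical representation of the edit equals m1
    win <- c(max(1L, mutationPos(m1) - 30L), mutationPos(m1) + 30L)
    edited <- applyMutation(m1, ref, win[1], win[2])
    original <- getRefSeq(ref, "chr1", win[1], win[2])
    expect_false(identical(edited, original))
    reps <- enumerateEquivalentRepresentations(m1, ref)
    rederived <- unique(vapply(reps, function(v)
      mutationId(normalizeMutation(resolveAlleles(v, ref), ref)),
      character(1)))
    expect_equal(rederived, mutationId(m1))
  }
})

test_that("readMutations accepts a FASTA path and mixed conventions", {
  fa <- fixtureFasta()
  ms <- readMutations(c("chr1:104:CA:C", "chr1:100:A:G"), fa)
  expect_length(ms, 2L)
  expect_true(all(vapply(ms, isNormalized, logical(1))))
  ## same deletion supplied anchorless and zero-based converges
  m0 <- readMutations("chr1:105:A:-", fa)[[1]]
  expect_equal(mutationId(m0), mutationId(ms[[1]]))
})
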