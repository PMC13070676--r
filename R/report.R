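## The high-level workflow: mutations in, per-fragment table out.

.TABLE_COLUMNS <- c(
  "mutation_id", "fragment_id", "outer_start", "outer_end", "size_bp",
  "tlen_abs", "inner_distance_bp", "motif5", "motif3", "motif3_top_strand",
  "softclip5_out", "softclip3_out", "softclip_inner", "n_insertions_bp",
  "n_deletions_bp", "status", "resolution", "flags")

.READ_COLUMNS <- c("left_flag", "left_mapq", "left_cigar", "left_window_baseq",
                   "right_flag", "right_mapq", "right_cigar",
                   "right_window_baseq")

.meanWindowBaseq <- function(r, w) {
  if (is.null(r)) return(NA_real_)
  rw <- readWindowSequence(r, w)
  if (!length(rw$qidx)) return(NA_real_)
  round(mean(r$qual[rw$qidx]), 2)
}

.emptyLocusRow <- function(verbose) {
  int0 <- integer(0); chr0 <- character(0)
  out <- list(mutation_id = chr0, fragment_id = chr0, outer_start = int0,
              outer_end = int0, size_bp = int0, tlen_abs = int0,
              inner_distance_bp = int0, motif5 = chr0, motif3 = chr0,
              motif3_top_strand = chr0, softclip5_out = int0,
              softclip3_out = int0, softclip_inner = int0,
              n_insertions_bp = int0, n_deletions_bp = int0, status = chr0,
              resolution = chr0, flags = chr0)
  if (verbose)
    out <- c(out, list(left_flag = int0, left_mapq = int0, left_cigar = chr0,
                       left_window_baseq = numeric(0), right_flag = int0,
                       right_mapq = int0, right_cigar = chr0,
                       right_window_baseq = numeric(0)))
  as.data.frame(out, stringsAsFactors = FALSE)
}

## one locus: select -> features -> genotype -> rows
.processLocus <- function(bam, m, reference, cfg, k, policy, minBaseq,
                          scanMargin, verbose) {
  pad <- cfg$windowBp + as.integer(scanMargin) + 1000L + k
  ctx <- .prefetchReference(reference, m@chrom,
                           m@pos - pad, m@pos + nchar(m@ref) - 1L + pad)
  w <- buildWindow(m, ctx)
  frags <- selectFragments(bam, m, cfg, scanMargin = scanMargin)
  mid <- mutationId(m)
  if (length(frags) == 0L) {
    warning("no fragments overlap ", mid, call. = FALSE)
    return(list(rows = NULL, vaf = locusVaf(character(0))))
  }
  n <- length(frags)
  featRows <- vector("list", n)
  statusV <- character(n); resolutionV <- character(n); flagsV <- character(n)
  if (verbose) {
    lFlag <- integer(n); lMapq <- integer(n); lCigar <- character(n)
    lBq <- numeric(n); rFlag <- integer(n); rMapq <- integer(n)
    rCigar <- character(n); rBq <- numeric(n)
  }
  for (i in seq_len(n)) {
    f <- frags[[i]]
    feat <- fragmentFeatures(f, ctx, k = k, policy = policy)
    callL <- genotypeRead(f@leftRead, m, w, ctx, minBaseq = minBaseq)
    r2 <- rightRead(f)
    callR <- if (is.null(r2)) NULL
             else genotypeRead(r2, m, w, ctx, minBaseq = minBaseq)
    fc <- genotypeFragment(callL, callR)
    featRows[[i]] <- feat
    statusV[i] <- fc$status
    resolutionV[i] <- fc$resolution
    flagsV[i] <- paste(sort(unique(c(feat$flags, fc$flags))),
                       collapse = ";")
    if (verbose) {
      lFlag[i] <- f@leftRead$flag; lMapq[i] <- f@leftRead$mapq
      lCigar[i] <- f@leftRead$cigar
      lBq[i] <- .meanWindowBaseq(f@leftRead, w)
      rFlag[i] <- if (is.null(r2)) NA_integer_ else r2$flag
      rMapq[i] <- if (is.null(r2)) NA_integer_ else r2$mapq
      rCigar[i] <- if (is.null(r2)) NA_character_ else r2$cigar
      rBq[i] <- .meanWindowBaseq(r2, w)
    }
  }
  fcol <- function(field, template)
    vapply(featRows, function(x)
      if (is.null(x[[field]]) || is.na(x[[field]])) template[NA_integer_]
      else x[[field]], template)
  rows <- data.frame(
    mutation_id = rep(mid, n),
    fragment_id = vapply(frags, fragmentId, character(1)),
    outer_start = fcol("outer_start", integer(1)),
    outer_end = fcol("outer_end", integer(1)),
    size_bp = fcol("size_bp", integer(1)),
    tlen_abs = fcol("tlen_abs", integer(1)),
    inner_distance_bp = fcol("inner_distance_bp", integer(1)),
    motif5 = fcol("motif5", character(1)),
    motif3 = fcol("motif3", character(1)),
    motif3_top_strand = fcol("motif3_top_strand", character(1)),
    softclip5_out = fcol("softclip5_out", integer(1)),
    softclip3_out = fcol("softclip3_out", integer(1)),
    softclip_inner = fcol("softclip_inner", integer(1)),
    n_insertions_bp = fcol("n_insertions_bp", integer(1)),
    n_deletions_bp = fcol("n_deletions_bp", integer(1)),
    status = statusV, resolution = resolutionV, flags = flagsV,
    stringsAsFactors = FALSE)
  if (verbose) {
    rows$left_flag <- lFlag; rows$left_mapq <- lMapq
    rows$left_cigar <- lCigar; rows$left_window_baseq <- lBq
    rows$right_flag <- rFlag; rows$right_mapq <- rMapq
    rows$right_cigar <- rCigar; rows$right_window_baseq <- rBq
  }
  ## deterministic within-locus order
  rows <- rows[order(rows$outer_start, rows$fragment_id), , drop = FALSE]
  list(rows = rows, vaf = locusVaf(rows$status))
}

#' Run the full fragmentomics workflow
#'
#' For each mutation: normalize it, select overlapping fragments from the
#' BAM, extract fragmentomic features, genotype reads and fragments, and
#' assemble one table row per (fragment x mutation). Per-locus VAF summaries
#' and a per-locus processing status are attached to the returned
#' \linkS4class{FragmentTable}. A failure at one locus is caught, recorded in
#' the status table, and does not stop other loci. Output ordering is
#' deterministic (mutation input order, then outer start, then fragment id)
#' and independent of \code{threads}.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param mutations a mutations file (VCF/TSV), character vector of
#'   \code{"chr:pos:ref:alt"} strings, or list of \linkS4class{Mutation}.
#' @param reference reference FASTA path or \linkS4class{ReferenceAccessor}.
#' @param windowBp recovery window half-width (default 600).
#' @param motifLength end-motif length k (default 5).
#' @param keepSoftclips count outer soft-clipped bases in the fragment size
#'   (default TRUE).
#' @param countNAsDeletion treat reference skips as deletions in the size
#'   (default TRUE).
#' @param minMapq minimum read mapping quality (default 0).
#' @param minBaseq minimum base quality inside the genotyping window
#'   (default 0 = off).
#' @param dropDuplicates exclude duplicate-flagged reads (default TRUE).
#' @param requireProperPair require the proper-pair flag (default FALSE).
#' @param threads number of worker processes for the per-locus loop
#'   (default 1); results are identical for any value.
#' @param verboseReads include per-read diagnostic columns (default FALSE).
#' @param coordinateBase coordinate convention of TSV/colon-string mutation
#'   input (default one-based).
#' @param formatHint optional mutation input format override.
#' @param scanMargin BAM scan margin beyond the window (default 5000 bp).
#' @return a \linkS4class{FragmentTable}.
#' @examples
#' \dontrun{
#' ft <- runFragtyper("sample.bam", "chr7:55242465:GGAATTAAGAGAAGC:-",
#'                    "genome.fa")
#' vafSummary(ft)
#' }
#' @importFrom parallel mclapply
#' @export
runFragtyper <- function(bam, mutations, reference, windowBp = 600L,
                         motifLength = 5L, keepSoftclips = TRUE,
                         countNAsDeletion = TRUE, minMapq = 0L,
                         minBaseq = 0L, dropDuplicates = TRUE,
                         requireProperPair = FALSE, threads = 1L,
                         verboseReads = FALSE,
                         coordinateBase = c("one_based", "zero_based"),
                         formatHint = NULL, scanMargin = 5000L) {
  coordinateBase <- match.arg(coordinateBase)
  if (length(mutations) == 0L) stop("no mutations provided")
  reference <- openReference(reference)
  ## parse up front (structural problems stop the run); resolve/normalize
  ## later, inside the per-locus error isolation
  pending <- if (is.list(mutations) && all(vapply(mutations, is, logical(1),
                                                  "Mutation"))) {
    mutations
  } else {
    parseVariants(mutations, formatHint, coordinateBase)
  }
  if (length(pending) == 0L) stop("no mutations provided")
  cfg <- selectionConfig(windowBp = windowBp, minMapq = minMapq,
                         dropDuplicates = dropDuplicates,
                         requireProperPair = requireProperPair)
  policy <- sizePolicy(keepOuterSoftclips = keepSoftclips,
                       countNAsDeletion = countNAsDeletion)
  k <- as.integer(motifLength)

  rawId <- function(x)
    if (is(x, "Mutation")) mutationId(x)
    else paste(x@chrom, x@pos, x@ref, x@alt, sep = ":")
  worker <- function(item) {
    tryCatch({
      m <- if (is(item, "Mutation")) {
        if (isNormalized(item)) item else normalizeMutation(item, reference)
      } else {
        normalizeMutation(resolveAlleles(item, reference), reference)
      }
      c(.processLocus(bam, m, reference, cfg, k, policy,
                      as.integer(minBaseq), scanMargin,
                      isTRUE(verboseReads)),
        list(error = NA_character_, mid = mutationId(m)))
    }, error = function(e)
      list(rows = NULL, vaf = locusVaf(character(0)),
           error = conditionMessage(e), mid = rawId(item)))
  }
  results <- if (threads > 1L) {
    parallel::mclapply(pending, worker, mc.cores = as.integer(threads),
                       mc.preschedule = TRUE)
  } else {
    lapply(pending, worker)
  }

  mids <- vapply(results, `[[`, character(1), "mid")
  rowList <- Filter(Negate(is.null), lapply(results, `[[`, "rows"))
  allRows <- if (length(rowList)) do.call(rbind, rowList)
             else .emptyLocusRow(isTRUE(verboseReads))
  vafDf <- S4Vectors::DataFrame(
    mutation_id = mids,
    n_mut = vapply(results, function(x) x$vaf$n_mut, integer(1)),
    n_wt = vapply(results, function(x) x$vaf$n_wt, integer(1)),
    n_oth = vapply(results, function(x) x$vaf$n_oth, integer(1)),
    n_ni = vapply(results, function(x) x$vaf$n_ni, integer(1)),
    vaf = vapply(results, function(x) x$vaf$vaf, numeric(1)))
  statusDf <- S4Vectors::DataFrame(
    mutation_id = mids,
    n_fragments = vapply(results, function(x)
      if (is.null(x$rows)) 0L else nrow(x$rows), integer(1)),
    status = vapply(results, function(x)
      if (is.na(x$error)) "ok" else x$error, character(1)))
  for (i in which(statusDf$status != "ok"))
    warning("locus ", mids[i], " failed: ", statusDf$status[i],
            call. = FALSE)
  new("FragmentTable", data = S4Vectors::DataFrame(allRows),
      vaf = vafDf, locusStatus = statusDf)
}

#' Write a fragment table to TSV
#'
#' Tab-separated, header row, UTF-8, newline-terminated; missing values are
#' written as \code{"NA"}. Round-trips losslessly through
#' \code{\link{readFragmentTable}}.
#'
#' @param t a \linkS4class{FragmentTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFragmentTable <- function(t, path) {
  stopifnot(is(t, "FragmentTable"))
  df <- as.data.frame(t@data)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a fragment table written by \code{\link{writeFragmentTable}}
#'
#' Per-locus VAF summaries are recomputed from the status column (they are a
#' pure function of it), so \code{read(write(t))} reproduces \code{t}.
#'
#' @param path TSV path.
#' @return a \linkS4class{FragmentTable}.
#' @export
readFragmentTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = NA, check.names = FALSE)
  if (!all(.TABLE_COLUMNS %in% names(df)))
    stop("not a fragment table: missing columns ",
         paste(setdiff(.TABLE_COLUMNS, names(df)), collapse = ", "))
  for (col in c("motif5", "motif3", "motif3_top_strand", "flags",
                "mutation_id", "fragment_id", "status", "resolution"))
    df[[col]] <- as.character(df[[col]])
  df$flags[is.na(df$flags)] <- ""
  mids <- unique(df$mutation_id)
  vafs <- lapply(mids, function(id) locusVaf(df$status[df$mutation_id == id]))
  vafDf <- S4Vectors::DataFrame(
    mutation_id = mids,
    n_mut = vapply(vafs, `[[`, integer(1), "n_mut"),
    n_wt = vapply(vafs, `[[`, integer(1), "n_wt"),
    n_oth = vapply(vafs, `[[`, integer(1), "n_oth"),
    n_ni = vapply(vafs, `[[`, integer(1), "n_ni"),
    vaf = vapply(vafs, `[[`, numeric(1), "vaf"))
  new("FragmentTable", data = S4Vectors::DataFrame(df), vaf = vafDf,
      locusStatus = S4Vectors::DataFrame(
        mutation_id = mids,
        n_fragments = vapply(mids, function(id)
          sum(df$mutation_id == id), integer(1)),
        status = rep("ok", length(mids))))
}
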