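## Visualization of fragment tables.
##
## Every plot function computes a plain numeric matrix first and builds the
## ggplot from it; the matrix is returned alongside the figure so tests (and
## users) work with the numbers, not pixels.

.plotTableDf <- function(t) {
  if (is(t, "FragmentTable")) as.data.frame(t@data)
  else as.data.frame(t)
}

.groupedTable <- function(t, groupBy, groups) {
  df <- .plotTableDf(t)
  if (!groupBy %in% names(df))
    stop("unknown grouping column '", groupBy, "' (columns: ",
         paste(names(df), collapse = ", "), ")")
  df$.group <- as.character(df[[groupBy]])
  if (!is.null(groups)) {
    missing <- setdiff(groups, unique(df$.group))
    if (length(missing))
      stop("requested group(s) not present: ",
           paste(missing, collapse = ", "))
    df <- df[df$.group %in% groups, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no fragments left after group filtering")
  df
}

#' Fragment-size distribution plot
#'
#' Per-group size profiles as density curves or histograms. The returned
#' matrix holds, for every observed integer size (rows) and group (columns),
#' the fragment count.
#'
#' @param t a \linkS4class{FragmentTable} or data.frame.
#' @param groupBy grouping column (default \code{"status"}).
#' @param groups optional subset of groups to show.
#' @param style \code{"density"} or \code{"histogram"}.
#' @param binwidth histogram bin width in bp (default 5).
#' @return list with \code{plot} (ggplot) and \code{matrix} (size x group
#'   counts).
#' @import ggplot2
#' @export
plotSizeDistribution <- function(t, groupBy = "status", groups = NULL,
                                 style = c("density", "histogram"),
                                 binwidth = 5) {
  style <- match.arg(style)
  df <- .groupedTable(t, groupBy, groups)
  df <- df[!is.na(df$size_bp), , drop = FALSE]
  if (nrow(df) == 0L) stop("no fragments with a defined size")
  mat <- as.matrix(unclass(table(size_bp = df$size_bp, group = df$.group)))
  p <- ggplot(df, aes(x = .data$size_bp, colour = .data$.group,
                      fill = .data$.group)) +
    labs(x = "fragment size (bp)", colour = groupBy, fill = groupBy) +
    theme_minimal()
  p <- if (style == "density")
    p + geom_density(alpha = 0.2) + labs(y = "density")
  else
    p + geom_histogram(binwidth = binwidth, alpha = 0.5,
                       position = "identity") + labs(y = "fragments")
  list(plot = p, matrix = mat)
}

#' End-motif bar plot
#'
#' Motif frequencies per group under three modes: \code{"proportion"}
#' (within-group motif proportions), \code{"count"} (raw counts) and
#' \code{"difference"} (proportion difference between exactly two groups).
#' The returned matrix is motifs x groups (one difference column for
#' \code{"difference"}).
#'
#' @param t a \linkS4class{FragmentTable} or data.frame.
#' @param end \code{"motif5"} or \code{"motif3"}.
#' @param groupBy grouping column (default \code{"status"}).
#' @param groups optional subset of groups.
#' @param mode \code{"proportion"}, \code{"count"} or \code{"difference"}.
#' @return list with \code{plot} and \code{matrix}.
#' @export
plotMotifBarplot <- function(t, end = c("motif5", "motif3"),
                             groupBy = "status", groups = NULL,
                             mode = c("proportion", "count", "difference")) {
  end <- match.arg(end); mode <- match.arg(mode)
  df <- .groupedTable(t, groupBy, groups)
  df <- df[!is.na(df[[end]]), , drop = FALSE]
  if (nrow(df) == 0L) stop("no fragments with a defined ", end)
  counts <- as.matrix(unclass(table(motif = df[[end]], group = df$.group)))
  mat <- switch(mode,
    count = counts,
    proportion = sweep(counts, 2L, pmax(colSums(counts), 1L), "/"),
    difference = {
      if (ncol(counts) != 2L)
        stop("mode 'difference' needs exactly two groups, got ",
             ncol(counts))
      prop <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
      diffMat <- matrix(prop[, 1L] - prop[, 2L], ncol = 1L,
                        dimnames = list(rownames(prop),
                                        paste(colnames(prop)[1L], "-",
                                              colnames(prop)[2L])))
      diffMat
    })
  long <- data.frame(motif = rep(rownames(mat), ncol(mat)),
                     group = rep(colnames(mat), each = nrow(mat)),
                     value = as.vector(mat), stringsAsFactors = FALSE)
  p <- ggplot(long, aes(x = .data$motif, y = .data$value,
                        fill = .data$group)) +
    geom_col(position = "dodge") +
    labs(x = paste(end, "motif"), y = mode, fill = groupBy) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
  list(plot = p, matrix = mat)
}

#' End nucleotide-composition bar plot
#'
#' Base composition at fragment ends pooled over all motif positions, per
#' group. The returned matrix is bases x groups with columns summing to 1.
#'
#' @inheritParams plotMotifBarplot
#' @return list with \code{plot} and \code{matrix}.
#' @export
plotFreqBarplot <- function(t, end = c("motif5", "motif3"),
                            groupBy = "status", groups = NULL) {
  end <- match.arg(end)
  df <- .groupedTable(t, groupBy, groups)
  df <- df[!is.na(df[[end]]), , drop = FALSE]
  if (nrow(df) == 0L) stop("no fragments with a defined ", end)
  grps <- sort(unique(df$.group))
  bases <- c("A", "C", "G", "T", "N")
  mat <- sapply(grps, function(g) {
    chars <- unlist(strsplit(df[[end]][df$.group == g], "", fixed = TRUE))
    cnt <- table(factor(chars, levels = bases))
    as.numeric(cnt) / max(sum(cnt), 1L)
  })
  mat <- matrix(mat, nrow = length(bases),
                dimnames = list(bases, grps))
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  long <- data.frame(base = rep(rownames(mat), ncol(mat)),
                     group = rep(colnames(mat), each = nrow(mat)),
                     value = as.vector(mat), stringsAsFactors = FALSE)
  p <- ggplot(long, aes(x = .data$base, y = .data$value,
                        fill = .data$group)) +
    geom_col(position = "dodge") +
    labs(x = paste("base at", end), y = "proportion", fill = groupBy) +
    theme_minimal()
  list(plot = p, matrix = mat)
}

#' Sequence-logo plot of end motifs
#'
#' Per-position nucleotide proportions of the selected end motifs, rendered
#' as a stacked letter logo (letter height proportional to frequency). The
#' returned matrix is positions x bases; each row sums to 1.
#'
#' @param t a \linkS4class{FragmentTable} or data.frame.
#' @param end \code{"motif5"} or \code{"motif3"}.
#' @param groupBy,groups optional filter: keep fragments whose
#'   \code{groupBy} value is in \code{groups} before tallying.
#' @return list with \code{plot} and \code{matrix}.
#' @export
plotSeqLogo <- function(t, end = c("motif5", "motif3"),
                        groupBy = "status", groups = NULL) {
  end <- match.arg(end)
  df <- .groupedTable(t, groupBy, groups)
  motifs <- df[[end]][!is.na(df[[end]])]
  if (!length(motifs)) stop("no fragments with a defined ", end)
  k <- unique(nchar(motifs))
  if (length(k) != 1L)
    stop("motifs of unequal length; cannot build a logo")
  bases <- c("A", "C", "G", "T", "N")
  chars <- matrix(unlist(strsplit(motifs, "", fixed = TRUE)),
                  ncol = k, byrow = TRUE)
  mat <- t(apply(chars, 2L, function(col)
    as.numeric(table(factor(col, levels = bases))) / length(col)))
  colnames(mat) <- bases
  rownames(mat) <- as.character(seq_len(k))
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  long <- data.frame(
    position = rep(seq_len(k), ncol(mat)),
    base = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat), stringsAsFactors = FALSE)
  long <- long[long$value > 0, , drop = FALSE]
  long <- long[order(long$position, long$value), , drop = FALSE]
  long$ymax <- stats::ave(long$value, long$position, FUN = cumsum)
  long$ymin <- long$ymax - long$value
  long$ymid <- (long$ymin + long$ymax) / 2
  baseCols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839",
                N = "#808080")
  p <- ggplot(long) +
    geom_rect(aes(xmin = .data$position - 0.45,
                  xmax = .data$position + 0.45,
                  ymin = .data$ymin, ymax = .data$ymax,
                  fill = .data$base), alpha = 0.15) +
    geom_text(aes(x = .data$position, y = .data$ymid, label = .data$base,
                  colour = .data$base, size = .data$value),
              fontface = "bold", show.legend = FALSE) +
    scale_colour_manual(values = baseCols) +
    scale_fill_manual(values = baseCols) +
    scale_size_continuous(range = c(2, 10)) +
    scale_x_continuous(breaks = seq_len(k)) +
    labs(x = "motif position", y = "proportion", fill = "base") +
    theme_minimal()
  list(plot = p, matrix = mat)
}
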