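#' Build and validate a genetic map table
#'
#' A genetic map is a tibble with columns `marker`, `chrom` and `pos`
#' (centimorgan position), ordered by chromosome and position.  Positions
#' within a linkage group must be non-decreasing; with `normalize = TRUE`
#' each group is shifted so its first marker sits at 0 cM.
#'
#' @param x a data frame with columns `marker`, `chrom`, `pos` (further
#'   columns are preserved).
#' @param normalize shift each linkage group to start at 0 cM?
#' @return a tibble of class `genetic_map`.
#' @export
genetic_map <- function(x, normalize = TRUE) {
  x <- tibble::as_tibble(x)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(x)))
    abort("a genetic map needs columns `marker`, `chrom`, `pos`")
  if (anyDuplicated(x$marker)) abort("duplicate marker names in map")
  if (any(!is.finite(x$pos)) || any(x$pos < 0))
    abort("map positions must be finite and non-negative")
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  if (normalize)
    x <- dplyr::mutate(x, pos = .data$pos - min(.data$pos),
                       .by = "chrom")
  class(x) <- c("genetic_map", class(x))
  x
}

#' Read or write a genetic map TSV
#'
#' The file format is three tab-separated columns: marker, chromosome and
#' position (cM for genetic maps, bp for physical maps); a header row is
#' expected.  Column names in the file are not significant, only their
#' order.
#'
#' @param path file path.
#' @param physical read positions as base pairs (returns a plain tibble
#'   with column `bp` instead of a normalized `genetic_map`)?
#' @return a `genetic_map` tibble (or a `marker`/`chrom`/`bp` tibble).
#' @export
read_genetic_map <- function(path, physical = FALSE) {
  tab <- readr::read_tsv(path, col_types = "ccd", col_names = TRUE,
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 3) abort("map file needs 3 columns: marker, chrom, pos")
  names(tab)[1:3] <- c("marker", "chrom", if (physical) "bp" else "pos")
  if (physical) {
    if (any(tab$bp <= 0 | tab$bp != round(tab$bp)))
      abort("physical positions must be positive integers")
    return(tab)
  }
  genetic_map(tab)
}

#' @rdname read_genetic_map
#' @param map a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  map <- genetic_map(map)           # re-validate and normalize on write
  readr::write_tsv(map, path)
  invisible(path)
}

#' Map summary statistics
#'
#' Summarises a genetic map per linkage group and over the whole map:
#' length (cM), marker count, bin count (a bin is a maximal set of markers
#' at an identical cM position), mean and maximum adjacent-bin distance,
#' and the number of gaps between adjacent bins exceeding `gap_threshold`.
#' The overall row (`chrom = "all"`) sums lengths, markers, bins and gaps;
#' its mean bin distance is total length over total within-group bin
#' steps.
#'
#' @param map a `genetic_map` (or data frame with `marker`/`chrom`/`pos`).
#' @param gap_threshold gap size in cM counted as a gap (default 15).
#' @param tol positions closer than this are one bin (default 1e-8).
#' @return a tibble with one row per group plus an `"all"` row.
#' @export
map_summary <- function(map, gap_threshold = 15, tol = 1e-8) {
  map <- genetic_map(map, normalize = FALSE)
  per <- dplyr::summarise(
    map,
    length = max(.data$pos) - min(.data$pos),
    n_markers = dplyr::n(),
    n_bins = {
      p <- sort(.data$pos)
      if (length(p) == 1) 1L else sum(diff(p) > tol) + 1L
    },
    mean_bin_dist = ifelse(.data$n_bins > 1,
                           .data$length / (.data$n_bins - 1), NA_real_),
    max_bin_dist = {
      b <- unique_bins(sort(.data$pos), tol)
      if (length(b) > 1) max(diff(b)) else NA_real_
    },
    n_gaps = {
      b <- unique_bins(sort(.data$pos), tol)
      sum(diff(b) > gap_threshold)
    },
    .by = "chrom"
  )
  all_row <- tibble::tibble(
    chrom = "all",
    length = sum(per$length),
    n_markers = sum(per$n_markers),
    n_bins = sum(per$n_bins),
    mean_bin_dist = sum(per$length) / sum(pmax(per$n_bins - 1L, 0L)),
    max_bin_dist = suppressWarnings(max(per$max_bin_dist, na.rm = TRUE)),
    n_gaps = sum(per$n_gaps)
  )
  dplyr::bind_rows(per, all_row)
}

unique_bins <- function(pos_sorted, tol = 1e-8) {
  if (length(pos_sorted) == 0) return(numeric(0))
  pos_sorted[c(TRUE, diff(pos_sorted) > tol)]
}

#' Spearman collinearity between two marker orders
#'
#' Measures the agreement of marker order between two maps by the Spearman
#' rank correlation over their common markers (ties receive mid-ranks).
#' Inputs may be character vectors of markers in map order, or data frames
#' with `marker` and `pos` columns (tied positions then tie the ranks).
#'
#' @param order_a,order_b marker orders (character vectors or
#'   `marker`/`pos` data frames).
#' @return Spearman correlation in \[-1, 1\].
#' @export
spearman_collinearity <- function(order_a, order_b) {
  ra <- order_ranks(order_a)
  rb <- order_ranks(order_b)
  common <- intersect(names(ra), names(rb))
  if (length(common) < 3)
    abort("need at least 3 common markers for collinearity")
  cor(rank(ra[common], ties.method = "average"),
      rank(rb[common], ties.method = "average"),
      method = "spearman")
}

order_ranks <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("marker", "pos") %in% names(x)) &&
        all(c("marker", "bp") %in% names(x)))
      x$pos <- x$bp
    if (anyDuplicated(x$marker)) abort("duplicate markers in order")
    setNames(x$pos, x$marker)
  } else {
    x <- as.character(x)
    if (anyDuplicated(x)) abort("duplicate markers in order")
    setNames(seq_along(x), x)
  }
}

#' Proportion of markers in a consistent order between two maps
#'
#' The fraction of common markers that can be arranged in the same order
#' on both maps, computed as the length of the longest subsequence of the
#' genetic order that is monotone in the other map's position, divided by
#' the number of common markers.  Because map orientation is arbitrary,
#' both orientations are tried and the larger value returned.
#'
#' @param genetic_order,physical_order marker orders as for
#'   [spearman_collinearity()].
#' @return fraction in \[0, 1\].
#' @export
consistent_order_proportion <- function(genetic_order, physical_order) {
  rg <- order_ranks(genetic_order)
  rp <- order_ranks(physical_order)
  common <- intersect(names(rg), names(rp))
  if (length(common) == 0) abort("no common markers")
  g <- common[order(rg[common])]        # common markers in genetic order
  v <- unname(rp[g])                    # their physical positions
  max(lis_length(v), lis_length(rev(v))) / length(v)
}

# longest strictly increasing subsequence via patience sorting:
# tails[k] = smallest possible tail of an increasing subsequence of length k
lis_length <- function(v) {
  tails <- numeric(0)
  for (x in v) {
    j <- sum(tails < x)                 # first tail >= x gets replaced
    tails[j + 1] <- x
  }
  length(tails)
}
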