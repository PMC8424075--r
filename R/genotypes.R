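#' Construct a genotype matrix for one biparental population
#'
#' A `geno_matrix` is an integer matrix of lines x markers holding the two
#' homozygous genotype classes of a RIL or DH population: `0` for the
#' parent-1 homozygote, `1` for the parent-2 homozygote, `NA` for missing
#' (which includes residual heterozygotes in selfed RILs).
#'
#' @param codes matrix (lines x markers) with values 0, 1 or `NA`;
#'   dimnames give line and marker names.
#' @param pop_type `"ril"` (recombinant inbred lines by repeated selfing)
#'   or `"dh"` (doubled haploids).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(codes, pop_type = c("ril", "dh")) {
  pop_type <- match.arg(pop_type)
  if (!is.matrix(codes)) abort("`codes` must be a matrix")
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% c(0L, 1L))
  if (any(bad)) abort("genotype codes must be 0, 1 or NA")
  if (is.null(colnames(codes)) && ncol(codes) > 0)
    colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  if (is.null(rownames(codes)) && nrow(codes) > 0)
    rownames(codes) <- paste0("L", seq_len(nrow(codes)))
  if (anyDuplicated(colnames(codes)))
    abort("duplicate marker names in genotype matrix")
  if (anyDuplicated(rownames(codes)))
    abort("duplicate line names in genotype matrix")
  structure(codes, pop_type = pop_type, class = c("geno_matrix", "matrix"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d lines x %d markers (%s), %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "pop_type"),
              100 * mean(is.na(x))))
  invisible(x)
}

pop_type <- function(geno) attr(geno, "pop_type") %||% "ril"

#' Read a genotype table
#'
#' Reads a delimited text file whose header row holds marker names and whose
#' first column holds line identifiers; the remaining cells are allele
#' symbols.  The default alphabet is `A` (parent-1 homozygote), `B`
#' (parent-2 homozygote), `H` (heterozygote) and `-` (missing).
#' Heterozygous calls cannot be represented in a homozygous-line matrix;
#' with `het_to_missing = TRUE` (the default, and the standard treatment
#' for selfed RIL data) they are recoded as missing, otherwise their
#' presence is an error.
#'
#' @param path file path to a TSV (or CSV, see `delim`) genotype table.
#' @param delim field delimiter; guessed from the file extension by default.
#' @param alleles named character vector with entries `a`, `b`, `het`,
#'   `missing` giving the four symbols.
#' @param het_to_missing recode heterozygous calls as missing?
#' @param pop_type population type passed to [geno_matrix()].
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path,
                           delim = NULL,
                           alleles = c(a = "A", b = "B", het = "H",
                                       missing = "-"),
                           het_to_missing = TRUE,
                           pop_type = c("ril", "dh")) {
  pop_type <- match.arg(pop_type)
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE, name_repair = "minimal")
  if (nrow(readr::problems(tab)) > 0)
    abort("malformed genotype file (ragged rows or parse failures)")
  if (nrow(tab) == 0 || ncol(tab) < 2)
    abort("empty genotype file")
  markers <- names(tab)[-1]
  if (anyDuplicated(markers))
    abort("duplicate marker columns in genotype file")
  lines <- tab[[1]]
  if (anyDuplicated(lines)) abort("duplicate line identifiers")
  raw <- as.matrix(tab[, -1, drop = FALSE])
  known <- raw %in% alleles | is.na(raw)
  if (!all(known))
    abort(sprintf("unknown allele symbol(s): %s",
                  paste(unique(raw[!known]), collapse = ", ")))
  if (any(raw == alleles[["het"]], na.rm = TRUE) && !het_to_missing)
    abort("heterozygous calls present but `het_to_missing = FALSE`")
  codes <- matrix(NA_integer_, nrow(raw), ncol(raw),
                  dimnames = list(lines, markers))
  codes[raw == alleles[["a"]]] <- 0L
  codes[raw == alleles[["b"]]] <- 1L
  geno_matrix(codes, pop_type = pop_type)
}

#' Marker quality control
#'
#' Removes markers failing the two standard biparental-population filters,
#' in order: (1) missing-data fraction strictly greater than `max_missing`;
#' (2) minor-allele frequency, computed over non-missing calls, strictly
#' lower than `min_maf`.  Markers sitting exactly at a threshold are
#' retained.  The removal report is attached as the `"removed"` attribute
#' (a tibble with one row per removed marker, its reason and statistic)
#' and can be retrieved with [qc_removed()].
#'
#' @param geno a [geno_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf minimum tolerated minor-allele frequency (default 0.30).
#' @return the filtered [geno_matrix()] with a `"removed"` attribute.
#' @export
qc_filter_markers <- function(geno, max_missing = 0.10, min_maf = 0.30) {
  stopifnot(inherits(geno, "geno_matrix"))
  miss <- colMeans(is.na(geno))
  drop_miss <- miss > max_missing
  f1 <- colMeans(geno == 1L, na.rm = TRUE)
  maf <- pmin(f1, 1 - f1)
  drop_maf <- !drop_miss & !is.na(maf) & maf < min_maf
  removed <- dplyr::bind_rows(
    tibble::tibble(marker = colnames(geno)[drop_miss],
                   reason = "missing",
                   statistic = unname(miss[drop_miss])),
    tibble::tibble(marker = colnames(geno)[drop_maf],
                   reason = "maf",
                   statistic = unname(maf[drop_maf]))
  )
  keep <- !(drop_miss | drop_maf)
  if (!any(keep))
    warn("no markers left after quality control",
         class = "clamap_empty_after_qc")
  out <- geno_matrix(geno[, keep, drop = FALSE], pop_type = pop_type(geno))
  attr(out, "removed") <- removed
  out
}

#' @rdname qc_filter_markers
#' @export
qc_removed <- function(geno) {
  attr(geno, "removed") %||%
    tibble::tibble(marker = character(), reason = character(),
                   statistic = double())
}
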