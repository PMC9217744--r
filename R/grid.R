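#' Fixed-width genomic bin grid
#'
#' A `bin_grid` records ordered chromosome names, their lengths in bp, and a
#' single bin width. All coordinates in the package are 0-based, half-open;
#' bins are indexed from 0 within each chromosome. The bin count per
#' chromosome is `ceiling(length / bin_width)`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param bin_width Bin width in bp (default 50 kb, the working resolution of
#'   16-fraction Repli-seq and the Hi-C analyses here).
#' @param autosome Logical vector (recycled) marking chromosomes that behave
#'   like autosomes; enrichment testing restricts to these. Default all TRUE.
#' @return A `bin_grid` object: a tibble with columns `chrom`, `length`,
#'   `n_bins`, `autosome`, plus a `bin_width` attribute.
#' @examples
#' g <- bin_grid(c(chrS = 10e6))
#' n_bins(g, "chrS")
#' @export
bin_grid <- function(chrom_lengths, bin_width = 50000, autosome = TRUE) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector")
  }
  if (length(bin_width) != 1 || bin_width <= 0) {
    stop("bin_width must be a single positive number")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  g <- tibble::tibble(
    chrom = names(chrom_lengths),
    length = as.numeric(chrom_lengths),
    n_bins = as.integer(ceiling(chrom_lengths / bin_width)),
    autosome = rep_len(as.logical(autosome), length(chrom_lengths))
  )
  attr(g, "bin_width") <- as.numeric(bin_width)
  class(g) <- c("bin_grid", class(g))
  g
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", nrow(x), " chromosome(s), bin width ",
      format(attr(x, "bin_width"), big.mark = ","), " bp\n", sep = "")
  NextMethod()
}

#' Bin width of a grid
#' @param grid A `bin_grid`.
#' @return Bin width in bp.
#' @export
bin_width <- function(grid) attr(grid, "bin_width")

#' Number of bins on a chromosome
#' @param grid A `bin_grid`.
#' @param chrom Chromosome name.
#' @return Integer bin count.
#' @export
n_bins <- function(grid, chrom) {
  i <- match(chrom, grid$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  grid$n_bins[i]
}

#' Map bp positions to bin indices and back
#'
#' `pos_to_bin()` maps a bp coordinate to its 0-based bin;
#' `bin_to_start()` returns the bp start of a bin. On bin-aligned intervals
#' the two maps are mutual inverses.
#'
#' @param pos bp coordinate(s).
#' @param bin 0-based bin index(es).
#' @param grid A `bin_grid`.
#' @return Integer bins / numeric bp starts.
#' @export
pos_to_bin <- function(pos, grid) as.integer(pos %/% bin_width(grid))

#' @rdname pos_to_bin
#' @export
bin_to_start <- function(bin, grid) as.numeric(bin) * bin_width(grid)

validate_chroms <- function(chrom, grid) {
  bad <- setdiff(unique(chrom), grid$chrom)
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Symmetric per-chromosome contact matrix
#'
#' Wraps a dense, square, symmetric, non-negative matrix of (balanced or raw)
#' Hi-C contact values for one chromosome on a [bin_grid()].
#'
#' @param mat Square numeric matrix (bins x bins).
#' @param chrom Chromosome name.
#' @param grid A `bin_grid`; `nrow(mat)` must equal the chromosome's bin count.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(mat, chrom, grid) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  validate_chroms(chrom, grid)
  if (nrow(mat) != n_bins(grid, chrom)) {
    stop("matrix has ", nrow(mat), " bins but ", chrom, " has ",
         n_bins(grid, chrom), " on this grid")
  }
  if (any(mat < 0)) stop("contact matrix has negative entries")
  rel <- max(abs(mat - t(mat))) / max(1, max(abs(mat)))
  if (rel > 1e-9) stop("contact matrix is not symmetric (relative deviation ",
                       signif(rel, 3), ")")
  structure(
    list(chrom = chrom, mat = mat, bin_width = bin_width(grid), grid = grid),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$chrom, ": ", nrow(x$mat), " x ", nrow(x$mat),
      " bins @ ", format(x$bin_width, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$mat)
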