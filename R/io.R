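#' Read genomic intervals from BED / narrowPeak text
#'
#' Tab-separated, no header; `browser` and `track` lines are skipped.
#' Malformed rows are rejected with the offending line number, never coerced.
#'
#' @param path File path.
#' @param format `"bed"` (3+ columns) or `"narrowPeak"` (10 columns).
#' @param grid Optional [bin_grid()]; when supplied, chromosome names and
#'   interval bounds are validated against it.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (strand is `"."` when absent from the file).
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak"), grid = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^(browser|track)\\b", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), name = character(),
                          score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < min_cols)) {
    bad <- lineno[which(nf < min_cols)[1]]
    stop("line ", bad, ": expected >= ", min_cols, " tab-separated columns")
  }
  get_col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, "")
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop("line ", bad, ": non-numeric start/end")
  }
  if (any(start >= end)) {
    bad <- lineno[which(start >= end)[1]]
    stop("line ", bad, ": start >= end")
  }
  if (any(start < 0)) {
    bad <- lineno[which(start < 0)[1]]
    stop("line ", bad, ": negative start")
  }
  name <- get_col(4)
  score <- suppressWarnings(as.numeric(get_col(5)))
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  if (!is.null(grid)) {
    validate_chroms(chrom, grid)
    len <- grid$length[match(chrom, grid$chrom)]
    if (any(end > len)) {
      bad <- lineno[which(end > len)[1]]
      stop("line ", bad, ": interval end exceeds chromosome length")
    }
  }
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = name, score = score, strand = strand)
}

#' Write intervals as BED6
#'
#' @param x Tibble with at least `chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` columns are written into BED columns 4-6.
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  n <- nrow(x)
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else rep(".", n)
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else rep(0, n)
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", n)
  df <- data.frame(x$chrom, format_bp(x$start), format_bp(x$end),
                   name, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a contact matrix from sparse-triplet or dense text
#'
#' Sparse triplet lines are `bin1 bin2 value` with `bin1 <= bin2` (0-based);
#' the matrix is symmetrized on read and missing pixels are zero. Duplicate
#' triplets are rejected as an ambiguous dialect. `#`-prefixed header lines
#' are ignored. An empty file yields the all-zero matrix.
#'
#' @param path File path.
#' @param grid A [bin_grid()] providing the bin count.
#' @param chrom Chromosome the matrix belongs to.
#' @param format `"triplet"` (default) or `"dense"`.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, grid, chrom, format = c("triplet", "dense")) {
  format <- match.arg(format)
  nb <- n_bins(grid, chrom)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(text = lines))
    dimnames(mat) <- NULL
    return(contact_matrix(mat, chrom, grid))
  }
  mat <- matrix(0, nb, nb)
  if (length(lines)) {
    tr <- utils::read.table(text = lines, col.names = c("bin1", "bin2", "value"))
    if (any(tr$bin1 > tr$bin2)) stop("triplet with bin1 > bin2")
    if (any(tr$bin1 < 0) || any(tr$bin2 >= nb)) {
      stop("bin index out of range for ", chrom, " (", nb, " bins)")
    }
    key <- paste(tr$bin1, tr$bin2)
    if (anyDuplicated(key)) {
      stop("duplicate triplet for pixel (", tr$bin1[which(duplicated(key))[1]],
           ", ", tr$bin2[which(duplicated(key))[1]], ")")
    }
    mat[cbind(tr$bin1 + 1L, tr$bin2 + 1L)] <- tr$value
    mat[cbind(tr$bin2 + 1L, tr$bin1 + 1L)] <- tr$value
  }
  contact_matrix(mat, chrom, grid)
}

#' Write a contact matrix as sparse upper-triangle triplets
#'
#' Writes `#chrom`, `#bin_width` and `#n_bins` header lines followed by
#' non-zero `bin1 bin2 value` triplets with `bin1 <= bin2`.
#'
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @export
write_contact_matrix <- function(cm, path) {
  idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#chrom=", cm$chrom),
               paste0("#bin_width=", format_bp(cm$bin_width)),
               paste0("#n_bins=", nrow(cm$mat))), con)
  if (nrow(idx)) {
    o <- order(idx[, 1], idx[, 2])
    writeLines(paste(idx[o, 1] - 1L, idx[o, 2] - 1L,
                     format(cm$mat[idx[o, , drop = FALSE]], trim = TRUE)), con)
  }
  invisible(path)
}

#' Read / write 16-fraction Repli-seq tables
#'
#' Wide tab-separated layout: `chrom`, `start`, `end`, then 16 value columns
#' ordered earliest-to-latest S phase. A `#fractions=S1..S16` sidecar header
#' line declares the convention. Rows are canonicalized to (chromosome order,
#' start) on read; a file without exactly 16 value columns is rejected.
#'
#' @param path File path.
#' @param grid Optional [bin_grid()] to validate bins against.
#' @return A [repliseq16()] in `raw` state.
#' @export
read_repliseq <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Repli-seq file")
  tab <- utils::read.table(text = lines, sep = "\t")
  nfrac <- ncol(tab) - 3L
  if (nfrac != 16L) {
    stop("expected 16 fractions, found ", nfrac)
  }
  bins <- tibble::tibble(chrom = as.character(tab[[1]]),
                         start = as.numeric(tab[[2]]),
                         end = as.numeric(tab[[3]]))
  sig <- as.matrix(tab[, 4:19])
  chrom_order <- if (!is.null(grid)) grid$chrom else unique(bins$chrom)
  o <- order(match(bins$chrom, chrom_order), bins$start)
  repliseq16(bins[o, ], sig[o, , drop = FALSE], state = "raw", grid = grid)
}

#' @rdname read_repliseq
#' @param rs A [repliseq16()].
#' @export
write_repliseq <- function(rs, path) {
  sig <- rs_signal(rs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#fractions=S1..S16", con)
  df <- data.frame(rs$chrom, format_bp(rs$start), format_bp(rs$end),
                   format(sig, trim = TRUE, digits = 15))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write loop (dot) calls as 10-column BEDPE
#'
#' Anchors are normalized so anchor 1 is the upstream anchor
#' (`start1 <= start2`) on both read and write. Only cis (same-chromosome)
#' records are accepted. An empty file yields an empty tibble.
#'
#' @param path File path.
#' @return Tibble with `chrom1,start1,end1,chrom2,start2,end2,name,score,strand1,strand2`.
#' @export
read_bedpe <- function(path) {
  empty <- tibble::tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                          chrom2 = character(), start2 = numeric(), end2 = numeric(),
                          name = character(), score = numeric(),
                          strand1 = character(), strand2 = character())
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|browser|track)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  ncols <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  tab <- utils::read.table(text = lines, sep = "\t",
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "numeric",
                                          "character", "numeric",
                                          "character", "character")[seq_len(min(ncols, 10L))])
  if (ncol(tab) < 6) stop("BEDPE needs >= 6 columns")
  if (any(tab[[1]] != tab[[4]])) stop("trans-chromosomal BEDPE record in cis-only mode")
  defaults <- list(NULL, NULL, NULL, NULL, NULL, NULL, ".", 0, ".", ".")
  if (ncol(tab) < 10) {
    for (k in (ncol(tab) + 1L):10L) tab[[k]] <- defaults[[k]]
  }
  flip <- tab[[2]] > tab[[5]]
  out <- tibble::tibble(
    chrom1 = tab[[1]],
    start1 = ifelse(flip, tab[[5]], tab[[2]]),
    end1 = ifelse(flip, tab[[6]], tab[[3]]),
    chrom2 = tab[[4]],
    start2 = ifelse(flip, tab[[2]], tab[[5]]),
    end2 = ifelse(flip, tab[[3]], tab[[6]]),
    name = as.character(tab[[7]]), score = as.numeric(tab[[8]]),
    strand1 = as.character(tab[[9]]), strand2 = as.character(tab[[10]])
  )
  out
}

#' @rdname read_bedpe
#' @param dots Tibble in the layout returned by [read_bedpe()].
#' @export
write_bedpe <- function(dots, path) {
  if (nrow(dots) && any(dots$chrom1 != dots$chrom2)) {
    stop("trans-chromosomal record in cis-only mode")
  }
  flip <- dots$start1 > dots$start2
  s1 <- ifelse(flip, dots$start2, dots$start1)
  e1 <- ifelse(flip, dots$end2, dots$end1)
  s2 <- ifelse(flip, dots$start1, dots$start2)
  e2 <- ifelse(flip, dots$end1, dots$end2)
  df <- data.frame(dots$chrom1, format_bp(s1), format_bp(e1),
                   dots$chrom2, format_bp(s2), format_bp(e2),
                   dots$name, dots$score, dots$strand1, dots$strand2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-bin A/B compartment labels from 4-column BED
#'
#' Column 4 must be `A` or `B`; intervals are expanded to bins on the grid.
#'
#' @param path File path.
#' @param grid A [bin_grid()].
#' @return Tibble with `chrom`, `bin`, `label`.
#' @export
read_compartments <- function(path, grid) {
  iv <- read_intervals(path, grid = grid)
  if (nrow(iv) && !all(iv$name %in% c("A", "B"))) {
    stop("compartment label column must be 'A' or 'B'")
  }
  purrr::pmap_dfr(iv, function(chrom, start, end, name, ...) {
    b0 <- pos_to_bin(start, grid)
    b1 <- pos_to_bin(end - 1, grid)
    tibble::tibble(chrom = chrom, bin = b0:b1, label = name)
  })
}

#' Read / write 4-column bedGraph tracks
#'
#' `chrom start end value`, tab-separated; `track`/`#` lines skipped on
#' read. Used for per-bin scalar tracks such as the two-fraction
#' log2(early/late) ratio.
#'
#' @param path File path.
#' @param grid Optional [bin_grid()] for validation.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, grid = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|browser|track)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric()))
  }
  tab <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("chrom", "start", "end", "value"))
  if (any(tab$start >= tab$end)) {
    stop("line ", which(tab$start >= tab$end)[1], ": start >= end")
  }
  if (!is.null(grid)) validate_chroms(tab$chrom, grid)
  tibble::as_tibble(tab)
}

#' @rdname read_bedgraph
#' @param track Tibble with `chrom`, `start`, `end` and one value column
#'   (the last column is written).
#' @export
write_bedgraph <- function(track, path) {
  val <- track[[ncol(track)]]
  df <- data.frame(track$chrom, format_bp(track$start),
                   format_bp(track$end), format(val, trim = TRUE, digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
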