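#' Assign CTCF/cohesin sites to boundaries
#'
#' A site belongs to a boundary when its position falls within the window
#' `[bin - win_bins, bin + win_bins + 1)` bins around the boundary. Each
#' site is assigned to at most one boundary — the one with the nearest bin
#' midpoint, ties to the leftmost boundary — so site counts partition the
#' site set. Per-boundary counts of CTCF+cohesin and cohesin-only sites are
#' recorded separately, and the genomically ordered strand vector of
#' assigned CTCF+cohesin sites is kept for orientation classification.
#'
#' @param boundaries Boundary tibble (`chrom`, `bin`).
#' @param sites Site tibble (`chrom`, `pos`, `strand`, `cobound` in
#'   `ctcf_cohesin` / `cohesin_only`).
#' @param bin_width Bin width in bp.
#' @param win_bins Assignment window half-width in bins (default 1,
#'   +/-50 kb at 50-kb bins: one bin of boundary-position uncertainty).
#' @return `boundaries` with `n_ctcf_cohesin`, `n_cohesin_only` and a
#'   `site_strands` list-column (ordered strands of stranded CTCF+cohesin
#'   sites).
#' @export
assign_sites_to_boundaries <- function(boundaries, sites, bin_width,
                                       win_bins = 1) {
  nb <- nrow(boundaries)
  boundaries$n_ctcf_cohesin <- 0L
  boundaries$n_cohesin_only <- 0L
  boundaries$site_strands <- rep(list(character(0)), nb)
  if (!nrow(sites)) return(boundaries)
  assigned_to <- rep(NA_integer_, nrow(sites))
  for (ch in unique(boundaries$chrom)) {
    brows <- which(boundaries$chrom == ch)
    srows <- which(sites$chrom == ch)
    if (!length(brows) || !length(srows)) next
    bb <- boundaries$bin[brows]
    mid <- (bb + 0.5) * bin_width
    pos <- sites$pos[srows]
    for (k in seq_along(srows)) {
      lo <- (bb - win_bins) * bin_width
      hi <- (bb + win_bins + 1) * bin_width
      inside <- which(pos[k] >= lo & pos[k] < hi)
      if (!length(inside)) next
      dist <- abs(pos[k] - mid[inside])
      pick <- inside[order(dist, bb[inside])[1]]  # nearest, ties leftmost
      assigned_to[srows[k]] <- brows[pick]
    }
  }
  for (b in seq_len(nb)) {
    mine <- which(assigned_to == b)
    if (!length(mine)) next
    mine <- mine[order(sites$pos[mine])]
    co <- sites$cobound[mine] == "ctcf_cohesin"
    boundaries$n_ctcf_cohesin[b] <- sum(co)
    boundaries$n_cohesin_only[b] <- sum(!co)
    st <- sites$strand[mine][co]
    boundaries$site_strands[[b]] <- st[st %in% c("+", "-")]
  }
  boundaries
}

#' Classify CTCF motif orientation at a boundary
#'
#' Operates on the genomically ordered strands of CTCF+cohesin-bound motifs
#' (unknown-strand sites are excluded from orientation logic). Zero
#' stranded sites give `none`; one site, or two or more on the same strand,
#' give `tandem_single`; two or more with both strands present give
#' `complex`. The sub-label (`single` / `tandem`; `convergent` when the
#' array runs + ... -, `divergent` when - ... +, otherwise `mixed`) is
#' reported as metadata and never feeds the class index.
#'
#' @param strands Character vector of `+` / `-` in genomic order.
#' @return List with `orientation` and `sub_label`.
#' @export
classify_orientation <- function(strands) {
  strands <- strands[strands %in% c("+", "-")]
  n <- length(strands)
  if (n == 0) return(list(orientation = "none", sub_label = "none"))
  if (n == 1) return(list(orientation = "tandem_single", sub_label = "single"))
  if (length(unique(strands)) == 1) {
    return(list(orientation = "tandem_single", sub_label = "tandem"))
  }
  first <- strands[1]; last <- strands[n]
  sub <- if (first == "+" && last == "-") "convergent" else
    if (first == "-" && last == "+") "divergent" else "mixed"
  list(orientation = "complex", sub_label = sub)
}

#' Stratify boundaries into the six classes
#'
#' Double-dot and single-dot boundaries pool into dot boundaries; the class
#' index is the exact 6-cell mapping of (dot group, orientation):
#' dot+complex = 1, dot+tandem/single = 2, dot+none = 3,
#' dotless+complex = 4, dotless+tandem/single = 5, dotless+none = 6.
#'
#' @param boundaries Boundary tibble with `dot_status` and either an
#'   `orientation` column or a `site_strands` list-column (from
#'   [assign_sites_to_boundaries()]) from which orientation is derived.
#' @return `boundaries` with `orientation`, `orientation_sub` and
#'   `class_index` columns.
#' @export
stratify_boundaries <- function(boundaries) {
  if (!"dot_status" %in% names(boundaries) ||
      any(is.na(boundaries$dot_status))) {
    stop("dot_status must be populated before stratification")
  }
  if (!"orientation" %in% names(boundaries)) {
    if (!"site_strands" %in% names(boundaries)) {
      stop("orientation (or site_strands) must be populated before stratification")
    }
    ori <- purrr::map(boundaries$site_strands, classify_orientation)
    boundaries$orientation <- purrr::map_chr(ori, "orientation")
    boundaries$orientation_sub <- purrr::map_chr(ori, "sub_label")
  }
  bad <- !boundaries$dot_status %in% c("double_dot", "single_dot", "dotless")
  if (any(bad)) stop("invalid dot_status: ", boundaries$dot_status[which(bad)[1]])
  dot <- boundaries$dot_status %in% c("double_dot", "single_dot")
  ocol <- match(boundaries$orientation, c("complex", "tandem_single", "none"))
  if (anyNA(ocol)) stop("invalid orientation: ",
                        boundaries$orientation[which(is.na(ocol))[1]])
  boundaries$class_index <- as.integer(ifelse(dot, ocol, ocol + 3L))
  boundaries
}

#' Flag boundaries overlapped by transcribed genes
#'
#' The flag is TRUE iff at least one active gene interval overlaps the
#' boundary window `[bin - win_bins, bin + win_bins + 1)` bins.
#'
#' @param boundaries Boundary tibble (`chrom`, `bin`).
#' @param genes Gene interval tibble (`chrom`, `start`, `end`) with a
#'   logical `active` column (or a `name` column equal to
#'   `active`/`inactive`).
#' @param bin_width Bin width in bp.
#' @param win_bins Window half-width in bins (default 1).
#' @return `boundaries` with a logical `transcribed` column.
#' @export
stratify_by_transcription <- function(boundaries, genes, bin_width,
                                      win_bins = 1) {
  if (!"active" %in% names(genes)) {
    if (!"name" %in% names(genes)) stop("genes need an active flag")
    genes$active <- genes$name == "active"
  }
  act <- genes[genes$active, ]
  boundaries$transcribed <- vapply(seq_len(nrow(boundaries)), function(k) {
    lo <- (boundaries$bin[k] - win_bins) * bin_width
    hi <- (boundaries$bin[k] + win_bins + 1) * bin_width
    any(act$chrom == boundaries$chrom[k] & act$start < hi & act$end > lo)
  }, logical(1))
  boundaries
}
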