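iz_bin_range <- function(izs, bin_width) {
  if (!all(c("start_bin", "end_bin") %in% names(izs))) {
    izs$start_bin <- as.integer(izs$start %/% bin_width)
    izs$end_bin <- as.integer(ceiling(izs$end / bin_width))
  }
  izs
}

# majority compartment label of a bin window; ties resolved by the label of
# tie_bin (for real IZs: the apex; for candidate windows: the center bin)
majority_label <- function(labels, start_bin, width, tie_bin = NULL) {
  idx <- (start_bin + 1L):(start_bin + width)
  lab <- labels[idx]
  na <- sum(lab == "A"); nb <- sum(lab == "B")
  if (na > nb) return("A")
  if (nb > na) return("B")
  if (is.null(tie_bin)) tie_bin <- start_bin + (width - 1L) %/% 2L
  labels[tie_bin + 1L]
}

#' Sample size- and compartment-matched null IZ sets
#'
#' For every replicate and every real IZ, a random interval of exactly the
#' same bin width is drawn uniformly among all bin-aligned start positions
#' (on any autosome chromosome of the grid, or the IZ's own chromosome with
#' `same_chrom = TRUE`) whose majority compartment label equals the IZ's.
#' The eligible-position set is enumerated exhaustively per (width, label),
#' so sampling is exact; an IZ with no eligible position is an error naming
#' the IZ.
#'
#' The majority label of a window is the label covering more than half its
#' bins; exact ties take the apex-bin label for real IZs and the center-bin
#' label for candidate windows.
#'
#' @param izs IZ tibble (from [call_izs()] or truth).
#' @param compartments Per-bin tibble `chrom`, `bin`, `label`.
#' @param grid A [bin_grid()]; only `autosome` chromosomes are sampled.
#' @param R Number of null replicates (default 1000).
#' @param seed Integer seed (recorded on the output).
#' @param same_chrom Restrict each null interval to its source chromosome.
#' @return A `null_iz_sets` tibble: `replicate`, `iz_id`, `chrom`,
#'   `start_bin`, `end_bin`, `width_bins`, `label`, `timing_class`, with
#'   attributes `R` and `seed`.
#' @export
sample_matched_nulls <- function(izs, compartments, grid, R = 1000,
                                 seed = 1L, same_chrom = FALSE) {
  bw <- bin_width(grid)
  izs <- iz_bin_range(izs, bw)
  izs$iz_id <- seq_len(nrow(izs))
  auto <- grid[grid$autosome, ]
  labs <- lapply(grid$chrom, function(ch) {
    cc <- compartments[compartments$chrom == ch, ]
    cc$label[order(cc$bin)]
  })
  names(labs) <- grid$chrom
  # majority label of every window of width w on every autosome, cached
  window_labels <- function(w) {
    lapply(auto$chrom, function(ch) {
      lab <- labs[[ch]]
      nbn <- length(lab)
      if (nbn < w) return(character(0))
      isA <- cumsum(c(0L, lab == "A"))
      isB <- cumsum(c(0L, lab == "B"))
      starts <- 0:(nbn - w)
      na <- isA[starts + w + 1L] - isA[starts + 1L]
      nb <- isB[starts + w + 1L] - isB[starts + 1L]
      out <- ifelse(na > nb, "A", ifelse(nb > na, "B",
                                         lab[starts + (w - 1L) %/% 2L + 1L]))
      out
    })
  }
  withr::with_seed(as.integer(seed), {
    cache <- list()
    draws <- purrr::map_dfr(seq_len(nrow(izs)), function(k) {
      w <- izs$end_bin[k] - izs$start_bin[k]
      lab_k <- majority_label(labs[[izs$chrom[k]]], izs$start_bin[k], w,
                              tie_bin = izs$apex_bin[k])
      keyw <- as.character(w)
      if (is.null(cache[[keyw]])) cache[[keyw]] <<- window_labels(w)
      wl <- cache[[keyw]]
      chrom_ok <- if (same_chrom) match(izs$chrom[k], auto$chrom) else
        seq_along(auto$chrom)
      elig <- purrr::map_dfr(chrom_ok, function(ci) {
        pos <- which(wl[[ci]] == lab_k) - 1L
        if (!length(pos)) return(NULL)
        tibble::tibble(chrom = auto$chrom[ci], start_bin = pos)
      })
      if (!nrow(elig)) {
        stop("no eligible null position for IZ ", k, " (width ", w,
             " bins, label ", lab_k, ")")
      }
      pick <- elig[sample.int(nrow(elig), R, replace = TRUE), ]
      tibble::tibble(replicate = seq_len(R), iz_id = k,
                     chrom = pick$chrom, start_bin = pick$start_bin,
                     end_bin = pick$start_bin + w, width_bins = w,
                     label = lab_k,
                     timing_class = izs$timing_class[k])
    })
    attr(draws, "R") <- as.integer(R)
    attr(draws, "seed") <- as.integer(seed)
    class(draws) <- c("null_iz_sets", class(draws))
    draws
  })
}

# does each interval [start_bin, end_bin) overlap any boundary window
# [b - win, b + win + 1)?  vectorized via sorted boundary bins per chrom
overlaps_any_boundary <- function(chrom, start_bin, end_bin, boundaries, win_bins) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    bb <- sort(boundaries$bin[boundaries$chrom == ch])
    rows <- which(chrom == ch)
    if (!length(bb)) next
    lo <- start_bin[rows] - win_bins          # min boundary bin that overlaps
    hi <- end_bin[rows] - 1L + win_bins       # max boundary bin that overlaps
    out[rows] <- findInterval(hi, bb) > findInterval(lo - 1L, bb)
  }
  out
}

#' Count IZs colocalized with boundaries
#'
#' An IZ colocalizes with a boundary when its interval overlaps the window
#' `[bin - win_bins, bin + win_bins + 1)` bins; each IZ is counted at most
#' once.
#'
#' @param izs IZ tibble.
#' @param boundaries Boundary tibble (`chrom`, `bin`).
#' @param bin_width Bin width in bp (needed if `izs` lacks bin columns).
#' @param win_bins Window half-width in bins (default 1, +/-50 kb).
#' @return Integer count.
#' @export
colocalization_count <- function(izs, boundaries, bin_width = NULL,
                                 win_bins = 1) {
  if (!nrow(izs)) return(0L)
  if (!all(c("start_bin", "end_bin") %in% names(izs))) {
    if (is.null(bin_width)) stop("bin_width needed to convert IZs to bins")
    izs <- iz_bin_range(izs, bin_width)
  }
  sum(overlaps_any_boundary(izs$chrom, izs$start_bin, izs$end_bin,
                            boundaries, win_bins))
}

#' Empirical randomization test of IZ-boundary colocalization
#'
#' For each (boundary class, IZ timing class) cell, the observed
#' colocalization count is compared with the counts obtained by the
#' size- and compartment-matched null sets. The right-tailed empirical P is
#' `(1 + #\{X_r >= X_obs\}) / (R + 1)` (add-one rule, so P is never 0 and
#' never below `1/(R+1)`); the left tail is the analogue with `<=`.
#'
#' @param izs IZ tibble with `timing_class`.
#' @param boundaries Boundary tibble with `class_index`.
#' @param nulls [sample_matched_nulls()] result generated from `izs`.
#' @param bin_width Bin width in bp (if `izs` lacks bin columns).
#' @param win_bins Colocalization window (default 1).
#' @return An `iz_enrichment` object; see [tidy.iz_enrichment()].
#' @export
empirical_enrichment <- function(izs, boundaries, nulls, bin_width = NULL,
                                 win_bins = 1) {
  R <- attr(nulls, "R")
  if (is.null(R) || R == 0) stop("nulls must contain >= 1 replicate")
  if (!is.null(bin_width)) izs <- iz_bin_range(izs, bin_width)
  classes <- sort(unique(boundaries$class_index))
  timings <- c("early", "early_mid", "late")
  cells <- expand.grid(class_index = classes, timing_class = timings,
                       stringsAsFactors = FALSE)
  null_counts <- matrix(0L, nrow(cells), R)
  tab <- purrr::pmap_dfr(cells, function(class_index, timing_class) {
    bcl <- boundaries[boundaries$class_index == class_index, ]
    obs_rows <- izs[!is.na(izs$timing_class) & izs$timing_class == timing_class, ]
    x_obs <- colocalization_count(obs_rows, bcl, win_bins = win_bins)
    nn <- nulls[nulls$timing_class == timing_class, ]
    xr <- integer(R)
    if (nrow(nn)) {
      hit <- overlaps_any_boundary(nn$chrom, nn$start_bin, nn$end_bin,
                                   bcl, win_bins)
      agg <- tapply(hit, nn$replicate, sum)
      xr[as.integer(names(agg))] <- as.integer(agg)
    }
    i <- which(cells$class_index == class_index &
                 cells$timing_class == timing_class)
    null_counts[i, ] <<- xr
    tibble::tibble(
      class_index = class_index, timing_class = timing_class,
      x_obs = x_obs, r = R,
      null_mean = mean(xr),
      p_right = (1 + sum(xr >= x_obs)) / (R + 1),
      p_left = (1 + sum(xr <= x_obs)) / (R + 1))
  })
  structure(list(table = tab, null_counts = null_counts,
                 win_bins = win_bins, r = R, seed = attr(nulls, "seed")),
            class = "iz_enrichment")
}

#' @export
print.iz_enrichment <- function(x, ...) {
  cat("<iz_enrichment> R =", x$r, "replicates, window +/-", x$win_bins,
      "bin(s)\n")
  print(x$table)
  invisible(x)
}

#' Tidy an IZ-boundary enrichment result
#'
#' @param x An `iz_enrichment` object.
#' @param ... Unused.
#' @return One row per (class, timing) cell: observed count, null mean,
#'   right- and left-tailed empirical P.
#' @export
tidy.iz_enrichment <- function(x, ...) x$table

#' @rdname tidy.iz_enrichment
#' @return For `glance`: a one-row summary (replicates, window, cells,
#'   smallest right-tailed P).
#' @export
glance.iz_enrichment <- function(x, ...) {
  tibble::tibble(r = x$r, win_bins = x$win_bins,
                 n_cells = nrow(x$table),
                 min_p_right = min(x$table$p_right))
}

#' Boundary-centered aggregate Repli-seq profile
#'
#' Averages, for each of the 16 fractions, the signal in a fixed window of
#' `flank_bins` bins on either side of each boundary (31 columns at the
#' default 15 = +/-750 kb at 50-kb bins). Windows truncated by chromosome
#' ends are excluded and counted.
#'
#' @param boundaries Boundary tibble (`chrom`, `bin`).
#' @param rs A [repliseq16()] (any normalization state; aggregate what you
#'   plot).
#' @param flank_bins Flank K in bins (default 15).
#' @param condition Optional condition label.
#' @return An `aggregate_profile`: list with `mat` (16 x (2K+1)), `n`,
#'   `n_excluded`, `flank_bins`, `condition`.
#' @export
aggregate_repliseq_profile <- function(boundaries, rs, flank_bins = 15,
                                       condition = NA_character_) {
  stopifnot(flank_bins >= 1)
  sig <- rs_signal(rs)
  k <- flank_bins
  acc <- matrix(0, 16, 2 * k + 1)
  n <- 0L; n_excl <- 0L
  for (ch in unique(boundaries$chrom)) {
    rows <- which(rs$chrom == ch)
    if (!length(rows)) next
    bw <- rs$end[rows[1]] - rs$start[rows[1]]
    bin_of <- rs$start[rows] %/% bw
    for (b in boundaries$bin[boundaries$chrom == ch]) {
      want <- (b - k):(b + k)
      idx <- rows[match(want, bin_of)]
      if (anyNA(idx)) { n_excl <- n_excl + 1L; next }
      acc <- acc + t(sig[idx, , drop = FALSE])
      n <- n + 1L
    }
  }
  mat <- if (n > 0) acc / n else matrix(NA_real_, 16, 2 * k + 1)
  structure(list(mat = mat, n = n, n_excluded = n_excl,
                 flank_bins = k, condition = condition),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat("<aggregate_profile> 16 x ", ncol(x$mat), " (flank ", x$flank_bins,
      " bins), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Length-normalized aggregate Repli-seq profile
#'
#' Per boundary and fraction, the signal over the left flanking domain is
#' resampled to K pseudo-bins and that over the right flanking domain to K
#' pseudo-bins by linear interpolation, with the boundary bin as the center
#' column (the right domain's first bin is the boundary bin; its resampling
#' grid therefore starts one step in, so a right flank of exactly K+1 bins
#' is returned unresampled). Boundaries lacking a flank are skipped.
#'
#' @param boundaries Boundary tibble with `left_start_bin` and
#'   `right_end_bin` (from [derive_boundaries()]).
#' @param rs A [repliseq16()].
#' @param K Pseudo-bins per flank.
#' @param condition Optional label.
#' @return An `aggregate_profile` with a 16 x (2K+1) matrix.
#' @export
length_normalized_profile <- function(boundaries, rs, K,
                                      condition = NA_character_) {
  sig <- rs_signal(rs)
  acc <- matrix(0, 16, 2 * K + 1)
  n <- 0L; n_skip <- 0L
  for (ch in unique(boundaries$chrom)) {
    rows <- which(rs$chrom == ch)
    if (!length(rows)) next
    bw <- rs$end[rows[1]] - rs$start[rows[1]]
    bin_of <- rs$start[rows] %/% bw
    bnd <- boundaries[boundaries$chrom == ch, ]
    for (i in seq_len(nrow(bnd))) {
      ls <- bnd$left_start_bin[i]; re <- bnd$right_end_bin[i]; b <- bnd$bin[i]
      if (is.na(ls) || is.na(re) || ls >= b || re <= b) { n_skip <- n_skip + 1L; next }
      left_idx <- rows[match(ls:(b - 1), bin_of)]
      right_idx <- rows[match(b:(re - 1), bin_of)]
      ctr_idx <- rows[match(b, bin_of)]
      if (anyNA(left_idx) || anyNA(right_idx) || is.na(ctr_idx)) {
        n_skip <- n_skip + 1L; next
      }
      prof <- vapply(1:16, function(f) {
        lv <- sig[left_idx, f]
        rv <- sig[right_idx, f]
        lres <- if (length(lv) == 1) rep(lv, K) else
          stats::approx(seq_along(lv), lv, xout = seq(1, length(lv), length.out = K))$y
        rres <- if (length(rv) == 1) rep(rv, K) else
          stats::approx(seq_along(rv), rv,
                        xout = seq(1, length(rv), length.out = K + 1)[-1])$y
        c(lres, sig[ctr_idx, f], rres)
      }, numeric(2 * K + 1))
      acc <- acc + t(prof)
      n <- n + 1L
    }
  }
  mat <- if (n > 0) acc / n else matrix(NA_real_, 16, 2 * K + 1)
  structure(list(mat = mat, n = n, n_excluded = n_skip,
                 flank_bins = K, condition = condition),
            class = "aggregate_profile")
}

#' Two-sample Mann-Whitney U test
#'
#' Rank-sum U with midrank tie handling. The P value is exact (full
#' enumeration of labelings) when `length(x) + length(y) <= 16` and there
#' are no ties, otherwise a normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative Only `two_tailed` is offered.
#' @return Tibble: `u` (U statistic for `x`), `p_value`, `method`, `n_x`,
#'   `n_y`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two_tailed") {
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal_approx",
                 n_x = length(x), n_y = length(y))
}

#' Compare IZ sets between two conditions at classified boundaries
#'
#' For each boundary class and timing class: the IZs of each condition
#' colocalized with that class's boundaries, their counts, width vectors
#' and medians, the two-tailed Mann-Whitney P on widths (NA when either
#' arm has fewer than 2 IZs) and the direction of the width effect.
#' Both IZ sets must have been called with identical parameters.
#'
#' @param izs_a,izs_b IZ tibbles for conditions A and B.
#' @param boundaries Classified boundary tibble (`class_index`).
#' @param bin_width Bin width in bp.
#' @param win_bins Colocalization window (default 1).
#' @return Tibble per (class, timing): `n_a`, `n_b`, `median_width_a`,
#'   `median_width_b`, `p_width`, `direction`, plus width list-columns.
#' @export
compare_iz_sets <- function(izs_a, izs_b, boundaries, bin_width,
                            win_bins = 1) {
  izs_a <- iz_bin_range(izs_a, bin_width)
  izs_b <- iz_bin_range(izs_b, bin_width)
  classes <- sort(unique(boundaries$class_index))
  timings <- c("early", "early_mid", "late")
  purrr::map_dfr(classes, function(cl) {
    bcl <- boundaries[boundaries$class_index == cl, ]
    purrr::map_dfr(timings, function(tc) {
      wa <- iz_widths_at(izs_a, bcl, tc, win_bins)
      wb <- iz_widths_at(izs_b, bcl, tc, win_bins)
      p <- if (length(wa) >= 2 && length(wb) >= 2) {
        mann_whitney_u(wa, wb)$p_value
      } else NA_real_
      ma <- if (length(wa)) stats::median(wa) else NA_real_
      mb <- if (length(wb)) stats::median(wb) else NA_real_
      tibble::tibble(
        class_index = cl, timing_class = tc,
        n_a = length(wa), n_b = length(wb),
        median_width_a = ma, median_width_b = mb,
        p_width = p,
        direction = dplyr::case_when(
          is.na(ma) | is.na(mb) ~ NA_character_,
          mb > ma ~ "B>A", mb < ma ~ "A>B", TRUE ~ "equal"),
        widths_a = list(wa), widths_b = list(wb))
    })
  })
}

iz_widths_at <- function(izs, bcl, timing_class, win_bins) {
  rows <- izs[!is.na(izs$timing_class) & izs$timing_class == timing_class, ]
  if (!nrow(rows)) return(numeric(0))
  hit <- overlaps_any_boundary(rows$chrom, rows$start_bin, rows$end_bin,
                               bcl, win_bins)
  rows$width_bp[hit]
}
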