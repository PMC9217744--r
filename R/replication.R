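#' 16-fraction Repli-seq container
#'
#' A tibble with one row per genomic bin (`chrom`, `start`, `end`) and 16
#' signal columns `f1`..`f16`, fraction 1 being earliest S phase. A `state`
#' attribute tracks normalization: `"raw"`, `"depth"` (equal per-fraction
#' totals) or `"unit_sum"` (each covered bin's 16-vector sums to 1).
#' Uncovered bins (all-zero raw signal) stay all-zero and are excluded from
#' downstream timing summaries.
#'
#' @param bins Tibble with `chrom`, `start`, `end`.
#' @param signal N x 16 non-negative matrix, columns earliest to latest.
#' @param state Normalization state flag.
#' @param grid Optional [bin_grid()] kept as an attribute.
#' @return A `repliseq16` tibble.
#' @export
repliseq16 <- function(bins, signal, state = c("raw", "depth", "unit_sum"),
                       grid = NULL) {
  state <- match.arg(state)
  signal <- as.matrix(signal)
  if (ncol(signal) != 16L) stop("expected 16 fractions, found ", ncol(signal))
  if (nrow(signal) != nrow(bins)) stop("signal rows must match bins")
  if (any(signal < 0, na.rm = TRUE)) stop("negative Repli-seq signal")
  colnames(signal) <- paste0("f", 1:16)
  out <- tibble::as_tibble(cbind(bins[, c("chrom", "start", "end")],
                                 as.data.frame(signal)))
  attr(out, "state") <- state
  attr(out, "grid") <- grid
  class(out) <- c("repliseq16", class(out))
  out
}

#' @export
print.repliseq16 <- function(x, ...) {
  cat("<repliseq16> ", nrow(x), " bins, state: ", rs_state(x), "\n", sep = "")
  NextMethod()
}

#' Accessors for `repliseq16` objects
#'
#' `rs_signal()` returns the N x 16 signal matrix, `rs_state()` the
#' normalization flag, `rs_covered()` the logical coverage mask (a bin is
#' uncovered when its raw 16-vector is all zero).
#'
#' @param rs A [repliseq16()].
#' @return Matrix / character / logical.
#' @export
rs_signal <- function(rs) as.matrix(rs[, paste0("f", 1:16)])

#' @rdname rs_signal
#' @export
rs_state <- function(rs) attr(rs, "state")

#' @rdname rs_signal
#' @export
rs_covered <- function(rs) rowSums(rs_signal(rs)) > 0

#' Normalize 16-fraction Repli-seq
#'
#' Three steps: (1) depth normalization — each fraction column is scaled so
#' all 16 fractions carry the same total signal (the mean raw total);
#' (2) unit-sum normalization — each covered bin's 16-vector is scaled to sum
#' to 1; (3) optional Gaussian smoothing along the genome within each
#' fraction (sd = `smooth_sd` bins, default 1), applied per chromosome with
#' an edge-renormalized kernel. Smoothing uses identical weights in every
#' fraction, so unit sums are preserved. Uncovered bins stay all-zero.
#'
#' @param rs A raw [repliseq16()].
#' @param smooth Apply step 3 (default TRUE).
#' @param smooth_sd Smoothing sd in bins.
#' @return A [repliseq16()] in `unit_sum` state.
#' @export
normalize_repliseq <- function(rs, smooth = TRUE, smooth_sd = 1) {
  if (rs_state(rs) != "raw") stop("normalize_repliseq expects raw state")
  sig <- rs_signal(rs)
  covered <- rowSums(sig) > 0
  totals <- colSums(sig)
  if (any(totals == 0)) {
    stop("fraction ", which(totals == 0)[1], " has zero total signal")
  }
  sig <- sweep(sig, 2, mean(totals) / totals, `*`)
  rsums <- rowSums(sig)
  sig[covered, ] <- sig[covered, , drop = FALSE] / rsums[covered]
  if (smooth) {
    half <- max(1L, ceiling(3 * smooth_sd))
    kern <- stats::dnorm(-half:half, sd = smooth_sd)
    for (ch in unique(rs$chrom)) {
      rows <- which(rs$chrom == ch)
      sig[rows, ] <- smooth_columns(sig[rows, , drop = FALSE], kern)
    }
    # smoothing mixes covered and uncovered rows; renormalize covered rows
    rsums <- rowSums(sig)
    ok <- covered & rsums > 0
    sig[ok, ] <- sig[ok, , drop = FALSE] / rsums[ok]
    sig[!covered, ] <- 0
  }
  repliseq16(rs[, 1:3], sig, state = "unit_sum", grid = attr(rs, "grid"))
}

# kernel-smooth each column of m along rows, renormalizing at edges
smooth_columns <- function(m, kern) {
  n <- nrow(m)
  half <- (length(kern) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (k in -half:half) {
    w <- kern[k + half + 1L]
    src <- (1:n) + k
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, , drop = FALSE] + w * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  out / wsum
}

#' Per-bin replication timing value
#'
#' The timing value T of a covered bin is the center of mass of its unit-sum
#' 16-vector: \eqn{T = \sum_f f \, p_f}, ranging 1 (earliest) to 16 (latest).
#' Uncovered bins get `NA`.
#'
#' @param rs A [repliseq16()] in `unit_sum` state.
#' @return Tibble `chrom`, `start`, `end`, `bin`, `timing`.
#' @export
compute_timing <- function(rs) {
  if (rs_state(rs) != "unit_sum") stop("compute_timing expects unit_sum state")
  sig <- rs_signal(rs)
  timing <- as.vector(sig %*% (1:16))
  timing[!rs_covered(rs)] <- NA_real_
  bw <- rs$end - rs$start
  tibble::tibble(chrom = rs$chrom, start = rs$start, end = rs$end,
                 bin = as.integer(rs$start %/% bw[1]), timing = timing)
}

#' Call replication initiation zones from 16-fraction Repli-seq
#'
#' IZs appear as local minima (early dips) of the per-bin timing track T.
#' Candidate apexes are local minima with prominence at least
#' `prominence_min` fractions relative to the surrounding +/-10 bins
#' (prominence = min over the two sides of the maximum T within 10 bins,
#' minus apex T). The IZ extent is the maximal run around the apex where T
#' stays within `flank_rise` fractions of the apex and is non-decreasing
#' moving outward. Apexes closer than `merge_gap_bins` are merged keeping
#' the earlier (lower-T) apex; overlapping extents are split at the timing
#' maximum between apexes, so returned IZs never overlap. The timing class
#' comes from apex T: early (T <= 5.5), early-mid (5.5 < T <= 10.5), late
#' (T > 10.5) — three near-equal waves of the 16 fractions.
#'
#' Calls are invariant to uniform rescaling of raw counts because T is
#' computed from unit-sum vectors.
#'
#' @param rs A [repliseq16()] (raw input is normalized internally with
#'   defaults; pass a `unit_sum` object to control normalization).
#' @param prominence_min Minimum apex prominence in fractions (default 0.5).
#' @param flank_rise Allowed rise above apex T inside the IZ (default 1.0).
#' @param merge_gap_bins Apexes closer than this are merged (default 2).
#' @param condition Optional condition label carried on every call.
#' @return Tibble `chrom`, `start`, `end`, `apex_bin`, `width_bp`,
#'   `prominence`, `apex_timing`, `timing_class`, `condition`.
#' @export
call_izs <- function(rs, prominence_min = 0.5, flank_rise = 1.0,
                     merge_gap_bins = 2, condition = NA_character_) {
  if (rs_state(rs) == "raw") rs <- normalize_repliseq(rs)
  timing <- compute_timing(rs)
  bw <- rs$end[1] - rs$start[1]
  out <- dplyr::group_by(timing, .data$chrom)
  out <- dplyr::group_modify(out, function(df, key) {
    call_izs_chrom(df, prominence_min, flank_rise, merge_gap_bins, bw)
  })
  out <- dplyr::ungroup(out)
  out$condition <- condition
  out
}

call_izs_chrom <- function(df, prominence_min, flank_rise, merge_gap_bins, bw) {
  empty <- tibble::tibble(start = numeric(), end = numeric(),
                          apex_bin = integer(), width_bp = numeric(),
                          prominence = numeric(), apex_timing = numeric(),
                          timing_class = character())
  tt <- df$timing
  n <- length(tt)
  if (n < 21) {
    warning("chromosome shorter than 21 bins: no IZ calls")
    return(empty)
  }
  tt_filled <- tt
  tt_filled[is.na(tt_filled)] <- Inf
  # local minima, leftmost bin of a plateau
  is_min <- vapply(seq_len(n), function(b) {
    if (!is.finite(tt_filled[b])) return(FALSE)
    left <- if (b > 1) tt_filled[b - 1] else Inf
    right <- if (b < n) tt_filled[b + 1] else Inf
    tt_filled[b] < left && tt_filled[b] <= right
  }, logical(1))
  cand <- which(is_min)
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(b) {
    lw <- tt_filled[max(1, b - 10):max(1, b - 1)]
    rw <- tt_filled[min(n, b + 1):min(n, b + 10)]
    lw <- lw[is.finite(lw)]; rw <- rw[is.finite(rw)]
    if (!length(lw) || !length(rw)) return(0)
    min(max(lw), max(rw)) - tt_filled[b]
  }, numeric(1))
  keep <- prom >= prominence_min
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # merge apexes closer than merge_gap_bins, keeping the earlier (lower T)
  o <- order(tt_filled[cand])
  kept <- logical(0); kept_idx <- integer(0)
  for (i in o) {
    if (!length(kept_idx) || all(abs(cand[i] - cand[kept_idx]) >= merge_gap_bins)) {
      kept_idx <- c(kept_idx, i)
    }
  }
  kept_idx <- sort(kept_idx)
  cand <- cand[kept_idx]; prom <- prom[kept_idx]
  # extents: walk outward while T non-decreasing and within flank_rise
  ext <- t(vapply(seq_along(cand), function(i) {
    b <- cand[i]; lim <- tt_filled[b] + flank_rise
    lo <- b
    while (lo > 1 && is.finite(tt_filled[lo - 1]) &&
           tt_filled[lo - 1] <= lim && tt_filled[lo - 1] >= tt_filled[lo]) lo <- lo - 1
    hi <- b
    while (hi < n && is.finite(tt_filled[hi + 1]) &&
           tt_filled[hi + 1] <= lim && tt_filled[hi + 1] >= tt_filled[hi]) hi <- hi + 1
    c(lo, hi)
  }, numeric(2)))
  # enforce non-overlap: cut at the timing maximum between adjacent apexes
  if (nrow(ext) > 1) {
    for (i in seq_len(nrow(ext) - 1)) {
      if (ext[i, 2] >= ext[i + 1, 1]) {
        between <- cand[i]:cand[i + 1]
        cut <- between[which.max(tt_filled[between])]
        ext[i, 2] <- min(ext[i, 2], cut - 1)
        ext[i + 1, 1] <- max(ext[i + 1, 1], cut + 1)
        ext[i, 2] <- max(ext[i, 2], cand[i])
        ext[i + 1, 1] <- min(ext[i + 1, 1], cand[i + 1])
      }
    }
  }
  apex_t <- tt_filled[cand]
  tibble::tibble(
    start = df$start[ext[, 1]],
    end = df$end[ext[, 2]],
    apex_bin = df$bin[cand],
    width_bp = df$end[ext[, 2]] - df$start[ext[, 1]],
    prominence = prom,
    apex_timing = apex_t,
    timing_class = timing_class_of(apex_t)
  )
}

#' Timing class from a timing value
#'
#' Cut points 5.5 and 10.5 split the 16 fractions into three near-equal
#' waves: early (1-5), early-mid (6-10), late (11-16).
#'
#' @param t Timing value(s) in fractions.
#' @return Character vector in `early`, `early_mid`, `late`.
#' @export
timing_class_of <- function(t) {
  dplyr::case_when(t <= 5.5 ~ "early", t <= 10.5 ~ "early_mid", TRUE ~ "late")
}

#' Two-fraction early/late log ratio
#'
#' Collapses 16 fractions to the classical two-fraction Repli-seq statistic:
#' E = sum of fractions 1-8, L = sum of fractions 9-16,
#' value = log2((E + pseudocount) / (L + pseudocount)).
#'
#' @param rs A [repliseq16()] in raw or depth state.
#' @param pseudocount Added to both halves (default 1).
#' @return Tibble `chrom`, `start`, `end`, `log2_el`.
#' @export
two_fraction_log_ratio <- function(rs, pseudocount = 1) {
  if (rs_state(rs) == "unit_sum") {
    stop("two_fraction_log_ratio expects raw or depth state")
  }
  sig <- rs_signal(rs)
  e <- rowSums(sig[, 1:8, drop = FALSE])
  l <- rowSums(sig[, 9:16, drop = FALSE])
  tibble::tibble(chrom = rs$chrom, start = rs$start, end = rs$end,
                 log2_el = log2((e + pseudocount) / (l + pseudocount)))
}
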