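#' Distance-decay expected profile of a contact matrix
#'
#' The expected value at distance d bins is the arithmetic mean over all
#' pixels \{M[i, i+d]\} of the chromosome. Distances with fewer than
#' `min_obs` pixels (the long-range tail) are pooled into logarithmically
#' spaced distance groups to control variance; each pooled distance gets its
#' group mean.
#'
#' @param cm A [contact_matrix()].
#' @param min_obs Minimum pixels per distance before pooling (default 100).
#' @return An `expected_profile` tibble: `distance`, `expected`, `n`,
#'   `pooled`.
#' @export
compute_expected <- function(cm, min_obs = 100) {
  m <- cm$mat
  n <- nrow(m)
  if (n == 0) stop("empty matrix")
  sums <- counts <- numeric(n)
  for (d in 0:(n - 1)) {
    idx <- cbind(1:(n - d), (1 + d):n)
    sums[d + 1] <- sum(m[idx])
    counts[d + 1] <- n - d
  }
  expected <- sums / counts
  pooled <- counts < min_obs
  if (any(pooled)) {
    d <- which(pooled) - 1L
    grp <- floor(16 * log2(d + 1))
    gs <- tapply(sums[pooled], grp, sum)
    gc <- tapply(counts[pooled], grp, sum)
    expected[pooled] <- (gs / gc)[as.character(grp)]
  }
  out <- tibble::tibble(distance = 0:(n - 1), expected = expected,
                        n = as.integer(counts), pooled = pooled)
  class(out) <- c("expected_profile", class(out))
  out
}

# expected value lookup at (possibly vectorized) distances
expected_at <- function(exp_profile, d) {
  exp_profile$expected[d + 1L]
}

#' Observed/expected transform
#'
#' @param cm A [contact_matrix()].
#' @param exp_profile Result of [compute_expected()].
#' @return Dense O/E matrix; pixels with zero expected value become `NA`.
#' @export
oe_matrix <- function(cm, exp_profile) {
  n <- nrow(cm$mat)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  e <- matrix(expected_at(exp_profile, d), n, n)
  out <- cm$mat / e
  out[e == 0] <- NA
  out
}

#' Insulation score track
#'
#' For each bin b the mean contact value over the square
#' `[b-w, b-1] x [b, b+w-1]` (the inter-domain square the bin's boundary
#' would insulate) is computed; the score is `log2(mean / chromosome median
#' of the statistic)`. Scores are undefined within `window_bins` of the
#' chromosome ends. Minima positions are invariant to scaling the matrix.
#'
#' @param cm A [contact_matrix()].
#' @param window_bins Square size w in bins (>= 2).
#' @return Tibble `bin`, `score` (NA where undefined), with attribute
#'   `window_bins`.
#' @export
compute_insulation <- function(cm, window_bins) {
  m <- cm$mat
  n <- nrow(m)
  w <- as.integer(window_bins)
  if (w < 2) stop("window_bins must be >= 2")
  if (2 * w > n) stop("window exceeds half the chromosome")
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # sat[j, i] = sum m[1:i, 1:j]
  sat <- t(sat)
  block_sum <- function(r1, r2, c1, c2) {
    s <- sat[cbind(r2, c2)]
    s <- s - ifelse(r1 > 1, sat[cbind(pmax(r1 - 1, 1), c2)], 0)
    s <- s - ifelse(c1 > 1, sat[cbind(r2, pmax(c1 - 1, 1))], 0)
    s + ifelse(r1 > 1 & c1 > 1, sat[cbind(pmax(r1 - 1, 1), pmax(c1 - 1, 1))], 0)
  }
  bins <- w:(n - w)          # 0-based defined range
  r1 <- bins - w + 1L; r2 <- bins            # 1-based rows b-w..b-1
  c1 <- bins + 1L; c2 <- bins + w            # 1-based cols b..b+w-1
  means <- block_sum(r1, r2, c1, c2) / w^2
  med <- stats::median(means[means > 0])
  score <- rep(NA_real_, n)
  score[bins + 1L] <- ifelse(means > 0, log2(means / med), NA_real_)
  out <- tibble::tibble(bin = 0:(n - 1), score = score)
  attr(out, "window_bins") <- w
  out
}

# local minima of x (leftmost of plateaus) with prominence >= prom_min,
# prominence measured against the max of each flanking wing
find_minima <- function(x, prom_min, wing) {
  n <- length(x)
  xf <- ifelse(is.na(x), Inf, x)
  cand <- which(vapply(seq_len(n), function(b) {
    if (!is.finite(xf[b])) return(FALSE)
    left <- if (b > 1) xf[b - 1] else Inf
    right <- if (b < n) xf[b + 1] else Inf
    xf[b] < left && xf[b] <= right
  }, logical(1)))
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(b) {
    lw <- xf[max(1, b - wing):max(1, b - 1)]
    rw <- xf[min(n, b + 1):min(n, b + wing)]
    lw <- lw[is.finite(lw)]; rw <- rw[is.finite(rw)]
    if (!length(lw) || !length(rw)) return(0)
    min(max(lw), max(rw)) - xf[b]
  }, numeric(1))
  cand[prom >= prom_min]
}

#' Call domains by multi-scale insulation minima
#'
#' For each window size, boundaries are the local minima of the insulation
#' track with prominence at least `prominence_min`; candidate boundaries are
#' merged across windows (candidates within +/-1 bin collapse to the
#' deepest minimum, ties to the leftmost bin). Domains are the intervals
#' between consecutive merged boundaries. Edges supported only by the
#' finest window mark subTAD-level structure: leaf domains inside a span
#' between consecutive coarse-supported edges become level 1 and the span
#' itself is emitted as a level-0 parent domain.
#'
#' @param cm A [contact_matrix()].
#' @param windows Insulation window sizes in bins (default 4, 8, 16 =
#'   200/400/800 kb at 50-kb bins). Duplicates are ignored.
#' @param prominence_min Minimum insulation-minimum prominence (default 0.1).
#' @param smooth_sd Gaussian smoothing (sd in bins) applied to each
#'   insulation track before minima detection; suppresses counting-noise
#'   dips on domain-interior plateaus. 0 disables.
#' @return Tibble of domains: `chrom`, `start_bin`, `end_bin`, `start`,
#'   `end`, `level`. Attribute `edges` holds the merged boundary candidates
#'   (`bin`, `score`, `coarse`). If no boundary is found the whole
#'   chromosome is returned as one domain with a warning.
#' @export
call_domains <- function(cm, windows = c(4, 8, 16), prominence_min = 0.1,
                         smooth_sd = 1.5) {
  windows <- sort(unique(as.integer(windows)))
  n <- nrow(cm$mat)
  cand <- purrr::map_dfr(windows, function(w) {
    ins <- compute_insulation(cm, w)
    sc <- ins$score
    if (smooth_sd > 0) {
      half <- ceiling(3 * smooth_sd)
      kern <- stats::dnorm(-half:half, sd = smooth_sd)
      ok <- !is.na(sc)
      sm <- sc
      sm[ok] <- as.vector(smooth_columns(matrix(sc[ok], ncol = 1), kern))
      sc <- sm
    }
    mins <- find_minima(sc, prominence_min, wing = 2L * w)
    tibble::tibble(bin = ins$bin[mins], score = sc[mins], window = w)
  })
  if (!nrow(cand)) {
    warning("no boundaries found on ", cm$chrom, "; returning one domain")
    out <- tibble::tibble(chrom = cm$chrom, start_bin = 0L, end_bin = n,
                          level = 0L)
    return(finalize_domains2(out, cm))
  }
  cand <- cand[order(cand$bin, cand$score), ]
  # cluster candidate bins within +/-1 and keep the deepest (then leftmost)
  cand$grp <- cumsum(c(1, diff(cand$bin) > 1))
  edges <- dplyr::summarise(
    dplyr::group_by(cand, .data$grp),
    bin = .data$bin[order(.data$score, .data$bin)[1]],
    score = min(.data$score),
    coarse = any(.data$window > windows[1]) || length(windows) == 1,
    .groups = "drop")
  edges <- edges[order(edges$bin), c("bin", "score", "coarse")]
  b <- edges$bin
  starts <- c(0L, b); ends <- c(b, n)
  leaves <- tibble::tibble(chrom = cm$chrom, start_bin = starts,
                           end_bin = ends, level = 0L)
  # parents span consecutive coarse-supported edges (chromosome ends count)
  coarse_pos <- c(0L, b[edges$coarse], n)
  parents <- list()
  for (k in seq_len(length(coarse_pos) - 1)) {
    s <- coarse_pos[k]; e <- coarse_pos[k + 1]
    inside <- leaves$start_bin >= s & leaves$end_bin <= e
    if (sum(inside) >= 2) {
      leaves$level[inside] <- 1L
      parents[[length(parents) + 1]] <- tibble::tibble(
        chrom = cm$chrom, start_bin = s, end_bin = e, level = 0L)
    }
  }
  out <- dplyr::bind_rows(leaves, parents)
  out <- out[order(out$start_bin, -(out$end_bin - out$start_bin)), ]
  out <- finalize_domains2(out, cm)
  attr(out, "edges") <- edges
  out
}

finalize_domains2 <- function(d, cm) {
  d$start <- d$start_bin * cm$bin_width
  d$end <- d$end_bin * cm$bin_width
  d
}

#' Call dots (loops) with a local-background Poisson test
#'
#' Every pixel at distance `dmin_bins <= j - i <= dmax_bins` is tested
#' against a local expected value: lambda = expected(j - i) x (sum of
#' observed over the donut ring / sum of expected over the ring), where the
#' ring is the square of Chebyshev radius `donut_outer` minus the square of
#' radius `donut_inner` minus the pixel's row and column arms. The P value
#' is the Poisson upper tail P(X >= obs | lambda); BH correction runs over
#' all tested pixels. Pixels with `q <= q_max` and `obs/lambda >=
#' enrich_min` are clustered by 8-connectivity; each cluster's maximum-
#' observed pixel is flagged as the centroid.
#'
#' @param cm A [contact_matrix()] of counts.
#' @param exp_profile [compute_expected()] result.
#' @param dmin_bins,dmax_bins Tested distance range in bins (defaults 2, 60).
#' @param donut_outer,donut_inner Ring radii in bins (defaults 5, 2).
#' @param enrich_min Minimum observed/lambda (default 1.75).
#' @param q_max BH q-value threshold (default 0.10).
#' @param min_cluster_pixels Minimum significant pixels per reported cluster
#'   (default 2): a dot is a punctate group of adjacent enriched pixels, so
#'   isolated single-pixel fluctuations are dropped.
#' @return Tibble of significant pixels: `chrom`, `bin1`, `bin2`, `obs`,
#'   `lambda`, `enrichment`, `p`, `q`, `cluster`, `centroid`. Attribute
#'   `n_tested` and `n_skipped` record the test universe; pixels whose ring
#'   lies entirely off-matrix are skipped and counted.
#' @export
call_dots <- function(cm, exp_profile, dmin_bins = 2, dmax_bins = 60,
                      donut_outer = 5, donut_inner = 2,
                      enrich_min = 1.75, q_max = 0.10,
                      min_cluster_pixels = 2) {
  if (dmin_bins < 2) stop("dmin_bins must be >= 2")
  if (!(donut_outer > donut_inner && donut_inner >= 1)) {
    stop("need donut_outer > donut_inner >= 1")
  }
  m <- cm$mat
  n <- nrow(m)
  dmax_bins <- min(dmax_bins, n - 1L)
  pix <- purrr::map_dfr(dmin_bins:dmax_bins, function(d) {
    tibble::tibble(i = 1:(n - d), j = (1 + d):n, d = d)
  })
  offs <- expand.grid(di = -donut_outer:donut_outer,
                      dj = -donut_outer:donut_outer)
  offs <- offs[pmax(abs(offs$di), abs(offs$dj)) > donut_inner &
                 offs$di != 0 & offs$dj != 0, ]
  # four local backgrounds (donut ring, lower-left quadrant, horizontal and
  # vertical arms beyond the inner radius); lambda takes the strictest one,
  # so ordinary domain- and subTAD-corner enrichment is not called as a dot
  arms <- expand.grid(di = -donut_outer:donut_outer,
                      dj = -donut_outer:donut_outer)
  arms <- arms[(arms$di == 0 & abs(arms$dj) > donut_inner) |
                 (arms$dj == 0 & abs(arms$di) > donut_inner), ]
  arms$region <- ifelse(arms$di == 0, "h", "v")
  offs$region <- ifelse(offs$di > 0 & offs$dj < 0, "ll", "donut")
  all_offs <- rbind(offs[, c("di", "dj", "region")], arms)
  regions <- c("donut", "ll", "h", "v")
  obs_r <- exp_r <- lapply(regions, function(r) numeric(nrow(pix)))
  names(obs_r) <- names(exp_r) <- regions
  n_donut <- numeric(nrow(pix))
  for (k in seq_len(nrow(all_offs))) {
    ii <- pix$i + all_offs$di[k]
    jj <- pix$j + all_offs$dj[k]
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & ii != jj
    v <- m[cbind(ii[ok], jj[ok])]
    e <- expected_at(exp_profile, abs(jj[ok] - ii[ok]))
    r <- all_offs$region[k]
    obs_r[[r]][ok] <- obs_r[[r]][ok] + v
    exp_r[[r]][ok] <- exp_r[[r]][ok] + e
  }
  # the donut ring includes the lower-left quadrant cells as well
  obs_ring <- obs_r$donut + obs_r$ll
  exp_ring <- exp_r$donut + exp_r$ll
  usable <- exp_ring > 0
  n_skipped <- sum(!usable)
  pix <- pix[usable, ]
  obs <- m[cbind(pix$i, pix$j)]
  safe_ratio <- function(o, e) ifelse(e > 0, o / e, 0)
  ratio <- pmax(safe_ratio(obs_ring, exp_ring),
                safe_ratio(obs_r$ll, exp_r$ll),
                safe_ratio(obs_r$h, exp_r$h),
                safe_ratio(obs_r$v, exp_r$v))[usable]
  lambda <- expected_at(exp_profile, pix$d) * ratio
  p <- stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- which(q <= q_max & obs / lambda >= enrich_min & obs > 0)
  enr <- obs[sig] / lambda[sig]
  out <- tibble::tibble(
    chrom = cm$chrom,
    bin1 = pix$i[sig] - 1L, bin2 = pix$j[sig] - 1L,
    obs = obs[sig], lambda = lambda[sig],
    enrichment = enr,
    p = p[sig], q = q[sig])
  if (nrow(out)) {
    cl <- cluster_pixels(out$bin1, out$bin2)
    out$cluster <- cl
    keep <- cl %in% which(tabulate(cl) >= min_cluster_pixels)
    out <- out[keep, ]
    cl <- cl[keep]
    out$centroid <- FALSE
    for (g in unique(cl)) {
      rows <- which(cl == g)
      out$centroid[rows[order(-out$obs[rows], out$bin1[rows], out$bin2[rows])[1]]] <- TRUE
    }
  } else {
    out$cluster <- integer(0)
    out$centroid <- logical(0)
  }
  attr(out, "n_tested") <- sum(usable)
  attr(out, "n_skipped") <- n_skipped
  out
}

# union-find clustering of pixels under 8-connectivity
cluster_pixels <- function(b1, b2) {
  n <- length(b1)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  key <- function(a, b) a * 1e6 + b
  lookup <- stats::setNames(seq_len(n), key(b1, b2))
  for (idx in seq_len(n)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- lookup[as.character(key(b1[idx] + di, b2[idx] + dj))]
      if (!is.na(nb)) {
        ra <- find(idx); rb <- find(nb)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Flag corner-dot domains by co-registering dots with domain corners
#'
#' A domain is a corner-dot domain iff some dot has anchor 1 within
#' `tol_bins` of the domain's first bin and anchor 2 within `tol_bins` of
#' its last bin. Supporting dot ids are recorded.
#'
#' @param domains Domain tibble (from [call_domains()] or external calls).
#' @param dots Dot tibble with `bin1`, `bin2`; if a `centroid` column is
#'   present only centroid pixels are used (one per cluster).
#' @param tol_bins Corner tolerance in bins (default 2).
#' @return `domains` with `corner_dot` flag and `dot_ids` list-column.
#' @export
coregister_corner_dots <- function(domains, dots, tol_bins = 2) {
  if ("centroid" %in% names(dots)) dots <- dots[dots$centroid, ]
  dot_id <- seq_len(nrow(dots))
  domains$corner_dot <- FALSE
  domains$dot_ids <- vector("list", nrow(domains))
  for (k in seq_len(nrow(domains))) {
    same <- dots$chrom == domains$chrom[k]
    hit <- same &
      abs(dots$bin1 - domains$start_bin[k]) <= tol_bins &
      abs(dots$bin2 - (domains$end_bin[k] - 1L)) <= tol_bins
    if (any(hit)) {
      domains$corner_dot[k] <- TRUE
      domains$dot_ids[[k]] <- dot_id[hit]
    }
  }
  domains
}

#' Derive classified boundaries from (corner-dot-flagged) domains
#'
#' Boundary positions are the distinct interior domain-edge bins
#' (chromosome ends excluded; edges within +/-1 bin are merged to the
#' leftmost). Each boundary collects the domains of any level ending at it
#' (left flank) and starting at it (right flank, +/-1 bin) and is labelled
#' `double_dot` (corner-dot domain on both sides), `single_dot` (exactly
#' one side) or `dotless`. The longest flank on each side is recorded for
#' profile windows.
#'
#' @param domains Domain tibble with `corner_dot` flags (see
#'   [coregister_corner_dots()]); a missing `corner_dot` column is treated
#'   as all-FALSE.
#' @param insulation Optional insulation track (`bin`, `score`) used to fill
#'   the boundary `insulation` column.
#' @return Tibble: `chrom`, `bin`, `dot_status`, `left_start_bin`,
#'   `right_end_bin`, `n_left`, `n_right`, `insulation`.
#' @export
derive_boundaries <- function(domains, insulation = NULL) {
  if (!"corner_dot" %in% names(domains)) domains$corner_dot <- FALSE
  purrr::map_dfr(split(domains, domains$chrom), function(dom) {
    chrom_end <- max(dom$end_bin)
    edges <- sort(unique(c(dom$start_bin, dom$end_bin)))
    edges <- edges[edges > 0 & edges < chrom_end]
    if (!length(edges)) return(NULL)
    grp <- cumsum(c(1, diff(edges) > 1))
    reps <- tapply(edges, grp, min)  # leftmost of each +/-1 cluster
    purrr::map_dfr(as.integer(reps), function(b) {
      left <- dom[abs(dom$end_bin - b) <= 1, ]
      right <- dom[abs(dom$start_bin - b) <= 1, ]
      if (!nrow(left) || !nrow(right)) return(NULL)  # chromosome end
      ld <- any(left$corner_dot); rd <- any(right$corner_dot)
      tibble::tibble(
        chrom = dom$chrom[1], bin = b,
        dot_status = if (ld && rd) "double_dot" else
          if (ld || rd) "single_dot" else "dotless",
        left_start_bin = left$start_bin[which.max(b - left$start_bin)],
        right_end_bin = right$end_bin[which.max(right$end_bin - b)],
        n_left = nrow(left), n_right = nrow(right))
    })
  })
}

#' Aggregate peak analysis around classified boundaries
#'
#' For each boundary the O/E submatrix spanning its left and right flanking
#' domains is rescaled to `resize_bins x resize_bins` by bilinear
#' interpolation and averaged within each boundary class.
#'
#' @param cm A [contact_matrix()].
#' @param exp_profile [compute_expected()] result.
#' @param boundaries Boundary tibble with `left_start_bin`, `right_end_bin`
#'   and (optionally) `class_index`; absent classes give an empty map with
#'   n = 0, not an error.
#' @param resize_bins Output size per side (default 30).
#' @return An `apa_result`: list of per-class `list(map, n)`.
#' @export
aggregate_peak_analysis <- function(cm, exp_profile, boundaries,
                                    resize_bins = 30) {
  oe <- oe_matrix(cm, exp_profile)
  if (!nrow(boundaries)) {
    return(structure(list(all = list(map = matrix(NA_real_, 0, 0), n = 0L)),
                     class = "apa_result"))
  }
  classes <- if ("class_index" %in% names(boundaries)) {
    sort(unique(boundaries$class_index))
  } else NA
  res <- lapply(classes, function(cl) {
    rows <- if (is.na(cl[1])) boundaries else
      boundaries[boundaries$class_index == cl, ]
    rows <- rows[rows$chrom == cm$chrom, ]
    if (!nrow(rows)) return(list(map = matrix(NA_real_, 0, 0), n = 0L))
    maps <- purrr::pmap(rows, function(left_start_bin, right_end_bin, ...) {
      idx <- (left_start_bin + 1L):right_end_bin
      resize_matrix(oe[idx, idx, drop = FALSE], resize_bins)
    })
    list(map = Reduce(`+`, maps) / length(maps), n = length(maps))
  })
  names(res) <- if (is.na(classes[1])) "all" else paste0("class", classes)
  structure(res, class = "apa_result")
}

# bilinear resize of a matrix to k x k via separable linear interpolation
resize_matrix <- function(m, k) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (n1 == k && n2 == k) return(m)
  x1 <- if (n1 > 1) seq(1, n1, length.out = k) else rep(1, k)
  x2 <- if (n2 > 1) seq(1, n2, length.out = k) else rep(1, k)
  tmp <- apply(m, 2, function(col) {
    if (n1 == 1) rep(col, k) else stats::approx(seq_len(n1), col, xout = x1)$y
  })
  t(apply(tmp, 1, function(row) {
    if (n2 == 1) rep(row, k) else stats::approx(seq_len(n2), row, xout = x2)$y
  }))
}

#' Loops per boundary
#'
#' Counts, for every boundary, the dots with at least one anchor within
#' `win_bins` bins of the boundary position; each dot counts once per
#' boundary.
#'
#' @param boundaries Boundary tibble (`chrom`, `bin`).
#' @param dots Dot tibble (`chrom`, `bin1`, `bin2`); centroids only if the
#'   column is present.
#' @param win_bins Window half-width in bins (default 2).
#' @return `boundaries` with an `n_loops` column.
#' @export
loops_per_boundary <- function(boundaries, dots, win_bins = 2) {
  if ("centroid" %in% names(dots)) dots <- dots[dots$centroid, ]
  boundaries$n_loops <- vapply(seq_len(nrow(boundaries)), function(k) {
    same <- dots$chrom == boundaries$chrom[k]
    sum(same & (abs(dots$bin1 - boundaries$bin[k]) <= win_bins |
                  abs(dots$bin2 - boundaries$bin[k]) <= win_bins))
  }, numeric(1))
  boundaries
}

#' A/B compartments from the O/E correlation eigenvector
#'
#' The O/E matrix is converted to a Pearson correlation matrix whose leading
#' eigenvector partitions bins into two compartments. The sign is oriented
#' so that bins positively correlated with `reference` (e.g. active-gene
#' density) are labelled A; with a [repliseq16()] instead, A is the side
#' with the lower mean timing value; with neither, the first non-zero
#' entry is made positive (arbitrary but deterministic).
#'
#' @param cm A [contact_matrix()] (>= 10 bins).
#' @param exp_profile [compute_expected()] result.
#' @param reference Optional per-bin numeric reference track.
#' @param rs Optional [repliseq16()] for timing-based orientation.
#' @return Tibble `chrom`, `bin`, `eigen`, `label` (`A`/`B`/`NA`).
#' @export
compute_compartments <- function(cm, exp_profile, reference = NULL, rs = NULL) {
  n <- nrow(cm$mat)
  if (n < 10) stop("matrix must have >= 10 bins")
  oe <- oe_matrix(cm, exp_profile)
  oe[is.na(oe)] <- 0
  ok <- apply(oe, 1, stats::sd) > 0
  eig <- rep(NA_real_, n)
  if (sum(ok) >= 2) {
    cc <- stats::cor(oe[ok, ok, drop = FALSE])
    cc[is.na(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    eig[ok] <- ev
  }
  flip <- FALSE
  if (!is.null(reference)) {
    r <- stats::cor(eig, reference, use = "complete.obs")
    flip <- isTRUE(r < 0)
  } else if (!is.null(rs)) {
    tt <- compute_timing(if (rs_state(rs) == "raw") normalize_repliseq(rs) else rs)
    tt <- tt$timing[tt$chrom == cm$chrom]
    mean_pos <- mean(tt[which(eig > 0)], na.rm = TRUE)
    mean_neg <- mean(tt[which(eig < 0)], na.rm = TRUE)
    flip <- isTRUE(mean_pos > mean_neg)  # A should replicate earlier
  } else {
    nz <- which(!is.na(eig) & eig != 0)
    flip <- length(nz) > 0 && eig[nz[1]] < 0
  }
  if (flip) eig <- -eig
  label <- ifelse(is.na(eig) | eig == 0, NA_character_,
                  ifelse(eig > 0, "A", "B"))
  tibble::tibble(chrom = cm$chrom, bin = 0:(n - 1), eigen = eig, label = label)
}
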