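toy_compartments <- function(labels, chrom = "t") {
  tibble::tibble(chrom = chrom, bin = seq_along(labels) - 1L, label = labels)
}

toy_izs <- function(apex, width, timing = "early", chrom = "t", bw = 5e4) {
  h <- (width - 1) %/% 2
  tibble::tibble(chrom = chrom,
                 start = (apex - h) * bw, end = (apex + h + 1) * bw,
                 start_bin = as.integer(apex - h),
                 end_bin = as.integer(apex + h + 1),
                 apex_bin = as.integer(apex),
                 width_bp = width * bw, timing_class = timing)
}

test_that("matched nulls preserve widths exactly and honor compartment labels", {
  g <- bin_grid(c(t = 100 * 5e4))
  comp <- toy_compartments(rep(c("A", "B"), each = 50))
  izs <- dplyr::bind_rows(toy_izs(10, 3), toy_izs(70, 5, "late"))
  nulls <- sample_matched_nulls(izs, comp, g, R = 50, seed = 9)
  expect_equal(nrow(nulls), 100)
  # width multiset preserved in every replicate
  for (r in 1:50) {
    expect_setequal(nulls$width_bins[nulls$replicate == r], c(3, 5))
  }
  # placements stay within label-compatible territory
  labs <- rep(c("A", "B"), each = 50)
  for (k in seq_len(nrow(nulls))) {
    w <- nulls$width_bins[k]
    win <- labs[(nulls$start_bin[k] + 1):(nulls$start_bin[k] + w)]
    expect_equal(names(which.max(table(win))), nulls$label[k])
  }
  # determinism
  expect_identical(sample_matched_nulls(izs, comp, g, R = 50, seed = 9), nulls)
  expect_false(identical(sample_matched_nulls(izs, comp, g, R = 50, seed = 10),
                         nulls))
})

test_that("degenerate matching: all-A genome accepts any position; unique windows pin the null", {
  g <- bin_grid(c(t = 60 * 5e4))
  compA <- toy_compartments(rep("A", 60))
  nulls <- sample_matched_nulls(toy_izs(30, 3), compA, g, R = 100, seed = 1)
  expect_true(all(nulls$width_bins == 3))
  expect_gt(length(unique(nulls$start_bin)), 10)

  # exactly one eligible window: a single B bin with width-1 intervals
  labs <- rep("A", 60); labs[21] <- "B"     # bin 20 (0-based)
  compB <- toy_compartments(labs)
  izB <- toy_izs(20, 1); izB$timing_class <- "late"
  nullsB <- sample_matched_nulls(izB, compB, g, R = 25, seed = 4)
  expect_true(all(nullsB$start_bin == 20))
  expect_equal(unique(nullsB$label), "B")

  # impossible matching errors, naming the IZ: the only B territory sits on
  # a non-autosome chromosome, and sampling is restricted to autosomes
  gx <- bin_grid(c(auto = 30 * 5e4, chrX = 30 * 5e4),
                 autosome = c(TRUE, FALSE))
  compx <- dplyr::bind_rows(toy_compartments(rep("A", 30), "auto"),
                            toy_compartments(rep("B", 30), "chrX"))
  izx <- toy_izs(10, 3, chrom = "chrX")
  expect_error(sample_matched_nulls(izx, compx, gx, R = 5, seed = 1),
               "no eligible.*label B")
})

test_that("nulls exclude non-autosome chromosomes", {
  g <- bin_grid(c(auto = 50 * 5e4, chrX = 50 * 5e4),
                autosome = c(TRUE, FALSE))
  comp <- dplyr::bind_rows(toy_compartments(rep("A", 50), "auto"),
                           toy_compartments(rep("A", 50), "chrX"))
  izs <- toy_izs(10, 3, chrom = "auto")
  nulls <- sample_matched_nulls(izs, comp, g, R = 200, seed = 2)
  expect_true(all(nulls$chrom == "auto"))
})

test_that("colocalization counting matches brute-force enumeration", {
  bnd <- tibble::tibble(chrom = "t", bin = c(5L, 20L, 21L, 40L))
  # IZ exactly covering a boundary bin counts; two bins away does not
  expect_equal(colocalization_count(toy_izs(5, 1), bnd, win_bins = 1), 1)
  expect_equal(colocalization_count(toy_izs(42, 1), bnd, win_bins = 1), 0)
  expect_equal(colocalization_count(toy_izs(41, 1), bnd, win_bins = 1), 1)

  # randomized toys against the brute-force oracle
  set.seed(11)
  for (trial in 1:300) {
    nb <- sample(3:8, 1)
    bb <- sort(sample(0:80, nb))
    ni <- sample(2:20, 1)
    apex <- sample(2:78, ni, replace = TRUE)
    w <- sample(c(1, 3, 5), ni, replace = TRUE)
    izs <- dplyr::bind_rows(lapply(seq_len(ni), function(k) toy_izs(apex[k], w[k])))
    win <- sample(0:2, 1)
    got <- colocalization_count(izs, tibble::tibble(chrom = "t", bin = bb),
                                win_bins = win)
    want <- brute_coloc(izs$start_bin, izs$end_bin, bb, win)
    expect_equal(got, want)
  }
})

test_that("empirical P follows the add-one formula with hand-checked cases", {
  make_nulls <- function(counts_by_replicate, width = 3) {
    # place one null interval per replicate either on or off the boundary
    R <- length(counts_by_replicate)
    tb <- dplyr::bind_rows(lapply(seq_len(R), function(r) {
      n_on <- counts_by_replicate[r]
      apexes <- c(rep(50, n_on), rep(10, 5 - n_on))  # boundary at bin 50
      tibble::tibble(replicate = r, iz_id = 1:5, chrom = "t",
                     start_bin = apexes - 1L, end_bin = apexes + 2L,
                     width_bins = width, label = "A", timing_class = "early")
    }))
    attr(tb, "R") <- R; attr(tb, "seed") <- 0L
    class(tb) <- c("null_iz_sets", class(tb))
    tb
  }
  bnd <- tibble::tibble(chrom = "t", bin = 50L, class_index = 1L)
  # observed: 3 of 5 IZs at the boundary
  izs <- dplyr::bind_rows(lapply(c(50, 50, 50, 10, 10), function(a) toy_izs(a, 3)))
  nulls <- make_nulls(c(0, 1, 2, 3, 4))
  enr <- empirical_enrichment(izs, bnd, nulls, win_bins = 1)
  row <- tidy(enr)[tidy(enr)$timing_class == "early", ]
  expect_equal(row$x_obs, 3)
  expect_equal(row$p_right, (1 + 2) / 6)   # nulls {3, 4} >= 3
  expect_equal(row$p_left, (1 + 4) / 6)

  # X_obs beating every null -> the formula minimum
  nulls0 <- make_nulls(rep(0, 999))
  enr0 <- empirical_enrichment(izs, bnd, nulls0, win_bins = 1)
  expect_equal(tidy(enr0)$p_right[tidy(enr0)$timing_class == "early"], 1 / 1000)

  # X_obs = 0 -> right P is 1
  izs_off <- dplyr::bind_rows(lapply(rep(10, 5), function(a) toy_izs(a, 3)))
  enr_off <- empirical_enrichment(izs_off, bnd, nulls, win_bins = 1)
  expect_equal(tidy(enr_off)$p_right[tidy(enr_off)$timing_class == "early"], 1)

  # monotonicity: raising X_obs with fixed nulls never raises P_right
  ps <- vapply(0:5, function(x) {
    izx <- dplyr::bind_rows(lapply(c(rep(50, x), rep(10, 5 - x)),
                                   function(a) toy_izs(a, 3)))
    e <- empirical_enrichment(izx, bnd, nulls, win_bins = 1)
    tidy(e)$p_right[tidy(e)$timing_class == "early"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))

  expect_error(empirical_enrichment(izs, bnd, izs, win_bins = 1), "replicate")

  gl <- glance(enr)
  expect_equal(gl$r, 5)
  expect_equal(gl$n_cells, 3)
})

test_that("fixed-window aggregate profiles have the documented geometry", {
  rs <- small_repliseq()
  bnd <- tibble::tibble(chrom = "chrA", bin = c(100L, 200L))
  prof <- aggregate_repliseq_profile(bnd, rs, flank_bins = 15)
  expect_equal(dim(prof$mat), c(16, 31))
  expect_equal(prof$n, 2)

  # single boundary -> its own window
  p1 <- aggregate_repliseq_profile(bnd[1, ], rs, flank_bins = 3)
  win <- t(rs_signal(rs)[98:104, ])
  expect_equal(p1$mat, win, ignore_attr = TRUE)

  # spatially uniform signal -> identical columns
  bins <- tibble::tibble(chrom = "t", start = (0:49) * 5e4, end = (1:50) * 5e4)
  sigu <- matrix(rep(c(1:16), each = 50), 50, 16)
  rsu <- repliseq16(bins, sigu, state = "raw")
  pu <- aggregate_repliseq_profile(tibble::tibble(chrom = "t", bin = 25L),
                                   rsu, flank_bins = 5)
  expect_true(all(apply(pu$mat, 1, function(x) diff(range(x))) == 0))

  # truncated windows are excluded and counted
  pt <- aggregate_repliseq_profile(tibble::tibble(chrom = "t", bin = 2L),
                                   rsu, flank_bins = 5)
  expect_equal(pt$n, 0)
  expect_equal(pt$n_excluded, 1)
})

test_that("length-normalized profiles interpolate flanking domains correctly", {
  bins <- tibble::tibble(chrom = "t", start = (0:49) * 5e4, end = (1:50) * 5e4)
  # fraction-independent linear ramp along the genome
  ramp <- matrix(rep(1:50, 16), 50, 16)
  rsr <- repliseq16(bins, ramp, state = "raw")
  # left domain exactly K bins, right exactly K + 1 bins -> identity window
  K <- 4
  bnd <- tibble::tibble(chrom = "t", bin = 20L,
                        left_start_bin = 16L, right_end_bin = 25L)
  prof <- length_normalized_profile(bnd, rsr, K = K)
  expect_equal(prof$mat[1, ], as.numeric(17:25), ignore_attr = TRUE)

  # a 2K-bin ramp domain resampled to K matches closed-form interpolation
  bnd2 <- tibble::tibble(chrom = "t", bin = 24L,
                         left_start_bin = 16L, right_end_bin = 33L)
  prof2 <- length_normalized_profile(bnd2, rsr, K = K)
  left_vals <- ramp[17:24, 1]   # bins 16..23
  want_left <- stats::approx(seq_along(left_vals), left_vals,
                             xout = seq(1, 8, length.out = K))$y
  expect_equal(prof2$mat[1, 1:K], want_left, ignore_attr = TRUE)

  # uniform signal -> flat profile; missing flank -> skipped
  flat <- repliseq16(bins, matrix(3, 50, 16), state = "raw")
  pf <- length_normalized_profile(bnd, flat, K = 3)
  expect_true(all(pf$mat == 3))
  pskip <- length_normalized_profile(
    tibble::tibble(chrom = "t", bin = 20L, left_start_bin = NA_integer_,
                   right_end_bin = 25L), flat, K = 3)
  expect_equal(pskip$n, 0)
  expect_equal(pskip$n_excluded, 1)
})

test_that("Mann-Whitney U matches full enumeration and is symmetric", {
  out <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(out$u, 0, ignore_attr = TRUE)
  expect_equal(out$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(out$method, "exact")

  # identical samples: P = 1 within tolerance; swapping is symmetric
  x <- c(1.2, 3.4, 5.6)
  expect_equal(mann_whitney_u(x, x)$p_value, 1, tolerance = 0.01)
  a <- stats::runif(6); b <- stats::runif(5)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)

  # full enumeration oracle for all partitions with n_x + n_y <= 8
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(pooled); m <- length(x)
    u_of <- function(idx) {
      r <- rank(pooled)
      sum(r[idx]) - m * (m + 1) / 2
    }
    u_obs <- u_of(seq_len(m))
    combos <- utils::combn(n, m)
    us <- apply(combos, 2, u_of)
    mu <- m * (length(y)) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  }
  set.seed(3)
  for (trial in 1:40) {
    n_tot <- sample(3:8, 1)
    m <- sample(1:(n_tot - 1), 1)
    vals <- sample(seq(0.1, 50, by = 0.7), n_tot)  # distinct -> no ties
    x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, enum_p(x, y), tolerance = 1e-10)
  }

  # ties force the corrected normal approximation
  expect_equal(mann_whitney_u(c(1, 1, 2), c(1, 2, 2))$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("condition comparison reports identity and planted direction", {
  bnd <- tibble::tibble(chrom = "t", bin = c(10L, 30L, 50L), class_index = 1L)
  izs <- dplyr::bind_rows(lapply(c(10, 30, 50), function(a) toy_izs(a, 3)))
  izs$width_bp <- c(3, 5, 7) * 5e4
  same <- compare_iz_sets(izs, izs, bnd, bin_width = 5e4)
  row <- same[same$class_index == 1 & same$timing_class == "early", ]
  expect_equal(row$median_width_a, row$median_width_b)
  expect_equal(row$p_width, 1, tolerance = 0.05)

  doubled <- izs; doubled$width_bp <- izs$width_bp * 2
  cmp <- compare_iz_sets(izs, doubled, bnd, bin_width = 5e4)
  row2 <- cmp[cmp$class_index == 1 & cmp$timing_class == "early", ]
  expect_equal(row2$median_width_b / row2$median_width_a, 2)
  expect_equal(row2$direction, "B>A")

  # an arm with < 2 IZs leaves P undefined but reports widths
  cmp1 <- compare_iz_sets(izs[1, ], izs, bnd, bin_width = 5e4)
  r1 <- cmp1[cmp1$class_index == 1 & cmp1$timing_class == "early", ]
  expect_true(is.na(r1$p_width))
  expect_equal(r1$n_a, 1)
})
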