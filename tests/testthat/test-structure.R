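toy_grid <- function(n, chrom = "t") {
  g <- n * 50000; names(g) <- chrom
  bin_grid(g)
}

test_that("expected profile is the per-distance mean, with hand-checked values", {
  m <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3)
  cm <- contact_matrix(m, "t", toy_grid(3))
  ex <- compute_expected(cm, min_obs = 1)
  expect_equal(ex$expected[ex$distance == 1], mean(c(2, 6)))
  expect_equal(ex$expected[ex$distance == 0], 0)
  expect_equal(ex$expected[ex$distance == 2], 4)

  cm2 <- contact_matrix(matrix(7, 20, 20), "t", toy_grid(20))
  ex2 <- compute_expected(cm2, min_obs = 1)
  expect_true(all(ex2$expected == 7))
  expect_identical(compute_expected(cm2, min_obs = 1), ex2)

  # long-range pooling pools sums/counts, never invents negative values
  cm3 <- small_matrix()
  ex3 <- compute_expected(cm3)
  expect_true(all(ex3$expected >= 0))
  expect_true(any(ex3$pooled))
  expect_false(any(ex3$pooled & ex3$n >= 100))
})

test_that("insulation is flat on uniform maps, dips at block junctions, ignores scaling", {
  cm <- contact_matrix(matrix(5, 40, 40), "t", toy_grid(40))
  ins <- compute_insulation(cm, 4)
  expect_true(all(abs(ins$score[!is.na(ins$score)]) < 1e-9))
  expect_true(all(is.na(ins$score[c(1:4, 38:40)])))

  # two-block matrix: brute-force check that the junction is the
  # unique minimum over all defined bins
  n <- 40
  blocks <- matrix(1, n, n)
  blocks[1:20, 1:20] <- 8; blocks[21:40, 21:40] <- 8
  diag(blocks) <- 8
  cmb <- contact_matrix(blocks, "t", toy_grid(n))
  insb <- compute_insulation(cmb, 4)
  brute <- vapply(4:(n - 4), function(b) {
    mean(blocks[(b - 4 + 1):b, (b + 1):(b + 4)])
  }, numeric(1))
  expect_equal(which.min(insb$score[5:(n - 4 + 1)]), which.min(brute))
  expect_equal(insb$bin[which.min(insb$score)], 20)

  cmk <- contact_matrix(blocks * 13, "t", toy_grid(n))
  insk <- compute_insulation(cmk, 4)
  expect_equal(insk$score, insb$score, tolerance = 1e-12)

  expect_error(compute_insulation(cmb, 30), "half")
  expect_error(compute_insulation(cmb, 1), ">= 2")
})

test_that("domain calling recovers planted structure and degrades gracefully", {
  truth <- small_truth()
  doms <- call_domains(small_matrix())
  edges <- attr(doms, "edges")
  truthb <- truth$boundaries$bin
  recall <- mean(vapply(truthb, function(b) any(abs(edges$bin - b) <= 1), logical(1)))
  precision <- mean(vapply(edges$bin, function(b) any(abs(truthb - b) <= 1), logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # leaf domains partition; parents nest
  leaves <- doms[doms$level == 1 | !vapply(seq_len(nrow(doms)), function(i) {
    any(doms$start_bin <= doms$start_bin[i] & doms$end_bin >= doms$end_bin[i] &
          seq_len(nrow(doms)) != i)
  }, logical(1)), ]

  cmu <- contact_matrix(matrix(3, 50, 50), "t", toy_grid(50))
  expect_warning(du <- call_domains(cmu), "no boundaries")
  expect_equal(nrow(du), 1)
  expect_equal(du$end_bin - du$start_bin, 50)

  dd1 <- call_domains(small_matrix(), windows = c(4, 8, 16))
  dd2 <- call_domains(small_matrix(), windows = c(4, 4, 8, 16, 16))
  expect_identical(dd1$start_bin, dd2$start_bin)
})

test_that("dot P values match the Poisson tail oracle to 1e-10 on a toy map", {
  set.seed(42)
  n <- 50
  lam <- 30 * (1 + abs(outer(1:n, 1:n, `-`)))^-1
  m <- matrix(rpois(n * n, lam), n)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m[3, 10] <- m[10, 3] <- 60  # a planted spike
  cm <- contact_matrix(m, "t", toy_grid(n))
  ex <- compute_expected(cm, min_obs = 1)
  dots <- call_dots(cm, ex, dmin_bins = 2, dmax_bins = 20, q_max = 1,
                    enrich_min = 0, min_cluster_pixels = 1)
  # brute-force oracle: direct Poisson summation
  oracle <- vapply(seq_len(nrow(dots)), function(k) {
    obs <- dots$obs[k]; lambda <- dots$lambda[k]
    1 - sum(exp(-lambda) * lambda^(0:(obs - 1)) / factorial(0:(obs - 1)))
  }, numeric(1))
  ok <- dots$obs <= 150  # factorial overflow guard for the oracle itself
  expect_lt(max(abs(dots$p[ok] - oracle[ok])), 1e-10)

  # obs = 0 -> upper tail is 1 (never significant)
  expect_true(all(dots$obs > 0))
})

test_that("planted dots are recovered and clusters carry one centroid each", {
  truth <- small_truth()
  dots <- call_dots(small_matrix(), small_expected())
  cent <- dots[dots$centroid, ]
  tl <- truth$loops
  recall <- mean(vapply(seq_len(nrow(tl)), function(k) {
    any(abs(cent$bin1 - tl$bin1[k]) <= 2 & abs(cent$bin2 - tl$bin2[k]) <= 2)
  }, logical(1)))
  expect_gte(recall, 0.9)
  expect_equal(sum(dots$centroid), length(unique(dots$cluster)))
  expect_true(all(dots$p > 0 & dots$p <= 1))
  expect_true(all(dots$q <= 0.1))
  expect_true(all(dots$enrichment >= 1.75))
  expect_true(all(dots$bin2 - dots$bin1 >= 2))
})

test_that("false-discovery control holds on a structureless map", {
  set.seed(99)
  n <- 300
  lam <- 100 * (1 + abs(outer(1:n, 1:n, `-`)))^-1
  m <- matrix(rpois(n * n, lam), n)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  cm <- contact_matrix(m, "null", toy_grid(n, "null"))
  dots <- call_dots(cm, compute_expected(cm))
  n_tested <- attr(dots, "n_tested")
  expect_lte(nrow(dots), 0.001 * n_tested)
})

test_that("corner-dot co-registration follows the tolerance exactly", {
  g <- toy_grid(100)
  doms <- tibble::tibble(chrom = "t", start_bin = c(10L, 40L),
                         end_bin = c(40L, 70L), level = 0L)
  dots <- tibble::tibble(chrom = "t", bin1 = c(10, 43), bin2 = c(39, 69))
  out <- coregister_corner_dots(doms, dots, tol_bins = 0)
  expect_equal(out$corner_dot, c(TRUE, FALSE))
  out2 <- coregister_corner_dots(doms, dots, tol_bins = 2)
  expect_equal(out2$corner_dot, c(TRUE, FALSE))  # anchor 3 bins off start
  out3 <- coregister_corner_dots(doms, dots, tol_bins = 3)
  expect_equal(out3$corner_dot, c(TRUE, TRUE))
  expect_equal(out$dot_ids[[1]], 1)

  truth <- small_truth()
  dd <- coregister_corner_dots(call_domains(small_matrix()),
                               call_dots(small_matrix(), small_expected()),
                               tol_bins = 2)
  dotted <- truth$domains[truth$domains$dotted, ]
  acc <- mean(vapply(seq_len(nrow(dotted)), function(k) {
    any(dd$corner_dot & abs(dd$start_bin - dotted$start_bin[k]) <= 2 &
          abs(dd$end_bin - dotted$end_bin[k]) <= 2)
  }, logical(1)))
  expect_gte(acc, 0.95)
})

test_that("boundary derivation resolves flanks, dot status and nested edges", {
  doms <- tibble::tibble(
    chrom = "t",
    start_bin = c(0L, 20L, 50L),
    end_bin = c(20L, 50L, 80L),
    level = 0L,
    corner_dot = c(TRUE, TRUE, FALSE))
  b <- derive_boundaries(doms)
  expect_equal(b$bin, c(20, 50))
  expect_equal(b$dot_status, c("double_dot", "single_dot"))
  expect_equal(b$left_start_bin, c(0, 20))
  expect_equal(b$right_end_bin, c(50, 80))

  # nested fixture: a parent edge 1 bin off the leaf edge merges into one
  # boundary with both flanks' domains attached (hand-resolved)
  nested <- tibble::tibble(
    chrom = "t",
    start_bin = c(0L, 20L, 0L, 21L),
    end_bin = c(20L, 40L, 21L, 60L),
    level = c(1L, 1L, 0L, 0L),
    corner_dot = c(FALSE, TRUE, FALSE, FALSE))
  bn <- derive_boundaries(nested)
  expect_equal(nrow(bn), 1)
  expect_equal(bn$bin, 20)         # leftmost representative of {20, 21}
  expect_equal(bn$n_left, 2)       # leaf [0,20) and parent [0,21)
  expect_equal(bn$n_right, 2)      # leaf [20,40) and parent [21,60)
  expect_equal(bn$dot_status, "single_dot")

  # dotless both sides
  plain <- doms; plain$corner_dot <- FALSE
  expect_equal(derive_boundaries(plain)$dot_status, c("dotless", "dotless"))
})

test_that("aggregate peak analysis resizes, averages, and shows corner enrichment", {
  # uniform matrix -> O/E aggregate of 1 everywhere
  n <- 60
  cm <- contact_matrix(matrix(4, n, n), "t", toy_grid(n))
  ex <- compute_expected(cm, min_obs = 1)
  bnd <- tibble::tibble(chrom = "t", bin = 30L, left_start_bin = 15L,
                        right_end_bin = 45L, class_index = 1L)
  apa <- aggregate_peak_analysis(cm, ex, bnd, resize_bins = 30)
  expect_equal(dim(apa$class1$map), c(30, 30))
  expect_true(all(abs(apa$class1$map - 1) < 1e-12))
  expect_equal(apa$class1$n, 1)

  # identity resize: window already resize_bins wide equals its own O/E
  set.seed(1)
  m <- matrix(rpois(n * n, 10), n); m[upper.tri(m)] <- t(m)[upper.tri(m)]
  cm2 <- contact_matrix(m, "t", toy_grid(n))
  ex2 <- compute_expected(cm2, min_obs = 1)
  oe <- oe_matrix(cm2, ex2)
  apa2 <- aggregate_peak_analysis(cm2, ex2, bnd, resize_bins = 30)
  expect_equal(apa2$class1$map, oe[16:45, 16:45], ignore_attr = TRUE)

  # empty class: empty map with n = 0, not an exception
  bnd0 <- bnd[0, ]
  apa0 <- aggregate_peak_analysis(cm2, ex2, bnd0, resize_bins = 10)
  expect_equal(apa0$all$n, 0)

  # synthetic class-1 aggregate: corner pixels beat off-corner flanks
  truth <- small_truth()
  doms <- coregister_corner_dots(call_domains(small_matrix()),
                                 call_dots(small_matrix(), small_expected()), 2)
  bset <- derive_boundaries(doms)
  bset <- dplyr::inner_join(bset,
                            truth$boundaries[, c("bin", "class_index")],
                            by = "bin")
  apa1 <- aggregate_peak_analysis(small_matrix(), small_expected(),
                                  bset[bset$class_index == 1, ],
                                  resize_bins = 30)
  mp <- apa1$class1$map
  # the flanking domains' corner dots sit at (domain start, boundary) and
  # (boundary, domain end): rows 1-2 x center columns, center rows x cols 29-30
  corner <- mean(c(mp[1:2, 14:16], mp[14:16, 29:30]))
  flank <- mean(c(mp[1:2, 20:24], mp[7:11, 29:30]))
  expect_gt(corner, flank)
})

test_that("loops per boundary counts dots once within the window", {
  bnd <- tibble::tibble(chrom = "t", bin = c(10L, 30L, 50L, 70L, 90L))
  dots <- tibble::tibble(chrom = "t",
                         bin1 = c(9, 10, 28, 49),
                         bin2 = c(11, 40, 52, 51))
  out <- loops_per_boundary(bnd, dots, win_bins = 2)
  # hand enumeration: b10 <- dots 1 (both anchors) and 2 (anchor1);
  # b30 <- dots 3 (bin1=28); b50 <- dots 3 (bin2=52) and 4 (both anchors)
  expect_equal(out$n_loops, c(2, 1, 2, 0, 0))
  none <- loops_per_boundary(bnd, dots[0, ], win_bins = 2)
  expect_equal(none$n_loops, rep(0, 5))
})

test_that("compartment eigenvector recovers planted blocks and obeys orientation", {
  set.seed(7)
  n <- 80
  lab <- rep(rep(c("A", "B"), 4), each = 10)
  lam <- 50 * (1 + abs(outer(1:n, 1:n, `-`)))^-1
  same <- outer(lab, lab, `==`)
  lam[same] <- lam[same] * 2
  m <- matrix(rpois(n * n, lam), n); m[upper.tri(m)] <- t(m)[upper.tri(m)]
  cm <- contact_matrix(m, "t", toy_grid(n))
  ex <- compute_expected(cm, min_obs = 1)
  ref <- ifelse(lab == "A", 1, 0)
  cc <- compute_compartments(cm, ex, reference = ref)
  expect_equal(cc$label, lab)
  cc_flip <- compute_compartments(cm, ex, reference = -ref)
  expect_equal(cc_flip$label, ifelse(lab == "A", "B", "A"))
  expect_identical(compute_compartments(cm, ex, reference = ref), cc)
  expect_error(compute_compartments(
    contact_matrix(matrix(1, 5, 5), "t", toy_grid(5)), ex), ">= 10")
})
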