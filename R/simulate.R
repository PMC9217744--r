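#' Configuration for the synthetic genome generator
#'
#' Bundles every knob of the planted-architecture simulation: chromosome
#' sizes, per-class boundary counts, domain geometry, IZ planting
#' probabilities per (boundary class, timing class), replication-timing
#' field geometry, and observation-noise depths. Defaults describe the
#' study conditions exercised throughout the package: a 50-Mb chromosome at
#' 50-kb bins, sixteen boundaries per class, strong early-IZ planting at
#' class-1 boundaries (0.7) against a 0.05 background at other classes, and
#' late-IZ planting concentrated at weak dotless boundaries.
#'
#' @param chrom_lengths Named bp lengths; bin width must divide each.
#' @param bin_width Bin width in bp.
#' @param autosome Logical, recycled over chromosomes.
#' @param boundaries_per_class Integer vector length 6: requested boundaries
#'   for classes 1-6 (met exactly or the generator errors).
#' @param domain_size_bins Length-2 range of leaf-domain sizes in bins.
#' @param nesting_prob Probability that two adjacent leaf domains are
#'   covered by a parent TAD (children become level-1 subTADs).
#' @param p_iz 6 x 3 matrix of IZ planting probabilities, rows = classes
#'   1-6, columns = `early`, `early_mid`, `late`; row sums must be <= 1
#'   (at most one IZ is planted per boundary).
#' @param background_iz_per_mb Poisson rate of off-boundary IZs per Mb.
#' @param iz_width_bins Named list of odd candidate widths (bins) per timing
#'   class.
#' @param apex_timing Named list of length-2 timing (fraction) ranges for IZ
#'   apexes per timing class.
#' @param iz_edge_rise Fractions by which timing rises from apex to IZ edge
#'   (the within-IZ ramp).
#' @param iz_shoulder_rise,iz_shoulder_bins Just outside the IZ edge, timing
#'   climbs steeply (`iz_shoulder_rise` fractions/bin over
#'   `iz_shoulder_bins` bins) before settling to the fork slope, making the
#'   IZ extent sharply delimited in the timing field.
#' @param fork_slope_per_mb Replication-fork slope outside IZs
#'   (fractions/Mb, default 4), capped at fraction 16.
#' @param fraction_spread SD (in fraction units) of the Gaussian spread of
#'   signal across fractions around the true timing.
#' @param repliseq_depth Expected total Repli-seq counts per bin.
#' @param contact_depth Expected contact count at distance 0.
#' @param alpha Contact-decay exponent.
#' @param domain_mult,dot_mult,compartment_mult Enrichment multipliers (> 0)
#'   for shared-domain pixels, corner-dot pixels, and same-compartment
#'   long-range pixels.
#' @param dot_radius_bins Chebyshev radius of the corner-dot focal block.
#' @param compartment_cutoff_bins Minimum distance for the compartment
#'   multiplier to apply.
#' @param compartment_block_bins Length-2 range of A/B block sizes in bins.
#' @param complex_sites,tandem_sites Ranges of CTCF+cohesin site counts
#'   planted at complex / tandem boundaries.
#' @param p_single At tandem_single boundaries, probability of a single site
#'   rather than a same-strand tandem array.
#' @param cohesin_only_rate Poisson mean of cohesin-only sites per boundary.
#' @param decoy_per_mb Rate of scattered decoy CTCF+cohesin sites
#'   (uniform position and strand) emitted by [simulate_binding_sites()].
#' @param extra_loops_per_class1 Gained long-range loops planted per class-1
#'   boundary (0 in the wild-type condition; raise to emulate a
#'   WAPL-depletion analogue).
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    chrom_lengths = c(chrSim = 50e6),
    bin_width = 50000,
    autosome = TRUE,
    boundaries_per_class = rep(16L, 6),
    domain_size_bins = c(8, 20),
    nesting_prob = 0.3,
    p_iz = default_p_iz(),
    background_iz_per_mb = 0.05,
    iz_width_bins = list(early = 3, early_mid = c(3, 5), late = c(5, 7)),
    apex_timing = list(early = c(2.5, 4.3), early_mid = c(6.5, 8.3),
                       late = c(11.5, 13.3)),
    iz_edge_rise = 1.0,
    iz_shoulder_rise = 1.5,
    iz_shoulder_bins = 2,
    fork_slope_per_mb = 4,
    fraction_spread = 1.5,
    repliseq_depth = 200,
    contact_depth = 100,
    alpha = 1,
    domain_mult = 2,
    dot_mult = 4,
    dot_radius_bins = 1,
    compartment_mult = 1.5,
    compartment_cutoff_bins = 40,
    compartment_block_bins = c(20, 40),
    complex_sites = c(2, 4),
    tandem_sites = c(2, 3),
    p_single = 0.5,
    cohesin_only_rate = 1,
    decoy_per_mb = 0.2,
    extra_loops_per_class1 = 0,
    seed = 1L) {
  cfg <- as.list(environment())
  if (any(chrom_lengths %% bin_width != 0)) {
    stop("bin_width must divide every chromosome length")
  }
  if (length(boundaries_per_class) != 6 || any(boundaries_per_class < 0)) {
    stop("boundaries_per_class must be 6 non-negative counts")
  }
  p_iz <- as.matrix(p_iz)
  if (!all(dim(p_iz) == c(6, 3))) stop("p_iz must be 6 x 3")
  if (any(p_iz < 0 | p_iz > 1)) stop("p_iz entries must lie in [0, 1]")
  if (any(rowSums(p_iz) > 1 + 1e-12)) stop("p_iz row sums must be <= 1")
  colnames(p_iz) <- c("early", "early_mid", "late")
  cfg$p_iz <- p_iz
  for (m in c("domain_mult", "dot_mult", "compartment_mult")) {
    if (cfg[[m]] <= 0) stop(m, " must be > 0")
  }
  if (diff(range(domain_size_bins)) < 0 || min(domain_size_bins) < 2) {
    stop("domain_size_bins must be an increasing range >= 2")
  }
  cfg$boundaries_per_class <- as.integer(boundaries_per_class)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "simulation_config"
  cfg
}

#' @rdname simulation_config
#' @export
default_p_iz <- function() {
  matrix(c(0.70, 0.30, 0.10, 0.05, 0.05, 0.05,   # early
           0.10, 0.10, 0.05, 0.05, 0.10, 0.10,   # early_mid
           0.02, 0.05, 0.05, 0.10, 0.30, 0.40),  # late
         nrow = 6, dimnames = list(NULL, c("early", "early_mid", "late")))
}

orientation_of_class <- function(class_index) {
  c("complex", "tandem_single", "none")[(class_index - 1L) %% 3L + 1L]
}

#' Simulate planted genome architecture
#'
#' Lays out leaf domains tiling each chromosome, places the requested number
#' of boundaries of each of the six classes (classes 1-3 corner-dot,
#' 4-6 dotless), plants corner-dot loops on the flanking domains of
#' dot-class boundaries, CTCF+cohesin motif arrays matching each class's
#' orientation grammar, alternating A/B compartment blocks, and IZs at
#' boundaries with the configured per-(class, timing) probabilities plus a
#' Poisson background away from boundaries. Dot-class boundaries occupy the
#' left block of each chromosome and dotless-class the right, so no dotted
#' domain ever flanks a dotless-class boundary; class labels are shuffled
#' within each block. With probability `nesting_prob` two adjacent leaf
#' domains are additionally covered by a parent TAD, giving true nesting
#' without creating extra edges.
#'
#' @param config A [simulation_config()].
#' @return An `architecture_truth` object: list with `grid`, `domains`,
#'   `boundaries`, `loops`, `sites`, `compartments`, `izs`, `config`,
#'   `seed`.
#' @export
simulate_architecture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_architecture_impl(config))
}

simulate_architecture_impl <- function(cfg) {
  grid <- bin_grid(cfg$chrom_lengths, cfg$bin_width, cfg$autosome)
  counts <- cfg$boundaries_per_class
  dot_labels <- rep(1:3, counts[1:3])
  less_labels <- rep(4:6, counts[4:6])
  if (length(dot_labels) > 1) dot_labels <- sample(dot_labels)
  if (length(less_labels) > 1) less_labels <- sample(less_labels)
  # split boundary lists across chromosomes proportionally to bin counts
  share <- grid$n_bins / sum(grid$n_bins)
  n_chrom <- nrow(grid)
  alloc_dot <- largest_remainder(length(dot_labels), share)
  alloc_less <- largest_remainder(length(less_labels), share)
  domains <- boundaries <- loops <- sites <- compart <- izs <- list()
  b_id <- 0L; d_id <- 0L; dot_id <- 0L
  dcut <- cumsum(alloc_dot); lcut <- cumsum(alloc_less)
  for (ci in seq_len(n_chrom)) {
    ch <- grid$chrom[ci]
    nb <- grid$n_bins[ci]
    dl <- dot_labels[seq_len(alloc_dot[ci]) + c(0, dcut)[ci]]
    ll <- less_labels[seq_len(alloc_less[ci]) + c(0, lcut)[ci]]
    labels <- c(dl, ll)
    m_dot <- length(dl)
    n_dom <- length(labels) + 1L
    if (n_dom * cfg$domain_size_bins[1] > nb) {
      stop("requested boundary count infeasible for chromosome ", ch)
    }
    # layout stage: own substream per chromosome, so configs differing only
    # in IZ/loop planting share identical domains, boundaries and sites
    withr::with_seed(cfg$seed + 10000L + ci, {
    sizes <- sample(seq(cfg$domain_size_bins[1], cfg$domain_size_bins[2]),
                    n_dom, replace = TRUE)
    if (sum(sizes) > nb) {
      sizes <- pmax(cfg$domain_size_bins[1],
                    floor(sizes * nb / sum(sizes)))
      if (sum(sizes) > nb) {
        # dense packing: fall back to near-even allocation
        sizes <- rep(nb %/% n_dom, n_dom)
      }
    }
    # spread the remainder over all domains so coverage stays uniform
    left <- nb - sum(sizes)
    sizes <- sizes + left %/% n_dom
    extra <- left %% n_dom
    if (extra > 0) {
      bump <- sample.int(n_dom, extra)
      sizes[bump] <- sizes[bump] + 1L
    }
    edges <- cumsum(sizes)
    starts <- c(0L, edges[-n_dom])
    ends <- edges  # exclusive
    dotted <- c(rep(TRUE, m_dot), rep(FALSE, n_dom - m_dot))
    # leaf domains
    leaf <- tibble::tibble(
      chrom = ch, start_bin = as.integer(starts), end_bin = as.integer(ends),
      level = 0L, dotted = dotted, domain_id = d_id + seq_len(n_dom)
    )
    d_id <- d_id + n_dom
    # nesting: cover adjacent leaf pairs with an (undotted) parent
    parents <- list()
    i <- 1L
    while (i < n_dom) {
      if (stats::runif(1) < cfg$nesting_prob) {
        leaf$level[c(i, i + 1L)] <- 1L
        d_id <- d_id + 1L
        parents[[length(parents) + 1L]] <- tibble::tibble(
          chrom = ch, start_bin = leaf$start_bin[i],
          end_bin = leaf$end_bin[i + 1L], level = 0L, dotted = FALSE,
          domain_id = d_id)
        i <- i + 2L
      } else i <- i + 1L
    }
    dom_ch <- dplyr::bind_rows(leaf, parents)
    # corner-dot loops on dotted leaves: anchors (start bin, last bin)
    cd <- leaf[leaf$dotted, ]
    loops_ch <- tibble::tibble(
      chrom = character(), bin1 = integer(), bin2 = integer(),
      type = character(), dot_id = integer(), domain_id = integer())
    if (nrow(cd)) {
      loops_ch <- tibble::tibble(
        chrom = ch, bin1 = cd$start_bin, bin2 = cd$end_bin - 1L,
        type = "corner", dot_id = dot_id + seq_len(nrow(cd)),
        domain_id = cd$domain_id)
      dot_id <- dot_id + nrow(cd)
    }
    # boundaries at interior leaf edges
    bnd_bins <- as.integer(ends[-n_dom])
    dot_status <- character(length(labels))
    for (j in seq_along(labels)) {
      lf <- dotted[j]; rf <- if (j + 1L <= n_dom) dotted[j + 1L] else FALSE
      dot_status[j] <- if (lf && rf) "double_dot" else
        if (lf || rf) "single_dot" else "dotless"
    }
    bnd <- tibble::tibble(
      boundary_id = b_id + seq_along(labels),
      chrom = ch, bin = bnd_bins,
      class_index = as.integer(labels),
      dot_status = dot_status,
      orientation = orientation_of_class(labels)
    )
    b_id <- b_id + length(labels)
    # planted CTCF/cohesin sites
    sites_ch <- purrr::pmap_dfr(bnd, function(boundary_id, chrom, bin,
                                              class_index, orientation, ...) {
      plant_sites(boundary_id, chrom, bin, orientation, cfg)
    })
    # compartment blocks
    lab0 <- sample(c("A", "B"), 1)
    blocks <- integer(0)
    while (sum(blocks) < nb) {
      blocks <- c(blocks, sample(seq(cfg$compartment_block_bins[1],
                                     cfg$compartment_block_bins[2]), 1))
    }
    lab <- rep(rep(c(lab0, setdiff(c("A", "B"), lab0)),
                   length.out = length(blocks)), times = blocks)[seq_len(nb)]
    comp_ch <- tibble::tibble(chrom = ch, bin = 0:(nb - 1L), label = lab)
    })
    # IZ / gained-loop stage: separate substream
    withr::with_seed(cfg$seed + 20000L + ci, {
    iz_ch <- empty_iz_tbl()
    iz_ch <- dplyr::bind_rows(iz_ch, purrr::pmap_dfr(bnd, function(boundary_id, chrom, bin,
                                           class_index, ...) {
      p <- cfg$p_iz[class_index, ]
      u <- stats::runif(1)
      tc <- if (u < p[1]) "early" else if (u < p[1] + p[2]) "early_mid" else
        if (u < sum(p)) "late" else NA_character_
      if (is.na(tc)) return(NULL)
      make_iz(chrom, bin, tc, cfg, boundary_id, nb)
    }))
    # background IZs away from boundaries and planted IZs
    n_bg <- stats::rpois(1, cfg$background_iz_per_mb * grid$length[ci] / 1e6)
    if (n_bg > 0) {
      taken <- c(bnd_bins, iz_ch$apex_bin)
      for (k in seq_len(n_bg)) {
        for (try in 1:50) {
          a <- sample(10:(nb - 11L), 1)
          if (!length(taken) || min(abs(a - taken)) >= 10) {
            tc <- sample(c("early", "early_mid", "late"), 1,
                         prob = c(0.2, 0.3, 0.5))
            iz_ch <- dplyr::bind_rows(iz_ch, make_iz(ch, a, tc, cfg, NA_integer_, nb))
            taken <- c(taken, a)
            break
          }
        }
      }
    }
    # gained long-range loops at class-1 boundaries (WAPL-KD analogue)
    if (cfg$extra_loops_per_class1 > 0) {
      c1 <- bnd$bin[bnd$class_index == 1L]
      for (b in c1) {
        for (k in seq_len(cfg$extra_loops_per_class1)) {
          d <- sample(20:50, 1) * sample(c(-1L, 1L), 1)
          partner <- b + d
          if (partner < 0 || partner >= nb) partner <- b - d
          dot_id <- dot_id + 1L
          loops_ch <- dplyr::bind_rows(loops_ch, tibble::tibble(
            chrom = ch, bin1 = min(b, partner), bin2 = max(b, partner),
            type = "gained", dot_id = dot_id, domain_id = NA_integer_))
        }
      }
    }
    })
    iz_ch <- flag_expressed(iz_ch, cfg)
    domains[[ci]] <- dom_ch; boundaries[[ci]] <- bnd; loops[[ci]] <- loops_ch
    sites[[ci]] <- sites_ch; compart[[ci]] <- comp_ch; izs[[ci]] <- iz_ch
  }
  structure(list(
    grid = grid,
    domains = finalize_domains(dplyr::bind_rows(domains), grid),
    boundaries = dplyr::bind_rows(boundaries),
    loops = dplyr::bind_rows(loops),
    sites = dplyr::bind_rows(sites),
    compartments = dplyr::bind_rows(compart),
    izs = dplyr::bind_rows(izs),
    config = cfg,
    seed = cfg$seed
  ), class = "architecture_truth")
}

finalize_domains <- function(d, grid) {
  bw <- bin_width(grid)
  d$start <- d$start_bin * bw
  d$end <- d$end_bin * bw
  d
}

largest_remainder <- function(total, share) {
  raw <- total * share
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

plant_sites <- function(boundary_id, chrom, bin, orientation, cfg) {
  bw <- cfg$bin_width
  strands <- character(0)
  if (orientation == "complex") {
    n <- sample(seq(cfg$complex_sites[1], cfg$complex_sites[2]), 1)
    strands <- c("+", "-", sample(c("+", "-"), max(0, n - 2), replace = TRUE))
    strands <- sample(strands)
  } else if (orientation == "tandem_single") {
    if (stats::runif(1) < cfg$p_single) {
      strands <- sample(c("+", "-"), 1)
    } else {
      n <- sample(seq(cfg$tandem_sites[1], cfg$tandem_sites[2]), 1)
      strands <- rep(sample(c("+", "-"), 1), n)
    }
  }
  n_co <- stats::rpois(1, cfg$cohesin_only_rate)
  n_all <- length(strands) + n_co
  if (n_all == 0) return(NULL)
  strand <- c(strands, sample(c("+", "-"), n_co, replace = TRUE))
  cobound <- c(rep("ctcf_cohesin", length(strands)), rep("cohesin_only", n_co))
  ord <- sample.int(n_all)  # interleave cobound and cohesin-only positions
  tibble::tibble(
    chrom = chrom,
    pos = bin * bw + sort(stats::runif(n_all, 0.05, 0.95)) * bw,
    strand = strand[ord],
    cobound = cobound[ord],
    boundary_id = boundary_id,
    decoy = FALSE
  )
}

# timing contribution of one IZ at bin distances `dist` from its apex:
# linear ramp to tau + edge_rise at the IZ edge (half-width h), a steep
# shoulder just beyond, then the fork slope, capped downstream at 16
iz_tau_profile <- function(dist, tau0, h, cfg) {
  slope_bin <- cfg$fork_slope_per_mb * cfg$bin_width / 1e6
  inside <- tau0 + cfg$iz_edge_rise * (if (h > 0) dist / h else dist)
  past <- pmax(dist - h, 0)
  sh <- pmin(past, cfg$iz_shoulder_bins)
  outside <- tau0 + cfg$iz_edge_rise + cfg$iz_shoulder_rise * sh +
    slope_bin * pmax(past - cfg$iz_shoulder_bins, 0)
  ifelse(dist <= h, inside, outside)
}

# An IZ is expressed (fires) only if no earlier-firing IZ's fork reaches its
# apex first: passive replication. Origins are licensed in excess; the truth
# table keeps every planted IZ and flags the subset that shapes the timing
# field. Per-class apex-timing ranges are narrower than the shadowing reach
# at the minimum boundary spacing, so same-timing-class IZs never shadow
# each other.
flag_expressed <- function(izs, cfg) {
  if (!nrow(izs)) { izs$expressed <- logical(0); return(izs) }
  o <- order(izs$tau)
  expressed <- rep(TRUE, nrow(izs))
  kept <- integer(0)
  for (k in o) {
    ok <- TRUE
    for (m in kept) {
      d <- abs(izs$apex_bin[k] - izs$apex_bin[m])
      h_m <- (izs$width_bins[m] - 1) %/% 2
      h_k <- (izs$width_bins[k] - 1) %/% 2
      field_m <- iz_tau_profile(d, izs$tau[m], h_m, cfg)
      if (d < h_m + h_k + 2 || field_m < izs$tau[k] + 2) { ok <- FALSE; break }
    }
    expressed[k] <- ok
    if (ok) kept <- c(kept, k)
  }
  izs$expressed <- expressed
  izs
}

empty_iz_tbl <- function() {
  tibble::tibble(chrom = character(), apex_bin = integer(),
                 start_bin = integer(), end_bin = integer(),
                 width_bins = integer(), width_bp = numeric(),
                 timing_class = character(), tau = numeric(),
                 amplitude = numeric(), boundary_id = integer())
}

make_iz <- function(chrom, apex, timing_class, cfg, boundary_id, nb) {
  w <- cfg$iz_width_bins[[timing_class]]
  w <- if (length(w) > 1) sample(w, 1) else w
  tau <- stats::runif(1, cfg$apex_timing[[timing_class]][1],
                      cfg$apex_timing[[timing_class]][2])
  h <- (w - 1) %/% 2
  lo <- max(0L, as.integer(apex - h)); hi <- min(nb - 1L, as.integer(apex + h))
  tibble::tibble(
    chrom = chrom, apex_bin = as.integer(apex),
    start_bin = lo, end_bin = hi + 1L,
    width_bins = hi - lo + 1L,
    width_bp = (hi - lo + 1L) * cfg$bin_width,
    timing_class = timing_class, tau = tau, amplitude = 1,
    boundary_id = boundary_id
  )
}

#' @export
print.architecture_truth <- function(x, ...) {
  cat("<architecture_truth> ", nrow(x$grid), " chromosome(s), ",
      nrow(x$boundaries), " boundaries, ", nrow(x$izs), " IZs, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a Hi-C contact matrix from planted architecture
#'
#' Expected value model for pixel (i, j):
#' \deqn{\lambda(i,j) = depth \cdot (1+|i-j|)^{-\alpha} \cdot m_{dom}^{s(i,j)}
#'   \cdot m_{dot}^{[dot]} \cdot m_{comp}^{[comp]}}
#' where `s(i,j)` is the number of planted domains (any level) containing
#' both bins, the dot multiplier applies within `dot_radius_bins` (Chebyshev)
#' of a planted loop anchor pair, and the compartment multiplier applies
#' when both bins share a label and their distance exceeds
#' `compartment_cutoff_bins`. Counts are Poisson draws; the matrix is
#' symmetric by construction.
#'
#' @param truth An [simulate_architecture()] result.
#' @param chrom Chromosome to simulate (default: first on the grid).
#' @return A [contact_matrix()] of integer counts.
#' @export
simulate_contact_matrix <- function(truth, chrom = truth$grid$chrom[1]) {
  cfg <- truth$config
  ci <- match(chrom, truth$grid$chrom)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  withr::with_seed(cfg$seed + 1000L + ci, {
    nb <- truth$grid$n_bins[ci]
    d <- abs(outer(seq_len(nb), seq_len(nb), `-`))
    lambda <- cfg$contact_depth * (1 + d)^(-cfg$alpha)
    doms <- truth$domains[truth$domains$chrom == chrom, ]
    for (k in seq_len(nrow(doms))) {
      idx <- (doms$start_bin[k] + 1L):doms$end_bin[k]
      lambda[idx, idx] <- lambda[idx, idx] * cfg$domain_mult
    }
    lps <- truth$loops[truth$loops$chrom == chrom, ]
    r <- cfg$dot_radius_bins
    for (k in seq_len(nrow(lps))) {
      ri <- pmax(1L, lps$bin1[k] + 1L - r):pmin(nb, lps$bin1[k] + 1L + r)
      cj <- pmax(1L, lps$bin2[k] + 1L - r):pmin(nb, lps$bin2[k] + 1L + r)
      lambda[ri, cj] <- lambda[ri, cj] * cfg$dot_mult
      lambda[cj, ri] <- lambda[cj, ri] * cfg$dot_mult
    }
    lab <- truth$compartments$label[truth$compartments$chrom == chrom]
    same <- outer(lab, lab, `==`) & d > cfg$compartment_cutoff_bins
    lambda[same] <- lambda[same] * cfg$compartment_mult
    up <- upper.tri(lambda, diag = TRUE)
    counts <- matrix(0, nb, nb)
    counts[up] <- stats::rpois(sum(up), lambda[up])
    counts <- counts + t(counts) - diag(diag(counts))
    contact_matrix(counts, chrom, truth$grid)
  })
}

#' True replication-timing field of a simulated chromosome
#'
#' Timing at the apex equals the planted apex timing; it rises by
#' `iz_edge_rise` fractions from apex to IZ edge (linear in bins), then
#' climbs at the fork slope away from the IZ, capped at fraction 16.
#' Between IZs the field is the minimum over their contributions — the
#' V/U-shaped geometry of 16-fraction Repli-seq.
#'
#' @param truth Architecture truth.
#' @param chrom Chromosome name.
#' @return Numeric timing per bin (length = bin count).
#' @export
true_timing_field <- function(truth, chrom) {
  cfg <- truth$config
  nb <- n_bins(truth$grid, chrom)
  tau <- rep(16, nb)
  izs <- truth$izs[truth$izs$chrom == chrom, ]
  if ("expressed" %in% names(izs)) izs <- izs[izs$expressed, ]
  bins <- 0:(nb - 1L)
  for (k in seq_len(nrow(izs))) {
    h <- max((izs$width_bins[k] - 1) %/% 2, 0L)
    dist <- abs(bins - izs$apex_bin[k])
    tau <- pmin(tau, iz_tau_profile(dist, izs$tau[k], h, cfg))
  }
  pmin(pmax(tau, 1), 16)
}

#' Simulate 16-fraction Repli-seq from planted architecture
#'
#' Each bin's expected signal in fraction f is proportional to the Gaussian
#' density of f around the bin's true timing (sd = `fraction_spread`),
#' scaled to `repliseq_depth` expected total counts, then Poisson-noised.
#'
#' @param truth Architecture truth.
#' @return A raw [repliseq16()] covering every chromosome on the grid.
#' @export
simulate_repliseq <- function(truth) {
  cfg <- truth$config
  withr::with_seed(cfg$seed + 2000L, {
    parts <- lapply(seq_len(nrow(truth$grid)), function(ci) {
      ch <- truth$grid$chrom[ci]
      nb <- truth$grid$n_bins[ci]
      tau <- true_timing_field(truth, ch)
      dens <- vapply(1:16, function(f) stats::dnorm(f, tau, cfg$fraction_spread),
                     numeric(nb))
      dens <- dens / rowSums(dens)
      lam <- dens * cfg$repliseq_depth
      sig <- matrix(stats::rpois(length(lam), lam), nrow = nb)
      bw <- cfg$bin_width
      list(bins = tibble::tibble(chrom = ch, start = (0:(nb - 1)) * bw,
                                 end = (1:nb) * bw),
           sig = sig)
    })
    repliseq16(dplyr::bind_rows(lapply(parts, `[[`, "bins")),
               do.call(rbind, lapply(parts, `[[`, "sig")),
               state = "raw", grid = truth$grid)
  })
}

#' Emit binding sites from planted architecture
#'
#' Returns every planted CTCF+cohesin / cohesin-only site, plus uniformly
#' scattered decoy CTCF+cohesin sites with uniform random strand at
#' `decoy_per_mb` (a neutral null for the orientation classifier).
#'
#' @param truth Architecture truth.
#' @param decoy_per_mb Decoy rate; defaults to the config value. Set 0 for
#'   planted sites only.
#' @return Tibble `chrom`, `pos`, `strand`, `cobound`, `boundary_id`,
#'   `decoy`.
#' @export
simulate_binding_sites <- function(truth, decoy_per_mb = truth$config$decoy_per_mb) {
  cfg <- truth$config
  withr::with_seed(cfg$seed + 3000L, {
    out <- truth$sites
    if (decoy_per_mb > 0) {
      for (ci in seq_len(nrow(truth$grid))) {
        n <- stats::rpois(1, decoy_per_mb * truth$grid$length[ci] / 1e6)
        if (n == 0) next
        out <- dplyr::bind_rows(out, tibble::tibble(
          chrom = truth$grid$chrom[ci],
          pos = stats::runif(n, 0, truth$grid$length[ci]),
          strand = sample(c("+", "-"), n, replace = TRUE),
          cobound = "ctcf_cohesin",
          boundary_id = NA_integer_,
          decoy = TRUE))
      }
    }
    dplyr::arrange(out, match(.data$chrom, truth$grid$chrom), .data$pos)
  })
}

#' Run the full generator
#'
#' Convenience wrapper producing truth plus all observables.
#'
#' @param config A [simulation_config()].
#' @return List with `truth`, `matrices` (named list of [contact_matrix()]),
#'   `repliseq`, `sites`.
#' @export
simulate_genome <- function(config) {
  truth <- simulate_architecture(config)
  mats <- lapply(truth$grid$chrom, function(ch) simulate_contact_matrix(truth, ch))
  names(mats) <- truth$grid$chrom
  list(truth = truth,
       matrices = mats,
       repliseq = simulate_repliseq(truth),
       sites = simulate_binding_sites(truth))
}

#' Write a simulated genome as a text fixture directory
#'
#' Writes `truth_boundaries.tsv`, `truth_izs.tsv`, `domains.bed`,
#' `sites.bed` (cobound flag in the name column, strand in column 6),
#' `compartments.bed`, `loops.bedpe`, one `matrix_<chrom>.txt` sparse
#' triplet file per chromosome, `chrom.sizes`, and `repliseq.tsv`.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim$truth
  bw <- bin_width(truth$grid)
  utils::write.table(truth$boundaries, file.path(dir, "truth_boundaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$izs, file.path(dir, "truth_izs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_intervals(tibble::tibble(chrom = truth$domains$chrom,
                                 start = truth$domains$start,
                                 end = truth$domains$end,
                                 name = paste0("level", truth$domains$level),
                                 score = 0, strand = "."),
                  file.path(dir, "domains.bed"))
  write_intervals(tibble::tibble(chrom = sim$sites$chrom,
                                 start = floor(sim$sites$pos),
                                 end = floor(sim$sites$pos) + 1,
                                 name = sim$sites$cobound,
                                 score = 0, strand = sim$sites$strand),
                  file.path(dir, "sites.bed"))
  comp <- dplyr::summarise(
    dplyr::group_by(truth$compartments, .data$chrom,
                    run = cumsum(c(1, diff(as.integer(factor(.data$label))) != 0))),
    start = min(.data$bin) * bw, end = (max(.data$bin) + 1) * bw,
    name = .data$label[1], .groups = "drop")
  write_intervals(comp[order(match(comp$chrom, truth$grid$chrom), comp$start),
                       c("chrom", "start", "end", "name")],
                  file.path(dir, "compartments.bed"))
  write_bedpe(tibble::tibble(
    chrom1 = truth$loops$chrom, start1 = truth$loops$bin1 * bw,
    end1 = (truth$loops$bin1 + 1) * bw,
    chrom2 = truth$loops$chrom, start2 = truth$loops$bin2 * bw,
    end2 = (truth$loops$bin2 + 1) * bw,
    name = truth$loops$type, score = 0, strand1 = ".", strand2 = "."),
    file.path(dir, "loops.bedpe"))
  for (ch in names(sim$matrices)) {
    write_contact_matrix(sim$matrices[[ch]], file.path(dir, paste0("matrix_", ch, ".txt")))
  }
  writeLines(paste(truth$grid$chrom, format_bp(truth$grid$length), sep = "\t"),
             file.path(dir, "chrom.sizes"))
  write_repliseq(sim$repliseq, file.path(dir, "repliseq.tsv"))
  invisible(dir)
}
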