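# Shared simulated fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

small_config <- function(seed = 7) {
  simulation_config(chrom_lengths = c(chrA = 20e6),
                    boundaries_per_class = rep(3L, 6), seed = seed)
}

small_truth <- function() fixture("small_truth", function() {
  simulate_architecture(small_config())
})

small_matrix <- function() fixture("small_matrix", function() {
  simulate_contact_matrix(small_truth())
})

small_expected <- function() fixture("small_expected", function() {
  compute_expected(small_matrix())
})

small_repliseq <- function() fixture("small_repliseq", function() {
  simulate_repliseq(small_truth())
})

# a repliseq16 with a fully deterministic signal from a given timing vector
rs_from_timing <- function(tau, spread = 1.5, depth = 1000, chrom = "chrT") {
  n <- length(tau)
  dens <- vapply(1:16, function(f) stats::dnorm(f, tau, spread), numeric(n))
  dens <- dens / rowSums(dens)
  repliseq16(tibble::tibble(chrom = chrom,
                            start = (0:(n - 1)) * 50000,
                            end = (1:n) * 50000),
             dens * depth, state = "raw")
}

# brute-force IZ-boundary colocalization: count intervals overlapping any
# boundary window, by direct pairwise enumeration
brute_coloc <- function(iz_start, iz_end, bnd_bins, win) {
  sum(vapply(seq_along(iz_start), function(k) {
    any(bnd_bins + win >= iz_start[k] & bnd_bins - win <= iz_end[k] - 1)
  }, logical(1)))
}
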