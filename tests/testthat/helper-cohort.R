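# Shared tiny fixtures, built in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 4-Mb, 2 x 10-cell cohort: enough to exercise every interface cheaply
tiny_config <- function(seed = 101L) {
  sim_config(
    genome = data.frame(chrom = "chrT", length = 4e6),
    cell_types = data.frame(
      name = c("A", "B"), n_cells = c(10L, 10L), pi_short = c(0.85, 0.45),
      pseudotime_center = c(0.25, 0.75), pseudotime_spread = c(0.15, 0.15),
      comp_amplitude = c(0.3, 0.6)),
    contacts_per_cell = list(meanlog = log(4e4), sdlog = 0.2),
    seed = seed)
}

tiny_cohort <- function() memo("tiny_cohort", simulate_cohort(tiny_config()))

# random banded symmetric matrix for oracle comparisons
random_band <- function(n, D, seed, resolution = 1e4) {
  withr_seed <- seed
  set.seed(withr_seed)
  M <- matrix(rpois(n * n, 3) * 1.0, n, n)
  M <- (M + t(M)) / 2
  dense_to_band(M, D, resolution)
}

# brute-force ring-background subtraction (reference for the compiled path)
ring_subtract_bruteforce <- function(E, inner = 3L, outer = 5L) {
  n <- E$n_bins; D <- E$max_offset
  dense <- band_to_dense(E)
  out <- E
  for (d in 0:D) for (i in seq_len(n - d)) {
    vals <- c()
    for (a in -(outer - 1):(outer - 1)) for (b in -(outer - 1):(outer - 1)) {
      r <- max(abs(a), abs(b))
      if (r <= inner || r >= outer) next
      ii <- i + a; jj <- i + d + b
      if (ii < 1 || jj < 1 || ii > n || jj > n) next
      if (abs(jj - ii) > D) next
      v <- dense[ii, jj]
      if (!is.na(v)) vals <- c(vals, v)
    }
    bg <- if (length(vals)) mean(vals) else 0
    out$mat[d + 1L, i] <- E$mat[d + 1L, i] - bg
  }
  out
}
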