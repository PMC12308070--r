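# Shared fixtures, built in code at test time.

small_genome <- function(seed = 11L) {
  simulate_genome(seed,
    n_chrom = 2L, lengths = 2e5,
    island_rate = 1 / 20000, low_map_fraction = 0.05, dark_fraction = 0.02
  )
}

small_cohort <- function(seed = 12L, n_hc = 20L, n_scz = 16L) {
  simulate_cohort(seed,
    n_hc = n_hc, n_scz = n_scz,
    n_imaging_hc = max(2L, n_hc - 2L), n_imaging_scz = max(2L, n_scz - 2L)
  )
}

full_cohort <- function(seed = 13L) {
  simulate_cohort(seed)
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments
# (independent oracle; only feasible for tiny n).
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combs <- utils::combn(n, length(a))
  w_all <- apply(combs, 2L, function(ix) sum(r[ix]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force overlap count oracle.
brute_count <- function(grid, frags) {
  vapply(seq_len(nrow(grid)), function(i) {
    sum(frags$chrom == grid$chrom[i] &
      frags$start < grid$end[i] & frags$end > grid$start[i])
  }, numeric(1))
}
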