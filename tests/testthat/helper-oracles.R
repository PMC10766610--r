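# Independent oracles for the rank-based hypergeometric statistic, kept
# deliberately separate from the package's log-space implementation.

# Exact upper tail P(X >= j) by direct summation of the hypergeometric pmf
# with integer choose(); exact in double precision for small M.
oracle_hypergeom_sf <- function(j, M, N, r) {
  ks <- seq(j, min(N, r))
  if (length(ks) == 0L) return(0)
  sum(choose(N, ks) * choose(M - N, r - ks)) / choose(M, r)
}

# Brute-force oracle: enumerate every one of the C(M, r) equally likely draw
# sets and count those containing at least j of the special wells 1..N.
oracle_hypergeom_sf_enum <- function(j, M, N, r) {
  draws <- utils::combn(M, r)
  hits <- colSums(draws <= N)
  mean(hits >= j)
}

oracle_rsa_log10p <- function(ranks, M) {
  r <- sort(ranks)
  N <- length(r)
  log10(min(vapply(seq_len(N),
                   function(j) oracle_hypergeom_sf(j, M, N, r[j]),
                   numeric(1))))
}

# Small noisy screen used by several test files.
tiny_screen <- function(n_genes = 60, hit_genes = NULL, seed = 7, ...) {
  simulate_screen(screen_sim_config(n_genes = n_genes, hit_genes = hit_genes,
                                    seed = seed, ...))
}
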