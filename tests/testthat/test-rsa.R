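test_that("hypergeometric upper tail matches exact enumeration", {
  # brute-force draw enumeration on a handful of small cases
  cases <- list(c(j = 2, M = 10, N = 2, r = 2),
                c(j = 1, M = 10, N = 2, r = 9),
                c(j = 2, M = 8, N = 3, r = 4),
                c(j = 3, M = 9, N = 4, r = 6),
                c(j = 1, M = 7, N = 7, r = 1))
  for (cs in cases) {
    expect_equal(hypergeom_sf(cs["j"], cs["M"], cs["N"], cs["r"]),
                 oracle_hypergeom_sf_enum(cs["j"], cs["M"], cs["N"], cs["r"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(hypergeom_sf(2, 10, 2, 2), 1 / 45, tolerance = 1e-12)
  expect_equal(hypergeom_sf(1, 10, 2, 9), 1)     # cannot miss both specials
  expect_equal(hypergeom_sf(1, 12, 12, 3), 1)    # all wells are special
  expect_error(hypergeom_sf(3, 10, 2, 5), "require")
  expect_error(hypergeom_sf(1, 10, 2, 11), "require")
})

test_that("RSA log10 P agrees with the enumeration oracle exhaustively", {
  # every rank configuration with M <= 12, N <= 4
  for (M in 3:12) {
    for (N in 1:min(4, M)) {
      configs <- utils::combn(M, N)
      for (i in seq_len(ncol(configs))) {
        ranks <- configs[, i]
        expect_equal(rsa_log10p(ranks, M), oracle_rsa_log10p(ranks, M),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("worked RSA values match hand-computable cases", {
  expect_equal(rsa_log10p(c(1, 2), 10), log10(1 / 45), tolerance = 1e-9)
  expect_equal(rsa_log10p(c(9, 10), 10), 0)        # worst ranks: P = 1
  expect_equal(rsa_log10p(c(1, 2, 3), 3), 0)       # gene occupies whole list
  expect_equal(rsa_log10p(c(1, 2, 3), 2829),
               log10(1 / choose(2829, 3)), tolerance = 1e-9)
  expect_equal(rsa_log10p(c(1, 2, 3), 2829), -9.576, tolerance = 1e-3)
})

test_that("RSA is monotone, exchangeable and union-bounded under the null", {
  set.seed(8)
  for (rep in 1:25) {
    M <- sample(8:40, 1)
    N <- sample(2:4, 1)
    ranks <- sort(sample(M, N))
    p0 <- rsa_log10p(ranks, M)
    # improving any single rank never increases P
    j <- sample(N, 1)
    better <- ranks
    better[j] <- better[j] - 1L
    if (!better[j] %in% ranks[-j] && better[j] >= 1) {
      expect_lte(rsa_log10p(better, M), p0 + 1e-12)
    }
    # order of the supplied ranks is irrelevant
    expect_equal(rsa_log10p(sample(ranks), M), p0)
  }
  # null simulation: P(rsa P <= alpha) <= N * alpha (union bound)
  set.seed(9)
  M <- 200; N <- 3; alpha <- 0.05
  p <- replicate(4000, 10^rsa_log10p(sample(M, N), M))
  expect_lte(mean(p <= alpha), N * alpha * 1.15)  # Monte-Carlo headroom
})

test_that("ranking is conservative under ties and deterministic", {
  norm <- data.frame(
    plate_id = "LP1", replicate_id = "R1",
    well_id = sprintf("A%02d", 1:6),
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    well_class = "library", qc_pass = TRUE,
    rel_change = c(5, 5, 1, 1, 1, 1),
    robust_z = c(3, 3, 1, 1, 0.5, 0.2),
    stringsAsFactors = FALSE)
  ranked <- rank_wells(norm)
  # the two tied top wells of g1 both take the worst rank of the block
  expect_equal(ranked$gene_ranks$g1, c(2, 2))
  expect_equal(rsa_log10p(ranked$gene_ranks$g1, ranked$M),
               log10(oracle_hypergeom_sf(2, 6, 2, 2)))
  # tied g2 wells take rank 4; direction = "down" reverses the ordering
  expect_equal(ranked$gene_ranks$g2, c(4, 4))
  down <- rank_wells(norm, direction = "down")
  expect_equal(down$gene_ranks$g1, c(6, 6))
  # shuffling input rows changes nothing
  set.seed(1)
  ranked2 <- rank_wells(norm[sample(6), ])
  expect_equal(ranked2$gene_ranks, ranked$gene_ranks)
  expect_equal(ranked2$wells$well_id, ranked$wells$well_id)
})

test_that("score_genes summarizes per gene and flags QC-excluded genes", {
  sim <- simulate_screen(screen_sim_config(
    n_genes = 60, hit_genes = c(G0010 = 1), infection_failure_rate = 0,
    seed = 13))
  norm <- normalize_screen(sim$wells)$wells
  scores <- score_genes(norm, library = sim$library)
  expect_equal(nrow(scores), 60L)
  expect_true(all(scores$qc_pass))
  expect_true(all(scores$rsa_log10p <= 0, na.rm = TRUE))
  expect_equal(scores$n_wells_used, rep(3L, 60))
  # the planted full-rescue gene is the top scorer with max rel change ~ 10x
  top <- scores[which.min(scores$rsa_log10p), ]
  expect_equal(top$gene_id, "G0010")
  expect_equal(top$max_rel_change, 10, tolerance = 0.25)
  expect_equal(top$rsa_log10p, log10(1 / choose(180, 3)), tolerance = 0.02)

  # a gene whose wells all failed QC is reported, not scored
  norm2 <- norm
  norm2$qc_pass[norm2$gene_id == "G0005"] <- FALSE
  scores2 <- score_genes(norm2, library = sim$library)
  g5 <- scores2[scores2$gene_id == "G0005", ]
  expect_false(g5$qc_pass)
  expect_true(is.na(g5$rsa_log10p))
  expect_equal(g5$n_wells_used, 0L)

  # genes present in wells but absent from the library are named
  norm3 <- norm
  norm3$gene_id[norm3$gene_id == "G0003"] <- "NOT_A_GENE"
  expect_error(score_genes(norm3, library = sim$library), "NOT_A_GENE")
})
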