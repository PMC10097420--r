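test_that("TPM normalises counts by length and sums to one million", {
  expect_equal(tpm(c(10, 10), c(1000, 2000)),
               c(2/3, 1/3) * 1e6, tolerance = 1e-9)
  expect_equal(tpm(5, 1234), 1e6)
  expect_equal(tpm(c(0, 5), c(1000, 1000)), c(0, 1e6))
  expect_warning(z <- tpm(c(0, 0), c(1000, 1000)), "zero")
  expect_equal(z, c(0, 0))
  expect_error(tpm(1, 0), class = "poebias_domain_error")
})

test_that("gene-level decomposition separates parental from strain effects", {
  pure_parent <- count_table(pat_bc = 600, mat_bc = 400,
                             pat_cb = 600, mat_cb = 400)
  res <- gene_ase(pure_parent)
  expect_equal(res$parental_pct, 60)
  expect_equal(res$strain_pct, 50)

  pure_strain <- count_table(pat_bc = 600, mat_bc = 400,
                             pat_cb = 400, mat_cb = 600)
  res <- gene_ase(pure_strain)
  expect_equal(res$parental_pct, 50)
  expect_equal(res$strain_pct, 60)

  expect_error(gene_ase(pure_parent[pure_parent$cross == "BxC", ]),
               class = "poebias_missing_cross")
  zero <- count_table(pat_bc = 0, mat_bc = 0, pat_cb = 10, mat_cb = 10)
  expect_error(gene_ase(zero), class = "poebias_undefined_bias")
})

test_that("decomposition recovers a simulated parental effect at high depth", {
  cfg <- sim_config(n_genes = 1, theta_p = 0.6, theta_s = 0, depth = 1e5,
                    n_replicates = 8)
  tab <- simulate_counts(cfg, seed = 99)
  res <- gene_ase(tab)
  expect_lt(abs(res$parental_pct - 60), 1)
})

test_that("per-cross percents and scores reconstruct each other exactly", {
  set.seed(17)
  for (i in 1:20) {
    tab <- count_table(pat_bc = rpois(3, 500), mat_bc = rpois(3, 500),
                       pat_cb = rpois(3, 500), mat_cb = rpois(3, 500))
    res <- gene_ase(tab)
    back <- cross_percents_from_scores(res$parental_pct, res$strain_pct)
    expect_equal(back$paternal_pct_bc, res$paternal_pct_bc)
    expect_equal(back$paternal_pct_cb, res$paternal_pct_cb)
  }
})

test_that("low-count filter drops genes thin in either cross", {
  expect_true(low_count_filter(count_table(pat_bc = 500, mat_bc = 500,
                                           pat_cb = 500, mat_cb = 500), 50))
  expect_false(low_count_filter(count_table(pat_bc = 20, mat_bc = 10,
                                            pat_cb = 500, mat_cb = 500), 50))
  expect_true(low_count_filter(count_table(pat_bc = 1, mat_bc = 0,
                                           pat_cb = 1, mat_cb = 0), 1))
})

test_that("permutation screen: null statistic of balanced replicates gives p = 1", {
  tab <- count_table(pat_bc = c(50, 50), mat_bc = c(50, 50),
                     pat_cb = c(50, 50), mat_cb = c(50, 50))
  expect_equal(permutation_parent_test(tab, n_perm = 199, seed = 1), 1)
  expect_warning(permutation_parent_test(tab, n_perm = 50, seed = 1),
                 "granularity")
})

test_that("permutation screen is seed-reproducible and detects strong effects", {
  cfg <- sim_config(n_genes = 1, theta_p = 0.9, depth = 1e4,
                    n_replicates = 6)
  tab <- simulate_counts(cfg, seed = 3)
  p1 <- permutation_parent_test(tab, n_perm = 999, seed = 42)
  p2 <- permutation_parent_test(tab, n_perm = 999, seed = 42)
  expect_identical(p1, p2)
  expect_lte(p1, 0.01)
})

test_that("table-level ASE summarises every gene with TPM and filtering", {
  cfg <- sim_config(n_genes = 20, theta_p = 0.5, depth = 1000,
                    n_replicates = 3)
  tab <- simulate_counts(cfg, seed = 8)
  res <- ase_table(tab, min_reads_per_cross = 20)
  expect_equal(nrow(res), 20L)
  expect_true(all(res$kept))
  expect_false(anyNA(res$mean_tpm))
  ## TPM of the pooled per-replicate library sums to 1e6 per replicate,
  ## so per-gene means over replicates sum to 1e6 too
  expect_equal(sum(res$mean_tpm), 1e6, tolerance = 1e-6)

  ## a starving gene gets filtered, not reported as biased
  tab$maternal_reads[tab$gene_id == "gene001"] <- 0
  tab$paternal_reads[tab$gene_id == "gene001"] <- 1
  res2 <- ase_table(tab, min_reads_per_cross = 20)
  expect_false(res2$kept[res2$gene_id == "gene001"])
  expect_true(is.na(res2$parental_pct[res2$gene_id == "gene001"]))
})
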