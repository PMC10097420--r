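test_that("percent bias from pooled reads and fold changes", {
  expect_equal(paternal_percent_from_reads(150, 200), 75)
  expect_equal(paternal_percent_from_reads(100, 200), 50)
  expect_error(paternal_percent_from_reads(0, 0),
               class = "poebias_undefined_bias")

  expect_equal(maternal_percent_from_fold_change(1), 50)
  expect_equal(maternal_percent_from_fold_change(3), 75)
  expect_equal(maternal_percent_from_fold_change(0), 0)
  expect_error(maternal_percent_from_fold_change(-1),
               class = "poebias_domain_error")
})

test_that("fold-change map is a bijection whose inverse recovers fc", {
  fc <- c(1e-4, 0.1, 0.5, 1, 2, 7, 1e4)
  pct <- maternal_percent_from_fold_change(fc)
  expect_true(all(diff(pct) > 0))
  expect_equal(pct / (100 - pct), fc, tolerance = 1e-9)
})

test_that("reciprocal mean cancels strain effects; strain score cancels parental", {
  expect_equal(reciprocal_mean_paternal(60, 60), 60)
  expect_equal(reciprocal_mean_paternal(60, 40), 50)
  expect_equal(reciprocal_mean_paternal(70, 50), 60)
  expect_equal(strain_percent(60, 40), 60)
  expect_equal(strain_percent(70, 70), 50)
  expect_equal(strain_percent(50, 50), 50)
  expect_true(is.na(reciprocal_mean_paternal(60, NA)))
})

test_that("(parental, strain) is an exact invertible transform of cross percents", {
  set.seed(7)
  bc <- runif(200, 0, 100)
  cb <- runif(200, 0, 100)
  back <- cross_percents_from_scores(reciprocal_mean_paternal(bc, cb),
                                     strain_percent(bc, cb))
  expect_equal(back$paternal_pct_bc, bc)
  expect_equal(back$paternal_pct_cb, cb)
})

test_that("maximum bias symmetrises and tracks the preferred parent", {
  expect_equal(max_bias(c(48, 53)),
               list(bias_pct = 53, preferred_parent = "paternal"))
  expect_equal(max_bias(95)$bias_pct, 95)
  expect_equal(max_bias(c(40, 60)),
               list(bias_pct = 60, preferred_parent = "both"))
  expect_equal(max_bias(c(50, 50))$preferred_parent, "none")
  expect_equal(max_bias(30)$preferred_parent, "maternal")
  expect_error(max_bias(numeric()), class = "poebias_domain_error")
})

test_that("bias bins partition [50, 100] with half-open boundaries", {
  expect_equal(as.character(assign_bin(59.9)), "50-60")
  expect_equal(as.character(assign_bin(60)), "60-70")
  expect_equal(as.character(assign_bin(100)), "90-100")
  expect_error(assign_bin(49.9), class = "poebias_domain_error")
  ## every valid bias maps to exactly one bin
  set.seed(11)
  v <- c(runif(500, 50, 100), 50, 60, 70, 80, 90, 100)
  bins <- assign_bin(v)
  expect_false(anyNA(bins))
  lo <- as.numeric(substr(as.character(bins), 1, 2))
  expect_true(all(v >= lo & (v < lo + 10 | (lo == 90 & v <= 100))))
})

test_that("canonical threshold is strictly greater than 70", {
  expect_equal(canonical_flag(84), "canonical")
  expect_equal(canonical_flag(65), "weak")
  expect_equal(canonical_flag(70), "weak")
})

test_that("per-gene bias summary works from reciprocal percents and fold changes", {
  calls <- data.frame(gene_id = c("g1", "g1", "g2"), study = "S",
                      tissue = c("a", "b", "a"),
                      paternal_pct_bc = c(70, 55, 30),
                      paternal_pct_cb = c(50, 55, 30))
  res <- summarise_gene_bias(calls)
  expect_equal(res$bias_pct[res$gene_id == "g1"], 60)      # (70+50)/2
  expect_equal(res$preferred_parent[res$gene_id == "g2"], "maternal")
  expect_equal(as.character(res$bin), c("60-70", "70-80"))

  fc <- data.frame(gene_id = "g3", study = "S", tissue = "a",
                   fold_change_mat_over_pat = 3)
  resfc <- summarise_gene_bias(fc)
  expect_equal(resfc$bias_pct, 75)                          # maternal 75%
  expect_equal(resfc$preferred_parent, "maternal")
})
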