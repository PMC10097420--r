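test_that("amplification correction is odds normalisation against gDNA", {
  expect_equal(correct_amplification(60, 50), 60)
  expect_equal(correct_amplification(40, 40), 50)
  ## odds 1.5 / 0.6667 = 2.25 -> 100 * 2.25 / 3.25
  expect_equal(correct_amplification(60, 40), 100 * 2.25 / 3.25,
               tolerance = 1e-4)
  expect_warning(correct_amplification(100, 50), "clamped")
})

test_that("correction identities hold over the whole domain", {
  x <- seq(1, 99, by = 0.5)
  expect_equal(correct_amplification(x, x), rep(50, length(x)))
  expect_equal(correct_amplification(x, 50), x)
  ## distortion is the exact inverse wherever the distorted value stays
  ## inside the measurable (1, 99) range
  inner <- seq(5, 95, by = 0.5)
  for (gd in c(20, 40, 50, 65, 80)) {
    expect_equal(correct_amplification(distort_amplification(inner, gd), gd),
                 inner, tolerance = 1e-9)
  }
})

test_that("expression gate fails strictly below 0.05 of the reference", {
  expect_false(expression_gate(0.04))
  expect_true(expression_gate(0.05))
  expect_true(expression_gate(1.2))
  expect_error(expression_gate(-1), class = "poebias_domain_error")
})

test_that("tissue mean averages within crosses then across crosses", {
  m <- data.frame(cross = c("BxC", "BxC", "CxB", "CxB"),
                  paternal_pct_raw = c(58, 56, 57, 55),
                  gdna_paternal_pct = 50)
  expect_equal(tissue_mean(m), 56.5)
  m2 <- data.frame(cross = c("BxC", "BxC", "CxB", "CxB"),
                   paternal_pct_raw = c(60, 60, 40, 40),
                   gdna_paternal_pct = 50)
  expect_equal(tissue_mean(m2), 50)       # strain effect cancels
  expect_true(is.na(tissue_mean(m[m$cross == "BxC", ])))
})

test_that("gene calling follows the 45-55 window with category precedence", {
  pat <- c(P7.cortex = 56.6, P7.hyp = 55.6, P7.cb = 57.8, P7.hipp = 54.8,
           P7.bs = 58.8, P60.cortex = 58.1, P60.hyp = 56.1, P60.cb = 55.4,
           P60.hipp = 55.0, P60.bs = 55.2)
  expect_equal(call_gene(pat)$category, "Paternal")

  bi <- c(50.7, 49.2, 50.3, 49.8, 50.1)
  expect_equal(call_gene(bi)$category, "Biallelic")

  plac <- c(placenta = 43.9, liver = 50.9, brain = 52.6, cortex = 49.6)
  expect_equal(call_gene(plac, is_placenta = names(plac) == "placenta")$category,
               "Placental_maternal")

  expect_equal(call_gene(c(a = NA_real_, b = NA_real_))$category,
               "Low_expression")
  expect_equal(call_gene(c(a = 60), gate_passed = FALSE)$category,
               "Low_expression")
  ## boundary values sit inside the closed biallelic window
  expect_equal(call_gene(c(a = 55, b = 45))$category, "Biallelic")
  expect_warning(res <- call_gene(c(a = 60, b = 40, c = 41)),
                 "conflicting")
  expect_equal(res$category, "Maternal")
  expect_true(res$conflicting)
})

test_that("raising all tissue means never moves a call toward Maternal", {
  set.seed(23)
  rank_of <- c(Maternal = -1, Placental_maternal = -0.5, Low_expression = 0,
               Biallelic = 0, Placental_paternal = 0.5, Paternal = 1)
  for (i in 1:30) {
    means <- runif(5, 35, 65)
    base <- suppressWarnings(call_gene(means)$category)
    up <- suppressWarnings(call_gene(means + runif(1, 0, 5))$category)
    expect_gte(rank_of[[up]], rank_of[[base]])
  }
})

test_that("strain flag needs more than one out-of-window tissue", {
  expect_true(strain_flag(c(60, 58, 50)))
  expect_false(strain_flag(c(60, 50, 50)))
  expect_false(strain_flag(c(45, 55)))    # boundary is inside the window
})

test_that("full caller recovers categories from simulated pyro measurements", {
  truth_p <- c(0.85, 0.15, 0.5, 0.5)
  cfg <- sim_config(n_genes = 4, theta_p = truth_p, theta_s = c(0, 0, 0, 0.1),
                    pyro_noise_sd = 1, gdna_bias = c(50, 40, 60, 50),
                    rel_expression = c(1, 1, 1, 0.01))
  pyro <- simulate_pyro(cfg, seed = 12)
  res <- validate_calls(pyro)
  expect_equal(res$category[match(sprintf("gene%03d", 1:4), res$gene_id)],
               c("Paternal", "Maternal", "Biallelic", "Low_expression"))
  ## strain effect shows up in the per-tissue strain scores of gene004 only
  tiss <- attr(res, "tissues")
  expect_true(all(abs(tiss$strain_pct[tiss$gene_id == "gene003"] - 50) < 3))
})

test_that("bundled validation panel reproduces the printed per-row statuses", {
  panel <- load_validation_panel()
  calls <- panel_calls(panel)
  merged <- merge(calls, panel$wide[, c("gene", "reported_status")],
                  by = "gene")
  ## normalise the caller's sub-categories to the printed vocabulary
  simple <- sub("^Placental_(maternal|paternal)$", "Placental",
                merged$category)
  simple <- sub("^Low_expression$", "Low expression", simple)
  ## two rows are documented discrepancies: Calm1 (printed Biallelic despite
  ## a sub-45 brain-stem value; strict rule says Maternal) and Slc25a29
  ## (row duplicates its neighbour and mixes directions)
  comparable <- !merged$gene %in% c("Calm1", "Slc25a29")
  expect_equal(simple[comparable], merged$reported_status[comparable])
  expect_equal(simple[merged$gene == "Calm1"], "Maternal")
})
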