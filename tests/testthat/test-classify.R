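test_that("interval gap distance handles overlap, gap, and chromosomes", {
  a <- gene_df("a", "chr1", 100L, 200L)
  expect_equal(interval_distance(a, gene_df("b", "chr1", 150L, 300L)), 0)
  expect_equal(interval_distance(a, gene_df("b", "chr1", 500L, 600L)), 300)
  expect_equal(interval_distance(a, gene_df("b", "chr2", 100L, 200L)), Inf)
})

test_that("class assignment follows the 1 Mb proximity rules", {
  known <- gene_df("known1", "chr1", 10000000L, 10010000L)
  cand <- gene_df(c("n1", "n2", "n3", "n4"), "chr1",
                  c(10500000L, 20000000L, 20400000L, 30000000L),
                  c(10501000L, 20001000L, 20401000L, 30001000L))
  cls <- assign_class(cand, known)
  expect_equal(cls$class[match(c("n1", "n2", "n3", "n4"), cls$gene_id)],
               c("class3", "class2", "class2", "class1"))
  expect_equal(cls$class[cls$gene_id == "known1"], "known")

  dup <- gene_df("known1", "chr2", 1L, 10L)
  expect_error(assign_class(dup, known), class = "poebias_conflict_error")
})

test_that("class assignment matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:30) {
    known <- random_genes(sample(3:10, 1), prefix = "k", max_pos = 3e7)
    cand <- random_genes(sample(5:50, 1), prefix = "n", max_pos = 3e7)
    got <- assign_class(cand, known)
    expect_equal(got$class[match(cand$gene_id, got$gene_id)],
                 brute_force_classes(cand, known),
                 info = paste("instance", i))
  }
})

test_that("class assignment is invariant to permutation and joint translation", {
  set.seed(5)
  known <- random_genes(5, prefix = "k", max_pos = 2e7)
  cand <- random_genes(20, prefix = "n", max_pos = 2e7)
  ref <- assign_class(cand, known)
  perm <- assign_class(cand[sample(nrow(cand)), ], known[sample(5), ])
  expect_equal(perm[order(perm$gene_id), ], ref[order(ref$gene_id), ],
               ignore_attr = TRUE)
  shift <- function(df) { df$start <- df$start + 1L; df$end <- df$end + 1L; df }
  expect_equal(assign_class(shift(cand), shift(known))$class, ref$class)
})

test_that("class-2 and class-1 labels verify post-hoc against the window", {
  set.seed(31)
  known <- random_genes(4, prefix = "k", max_pos = 4e7)
  cand <- random_genes(40, prefix = "n", max_pos = 4e7)
  cls <- assign_class(cand, known)$class[seq_len(nrow(cand))]
  for (i in which(cls == "class2")) {
    d <- interval_distance(cand[rep(i, nrow(cand)), ], cand)[-i]
    expect_true(min(d) <= 1e6)
  }
  for (i in which(cls == "class1")) {
    d <- interval_distance(cand[rep(i, nrow(cand)), ], cand)[-i]
    if (length(d)) expect_true(min(d) > 1e6)
  }
})

test_that("periphery status uses strict midpoint flanking", {
  g <- gene_df("g", "chr1", 4999000L, 5001000L)   # midpoint 5 Mb
  knowns <- gene_df(c("k1", "k2"), "chr1", c(3999000L, 5999000L),
                    c(4001000L, 6001000L))        # 4 and 6 Mb
  expect_equal(periphery_status(g, knowns), "flanked")

  g2 <- gene_df("g", "chr1", 2999000L, 3001000L)  # midpoint 3 Mb
  k3 <- gene_df(c("k1", "k2", "k3"), "chr1",
                c(3999000L, 4999000L, 5999000L),
                c(4001000L, 5001000L, 6001000L))
  expect_equal(periphery_status(g2, k3), "peripheral")

  ## equal midpoint does not count as flanking (strict inequality)
  g3 <- gene_df("g", "chr1", 3999000L, 4001000L)
  expect_equal(periphery_status(g3, k3[1, ]), "peripheral")
  expect_error(periphery_status(g, knowns[0, ]), class = "poebias_domain_error")
})

test_that("ICR orientation compares preferred parent with methylated parent", {
  expect_equal(icr_orientation("maternal", "maternal"), "meth_icr")
  expect_equal(icr_orientation("paternal", "maternal"), "un_icr")
  expect_equal(icr_orientation("both", "paternal"), "both")
  expect_equal(icr_orientation("maternal", NA), "no_icr")
  expect_error(icr_orientation("neither", "maternal"),
               class = "poebias_domain_error")
})
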