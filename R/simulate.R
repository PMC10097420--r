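## Synthetic-data generators.
##
## Every input the pipeline consumes can be generated here with known ground
## truth: gene registries with clusters and ICRs laid out so that true
## class labels are determined by construction, reciprocal-cross binomial
## allele counts with additive parental and strain effects, and noisy
## pyrosequencing assays whose amplification distortion is the exact inverse
## of the caller's correction. All generators are pure functions of
## (config, seed).

#' Simulation configuration
#'
#' Defaults mirror the reciprocal C57BL/6 x CastEiJ study designs the
#' pipeline targets: six biological replicates per reciprocal cross, about
#' 1e4 informative reads per gene and replicate, pyrosequencing with four
#' biological replicates and 1.5-point Gaussian assay noise, and a panel
#' geometry of 7 known imprinted clusters, 8 isolated novel singletons and
#' 5 novel clusters of 3.
#'
#' @param n_genes Number of genes for count/pyro simulations.
#' @param n_known_clusters,known_genes_per_cluster Known imprinted cluster
#'   layout (each cluster gets one ICR with a random methylated parent).
#' @param n_class1 Isolated novel singletons.
#' @param n_class2_clusters,class2_genes_per_cluster Novel cluster layout.
#' @param n_class3_per_cluster Novel candidates placed within 1 Mb of each
#'   known cluster.
#' @param theta_p True paternal fraction(s) in \[0, 1\] (0.5 = no parental
#'   effect); recycled over genes.
#' @param theta_s Strain effect in probability units: the Cast allele's
#'   fraction is shifted by `+theta_s` (recycled over genes).
#' @param depth Reads per gene per replicate.
#' @param n_replicates Replicates per reciprocal cross.
#' @param pyro_noise_sd Gaussian noise SD of a pyrosequencing replicate, in
#'   percentage points.
#' @param gdna_bias Assay-level amplification bias, as the percent paternal
#'   the gDNA control would read (50 = unbiased); recycled over genes.
#' @param rel_expression Relative expression (target/Tbp) per gene,
#'   recycled.
#' @param clip Success probabilities are clipped to this range to avoid
#'   degenerate binomials while still permitting 98:2 imprinting.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 100,
                       n_known_clusters = 7, known_genes_per_cluster = 4,
                       n_class1 = 8,
                       n_class2_clusters = 5, class2_genes_per_cluster = 3,
                       n_class3_per_cluster = 3,
                       theta_p = 0.5, theta_s = 0,
                       depth = 1e4, n_replicates = 6,
                       pyro_noise_sd = 1.5, gdna_bias = 50,
                       rel_expression = 1, clip = c(0.02, 0.98)) {
  stopifnot(n_genes >= 1, depth >= 1, n_replicates >= 1,
            all(theta_p >= 0 & theta_p <= 1), pyro_noise_sd >= 0,
            all(gdna_bias > 0 & gdna_bias < 100),
            clip[1L] > 0, clip[2L] < 1, clip[1L] < clip[2L])
  structure(list(n_genes = n_genes,
                 n_known_clusters = n_known_clusters,
                 known_genes_per_cluster = known_genes_per_cluster,
                 n_class1 = n_class1,
                 n_class2_clusters = n_class2_clusters,
                 class2_genes_per_cluster = class2_genes_per_cluster,
                 n_class3_per_cluster = n_class3_per_cluster,
                 theta_p = theta_p, theta_s = theta_s, depth = depth,
                 n_replicates = n_replicates,
                 pyro_noise_sd = pyro_noise_sd, gdna_bias = gdna_bias,
                 rel_expression = rel_expression, clip = clip),
            class = "sim_config")
}

## place `n` gene intervals inside a slot, spaced `pitch` bp apart
place_genes <- function(ids, chrom, origin, pitch = 2e5, width = 1e4,
                        jitter = 5e4) {
  n <- length(ids)
  start <- origin + (seq_len(n) - 1L) * pitch +
    as.integer(stats::runif(n, 0, jitter))
  new_gene_records(ids, chrom, start, start + width,
                   strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate a gene registry with ground-truth class labels
#'
#' Lays out known imprinted clusters (each with an ICR), novel candidates
#' within 1 Mb of a known cluster (true class3), novel clusters more than
#' 1 Mb from anything known (true class2), and isolated novel singletons
#' (true class1). Units are separated by slots far wider than the class
#' window so the truth labels are unambiguous by construction.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param window Class window the layout must respect, default 1 Mb.
#' @return A list with `genes` (gene records plus `status`, `truth_class`,
#'   `cluster_id`) and `icrs` (ICR records, one per known cluster).
#' @export
simulate_registry <- function(config, seed, window = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    slot <- 8 * window           # between-unit pitch: >> window
    chrom_len <- 2e8
    per_chrom <- floor(chrom_len / slot) - 1L
    n_units <- config$n_known_clusters + config$n_class1 +
      config$n_class2_clusters
    if (per_chrom < 1L) stop_poebias("infeasible spacing",
                                     class = "poebias_domain_error")
    unit_chrom <- paste0("chr", (seq_len(n_units) - 1L) %/% per_chrom + 1L)
    unit_origin <- ((seq_len(n_units) - 1L) %% per_chrom) * slot + 2 * window
    genes <- list()
    icrs <- list()
    u <- 0L
    for (k in seq_len(config$n_known_clusters)) {
      u <- u + 1L
      cl <- sprintf("cluster%02d", k)
      kn <- place_genes(sprintf("%s_known%d", cl,
                                seq_len(config$known_genes_per_cluster)),
                        unit_chrom[u], unit_origin[u])
      kn$status <- "known"
      kn$truth_class <- "known"
      kn$cluster_id <- cl
      ## candidates just outside the cluster span but within the window
      n3 <- config$n_class3_per_cluster
      if (n3 > 0L) {
        off <- as.integer(stats::runif(n3, 5e4, window - 5e4))
        side <- sample(c(-1L, 1L), n3, replace = TRUE)
        start <- ifelse(side < 0, min(kn$start) - off - 1e4L,
                        max(kn$end) + off)
        c3 <- new_gene_records(sprintf("%s_cand%d", cl, seq_len(n3)),
                               unit_chrom[u], start, start + 1e4L,
                               strand = sample(c("+", "-"), n3, TRUE))
        c3$status <- "novel"
        c3$truth_class <- "class3"
        c3$cluster_id <- cl
        kn <- rbind(kn, c3)
      }
      genes[[length(genes) + 1L]] <- kn
      icr_start <- as.integer(mean(c(min(kn$start), max(kn$end))))
      icrs[[k]] <- data.frame(
        icr_id = paste0(cl, "_icr"), chrom = unit_chrom[u],
        start = icr_start, end = icr_start + 2000L,
        methylated_parent = sample(c("maternal", "paternal"), 1L,
                                   prob = c(0.8, 0.2)),
        cluster_id = cl, stringsAsFactors = FALSE)
    }
    for (k in seq_len(config$n_class2_clusters)) {
      u <- u + 1L
      cl <- sprintf("novelcluster%02d", k)
      g <- place_genes(sprintf("%s_cand%d", cl,
                               seq_len(config$class2_genes_per_cluster)),
                       unit_chrom[u], unit_origin[u])
      g$status <- "novel"
      g$truth_class <- if (config$class2_genes_per_cluster > 1L)
        "class2" else "class1"
      g$cluster_id <- cl
      genes[[length(genes) + 1L]] <- g
    }
    for (k in seq_len(config$n_class1)) {
      u <- u + 1L
      g <- place_genes(sprintf("singleton%02d", k), unit_chrom[u],
                       unit_origin[u])
      g$status <- "novel"
      g$truth_class <- "class1"
      g$cluster_id <- NA_character_
      genes[[length(genes) + 1L]] <- g
    }
    list(genes = do.call(rbind, genes), icrs = do.call(rbind, icrs))
  })
}

clip_prob <- function(p, clip) pmin(pmax(p, clip[1L]), clip[2L])

#' Simulate reciprocal-cross allele-specific read counts
#'
#' Per replicate, paternal reads are Binomial(depth, p) with
#' `p = clip(theta_p + s * theta_s)` where `s = +1` in the BxC cross (the
#' paternal allele is Cast) and `s = -1` in CxB (the maternal allele is
#' Cast). Effects are additive on the probability scale, so the
#' reciprocal-mean parental estimator is exactly unbiased away from the
#' clip bounds.
#'
#' @param config A [sim_config()]; `theta_p`, `theta_s` and `gene_ids`
#'   settings are recycled over `n_genes`.
#' @param seed Integer seed.
#' @param gene_ids Optional gene identifiers (default `gene001...`).
#' @return Allele-count data.frame (`gene_id replicate cross maternal_reads
#'   paternal_reads length`) with the per-gene truth attached as attribute
#'   `"truth"` (`gene_id, theta_p, theta_s`).
#' @export
simulate_counts <- function(config, seed, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  theta_p <- rep_len(config$theta_p, n)
  theta_s <- rep_len(config$theta_s, n)
  with_seed(seed, {
    lengths <- as.integer(round(stats::runif(n, 500, 5000)))
    grid <- expand.grid(gene = seq_len(n),
                        replicate = seq_len(config$n_replicates),
                        cross = c("BxC", "CxB"), stringsAsFactors = FALSE)
    s <- ifelse(grid$cross == "BxC", 1, -1)
    p <- clip_prob(theta_p[grid$gene] + s * theta_s[grid$gene], config$clip)
    pat <- stats::rbinom(nrow(grid), size = config$depth, prob = p)
    out <- data.frame(gene_id = gene_ids[grid$gene],
                      replicate = grid$replicate, cross = grid$cross,
                      maternal_reads = config$depth - pat,
                      paternal_reads = pat,
                      length = lengths[grid$gene],
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(gene_id = gene_ids, theta_p = theta_p,
                                     theta_s = theta_s,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Simulate pyrosequencing validation measurements
#'
#' Per gene, tissue, cross and replicate: the true per-cross paternal
#' percent `100 * clip(theta_p + s * theta_s)` is distorted by the assay's
#' amplification bias ([distort_amplification()], the exact inverse of the
#' caller's correction), Gaussian noise of `pyro_noise_sd` points is added,
#' and the result clipped to \[0, 100\].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param tissues Character vector of tissue names; the first is marked as
#'   placenta when named `"placenta"`.
#' @param n_pyro_replicates Biological replicates per cross, default 4.
#' @param gene_ids Optional identifiers.
#' @return Pyrosequencing measurement data.frame in the [validate_calls()]
#'   dialect, with per-gene truth attached as attribute `"truth"`.
#' @export
simulate_pyro <- function(config, seed,
                          tissues = c("placenta", "liver", "brain"),
                          n_pyro_replicates = 4, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(n))
  theta_p <- rep_len(config$theta_p, n)
  theta_s <- rep_len(config$theta_s, n)
  gdna <- rep_len(config$gdna_bias, n)
  rel <- rep_len(config$rel_expression, n)
  with_seed(seed, {
    grid <- expand.grid(gene = seq_len(n), tissue = tissues,
                        cross = c("BxC", "CxB"),
                        replicate = seq_len(n_pyro_replicates),
                        stringsAsFactors = FALSE)
    s <- ifelse(grid$cross == "BxC", 1, -1)
    true_pct <- 100 * clip_prob(theta_p[grid$gene] + s * theta_s[grid$gene],
                                config$clip)
    raw <- distort_amplification(true_pct, gdna[grid$gene]) +
      stats::rnorm(nrow(grid), 0, config$pyro_noise_sd)
    out <- data.frame(gene_id = gene_ids[grid$gene], tissue = grid$tissue,
                      cross = grid$cross, replicate = grid$replicate,
                      paternal_pct_raw = pmin(pmax(raw, 0), 100),
                      gdna_paternal_pct = gdna[grid$gene],
                      rel_expression = rel[grid$gene],
                      is_placenta = grid$tissue == "placenta",
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(gene_id = gene_ids, theta_p = theta_p,
                                     theta_s = theta_s, gdna_bias = gdna,
                                     stringsAsFactors = FALSE)
    out
  })
}
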