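## Replicate-level allele-specific expression decomposition.
##
## Input tables follow the dialect
##   gene_id replicate cross maternal_reads paternal_reads length
## with cross in {BxC, CxB}. Replicates are pooled by summing counts within a
## cross before fractions are taken (a per-replicate-mean alternative is
## available via pool_replicates = FALSE).

check_cross <- function(cross) {
  bad <- !cross %in% c("BxC", "CxB")
  if (any(bad)) {
    stop_poebias("cross labels must be BxC or CxB, got: ",
                 paste(unique(cross[bad]), collapse = ", "),
                 class = "poebias_parse_error")
  }
}

#' Transcripts per million
#'
#' Length-normalised expression: `rate_g = count_g / length_g`,
#' `tpm_g = 1e6 * rate_g / sum(rates)`. TPM sums to 1e6 (all-zero counts
#' return all-zero TPM with a warning).
#'
#' @param counts Per-gene summed read counts.
#' @param lengths Per-gene lengths in bp (positive).
#' @return Numeric vector of TPM values.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) {
    stop_poebias("gene lengths must be positive", class = "poebias_domain_error")
  }
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) {
    warning("all counts are zero; TPM undefined, returning zeros",
            call. = FALSE)
    return(rep(0, length(counts)))
  }
  1e6 * rate / total
}

#' Parental and strain decomposition for one gene
#'
#' Pools replicate counts within each reciprocal cross, takes per-cross
#' paternal percents, and maps them to a parental-origin score
#' ([reciprocal_mean_paternal()]) and a strain score ([strain_percent()]).
#'
#' @param table Allele-count data.frame for a single gene (columns
#'   `replicate, cross, maternal_reads, paternal_reads`).
#' @param pool_replicates Pool counts before taking fractions (default); if
#'   `FALSE`, per-replicate fractions are averaged instead.
#' @return A list with `parental_pct`, `strain_pct`, `paternal_pct_bc`,
#'   `paternal_pct_cb`, `n_rep_bc`, `n_rep_cb`.
#' @export
gene_ase <- function(table, pool_replicates = TRUE) {
  check_cross(table$cross)
  if (any(table$maternal_reads < 0) || any(table$paternal_reads < 0)) {
    stop_poebias("negative read counts", class = "poebias_domain_error")
  }
  per_cross <- function(cr) {
    sub <- table[table$cross == cr, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop_poebias("no replicates for cross ", cr,
                   class = "poebias_missing_cross")
    }
    tot <- sub$maternal_reads + sub$paternal_reads
    if (sum(tot) == 0) {
      stop_poebias("undefined allelic bias: zero total reads in cross ", cr,
                   class = "poebias_undefined_bias")
    }
    if (pool_replicates) {
      paternal_percent_from_reads(sum(sub$paternal_reads), sum(tot))
    } else {
      ok <- tot > 0
      mean(100 * sub$paternal_reads[ok] / tot[ok])
    }
  }
  bc <- per_cross("BxC")
  cb <- per_cross("CxB")
  list(parental_pct = reciprocal_mean_paternal(bc, cb),
       strain_pct = strain_percent(bc, cb),
       paternal_pct_bc = bc, paternal_pct_cb = cb,
       n_rep_bc = sum(table$cross == "BxC"),
       n_rep_cb = sum(table$cross == "CxB"))
}

#' Low-count filter on pooled per-cross totals
#'
#' Drops a gene when the pooled read total in either cross falls below the
#' threshold; low depth is the classic failure mode behind spurious weak
#' biases (a single read then shifts the fraction by several points).
#'
#' @param table Allele-count data.frame for one gene.
#' @param min_reads_per_cross Minimum pooled reads per cross (default 20,
#'   below which one read moves the fraction by >= 5 points).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
low_count_filter <- function(table, min_reads_per_cross = 20) {
  stopifnot(min_reads_per_cross >= 1)
  check_cross(table$cross)
  totals <- tapply(table$maternal_reads + table$paternal_reads, table$cross,
                   sum)
  all(c("BxC", "CxB") %in% names(totals)) &&
    all(totals >= min_reads_per_cross)
}

#' Permutation screen for a parental-origin effect
#'
#' A label-flip permutation test on replicate-level paternal fractions: the
#' statistic is `|parental_pct - 50|` with the parental score computed from
#' per-cross means of replicate fractions; the null is built by flipping the
#' maternal/paternal labels independently within replicates (preserving the
#' cross structure), and `p = (1 + #perm >= observed) / (1 + n_perm)`. This
#' is a simple significance screen, not a reimplementation of published
#' resampling callers.
#'
#' @param table Allele-count data.frame for one gene, at least two
#'   replicates per cross.
#' @param n_perm Number of permutations (warning below 99: p-value
#'   granularity).
#' @param seed Integer seed; same seed, same p.
#' @return Permutation p-value in (0, 1\].
#' @export
permutation_parent_test <- function(table, n_perm = 999, seed = 1L) {
  check_cross(table$cross)
  if (n_perm < 99) {
    warning("n_perm < 99 gives coarse p-value granularity", call. = FALSE)
  }
  tot <- table$maternal_reads + table$paternal_reads
  if (any(tot == 0)) {
    stop_poebias("replicate with zero total reads",
                 class = "poebias_undefined_bias")
  }
  if (sum(table$cross == "BxC") < 2L || sum(table$cross == "CxB") < 2L) {
    stop_poebias("need >= 2 replicates per cross",
                 class = "poebias_domain_error")
  }
  f <- table$paternal_reads / tot
  idx_b <- table$cross == "BxC"
  parental <- function(fr) (mean(fr[idx_b]) + mean(fr[!idx_b])) / 2
  obs <- abs(parental(f) - 0.5)
  with_seed(seed, {
    n <- length(f)
    flips <- matrix(stats::runif(n_perm * n) < 0.5, nrow = n_perm)
    fm <- matrix(f, nrow = n_perm, ncol = n, byrow = TRUE)
    fm[flips] <- 1 - fm[flips]
    stat <- abs((rowMeans(fm[, idx_b, drop = FALSE]) +
                   rowMeans(fm[, !idx_b, drop = FALSE])) / 2 - 0.5)
    (1 + sum(stat >= obs - 1e-12)) / (1 + n_perm)
  })
}

#' Per-gene ASE results for a full allele-count table
#'
#' Applies [low_count_filter()], [gene_ase()] and per-replicate TPM (summing
#' the two alleles' counts per gene and replicate, then averaging across
#' replicates) over every gene of an allele-count table, optionally running
#' the permutation screen.
#'
#' @param table Allele-count data.frame (`gene_id replicate cross
#'   maternal_reads paternal_reads length`).
#' @param min_reads_per_cross Passed to [low_count_filter()]; filtered genes
#'   are reported with `kept = FALSE` and `NA` scores.
#' @param n_perm Permutations for the screen; `0` skips it.
#' @param seed Seed for the permutation screen.
#' @return Data.frame with one row per gene: `gene_id, parental_pct,
#'   strain_pct, paternal_pct_bc, paternal_pct_cb, mean_tpm, n_rep_bc,
#'   n_rep_cb, kept` and `permutation_p` when the screen is run.
#' @export
ase_table <- function(table, min_reads_per_cross = 20, n_perm = 0,
                      seed = 1L) {
  need <- c("gene_id", "replicate", "cross", "maternal_reads",
            "paternal_reads")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_poebias("allele-count table lacks column(s): ",
                 paste(miss, collapse = ", "), class = "poebias_parse_error")
  }
  genes <- unique(table$gene_id)
  ## per-replicate TPM over genes, then mean per gene
  mean_tpm <- rep(NA_real_, length(genes))
  names(mean_tpm) <- genes
  if ("length" %in% names(table)) {
    total <- table$maternal_reads + table$paternal_reads
    rep_key <- paste(table$cross, table$replicate)
    tpm_sum <- stats::setNames(numeric(length(genes)), genes)
    tpm_n <- stats::setNames(numeric(length(genes)), genes)
    for (rk in unique(rep_key)) {
      sel <- rep_key == rk
      sub_genes <- table$gene_id[sel]
      v <- tpm(total[sel], table$length[sel])
      tpm_sum[sub_genes] <- tpm_sum[sub_genes] + v
      tpm_n[sub_genes] <- tpm_n[sub_genes] + 1
    }
    mean_tpm <- tpm_sum / pmax(tpm_n, 1)
  }
  rows <- lapply(genes, function(g) {
    sub <- table[table$gene_id == g, , drop = FALSE]
    kept <- low_count_filter(sub, min_reads_per_cross)
    res <- if (kept) gene_ase(sub) else
      list(parental_pct = NA_real_, strain_pct = NA_real_,
           paternal_pct_bc = NA_real_, paternal_pct_cb = NA_real_,
           n_rep_bc = sum(sub$cross == "BxC"),
           n_rep_cb = sum(sub$cross == "CxB"))
    out <- data.frame(gene_id = g, parental_pct = res$parental_pct,
                      strain_pct = res$strain_pct,
                      paternal_pct_bc = res$paternal_pct_bc,
                      paternal_pct_cb = res$paternal_pct_cb,
                      mean_tpm = unname(mean_tpm[g]),
                      n_rep_bc = res$n_rep_bc, n_rep_cb = res$n_rep_cb,
                      kept = kept, stringsAsFactors = FALSE)
    if (n_perm > 0) {
      out$permutation_p <- if (kept)
        permutation_parent_test(sub, n_perm = n_perm, seed = seed) else
          NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
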