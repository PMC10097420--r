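## Shared fixture builders and independent oracles.

gene_df <- function(gene_id, chrom, start, end, strand = "+",
                    names = gene_id, ...) {
  data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, names = names, ...,
             stringsAsFactors = FALSE)
}

## Independent O(n^2) classification oracle: plain arithmetic loops, no
## shared code with assign_class (which goes through GenomicRanges).
brute_force_classes <- function(candidates, knowns, window = 1e6) {
  gap <- function(c1, s1, e1, c2, s2, e2) {
    if (c1 != c2) return(Inf)
    if (s1 < e2 && s2 < e1) return(0)
    max(s1, s2) - min(e1, e2)
  }
  n <- nrow(candidates)
  out <- character(n)
  for (i in seq_len(n)) {
    dk <- Inf
    for (j in seq_len(nrow(knowns))) {
      dk <- min(dk, gap(candidates$chrom[i], candidates$start[i],
                        candidates$end[i], knowns$chrom[j],
                        knowns$start[j], knowns$end[j]))
    }
    if (dk <= window) { out[i] <- "class3"; next }
    dn <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      dn <- min(dn, gap(candidates$chrom[i], candidates$start[i],
                        candidates$end[i], candidates$chrom[j],
                        candidates$start[j], candidates$end[j]))
    }
    out[i] <- if (dn <= window) "class2" else "class1"
  }
  out
}

## random gene tables for property-style checks
random_genes <- function(n, prefix = "g", chroms = c("chr1", "chr2"),
                         max_pos = 1e7) {
  start <- as.integer(runif(n, 0, max_pos))
  gene_df(sprintf("%s%03d", prefix, seq_len(n)),
          sample(chroms, n, replace = TRUE), start,
          start + as.integer(runif(n, 100, 5e4)),
          strand = sample(c("+", "-"), n, replace = TRUE))
}

## small allele-count table builder
count_table <- function(gene_id = "g1", pat_bc, mat_bc, pat_cb, mat_cb) {
  rbind(
    data.frame(gene_id = gene_id, replicate = seq_along(pat_bc),
               cross = "BxC", maternal_reads = mat_bc,
               paternal_reads = pat_bc, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, replicate = seq_along(pat_cb),
               cross = "CxB", maternal_reads = mat_cb,
               paternal_reads = pat_cb, stringsAsFactors = FALSE))
}
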