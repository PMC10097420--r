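## Genomic-context classification of candidates.
##
## Novel candidates are labelled by proximity to known imprinted genes:
##   class3 - within `window` (default 1 Mb) of a known imprinted gene;
##   class2 - else within `window` of another novel candidate;
##   class1 - isolated singleton.
## Distance is the interval gap (0 when overlapping, Inf across chromosomes).

#' Gap distance between two genomic intervals
#'
#' 0 if the intervals overlap or abut, the gap in bp otherwise, `Inf` when the
#' intervals are on different chromosomes. Coordinates 0-based half-open.
#'
#' @param a,b Gene-record data.frames (rows recycled to common length).
#' @return Numeric vector of distances in bp.
#' @export
interval_distance <- function(a, b) {
  gap <- pmax(a$start, b$start) - pmin(a$end, b$end)
  ifelse(a$chrom == b$chrom, pmax(0, gap), Inf)
}

#' Classify novel candidates by genomic context
#'
#' @param candidates Gene-record data.frame of novel candidates.
#' @param knowns Gene-record data.frame of known imprinted genes. A gene
#'   appearing in both tables is a conflict error.
#' @param window Proximity window in bp; "within" means gap `<= window`.
#'   Default 1 Mb.
#' @return Data.frame `gene_id, status, class` covering candidates
#'   (`status = "novel"`, `class` in `class1/class2/class3`) and knowns
#'   (`status = class = "known"`), in input order (candidates first).
#' @export
assign_class <- function(candidates, knowns, window = 1e6) {
  stopifnot(window > 0)
  candidates <- validate_gene_records(candidates, "candidates")
  knowns <- validate_gene_records(knowns, "knowns")
  dup <- intersect(unlist(gene_names(candidates)), unlist(gene_names(knowns)))
  if (length(dup)) {
    stop_poebias("gene(s) present in both candidate and known lists: ",
                 paste(dup, collapse = ", "), class = "poebias_conflict_error")
  }
  n <- nrow(candidates)
  cls <- character(n)
  if (n > 0L) {
    cand_gr <- genes_as_granges(candidates)
    d_known <- rep(Inf, n)
    if (nrow(knowns) > 0L) {
      hits <- GenomicRanges::distanceToNearest(
        cand_gr, genes_as_granges(knowns), ignore.strand = TRUE)
      d_known[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    }
    d_novel <- rep(Inf, n)
    if (n > 1L) {
      hits <- GenomicRanges::distanceToNearest(cand_gr, ignore.strand = TRUE)
      d_novel[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    }
    cls <- ifelse(d_known <= window, "class3",
                  ifelse(d_novel <= window, "class2", "class1"))
  }
  rbind(
    data.frame(gene_id = candidates$gene_id, status = "novel", class = cls,
               stringsAsFactors = FALSE),
    data.frame(gene_id = knowns$gene_id, status = "known", class = "known",
               stringsAsFactors = FALSE))
}

#' Peripheral or flanked position of a gene within a known cluster
#'
#' A class-3 gene is `flanked` when at least one known gene midpoint lies
#' strictly to its left and at least one strictly to its right on the same
#' chromosome; otherwise it sits at the cluster `peripheral`.
#'
#' @param gene One-row gene-record data.frame.
#' @param cluster_knowns Gene-record data.frame of the known genes in the
#'   linked cluster (non-empty).
#' @return `"flanked"` or `"peripheral"`.
#' @export
periphery_status <- function(gene, cluster_knowns) {
  if (nrow(cluster_knowns) == 0L) {
    stop_poebias("cluster has no known genes", class = "poebias_domain_error")
  }
  same <- cluster_knowns[cluster_knowns$chrom == gene$chrom[1L], , drop = FALSE]
  if (nrow(same) == 0L) return("peripheral")
  gm <- (gene$start[1L] + gene$end[1L]) / 2
  km <- (same$start + same$end) / 2
  if (any(km < gm) && any(km > gm)) "flanked" else "peripheral"
}

#' Orientation of the preferred allele relative to ICR methylation
#'
#' `meth_icr` when the gene's preferentially expressed allele is the parental
#' chromosome carrying germline methylation at the cluster's imprinting
#' control region, `un_icr` when it is the unmethylated one, `both` when the
#' gene is reported as biased in both directions across tissues, and
#' `no_icr` when the cluster has no linked ICR.
#'
#' @param preferred_parent `"maternal"`, `"paternal"`, or `"both"`
#'   (vectorised).
#' @param methylated_parent The ICR's methylated parent (`"maternal"` or
#'   `"paternal"`), recycled; `NA` for clusters without a linked ICR.
#' @return Character vector in `meth_icr/un_icr/both/no_icr`.
#' @export
icr_orientation <- function(preferred_parent, methylated_parent) {
  bad <- !preferred_parent %in% c("maternal", "paternal", "both")
  if (any(bad)) {
    stop_poebias("preferred_parent must be maternal/paternal/both",
                 class = "poebias_domain_error")
  }
  n <- max(length(preferred_parent), length(methylated_parent))
  pp <- rep_len(preferred_parent, n)
  mp <- rep_len(methylated_parent, n)
  ifelse(is.na(mp), "no_icr",
         ifelse(pp == "both", "both",
                ifelse(pp == mp, "meth_icr", "un_icr")))
}
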