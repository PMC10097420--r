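## Cross-study overlap of candidate sets.

#' Build a gene-by-study membership matrix
#'
#' One row per merged gene, one column per study (or study-tissue), `TRUE`
#' when any tissue of that study reported the gene. Gene names are first
#' collapsed under the alias closure so that the same transcript reported
#' under alternative names by different studies occupies a single row.
#'
#' @param calls Data.frame with columns `gene_id` and `study` (and
#'   optionally `tissue`).
#' @param alias_map Optional two-column data.frame of equivalent name pairs.
#' @param by `"study"` (default) or `"study_tissue"` for tissue-level
#'   columns (`study tissue` pasted with `:`).
#' @param tissue Optional tissue name; restricts `calls` to that tissue
#'   before building (tissue-level comparisons across studies).
#' @return Logical matrix with gene rownames and study colnames; every row
#'   has at least one `TRUE`.
#' @export
build_membership <- function(calls, alias_map = NULL,
                             by = c("study", "study_tissue"), tissue = NULL) {
  by <- match.arg(by)
  if (!all(c("gene_id", "study") %in% names(calls))) {
    stop_poebias("calls must have gene_id and study columns",
                 class = "poebias_parse_error")
  }
  if (!is.null(tissue)) {
    calls <- calls[calls$tissue %in% tissue, , drop = FALSE]
  }
  if (nrow(calls) == 0L) {
    return(matrix(logical(), 0L, 0L))
  }
  gene <- as.character(calls$gene_id)
  if (!is.null(alias_map) && nrow(as.data.frame(alias_map)) > 0L) {
    am <- as.data.frame(alias_map, stringsAsFactors = FALSE)
    universe <- unique(c(gene, am[[1L]], am[[2L]]))
    parent <- uf_new(universe)
    for (k in seq_len(nrow(am))) {
      parent <- uf_union(parent, am[[k, 1L]], am[[k, 2L]])
    }
    roots <- vapply(universe, function(n) uf_find(parent, n), integer(1L))
    canon <- vapply(split(universe, roots), function(g) min(g), character(1L))
    gene <- canon[as.character(roots[gene])]
  }
  col <- if (by == "study") as.character(calls$study) else
    paste(calls$study, calls$tissue, sep = ":")
  genes <- sort(unique(gene))
  cols <- sort(unique(col))
  m <- matrix(FALSE, length(genes), length(cols),
              dimnames = list(genes, cols))
  m[cbind(match(gene, genes), match(col, cols))] <- TRUE
  m
}

#' Overlap counts by degree and by exact study subset
#'
#' @param membership Logical membership matrix from [build_membership()].
#' @param strata Optional named vector (names = gene rownames) of a gene
#'   attribute (e.g. class label or known/novel status) to stratify the
#'   degree counts by; genes missing from `strata` are an error.
#' @return A list with `degree` (data.frame `n_studies, n_genes`), `subset`
#'   (data.frame `subset, n_genes` with `subset` the `+`-joined column
#'   names), and, when `strata` is given, `stratified` (data.frame
#'   `stratum, n_studies, n_genes`). Degree and subset counts each sum to
#'   the number of rows.
#' @export
overlap_counts <- function(membership, strata = NULL) {
  if (nrow(membership) == 0L) {
    return(list(degree = data.frame(n_studies = integer(), n_genes = integer()),
                subset = data.frame(subset = character(),
                                    n_genes = integer())))
  }
  if (any(rowSums(membership) == 0L)) {
    warning("dropping rows with no study membership", call. = FALSE)
    membership <- membership[rowSums(membership) > 0L, , drop = FALSE]
  }
  deg <- rowSums(membership)
  degree <- as.data.frame(table(n_studies = deg), stringsAsFactors = FALSE)
  names(degree)[2L] <- "n_genes"
  degree$n_studies <- as.integer(degree$n_studies)
  pat <- apply(membership, 1L, function(r)
    paste(colnames(membership)[r], collapse = "+"))
  subset <- as.data.frame(table(subset = pat), stringsAsFactors = FALSE)
  names(subset)[2L] <- "n_genes"
  out <- list(degree = degree, subset = subset)
  if (!is.null(strata)) {
    miss <- setdiff(rownames(membership), names(strata))
    if (length(miss)) {
      stop_poebias("strata missing for gene(s): ",
                   paste(utils::head(miss, 3L), collapse = ", "),
                   class = "poebias_domain_error")
    }
    st <- strata[rownames(membership)]
    strat <- as.data.frame(table(stratum = st, n_studies = deg),
                           stringsAsFactors = FALSE)
    names(strat)[3L] <- "n_genes"
    strat$n_studies <- as.integer(strat$n_studies)
    strat <- strat[strat$n_genes > 0L, , drop = FALSE]
    rownames(strat) <- NULL
    out$stratified <- strat
  }
  out
}
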