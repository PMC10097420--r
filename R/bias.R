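## Allelic bias metrics.
##
## All percentages are expressed as percent of reads (or signal) from the
## paternal allele unless stated otherwise. Reciprocal crosses are labelled
## BxC (C57BL/6 dam x CastEiJ sire: paternal allele is Cast) and CxB
## (CastEiJ dam x C57BL/6 sire: maternal allele is Cast). Averaging the
## paternal percent over the two crosses cancels strain effects; the
## complementary combination isolates the Cast-allele (strain) share.

BIAS_BIN_LABELS <- c("50-60", "60-70", "70-80", "80-90", "90-100")

#' Percent paternal expression from pooled allele-specific read counts
#'
#' Computes `100 * paternal / total` with reads summed over both reciprocal
#' crosses. The maternal percent is the complement to 100.
#'
#' @param paternal_reads Non-negative paternal read count(s).
#' @param total_reads Positive total read count(s); a zero total is an error
#'   (the gene must be filtered, not silently reported as 50%).
#' @return Percent paternal, vectorised.
#' @export
paternal_percent_from_reads <- function(paternal_reads, total_reads) {
  if (any(total_reads <= 0)) {
    stop_poebias("undefined allelic bias: total read count is zero",
                 class = "poebias_undefined_bias")
  }
  if (any(paternal_reads < 0) || any(paternal_reads > total_reads)) {
    stop_poebias("paternal reads must lie in [0, total]",
                 class = "poebias_domain_error")
  }
  100 * paternal_reads / total_reads
}

#' Percent maternal expression from a maternal/paternal fold change
#'
#' `100 * fc / (1 + fc)`: a strictly increasing map from fold change to
#' percent, with fc = 1 giving 50% and fc -> Inf giving 100%.
#'
#' @param fc Non-negative fold change(s), maternal over paternal.
#' @return Percent maternal, vectorised.
#' @export
maternal_percent_from_fold_change <- function(fc) {
  if (any(fc < 0)) {
    stop_poebias("fold change must be non-negative",
                 class = "poebias_domain_error")
  }
  ifelse(is.infinite(fc), 100, 100 * fc / (1 + fc))
}

#' Parental-origin score: mean paternal percent over reciprocal crosses
#'
#' The arithmetic mean of the paternal percent in the BxC and CxB crosses. A
#' pure strain effect shifts the two crosses in opposite directions and
#' cancels exactly; what remains tracks parental origin.
#'
#' @param paternal_pct_bc,paternal_pct_cb Percent paternal in each cross,
#'   both in \[0, 100\]. Missing values propagate as `NA` (never a mean of
#'   one cross).
#' @return Percent paternal attributable to parental origin.
#' @export
reciprocal_mean_paternal <- function(paternal_pct_bc, paternal_pct_cb) {
  check_percent(paternal_pct_bc, "paternal_pct_bc")
  check_percent(paternal_pct_cb, "paternal_pct_cb")
  (paternal_pct_bc + paternal_pct_cb) / 2
}

#' Strain score: mean Cast-allele percent over reciprocal crosses
#'
#' `(pct_bc + (100 - pct_cb)) / 2`, i.e. the Cast-allele share averaged over
#' crosses (in BxC the paternal allele is Cast, in CxB the maternal one). A
#' pure parental-origin effect cancels, leaving 50.
#'
#' @inheritParams reciprocal_mean_paternal
#' @return Percent of expression from the Cast allele.
#' @export
strain_percent <- function(paternal_pct_bc, paternal_pct_cb) {
  check_percent(paternal_pct_bc, "paternal_pct_bc")
  check_percent(paternal_pct_cb, "paternal_pct_cb")
  (paternal_pct_bc + (100 - paternal_pct_cb)) / 2
}

#' Reconstruct per-cross paternal percents from parental and strain scores
#'
#' The inverse of the ([reciprocal_mean_paternal()], [strain_percent()])
#' transform: `pct_bc = parental + strain - 50`,
#' `pct_cb = parental - strain + 50`. Exact by construction.
#'
#' @param parental_pct,strain_pct Scores as returned by the forward pair.
#' @return A list with elements `paternal_pct_bc` and `paternal_pct_cb`.
#' @export
cross_percents_from_scores <- function(parental_pct, strain_pct) {
  list(paternal_pct_bc = parental_pct + strain_pct - 50,
       paternal_pct_cb = parental_pct - strain_pct + 50)
}

#' Maximum symmetric allelic bias across tissues
#'
#' Per-tissue paternal percents are symmetrised to \[50, 100\] via
#' `max(v, 100 - v)` and the maximum taken; the preferred parent is the
#' direction achieving that maximum (`"both"` if tissues favouring opposite
#' parents tie at the maximum, `"none"` if the maximum is exactly 50).
#'
#' @param paternal_pcts Numeric vector of per-tissue paternal percents in
#'   \[0, 100\]; `NA`s are dropped.
#' @return A list with `bias_pct` (in \[50, 100\]) and `preferred_parent`
#'   (one of `"maternal"`, `"paternal"`, `"both"`, `"none"`).
#' @export
max_bias <- function(paternal_pcts) {
  v <- paternal_pcts[!is.na(paternal_pcts)]
  if (length(v) == 0L) {
    stop_poebias("max_bias needs at least one bias value",
                 class = "poebias_domain_error")
  }
  check_percent(v, "paternal percent")
  sym <- pmax(v, 100 - v)
  m <- max(sym)
  if (m == 50) {
    return(list(bias_pct = 50, preferred_parent = "none"))
  }
  at_max <- abs(sym - m) < 1e-9
  dirs <- unique(ifelse(v[at_max] > 50, "paternal", "maternal"))
  parent <- if (length(dirs) == 2L) "both" else dirs
  list(bias_pct = m, preferred_parent = parent)
}

#' Assign a symmetric bias to one of five 10-point bins
#'
#' Bins are left-closed right-open — \[50,60), \[60,70), \[70,80), \[80,90) —
#' with the top bin closed: \[90,100\].
#'
#' @param bias Percent(s) in \[50, 100\].
#' @return Factor with levels `50-60`, `60-70`, `70-80`, `80-90`, `90-100`.
#' @export
assign_bin <- function(bias) {
  check_percent(bias, "bias", lo = 50, hi = 100)
  idx <- findInterval(bias, c(50, 60, 70, 80, 90, 100),
                      rightmost.closed = TRUE)
  factor(BIAS_BIN_LABELS[idx], levels = BIAS_BIN_LABELS)
}

#' Canonical-imprinting flag
#'
#' A gene is canonically biased when more than 70% of its expression comes
#' from the preferred allele in at least one tissue (strict inequality: a
#' 70:30 ratio is still "weak").
#'
#' @param bias Symmetric percent(s) in \[50, 100\].
#' @return Character vector, `"canonical"` or `"weak"`.
#' @export
canonical_flag <- function(bias) {
  check_percent(bias, "bias", lo = 50, hi = 100)
  ifelse(bias > 70, "canonical", "weak")
}

#' Summarise per-study, per-tissue calls into per-gene bias values
#'
#' Consumes the study-call TSV dialect: either columns
#' `gene_id study tissue paternal_pct_bc paternal_pct_cb` (reciprocal
#' percents; a strain-cancelling mean is taken) or
#' `gene_id study tissue fold_change_mat_over_pat` (converted via
#' [maternal_percent_from_fold_change()]), or a precomputed
#' `paternal_pct` column. Returns one row per gene with the maximum symmetric
#' bias, preferred parent, bin, and canonical flag.
#'
#' @param calls Data.frame of per-tissue study calls.
#' @return Data.frame `gene_id, bias_pct, preferred_parent, bin, canonical`.
#' @export
summarise_gene_bias <- function(calls) {
  if (all(c("paternal_pct_bc", "paternal_pct_cb") %in% names(calls))) {
    pat <- reciprocal_mean_paternal(calls$paternal_pct_bc,
                                    calls$paternal_pct_cb)
  } else if ("fold_change_mat_over_pat" %in% names(calls)) {
    pat <- 100 - maternal_percent_from_fold_change(
      calls$fold_change_mat_over_pat)
  } else if ("paternal_pct" %in% names(calls)) {
    pat <- calls$paternal_pct
  } else {
    stop_poebias("calls must carry reciprocal percents, a fold change, ",
                 "or paternal_pct", class = "poebias_parse_error")
  }
  res <- lapply(split(pat, calls$gene_id), max_bias)
  data.frame(gene_id = names(res),
             bias_pct = vapply(res, `[[`, numeric(1L), "bias_pct"),
             preferred_parent = vapply(res, `[[`, character(1L),
                                       "preferred_parent"),
             bin = assign_bin(vapply(res, `[[`, numeric(1L), "bias_pct")),
             canonical = canonical_flag(
               vapply(res, `[[`, numeric(1L), "bias_pct")),
             row.names = NULL, stringsAsFactors = FALSE)
}
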