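## Pyrosequencing validation calling.
##
## Raw per-replicate percent-paternal measurements are corrected for primer
## amplification bias against a matched genomic-DNA assay (gDNA is truly
## 50:50, so its measured deviation is pure assay bias), averaged within each
## reciprocal cross and then across crosses to cancel strain effects, gated
## on expression relative to the housekeeping reference, and called per
## tissue against the 45-55% biallelic window.

#' Correct a pyrosequencing measurement for amplification bias
#'
#' Odds normalisation against the matched gDNA assay: corrected odds equal
#' raw odds divided by gDNA odds, mapped back to a percent. This is the
#' unique odds-multiplicative correction that leaves an unbiased assay
#' (gDNA = 50) untouched and maps the gDNA measurement itself to exactly 50.
#' Values at 0 or 100 are clamped to \[1, 99\] with a warning before odds
#' are formed.
#'
#' @param paternal_pct_raw Raw percent-paternal measurement(s).
#' @param gdna_paternal_pct Percent paternal measured on genomic DNA for the
#'   same assay.
#' @return Corrected percent paternal, vectorised.
#' @export
correct_amplification <- function(paternal_pct_raw, gdna_paternal_pct) {
  clamp <- function(x, what) {
    out <- pmin(pmax(x, 1), 99)
    if (any(!is.na(x) & (x <= 0 | x >= 100))) {
      warning(what, " at or beyond 0/100 clamped to [1, 99]", call. = FALSE)
    }
    out
  }
  raw <- clamp(paternal_pct_raw, "raw percent")
  gd <- clamp(gdna_paternal_pct, "gDNA percent")
  o <- (raw / (100 - raw)) / (gd / (100 - gd))
  100 * o / (1 + o)
}

#' Distort a true percent by a known amplification bias
#'
#' The exact inverse of [correct_amplification()]: multiplies the true odds
#' by the assay's gDNA odds. Used by the synthetic generator so that
#' correction recovers truth.
#'
#' @param true_pct True percent paternal.
#' @param gdna_paternal_pct Assay bias as the percent the gDNA would read.
#' @return Distorted (raw) percent paternal.
#' @export
distort_amplification <- function(true_pct, gdna_paternal_pct) {
  p <- pmin(pmax(true_pct, 1), 99)
  g <- pmin(pmax(gdna_paternal_pct, 1), 99)
  o <- (p / (100 - p)) * (g / (100 - g))
  100 * o / (1 + o)
}

#' Expression gate against the housekeeping reference
#'
#' Fails when relative expression (target over *Tbp*) is strictly below the
#' threshold; such genes give inconsistent pyrosequencing replicates and are
#' not analysed further.
#'
#' @param rel_expression Non-negative relative expression value(s).
#' @param threshold Gate (default 0.05 times the reference).
#' @return Logical vector, `TRUE` = pass.
#' @export
expression_gate <- function(rel_expression, threshold = 0.05) {
  if (any(rel_expression < 0, na.rm = TRUE)) {
    stop_poebias("relative expression must be non-negative",
                 class = "poebias_domain_error")
  }
  !is.na(rel_expression) & rel_expression >= threshold
}

#' Corrected reciprocal-mean paternal percent for one gene and tissue
#'
#' Replicate measurements are corrected for amplification bias, averaged
#' within each reciprocal cross, and the two cross means averaged. Returns
#' `NA` when either cross is entirely missing (never a mean of one cross).
#'
#' @param measurements Data.frame for one gene x tissue with columns
#'   `cross, paternal_pct_raw, gdna_paternal_pct`.
#' @return Corrected mean percent paternal, or `NA`.
#' @export
tissue_mean <- function(measurements) {
  check_cross(measurements$cross)
  corr <- correct_amplification(measurements$paternal_pct_raw,
                                measurements$gdna_paternal_pct)
  if (!all(c("BxC", "CxB") %in% measurements$cross)) return(NA_real_)
  m <- tapply(corr, measurements$cross, mean)
  unname((m[["BxC"]] + m[["CxB"]]) / 2)
}

#' Strain-bias flag over per-tissue strain scores
#'
#' `TRUE` when the strain score falls strictly outside the 45-55 window in
#' at least two tissues.
#'
#' @param strain_pcts Per-tissue strain scores (percent Cast allele).
#' @param window Inclusive no-bias window, default `c(45, 55)`.
#' @return Logical flag.
#' @export
strain_flag <- function(strain_pcts, window = c(45, 55)) {
  v <- strain_pcts[!is.na(strain_pcts)]
  sum(v < window[1L] | v > window[2L]) >= 2L
}

#' Call the validation status of one gene from its tissue means
#'
#' Each tissue with a usable value is called paternally biased when its
#' corrected reciprocal mean exceeds 55%, maternally biased below 45%, and
#' biallelic inside the closed window. Category precedence:
#' `Low_expression` (no tissue passes the expression gate or carries data)
#' over `Placental_maternal`/`Placental_paternal` (the only out-of-window
#' tissue is the placenta) over directional `Paternal`/`Maternal` (any
#' non-placental tissue called in that direction) over `Biallelic`.
#' Conflicting directions across somatic tissues are resolved by majority
#' (ties by the larger mean deviation from 50) and flagged.
#'
#' @param tissue_means Named numeric vector of corrected reciprocal-mean
#'   paternal percents (`NA` = not measured).
#' @param is_placenta Logical vector marking placental tissue(s); recycled.
#' @param gate_passed Logical vector of expression-gate results per tissue;
#'   recycled (default all pass). Failed tissues are treated as having no
#'   value.
#' @param window Inclusive biallelic window, default `c(45, 55)`.
#' @return A list with `category`, per-tissue `calls`
#'   (`paternal/maternal/biallelic/no_data`), and `conflicting` (logical).
#' @export
call_gene <- function(tissue_means, is_placenta = FALSE, gate_passed = TRUE,
                      window = c(45, 55)) {
  n <- length(tissue_means)
  is_placenta <- rep_len(is_placenta, n)
  gate_passed <- rep_len(gate_passed, n)
  usable <- !is.na(tissue_means) & gate_passed
  calls <- rep("no_data", n)
  names(calls) <- names(tissue_means)
  calls[usable] <- ifelse(tissue_means[usable] > window[2L], "paternal",
                          ifelse(tissue_means[usable] < window[1L],
                                 "maternal", "biallelic"))
  conflicting <- FALSE
  if (!any(usable)) {
    category <- "Low_expression"
  } else {
    out <- usable & calls != "biallelic"
    if (!any(out)) {
      category <- "Biallelic"
    } else if (all(is_placenta[out])) {
      dir <- unique(calls[out])
      category <- paste0("Placental_", dir[1L])
      conflicting <- length(dir) > 1L
    } else {
      somatic <- out & !is_placenta
      dirs <- calls[somatic]
      if (all(dirs == "paternal")) {
        category <- "Paternal"
      } else if (all(dirs == "maternal")) {
        category <- "Maternal"
      } else {
        conflicting <- TRUE
        n_pat <- sum(dirs == "paternal")
        n_mat <- sum(dirs == "maternal")
        if (n_pat != n_mat) {
          category <- if (n_pat > n_mat) "Paternal" else "Maternal"
        } else {
          dev <- tissue_means[somatic] - 50
          category <- if (mean(dev[dirs == "paternal"]) >
                            abs(mean(dev[dirs == "maternal"])))
            "Paternal" else "Maternal"
        }
        warning("conflicting directional calls across somatic tissues; ",
                "majority category reported", call. = FALSE)
      }
    }
  }
  list(category = category, calls = calls, conflicting = conflicting)
}

#' Run the full validation caller over a pyrosequencing measurement table
#'
#' Input dialect: `gene_id tissue cross replicate paternal_pct_raw
#' gdna_paternal_pct rel_expression is_placenta`. Per gene and tissue the
#' replicate measurements are corrected and averaged ([tissue_mean()]), the
#' expression gate applied to the mean relative expression, a per-tissue
#' strain score computed from the per-cross corrected means, and the gene's
#' category called ([call_gene()]) together with its strain-bias flag.
#'
#' @param measurements Pyrosequencing measurement data.frame.
#' @param biallelic_window Inclusive window, default `c(45, 55)`.
#' @param expression_threshold Gate, default 0.05.
#' @return Data.frame with one row per gene (`gene_id, category,
#'   strain_flag, conflicting, n_tissues_measured`); the long per-tissue
#'   table (`gene_id, tissue, mean_pct, strain_pct, gate_passed, call`) is
#'   attached as attribute `"tissues"`.
#' @export
validate_calls <- function(measurements, biallelic_window = c(45, 55),
                           expression_threshold = 0.05) {
  need <- c("gene_id", "tissue", "cross", "replicate", "paternal_pct_raw",
            "gdna_paternal_pct")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop_poebias("measurement table lacks column(s): ",
                 paste(miss, collapse = ", "), class = "poebias_parse_error")
  }
  if (is.null(measurements$rel_expression)) measurements$rel_expression <- 1
  if (is.null(measurements$is_placenta)) measurements$is_placenta <- FALSE
  tissue_rows <- list()
  gene_rows <- list()
  for (g in unique(measurements$gene_id)) {
    sub <- measurements[measurements$gene_id == g, , drop = FALSE]
    tissues <- unique(sub$tissue)
    means <- strains <- stats::setNames(rep(NA_real_, length(tissues)),
                                        tissues)
    gates <- plac <- stats::setNames(rep(FALSE, length(tissues)), tissues)
    for (ti in tissues) {
      tsub <- sub[sub$tissue == ti, , drop = FALSE]
      gates[ti] <- expression_gate(mean(tsub$rel_expression),
                                   expression_threshold)
      plac[ti] <- any(tsub$is_placenta)
      means[ti] <- tissue_mean(tsub)
      if (all(c("BxC", "CxB") %in% tsub$cross)) {
        corr <- correct_amplification(tsub$paternal_pct_raw,
                                      tsub$gdna_paternal_pct)
        m <- tapply(corr, tsub$cross, mean)
        strains[ti] <- strain_percent(m[["BxC"]], m[["CxB"]])
      }
    }
    res <- call_gene(means, is_placenta = plac, gate_passed = gates,
                     window = biallelic_window)
    sflag <- strain_flag(strains, window = biallelic_window)
    tissue_rows[[g]] <- data.frame(
      gene_id = g, tissue = tissues, mean_pct = unname(means),
      strain_pct = unname(strains), gate_passed = unname(gates),
      call = unname(res$calls), stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(
      gene_id = g, category = res$category, strain_flag = sflag,
      conflicting = res$conflicting,
      n_tissues_measured = sum(!is.na(means) & gates),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, gene_rows)
  rownames(out) <- NULL
  attr(out, "tissues") <- do.call(rbind, c(tissue_rows,
                                           make.row.names = FALSE))
  out
}

#' Load the bundled allele-specific pyrosequencing validation panel
#'
#' A panel of mouse imprinting candidates (novel singletons, novel clusters,
#' and genes near known imprinted domains, plus known imprinted controls)
#' assayed by allele-specific pyrosequencing across thirteen tissues and
#' three developmental stages. Values are corrected reciprocal-cross mean
#' percent-paternal expression; empty cells mark tissues that were not
#' assayed or fell below the expression gate.
#'
#' @param path Path to the panel TSV (defaults to the bundled copy).
#' @return A list with `wide` (the table as shipped) and `long`
#'   (`gene, class, region, tissue, stage, is_placenta, mean_pct`).
#' @export
load_validation_panel <- function(path = system.file(
  "extdata", "validation_panel.tsv", package = "poebias")) {
  wide <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  tissue_cols <- grep("^(e16|P7|P60)\\.", names(wide), value = TRUE)
  long <- do.call(rbind, lapply(tissue_cols, function(col) {
    parts <- strsplit(col, ".", fixed = TRUE)[[1L]]
    data.frame(gene = wide$gene, class = wide$class, region = wide$region,
               tissue = parts[2L], stage = parts[1L],
               is_placenta = parts[2L] == "placenta",
               mean_pct = suppressWarnings(as.numeric(wide[[col]])),
               stringsAsFactors = FALSE)
  }))
  list(wide = wide, long = long)
}

#' Call validation categories for the bundled panel
#'
#' Applies [call_gene()] to each gene's per-tissue means (tissues without a
#' printed value carry no data, so genes with no values at all come out as
#' `Low_expression`).
#'
#' @param panel Result of [load_validation_panel()].
#' @return Data.frame `gene, class, region, category, conflicting`.
#' @export
panel_calls <- function(panel) {
  long <- panel$long
  rows <- lapply(unique(long$gene), function(g) {
    sub <- long[long$gene == g, , drop = FALSE]
    means <- stats::setNames(sub$mean_pct,
                             paste(sub$stage, sub$tissue, sep = "."))
    res <- call_gene(means, is_placenta = sub$is_placenta)
    data.frame(gene = g, class = sub$class[1L], region = sub$region[1L],
               category = res$category, conflicting = res$conflicting,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
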