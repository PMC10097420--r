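## Gene and ICR registry I/O.
##
## Gene records are plain data.frames with columns
##   gene_id, chrom, start, end, strand, names
## Coordinates are 0-based half-open (BED convention) throughout the package.
## `names` holds the primary name plus aliases as a comma-separated string;
## `gene_names()` splits it. Extra columns (e.g. status, cluster_id) are
## carried through untouched so the same reader serves the known-gene registry.

GENE_COLS <- c("gene_id", "chrom", "start", "end", "strand", "names")

new_gene_records <- function(gene_id, chrom, start, end,
                             strand = "*", names = gene_id, ...) {
  n <- length(gene_id)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   names = rep_len(as.character(names), n),
                   ..., stringsAsFactors = FALSE)
  validate_gene_records(df)
}

validate_gene_records <- function(df, where = "gene table") {
  miss <- setdiff(GENE_COLS, names(df))
  if (length(miss)) {
    stop_poebias(where, " lacks column(s): ", paste(miss, collapse = ", "),
                 class = "poebias_parse_error")
  }
  df$strand[is.na(df$strand) | df$strand == "." | df$strand == ""] <- "*"
  bad_strand <- !df$strand %in% c("+", "-", "*")
  if (any(bad_strand)) {
    stop_poebias(where, ": invalid strand at row ",
                 which(bad_strand)[1L], class = "poebias_parse_error")
  }
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end
  if (any(bad)) {
    stop_poebias(where, ": start >= end (or non-numeric) at row ",
                 which(bad)[1L], class = "poebias_validation_error")
  }
  if (any(is.na(df$chrom) | df$chrom == "")) {
    stop_poebias(where, ": empty chromosome at row ",
                 which(is.na(df$chrom) | df$chrom == "")[1L],
                 class = "poebias_validation_error")
  }
  if (any(is.na(df$names) | df$names == "")) {
    stop_poebias(where, ": empty name set at row ",
                 which(is.na(df$names) | df$names == "")[1L],
                 class = "poebias_validation_error")
  }
  rownames(df) <- NULL
  df
}

#' Split the comma-separated name sets of gene records
#'
#' @param records Gene-record data.frame.
#' @return A list of character vectors, one per record.
#' @export
gene_names <- function(records) {
  strsplit(records$names, ",", fixed = TRUE)
}

#' Read a gene coordinate table
#'
#' Reads gene records from BED (4-6 columns, via [rtracklayer::import()]) or
#' from the package TSV dialect with header
#' `gene_id chrom start end strand names`. Coordinates are kept 0-based
#' half-open. A TSV may declare its convention in a leading comment line
#' `# coord_system: 1-based` (closed 1-based starts are then shifted down by
#' one); the default is 0-based half-open.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"bed"`; guessed from the file extension by
#'   default.
#' @return A gene-record data.frame (extra TSV columns are retained).
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_poebias("file not found: ", path, class = "poebias_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    if (length(readLines(path, warn = FALSE)) == 0L) {
      return(new_gene_records(character(), character(), integer(), integer()))
    }
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) {
                     stop_poebias("malformed BED '", path, "': ",
                                  conditionMessage(e),
                                  class = "poebias_parse_error")
                   })
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("feature_", seq_along(gr))
    df <- data.frame(gene_id = nm,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     names = nm, stringsAsFactors = FALSE)
    return(validate_gene_records(df, where = path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  one_based <- FALSE
  comment <- ""
  if (length(first) && startsWith(first, "#")) {
    comment <- first
    one_based <- grepl("coord_system:\\s*1-based", first)
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) {
    return(new_gene_records(character(), character(), integer(), integer()))
  }
  nstart <- suppressWarnings(as.integer(df$start))
  nend <- suppressWarnings(as.integer(df$end))
  bad <- (is.na(nstart) & !is.na(df$start)) | (is.na(nend) & !is.na(df$end))
  if (any(bad)) {
    stop_poebias(path, ": non-numeric coordinate at line ",
                 which(bad)[1L] + 1L + (comment != ""),
                 class = "poebias_parse_error")
  }
  df$start <- nstart - if (one_based) 1L else 0L
  df$end <- nend
  validate_gene_records(df, where = path)
}

#' Write gene records as TSV
#'
#' Writes the package TSV dialect (0-based half-open, declared in a leading
#' comment line) so that [read_gene_table()] round-trips the records exactly.
#'
#' @param records Gene-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(records, path) {
  records <- validate_gene_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coord_system: 0-based-half-open", con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an imprinting-control-region table
#'
#' TSV dialect `icr_id chrom start end methylated_parent cluster_id`, 0-based
#' half-open. `methylated_parent` must be `maternal` or `paternal` — the
#' parental allele carrying germline methylation at the ICR.
#'
#' @param path Path to the TSV.
#' @return A data.frame of ICR records.
#' @export
read_icr_table <- function(path) {
  if (!file.exists(path)) {
    stop_poebias("file not found: ", path, class = "poebias_io_error")
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("icr_id", "chrom", "start", "end", "methylated_parent",
            "cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_poebias(path, " lacks column(s): ", paste(miss, collapse = ", "),
                 class = "poebias_parse_error")
  }
  bad <- !df$methylated_parent %in% c("maternal", "paternal")
  if (any(bad)) {
    stop_poebias(path, ": methylated_parent must be maternal/paternal at row ",
                 which(bad)[1L], class = "poebias_validation_error")
  }
  if (any(df$start >= df$end)) {
    stop_poebias(path, ": start >= end at row ",
                 which(df$start >= df$end)[1L],
                 class = "poebias_validation_error")
  }
  df
}

#' Convert gene records to a GRanges
#'
#' @param records Gene-record data.frame (0-based half-open).
#' @return A [GenomicRanges::GRanges] (1-based closed, per Bioconductor).
#' @export
genes_as_granges <- function(records) {
  GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand,
    gene_id = records$gene_id)
}

## union-find over a character universe
uf_new <- function(items) stats::setNames(seq_along(items), items)
uf_find <- function(parent, i) {
  while (parent[[i]] != i) i <- parent[[i]]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
  parent
}

#' Merge gene records that share a name under an alias closure
#'
#' Records whose name sets intersect — directly or through user-supplied alias
#' pairs — are merged into one record spanning the union of their intervals,
#' with name sets unioned. This mirrors the meta-analysis step of merging
#' transcripts reported under alternative names by different studies. The
#' operation is idempotent and independent of input row order.
#'
#' @param records Gene-record data.frame.
#' @param alias_map Two-column data.frame (or matrix) of equivalent name
#'   pairs; `NULL` for none. Pairs naming genes absent from `records` are
#'   ignored with a warning.
#' @return A merged gene-record data.frame sorted by (chrom, start, gene_id).
#'   Merging records on different chromosomes is an error.
#' @export
merge_aliases <- function(records, alias_map = NULL) {
  records <- validate_gene_records(records)
  if (nrow(records) == 0L) return(records)
  name_sets <- gene_names(records)
  universe <- unique(unlist(name_sets))
  parent <- uf_new(universe)
  for (ns in name_sets) {
    if (length(ns) > 1L) {
      for (k in seq_along(ns)[-1L]) parent <- uf_union(parent, ns[1L], ns[k])
    }
  }
  if (!is.null(alias_map)) {
    am <- as.data.frame(alias_map, stringsAsFactors = FALSE)
    if (ncol(am) < 2L) {
      stop_poebias("alias_map needs two columns", class = "poebias_parse_error")
    }
    unknown <- setdiff(unique(c(am[[1L]], am[[2L]])), universe)
    if (length(unknown)) {
      warning("alias_map names not present in records, ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- am[[1L]] %in% universe & am[[2L]] %in% universe
    for (k in which(keep)) {
      parent <- uf_union(parent, am[[k, 1L]], am[[k, 2L]])
    }
  }
  root_of <- vapply(universe, function(n) uf_find(parent, n), integer(1L))
  comp <- vapply(name_sets, function(ns) root_of[[ns[1L]]], integer(1L))
  merged <- lapply(split(seq_len(nrow(records)), comp), function(idx) {
    sub <- records[idx, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1L) {
      stop_poebias("alias merge conflict: records on different chromosomes (",
                   paste(sort(unique(sub$gene_id)), collapse = ", "), ")",
                   class = "poebias_conflict_error")
    }
    out <- sub[which.min(rank(sub$gene_id)), , drop = FALSE]
    out$start <- min(sub$start)
    out$end <- max(sub$end)
    strands <- unique(sub$strand)
    out$strand <- if (length(strands) == 1L) strands else "*"
    out$names <- paste(sort(unique(unlist(gene_names(sub)))), collapse = ",")
    out
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
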