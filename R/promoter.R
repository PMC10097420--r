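## Strand-aware promoter windows and interval-signal summaries.

#' Promoter windows upstream of the transcription start site
#'
#' For a `+` strand gene the promoter is the `size` bp immediately upstream
#' of `start` (`[start - size, start)`); for a `-` strand gene it is
#' `[end, end + size)`. Windows are clipped at coordinate 0 with a warning;
#' unknown strand is an error (never silently assumed `+`).
#'
#' @param records Gene-record data.frame (0-based half-open).
#' @param size Window size in bp, default 500.
#' @return Data.frame `gene_id, chrom, start, end, strand`.
#' @export
promoter_window <- function(records, size = 500) {
  stopifnot(size > 0)
  if (any(records$strand == "*")) {
    stop_poebias("promoter window needs a known strand for: ",
                 paste(records$gene_id[records$strand == "*"],
                       collapse = ", "), class = "poebias_domain_error")
  }
  start <- ifelse(records$strand == "+", records$start - size, records$end)
  end <- ifelse(records$strand == "+", records$start, records$end + size)
  if (any(start < 0)) {
    warning("promoter window clipped at coordinate 0 for: ",
            paste(records$gene_id[start < 0], collapse = ", "),
            call. = FALSE)
    start <- pmax(start, 0)
  }
  data.frame(gene_id = records$gene_id, chrom = records$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = records$strand, stringsAsFactors = FALSE)
}

#' Read a bedGraph signal track
#'
#' Imports a bedGraph via [rtracklayer::import()]; overlapping intervals are
#' resolved by disjoining and averaging their values, with a warning.
#'
#' @param path Path to the bedGraph file.
#' @return A [GenomicRanges::GRanges] with a `score` column, disjoint within
#'   each chromosome.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) {
    stop_poebias("file not found: ", path, class = "poebias_io_error")
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!GenomicRanges::isDisjoint(gr)) {
    warning("overlapping track intervals resolved by averaging",
            call. = FALSE)
    dj <- GenomicRanges::disjoin(gr, with.revmap = TRUE)
    dj$score <- vapply(dj$revmap, function(i) mean(gr$score[i]), numeric(1L))
    dj$revmap <- NULL
    gr <- dj
  }
  gr
}

#' Base-pair-weighted mean signal over windows
#'
#' For each window, the track values of overlapping intervals are averaged
#' with weights equal to the number of covered bases; bases without coverage
#' are excluded from the mean (sparse-coverage convention). With
#' `zero_fill = TRUE` uncovered bases instead contribute zeros over the full
#' window width. Windows with no coverage return `NA`.
#'
#' @param track `GRanges` signal track from [read_signal_track()].
#' @param windows Data.frame `chrom, start, end` (0-based half-open), e.g.
#'   from [promoter_window()].
#' @param zero_fill Treat uncovered bases as signal 0 (default `FALSE`).
#' @return Numeric vector of mean signals, one per window.
#' @export
mean_signal <- function(track, windows, zero_fill = FALSE) {
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  ## windows and track may legitimately live on disjoint chromosomes
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(win_gr, track, ignore.strand = TRUE))
  out <- rep(NA_real_, length(win_gr))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    piece <- IRanges::pintersect(
      IRanges::ranges(win_gr)[q],
      IRanges::ranges(track)[S4Vectors::subjectHits(hits)])
    w <- IRanges::width(piece)
    val <- track$score[S4Vectors::subjectHits(hits)]
    num <- tapply(w * val, q, sum)
    den <- tapply(w, q, sum)
    idx <- as.integer(names(num))
    out[idx] <- as.numeric(num) /
      if (zero_fill) (windows$end - windows$start)[idx] else as.numeric(den)
  }
  if (zero_fill) out[is.na(out)] <- 0
  out
}

#' Mean promoter signal for a set of genes over one or more tracks
#'
#' Convenience wrapper: builds promoter windows and summarises each track
#' over them.
#'
#' @param records Gene-record data.frame with known strands.
#' @param tracks Named list of `GRanges` tracks (or a single track).
#' @param size Promoter size in bp, default 500.
#' @param zero_fill Passed to [mean_signal()].
#' @return Data.frame `gene_id, window_chrom, window_start, window_end`
#'   plus one `mean_<track>` column per track.
#' @export
promoter_signal_matrix <- function(records, tracks, size = 500,
                                   zero_fill = FALSE) {
  win <- promoter_window(records, size = size)
  if (methods::is(tracks, "GRanges")) tracks <- list(signal = tracks)
  out <- data.frame(gene_id = win$gene_id, window_chrom = win$chrom,
                    window_start = win$start, window_end = win$end,
                    stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    out[[paste0("mean_", nm)]] <- mean_signal(tracks[[nm]], win,
                                              zero_fill = zero_fill)
  }
  out
}
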