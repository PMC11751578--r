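# Tabular homology-search results ("m8" BLAST/MMseqs format) and the
# identity/coverage template filter.

M8_COLS <- c("qseqid", "sseqid", "pident", "alnlen", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bits")

#' Read a 12-column tab-separated hit table
#'
#' Standard "m8" homology-search output (query, target, percent identity,
#' alignment length, mismatches, gap opens, query/target start/end,
#' e-value, bit score), with an optional 13th `qlen` column. Query lengths
#' can alternatively be supplied later from a companion FASTA via
#' [filter_template_hits()].
#'
#' @param path tab-separated file path.
#' @return Tibble of hit records.
#' @export
read_hits_m8 <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 12) {
    stop("m8 hit table must have at least 12 columns, found ", ncol(raw),
         call. = FALSE)
  }
  names(raw)[1:12] <- M8_COLS
  if (ncol(raw) >= 13) names(raw)[13] <- "qlen"
  tibble::as_tibble(raw[, names(raw) %in% c(M8_COLS, "qlen")])
}

#' Filter template hits on identity and query coverage
#'
#' Keeps hits whose percent identity lies within `[id_min, id_max]` and
#' whose query coverage `(qend - qstart + 1) / qlen` is at least
#' `cov_min`, then retains at most one hit per query: the best e-value
#' among the survivors (ties broken by higher identity, then by
#' lexicographic target id). The defaults (30-70% identity, at least 80%
#' coverage) select templates that are informative without being
#' near-identical to the modeling target.
#'
#' @param hits tibble of hit records (see [read_hits_m8()]).
#' @param id_min,id_max percent-identity window (default 30, 70).
#' @param cov_min minimum query coverage as a fraction (default 0.8).
#' @param qlen optional named vector or tibble (`qseqid`, `qlen`) with
#'   query lengths; used when the table lacks a `qlen` column. A path to a
#'   FASTA file of query sequences is also accepted.
#' @return Filtered tibble, one row per query, a subset of the input.
#' @export
filter_template_hits <- function(hits, id_min = 30, id_max = 70,
                                 cov_min = 0.8, qlen = NULL) {
  hits <- tibble::as_tibble(hits)
  stopifnot(all(c("qseqid", "sseqid", "pident", "qstart", "qend", "evalue")
                %in% names(hits)))
  if (!"qlen" %in% names(hits)) {
    if (is.null(qlen)) {
      stop("query lengths unknown: supply a 13-column table or `qlen`",
           call. = FALSE)
    }
    if (is.character(qlen) && length(qlen) == 1 && file.exists(qlen)) {
      seqs <- Biostrings::readAAStringSet(qlen)
      qlen <- stats::setNames(Biostrings::width(seqs),
                              sub("\\s.*$", "", names(seqs)))
    }
    if (is.data.frame(qlen)) qlen <- stats::setNames(qlen$qlen, qlen$qseqid)
    hits$qlen <- unname(qlen[hits$qseqid])
  }
  unknown <- is.na(hits$qlen)
  if (any(unknown)) {
    warning("skipping ", length(unique(hits$qseqid[unknown])),
            " query(ies) with unknown length")
    hits <- hits[!unknown, , drop = FALSE]
  }
  kept <- dplyr::filter(
    hits,
    .data$pident >= id_min, .data$pident <= id_max,
    (.data$qend - .data$qstart + 1) / .data$qlen >= cov_min
  )
  kept <- dplyr::arrange(kept, .data$qseqid, .data$evalue,
                         dplyr::desc(.data$pident), .data$sseqid)
  dplyr::slice_head(dplyr::group_by(kept, .data$qseqid), n = 1L) |>
    dplyr::ungroup()
}
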