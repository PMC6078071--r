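## N-terminal extension detection. A nucleus-encoded protein targeted to
## a complex plastid carries a bipartite presequence (signal peptide then
## transit-peptide-like region) upstream of the region aligning to its
## bacterial homologs. The extension boundary is fixed as the median
## first-aligned column of the bacterial reference rows; the extension is
## the query residues strictly before it. SP/TP predictions are ingested
## from an external table (SignalP/ChloroP-style output), never
## recomputed, and the TP verdict is only meaningful when an SP was
## predicted (the conditional decision order).

#' Read a protein multiple alignment from FASTA
#'
#' @param path FASTA file (gap character `-`).
#' @return named character vector of equal-length aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(aln), names(aln))
  msa_check(out)
  out
}

msa_check <- function(msa) {
  stopifnot(is.character(msa), length(msa) >= 1L, !is.null(names(msa)))
  if (anyDuplicated(names(msa)))
    stop2("duplicate sequence ids in alignment")
  if (length(unique(nchar(msa))) != 1L)
    stop2("alignment rows have unequal lengths")
  invisible(msa)
}

msa_matrix <- function(msa) {
  msa_check(msa)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

first_residue_column <- function(row_chars) {
  idx <- which(row_chars != "-")
  if (!length(idx)) return(NA_integer_)
  idx[1L]
}

#' Reference start column of an alignment
#'
#' The median (lower median on ties) over the reference rows of each
#' row's first non-gap column. Columns are 1-based.
#'
#' @param msa named character vector of aligned sequences.
#' @param reference_ids ids of the (bacterial) reference rows.
#' @return 1-based column index.
#' @export
reference_start_column <- function(msa, reference_ids) {
  m <- msa_matrix(msa)
  missing <- setdiff(reference_ids, rownames(m))
  if (length(missing))
    stop2("reference id(s) absent from alignment: ",
          paste(missing, collapse = ", "))
  starts <- vapply(reference_ids,
                   function(id) first_residue_column(m[id, ]), 0L)
  if (anyNA(starts))
    stop2("reference row(s) entirely gaps: ",
          paste(reference_ids[is.na(starts)], collapse = ", "))
  starts <- sort(starts)
  starts[[(length(starts) + 1L) %/% 2L]]   # lower median
}

#' Detect an N-terminal extension of a query relative to bacterial homologs
#'
#' @param msa named character vector of aligned sequences.
#' @param query_id query row id.
#' @param reference_ids reference row ids.
#' @param min_len minimum residue count for `has_extension` (default 10).
#' @return an `extension_report`: `query_id`, `extension_length` (non-gap
#'   query residues before the reference start column), `has_extension`,
#'   `sp_predicted`/`tp_predicted` (NA until merged), `reference_ids`.
#' @export
detect_extension <- function(msa, query_id, reference_ids, min_len = 10L) {
  stopifnot(is_count(min_len))
  m <- msa_matrix(msa)
  if (!query_id %in% rownames(m))
    stop2("query id '", query_id, "' absent from alignment")
  qrow <- m[query_id, ]
  if (all(qrow == "-")) stop2("query row is entirely gaps")
  start <- reference_start_column(msa, reference_ids)
  len <- if (start <= 1L) 0L else sum(qrow[seq_len(start - 1L)] != "-")
  structure(list(query_id = query_id, extension_length = as.integer(len),
                 has_extension = len >= min_len, min_len = as.integer(min_len),
                 sp_predicted = NA, tp_predicted = NA,
                 reference_ids = reference_ids),
            class = "extension_report")
}

#' Merge external SP/TP predictions into an extension report
#'
#' Rows are keyed by query id with logical `sp` and `tp` columns. The
#' transit-peptide verdict is conditional on the signal peptide: when
#' `sp` is FALSE, `tp` is forced back to unknown (with a warning if the
#' table claimed one).
#'
#' @param report an `extension_report`.
#' @param preds a data.frame with columns `id`, `sp`, `tp`, or a path to
#'   such a TSV.
#' @return the updated `extension_report`.
#' @export
merge_external_predictions <- function(report, preds) {
  stopifnot(inherits(report, "extension_report"))
  if (is.character(preds)) preds <- read.delim(preds, stringsAsFactors = FALSE)
  if (!all(c("id", "sp", "tp") %in% names(preds)))
    stop2("predictions table must have columns id, sp, tp")
  row <- preds[preds$id == report$query_id, , drop = FALSE]
  if (!nrow(row)) return(report)
  sp <- as.logical(row$sp[1L]); tp <- as.logical(row$tp[1L])
  report$sp_predicted <- sp
  if (isTRUE(sp)) {
    report$tp_predicted <- tp
  } else {
    if (isTRUE(tp))
      warning("TP prediction without SP for '", report$query_id,
              "': stored as unknown (SP-then-TP order)", call. = FALSE)
    report$tp_predicted <- NA
  }
  report
}

#' Summarize extension reports
#'
#' Reproduces the reporting shape "N of M transcripts bear N-terminal
#' extensions; S of N have a predicted SP; K have both SP and TP".
#'
#' @param reports list of `extension_report`s.
#' @return a list with `n_total`, `n_extension`, `n_sp`, `n_sp_tp`.
#' @export
extension_summary <- function(reports) {
  if (inherits(reports, "extension_report")) reports <- list(reports)
  has <- vapply(reports, function(r) isTRUE(r$has_extension), NA)
  sp <- vapply(reports, function(r) isTRUE(r$sp_predicted), NA)
  tp <- vapply(reports, function(r) isTRUE(r$tp_predicted), NA)
  list(n_total = length(reports), n_extension = sum(has),
       n_sp = sum(has & sp), n_sp_tp = sum(has & sp & tp))
}

#' @export
print.extension_report <- function(x, ...) {
  cat(sprintf("<extension_report> %s: %d residue(s)%s; SP=%s TP=%s\n",
              x$query_id, x$extension_length,
              if (x$has_extension) " (extension)" else "",
              format(x$sp_predicted), format(x$tp_predicted)))
  invisible(x)
}
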