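#' Read a V(D)J contig annotation table
#'
#' Reads single-cell TCR contig annotations in either the 10x Cell Ranger
#' `filtered_contig_annotations.csv` dialect or the AIRR Rearrangement TSV
#' dialect, mapping columns onto a unified schema: `barcode`, `is_cell`,
#' `high_confidence`, `locus`, `v_call`, `d_call`, `j_call`, `c_call`,
#' `junction_aa`, `productive_raw`, `umis`, `contig_id`. Raw flag values
#' are preserved verbatim; no coercion happens at read time.
#'
#' @param path path to the contig table.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return a data frame of contig records, one row per input data row.
#' @examples
#' f <- system.file("extdata", "locus", "human_TRB.tsv", package = "tcrtrace")
#' # (see generate_sample() for producing a readable contig table)
#' @export
read_contig_table <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read contig table: ", path)
  if (dialect == "tenx_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    mandatory <- c("barcode", "is_cell", "high_confidence", "chain",
                   "v_gene", "d_gene", "j_gene", "c_gene", "cdr3",
                   "productive")
    missing <- setdiff(mandatory, names(raw))
    if (length(missing))
      stop("tenx_csv table is missing mandatory column(s): ",
           paste(missing, collapse = ", "))
    rec <- data.frame(
      barcode = raw$barcode,
      is_cell = raw$is_cell,
      high_confidence = raw$high_confidence,
      locus = raw$chain,
      v_call = raw$v_gene,
      d_call = raw$d_gene,
      j_call = raw$j_gene,
      c_call = raw$c_gene,
      junction_aa = raw$cdr3,
      productive_raw = raw$productive,
      stringsAsFactors = FALSE)
    rec$umis <- if ("umis" %in% names(raw))
      suppressWarnings(as.integer(raw$umis)) else NA_integer_
    rec$contig_id <- if ("contig_id" %in% names(raw)) raw$contig_id else
      sprintf("%s_contig_%d", rec$barcode, seq_len(nrow(rec)))
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    mandatory <- c("cell_id", "locus", "v_call", "d_call", "j_call",
                   "c_call", "junction_aa", "productive")
    missing <- setdiff(mandatory, names(raw))
    if (length(missing))
      stop("airr_tsv table is missing mandatory column(s): ",
           paste(missing, collapse = ", "))
    rec <- data.frame(
      barcode = raw$cell_id,
      is_cell = if ("is_cell" %in% names(raw)) raw$is_cell else NA_character_,
      high_confidence = if ("high_confidence" %in% names(raw))
        raw$high_confidence else NA_character_,
      locus = raw$locus,
      v_call = raw$v_call,
      d_call = raw$d_call,
      j_call = raw$j_call,
      c_call = raw$c_call,
      junction_aa = raw$junction_aa,
      productive_raw = raw$productive,
      stringsAsFactors = FALSE)
    rec$umis <- if ("duplicate_count" %in% names(raw))
      suppressWarnings(as.integer(raw$duplicate_count)) else NA_integer_
    rec$contig_id <- if ("sequence_id" %in% names(raw)) raw$sequence_id else
      sprintf("%s_contig_%d", rec$barcode, seq_len(nrow(rec)))
  }
  for (col in c("v_call", "d_call", "j_call", "c_call", "junction_aa"))
    rec[[col]][is.na(rec[[col]])] <- ""
  if (anyDuplicated(rec$contig_id))
    stop("contig_id values are not unique within the sample")
  class(rec) <- c("contig_table", "data.frame")
  rec
}

#' Apply the four contig QC screening criteria
#'
#' Drops contigs that fail any of the four screens, attributing each
#' dropped record to the first failing criterion in this fixed order:
#' (1) `is_cell` not true (`not_cell`), (2) `high_confidence` not true
#' (`low_confidence`), (3) locus outside TRA/TRB (`wrong_chain`),
#' (4) `productive` neither true nor false, e.g. `"None"`
#' (`productive_none`). Flag comparison is case-insensitive; flags absent
#' from the input dialect pass their criterion, while unrecognized literal
#' values fail it.
#'
#' @param records contig data frame from [read_contig_table()].
#' @return a list with elements `kept` (filtered contig data frame) and
#'   `report` (a `qc_report`: `n_input`, `n_kept`, `n_dropped_by_reason`).
#' @export
apply_qc_filters <- function(records) {
  n <- nrow(records)
  reasons <- c("not_cell", "low_confidence", "wrong_chain", "productive_none")
  if (n == 0) {
    report <- structure(list(n_input = 0L, n_kept = 0L,
                             n_dropped_by_reason = stats::setNames(
                               rep(0L, 4), reasons)),
                        class = "qc_report")
    return(list(kept = records, report = report))
  }
  is_cell <- normalize_flag(records$is_cell)
  hi_conf <- normalize_flag(records$high_confidence)
  prod <- normalize_flag(records$productive_raw)
  fail_cell <- !is.na(is_cell) & is_cell != "true"
  fail_conf <- !is.na(hi_conf) & hi_conf != "true"
  fail_chain <- !(records$locus %in% c("TRA", "TRB"))
  fail_prod <- is.na(prod) | !(prod %in% c("true", "false"))
  reason <- rep(NA_character_, n)
  reason[fail_prod] <- "productive_none"
  reason[fail_chain] <- "wrong_chain"
  reason[fail_conf] <- "low_confidence"
  reason[fail_cell] <- "not_cell"
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  tab <- stats::setNames(
    vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1)),
    reasons)
  report <- structure(list(n_input = n, n_kept = nrow(kept),
                           n_dropped_by_reason = tab),
                      class = "qc_report")
  stopifnot(report$n_input == report$n_kept + sum(tab))
  list(kept = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Contig QC report\n")
  cat("  input:", x$n_input, " kept:", x$n_kept, "\n")
  for (r in names(x$n_dropped_by_reason))
    cat(sprintf("  dropped %-16s %d\n", paste0(r, ":"),
                x$n_dropped_by_reason[[r]]))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [apply_qc_filters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, n_kept = report$n_kept,
         n_dropped_by_reason = as.list(report$n_dropped_by_reason)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write contig records as an AIRR Rearrangement TSV
#'
#' Re-emits (kept) contig records using AIRR column names, with the QC
#' flags carried as extension columns.
#'
#' @param records contig data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(records, path) {
  out <- data.frame(
    sequence_id = records$contig_id,
    cell_id = records$barcode,
    locus = records$locus,
    v_call = records$v_call,
    d_call = records$d_call,
    j_call = records$j_call,
    c_call = records$c_call,
    junction_aa = records$junction_aa,
    productive = records$productive_raw,
    duplicate_count = records$umis,
    is_cell = records$is_cell,
    high_confidence = records$high_confidence,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
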