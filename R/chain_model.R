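#' Call a chain functional or non-functional
#'
#' A chain is functional (F) only when its contig is productive and its V
#' segment is a functional gene (not a pseudogene or ORF-class segment):
#' a fully transcribed in-frame rearrangement of a functional V. Everything
#' else — non-productive contigs, pseudogene/ORF V calls, or chains with a
#' missing V call — is non-functional (N).
#'
#' @param record one contig record (a one-row data frame or list with
#'   `productive_raw` and `v_call`).
#' @param functional_v_table character vector of functional V gene names,
#'   e.g. from [functional_v_genes()].
#' @param known_genes optional character vector of all V genes in the locus
#'   model; a non-empty `v_call` outside it raises an unknown-gene error.
#' @return `"F"` or `"N"`.
#' @export
call_chain_functionality <- function(record, functional_v_table,
                                     known_genes = NULL) {
  prod <- normalize_flag(record$productive_raw)
  if (is.na(prod) || !(prod %in% c("true", "false")))
    stop("record has not passed QC: productive flag is '",
         record$productive_raw, "'")
  v <- record$v_call
  if (nzchar(v) && !is.null(known_genes) && !(v %in% known_genes))
    stop("unknown gene '", v, "': not in the locus model")
  if (prod == "true" && nzchar(v) && v %in% functional_v_table) "F" else "N"
}

chain_identity_key <- function(ch) {
  paste(ch$locus, ch$v_call, ch$d_call, ch$j_call, ch$c_call,
        ch$junction_aa, sep = "|")
}

#' Collapse one barcode's contigs into a cell profile
#'
#' Deduplicates contigs that share the full identity key
#' (locus, V, D, J, C, CDR3 amino-acid junction) — keeping the contig with
#' the larger UMI count, or the first seen when UMIs are absent — calls each
#' distinct chain F or N, and tallies the four (locus x status) counts.
#' Chains with an empty V or J call are retained as N with a warning: they
#' still occupy a chain slot for pattern counting.
#'
#' @param records contig records for a single barcode (all QC-passed).
#' @param functional_v_table functional V gene names.
#' @param known_genes optional vector of all V genes in the locus model.
#' @return a `cell_profile`: list with `barcode`, `chains` (data frame with
#'   `locus`, `v_call`, `d_call`, `j_call`, `c_call`, `junction_aa`,
#'   `status`), and counts `n_tra_f`, `n_tra_n`, `n_trb_f`, `n_trb_n`.
#' @export
collapse_cell_chains <- function(records, functional_v_table,
                                 known_genes = NULL) {
  if (nrow(records) == 0)
    stop("cannot build a cell profile from zero chains")
  if (length(unique(records$barcode)) != 1)
    stop("records span more than one barcode")
  keys <- chain_identity_key(records)
  # stable order independent of input permutation: sort by key, then pick
  # the max-UMI representative within each key
  ord <- order(keys, -ifelse(is.na(records$umis), -Inf, records$umis),
               records$contig_id)
  records <- records[ord, , drop = FALSE]
  keep <- !duplicated(keys[ord])
  ch <- records[keep, c("locus", "v_call", "d_call", "j_call", "c_call",
                        "junction_aa", "productive_raw"), drop = FALSE]
  if (any(!nzchar(ch$v_call) | !nzchar(ch$j_call)))
    warning("barcode ", records$barcode[1],
            ": chain(s) with missing V or J call retained as N")
  ch$status <- vapply(seq_len(nrow(ch)), function(i) {
    if (!nzchar(ch$v_call[i]) || !nzchar(ch$j_call[i])) return("N")
    call_chain_functionality(ch[i, ], functional_v_table, known_genes)
  }, character(1))
  ch$productive_raw <- NULL
  rownames(ch) <- NULL
  new_cell_profile(records$barcode[1], ch)
}

#' Construct a cell profile from a chain table
#'
#' Low-level constructor used by [collapse_cell_chains()] and by tests.
#'
#' @param barcode cell barcode.
#' @param chains data frame with columns `locus`, `v_call`, `d_call`,
#'   `j_call`, `c_call`, `junction_aa`, `status`.
#' @return a `cell_profile`.
#' @export
new_cell_profile <- function(barcode, chains) {
  stopifnot(all(c("locus", "status") %in% names(chains)),
            all(chains$locus %in% c("TRA", "TRB")),
            all(chains$status %in% c("F", "N")))
  if (anyDuplicated(chain_identity_key(chains)))
    stop("profile contains two chains with equal identity keys")
  p <- list(barcode = barcode, chains = chains,
            n_tra_f = sum(chains$locus == "TRA" & chains$status == "F"),
            n_tra_n = sum(chains$locus == "TRA" & chains$status == "N"),
            n_trb_f = sum(chains$locus == "TRB" & chains$status == "F"),
            n_trb_n = sum(chains$locus == "TRB" & chains$status == "N"))
  class(p) <- "cell_profile"
  p
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("<cell_profile> %s: %d chain(s) [TRB F/N %d/%d, TRA F/N %d/%d]\n",
              x$barcode, nrow(x$chains), x$n_trb_f, x$n_trb_n,
              x$n_tra_f, x$n_tra_n))
  invisible(x)
}

#' Build cell profiles for every barcode in a filtered contig table
#'
#' @param kept QC-passed contig data frame.
#' @param species `"human"` or `"mouse"`; fixes the functional-V table.
#' @param normalize normalize gene calls against the locus maps (strip
#'   alleles, resolve dual/ambiguous names) before collapsing.
#' @return named list of `cell_profile` objects, keyed and ordered by
#'   barcode.
#' @export
build_cell_profiles <- function(kept, species = "human", normalize = TRUE) {
  if (nrow(kept) == 0) return(list())
  maps <- list(TRA = load_locus(species, "TRA"),
               TRB = load_locus(species, "TRB"))
  if (normalize) {
    for (i in seq_len(nrow(kept))) {
      m <- maps[[kept$locus[i]]]
      for (col in c("v_call", "d_call", "j_call", "c_call"))
        kept[[col]][i] <- normalize_gene_call(kept[[col]][i], m)
    }
  }
  fun_v <- functional_v_genes(species)
  known <- unlist(lapply(maps, function(m)
    m$genes$name[m$genes$segment_class == "V"]), use.names = FALSE)
  by_bc <- split(seq_len(nrow(kept)), kept$barcode)
  out <- lapply(by_bc, function(idx)
    collapse_cell_chains(kept[idx, , drop = FALSE], fun_v, known))
  out[order(names(out))]
}
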