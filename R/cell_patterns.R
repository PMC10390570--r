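#' The 23 chain-pattern categories
#'
#' Cells are labelled by the multiset of their distinct chains over
#' (locus x functional status): four single-chain categories, ten two-chain
#' categories, eight same-locus three-chain categories, and a final
#' "others" category absorbing every remaining combination (mixed-locus
#' three-chain cells and all cells with four or more distinct chains).
#'
#' @return data frame with `code` (1-23), `name`, and the defining counts
#'   `n_trb_f`, `n_trb_n`, `n_tra_f`, `n_tra_n` (`NA` for "others").
#' @export
pattern_labels <- function() {
  if (!is.null(.tcrtrace_cache$pattern_labels))
    return(.tcrtrace_cache$pattern_labels)
  sig <- list(
    # code, bF, bN, aF, aN
    c(1, 1, 0, 0, 0), c(2, 0, 1, 0, 0), c(3, 0, 0, 1, 0), c(4, 0, 0, 0, 1),
    c(5, 2, 0, 0, 0), c(6, 1, 1, 0, 0), c(7, 0, 2, 0, 0),
    c(8, 0, 0, 2, 0), c(9, 0, 0, 1, 1), c(10, 0, 0, 0, 2),
    c(11, 1, 0, 1, 0), c(12, 1, 0, 0, 1), c(13, 0, 1, 1, 0),
    c(14, 0, 1, 0, 1),
    c(15, 3, 0, 0, 0), c(16, 2, 1, 0, 0), c(17, 1, 2, 0, 0),
    c(18, 0, 3, 0, 0),
    c(19, 0, 0, 3, 0), c(20, 0, 0, 2, 1), c(21, 0, 0, 1, 2),
    c(22, 0, 0, 0, 3))
  df <- as.data.frame(do.call(rbind, sig))
  names(df) <- c("code", "n_trb_f", "n_trb_n", "n_tra_f", "n_tra_n")
  part <- function(n, locus, st) {
    if (n == 0) character(0) else rep(sprintf("%s(%s)", locus, st), n)
  }
  df$name <- vapply(seq_len(nrow(df)), function(i)
    paste(c(part(df$n_trb_f[i], "TRB", "F"), part(df$n_trb_n[i], "TRB", "N"),
            part(df$n_tra_f[i], "TRA", "F"), part(df$n_tra_n[i], "TRA", "N")),
          collapse = "+"),
    character(1))
  out <- rbind(df[, c("code", "name", "n_trb_f", "n_trb_n", "n_tra_f",
                      "n_tra_n")],
               data.frame(code = 23, name = "others", n_trb_f = NA,
                          n_trb_n = NA, n_tra_f = NA, n_tra_n = NA))
  .tcrtrace_cache$pattern_labels <- out
  out
}

.tcrtrace_cache <- new.env(parent = emptyenv())

#' Assign a cell its chain-pattern category
#'
#' The label depends only on the multiset of (locus, status) over the
#' cell's distinct chains; gene usage and junctions play no role.
#'
#' @param profile a `cell_profile`.
#' @return one row of [pattern_labels()]: `code` and `name`.
#' @export
assign_pattern <- function(profile) {
  stopifnot(nrow(profile$chains) >= 1)
  lab <- pattern_labels()
  hit <- which(!is.na(lab$n_trb_f) &
                 lab$n_trb_f == profile$n_trb_f &
                 lab$n_trb_n == profile$n_trb_n &
                 lab$n_tra_f == profile$n_tra_f &
                 lab$n_tra_n == profile$n_tra_n)
  if (length(hit) == 1) lab[hit, c("code", "name")]
  else lab[lab$code == 23, c("code", "name")]
}

#' Group a cell by its number of distinct chains
#'
#' @param profile a `cell_profile`.
#' @return `"one"`, `"two"`, or `"three_plus"`.
#' @export
chain_count_group <- function(profile) {
  n <- nrow(profile$chains)
  stopifnot(n >= 1)
  if (n == 1) "one" else if (n == 2) "two" else "three_plus"
}

#' Classify a cell as single, multiple, or abnormal TCR
#'
#' A cell is *abnormal* when it cannot pair a functional beta with a
#' functional alpha chain (no TRB(F) or no TRA(F)); *single* when it has
#' exactly one TRB(F) and one TRA(F), regardless of extra non-functional
#' chains; and *multiple* when both loci contribute at least one functional
#' chain and three or more functional chains are present in total, so that
#' more than one functional beta+alpha receptor could be assembled.
#'
#' @param profile a `cell_profile`.
#' @return `"single"`, `"multiple"`, or `"abnormal"`.
#' @export
classify_tcr_status <- function(profile) {
  stopifnot(nrow(profile$chains) >= 1)
  bf <- profile$n_trb_f
  af <- profile$n_tra_f
  if (bf == 0 || af == 0) "abnormal"
  else if (bf == 1 && af == 1) "single"
  else "multiple"
}

#' Can the cell assemble a functional TCR?
#'
#' @param profile a `cell_profile`.
#' @return `TRUE` iff the cell has at least one TRB(F) and one TRA(F)
#'   chain; equivalently, its status is not `"abnormal"`.
#' @export
is_functional_cell <- function(profile) {
  stopifnot(nrow(profile$chains) >= 1)
  profile$n_trb_f >= 1 && profile$n_tra_f >= 1
}

#' Classify every cell in a sample
#'
#' @param profiles list of `cell_profile` objects (e.g. from
#'   [build_cell_profiles()]).
#' @return data frame with one row per cell: `barcode`, `pattern_code`,
#'   `pattern_name`, `chain_group`, `status`, `functional`, and the four
#'   chain counts.
#' @export
classify_cells <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    pat <- assign_pattern(p)
    data.frame(barcode = p$barcode,
               pattern_code = pat$code,
               pattern_name = pat$name,
               chain_group = chain_count_group(p),
               status = classify_tcr_status(p),
               functional = is_functional_cell(p),
               n_trb_f = p$n_trb_f, n_trb_n = p$n_trb_n,
               n_tra_f = p$n_tra_f, n_tra_n = p$n_tra_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
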