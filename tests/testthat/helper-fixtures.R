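# Shared fixture builders. Everything is constructed in code; no binary
# fixtures.

# one contig record row with sensible defaults
make_record <- function(barcode = "BC1", is_cell = "True",
                        high_confidence = "True", locus = "TRB",
                        v_call = "TRBV19", d_call = "TRBD1",
                        j_call = "TRBJ1-5", c_call = "TRBC1",
                        junction_aa = "CASSIRSSYEQYF",
                        productive_raw = "True", umis = 10L,
                        contig_id = NULL) {
  data.frame(barcode = barcode, is_cell = is_cell,
             high_confidence = high_confidence, locus = locus,
             v_call = v_call, d_call = d_call, j_call = j_call,
             c_call = c_call, junction_aa = junction_aa,
             productive_raw = productive_raw, umis = umis,
             contig_id = contig_id %||%
               paste0("ctg_", substr(tempfile(""), 30, 40)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a cell profile from (locus, status) count spec; gene calls are
# irrelevant for pattern/status logic, so placeholders are used
make_profile <- function(n_trb_f = 0, n_trb_n = 0, n_tra_f = 0, n_tra_n = 0,
                         barcode = "BC1") {
  n <- n_trb_f + n_trb_n + n_tra_f + n_tra_n
  stopifnot(n >= 1)
  chains <- data.frame(
    locus = c(rep("TRB", n_trb_f + n_trb_n), rep("TRA", n_tra_f + n_tra_n)),
    v_call = sprintf("V%d", seq_len(n)),
    d_call = "", j_call = sprintf("J%d", seq_len(n)), c_call = "",
    junction_aa = sprintf("CJ%dF", seq_len(n)),
    status = c(rep("F", n_trb_f), rep("N", n_trb_n),
               rep("F", n_tra_f), rep("N", n_tra_n)),
    stringsAsFactors = FALSE)
  new_cell_profile(barcode, chains)
}

# all chain multisets over {TRB,TRA} x {F,N} with sizes in `sizes`,
# as a data frame of the four counts
all_multisets <- function(sizes = 1:4) {
  out <- expand.grid(n_trb_f = 0:max(sizes), n_trb_n = 0:max(sizes),
                     n_tra_f = 0:max(sizes), n_tra_n = 0:max(sizes))
  out[rowSums(out) %in% sizes, , drop = FALSE]
}

# Independent rule enumeration for the 23 pattern categories, transcribed
# directly from the published category list as a literal lookup: the key is
# the sorted multiset of chain labels.
oracle_pattern_code <- function(bF, bN, aF, aN) {
  key <- paste(sort(c(rep("B.F", bF), rep("B.N", bN),
                      rep("A.F", aF), rep("A.N", aN))), collapse = "+")
  lut <- c(
    "B.F" = 1, "B.N" = 2, "A.F" = 3, "A.N" = 4,
    "B.F+B.F" = 5, "B.F+B.N" = 6, "B.N+B.N" = 7,
    "A.F+A.F" = 8, "A.F+A.N" = 9, "A.N+A.N" = 10,
    "A.F+B.F" = 11, "A.N+B.F" = 12, "A.F+B.N" = 13, "A.N+B.N" = 14,
    "B.F+B.F+B.F" = 15, "B.F+B.F+B.N" = 16, "B.F+B.N+B.N" = 17,
    "B.N+B.N+B.N" = 18,
    "A.F+A.F+A.F" = 19, "A.F+A.F+A.N" = 20, "A.F+A.N+A.N" = 21,
    "A.N+A.N+A.N" = 22)
  if (key %in% names(lut)) unname(lut[key]) else 23
}

# Independent status rule: no functional beta+alpha pair -> abnormal;
# exactly one of each -> single; otherwise multiple.
oracle_status <- function(bF, bN, aF, aN) {
  if (bF == 0 || aF == 0) "abnormal"
  else if (bF == 1 && aF == 1) "single"
  else "multiple"
}

# enumerate every possible rearrangement event on a locus map (used for
# exhaustive rule-vs-oracle comparisons on the toy locus)
all_events <- function(map) {
  g <- map$genes
  vs <- g$name[g$segment_class == "V"]
  out <- list()
  if (map$locus == "TRB") {
    for (cl in c("DJC1", "DJC2")) {
      d <- g$name[g$segment_class == "D" & g$cluster == cl]
      cc <- g$name[g$segment_class == "C" & g$cluster == cl]
      js <- g$name[g$segment_class == "J" & g$cluster == cl]
      for (v in vs) for (j in js)
        out[[length(out) + 1]] <-
          rearrangement_event("TRB", v, j, d, cc, "F", map)
    }
  } else {
    js <- g$name[g$segment_class == "J"]
    cc <- g$name[g$segment_class == "C"]
    for (v in vs) for (j in js)
      out[[length(out) + 1]] <-
        rearrangement_event("TRA", v, j, "", cc, "F", map)
  }
  out
}

# rule-based verdict: can events a and b coexist on one chromosome under
# any supported mechanism (either role assignment)?
rule_same_chromosome <- function(a, b, map) {
  if (map$locus == "TRB")
    trb_trec_compatible(a, b, map) || trb_trec_compatible(b, a, map) ||
      trb_inversion_compatible(a, b, map)
  else
    tra_trec_compatible(a, b, map) || tra_trec_compatible(b, a, map)
}

# oracle verdict for the same question, via direct excision simulation in
# both chronological orders
oracle_same_chromosome_any <- function(a, b, map) {
  !is.null(tcrtrace:::oracle_same_chromosome(a, b, map)) ||
    !is.null(tcrtrace:::oracle_same_chromosome(b, a, map))
}

# draw one random fully-specified event on a packaged map
random_event <- function(map, rng_v_pool = NULL) {
  g <- map$genes
  if (map$locus == "TRB") {
    cl <- sample(c("DJC1", "DJC2"), 1)
    v <- sample(g$name[g$segment_class == "V"], 1)
    j <- sample(g$name[g$segment_class == "J" & g$cluster == cl], 1)
    d <- g$name[g$segment_class == "D" & g$cluster == cl]
    cc <- g$name[g$segment_class == "C" & g$cluster == cl]
    rearrangement_event("TRB", v, j, d, cc, "F", map)
  } else {
    v <- sample(g$name[g$segment_class == "V"], 1)
    j <- sample(g$name[g$segment_class == "J"], 1)
    rearrangement_event("TRA", v, j, "", "TRAC", "F", map)
  }
}
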