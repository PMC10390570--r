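#' Default chain-pattern weights for the synthetic generator
#'
#' A qualitatively thymus-like mixture: roughly half of the cells can pair
#' a functional beta with a functional alpha chain, single-chain dropouts
#' are common, and three-or-more-chain cells are a small minority. These
#' are the generator's study conditions, not estimates of any published
#' per-pattern table (none is printed at that resolution).
#'
#' @return named numeric vector of length 23 summing to 1, named by
#'   pattern code.
#' @export
default_pattern_weights <- function() {
  w <- c(
    `1` = 0.10, `2` = 0.04, `3` = 0.08, `4` = 0.04,
    `5` = 0.015, `6` = 0.015, `7` = 0.01, `8` = 0.015, `9` = 0.015,
    `10` = 0.01, `11` = 0.40, `12` = 0.05, `13` = 0.05, `14` = 0.03,
    `15` = 0.004, `16` = 0.004, `17` = 0.004, `18` = 0.003,
    `19` = 0.004, `20` = 0.004, `21` = 0.004, `22` = 0.003,
    `23` = 0.10)
  w / sum(w)
}

#' Build a synthetic-sample configuration
#'
#' @param n_cells number of cells to generate.
#' @param pattern_weights nonnegative 23-vector of pattern weights
#'   (normalized internally).
#' @param mechanism_plant_rates named proportions of cells planted with a
#'   mechanism-compatible multi-chain architecture; names among
#'   `trec_circle_beta`, `trec_circle_alpha`, `inversion_v30`.
#' @param qc_noise named proportions (of `n_cells`) of injected
#'   QC-failing contig rows: `not_cell`, `low_confidence`, `wrong_chain`,
#'   `productive_none`.
#' @param species `"human"` or `"mouse"`.
#' @param seed integer seed; fully determines the output.
#' @param dialect output dialect, `"tenx_csv"` or `"airr_tsv"`.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cells,
                         pattern_weights = default_pattern_weights(),
                         mechanism_plant_rates = c(trec_circle_beta = 0,
                                                   trec_circle_alpha = 0,
                                                   inversion_v30 = 0),
                         qc_noise = c(not_cell = 0, low_confidence = 0,
                                      wrong_chain = 0, productive_none = 0),
                         species = "human", seed = 1,
                         dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (length(pattern_weights) != 23 || any(pattern_weights < 0) ||
      sum(pattern_weights) <= 0)
    stop("pattern_weights must be 23 nonnegative weights with positive sum")
  if (!species %in% c("human", "mouse")) stop("unsupported species ", species)
  if (sum(mechanism_plant_rates) > 1)
    stop("mechanism plant rates must sum to at most 1")
  structure(list(n_cells = n_cells,
                 pattern_weights = pattern_weights / sum(pattern_weights),
                 mechanism_plant_rates = mechanism_plant_rates,
                 qc_noise = qc_noise, species = species, seed = seed,
                 dialect = dialect),
            class = "synth_config")
}

random_junction <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste0("C", paste(sample(aa, sample(6:18, 1), replace = TRUE),
                      collapse = ""), "F"),
    character(1))
}

# gene pools per species, computed once per generate_sample() call
gene_pools <- function(species) {
  maps <- list(TRA = load_locus(species, "TRA"),
               TRB = load_locus(species, "TRB"))
  pool <- function(m, cls, fun = NULL, cluster = NULL, orient = NULL) {
    g <- m$genes
    k <- g$segment_class == cls
    if (!is.null(fun)) k <- k & (g$functionality %in% fun)
    if (!is.null(cluster)) k <- k & g$cluster == cluster
    if (!is.null(orient)) k <- k & g$orientation == orient
    g$name[k]
  }
  list(maps = maps,
       trb_v_fun_fwd = pool(maps$TRB, "V", "functional", orient = "forward"),
       trb_v_nonfun = pool(maps$TRB, "V", c("pseudogene", "ORF")),
       trb_v_rev = pool(maps$TRB, "V", orient = "reverse"),
       trb_j1 = pool(maps$TRB, "J", "functional", "DJC1"),
       trb_j2 = pool(maps$TRB, "J", "functional", "DJC2"),
       tra_v_fun = pool(maps$TRA, "V", "functional"),
       tra_v_nonfun = pool(maps$TRA, "V", c("pseudogene", "ORF")),
       tra_j_fun = pool(maps$TRA, "J", "functional"))
}

# draw one chain of the requested locus/status; returns a one-row contig df
draw_chain <- function(locus, status, pools) {
  if (locus == "TRB") {
    cl <- sample(1:2, 1)
    j <- sample(if (cl == 1) pools$trb_j1 else pools$trb_j2, 1)
    d <- sprintf("TRBD%d", cl)
    cc <- sprintf("TRBC%d", cl)
  } else {
    j <- sample(pools$tra_j_fun, 1)
    d <- ""
    cc <- "TRAC"
  }
  if (status == "F") {
    v <- sample(if (locus == "TRB") pools$trb_v_fun_fwd else pools$tra_v_fun, 1)
    prod <- "True"
  } else if (stats::runif(1) < 0.5) {
    v <- sample(if (locus == "TRB")
      c(pools$trb_v_fun_fwd, pools$trb_v_nonfun)
      else c(pools$tra_v_fun, pools$tra_v_nonfun), 1)
    prod <- "False"
  } else {
    v <- sample(if (locus == "TRB") pools$trb_v_nonfun else pools$tra_v_nonfun, 1)
    prod <- "True"
  }
  data.frame(locus = locus, v_call = v, d_call = d, j_call = j, c_call = cc,
             junction_aa = random_junction(1), productive_raw = prod,
             status = status, stringsAsFactors = FALSE)
}

# chain multisets implied by each pattern code; code 23 draws one of a few
# mixed >=3-chain archetypes
pattern_chain_specs <- function(code) {
  lab <- pattern_labels()
  row <- lab[lab$code == code, ]
  if (code != 23) {
    data.frame(
      locus = c(rep("TRB", row$n_trb_f + row$n_trb_n),
                rep("TRA", row$n_tra_f + row$n_tra_n)),
      status = c(rep("F", row$n_trb_f), rep("N", row$n_trb_n),
                 rep("F", row$n_tra_f), rep("N", row$n_tra_n)),
      stringsAsFactors = FALSE)
  } else {
    arch <- list(c(1, 0, 1, 1), c(1, 1, 1, 0), c(2, 0, 2, 0),
                 c(1, 1, 1, 1), c(2, 1, 1, 0), c(0, 1, 1, 1))
    a <- arch[[sample(length(arch), 1)]]
    data.frame(
      locus = c(rep("TRB", a[1] + a[2]), rep("TRA", a[3] + a[4])),
      status = c(rep("F", a[1]), rep("N", a[2]),
                 rep("F", a[3]), rep("N", a[4])),
      stringsAsFactors = FALSE)
  }
}

# sample a mechanism-compatible event pair (plus a partner chain on the
# other locus), verifying feasibility with the excision oracle
plant_mechanism_chains <- function(mech, pools) {
  maps <- pools$maps
  if (mech == "trec_circle_beta") {
    repeat {
      vs <- sample(pools$trb_v_fun_fwd, 2)
      ord <- vapply(vs, function(v) maps$TRB$index[[v]], numeric(1))
      vu <- vs[which.min(ord)]; vd <- vs[which.max(ord)]
      a <- rearrangement_event("TRB", vd, sample(pools$trb_j1, 1), "TRBD1",
                               "TRBC1", "F", maps$TRB)
      b <- rearrangement_event("TRB", vu, sample(pools$trb_j2, 1), "TRBD2",
                               "TRBC2", "F", maps$TRB)
      if (trb_trec_compatible(a, b, maps$TRB)) break
    }
    loc <- oracle_same_chromosome(a, b, maps$TRB)
    stopifnot(!is.null(loc), loc[1] == "circle", loc[2] == "chromosome")
    extra <- draw_chain("TRA", "F", pools)
  } else if (mech == "trec_circle_alpha") {
    repeat {
      vs <- sample(pools$tra_v_fun, 2)
      js <- sample(pools$tra_j_fun, 2)
      vo <- vapply(vs, function(v) maps$TRA$index[[v]], numeric(1))
      jo <- vapply(js, function(j) maps$TRA$index[[j]], numeric(1))
      a <- rearrangement_event("TRA", vs[which.max(vo)], js[which.min(jo)],
                               "", "TRAC", "F", maps$TRA)
      b <- rearrangement_event("TRA", vs[which.min(vo)], js[which.max(jo)],
                               "", "TRAC", "F", maps$TRA)
      if (tra_trec_compatible(a, b, maps$TRA)) break
    }
    loc <- oracle_same_chromosome(a, b, maps$TRA)
    stopifnot(!is.null(loc), loc[1] == "circle", loc[2] == "chromosome")
    extra <- draw_chain("TRB", "F", pools)
  } else if (mech == "inversion_v30") {
    a <- rearrangement_event("TRB", pools$trb_v_rev, sample(pools$trb_j2, 1),
                             "TRBD2", "TRBC2", "F", maps$TRB)
    b <- rearrangement_event("TRB", sample(pools$trb_v_fun_fwd, 1),
                             sample(pools$trb_j1, 1), "TRBD1", "TRBC1", "F",
                             maps$TRB)
    stopifnot(trb_inversion_compatible(a, b, maps$TRB))
    loc <- oracle_same_chromosome(a, b, maps$TRB)
    stopifnot(!is.null(loc), all(loc == "chromosome"))
    extra <- draw_chain("TRA", "F", pools)
  } else stop("unknown mechanism ", mech)
  ev_df <- function(ev) data.frame(
    locus = ev$locus, v_call = ev$v_call, d_call = ev$d_call,
    j_call = ev$j_call, c_call = ev$c_call,
    junction_aa = random_junction(1), productive_raw = "True",
    status = ev$status, stringsAsFactors = FALSE)
  rbind(ev_df(a), ev_df(b), extra)
}

#' Generate a synthetic contig table with truth labels
#'
#' Draws each cell's chain multiset from the configured 23-pattern weights,
#' samples locus-consistent V/(D)/J/C genes (cluster-consistent D/J/C for
#' TRB) uniformly from the packaged locus tables, makes non-functional
#' chains either non-productive or productive-with-pseudogene/ORF-V, plants
#' mechanism-compatible multi-chain cells (verified against the excision
#' oracle at generation time), appends the configured QC-failing noise
#' rows, and writes the table in the configured dialect. The same
#' configuration (including seed) always yields a byte-identical file.
#'
#' @param config a [synth_config()].
#' @param path output file path (default: a tempfile with the dialect's
#'   extension).
#' @return list with `path`, `truth` (per-cell data frame: `barcode`,
#'   `pattern_code`, `status`, `chain_group`, `mechanism`, `events`), and
#'   `records` (the in-memory contig table as written, unified schema).
#' @export
generate_sample <- function(config, path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(path))
    path <- tempfile(fileext = if (config$dialect == "tenx_csv") ".csv"
                     else ".tsv")
  set.seed(config$seed)
  n <- config$n_cells
  pools <- gene_pools(config$species)
  lab <- pattern_labels()

  contigs <- list()
  truth <- list()
  if (n > 0) {
    codes <- sample(1:23, n, replace = TRUE, prob = config$pattern_weights)
    rates <- config$mechanism_plant_rates
    planted <- rep(NA_character_, n)
    n_plant <- round(rates * n)
    if (sum(n_plant) > 0) {
      idx <- sample(n, sum(n_plant))
      planted[idx] <- rep(names(n_plant), n_plant)
    }
    barcodes <- sprintf("CELL%06d-1", seq_len(n))
    for (i in seq_len(n)) {
      if (!is.na(planted[i])) {
        ch <- plant_mechanism_chains(planted[i], pools)
      } else {
        spec <- pattern_chain_specs(codes[i])
        repeat {
          ch <- do.call(rbind, lapply(seq_len(nrow(spec)), function(k)
            draw_chain(spec$locus[k], spec$status[k], pools)))
          if (!anyDuplicated(chain_identity_key(ch))) break
        }
      }
      prof <- new_cell_profile(barcodes[i], ch)
      pat <- assign_pattern(prof)
      truth[[i]] <- data.frame(
        barcode = barcodes[i], pattern_code = pat$code,
        status = classify_tcr_status(prof),
        chain_group = chain_count_group(prof),
        mechanism = ifelse(is.na(planted[i]), "none", planted[i]),
        events = paste(apply(ch[, c("locus", "v_call", "d_call", "j_call",
                                    "c_call", "status")], 1, paste,
                             collapse = "/"), collapse = ";"),
        stringsAsFactors = FALSE)
      ch$barcode <- barcodes[i]
      ch$is_cell <- "True"
      ch$high_confidence <- "True"
      contigs[[i]] <- ch
    }
  }

  # QC-failing noise rows, reusing real barcodes where possible
  noise <- list()
  n_noise <- round(config$qc_noise * n)
  if (length(n_noise) && sum(n_noise, na.rm = TRUE) > 0 && n > 0) {
    for (reason in names(n_noise)) {
      k <- n_noise[[reason]]
      if (is.na(k) || k == 0) next
      for (j in seq_len(k)) {
        ch <- draw_chain(sample(c("TRA", "TRB"), 1), "N", pools)
        ch$barcode <- sprintf("CELL%06d-1", sample(n, 1))
        ch$is_cell <- "True"
        ch$high_confidence <- "True"
        if (reason == "not_cell") ch$is_cell <- "FALSE"
        if (reason == "low_confidence") ch$high_confidence <- "FALSE"
        if (reason == "wrong_chain") ch$locus <- "IGH"
        if (reason == "productive_none") ch$productive_raw <- "None"
        noise[[length(noise) + 1]] <- ch
      }
    }
  }

  all_ch <- do.call(rbind, c(contigs, noise))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(barcode = character(0), pattern_code = integer(0),
               status = character(0), chain_group = character(0),
               mechanism = character(0), events = character(0))
  records <- if (is.null(all_ch)) {
    data.frame(barcode = character(0), is_cell = character(0),
               high_confidence = character(0), locus = character(0),
               v_call = character(0), d_call = character(0),
               j_call = character(0), c_call = character(0),
               junction_aa = character(0), productive_raw = character(0),
               umis = integer(0), contig_id = character(0))
  } else {
    data.frame(barcode = all_ch$barcode, is_cell = all_ch$is_cell,
               high_confidence = all_ch$high_confidence,
               locus = all_ch$locus, v_call = all_ch$v_call,
               d_call = all_ch$d_call, j_call = all_ch$j_call,
               c_call = all_ch$c_call, junction_aa = all_ch$junction_aa,
               productive_raw = all_ch$productive_raw,
               umis = sample(1:200, nrow(all_ch), replace = TRUE),
               contig_id = sprintf("contig_%06d", seq_len(nrow(all_ch))),
               stringsAsFactors = FALSE)
  }
  write_contig_table(records, path, config$dialect)
  list(path = path, truth = truth, records = records)
}

#' Write contig records in a supported dialect
#'
#' @param records unified-schema contig data frame.
#' @param path output file path.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return `path`, invisibly.
#' @export
write_contig_table <- function(records, path,
                               dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tenx_csv") {
    out <- data.frame(
      barcode = records$barcode, is_cell = records$is_cell,
      contig_id = records$contig_id,
      high_confidence = records$high_confidence,
      chain = records$locus, v_gene = records$v_call,
      d_gene = records$d_call, j_gene = records$j_call,
      c_gene = records$c_call,
      full_length = rep("True", nrow(records)),
      productive = records$productive_raw, cdr3 = records$junction_aa,
      umis = records$umis, stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    write_airr_tsv(records, path)
  }
  invisible(path)
}

#' Simulate the sequential biallelic rearrangement process
#'
#' Each cell attempts a rearrangement on its first allele, productive with
#' probability `p_productive`; on failure it attempts its second (and last)
#' allele with the same probability. At p = 1/3, the expected fraction of
#' cells productive on the first attempt is 1/3 and on the second
#' (1 - 1/3) x 1/3 = 2/9.
#'
#' @param n_cells number of simulated cells.
#' @param p_productive per-attempt probability of a productive join,
#'   strictly between 0 and 1 (1 allowed as the degenerate case).
#' @param seed integer seed.
#' @return data frame with one row per cell: `cell`, `n_attempts`,
#'   `outcome` (`productive_first`, `productive_second`, `failed`).
#' @export
simulate_rearrangement_process <- function(n_cells, p_productive, seed = 1) {
  stopifnot(p_productive > 0, p_productive <= 1)
  set.seed(seed)
  first <- stats::runif(n_cells) < p_productive
  second <- !first & (stats::runif(n_cells) < p_productive)
  data.frame(cell = seq_len(n_cells),
             n_attempts = ifelse(first, 1L, 2L),
             outcome = ifelse(first, "productive_first",
                              ifelse(second, "productive_second", "failed")),
             stringsAsFactors = FALSE)
}
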