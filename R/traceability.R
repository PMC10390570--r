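#' Construct a rearrangement event
#'
#' One V(D)J rearrangement observed in a cell, resolved against a locus
#' map. For TRB, the D-J-C cluster is taken from the J call and must agree
#' with the D and C calls when those are present (C-gene consistency is
#' used as cluster evidence when the D call is missing from the contig
#' annotation: a missing D is imputed as the cluster's D segment).
#'
#' @param locus `"TRA"` or `"TRB"`.
#' @param v_call,j_call gene names (required).
#' @param d_call,c_call gene names or `""` (TRB only for `d_call`).
#' @param status `"F"` or `"N"`.
#' @param map the matching `locus_map`.
#' @return a `rearrangement_event` (list with resolved gene rows and, for
#'   TRB, `cluster`).
#' @export
rearrangement_event <- function(locus, v_call, j_call, d_call = "",
                                c_call = "", status = "F", map) {
  stopifnot(locus %in% c("TRA", "TRB"), map$locus == locus)
  v <- locus_gene(v_call, map)
  j <- locus_gene(j_call, map)
  ev <- list(locus = locus, v_call = v_call, j_call = j_call,
             d_call = d_call, c_call = c_call, status = status,
             v = v, j = j)
  if (locus == "TRB") {
    cluster <- j$cluster
    if (nzchar(c_call)) {
      cgene <- locus_gene(c_call, map)
      if (cgene$cluster != cluster)
        stop("inconsistent event: ", j_call, " is in ", cluster, " but ",
             c_call, " is in ", cgene$cluster)
    }
    if (!nzchar(d_call)) {
      d_call <- map$genes$name[map$genes$segment_class == "D" &
                                 map$genes$cluster == cluster]
      ev$d_call <- d_call
    }
    d <- locus_gene(d_call, map)
    if (d$cluster != cluster)
      stop("inconsistent event: ", d_call, " is in ", d$cluster, " but ",
           j_call, " is in ", cluster)
    ev$d <- d
    ev$cluster <- cluster
  }
  class(ev) <- "rearrangement_event"
  ev
}

event_label <- function(ev) {
  paste(c(ev$v_call, if (ev$locus == "TRB") ev$d_call, ev$j_call,
          if (nzchar(ev$c_call)) ev$c_call), collapse = "-")
}

# RSS validity of an event's own joins (V->D and D->J for TRB, V->J for TRA)
event_rss_ok <- function(ev) {
  if (ev$locus == "TRB")
    rss_compatible(ev$v, ev$d) && rss_compatible(ev$d, ev$j)
  else
    rss_compatible(ev$v, ev$j)
}

#' Can a TREC circle explain two TRB rearrangements on one chromosome?
#'
#' Tests whether event `a` could be the first (circle-resident)
#' rearrangement and event `b` the second (chromosome-resident) one on a
#' single TRB allele: `a` must use the upstream D-J-C cluster (DJC1), `b`
#' the downstream cluster (DJC2), `b`'s V segment must lie strictly 5' of
#' `a`'s V (so that `b`'s V-to-D2 excision interval contains `a`'s complete
#' VDJ join, which then persists on the excised circle), both V segments
#' must be in forward orientation, and all joins must obey the 12/23 rule.
#'
#' @param a,b `rearrangement_event`s on TRB.
#' @param map the TRB `locus_map`.
#' @return logical; `TRUE` assigns the roles a = circle, b = chromosome.
#' @export
trb_trec_compatible <- function(a, b, map) {
  stopifnot(a$locus == "TRB", b$locus == "TRB")
  a$cluster == "DJC1" && b$cluster == "DJC2" &&
    a$v$orientation == "forward" && b$v$orientation == "forward" &&
    a$v_call != b$v_call &&
    upstream_of(b$v_call, a$v_call, map) &&
    event_rss_ok(a) && event_rss_ok(b)
}

#' Can a TREC circle explain two TRA rearrangements on one chromosome?
#'
#' `a` is circle-resident and `b` chromosome-resident when `b`'s V lies
#' strictly 5' of `a`'s V and `b`'s J strictly 3' of `a`'s J, so `b`'s
#' V-to-J excision interval contains `a`'s complete VJ join; joins must
#' obey the 12/23 rule.
#'
#' @param a,b `rearrangement_event`s on TRA.
#' @param map the TRA `locus_map`.
#' @return logical; `TRUE` assigns the roles a = circle, b = chromosome.
#' @export
tra_trec_compatible <- function(a, b, map) {
  stopifnot(a$locus == "TRA", b$locus == "TRA")
  a$v_call != b$v_call && a$j_call != b$j_call &&
    upstream_of(b$v_call, a$v_call, map) &&
    upstream_of(a$j_call, b$j_call, map) &&
    event_rss_ok(a) && event_rss_ok(b)
}

#' Can inversional recombination explain two TRB rearrangements on one
#' chromosome?
#'
#' The TRB locus carries one V segment in reverse transcriptional
#' orientation 3' of both D-J-C clusters (human TRBV30, mouse TRBV31).
#' Its rearrangement inverts, rather than deletes, the intervening DNA, so
#' a second join can coexist on the same chromosome. Feasibility requires
#' exactly one of the two events to use the reverse V, that event to use
#' the downstream cluster (DJC2), and the other (forward-V) event to use
#' DJC1: a forward V joining DJC2 would delete the DJC1 cluster, and an
#' inversion onto DJC1 flips the DJC2 cluster out of joining orientation.
#' The relation is symmetric in its arguments.
#'
#' @param a,b `rearrangement_event`s on TRB.
#' @param map the TRB `locus_map`.
#' @return logical.
#' @export
trb_inversion_compatible <- function(a, b, map) {
  stopifnot(a$locus == "TRB", b$locus == "TRB")
  rev_a <- a$v$orientation == "reverse"
  rev_b <- b$v$orientation == "reverse"
  if (rev_a == rev_b) return(FALSE)
  rev_ev <- if (rev_a) a else b
  fwd_ev <- if (rev_a) b else a
  rev_ev$cluster == "DJC2" && fwd_ev$cluster == "DJC1" &&
    fwd_ev$v$orientation == "forward" &&
    event_rss_ok(rev_ev) && event_rss_ok(fwd_ev)
}

## ---- brute-force excision oracle --------------------------------------

new_chromosome <- function(map) {
  lapply(seq_len(nrow(map$genes)), function(i)
    list(kind = "segment", name = map$genes$name[i],
         class = map$genes$segment_class[i],
         orientation = map$genes$orientation[i],
         gene = map$genes[i, ], event = NA_integer_, flipped = FALSE))
}

find_segment <- function(chrom, name) {
  for (i in seq_along(chrom)) {
    e <- chrom[[i]]
    if (e$kind == "segment" && e$name == name && !e$flipped) return(i)
  }
  0L
}

# join entries at positions u (5' partner) and d (3' partner); deletional
# joins excise the open interval into a circle, inversional joins flip it
# in place (flipped entries take no further part in rearrangement)
apply_join <- function(state, u, d, event_idx, inversional = FALSE) {
  chrom <- state$chrom
  lo <- min(u, d); hi <- max(u, d)
  between <- if (hi - lo > 1) chrom[(lo + 1):(hi - 1)] else list()
  merged <- list(kind = "composite",
                 members = c(entry_members(chrom[[lo]]),
                             entry_members(chrom[[hi]])),
                 event = event_idx, flipped = FALSE)
  head <- if (lo > 1) chrom[1:(lo - 1)] else list()
  tail <- if (hi < length(chrom)) chrom[(hi + 1):length(chrom)] else list()
  if (inversional) {
    between <- lapply(rev(between), function(e) { e$flipped <- TRUE; e })
    state$chrom <- c(head, list(merged), between, tail)
  } else {
    state$chrom <- c(head, list(merged), tail)
    if (length(between)) state$circles <- c(state$circles, list(between))
  }
  state
}

entry_members <- function(e) {
  if (e$kind == "segment") e$name else e$members
}

# apply one rearrangement event to a chromosome state; returns the updated
# state or NULL when the event is physically infeasible there
apply_event <- function(state, ev, event_idx, map) {
  if (!event_rss_ok(ev)) return(NULL)
  if (ev$locus == "TRB") {
    pd <- find_segment(state$chrom, ev$d_call)
    pj <- find_segment(state$chrom, ev$j_call)
    if (pd == 0 || pj == 0 || pd >= pj) return(NULL)
    state <- apply_join(state, pd, pj, event_idx)
    pv <- find_segment(state$chrom, ev$v_call)
    pc <- composite_pos(state$chrom, event_idx)
    if (pv == 0) return(NULL)
    if (ev$v$orientation == "forward") {
      if (pv >= pc) return(NULL)
      apply_join(state, pv, pc, event_idx)
    } else {
      if (pv <= pc) return(NULL)
      apply_join(state, pc, pv, event_idx, inversional = TRUE)
    }
  } else {
    pv <- find_segment(state$chrom, ev$v_call)
    pj <- find_segment(state$chrom, ev$j_call)
    if (pv == 0 || pj == 0 || pv >= pj) return(NULL)
    if (ev$v$orientation != "forward") return(NULL)
    apply_join(state, pv, pj, event_idx)
  }
}

composite_pos <- function(chrom, event_idx) {
  for (i in seq_along(chrom))
    if (chrom[[i]]$kind == "composite" && !chrom[[i]]$flipped &&
        identical(chrom[[i]]$event, event_idx)) return(i)
  0L
}

# where did each event's join end up? "chromosome", "circle", or NA if the
# event could not be applied
simulate_chromosome <- function(events, map) {
  state <- list(chrom = new_chromosome(map), circles = list())
  ok <- rep(FALSE, length(events))
  for (i in seq_along(events)) {
    nxt <- apply_event(state, events[[i]], i, map)
    if (is.null(nxt)) return(list(ok = ok, location = NULL))
    state <- nxt
    ok[i] <- TRUE
  }
  loc <- vapply(seq_along(events), function(i) {
    if (composite_pos(state$chrom, i) > 0 ||
        any(vapply(state$chrom, function(e)
          e$kind == "composite" && e$flipped && identical(e$event, i),
          logical(1))))
      return("chromosome")
    for (circ in state$circles)
      for (e in circ)
        if (e$kind == "composite" && identical(e$event, i)) return("circle")
    NA_character_
  }, character(1))
  list(ok = ok, location = loc)
}

#' Brute-force excision simulation of a rearrangement scheme
#'
#' Independent correctness reference for the rule-based compatibility
#' checks. The locus is modelled as its ordinal segment sequence on one or
#' two homologous chromosomes. Events are applied in the scheme's order on
#' their assigned chromosome: a deletional join excises the open interval
#' between the joined segments onto a circle (whose contents are tracked),
#' an inversional join (reverse-orientation V) inverts the interval in
#' place; inverted segments take no further part in joining. Each physical
#' segment is used by at most one join.
#'
#' @param events list of `rearrangement_event`s, all on `map`'s locus.
#' @param map a `locus_map`.
#' @param scheme list with `chromosome` (integer vector in \{1, 2\}, one
#'   entry per event) and `order` (permutation of `seq_along(events)`:
#'   chronological order of the rearrangements).
#' @return `TRUE` iff every event can be applied and its complete join ends
#'   up either on a final chromosome or intact on an excised circle.
#' @export
brute_force_excision_oracle <- function(events, map, scheme) {
  n <- length(events)
  stopifnot(length(scheme$chromosome) == n,
            setequal(scheme$order, seq_len(n)))
  for (chrom_id in unique(scheme$chromosome)) {
    idx <- scheme$order[scheme$chromosome[scheme$order] == chrom_id]
    res <- simulate_chromosome(events[idx], map)
    if (!all(res$ok)) return(FALSE)
  }
  TRUE
}

# can events a (first) then b (second) coexist on ONE chromosome, and where
# does each join end up?  Used by tests and by the planted-data generator.
oracle_same_chromosome <- function(a, b, map) {
  res <- simulate_chromosome(list(a, b), map)
  if (!all(res$ok)) return(NULL)
  res$location
}

#' Classify the same-chromosome mechanisms feasible for a cell
#'
#' For every locus on which the cell carries two or more distinct
#' rearrangements, enumerates all ordered event pairs and records every
#' feasible same-chromosome mechanism (TREC-circle transcription for TRB or
#' TRA; inversional recombination of the reverse V) together with its role
#' assignment (which event sits on the excised circle and which on the
#' chromosome). With two same-locus events, ordinary biallelic
#' rearrangement (`two_chromosomes`) is always additionally feasible. With
#' three or more, the cell is explained only if the events can be covered
#' by at most two chromosomes, pairing events on a shared chromosome via a
#' supported mechanism; otherwise `unexplained` is reported.
#'
#' @param profile a `cell_profile` with at least two same-locus chains.
#' @param species `"human"` or `"mouse"`, or a named list of `locus_map`s
#'   (`TRA`, `TRB`).
#' @return a `mechanism_call`: `barcode`, `feasible` (union over loci),
#'   `roles` (data frame: locus, mechanism, circle/chromosome event
#'   labels), and `loci` (per-locus detail).
#' @export
classify_cell_mechanism <- function(profile, species = "human") {
  maps <- if (is.list(species) && !is.null(species$TRB)) species
  else list(TRA = load_locus(species, "TRA"),
            TRB = load_locus(species, "TRB"))
  ch <- profile$chains
  ch <- ch[nzchar(ch$v_call) & nzchar(ch$j_call), , drop = FALSE]
  loci <- list()
  for (locus in c("TRA", "TRB")) {
    sub <- ch[ch$locus == locus, , drop = FALSE]
    if (nrow(sub) < 2) next
    map <- maps[[locus]]
    events <- lapply(seq_len(nrow(sub)), function(i)
      rearrangement_event(locus, sub$v_call[i], sub$j_call[i],
                          sub$d_call[i], sub$c_call[i], sub$status[i], map))
    loci[[locus]] <- classify_locus_mechanisms(events, map, locus)
  }
  if (!length(loci))
    stop("mechanism classification needs >=2 same-locus distinct chains")
  roles <- do.call(rbind, lapply(names(loci), function(l) loci[[l]]$roles))
  call <- list(barcode = profile$barcode,
               feasible = sort(unique(unlist(lapply(loci, `[[`, "feasible")))),
               roles = roles, loci = loci)
  class(call) <- "mechanism_call"
  call
}

classify_locus_mechanisms <- function(events, map, locus) {
  n <- length(events)
  pair_mech <- list()  # list of (i, j, mechanism): i = circle/first role
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- events[[i]]; b <- events[[j]]
    if (locus == "TRB") {
      if (trb_trec_compatible(a, b, map))
        pair_mech[[length(pair_mech) + 1]] <-
          list(i = i, j = j, mechanism = "trec_circle_beta")
      if (i < j && trb_inversion_compatible(a, b, map))
        pair_mech[[length(pair_mech) + 1]] <-
          list(i = i, j = j, mechanism = "inversion_v30")
    } else {
      if (tra_trec_compatible(a, b, map))
        pair_mech[[length(pair_mech) + 1]] <-
          list(i = i, j = j, mechanism = "trec_circle_alpha")
    }
  }
  compatible_pair <- function(i, j)
    any(vapply(pair_mech, function(p)
      (p$i == i && p$j == j) || (p$i == j && p$j == i), logical(1)))
  feasible <- character(0)
  used_pairs <- NULL
  if (n <= 2) {
    feasible <- "two_chromosomes"
    used_pairs <- pair_mech
  } else if (n == 3) {
    used_pairs <- Filter(function(p) TRUE, pair_mech)
    if (!length(pair_mech)) feasible <- "unexplained"
  } else if (n == 4) {
    pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                     list(c(1, 4), c(2, 3)))
    used <- logical(length(pair_mech))
    any_cover <- FALSE
    for (pg in pairings) {
      if (compatible_pair(pg[[1]][1], pg[[1]][2]) &&
          compatible_pair(pg[[2]][1], pg[[2]][2])) {
        any_cover <- TRUE
        for (k in seq_along(pair_mech)) {
          p <- pair_mech[[k]]
          for (pr in pg)
            if (setequal(c(p$i, p$j), pr)) used[k] <- TRUE
        }
      }
    }
    used_pairs <- pair_mech[used]
    if (!any_cover) feasible <- "unexplained"
  } else {
    feasible <- "unexplained"
    used_pairs <- list()
  }
  mechs <- unique(vapply(used_pairs, `[[`, character(1), "mechanism"))
  feasible <- sort(unique(c(feasible, mechs)))
  roles <- if (length(used_pairs)) do.call(rbind, lapply(used_pairs, function(p) {
    # TREC mechanisms: the first (circle-resident) event is p$i; inversional
    # joining retains both joins on the chromosome, so no circle role exists
    if (p$mechanism == "inversion_v30")
      data.frame(locus = locus, mechanism = p$mechanism,
                 circle_event = NA_character_,
                 chromosome_event = paste(event_label(events[[p$i]]),
                                          event_label(events[[p$j]]),
                                          sep = " + "),
                 stringsAsFactors = FALSE)
    else
      data.frame(locus = locus, mechanism = p$mechanism,
                 circle_event = event_label(events[[p$i]]),
                 chromosome_event = event_label(events[[p$j]]),
                 stringsAsFactors = FALSE)
  }))
  else NULL
  list(n_events = n, feasible = feasible, roles = roles,
       events = vapply(events, event_label, character(1)))
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s: feasible = {%s}\n", x$barcode,
              paste(x$feasible, collapse = ", ")))
  if (!is.null(x$roles))
    for (i in seq_len(nrow(x$roles)))
      cat(sprintf("  %s %s: circle = %s, chromosome = %s\n",
                  x$roles$locus[i], x$roles$mechanism[i],
                  x$roles$circle_event[i], x$roles$chromosome_event[i]))
  invisible(x)
}

#' Trace all multi-rearrangement cells in a sample
#'
#' @param profiles list of `cell_profile`s.
#' @param species `"human"` or `"mouse"`.
#' @return data frame with one row per (cell, feasible mechanism-role),
#'   or `NULL` when no cell qualifies.
#' @export
trace_sample <- function(profiles, species = "human") {
  maps <- list(TRA = load_locus(species, "TRA"),
               TRB = load_locus(species, "TRB"))
  rows <- list()
  for (p in profiles) {
    ch <- p$chains[nzchar(p$chains$v_call) & nzchar(p$chains$j_call), ]
    if (max(table(factor(ch$locus, c("TRA", "TRB")))) < 2) next
    mc <- classify_cell_mechanism(p, maps)
    base <- data.frame(barcode = p$barcode,
                       feasible = paste(mc$feasible, collapse = ","),
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- if (!is.null(mc$roles))
      cbind(base[rep(1, nrow(mc$roles)), , drop = FALSE], mc$roles)
    else cbind(base, data.frame(locus = NA, mechanism = NA,
                                circle_event = NA, chromosome_event = NA))
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
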