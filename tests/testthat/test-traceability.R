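trb <- load_locus("human", "TRB")
tra <- load_locus("human", "TRA")

ev_b <- function(v, d, j, cc) rearrangement_event("TRB", v, j, d, cc, "F", trb)
ev_a <- function(v, j) rearrangement_event("TRA", v, j, "", "TRAC", "F", tra)

test_that("event construction enforces cluster consistency and imputes D", {
  expect_error(ev_b("TRBV19", "TRBD1", "TRBJ2-3", "TRBC2"), "inconsistent")
  expect_error(ev_b("TRBV19", "TRBD2", "TRBJ1-3", "TRBC1"), "inconsistent")
  e <- rearrangement_event("TRB", "TRBV19", "TRBJ2-3", "", "TRBC2",
                           "F", trb)
  expect_equal(e$d_call, "TRBD2")
  expect_equal(e$cluster, "DJC2")
  expect_error(rearrangement_event("TRB", "TRBV999", "TRBJ1-1", "TRBD1",
                                   "", "F", trb), "unknown gene")
})

test_that("TRB TREC compatibility requires DJC1-then-DJC2 with an upstream second V", {
  a <- ev_b("TRBV19", "TRBD1", "TRBJ1-5", "TRBC1")
  b <- ev_b("TRBV5-1", "TRBD2", "TRBJ2-3", "TRBC2")
  expect_true(trb_trec_compatible(a, b, trb))
  # role asymmetry: both orders are never simultaneously compatible
  expect_false(trb_trec_compatible(b, a, trb))
  # both events in the DJC1 cluster: the D1 segment cannot be used twice
  a2 <- ev_b("TRBV5-1", "TRBD1", "TRBJ1-2", "TRBC1")
  expect_false(trb_trec_compatible(a, a2, trb))
  # second V downstream of the first: its excision cannot carry the join
  a3 <- ev_b("TRBV5-1", "TRBD1", "TRBJ1-2", "TRBC1")
  b3 <- ev_b("TRBV19", "TRBD2", "TRBJ2-1", "TRBC2")
  expect_false(trb_trec_compatible(a3, b3, trb))
  # oracle agreement on all three cases
  expect_equal(oracle_same_chromosome_any(a, b, trb), TRUE)
  expect_equal(oracle_same_chromosome_any(a, a2, trb), FALSE)
  expect_equal(oracle_same_chromosome_any(a3, b3, trb), FALSE)
})

test_that("TRA TREC compatibility requires a nested V-J excision interval", {
  a <- ev_a("TRAV26-1", "TRAJ39")
  b <- ev_a("TRAV8-4", "TRAJ20")
  expect_true(upstream_of("TRAV8-4", "TRAV26-1", tra))
  expect_true(upstream_of("TRAJ39", "TRAJ20", tra))
  expect_true(tra_trec_compatible(a, b, tra))
  expect_false(tra_trec_compatible(b, a, tra))
  # shared J segment cannot serve two joins on one chromosome
  expect_false(tra_trec_compatible(a, ev_a("TRAV8-4", "TRAJ39"), tra))
  # second J upstream of the first: the first join is not inside the excision
  expect_false(tra_trec_compatible(a, ev_a("TRAV8-4", "TRAJ45"), tra))
  expect_true(oracle_same_chromosome_any(a, b, tra))
  expect_false(oracle_same_chromosome_any(a, ev_a("TRAV8-4", "TRAJ45"), tra))
})

test_that("inversional compatibility needs the reverse V on DJC2 plus a DJC1 partner", {
  r <- ev_b("TRBV30", "TRBD2", "TRBJ2-5", "TRBC2")
  f <- ev_b("TRBV12-3", "TRBD1", "TRBJ1-1", "TRBC1")
  expect_true(trb_inversion_compatible(r, f, trb))
  expect_true(trb_inversion_compatible(f, r, trb))  # symmetric
  # neither V reverse
  f2 <- ev_b("TRBV19", "TRBD2", "TRBJ2-2", "TRBC2")
  expect_false(trb_inversion_compatible(f, f2, trb))
  # reverse V on DJC1 flips the DJC2 cluster out of joining orientation
  r1 <- ev_b("TRBV30", "TRBD1", "TRBJ1-4", "TRBC1")
  expect_false(trb_inversion_compatible(r1, f2, trb))
  expect_false(oracle_same_chromosome_any(r1, f2, trb))
  # both events claiming the single reverse V
  r2 <- ev_b("TRBV30", "TRBD1", "TRBJ1-2", "TRBC1")
  expect_false(trb_inversion_compatible(r, r2, trb))
  expect_false(oracle_same_chromosome_any(r, r2, trb))
  expect_true(oracle_same_chromosome_any(r, f, trb))
})

test_that("the excision oracle validates schemes and detects segment reuse", {
  a <- ev_b("TRBV19", "TRBD1", "TRBJ1-5", "TRBC1")
  b <- ev_b("TRBV5-1", "TRBD2", "TRBJ2-3", "TRBC2")
  # b after a on one chromosome: a's join survives on the excised circle
  expect_true(brute_force_excision_oracle(
    list(a, b), trb, list(chromosome = c(1, 1), order = c(1, 2))))
  # two D1-cluster joins on one chromosome reuse the D1 segment
  a2 <- ev_b("TRBV5-1", "TRBD1", "TRBJ1-2", "TRBC1")
  expect_false(brute_force_excision_oracle(
    list(a, a2), trb, list(chromosome = c(1, 1), order = c(1, 2))))
  # on two chromosomes the same pair is fine
  expect_true(brute_force_excision_oracle(
    list(a, a2), trb, list(chromosome = c(1, 2), order = c(1, 2))))
  expect_error(brute_force_excision_oracle(
    list(a, b), trb, list(chromosome = 1, order = c(1, 2))))
})

test_that("rules match the excision oracle exhaustively on the toy locus", {
  toy_b <- load_locus("toy", "TRB")
  toy_a <- load_locus("toy", "TRA")
  for (map in list(toy_b, toy_a)) {
    evs <- all_events(map)
    n_checked <- 0L
    for (i in seq_along(evs)) for (j in seq_along(evs)) {
      if (i >= j) next
      a <- evs[[i]]; b <- evs[[j]]
      if (a$v_call == b$v_call && a$j_call == b$j_call) next
      expect_equal(rule_same_chromosome(a, b, map),
                   oracle_same_chromosome_any(a, b, map),
                   info = paste(map$locus, tcrtrace:::event_label(a),
                                tcrtrace:::event_label(b)))
      n_checked <- n_checked + 1L
    }
    expect_gt(n_checked, 30)
  }
})

test_that("classify_cell_mechanism reports feasible mechanisms with roles", {
  chains <- data.frame(
    locus = "TRB",
    v_call = c("TRBV19", "TRBV5-1", "TRBV28"),
    d_call = c("TRBD1", "TRBD2", "TRBD1"),
    j_call = c("TRBJ1-5", "TRBJ2-3", "TRBJ1-1"),
    c_call = c("TRBC1", "TRBC2", "TRBC1"),
    junction_aa = c("CASSAF", "CASSBF", "CASSCF"),
    status = c("F", "F", "N"), stringsAsFactors = FALSE)
  mc <- classify_cell_mechanism(new_cell_profile("BC", chains), "human")
  expect_true("trec_circle_beta" %in% mc$feasible)
  expect_false("two_chromosomes" %in% mc$feasible)  # 3 same-locus events
  role <- mc$roles[mc$roles$mechanism == "trec_circle_beta", ]
  expect_true(all(grepl("TRBD1", role$circle_event)))
  expect_true(all(grepl("TRBD2", role$chromosome_event)))

  # a biallelic pair with no same-chromosome mechanism
  chains2 <- chains[c(1, 3), ]
  mc2 <- classify_cell_mechanism(new_cell_profile("BC2", chains2), "human")
  expect_equal(mc2$feasible, "two_chromosomes")

  # three same-locus events with no compatible pair are unexplained
  chains3 <- data.frame(
    locus = "TRB", v_call = c("TRBV2", "TRBV9", "TRBV19"),
    d_call = "TRBD1", j_call = c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3"),
    c_call = "TRBC1", junction_aa = c("CA1F", "CA2F", "CA3F"),
    status = "F", stringsAsFactors = FALSE)
  mc3 <- classify_cell_mechanism(new_cell_profile("BC3", chains3), "human")
  expect_equal(mc3$feasible, "unexplained")
  expect_error(classify_cell_mechanism(make_profile(n_trb_f = 1,
                                                    n_tra_f = 1), "human"))
})

test_that("non-functional chains participate in traceability like functional ones", {
  chains <- data.frame(
    locus = "TRB",
    v_call = c("TRBV19", "TRBV5-1"),
    d_call = c("TRBD1", "TRBD2"),
    j_call = c("TRBJ1-5", "TRBJ2-3"),
    c_call = c("TRBC1", "TRBC2"),
    junction_aa = c("CASSAF", "CASSBF"),
    status = c("N", "N"), stringsAsFactors = FALSE)
  mc <- classify_cell_mechanism(new_cell_profile("BC", chains), "human")
  expect_true("trec_circle_beta" %in% mc$feasible)
  expect_true("two_chromosomes" %in% mc$feasible)
})

test_that("mouse traceability uses TRBV31 as the reverse V", {
  mtrb <- load_locus("mouse", "TRB")
  r <- rearrangement_event("TRB", "TRBV31", "TRBJ2-4", "TRBD2", "TRBC2",
                           "F", mtrb)
  f <- rearrangement_event("TRB", "TRBV13-1", "TRBJ1-3", "TRBD1", "TRBC1",
                           "F", mtrb)
  expect_true(trb_inversion_compatible(r, f, mtrb))
  expect_true(oracle_same_chromosome_any(r, f, mtrb))
})
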