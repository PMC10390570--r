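test_that("generated contig tables round-trip through both dialects", {
  cfg <- synth_config(200, seed = 7)
  g <- generate_sample(cfg)
  rec <- read_contig_table(g$path, "tenx_csv")
  expect_equal(nrow(rec), nrow(g$records))
  for (col in c("barcode", "locus", "v_call", "d_call", "j_call", "c_call",
                "junction_aa", "productive_raw", "umis"))
    expect_equal(rec[[col]], g$records[[col]], info = col)

  airr_path <- tempfile(fileext = ".tsv")
  write_contig_table(g$records, airr_path, "airr_tsv")
  rec2 <- read_contig_table(airr_path, "airr_tsv")
  expect_equal(rec2$locus, rec$locus)
  expect_equal(rec2$v_call, rec$v_call)
  expect_equal(rec2$junction_aa, rec$junction_aa)
})

test_that("AIRR field mapping lands on the unified schema", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c(
    "cell_id\tlocus\tv_call\td_call\tj_call\tc_call\tjunction_aa\tproductive",
    "BC-1\tTRB\tTRBV19\tTRBD1\tTRBJ1-5\tTRBC1\tCASSIRSSYEQYF\tT"), p)
  rec <- read_contig_table(p, "airr_tsv")
  expect_equal(rec$locus, "TRB")
  expect_equal(rec$v_call, "TRBV19")
  expect_equal(rec$barcode, "BC-1")
  # flags absent from the dialect are absent, not failures
  expect_true(is.na(rec$is_cell))
})

test_that("missing mandatory columns raise a format error naming them", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("barcode,is_cell,chain", "BC1,True,TRB"), p)
  expect_error(read_contig_table(p, "tenx_csv"), "high_confidence")
  expect_error(read_contig_table(tempfile(), "tenx_csv"), "cannot read")
})

test_that("QC drops by the first failing criterion and partitions input", {
  rec <- rbind(
    make_record(is_cell = "FALSE", contig_id = "c1"),
    # fails is_cell AND chain: must be attributed to not_cell (precedence)
    make_record(is_cell = "FALSE", locus = "IGH", contig_id = "c2"),
    make_record(high_confidence = "FALSE", contig_id = "c3"),
    make_record(locus = "IGH", contig_id = "c4"),
    make_record(locus = "TRG", contig_id = "c5"),
    make_record(locus = "Multi", contig_id = "c6"),
    make_record(productive_raw = "None", contig_id = "c7"),
    make_record(contig_id = "c8"),
    make_record(locus = "TRA", v_call = "TRAV1-1", d_call = "",
                j_call = "TRAJ33", c_call = "TRAC",
                productive_raw = "False", contig_id = "c9"),
    make_record(is_cell = "true", productive_raw = "true", contig_id = "c10"))
  res <- apply_qc_filters(rec)
  expect_equal(res$report$n_input, 10L)
  expect_equal(res$report$n_kept, 3L)
  expect_equal(res$report$n_dropped_by_reason,
               c(not_cell = 2L, low_confidence = 1L, wrong_chain = 3L,
                 productive_none = 1L))
  # partition: every record is kept or counted under exactly one reason
  expect_equal(res$report$n_kept + sum(res$report$n_dropped_by_reason),
               res$report$n_input)
  expect_setdiff <- setdiff(res$kept$contig_id, c("c8", "c9", "c10"))
  expect_length(expect_setdiff, 0)
})

test_that("QC is idempotent on its kept set", {
  g <- generate_sample(synth_config(
    100, seed = 3,
    qc_noise = c(not_cell = 0.05, low_confidence = 0.05, wrong_chain = 0.05,
                 productive_none = 0.05)))
  rec <- read_contig_table(g$path, "tenx_csv")
  r1 <- apply_qc_filters(rec)
  expect_true(all(r1$report$n_dropped_by_reason > 0))
  r2 <- apply_qc_filters(r1$kept)
  expect_equal(r2$kept, r1$kept)
  expect_true(all(r2$report$n_dropped_by_reason == 0))
})

test_that("unrecognized flag literals fail their criterion", {
  rec <- rbind(make_record(is_cell = "maybe", contig_id = "x1"),
               make_record(productive_raw = "", contig_id = "x2"))
  res <- apply_qc_filters(rec)
  expect_equal(unname(res$report$n_dropped_by_reason["not_cell"]), 1L)
  expect_equal(unname(res$report$n_dropped_by_reason["productive_none"]), 1L)
})

test_that("the same logical sample yields identical kept sets in both dialects", {
  g <- generate_sample(synth_config(
    150, seed = 11,
    qc_noise = c(not_cell = 0.03, low_confidence = 0.02, wrong_chain = 0.03,
                 productive_none = 0.04)))
  p10 <- tempfile(fileext = ".csv"); pa <- tempfile(fileext = ".tsv")
  write_contig_table(g$records, p10, "tenx_csv")
  write_contig_table(g$records, pa, "airr_tsv")
  k1 <- apply_qc_filters(read_contig_table(p10, "tenx_csv"))$kept
  k2 <- apply_qc_filters(read_contig_table(pa, "airr_tsv"))$kept
  cols <- c("barcode", "locus", "v_call", "d_call", "j_call", "c_call",
            "junction_aa")
  expect_equal(k1[, cols], k2[, cols], ignore_attr = TRUE)
})

test_that("QC report JSON serializes the tallies", {
  g <- generate_sample(synth_config(50, seed = 2,
                                    qc_noise = c(not_cell = 0.1,
                                                 low_confidence = 0,
                                                 wrong_chain = 0,
                                                 productive_none = 0.1)))
  res <- apply_qc_filters(read_contig_table(g$path, "tenx_csv"))
  f <- tempfile(fileext = ".json")
  write_qc_report(res$report, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$n_input, res$report$n_input)
  expect_equal(j$n_dropped_by_reason$not_cell, 5)
})
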