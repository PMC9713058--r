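test_that("carrier frequencies print with half-up rounding to one decimal", {
  expect_equal(carrier_frequency(12, 128), 9.4)
  expect_equal(carrier_frequency(5, 128), 3.9)
  expect_equal(carrier_frequency(3, 128), 2.3)
  expect_equal(carrier_frequency(27, 128), 21.1)
  expect_equal(carrier_frequency(0, 128), 0.0)
  expect_equal(carrier_frequency(1, 16), 6.3)   # 6.25 rounds half-up
  expect_error(carrier_frequency(1, 0), "positive")
})

test_that("carrier frequency is monotone and scale-consistent", {
  for (k in 0:20)
    expect_lte(carrier_frequency(k, 50), carrier_frequency(k + 1, 50))
  for (k in c(3, 7, 12))
    expect_equal(carrier_frequency(k, 128), carrier_frequency(10 * k, 1280))
})

test_that("inheritance strata count unique patients per stratum", {
  fx <- fixture_table1()
  cls <- classify_variant_table(fx$variants, fx$criteria,
                                prefer_printed = TRUE)
  inh <- summarize_by_inheritance(fx$variants, cls, fx$panel, 128)
  expect_equal(inh$carriers_AD$count, 12)       # patient 113 counted once
  expect_equal(inh$carriers_AD$percent, 9.4)

  b <- ar_augmented_bundle()
  cls2 <- classify_variant_table(b$variants, b$criteria,
                                 prefer_printed = TRUE)
  inh2 <- summarize_by_inheritance(b$variants, cls2, b$panel, 128)
  expect_equal(inh2$carriers_AD$count, 12)
  expect_equal(inh2$carriers_AD_plus_ARhet$count, 27)
  expect_equal(inh2$carriers_AD_plus_ARhet$percent, 21.1)

  empty <- fx$variants[0, ]; class(empty) <- class(fx$variants)
  inh0 <- summarize_by_inheritance(empty, cls[0, ], fx$panel, 128)
  expect_equal(inh0$carriers_AD$count, 0)
})

test_that("genes off the panel are reported by name", {
  x <- make_calls("A", gene = "NOTAPANELGENE")
  cls <- classify_variant_table(
    x, data.frame(variant_id = unique(x$variant_id), codes = "PVS1,PM2"))
  expect_error(summarize_by_inheritance(x, cls, default_panel(), 10),
               "NOTAPANELGENE")
})

test_that("duplicate carrier rows never change patient counts", {
  b <- ar_augmented_bundle()
  cls <- classify_variant_table(b$variants, b$criteria,
                                prefer_printed = TRUE)
  dup <- variant_calls(rbind(as.data.frame(b$variants),
                             as.data.frame(b$variants)[3, ]))
  inh1 <- summarize_by_inheritance(b$variants, cls, b$panel, 128)
  inh2 <- summarize_by_inheritance(dup, cls, b$panel, 128)
  expect_identical(inh1$carriers_AD_plus_ARhet$count,
                   inh2$carriers_AD_plus_ARhet$count)
  expect_identical(recurrent_gene_screen(b$variants, cls),
                   recurrent_gene_screen(dup, cls))
})

test_that("the recurrence screen ranks genes by unique carriers", {
  fx <- fixture_table1()
  cls <- classify_variant_table(fx$variants, fx$criteria,
                                prefer_printed = TRUE)
  rec <- recurrent_gene_screen(fx$variants, cls)
  expect_equal(rec$gene, c("CHEK2", "POT1", "BRCA2"))
  expect_equal(rec$n_patients, c(5L, 3L, 2L))
  all_genes <- recurrent_gene_screen(fx$variants, cls, min_patients = 1)
  expect_setequal(all_genes$gene,
                  c("ATM", "ATR", "BRCA2", "CHEK2", "POT1", "PALB2"))
  # invariant to record order
  shuf <- fx$variants[rev(seq_len(nrow(fx$variants))), ]
  class(shuf) <- class(fx$variants)
  expect_identical(recurrent_gene_screen(shuf, cls), rec)
  empty <- fx$variants[0, ]; class(empty) <- class(fx$variants)
  expect_equal(nrow(recurrent_gene_screen(empty, cls)), 0)
})

test_that("median onset uses the standard median and reports the range", {
  m <- median_onset(c(50, 66, 55, 77))
  expect_equal(m$median, 60.5)
  expect_equal(m$range, c(50, 77))
  expect_equal(median_onset(42)$median, 42)
  expect_equal(median_onset(c(1, 2, 3))$median, 2)
  expect_error(median_onset(numeric(0)), "no onset ages")
  expect_warning(m2 <- median_onset(c(60, NA)), "missing")
  expect_equal(m2$n, 1)
})

test_that("co-segregation partitions affected members by tested genotype", {
  fx <- fixture_table1()
  fam2 <- fx$pedigrees[["2"]]
  cs2 <- cosegregation_summary(fam2, "7:124503000:G:A")
  expect_true("2_II.2" %in% cs2$carrier_ids)
  expect_gte(cs2$affected_carriers, 1)

  fam3 <- fx$pedigrees[["3"]]
  pot1 <- cosegregation_summary(fam3, "7:124510000:T:A")
  expect_true("3_I.1" %in% pot1$noncarrier_ids)
  chek2 <- cosegregation_summary(fam3, "22:28695000:AC:A")
  expect_true("3_I.1" %in% chek2$carrier_ids)

  expect_warning(untested <- cosegregation_summary(fam2, "9:9:A:T"),
                 "untested")
  expect_equal(untested$untested_affected, sum(fam2$members$affected))
  expect_equal(untested$affected_carriers, 0)
})

cohort_report_json_for_test <- function(r)
  jsonlite::toJSON(germscreen:::cohort_report_json(r), auto_unbox = TRUE,
                   digits = NA)

test_that("the orchestrator reproduces the worked-example report", {
  fx <- fixture_table1()
  rep <- suppressWarnings(run_screen(fx))
  expect_equal(rep$carriers_AD$count, 12)
  expect_equal(rep$carriers_AD$percent, 9.4)
  expect_equal(rep$recurrent$gene, c("CHEK2", "POT1", "BRCA2"))
  expect_equal(rep$onset$POT1$median, 55)  # the three cohort carriers
  coseg <- rep$cosegregation[["3"]][["7:124510000:T:A"]]
  expect_equal(coseg$affected_noncarriers, 1)
  # determinism: identical inputs give identical reports
  rep2 <- suppressWarnings(run_screen(fx))
  expect_identical(cohort_report_json_for_test(rep),
                   cohort_report_json_for_test(rep2))
})

test_that("run_screen writes its stage outputs and fails with stage names", {
  fx <- fixture_table1()
  out <- tempfile()
  suppressWarnings(run_screen(fx, out_dir = out))
  expect_true(all(file.exists(file.path(out,
    c("filter_report.tsv", "classified.tsv", "association.tsv",
      "cohort_report.json")))))
  broken <- fx
  broken$criteria <- fx$criteria[-1, ]
  expect_error(suppressWarnings(run_screen(broken)), "classification")
  expect_error(run_screen(fx[-1]), "bundle lacks")
})
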