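empty_ref <- function() make_ref(list("global", 1000, "v_none", 1, 2000, 0))

test_that("quality filter removes failing carriers and drops emptied records", {
  x <- make_calls(c("A", "B", "C"), gene = "ATM",
                  pos = c(100L, 100L, 200L), dp = c(5, 50, 5),
                  gq = 99, ab = 0.5)
  out <- apply_quality_filter(x)
  expect_equal(sort(out$patient_id), "B")       # A and C fail depth
  expect_equal(n_variants(out), 1)              # C's record emptied
  ok <- make_calls(c("A", "B"), gene = "ATM", dp = 50, gq = 99, ab = 0.5)
  expect_identical(apply_quality_filter(ok), ok)
  expect_warning(apply_quality_filter(make_calls("A", "ATM")),
                 "no genotype metrics")
})

test_that("allele-balance bounds apply to heterozygotes only", {
  x <- make_calls(c("A", "B"), gene = "ATM", pos = 100L,
                  zygosity = c("het", "hom"), dp = 50, gq = 99,
                  ab = c(0.1, 1))
  out <- apply_quality_filter(x)
  expect_equal(out$patient_id, "B")
})

test_that("panel filter keeps panel genes and annotates inheritance", {
  x <- make_calls(c("A", "B"), gene = c("CHEK2", "TTN"), pos = c(100L, 200L))
  out <- apply_panel_filter(x, default_panel())
  expect_equal(out$gene, "CHEK2")
  expect_equal(out$inheritance, "AD")
  expect_equal(nrow(apply_panel_filter(x[0, ], default_panel())), 0)
  expect_error(apply_panel_filter(x, gene_panel(
    data.frame(gene = character(0), inheritance = character(0),
               category = character(0)))), "empty")
})

test_that("rarity filter compares allele frequency per subset", {
  fx <- fixture_table1()
  # published ultra-rare frequency 6/188088 = 3.19e-5 survives at 1e-3
  x <- fx$variants[fx$variants$variant_id == "7:124481000:G:C", ]
  class(x) <- class(fx$variants)
  expect_equal(n_variants(apply_rarity_filter(x, fx$ref_counts)), 1)
  # a common variant is removed
  common <- make_calls("A", gene = "G1", chrom = "9", pos = 5L)
  ref <- make_ref(list("global", 1000, "9:5:A:T", 20, 2000, 0))
  expect_equal(nrow(apply_rarity_filter(common, ref)), 0)
  # threshold 0: only reference-unobserved variants survive
  both <- make_calls(c("A", "B"), gene = "G1", chrom = "9",
                     pos = c(5L, 6L))
  cfg0 <- filter_config(max_global_maf = 0, max_subpop_maf = 0)
  out <- apply_rarity_filter(both, ref, cfg0)
  expect_equal(out$variant_id, "9:6:A:T")
})

test_that("impact filter retains protein-impacting classes", {
  x <- make_calls(c("A", "B", "C"), gene = "G",
                  pos = c(1L, 2L, 3L),
                  coding_impact = c("synonymous", "frameshift", "start_lost"))
  out <- apply_impact_filter(x)
  expect_setequal(out$coding_impact, c("frameshift", "start_lost"))
})

test_that("cascade telescopes and recovers planted variants over background", {
  b <- simulate_cohort(simulation_config(seed = 5, n_background = 100))
  res <- run_cascade(b$variants, b$panel, b$ref_counts)
  expect_setequal(unique(res$records$variant_id),
                  b$manifest$expected_survivors)
  rep <- res$report
  expect_equal(rep$n_out[-4], rep$n_in[-1])               # telescoping
  expect_equal(rep$n_in - rep$n_out, rep$n_removed)
  removed <- attr(rep, "removed")
  expect_equal(anyDuplicated(unlist(removed)), 0)          # disjoint
})

test_that("panel, rarity and impact commute as pure predicates", {
  b <- simulate_cohort(simulation_config(seed = 8, n_background = 60))
  cfg <- filter_config()
  steps <- list(
    p = function(d) apply_panel_filter(d, b$panel),
    r = function(d) apply_rarity_filter(d, b$ref_counts, cfg),
    i = function(d) apply_impact_filter(d, cfg))
  perms <- list(c("p","r","i"), c("r","i","p"), c("i","p","r"),
                c("i","r","p"))
  sets <- lapply(perms, function(ord) {
    cur <- b$variants
    for (s in ord) cur <- steps[[s]](cur)
    sort(unique(cur$variant_id))
  })
  for (k in 2:length(sets)) expect_equal(sets[[k]], sets[[1]])
})

test_that("raising the global MAF threshold never shrinks the surviving set", {
  b <- simulate_cohort(simulation_config(seed = 13, n_background = 80))
  prev <- character(0)
  for (thr in c(1e-4, 1e-3, 1e-2, 0.5)) {
    cfg <- filter_config(max_global_maf = thr, max_subpop_maf = 1)
    out <- apply_rarity_filter(b$variants, b$ref_counts, cfg)
    cur <- sort(unique(out$variant_id))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("empty cohorts and fully permissive configs pass through", {
  fx <- fixture_table1()
  empty <- fx$variants[0, ]
  class(empty) <- class(fx$variants)
  res <- run_cascade(empty, fx$panel, fx$ref_counts)
  expect_equal(nrow(res$records), 0)
  expect_equal(res$report$n_in, rep(0L, 4))
  expect_equal(res$report$n_out, rep(0L, 4))

  open_cfg <- filter_config(max_global_maf = 1, max_subpop_maf = 1,
                            allowed_impacts = coding_impacts(),
                            min_depth = 0, min_gq = 0,
                            het_ab_range = c(0, 1))
  all_panel <- gene_panel(data.frame(
    gene = unique(fx$variants$gene), inheritance = "AD",
    category = "MM_germline"))
  res2 <- suppressWarnings(
    run_cascade(fx$variants, all_panel, fx$ref_counts, open_cfg))
  expect_setequal(res2$records$variant_id, fx$variants$variant_id)
})
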