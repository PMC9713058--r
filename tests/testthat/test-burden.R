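test_that("contingency tables follow the carrier-counting definition", {
  ref <- make_ref(list("global", 118477, "v1", 6, 236954, 0))
  tab <- build_contingency(5, 128, ref, "global", "v1")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(5, 123, 6, 118471))
  expect_false(tab$unobserved)

  miss <- build_contingency(5, 128, ref, "global", "v_unseen")
  expect_equal(miss$c, 0)
  expect_true(miss$unobserved)

  # homozygotes carry two alleles but are one carrier
  ref2 <- make_ref(list("global", 1000, "v1", 10, 2000, 2))
  expect_equal(build_contingency(1, 50, ref2, "global", "v1")$c, 8)
})

test_that("multi-variant scope carriers sum over member variants", {
  ref <- make_ref(list("global", 1000, "v1", 3, 2000, 0),
                  list("global", 1000, "v2", 4, 2000, 0),
                  list("global", 1000, "v3", 9, 2000, 1))
  per_variant <- sum(vapply(c("v1", "v2"), function(v)
    build_contingency(0, 10, ref, "global", v)$c, integer(1)))
  expect_equal(build_contingency(0, 10, ref, "global", c("v1", "v2"))$c,
               per_variant)
  expect_equal(build_contingency(0, 10, ref, "global",
                                 c("v1", "v2", "v3"))$c, 3 + 4 + 8)
})

test_that("Woolf odds ratio and interval match the hand-derived values", {
  # cross-product: 10*95/(90*5) = 2.1111; log-SE sqrt(1/10+1/90+1/5+1/95)
  est <- odds_ratio_woolf(list(a = 10, b = 90, c = 5, d = 95))
  expect_equal(est$or, 950 / 450, tolerance = 1e-12)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(est$ci_low, exp(log(950 / 450) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(est$ci_high, exp(log(950 / 450) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(round(est$or, 3), 2.111)
  expect_equal(round(est$ci_low, 3), 0.695)
  expect_equal(round(est$ci_high, 3), 6.416)
})

test_that("balanced tables give OR 1 and zero cells give NA unless corrected", {
  expect_equal(odds_ratio_woolf(list(a = 6, b = 9, c = 2, d = 3))$or, 1)
  nas <- odds_ratio_woolf(list(a = 5, b = 123, c = 0, d = 10816))
  expect_true(is.na(nas$or) && is.na(nas$ci_low))
  corr <- odds_ratio_woolf(list(a = 5, b = 123, c = 0, d = 10816),
                           correction = TRUE)
  expect_equal(corr$or, (5.5 * 10816.5) / (123.5 * 0.5), tolerance = 1e-12)
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_p(list(a = 5, b = 0, c = 0, d = 5)), 2 / 252,
               tolerance = 1e-10)
  expect_equal(fisher_exact_p(list(a = 1, b = 1, c = 1, d = 1)), 1)
  expect_equal(fisher_exact_p(list(a = 0, b = 7, c = 0, d = 9)), 1)
  set.seed(4)
  for (i in 1:50) {
    cells <- as.list(rmultinom(1, sample(5:40, 1), rep(0.25, 4))[, 1])
    names(cells) <- c("a", "b", "c", "d")
    expect_equal(fisher_exact_p(cells),
                 fisher_enum_p(cells$a, cells$b, cells$c, cells$d),
                 tolerance = 1e-9,
                 info = paste(unlist(cells), collapse = ","))
  }
})

test_that("transposing rows inverts the OR and leaves p unchanged", {
  set.seed(9)
  for (i in 1:20) {
    t1 <- list(a = sample(1:30, 1), b = sample(1:30, 1),
               c = sample(1:30, 1), d = sample(1:30, 1))
    t2 <- list(a = t1$c, b = t1$d, c = t1$a, d = t1$b)
    expect_equal(odds_ratio_woolf(t1)$or, 1 / odds_ratio_woolf(t2)$or,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_p(t1), fisher_exact_p(t2), tolerance = 1e-12)
  }
})

test_that("associate counts a patient once per scope unit", {
  # two P/LP variants in one gene sharing a carrier
  x <- make_calls(c("A", "B", "A"), gene = "POT1", pos = c(1L, 1L, 2L))
  crit <- data.frame(variant_id = unique(x$variant_id),
                     codes = c("PVS1,PM2", "PVS1,PM2"))
  cls <- classify_variant_table(x, crit)
  ref <- make_ref(list("global", 1000, "1:1:A:T", 2, 2000, 0),
                  list("global", 1000, "1:2:A:T", 3, 2000, 0))
  res <- associate(x, cls, ref, cohort_n = 100)
  gene_row <- res[res$scope == "gene", ]
  expect_equal(gene_row$a, 2)        # A counted once at gene scope
  expect_equal(gene_row$c, 5)
  panel_row <- res[res$scope == "panel", ]
  expect_equal(panel_row$a, 2)
  expect_equal(nrow(res[res$scope == "variant", ]), 2)
})

test_that("matched cohort and reference rates give OR near 1", {
  ref <- make_ref(list("global", 1000, "1:1:A:T", 100, 2000, 0))
  x <- make_calls(sprintf("P%02d", 1:10), gene = "POT1", pos = 1L)
  cls <- classify_variant_table(
    x, data.frame(variant_id = "1:1:A:T", codes = "PVS1,PM2"))
  res <- associate(x, cls, ref, cohort_n = 100, scopes = "variant")
  expect_equal(res$or, 1, tolerance = 0.15)
  expect_gt(res$p, 0.5)
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  base <- data.frame(scope = "variant", unit = letters[1:4],
                     subset = "global", a = 1, b = 1, c = 1, d = 1,
                     or = 1, ci_low = 1, ci_high = 1,
                     p = c(0.01, 0.02, 0.03, 0.04), method = "woolf",
                     unobserved = FALSE)
  class(base) <- c("burden_assoc", "data.frame")
  expect_equal(bh_adjust(base)$q, rep(0.04, 4))
  one <- base[1, ]; class(one) <- class(base)
  expect_equal(bh_adjust(one)$q, 0.01)
  base$p <- rep(1, 4)
  expect_equal(bh_adjust(base)$q, rep(1, 4))
})
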