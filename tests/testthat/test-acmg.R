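test_that("published evidence sets classify to their expected tiers", {
  cases <- list(
    list(c("PVS1", "PM2", "PP3"), "pathogenic"),
    list(c("PM1", "PM2", "PP5", "PP2", "PP3"), "likely_pathogenic"),
    list(c("PVS1", "PM2", "PP5"), "pathogenic"),
    list(c("PVS1", "PP5", "PM2"), "pathogenic"),
    list("PM2", "VUS"),
    list("BA1", "benign"),
    list(c("BS1", "BP4"), "likely_benign"),
    list(c("BP4", "BP7"), "likely_benign"),
    list(c("PS1", "PS2"), "pathogenic"))
  for (cs in cases)
    expect_equal(classify_criteria(cs[[1]])$tier, cs[[2]],
                 info = paste(cs[[1]], collapse = "+"))
})

test_that("contradictory evidence resolves to VUS with the conflict flag", {
  cls <- classify_criteria(c("PVS1", "PM2", "BA1"))
  expect_equal(cls$tier, "VUS")
  expect_true(cls$conflict_flag)
  expect_false(classify_criteria(c("PVS1", "PM2"))$conflict_flag)
})

test_that("the rule trace is deterministic and matches the classification", {
  tr <- acmg_explain(c("PVS1", "PM2"))
  first <- tr$clause[tr$satisfied][1]
  expect_equal(first, classify_criteria(c("PVS1", "PM2"))$matched_rule)
  expect_equal(first, "PVS1 + 1 PM")  # the very-strong + one-moderate clause

  none <- acmg_explain(character(0))
  expect_false(any(none$satisfied))
  expect_equal(classify_criteria(character(0))$tier, "VUS")

  lp <- classify_criteria(c("PM1", "PM2", "PP2", "PP3"))
  expect_equal(lp$tier, "likely_pathogenic")
  expect_equal(lp$matched_rule, "2 PM + >=2 PP")
})

test_that("classification agrees with the brute-force rule table on random sets", {
  codes <- acmg_codes()$code
  set.seed(1)
  for (i in 1:400) {
    cs <- sample(codes, sample(0:4, 1))
    expect_equal(classify_criteria(cs)$tier, acmg_oracle(cs),
                 info = paste(cs, collapse = "+"))
  }
})

test_that("adding pathogenic evidence never moves the tier toward benign", {
  rank <- c(benign = 1, likely_benign = 2, VUS = 3,
            likely_pathogenic = 4, pathogenic = 5)
  path_codes <- acmg_codes()$code[acmg_codes()$direction == "pathogenic"]
  set.seed(2)
  for (i in 1:200) {
    base <- sample(path_codes, sample(0:3, 1))
    extra <- sample(setdiff(path_codes, base), 1)
    t0 <- classify_criteria(base)$tier
    t1 <- classify_criteria(c(base, extra))$tier
    expect_gte(rank[[t1]], rank[[t0]])
  }
})

test_that("codes validate, deduplicate and honour the PP5 switch", {
  expect_error(classify_criteria("PX9"), "unknown ACMG/AMP code")
  expect_equal(parse_criteria("PVS1, PM2 ,PM2"), c("PVS1", "PM2"))
  # without reputable-source codes the CHEK2-style set loses a leg
  with_pp5 <- classify_criteria(c("PVS1", "PM2", "PP5"))
  without <- classify_criteria(c("PVS1", "PM2", "PP5"), use_pp5 = FALSE)
  expect_equal(with_pp5$tier, "pathogenic")          # PVS1 + 1 PM + 1 PP
  expect_equal(without$tier, "likely_pathogenic")    # drops to PVS1 + 1 PM
  lp_set <- classify_criteria(c("PM1", "PP5", "PP2"), use_pp5 = FALSE)
  expect_equal(lp_set$tier, "VUS")          # PP5 no longer counted
})

test_that("strength overrides stay within direction", {
  down <- classify_criteria(c("PVS1", "PM2"),
                            strength_override = c(PVS1 = "strong"))
  expect_equal(down$tier, "likely_pathogenic")  # 1 PS + 1 PM
  expect_error(classify_criteria(c("PVS1", "BS1"),
                                 strength_override = c(BS1 = "very_strong")),
               "direction")
})

test_that("table classification joins criteria, screens, and reports gaps", {
  x <- make_calls(c("A", "B", "C"), gene = "G", pos = c(1L, 2L, 3L))
  crit <- data.frame(variant_id = unique(x$variant_id),
                     codes = c("PVS1,PM2", "PM2", "BA1"))
  cls <- classify_variant_table(x, crit)
  expect_equal(nrow(cls), 3)
  screened <- classify_variant_table(x, crit, screen_mode = TRUE)
  expect_equal(screened$variant_id, "1:1:A:T")
  expect_error(classify_variant_table(x, crit[-2, ]), "1:2:A:T")
  empty <- x[0, ]; class(empty) <- class(x)
  expect_equal(nrow(classify_variant_table(empty, crit)), 0)
})

test_that("printed tiers take precedence only when requested, with flags", {
  fx <- fixture_table1()
  cls <- classify_variant_table(fx$variants, fx$criteria,
                                prefer_printed = TRUE)
  expect_equal(sum(cls$known_discrepancy), 2)
  expect_setequal(cls$variant_id[cls$known_discrepancy],
                  c("13:32394600:A:G", "7:124481000:G:C"))
  engine <- classify_variant_table(fx$variants, fx$criteria)
  agree <- cls$variant_id[!cls$known_discrepancy]
  expect_equal(engine$tier[match(agree, engine$variant_id)],
               cls$tier[match(agree, cls$variant_id)])
})
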