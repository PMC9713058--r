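# ACMG/AMP 2015 evidence-combination engine: coded evidence items
# (PVS/PS/PM/PP pathogenic, BA/BS/BP benign) combined by the published
# clause table into a five-tier classification with a rule trace.

#' The ACMG/AMP evidence-code registry
#'
#' Every recognised code with its direction and default strength.
#' PP5/BP6 (reputable-source assertions) are included; they can be
#' rejected at classification time via `use_pp5 = FALSE` since later
#' guidance recommends against them.
#'
#' @return Data.frame with columns `code`, `direction`, `strength`.
#' @export
acmg_codes <- function() {
  data.frame(
    code = c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7)),
    direction = c(rep("pathogenic", 16), rep("benign", 12)),
    strength = c("very_strong", rep("strong", 4), rep("moderate", 6),
                 rep("supporting", 5), "stand_alone", rep("strong", 4),
                 rep("supporting", 7)),
    stringsAsFactors = FALSE)
}

#' Parse and validate a set of evidence codes
#'
#' @param codes Character vector of codes, or a single comma-separated
#'   string (e.g. `"PVS1,PM2,PP3"`).
#' @return Character vector of validated, de-duplicated codes.
#' @export
parse_criteria <- function(codes) {
  if (length(codes) == 1 && grepl(",", codes))
    codes <- strsplit(codes, ",")[[1]]
  codes <- toupper(trimws(codes))
  codes <- codes[nzchar(codes)]
  unknown <- setdiff(codes, acmg_codes()$code)
  if (length(unknown))
    stop("unknown ACMG/AMP code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unique(codes)
}

# effective strength counts after optional overrides
criteria_counts <- function(codes, use_pp5 = TRUE, strength_override = NULL) {
  reg <- acmg_codes()
  codes <- parse_criteria(codes)
  if (!use_pp5) codes <- setdiff(codes, c("PP5", "BP6"))
  dir <- reg$direction[match(codes, reg$code)]
  str <- reg$strength[match(codes, reg$code)]
  if (length(strength_override)) {
    for (cd in names(strength_override)) {
      i <- match(cd, codes)
      if (is.na(i)) next
      ov <- match.arg(strength_override[[cd]],
                      c("stand_alone", "very_strong", "strong", "moderate",
                        "supporting"))
      if ((dir[i] == "benign" && ov == "very_strong") ||
          (dir[i] == "pathogenic" && ov == "stand_alone"))
        stop("strength override for ", cd,
             " not available in its direction", call. = FALSE)
      str[i] <- ov
    }
  }
  cnt <- function(d, s) sum(dir == d & str == s)
  list(pvs = cnt("pathogenic", "very_strong"),
       ps = cnt("pathogenic", "strong"),
       pm = cnt("pathogenic", "moderate"),
       pp = cnt("pathogenic", "supporting"),
       ba = cnt("benign", "stand_alone"),
       bs = cnt("benign", "strong"),
       bp = cnt("benign", "supporting"),
       codes = codes)
}

# the published combining-rule clause table, in canonical order:
# pathogenic before likely-pathogenic, benign before likely-benign
acmg_clauses <- function() {
  list(
    list(tier = "pathogenic", label = "PVS1 + >=1 PS",
         pred = function(n) n$pvs >= 1 && n$ps >= 1),
    list(tier = "pathogenic", label = "PVS1 + >=2 PM",
         pred = function(n) n$pvs >= 1 && n$pm >= 2),
    list(tier = "pathogenic", label = "PVS1 + 1 PM + 1 PP",
         pred = function(n) n$pvs >= 1 && n$pm >= 1 && n$pp >= 1),
    list(tier = "pathogenic", label = "PVS1 + >=2 PP",
         pred = function(n) n$pvs >= 1 && n$pp >= 2),
    list(tier = "pathogenic", label = ">=2 PS",
         pred = function(n) n$ps >= 2),
    list(tier = "pathogenic", label = "1 PS + >=3 PM",
         pred = function(n) n$ps >= 1 && n$pm >= 3),
    list(tier = "pathogenic", label = "1 PS + 2 PM + >=2 PP",
         pred = function(n) n$ps >= 1 && n$pm >= 2 && n$pp >= 2),
    list(tier = "pathogenic", label = "1 PS + 1 PM + >=4 PP",
         pred = function(n) n$ps >= 1 && n$pm >= 1 && n$pp >= 4),
    list(tier = "likely_pathogenic", label = "PVS1 + 1 PM",
         pred = function(n) n$pvs >= 1 && n$pm >= 1),
    list(tier = "likely_pathogenic", label = "1 PS + 1-2 PM",
         pred = function(n) n$ps >= 1 && n$pm >= 1),
    list(tier = "likely_pathogenic", label = "1 PS + >=2 PP",
         pred = function(n) n$ps >= 1 && n$pp >= 2),
    list(tier = "likely_pathogenic", label = ">=3 PM",
         pred = function(n) n$pm >= 3),
    list(tier = "likely_pathogenic", label = "2 PM + >=2 PP",
         pred = function(n) n$pm >= 2 && n$pp >= 2),
    list(tier = "likely_pathogenic", label = "1 PM + >=4 PP",
         pred = function(n) n$pm >= 1 && n$pp >= 4),
    list(tier = "benign", label = "BA1 stand-alone",
         pred = function(n) n$ba >= 1),
    list(tier = "benign", label = ">=2 BS",
         pred = function(n) n$bs >= 2),
    list(tier = "likely_benign", label = "1 BS + 1 BP",
         pred = function(n) n$bs >= 1 && n$bp >= 1),
    list(tier = "likely_benign", label = ">=2 BP",
         pred = function(n) n$bp >= 2))
}

#' Combine ACMG/AMP evidence codes into a five-tier classification
#'
#' Evaluates the published combining rules over the supplied evidence
#' set. When both a pathogenic-direction clause (P or LP) and a
#' benign-direction clause (B or LB) are satisfied, the evidence is
#' contradictory and the variant is a VUS with `conflict_flag = TRUE`.
#' `matched_rule` is the first satisfied clause in canonical order
#' (pathogenic before likely-pathogenic, benign before likely-benign).
#'
#' @param codes Evidence codes (vector or comma-separated string).
#' @param use_pp5 Accept PP5/BP6 reputable-source codes (default TRUE).
#' @param strength_override Optional named character vector mapping a
#'   code to a non-default strength within its direction, e.g.
#'   `c(PVS1 = "strong")`.
#' @return An `acmg_classification` list: `tier` (one of `pathogenic`,
#'   `likely_pathogenic`, `VUS`, `likely_benign`, `benign`),
#'   `matched_rule`, `conflict_flag`, `codes`.
#' @export
classify_criteria <- function(codes, use_pp5 = TRUE,
                              strength_override = NULL) {
  n <- criteria_counts(codes, use_pp5, strength_override)
  sat <- vapply(acmg_clauses(), function(cl) cl$pred(n), logical(1))
  tiers <- vapply(acmg_clauses(), `[[`, character(1), "tier")
  labels <- vapply(acmg_clauses(), `[[`, character(1), "label")
  path_met <- any(sat[tiers %in% c("pathogenic", "likely_pathogenic")])
  ben_met <- any(sat[tiers %in% c("benign", "likely_benign")])
  if (path_met && ben_met) {
    out <- list(tier = "VUS", matched_rule = "conflicting evidence",
                conflict_flag = TRUE, codes = n$codes)
  } else if (any(sat)) {
    first <- which(sat)[1]
    out <- list(tier = tiers[first], matched_rule = labels[first],
                conflict_flag = FALSE, codes = n$codes)
  } else {
    out <- list(tier = "VUS", matched_rule = "no combining rule satisfied",
                conflict_flag = FALSE, codes = n$codes)
  }
  class(out) <- "acmg_classification"
  out
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat("ACMG/AMP classification: ", x$tier,
      if (x$conflict_flag) " (conflicting evidence)" else "",
      "\n  evidence: ", paste(x$codes, collapse = ", "),
      "\n  rule:     ", x$matched_rule, "\n", sep = "")
  invisible(x)
}

#' Trace every combining-rule clause against an evidence set
#'
#' Deterministic trace: one row per clause of the published rule table,
#' in canonical order, with its satisfaction status. The first
#' satisfied clause equals `matched_rule` of [classify_criteria()]
#' (absent an evidence conflict).
#'
#' @inheritParams classify_criteria
#' @return Data.frame with columns `clause`, `tier`, `satisfied`.
#' @export
acmg_explain <- function(codes, use_pp5 = TRUE, strength_override = NULL) {
  n <- criteria_counts(codes, use_pp5, strength_override)
  data.frame(
    clause = vapply(acmg_clauses(), `[[`, character(1), "label"),
    tier = vapply(acmg_clauses(), `[[`, character(1), "tier"),
    satisfied = vapply(acmg_clauses(), function(cl) cl$pred(n), logical(1)),
    stringsAsFactors = FALSE)
}

#' Classify every variant of a call table
#'
#' Joins a criteria table onto the unique variants of a cohort call
#' table and classifies each. In screen mode only pathogenic and
#' likely-pathogenic variants are retained (the P/LP screen of a
#' predisposition analysis).
#'
#' When the criteria table carries a `printed_tier` column (a published
#' expert assessment, as in a curated fixture) and
#' `prefer_printed = TRUE`, the published tier takes precedence for
#' downstream carrier counting; the engine's own tier is kept in
#' `engine_tier` and rows where the two disagree are flagged
#' `known_discrepancy`.
#'
#' @param x A `variant_calls` table.
#' @param criteria Data.frame with columns `variant_id` and `codes`
#'   (comma-separated evidence codes); optional `printed_tier`.
#' @param screen_mode Drop variants classified VUS / likely benign /
#'   benign (default FALSE).
#' @param use_pp5 Passed to [classify_criteria()].
#' @param prefer_printed Use `printed_tier` over the engine tier when
#'   available (default FALSE).
#' @return An `acmg_classified` data.frame: one row per variant with
#'   `variant_id`, `gene`, `inheritance` (if annotated), `n_carriers`,
#'   `tier`, `matched_rule`, `conflict_flag`, `codes` (plus
#'   `engine_tier` and `known_discrepancy` under `prefer_printed`).
#' @export
classify_variant_table <- function(x, criteria, screen_mode = FALSE,
                                   use_pp5 = TRUE, prefer_printed = FALSE) {
  stopifnot(inherits(x, "variant_calls"), is.data.frame(criteria))
  if (prefer_printed && !"printed_tier" %in% names(criteria))
    stop("prefer_printed requires a printed_tier column", call. = FALSE)
  uv <- unique_variants(x)
  if (nrow(uv)) {
    i <- match(uv$variant_id, criteria$variant_id)
    if (anyNA(i))
      stop("no ACMG/AMP criteria supplied for variant(s): ",
           paste(uv$variant_id[is.na(i)], collapse = ", "), call. = FALSE)
    cls <- lapply(criteria$codes[i],
                  function(cd) classify_criteria(cd, use_pp5 = use_pp5))
    uv$tier <- vapply(cls, `[[`, character(1), "tier")
    uv$matched_rule <- vapply(cls, `[[`, character(1), "matched_rule")
    uv$conflict_flag <- vapply(cls, `[[`, logical(1), "conflict_flag")
    uv$codes <- vapply(cls, function(z) paste(z$codes, collapse = ","),
                       character(1))
    if (prefer_printed) {
      uv$engine_tier <- uv$tier
      uv$tier <- criteria$printed_tier[i]
      uv$known_discrepancy <- uv$tier != uv$engine_tier
    }
  } else {
    uv$tier <- character(0); uv$matched_rule <- character(0)
    uv$conflict_flag <- logical(0); uv$codes <- character(0)
    if (prefer_printed) {
      uv$engine_tier <- character(0)
      uv$known_discrepancy <- logical(0)
    }
  }
  if (screen_mode)
    uv <- uv[uv$tier %in% c("pathogenic", "likely_pathogenic"), ,
             drop = FALSE]
  rownames(uv) <- NULL
  class(uv) <- c("acmg_classified", "data.frame")
  uv
}

#' @export
print.acmg_classified <- function(x, ...) {
  cat("ACMG/AMP classified variants:", nrow(x), "variant(s)\n")
  tb <- table(factor(x$tier, levels = c("pathogenic", "likely_pathogenic",
                                        "VUS", "likely_benign", "benign")))
  print(tb)
  invisible(x)
}
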