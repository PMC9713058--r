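# Multistep candidate-variant filtering cascade with a telescoping
# audit trail: quality -> panel -> rarity -> impact.

#' Filtering configuration
#'
#' Thresholds for the candidate-variant cascade. Rarity is an allele
#' frequency (AC/AN) compared per reference subset independently: a
#' variant survives only if its frequency is at or below the threshold
#' in every subset (`max_global_maf` for the subset named in
#' `global_subset` of [apply_rarity_filter()], `max_subpop_maf` for all
#' others). Defaults retain ultra-rare, protein-impacting variants with
#' conventionally sound genotype support.
#'
#' @param max_global_maf Maximum allele frequency in the global subset
#'   (default 0.001).
#' @param max_subpop_maf Maximum allele frequency in every other subset
#'   (default 0.001).
#' @param allowed_impacts Coding-impact classes retained by the impact
#'   filter (default: all protein-impacting classes, i.e. everything
#'   except `synonymous` and `other`).
#' @param min_depth Minimum per-carrier read depth (default 10).
#' @param min_gq Minimum per-carrier genotype quality (default 20).
#' @param het_ab_range Allowed alternate-allele fraction for
#'   heterozygous calls (default `c(0.25, 0.75)`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_global_maf = 0.001,
                          max_subpop_maf = 0.001,
                          allowed_impacts = c("missense", "nonsense",
                                              "frameshift", "splice_site",
                                              "start_lost", "inframe_indel"),
                          min_depth = 10, min_gq = 20,
                          het_ab_range = c(0.25, 0.75)) {
  stopifnot(max_global_maf >= 0, max_global_maf <= 1,
            max_subpop_maf >= 0, max_subpop_maf <= 1,
            length(het_ab_range) == 2,
            het_ab_range[1] >= 0, het_ab_range[2] <= 1,
            het_ab_range[1] < het_ab_range[2],
            min_depth >= 0, min_gq >= 0)
  allowed_impacts <- match.arg(allowed_impacts, coding_impacts(),
                               several.ok = TRUE)
  structure(list(max_global_maf = max_global_maf,
                 max_subpop_maf = max_subpop_maf,
                 allowed_impacts = allowed_impacts,
                 min_depth = min_depth, min_gq = min_gq,
                 het_ab_range = het_ab_range),
            class = "filter_config")
}

#' Genotype-quality filter
#'
#' Removes carriers whose genotype metrics fail the depth, genotype
#' quality or (for heterozygotes) allele-balance thresholds; variants
#' left with no carriers are dropped. When the table carries no metric
#' columns (e.g. it came from the TSV dialect), the step is a no-op
#' with a warning; missing individual metrics pass, by design
#' permissive.
#'
#' @param x A `variant_calls` table (metric columns `dp`, `gq`, `ab`).
#' @param config A [filter_config()].
#' @return Filtered `variant_calls`.
#' @export
apply_quality_filter <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "variant_calls"))
  if (!nrow(x)) return(x)
  if (!any(c("dp", "gq", "ab") %in% names(x))) {
    warning("no genotype metrics in variant table; quality filter skipped",
            call. = FALSE)
    return(x)
  }
  get <- function(col) if (col %in% names(x)) x[[col]] else rep(NA_real_, nrow(x))
  dp <- get("dp"); gq <- get("gq"); ab <- get("ab")
  fail <- (!is.na(dp) & dp < config$min_depth) |
          (!is.na(gq) & gq < config$min_gq) |
          (x$zygosity == "het" & !is.na(ab) &
             (ab < config$het_ab_range[1] | ab > config$het_ab_range[2]))
  out <- x[!fail, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  out
}

#' Candidate gene panel filter
#'
#' Keeps records whose gene is on the panel and annotates each
#' surviving record with the gene's inheritance mode.
#'
#' @param x A `variant_calls` table.
#' @param panel A `gene_panel`.
#' @return Filtered `variant_calls` with an `inheritance` column.
#' @export
apply_panel_filter <- function(x, panel) {
  stopifnot(inherits(x, "variant_calls"), inherits(panel, "gene_panel"))
  if (!nrow(panel)) stop("panel is empty", call. = FALSE)
  out <- x[x$gene %in% panel$gene, , drop = FALSE]
  out$inheritance <- panel$inheritance[match(out$gene, panel$gene)]
  rownames(out) <- NULL
  class(out) <- class(x)
  out
}

#' Population rarity filter
#'
#' A variant survives only if its allele frequency AC/AN is at or below
#' the configured threshold in every reference subset. Variants absent
#' from a subset count as frequency 0 (absent-as-zero policy); a listed
#' variant with AN = 0 is likewise treated as unobserved, with a
#' warning.
#'
#' @param x A `variant_calls` table.
#' @param ref A `ref_counts` table.
#' @param config A [filter_config()].
#' @param global_subset Name of the subset governed by
#'   `max_global_maf` (default `"global"`); all other subsets use
#'   `max_subpop_maf`.
#' @return Filtered `variant_calls`.
#' @export
apply_rarity_filter <- function(x, ref, config = filter_config(),
                                global_subset = "global") {
  stopifnot(inherits(x, "variant_calls"), inherits(ref, "ref_counts"))
  if (!nrow(x)) return(x)
  subsets <- ref_subsets(ref)
  vids <- unique(x$variant_id)
  keep_vid <- vapply(vids, function(v) {
    all(vapply(subsets, function(s) {
      thr <- if (identical(s, global_subset)) config$max_global_maf
             else config$max_subpop_maf
      ref_lookup(ref, s, v)$maf <= thr
    }, logical(1)))
  }, logical(1))
  out <- x[x$variant_id %in% vids[keep_vid], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  out
}

#' Coding-impact filter
#'
#' Keeps records whose coding impact is among the allowed
#' protein-impacting classes.
#'
#' @param x A `variant_calls` table.
#' @param config A [filter_config()].
#' @return Filtered `variant_calls`.
#' @export
apply_impact_filter <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "variant_calls"))
  out <- x[x$coding_impact %in% config$allowed_impacts, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  out
}

#' Run the full filtering cascade
#'
#' Applies quality, panel, rarity and impact filters in that fixed
#' order and records a telescoping per-step report (each step's
#' surviving count is the next step's input count; removed variant sets
#' are disjoint).
#'
#' @param x A `variant_calls` table.
#' @param panel A `gene_panel`.
#' @param ref A `ref_counts` table.
#' @param config A [filter_config()].
#' @param global_subset Passed to [apply_rarity_filter()].
#' @return List with `records` (surviving `variant_calls`) and
#'   `report` (a `filter_report`).
#' @export
run_cascade <- function(x, panel, ref, config = filter_config(),
                        global_subset = "global") {
  steps <- list(
    quality = function(d) apply_quality_filter(d, config),
    panel   = function(d) apply_panel_filter(d, panel),
    rarity  = function(d) apply_rarity_filter(d, ref, config, global_subset),
    impact  = function(d) apply_impact_filter(d, config))
  cur <- x
  rep_rows <- list()
  removed <- list()
  for (nm in names(steps)) {
    n_in <- n_variants(cur)
    before_ids <- unique(cur$variant_id)
    cur <- steps[[nm]](cur)
    after_ids <- unique(cur$variant_id)
    removed[[nm]] <- setdiff(before_ids, after_ids)
    rep_rows[[nm]] <- data.frame(step = nm, n_in = n_in,
                                 n_out = length(after_ids),
                                 n_removed = length(removed[[nm]]),
                                 stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  class(report) <- c("filter_report", "data.frame")
  attr(report, "removed") <- removed
  list(records = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filtering cascade (unique variants):\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  removed <- attr(report, "removed")
  out <- as.data.frame(report)
  out$removed_variant_ids <- vapply(removed[out$step], paste,
                                    character(1), collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
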