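# Cohort-level reporting: carrier frequencies by inheritance mode,
# per-gene recurrence, onset-age summaries, pedigree co-segregation,
# and the end-to-end orchestrator.

# half-up rounding (printed percents use commercial rounding, not
# banker's): 9.375 -> 9.4
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Carrier frequency as a printed percent
#'
#' 100 * count / n, rounded half-up to one decimal (so 12/128 prints
#' as 9.4, 27/128 as 21.1).
#'
#' @param carrier_count Number of carriers.
#' @param cohort_n Cohort size (> 0).
#' @return Percent, one decimal.
#' @export
carrier_frequency <- function(carrier_count, cohort_n) {
  if (cohort_n <= 0) stop("cohort_n must be positive", call. = FALSE)
  stopifnot(carrier_count >= 0, carrier_count <= cohort_n)
  round_half_up(100 * carrier_count / cohort_n, 1)
}

#' Carrier counts by inheritance stratum
#'
#' Counts distinct patients carrying a P/LP variant in (i) dominantly
#' inherited (AD) panel genes and (ii) AD genes plus heterozygous
#' variants of recessively inherited (AR) genes. A patient with several
#' qualifying variants counts once per stratum.
#'
#' @param x The `variant_calls` table (supplies carriers and zygosity).
#' @param classified An `acmg_classified` table (P/LP rows are used).
#' @param panel A `gene_panel` supplying inheritance modes.
#' @param cohort_n Cohort size.
#' @return List with `carriers_AD` and `carriers_AD_plus_ARhet`, each
#'   `(count, percent, patient_ids)`, plus `cohort_n`.
#' @export
summarize_by_inheritance <- function(x, classified, panel, cohort_n) {
  stopifnot(inherits(x, "variant_calls"), inherits(panel, "gene_panel"),
            cohort_n > 0)
  plp <- classified[classified$tier %in% c("pathogenic",
                                           "likely_pathogenic"), ,
                    drop = FALSE]
  missing_genes <- setdiff(unique(plp$gene), panel$gene)
  if (length(missing_genes))
    stop("gene(s) absent from panel: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  inh <- setNames(panel$inheritance, panel$gene)
  calls <- x[x$variant_id %in% plp$variant_id, , drop = FALSE]
  calls$inheritance <- inh[calls$gene]
  ad_ids <- sort(unique(calls$patient_id[calls$inheritance == "AD"]))
  ar_het_ids <- sort(unique(calls$patient_id[calls$inheritance == "AR" &
                                             calls$zygosity == "het"]))
  both <- sort(union(ad_ids, ar_het_ids))
  stratum <- function(ids) list(count = length(ids),
                                percent = carrier_frequency(length(ids),
                                                            cohort_n),
                                patient_ids = ids)
  list(cohort_n = cohort_n,
       carriers_AD = stratum(ad_ids),
       carriers_AD_plus_ARhet = stratum(both))
}

#' Per-gene recurrence screen
#'
#' Genes in which at least `min_patients` distinct patients carry a
#' P/LP variant — the criterion for considering a gene further as a
#' predisposition candidate. Output is ordered by descending carrier
#' count, ties alphabetically.
#'
#' @param x The `variant_calls` table.
#' @param classified An `acmg_classified` table (P/LP rows are used).
#' @param min_patients Minimum distinct carriers (default 2).
#' @return Data.frame with columns `gene`, `n_patients`.
#' @export
recurrent_gene_screen <- function(x, classified, min_patients = 2) {
  stopifnot(inherits(x, "variant_calls"))
  plp <- classified[classified$tier %in% c("pathogenic",
                                           "likely_pathogenic"), ,
                    drop = FALSE]
  calls <- x[x$variant_id %in% plp$variant_id, , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(gene = character(0), n_patients = integer(0)))
  cnt <- tapply(calls$patient_id, calls$gene,
                function(p) length(unique(p)))
  out <- data.frame(gene = names(cnt), n_patients = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[out$n_patients >= min_patients, , drop = FALSE]
  out <- out[order(-out$n_patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median onset age with range
#'
#' Standard median (mean of the two central values for even n).
#'
#' @param ages Numeric vector of ages at diagnosis; NAs are dropped
#'   with a warning.
#' @return List with `median`, `range` (min, max), `n`.
#' @export
median_onset <- function(ages) {
  if (anyNA(ages)) {
    warning("dropping ", sum(is.na(ages)), " missing onset age(s)",
            call. = FALSE)
    ages <- ages[!is.na(ages)]
  }
  if (!length(ages)) stop("no onset ages supplied", call. = FALSE)
  list(median = median(ages), range = c(min(ages), max(ages)),
       n = length(ages))
}

#' Co-segregation counts for one variant in one pedigree
#'
#' Partitions the affected members of a pedigree by their tested
#' genotype for the variant: confirmed carriers, confirmed
#' non-carriers, and untested. If the pedigree records no genotype for
#' the variant at all, every affected member is counted untested, with
#' a warning.
#'
#' @param ped A `pedigree` object.
#' @param vid Variant identifier as used in the pedigree's
#'   `tested_variant` column.
#' @return List with `tested_affected`, `affected_carriers`,
#'   `affected_noncarriers`, `untested_affected`, and the member id
#'   vectors `carrier_ids` / `noncarrier_ids`.
#' @export
cosegregation_summary <- function(ped, vid) {
  stopifnot(inherits(ped, "pedigree"))
  aff <- ped$members$individual_id[ped$members$affected]
  if (!length(aff))
    stop("pedigree ", ped$family_id, " has no affected member",
         call. = FALSE)
  g <- ped$genotypes[ped$genotypes$tested_variant == vid, , drop = FALSE]
  if (!nrow(g))
    warning("no genotype recorded for ", vid, " in family ",
            ped$family_id, "; all affected counted untested",
            call. = FALSE)
  res <- setNames(g$tested_result, g$individual_id)
  status <- res[aff]
  status[is.na(status)] <- "untested"
  carrier_ids <- aff[status == "carrier"]
  noncarrier_ids <- aff[status == "noncarrier"]
  list(tested_affected = sum(status != "untested"),
       affected_carriers = length(carrier_ids),
       affected_noncarriers = length(noncarrier_ids),
       untested_affected = sum(status == "untested"),
       carrier_ids = carrier_ids, noncarrier_ids = noncarrier_ids)
}

#' Run the full screening pipeline on a data bundle
#'
#' Orchestrates filtering, classification, cohort summaries and burden
#' association over a bundle (as returned by [fixture_table1()] or
#' [simulate_cohort()], or assembled by hand): filters the variant
#' calls through [run_cascade()], classifies survivors with
#' [classify_variant_table()] in screen mode, then produces the
#' inheritance-stratified carrier summary, the recurrence screen,
#' per-recurrent-gene onset summaries, co-segregation counts for every
#' pedigree, and the carrier-burden association at all scopes.
#' Deterministic given its inputs.
#'
#' @param bundle List with elements `variants` (`variant_calls`),
#'   `criteria`, `ref_counts`, `panel`, `cohort_n`; optional
#'   `phenotypes`, `pedigrees`.
#' @param config A [filter_config()].
#' @param min_patients Recurrence threshold (default 2).
#' @param out_dir Optional directory; when given, the filter report,
#'   classified table, association table and a JSON cohort report are
#'   written there.
#' @return A `cohort_report` object.
#' @export
run_screen <- function(bundle, config = filter_config(), min_patients = 2,
                       out_dir = NULL) {
  need <- c("variants", "criteria", "ref_counts", "panel", "cohort_n")
  missing_parts <- setdiff(need, names(bundle))
  if (length(missing_parts))
    stop("bundle lacks element(s): ", paste(missing_parts, collapse = ", "),
         call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  casc <- stage("filtering",
                run_cascade(bundle$variants, bundle$panel,
                            bundle$ref_counts, config))
  classified <- stage("classification",
                      classify_variant_table(casc$records, bundle$criteria,
                                             screen_mode = TRUE,
                                             prefer_printed =
                                               isTRUE(bundle$prefer_printed)))
  inh <- stage("inheritance summary",
               summarize_by_inheritance(casc$records, classified,
                                        bundle$panel, bundle$cohort_n))
  recurrent <- stage("recurrence screen",
                     recurrent_gene_screen(casc$records, classified,
                                           min_patients))
  onset <- list()
  if (!is.null(bundle$phenotypes) && nrow(recurrent)) {
    calls <- casc$records[casc$records$variant_id %in%
                            classified$variant_id, , drop = FALSE]
    for (g in recurrent$gene) {
      ids <- unique(calls$patient_id[calls$gene == g])
      ages <- bundle$phenotypes$age_at_diagnosis[
        match(ids, bundle$phenotypes$patient_id)]
      if (all(is.na(ages))) next
      onset[[g]] <- suppressWarnings(median_onset(ages))
    }
  }
  coseg <- list()
  if (!is.null(bundle$pedigrees)) {
    for (ped in bundle$pedigrees) {
      vids <- unique(ped$genotypes$tested_variant)
      coseg[[ped$family_id]] <- lapply(
        setNames(vids, vids),
        function(v) cosegregation_summary(ped, v))
    }
  }
  assoc <- stage("burden association",
                 associate(casc$records, classified, bundle$ref_counts,
                           bundle$cohort_n))
  per_gene <- recurrent_gene_screen(casc$records, classified,
                                    min_patients = 1)
  report <- structure(list(
    cohort_n = bundle$cohort_n,
    filter_report = casc$report,
    records = casc$records,
    classified = classified,
    carriers_AD = inh$carriers_AD,
    carriers_AD_plus_ARhet = inh$carriers_AD_plus_ARhet,
    per_gene = per_gene,
    recurrent = recurrent,
    onset = onset,
    cosegregation = coseg,
    association = assoc), class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_filter_report(casc$report, file.path(out_dir, "filter_report.tsv"))
    write.table(as.data.frame(classified),
                file.path(out_dir, "classified.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    write_association_table(assoc, file.path(out_dir, "association.tsv"))
    jsonlite::write_json(cohort_report_json(report),
                         file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-ready view of a cohort report (no data.frame classes)
cohort_report_json <- function(r) {
  list(cohort_n = r$cohort_n,
       filter_report = as.data.frame(r$filter_report),
       carriers_AD = r$carriers_AD[c("count", "percent")],
       carriers_AD_plus_ARhet = r$carriers_AD_plus_ARhet[c("count",
                                                           "percent")],
       per_gene = r$per_gene,
       recurrent = r$recurrent,
       onset = r$onset,
       cosegregation = lapply(r$cosegregation, function(fam)
         lapply(fam, function(z) z[c("tested_affected", "affected_carriers",
                                     "affected_noncarriers",
                                     "untested_affected")])),
       association = as.data.frame(r$association))
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Germline predisposition screen, cohort n =", x$cohort_n, "\n\n")
  print(x$filter_report)
  cat("\nP/LP carriers, dominant (AD) genes: ", x$carriers_AD$count, "/",
      x$cohort_n, " (", x$carriers_AD$percent, "%)\n", sep = "")
  cat("P/LP carriers incl. AR heterozygotes: ",
      x$carriers_AD_plus_ARhet$count, "/", x$cohort_n, " (",
      x$carriers_AD_plus_ARhet$percent, "%)\n", sep = "")
  if (nrow(x$recurrent)) {
    cat("\nRecurrently affected genes (>= 2 carriers):\n")
    print.data.frame(x$recurrent)
  }
  for (g in names(x$onset))
    cat("\n", g, " carriers: median onset ", x$onset[[g]]$median,
        " y (range ", x$onset[[g]]$range[1], "-", x$onset[[g]]$range[2],
        ")\n", sep = "")
  if (nrow(x$association)) {
    cat("\nPanel-level burden vs reference subsets:\n")
    pan <- x$association[x$association$scope == "panel", , drop = FALSE]
    class(pan) <- c("burden_assoc", "data.frame")
    print(pan)
  }
  invisible(x)
}
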