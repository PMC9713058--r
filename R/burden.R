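# Carrier-based 2x2 burden association of cohort P/LP carriage against
# population reference subsets. Counting unit is the carrier
# (individual), not the allele: reference carriers are approximated as
# AC - nHom, which is exact for ultra-rare variants.

#' Build a 2x2 carrier contingency table against a reference subset
#'
#' Rows: cohort vs reference population; columns: carrier vs
#' non-carrier. Reference carriers for a variant are estimated as
#' AC - nHom (each homozygote contributes two alleles but one carrier);
#' for a multi-variant scope the per-variant estimates are summed
#' (distinct ultra-rare variants essentially never share reference
#' carriers). Variants absent from the subset contribute zero carriers
#' and set the `unobserved` flag.
#'
#' @param carrier_count Number of cohort carriers (a).
#' @param cohort_n Cohort size (a + b).
#' @param ref A `ref_counts` table.
#' @param subset Reference subset name.
#' @param variant_ids Variant id(s) defining the scope.
#' @return A `contingency` list with `a`, `b`, `c`, `d`,
#'   `subset`, `unobserved` (logical: any scope variant absent from the
#'   subset).
#' @export
build_contingency <- function(carrier_count, cohort_n, ref, subset,
                              variant_ids) {
  stopifnot(cohort_n > 0, carrier_count >= 0, carrier_count <= cohort_n)
  sizes <- attr(ref, "subsets")
  if (!subset %in% names(sizes))
    stop("unknown reference subset: ", subset, call. = FALSE)
  n_ref <- sizes[[subset]]
  looks <- lapply(variant_ids, function(v) ref_lookup(ref, subset, v))
  ref_carriers <- sum(vapply(looks, function(l) max(l$AC - l$nHom, 0L),
                             numeric(1)))
  if (ref_carriers > n_ref)
    stop("reference carriers (", ref_carriers, ") exceed subset size (",
         n_ref, ")", call. = FALSE)
  structure(list(a = as.integer(carrier_count),
                 b = as.integer(cohort_n - carrier_count),
                 c = as.integer(ref_carriers),
                 d = as.integer(n_ref - ref_carriers),
                 subset = subset,
                 unobserved = !all(vapply(looks, `[[`, logical(1),
                                          "observed"))),
            class = "contingency")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE,
         dimnames = list(c("cohort", "reference"),
                         c("carrier", "noncarrier")))
}

#' Odds ratio with a Woolf (log-normal) 95% confidence interval
#'
#' OR = ad/(bc); CI = exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' With any zero cell the estimate and interval are undefined and
#' reported as NA (the reporting convention for scopes with no
#' reference carriers), unless the Haldane-Anscombe continuity
#' correction (+0.5 to every cell) is enabled for exploratory use.
#'
#' @param tab A `contingency` table (or list with `a`, `b`, `c`, `d`).
#' @param correction Apply the +0.5 continuity correction to all cells
#'   when any cell is zero (default FALSE).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `method`.
#' @export
odds_ratio_woolf <- function(tab, correction = FALSE, conf_level = 0.95) {
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  stopifnot(length(cells) == 4, all(cells >= 0))
  method <- "woolf"
  if (any(cells == 0)) {
    if (!correction)
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  method = "woolf (undefined: zero cell)"))
    cells <- cells + 0.5
    method <- "woolf (Haldane-Anscombe corrected)"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se), method = method)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' The exact conditional test with both margins fixed: the two-sided p
#' sums the probabilities of all hypergeometric outcomes whose point
#' probability does not exceed that of the observed table
#' (minimum-likelihood definition, as implemented by
#' [stats::fisher.test()]).
#'
#' @param tab A `contingency` table (or list with `a`, `b`, `c`, `d`).
#' @param alternative Sidedness, default `"two.sided"`.
#' @return The p-value.
#' @export
fisher_exact_p <- function(tab, alternative = "two.sided") {
  m <- matrix(as.numeric(c(tab$a, tab$b, tab$c, tab$d)), nrow = 2,
              byrow = TRUE)
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' Carrier-burden association at variant, gene and panel scope
#'
#' For every requested scope unit and reference subset, builds the
#' carrier 2x2 table, the Woolf odds ratio with 95% CI and the
#' two-sided Fisher exact p. Cohort carriers are distinct patients: at
#' gene and panel scope a patient carrying several qualifying variants
#' is counted once ("carrier of >= 1 P/LP variant in scope").
#'
#' @param x The `variant_calls` table supplying carrier identities.
#' @param classified An `acmg_classified` table; only pathogenic /
#'   likely-pathogenic rows enter the association.
#' @param ref A `ref_counts` table.
#' @param cohort_n Cohort size (carriers and non-carriers).
#' @param scopes Any of `"variant"`, `"gene"`, `"panel"`.
#' @param subsets Reference subsets to test (default: all in `ref`).
#' @param correction Passed to [odds_ratio_woolf()].
#' @return A `burden_assoc` data.frame with columns `scope`, `unit`,
#'   `subset`, `a`, `b`, `c`, `d`, `or`, `ci_low`, `ci_high`, `p`,
#'   `method`, `unobserved`.
#' @export
associate <- function(x, classified, ref, cohort_n,
                      scopes = c("variant", "gene", "panel"),
                      subsets = ref_subsets(ref), correction = FALSE) {
  stopifnot(inherits(x, "variant_calls"), inherits(ref, "ref_counts"),
            cohort_n > 0)
  scopes <- match.arg(scopes, several.ok = TRUE)
  plp <- classified[classified$tier %in% c("pathogenic",
                                           "likely_pathogenic"), ,
                    drop = FALSE]
  calls <- x[x$variant_id %in% plp$variant_id, , drop = FALSE]
  units <- list()
  if ("variant" %in% scopes)
    for (v in unique(plp$variant_id))
      units[[length(units) + 1L]] <- list(scope = "variant", unit = v,
                                          vids = v)
  if ("gene" %in% scopes)
    for (g in unique(plp$gene))
      units[[length(units) + 1L]] <- list(
        scope = "gene", unit = g,
        vids = plp$variant_id[plp$gene == g])
  if ("panel" %in% scopes && nrow(plp))
    units[[length(units) + 1L]] <- list(scope = "panel", unit = "panel",
                                        vids = plp$variant_id)
  rows <- list()
  for (u in units) {
    carriers <- unique(calls$patient_id[calls$variant_id %in% u$vids])
    for (s in subsets) {
      tab <- build_contingency(length(carriers), cohort_n, ref, s, u$vids)
      orr <- odds_ratio_woolf(tab, correction = correction)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = u$scope, unit = u$unit, subset = s,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
        p = fisher_exact_p(tab), method = orr$method,
        unobserved = tab$unobserved, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scope = character(0), unit = character(0),
               subset = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), or = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
               method = character(0), unobserved = logical(0))
  rownames(out) <- NULL
  class(out) <- c("burden_assoc", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment of burden p-values
#'
#' Step-up FDR adjustment applied within each (scope, subset) family
#' of tests; the default report leaves p-values raw.
#'
#' @param results A `burden_assoc` data.frame.
#' @return The same data.frame with a `q` column.
#' @export
bh_adjust <- function(results) {
  stopifnot(inherits(results, "burden_assoc"))
  if (!nrow(results)) { results$q <- numeric(0); return(results) }
  results$q <- NA_real_
  for (key in unique(paste(results$scope, results$subset))) {
    idx <- paste(results$scope, results$subset) == key
    results$q[idx] <- p.adjust(results$p[idx], method = "BH")
  }
  results
}

#' @export
print.burden_assoc <- function(x, digits = 3, ...) {
  cat("Carrier-burden association:", nrow(x), "test(s)\n")
  df <- as.data.frame(x)
  for (cc in c("or", "ci_low", "ci_high"))
    df[[cc]] <- signif(df[[cc]], digits)
  df$p <- signif(df$p, digits)
  df$method <- NULL
  print.data.frame(df)
  invisible(x)
}

#' Write a burden association table as TSV
#' @param results A `burden_assoc` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
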