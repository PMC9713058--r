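# Synthetic cohort bundles with known ground truth, and the packaged
# worked-example fixture. The simulator emulates the study design the
# package targets: an unselected cohort of ~128 plasma-cell dyscrasia
# patients carrying a handful of planted rare P/LP variants in panel
# genes over a benign off-panel background, plus two reference
# population subsets (a global and an ancestry-matched stratum).

#' Simulation configuration
#'
#' Defaults mirror the target study design: 128 patients, reference
#' subsets of 118,477 (global) and 10,816 (population-matched)
#' individuals, planted variants matching the packaged worked-example
#' table, and 100 background variants in off-panel genes with minor
#' allele frequencies log-uniform on \[1e-4, 0.2\].
#'
#' @param seed Integer seed; identical config + seed reproduce the
#'   bundle exactly.
#' @param n_patients Cohort size (default 128).
#' @param panel A `gene_panel` (default [default_panel()]).
#' @param planted `"table1"` for the packaged worked-example variants,
#'   or a data.frame with columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `transcript`, `hgvs_c`, `hgvs_p`, `coding_impact`, `codes`
#'   (comma-separated evidence), `n_carriers`, and optional
#'   `ac_<subset>` reference allele counts.
#' @param n_background Number of background variants (default 100).
#' @param background_maf_range Log-uniform MAF range for background
#'   variants (default `c(1e-4, 0.2)`).
#' @param ref_subsets Named integer vector of reference subset sizes
#'   (default `c(global = 118477, finns = 10816)`).
#' @param finnish_enrichment Multiplier applied to background MAFs in
#'   every non-global subset, emulating population clustering of rare
#'   alleles (default 1 = none).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_patients = 128L,
                              panel = default_panel(),
                              planted = "table1",
                              n_background = 100L,
                              background_maf_range = c(1e-4, 0.2),
                              ref_subsets = c(global = 118477L,
                                              finns = 10816L),
                              finnish_enrichment = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_patients >= 0, n_background >= 0,
            length(background_maf_range) == 2,
            background_maf_range[1] > 0,
            background_maf_range[2] <= 0.5,
            background_maf_range[1] < background_maf_range[2],
            length(ref_subsets) >= 1, !is.null(names(ref_subsets)),
            finnish_enrichment > 0)
  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients), panel = panel,
                 planted = planted, n_background = as.integer(n_background),
                 background_maf_range = background_maf_range,
                 ref_subsets = ref_subsets,
                 finnish_enrichment = finnish_enrichment),
            class = "sim_config")
}

# planted-variant spec derived from the packaged worked-example table
planted_from_fixture <- function() {
  fx <- fixture_table1()
  uv <- unique_variants(fx$variants)
  uv$n_carriers <- as.integer(uv$n_carriers)
  uv$codes <- fx$criteria$codes[match(uv$variant_id,
                                      fx$criteria$variant_id)]
  for (s in ref_subsets(fx$ref_counts)) {
    uv[[paste0("ac_", s)]] <- vapply(uv$variant_id, function(v)
      ref_lookup(fx$ref_counts, s, v)$AC, integer(1))
  }
  uv
}

#' Simulate a self-contained cohort bundle
#'
#' Generates cohort variant calls (planted rare panel variants assigned
#' to randomly drawn patients; background variants carried at
#' Hardy-Weinberg given their MAF), per-carrier genotype metrics,
#' phenotypes, reference allele-count tables per subset, per-variant
#' evidence codes, and a ground-truth manifest recording every planted
#' fact. The cohort is unrelated; no pedigrees are generated.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory: writes `variants.tsv`,
#'   `variants.vcf`, `phenotypes.tsv`, `ref_counts.tsv`,
#'   `criteria.tsv`, `manifest.json` (and `pedigrees.ped` if any).
#' @return A bundle list (`variants`, `phenotypes`, `pedigrees`,
#'   `ref_counts`, `criteria`, `panel`, `cohort_n`, `manifest`).
#' @export
simulate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients <= 0)
    stop("n_patients must be positive", call. = FALSE)
  planted <- if (identical(config$planted, "table1"))
    planted_from_fixture() else config$planted
  if (any(planted$n_carriers > config$n_patients))
    stop("planted n_carriers exceeds n_patients", call. = FALSE)
  set.seed(config$seed)
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  subsets <- config$ref_subsets

  rows <- list()
  planted$carrier_ids <- character(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    carriers <- sample(patients, planted$n_carriers[i])
    planted$carrier_ids[i] <- paste(carriers, collapse = ",")
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = carriers, chrom = planted$chrom[i],
      pos = planted$pos[i], ref = planted$ref[i], alt = planted$alt[i],
      gene = planted$gene[i], transcript = planted$transcript[i],
      hgvs_c = planted$hgvs_c[i], hgvs_p = planted$hgvs_p[i],
      coding_impact = planted$coding_impact[i], zygosity = "het",
      stringsAsFactors = FALSE)
  }

  # benign background: off-panel genes, HW carriage at the drawn MAF
  bg <- NULL
  if (config$n_background > 0) {
    lr <- log(config$background_maf_range)
    maf <- exp(runif(config$n_background, lr[1], lr[2]))
    bases <- c("A", "C", "G", "T")
    bg <- data.frame(
      gene = sprintf("BG%04d", seq_len(config$n_background)),
      chrom = as.character(sample(1:22, config$n_background, replace = TRUE)),
      pos = sample.int(2e8, config$n_background),
      ref = sample(bases, config$n_background, replace = TRUE),
      maf = maf, stringsAsFactors = FALSE)
    bg$alt <- vapply(bg$ref, function(r) sample(setdiff(bases, r), 1),
                     character(1))
    bg$coding_impact <- sample(coding_impacts(), config$n_background,
                               replace = TRUE)
    bg$variant_id <- paste(bg$chrom, bg$pos, bg$ref, bg$alt, sep = ":")
    for (i in seq_len(nrow(bg))) {
      m <- bg$maf[i]
      p_hom <- m^2
      p_het <- 2 * m * (1 - m)
      u <- runif(config$n_patients)
      zyg <- ifelse(u < p_hom, "hom",
                    ifelse(u < p_hom + p_het, "het", "none"))
      carriers <- patients[zyg != "none"]
      if (!length(carriers)) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = carriers, chrom = bg$chrom[i], pos = bg$pos[i],
        ref = bg$ref[i], alt = bg$alt[i], gene = bg$gene[i],
        transcript = "", hgvs_c = "", hgvs_p = "",
        coding_impact = bg$coding_impact[i],
        zygosity = zyg[zyg != "none"], stringsAsFactors = FALSE)
    }
  }

  calls <- do.call(rbind, rows)
  # per-carrier genotype metrics: well-supported calls by construction
  calls$dp <- rpois(nrow(calls), 60) + 10L
  calls$gq <- 99
  ab <- rnorm(nrow(calls), 0.5, 0.05)
  calls$ab <- ifelse(calls$zygosity == "hom", 1, pmin(pmax(ab, 0.26), 0.74))
  variants <- variant_calls(calls)

  # reference counts: planted ACs as configured, background drawn
  # binomial at the (optionally enriched) subset MAF
  ref_rows <- list()
  for (s in names(subsets)) {
    n_ind <- subsets[[s]]
    an <- 2L * n_ind
    ac_col <- paste0("ac_", s)
    for (i in seq_len(nrow(planted))) {
      ac <- if (ac_col %in% names(planted)) planted[[ac_col]][i] else 0L
      if (is.na(ac) || ac == 0) next
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        subset = s, n_individuals = n_ind,
        variant_id = variant_id(planted$chrom[i], planted$pos[i],
                                planted$ref[i], planted$alt[i]),
        AC = ac, AN = an, nHom = 0L, stringsAsFactors = FALSE)
    }
    if (!is.null(bg)) {
      m_s <- if (identical(s, "global")) bg$maf else
        pmin(bg$maf * config$finnish_enrichment, 0.5)
      ac <- rbinom(nrow(bg), an, m_s)
      n_hom <- pmin(rbinom(nrow(bg), n_ind, m_s^2), ac %/% 2L)
      keep <- ac > 0
      if (any(keep))
        ref_rows[[length(ref_rows) + 1L]] <- data.frame(
          subset = s, n_individuals = n_ind,
          variant_id = bg$variant_id[keep], AC = ac[keep],
          AN = an, nHom = n_hom[keep], stringsAsFactors = FALSE)
    }
  }
  ref_counts <- reference_counts(do.call(rbind, ref_rows))

  # evidence codes: planted as configured; background coded benign or
  # insufficient depending on commonness
  planted_vid <- variant_id(planted$chrom, planted$pos, planted$ref,
                            planted$alt)
  criteria <- data.frame(variant_id = planted_vid, codes = planted$codes,
                         stringsAsFactors = FALSE)
  if (!is.null(bg)) {
    bg_codes <- ifelse(bg$maf > 0.05, "BA1",
                       ifelse(bg$maf > 0.001, "BS1,BP4", "PM2"))
    criteria <- rbind(criteria,
                      data.frame(variant_id = bg$variant_id,
                                 codes = bg_codes, stringsAsFactors = FALSE))
  }

  phenotypes <- phenotype_table(data.frame(
    patient_id = patients,
    diagnosis = sample(c("MM", "sMM", "MGUS", "PCL"), config$n_patients,
                       replace = TRUE, prob = c(0.78, 0.08, 0.10, 0.04)),
    age_at_diagnosis = pmin(pmax(round(rnorm(config$n_patients, 67, 10)),
                                 25), 90),
    sex = sample(c("F", "M"), config$n_patients, replace = TRUE),
    paraprotein = sample(c("IgG kappa", "IgG lambda", "IgA kappa",
                           "IgA lambda", "kappa light chain"),
                         config$n_patients, replace = TRUE),
    stringsAsFactors = FALSE))

  tiers <- vapply(planted$codes,
                  function(cd) classify_criteria(cd)$tier, character(1),
                  USE.NAMES = FALSE)
  plp_idx <- tiers %in% c("pathogenic", "likely_pathogenic")
  plp_carriers <- sort(unique(unlist(
    strsplit(planted$carrier_ids[plp_idx], ","))))
  manifest <- list(
    seed = config$seed, n_patients = config$n_patients,
    planted = data.frame(variant_id = planted_vid, gene = planted$gene,
                         codes = planted$codes, tier = tiers,
                         n_carriers = planted$n_carriers,
                         carrier_ids = planted$carrier_ids,
                         stringsAsFactors = FALSE),
    n_background = config$n_background,
    background_variant_ids = if (is.null(bg)) character(0) else bg$variant_id,
    expected_survivors = sort(planted_vid),
    expected_plp_carriers = plp_carriers,
    ref_subsets = as.list(subsets))

  bundle <- list(variants = variants, phenotypes = phenotypes,
                 pedigrees = list(), ref_counts = ref_counts,
                 criteria = criteria, panel = config$panel,
                 cohort_n = config$n_patients, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a bundle to disk
#'
#' Emits the TSV dialect and an equivalent VCF v4.2 (GT:DP:GQ:AD over
#' all cohort samples), plus phenotypes, reference counts, evidence
#' codes, pedigrees (if any) and the JSON manifest.
#'
#' @param bundle A bundle as returned by [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(bundle$variants, file.path(out_dir, "variants.tsv"))
  samples <- if (!is.null(bundle$phenotypes))
    bundle$phenotypes$patient_id else
      sort(unique(bundle$variants$patient_id))
  write_vcf(bundle$variants, samples, file.path(out_dir, "variants.vcf"))
  if (!is.null(bundle$phenotypes)) {
    phen <- as.data.frame(bundle$phenotypes)
    phen$diagnosis <- phen$diagnosis_detail
    phen$diagnosis_detail <- NULL
    write.table(phen, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  write.table(as.data.frame(bundle$ref_counts),
              file.path(out_dir, "ref_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write.table(bundle$criteria, file.path(out_dir, "criteria.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(bundle$panel))
    write.table(as.data.frame(bundle$panel),
                file.path(out_dir, "panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# minimal VCF v4.2 emission over the full sample set
write_vcf <- function(x, samples, path) {
  stopifnot(inherits(x, "variant_calls"))
  uv <- unique_variants(x)
  ord <- order(suppressWarnings(as.integer(uv$chrom)), uv$chrom, uv$pos)
  uv <- uv[ord, , drop = FALSE]
  esc <- function(s) gsub("[;= ]", "_", s)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description=\"Transcript\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS cDNA\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Coding impact\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- character(nrow(uv))
  for (i in seq_len(nrow(uv))) {
    vid <- uv$variant_id[i]
    sub <- x[x$variant_id == vid, , drop = FALSE]
    gt <- setNames(rep("0/0:80:99:40,0", length(samples)), samples)
    for (j in seq_len(nrow(sub))) {
      dp <- if ("dp" %in% names(sub) && !is.na(sub$dp[j])) sub$dp[j] else 60
      gq <- if ("gq" %in% names(sub) && !is.na(sub$gq[j])) sub$gq[j] else 99
      ab <- if ("ab" %in% names(sub) && !is.na(sub$ab[j])) sub$ab[j] else
        if (sub$zygosity[j] == "hom") 1 else 0.5
      alt_reads <- round(dp * ab)
      g <- if (sub$zygosity[j] == "hom") "1/1" else "0/1"
      gt[sub$patient_id[j]] <- sprintf("%s:%d:%d:%d,%d", g, as.integer(dp),
                                       as.integer(gq),
                                       as.integer(dp - alt_reads),
                                       as.integer(alt_reads))
    }
    info <- sprintf("GENE=%s;TRANSCRIPT=%s;HGVSC=%s;HGVSP=%s;IMPACT=%s",
                    esc(uv$gene[i]),
                    ifelse(nzchar(uv$transcript[i]), esc(uv$transcript[i]), "."),
                    ifelse(nzchar(uv$hgvs_c[i]), esc(uv$hgvs_c[i]), "."),
                    ifelse(nzchar(uv$hgvs_p[i]), esc(uv$hgvs_p[i]), "."),
                    uv$coding_impact[i])
    body[i] <- paste(c(uv$chrom[i], uv$pos[i], ".", uv$ref[i], uv$alt[i],
                       ".", "PASS", info, "GT:DP:GQ:AD", gt),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' The packaged worked-example fixture
#'
#' A small, fully classified cohort bundle bundled with the package:
#' 13 P/LP variant calls in dominantly inherited panel genes over 12
#' unique carriers of a 128-patient cohort (one patient carries two
#' variants), their printed ACMG/AMP evidence sets and classifications,
#' carrier phenotypes, reference allele counts (synthetic except the
#' one published global frequency; see the file's documentation), and
#' reconstructed pedigrees for the two families with multi-generation
#' myeloma. Genomic coordinates are synthetic placeholders on the
#' correct chromosomes; HGVS strings are carried verbatim and never
#' parsed. Two evidence sets do not satisfy any standard combining
#' clause for their printed tier and are flagged `known_discrepancy`.
#'
#' @return A bundle list with elements `variants`, `phenotypes`,
#'   `pedigrees`, `ref_counts`, `criteria` (columns `variant_id`,
#'   `codes`, `printed_tier`, `known_discrepancy`, `note`), `panel`,
#'   `cohort_n` (128), `prefer_printed` (TRUE) and `pot1_onset_ages`
#'   (the four carriers' onset ages; the fourth is inferred from the
#'   published range maximum).
#' @export
fixture_table1 <- function() {
  ext <- function(f) system.file("extdata", f, package = "germscreen",
                                 mustWork = TRUE)
  variants <- read_variant_table(ext("table1_variants.tsv"), "tsv")
  criteria <- read.delim(ext("table1_criteria.tsv"), sep = "\t", quote = "",
                         check.names = FALSE,
                         colClasses = "character")
  criteria$known_discrepancy <- criteria$known_discrepancy == "yes"
  tier_map <- c(P = "pathogenic", LP = "likely_pathogenic", VUS = "VUS",
                LB = "likely_benign", B = "benign")
  criteria$printed_tier <- unname(tier_map[criteria$printed_tier])
  phenotypes <- read_phenotypes(ext("table1_phenotypes.tsv"))
  list(variants = variants,
       phenotypes = phenotypes,
       pedigrees = read_pedigree(ext("table1_pedigrees.ped")),
       ref_counts = read_reference_counts(
         ext("table1_ref_counts_synthetic.tsv")),
       criteria = criteria,
       panel = default_panel(),
       cohort_n = 128L,
       prefer_printed = TRUE,
       pot1_onset_ages = as.integer(
         phenotypes$age_at_diagnosis[phenotypes$pot1_carrier == "yes"]))
}

#' Replicate 2x2 carrier draws under a known generative odds ratio
#'
#' Samples per-replicate cohort and reference carrier counts as
#' independent binomials with the reference carrier probability `p0`
#' and the cohort probability implied by `true_or`, then runs the
#' package's association machinery on each table. Supports coverage
#' and type-I-error calibration of the Woolf interval and the Fisher
#' exact test.
#'
#' @param n_reps Number of replicates (>= 1).
#' @param true_or Generative odds ratio (1 = null).
#' @param seed Integer seed.
#' @param n_cohort Cohort size per replicate (default 200).
#' @param n_ref Reference subset size per replicate (default 20000).
#' @param p0 Reference carrier probability (default 0.1, the scale of
#'   panel-wide P/LP carriage in a predisposition screen).
#' @param correction Passed to [odds_ratio_woolf()].
#' @return Data.frame with one row per replicate: `a`, `b`, `c`, `d`,
#'   `or`, `ci_low`, `ci_high`, `p`, `covered` (CI contains `true_or`).
#' @export
simulate_null_and_enriched <- function(n_reps, true_or = 1, seed = 1L,
                                       n_cohort = 200L, n_ref = 20000L,
                                       p0 = 0.1, correction = FALSE) {
  stopifnot(n_reps >= 1, true_or > 0, p0 > 0, p0 < 1)
  set.seed(seed)
  o0 <- p0 / (1 - p0)
  p1 <- true_or * o0 / (1 + true_or * o0)
  # one (a, c) pair per replicate so replicate streams are
  # prefix-consistent across different n_reps
  a <- integer(n_reps); cc <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    a[i] <- rbinom(1, n_cohort, p1)
    cc[i] <- rbinom(1, n_ref, p0)
  }
  out <- data.frame(a = a, b = n_cohort - a, c = cc, d = n_ref - cc,
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, covered = NA)
  for (i in seq_len(n_reps)) {
    tab <- list(a = out$a[i], b = out$b[i], c = out$c[i], d = out$d[i])
    est <- odds_ratio_woolf(tab, correction = correction)
    out$or[i] <- est$or
    out$ci_low[i] <- est$ci_low
    out$ci_high[i] <- est$ci_high
    out$p[i] <- fisher_exact_p(tab)
    out$covered[i] <- if (is.na(est$or)) NA else
      (est$ci_low <= true_or && true_or <= est$ci_high)
  }
  out
}
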