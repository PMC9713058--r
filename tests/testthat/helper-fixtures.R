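# Shared builders and independent oracles for the test suite.

# small long-form call table builder
make_calls <- function(patient_id, gene, chrom = "1",
                       pos = seq_along(patient_id) * 1000L,
                       ref = "A", alt = "T",
                       coding_impact = "missense", zygosity = "het",
                       dp = NULL, gq = NULL, ab = NULL) {
  n <- length(patient_id)
  df <- data.frame(patient_id = patient_id,
                   chrom = rep_len(chrom, n), pos = rep_len(pos, n),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   gene = rep_len(gene, n), transcript = "", hgvs_c = "",
                   hgvs_p = "", coding_impact = rep_len(coding_impact, n),
                   zygosity = rep_len(zygosity, n),
                   stringsAsFactors = FALSE)
  if (!is.null(dp)) df$dp <- rep_len(dp, n)
  if (!is.null(gq)) df$gq <- rep_len(gq, n)
  if (!is.null(ab)) df$ab <- rep_len(ab, n)
  variant_calls(df)
}

make_ref <- function(...) {
  rows <- list(...)
  reference_counts(do.call(rbind, lapply(rows, function(r)
    data.frame(subset = r[[1]], n_individuals = as.integer(r[[2]]),
               variant_id = r[[3]], AC = as.integer(r[[4]]),
               AN = as.integer(r[[5]]), nHom = as.integer(r[[6]]),
               stringsAsFactors = FALSE))))
}

# independent oracle: two-sided Fisher p by exhaustive hypergeometric
# enumeration over all tables with the observed margins
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b          # cohort row total
  n <- c + d          # reference row total
  k <- a + c          # carrier column total
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent oracle: literal transcription of the published ACMG/AMP
# combining-rule table, evaluated from raw code strings
acmg_oracle <- function(codes) {
  pvs <- sum(codes == "PVS1")
  ps <- sum(grepl("^PS[1-4]$", codes))
  pm <- sum(grepl("^PM[1-6]$", codes))
  pp <- sum(grepl("^PP[1-5]$", codes))
  ba <- sum(codes == "BA1")
  bs <- sum(grepl("^BS[1-4]$", codes))
  bp <- sum(grepl("^BP[1-7]$", codes))
  patho <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_patho <-
    (pvs >= 1 && pm >= 1) || (ps >= 1 && pm >= 1) || (ps >= 1 && pp >= 2) ||
    pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2
  if ((patho || likely_patho) && (benign || likely_benign)) return("VUS")
  if (patho) return("pathogenic")
  if (likely_patho) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "VUS"
}

# a bundle emulating the study conditions: the packaged worked-example
# carriers (all AD) plus 15 additional heterozygous carriers of a
# pathogenic variant in a recessively inherited panel gene
ar_augmented_bundle <- function() {
  fx <- fixture_table1()
  ad_carriers <- unique(fx$variants$patient_id)
  extra <- setdiff(sprintf("X%02d", 1:20), ad_carriers)[1:15]
  ar_calls <- data.frame(
    patient_id = extra, chrom = "1", pos = 45330000L, ref = "C", alt = "T",
    gene = "MUTYH", transcript = "NM_001128425.2", hgvs_c = "c.1187G>A",
    hgvs_p = "p.Gly396Asp", coding_impact = "missense", zygosity = "het",
    stringsAsFactors = FALSE)
  vars <- variant_calls(rbind(as.data.frame(fx$variants)[
    names(ar_calls)], ar_calls))
  crit <- rbind(
    fx$criteria[c("variant_id", "codes", "printed_tier")],
    data.frame(variant_id = "1:45330000:C:T", codes = "PS3,PM1,PM2,PP3",
               printed_tier = "pathogenic", stringsAsFactors = FALSE))
  list(variants = vars, criteria = crit, ref_counts = fx$ref_counts,
       panel = fx$panel, cohort_n = 128L, prefer_printed = TRUE,
       phenotypes = fx$phenotypes, pedigrees = fx$pedigrees)
}

# minimal two-sample VCF writer for parser tests
write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               lines), path)
  path
}
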