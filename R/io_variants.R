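# Cohort variant-call tables: the canonical in-memory model is a long-form
# data.frame with one row per (variant, carrier) pair, class "variant_calls".

#' Recognised coding-impact classes
#'
#' The protein-level consequence vocabulary used throughout the pipeline.
#' Input terms are normalised case-insensitively; "splicing" and
#' "splice" map to `splice_site`, "stopgain" to `nonsense`,
#' "startloss"/"start-lost" to `start_lost`.
#'
#' @return Character vector of the canonical impact terms.
#' @export
coding_impacts <- function() {
  c("missense", "nonsense", "frameshift", "splice_site", "start_lost",
    "inframe_indel", "synonymous", "other")
}

# map free-text impact terms onto the canonical vocabulary
normalize_impact <- function(x) {
  key <- gsub("[ _-]", "", tolower(trimws(x)))
  map <- c(
    missense = "missense", nonsense = "nonsense", stopgain = "nonsense",
    frameshift = "frameshift", splicesite = "splice_site",
    splicing = "splice_site", splice = "splice_site",
    startlost = "start_lost", startloss = "start_lost",
    inframeindel = "inframe_indel", inframe = "inframe_indel",
    synonymous = "synonymous", silent = "synonymous", other = "other")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown coding impact term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Reduce a variant to its minimal (normalised) representation
#'
#' Trims the shared suffix, then the shared prefix, of ref and alt,
#' keeping at least one base of each and adjusting the position for
#' trimmed prefix bases. This yields a single canonical key per variant
#' so cohort and reference tables join on identical identifiers.
#' Left-alignment against a reference genome is out of scope; inputs
#' are assumed to be parsimony-aligned as emitted by standard callers.
#'
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings.
#' @return List with elements `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  stopifnot(length(pos) == 1, nchar(ref) >= 1, nchar(alt) >= 1)
  if (ref == alt) stop("ref and alt alleles are identical", call. = FALSE)
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # shared suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # shared prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Canonical variant identifier
#'
#' `"chrom:pos:ref:alt"` with 1-based VCF coordinates after
#' [normalize_variant()] trimming.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (vectorised).
#' @return Character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  out <- character(n)
  for (i in seq_len(n)) {
    v <- normalize_variant(pos[i], ref[i], alt[i])
    out[i] <- paste(chrom[i], v$pos, v$ref, v$alt, sep = ":")
  }
  out
}

VARIANT_TSV_COLS <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                      "transcript", "hgvs_c", "hgvs_p", "coding_impact",
                      "zygosity")

#' Construct a cohort variant-call table
#'
#' Validates and classes a long-form data.frame (one row per variant x
#' carrier) as `variant_calls`. Alleles are normalised to their minimal
#' representation and a `variant_id` column is added.
#'
#' @param df Data.frame with columns `patient_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `transcript`, `hgvs_c`, `hgvs_p`,
#'   `coding_impact`, `zygosity`; optional per-carrier metric columns
#'   `dp`, `gq`, `ab`.
#' @return A `variant_calls` data.frame.
#' @export
variant_calls <- function(df) {
  missing_cols <- setdiff(VARIANT_TSV_COLS, names(df))
  if (length(missing_cols))
    stop("variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$pos <- as.integer(df$pos)
  if (nrow(df)) {
    if (any(df$pos < 1)) stop("variant pos must be >= 1", call. = FALSE)
    if (any(df$ref == df$alt)) stop("ref == alt", call. = FALSE)
    df$coding_impact <- normalize_impact(df$coding_impact)
    bad_zyg <- setdiff(unique(df$zygosity), c("het", "hom"))
    if (length(bad_zyg))
      stop("zygosity must be het/hom, got: ",
           paste(bad_zyg, collapse = ", "), call. = FALSE)
    norm <- lapply(seq_len(nrow(df)),
                   function(i) normalize_variant(df$pos[i], df$ref[i], df$alt[i]))
    df$pos <- vapply(norm, `[[`, integer(1), "pos")
    df$ref <- vapply(norm, `[[`, character(1), "ref")
    df$alt <- vapply(norm, `[[`, character(1), "alt")
  }
  df$variant_id <- if (nrow(df))
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":") else character(0)
  dup <- duplicated(df[c("variant_id", "patient_id")])
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_calls", "data.frame")
  df
}

#' Read a cohort variant table (VCF v4.2 or TSV dialect)
#'
#' The TSV dialect is tab-delimited UTF-8 with a header row and columns
#' `patient_id, chrom, pos, ref, alt, gene, transcript, hgvs_c, hgvs_p,
#' coding_impact, zygosity`. VCF input must carry GT in FORMAT;
#' multi-allelic sites are decomposed into biallelic records, carriers
#' are samples with at least one alternate allele, and per-carrier
#' DP/GQ/AD metrics are propagated when present (`ab` is the alternate
#' allele fraction from AD). Gene/transcript/HGVS/impact annotations
#' are taken from the INFO keys `GENE`, `TRANSCRIPT`, `HGVSC`, `HGVSP`,
#' `IMPACT` when available.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A `variant_calls` data.frame.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", colClasses = "character",
                     check.names = FALSE, quote = "")
    missing_cols <- setdiff(VARIANT_TSV_COLS, names(df))
    if (length(missing_cols))
      stop("malformed variant TSV header (line 1): missing ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    for (m in intersect(c("dp", "gq", "ab"), names(df)))
      df[[m]] <- as.numeric(df[[m]])
    variant_calls(df)
  } else {
    read_vcf_calls(path)
  }
}

# VCF reading via vcfR; decomposes multi-allelic sites.
read_vcf_calls <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-variant VCF drops to vector
  if (is.null(fix) || nrow(fix) == 0)
    return(variant_calls(empty_variant_df()))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2)
    stop("VCF has no sample genotype columns (GT required)", call. = FALSE)
  samples <- colnames(gt_raw)[-1]
  as_mat <- function(m) if (is.null(dim(m))) t(m) else m
  gt <- as_mat(vcfR::extract.gt(vcf, element = "GT"))
  dp <- as_mat(suppressWarnings(vcfR::extract.gt(vcf, "DP",
                                                 as.numeric = TRUE)))
  gq <- as_mat(suppressWarnings(vcfR::extract.gt(vcf, "GQ",
                                                 as.numeric = TRUE)))
  ad <- as_mat(suppressWarnings(vcfR::extract.gt(vcf, "AD")))
  info_key <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_key("GENE"); tx <- info_key("TRANSCRIPT")
  hgvsc <- info_key("HGVSC"); hgvsp <- info_key("HGVSP")
  impact <- info_key("IMPACT")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    g_i <- gt[i, , drop = TRUE]
    for (k in seq_along(alts)) {
      alleles <- lapply(strsplit(ifelse(is.na(g_i), ".", g_i), "[/|]"),
                        function(z) suppressWarnings(as.integer(z)))
      n_alt <- vapply(alleles, function(z) sum(z == k, na.rm = TRUE),
                      integer(1))
      carriers <- samples[n_alt >= 1]
      if (!length(carriers)) next
      zyg <- ifelse(n_alt[n_alt >= 1] >= 2, "hom", "het")
      ab_i <- rep(NA_real_, length(carriers))
      if (!all(is.na(ad[i, ]))) {
        ad_car <- ad[i, carriers]
        ab_i <- vapply(ad_car, function(s) {
          if (is.na(s)) return(NA_real_)
          v <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
          if (length(v) < k + 1 || sum(v, na.rm = TRUE) == 0) return(NA_real_)
          v[k + 1] / sum(v, na.rm = TRUE)
        }, numeric(1))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = carriers, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[k],
        gene = if (is.na(gene[i])) "" else gene[i],
        transcript = if (is.na(tx[i])) "" else tx[i],
        hgvs_c = if (is.na(hgvsc[i])) "" else hgvsc[i],
        hgvs_p = if (is.na(hgvsp[i])) "" else hgvsp[i],
        coding_impact = if (is.na(impact[i])) "other" else impact[i],
        zygosity = zyg,
        dp = as.numeric(dp[i, carriers]),
        gq = as.numeric(gq[i, carriers]),
        ab = ab_i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(variant_calls(empty_variant_df()))
  variant_calls(do.call(rbind, rows))
}

empty_variant_df <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)),
                                   length(VARIANT_TSV_COLS)),
                               VARIANT_TSV_COLS))
  df$pos <- integer(0)
  df
}

#' Write a variant table in the TSV dialect
#'
#' @param x A `variant_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  stopifnot(inherits(x, "variant_calls"))
  write.table(as.data.frame(x)[, VARIANT_TSV_COLS, drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Unique-variant view of a call table
#'
#' Collapses the long-form table to one row per variant with the number
#' of distinct carriers.
#'
#' @param x A `variant_calls` data.frame.
#' @return Data.frame with one row per `variant_id` and an
#'   `n_carriers` column.
#' @export
unique_variants <- function(x) {
  stopifnot(inherits(x, "variant_calls"))
  if (!nrow(x)) {
    out <- as.data.frame(x)[, setdiff(names(x), c("patient_id", "zygosity",
                                                  "dp", "gq", "ab")), drop = FALSE]
    out$n_carriers <- integer(0)
    return(out)
  }
  first <- !duplicated(x$variant_id)
  out <- as.data.frame(x)[first, setdiff(names(x),
    c("patient_id", "zygosity", "dp", "gq", "ab")), drop = FALSE]
  cnt <- tapply(x$patient_id, x$variant_id,
                function(p) length(unique(p)))
  out$n_carriers <- as.integer(cnt[out$variant_id])
  rownames(out) <- NULL
  out
}

#' Number of distinct variants in a call table
#' @param x A `variant_calls` data.frame.
#' @return Integer count of unique variant identifiers.
#' @export
n_variants <- function(x) length(unique(x$variant_id))

#' @export
print.variant_calls <- function(x, ...) {
  cat("Cohort variant calls: ", n_variants(x), " variant(s), ",
      length(unique(x$patient_id)), " carrier(s), ",
      nrow(x), " carrier-variant pair(s)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
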