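# Reference allele-count tables, gene panels, phenotype tables, pedigrees.

#' Construct a reference population allele-count table
#'
#' Per-subset population counts keyed by `variant_id`, emulating
#' population databases that publish AC (alternate allele count), AN
#' (total allele number) and nHom (homozygote count) per variant for
#' strata such as a global and an ancestry-matched subset.
#'
#' @param df Data.frame with columns `subset`, `n_individuals`,
#'   `variant_id`, `AC`, `AN`, `nHom`.
#' @return A `ref_counts` data.frame with a `subsets` attribute (named
#'   integer vector of subset sizes).
#' @export
reference_counts <- function(df) {
  need <- c("subset", "n_individuals", "variant_id", "AC", "AN", "nHom")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("reference count table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (m in c("n_individuals", "AC", "AN", "nHom"))
    df[[m]] <- as.integer(df[[m]])
  if (any(df$AC < 0) || any(df$AC > df$AN))
    stop("invalid reference counts: need 0 <= AC <= AN", call. = FALSE)
  if (any(df$nHom > df$AC / 2))
    stop("invalid reference counts: nHom must be <= AC/2", call. = FALSE)
  if (any(df$AN > 2 * df$n_individuals))
    stop("invalid reference counts: AN exceeds 2 * n_individuals",
         call. = FALSE)
  sizes <- tapply(df$n_individuals, df$subset, function(v) {
    u <- unique(v)
    if (length(u) > 1)
      stop("inconsistent n_individuals within a subset", call. = FALSE)
    u
  })
  rownames(df) <- NULL
  class(df) <- c("ref_counts", "data.frame")
  attr(df, "subsets") <- vapply(sizes, as.integer, integer(1))
  df
}

#' Read a reference allele-count TSV
#'
#' Tab-delimited with header `subset, n_individuals, variant_id, AC,
#' AN, nHom`; invariants (0 <= AC <= AN, nHom <= AC/2,
#' AN <= 2 n_individuals) are enforced on read.
#'
#' @param path File path.
#' @return A `ref_counts` data.frame.
#' @export
read_reference_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reference_counts(read.delim(path, sep = "\t", quote = "",
                              check.names = FALSE))
}

#' Names of the reference subsets in a table
#' @param ref A `ref_counts` table.
#' @return Character vector of subset names.
#' @export
ref_subsets <- function(ref) names(attr(ref, "subsets"))

#' Look up one variant in one reference subset
#'
#' The default policy for variants absent from the table is
#' "absent-as-zero with flag": AC/nHom are 0, AN is twice the subset
#' size and `observed` is FALSE (matching the convention of reporting
#' "N/A" frequencies for unobserved variants while treating them as
#' rare). A listed variant with AN = 0 is treated as unobserved, with a
#' warning.
#'
#' @param ref A `ref_counts` table.
#' @param subset Subset name.
#' @param vid Variant identifier.
#' @param absent_as_zero Apply the absent-as-zero policy (default TRUE);
#'   otherwise an unlisted variant is an error.
#' @return List with `AC`, `AN`, `nHom`, `maf`, `observed`.
#' @export
ref_lookup <- function(ref, subset, vid, absent_as_zero = TRUE) {
  sizes <- attr(ref, "subsets")
  if (!subset %in% names(sizes))
    stop("unknown reference subset: ", subset, call. = FALSE)
  hit <- which(ref$subset == subset & ref$variant_id == vid)
  if (!length(hit)) {
    if (!absent_as_zero)
      stop("variant ", vid, " not in reference subset ", subset,
           call. = FALSE)
    return(list(AC = 0L, AN = 2L * sizes[[subset]], nHom = 0L, maf = 0,
                observed = FALSE))
  }
  i <- hit[1]
  if (ref$AN[i] == 0) {
    warning("variant ", vid, " listed with AN = 0 in subset ", subset,
            "; treated as unobserved", call. = FALSE)
    return(list(AC = 0L, AN = 2L * sizes[[subset]], nHom = 0L, maf = 0,
                observed = FALSE))
  }
  list(AC = ref$AC[i], AN = ref$AN[i], nHom = ref$nHom[i],
       maf = ref$AC[i] / ref$AN[i], observed = TRUE)
}

#' @export
print.ref_counts <- function(x, ...) {
  sizes <- attr(x, "subsets")
  cat("Reference allele counts:", nrow(x), "row(s) over",
      length(sizes), "subset(s)\n")
  for (s in names(sizes))
    cat("  ", s, ": n = ", sizes[[s]], ", ",
        sum(x$subset == s), " listed variant(s)\n", sep = "")
  invisible(x)
}

# ---- gene panel -------------------------------------------------------

PANEL_CATEGORIES <- c("MM_germline", "disease_biology", "DNA_repair",
                      "somatic_MM")

#' Construct a candidate gene panel
#'
#' @param df Data.frame with columns `gene`, `inheritance` (AD/AR/XL)
#'   and `category`.
#' @return A `gene_panel` data.frame.
#' @export
gene_panel <- function(df) {
  need <- c("gene", "inheritance", "category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("duplicate gene(s) in panel: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$inheritance), c("AD", "AR", "XL"))
  if (length(bad))
    stop("inheritance must be AD/AR/XL, got: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("gene_panel", "data.frame")
  df
}

#' Read a gene panel TSV (`gene`, `inheritance`, `category`)
#' @param path File path.
#' @return A `gene_panel` data.frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gene_panel(read.delim(path, sep = "\t", quote = "", check.names = FALSE))
}

#' Default myeloma predisposition candidate panel
#'
#' A compact stand-in for a full candidate list: the dominantly
#' inherited genes in which the screen's example cohort carries P/LP
#' variants, the base-excision-repair gene MUTYH as a recessive
#' example, and genes recurrently proposed as myeloma predisposition or
#' disease-biology candidates. Real analyses should supply their own
#' panel via [read_panel()].
#'
#' @return A `gene_panel` data.frame.
#' @export
default_panel <- function() {
  gene_panel(data.frame(
    gene = c("ATM", "ATR", "BRCA2", "CHEK2", "POT1", "PALB2",
             "MUTYH", "DIS3", "KDM1A", "ARID1A", "USP45", "EP300",
             "DCHS1", "KIF1B"),
    inheritance = c("AD", "AD", "AD", "AD", "AD", "AD",
                    "AR", "AD", "AD", "AD", "AD", "AD", "AD", "AD"),
    category = c("DNA_repair", "DNA_repair", "DNA_repair", "DNA_repair",
                 "MM_germline", "DNA_repair", "DNA_repair", "MM_germline",
                 "MM_germline", "MM_germline", "MM_germline", "MM_germline",
                 "MM_germline", "MM_germline"),
    stringsAsFactors = FALSE))
}

# ---- phenotypes -------------------------------------------------------

#' Read a patient phenotype TSV
#'
#' Columns: `patient_id`, `diagnosis`, `age_at_diagnosis`, `sex`,
#' `paraprotein`, `other_malignancies`, `family_history` (the last two
#' are semicolon-separated free text). `diagnosis` is mapped onto the
#' plasma-cell dyscrasia spectrum (`MM`, `sMM`, `MGUS`, `PCL`, `other`);
#' the verbatim label is kept in `diagnosis_detail`.
#'
#' @param path File path.
#' @return A `phenotypes` data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                   colClasses = "character")
  phenotype_table(df)
}

#' @rdname read_phenotypes
#' @param df Data.frame with the phenotype columns above.
#' @export
phenotype_table <- function(df) {
  need <- c("patient_id", "diagnosis", "age_at_diagnosis", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in phenotype table", call. = FALSE)
  df$age_at_diagnosis <- as.integer(df$age_at_diagnosis)
  if (any(!is.na(df$age_at_diagnosis) & df$age_at_diagnosis <= 0))
    stop("age_at_diagnosis must be positive", call. = FALSE)
  bad_sex <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bad_sex))
    stop("sex must be F/M, got: ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  df$diagnosis_detail <- df$diagnosis
  canon <- function(d) {
    lead <- toupper(trimws(strsplit(d, "[- ]")[[1]][1]))
    switch(lead, MM = "MM", SMM = "sMM", MGUS = "MGUS", PCL = "PCL",
           "other")
  }
  df$diagnosis <- vapply(df$diagnosis, canon, character(1), USE.NAMES = FALSE)
  for (opt in c("paraprotein", "other_malignancies", "family_history"))
    if (!opt %in% names(df)) df[[opt]] <- ""
  rownames(df) <- NULL
  class(df) <- c("phenotypes", "data.frame")
  df
}

# ---- pedigrees --------------------------------------------------------

#' Read pedigrees from a PED file
#'
#' Standard six-column PED core (`family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex`, `phenotype`) with optional
#' extension columns `diagnosis`, `tested_variant`, `tested_result`
#' (carrier / noncarrier / untested). A header row is optional and
#' detected by its first field. Founders have parent id "0". One
#' individual may appear on several rows to record genotypes for
#' several variants; the structural columns must agree. Unresolved
#' parent references, self-parenting and ancestor cycles are rejected.
#'
#' @param path File path.
#' @return A list of `pedigree` objects, one per family, named by
#'   family id.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  has_header <- grepl("^family_id\\b", lines[1])
  if (has_header) lines <- lines[-1]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("PED rows need >= 6 tab-separated fields (line ",
         which(nf < 6)[1] + has_header, ")", call. = FALSE)
  pad <- function(v) c(v, rep("", 9 - length(v)))[1:9]
  m <- do.call(rbind, lapply(fields, pad))
  df <- data.frame(family_id = m[, 1], individual_id = m[, 2],
                   father_id = m[, 3], mother_id = m[, 4], sex = m[, 5],
                   phenotype = m[, 6], diagnosis = m[, 7],
                   tested_variant = m[, 8], tested_result = m[, 9],
                   stringsAsFactors = FALSE)
  lapply(split(df, df$family_id), build_pedigree)[unique(df$family_id)]
}

build_pedigree <- function(df) {
  ids <- unique(df$individual_id)
  first <- df[!duplicated(df$individual_id), , drop = FALSE]
  # structural consistency across repeated rows
  for (col in c("father_id", "mother_id", "sex", "phenotype")) {
    agg <- tapply(df[[col]], df$individual_id,
                  function(v) length(unique(v)))
    if (any(agg > 1))
      stop("inconsistent ", col, " for individual(s) ",
           paste(names(agg)[agg > 1], collapse = ", "), call. = FALSE)
  }
  parents <- c(first$father_id, first$mother_id)
  unresolved <- setdiff(setdiff(parents, c("0", "")), ids)
  if (length(unresolved))
    stop("unresolved parent id(s) in family ", first$family_id[1], ": ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  if (any(first$individual_id == first$father_id |
          first$individual_id == first$mother_id))
    stop("individual listed as its own parent in family ",
         first$family_id[1], call. = FALSE)
  # cycle check: walk ancestors from every individual
  parent_of <- rbind(setNames(first$father_id, first$individual_id),
                     setNames(first$mother_id, first$individual_id))
  for (id in ids) {
    seen <- character(0)
    frontier <- id
    while (length(frontier)) {
      nxt <- setdiff(unique(as.vector(parent_of[, intersect(frontier, ids),
                                                drop = FALSE])), c("0", ""))
      if (id %in% nxt)
        stop("pedigree cycle: ", id, " is its own ancestor in family ",
             first$family_id[1], call. = FALSE)
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, nxt)
    }
  }
  geno <- df[nzchar(df$tested_variant),
             c("individual_id", "tested_variant", "tested_result"),
             drop = FALSE]
  if (nrow(geno)) {
    bad <- setdiff(unique(geno$tested_result),
                   c("carrier", "noncarrier", "untested"))
    if (length(bad))
      stop("tested_result must be carrier/noncarrier/untested, got: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  members <- first[, c("individual_id", "father_id", "mother_id", "sex",
                       "phenotype", "diagnosis"), drop = FALSE]
  members$affected <- members$phenotype == "2"
  rownames(members) <- NULL
  rownames(geno) <- NULL
  structure(list(family_id = first$family_id[1], members = members,
                 genotypes = geno),
            class = "pedigree")
}

#' Founders of a pedigree (members with no listed parents)
#' @param ped A `pedigree` object.
#' @return Character vector of individual ids.
#' @export
pedigree_founders <- function(ped) {
  m <- ped$members
  m$individual_id[(m$father_id %in% c("0", "")) &
                  (m$mother_id %in% c("0", ""))]
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree ", x$family_id, ": ", nrow(x$members), " member(s), ",
      sum(x$members$affected), " affected, ",
      length(pedigree_founders(x)), " founder(s)\n", sep = "")
  invisible(x)
}
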