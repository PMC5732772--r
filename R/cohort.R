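#' Read and join genotype and phenotype tables into a cohort
#'
#' Builds the per-subject analysis table from a genotype dosage TSV (or the
#' output of [read_vcf_dosages()]) and a phenotype/covariate TSV. The two
#' tables are inner-joined on `subject_id`; subjects on urate-lowering drugs
#' and subjects missing the exposure (serum urate) or outcome (total
#' bilirubin) are excluded, with all exclusions counted in a join report.
#'
#' Genotype dosages are counts (0/1/2, `NA` for missing) of the oriented,
#' urate-increasing effect allele of each instrument SNP; orientation by
#' allele identity is performed on the VCF path, so a dosage TSV must already
#' follow this convention.
#'
#' @param genotype Path to a genotype TSV (`subject_id` plus one 0/1/2/NA
#'   column per SNP), or a data frame of the same shape.
#' @param phenotype Path to a phenotype TSV with columns `subject_id`, `age`,
#'   `sex` (male/female/M/F), `bmi`, `fbg`, `bun`, `su`, `tbil`,
#'   `urate_lowering_drug` (0/1/true/false), or an equivalent data frame.
#' @param weights A `snp_weights` table; every `snp_id` must be a genotype
#'   column.
#' @return A `cohort_table` data frame (one row per retained subject) with a
#'   `join_report` attribute: counts of input rows, joined rows, exclusions
#'   per reason and retained rows; and a `snp_ids` attribute naming the
#'   dosage columns.
#' @export
read_cohort <- function(genotype, phenotype, weights) {
  geno <- if (is.data.frame(genotype)) genotype else
    utils::read.delim(genotype, stringsAsFactors = FALSE)
  pheno <- if (is.data.frame(phenotype)) phenotype else
    utils::read.delim(phenotype, stringsAsFactors = FALSE)

  if (!"subject_id" %in% names(geno)) stop("genotype table lacks subject_id")
  if (!"subject_id" %in% names(pheno)) stop("phenotype table lacks subject_id")
  geno$subject_id <- as.character(geno$subject_id)
  pheno$subject_id <- as.character(pheno$subject_id)
  if (anyDuplicated(geno$subject_id))
    stop("duplicate subject_id in genotype table")
  if (anyDuplicated(pheno$subject_id))
    stop("duplicate subject_id in phenotype table")

  snp_ids <- weights$snp_id
  absent <- setdiff(snp_ids, names(geno))
  if (length(absent) > 0L) {
    stop("instrument SNP(s) absent from genotype columns: ",
         paste(absent, collapse = ", "))
  }
  for (s in snp_ids) {
    d <- geno[[s]]
    if (!is.numeric(d)) d <- suppressWarnings(as.numeric(d))
    bad <- which(!is.na(d) & !d %in% c(0, 1, 2))
    if (length(bad) > 0L) {
      stop("invalid dosage ", geno[[s]][bad[1L]], " for subject ",
           geno$subject_id[bad[1L]], ", SNP ", s, " (must be 0, 1, 2 or NA)")
    }
    geno[[s]] <- as.integer(d)
  }

  pheno_cols <- c("age", "sex", "bmi", "fbg", "bun", "su", "tbil",
                  "urate_lowering_drug")
  missing_cols <- setdiff(pheno_cols, names(pheno))
  if (length(missing_cols) > 0L) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("age", "bmi", "fbg", "bun", "su", "tbil")) {
    v <- pheno[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad) > 0L) {
        stop("non-numeric value '", v[bad[1L]], "' in phenotype column ", col,
             " for subject ", pheno$subject_id[bad[1L]])
      }
      pheno[[col]] <- num
    }
  }
  pheno$sex <- parse_sex(pheno$sex, pheno$subject_id)
  pheno$urate_lowering_drug <-
    parse_flag(pheno$urate_lowering_drug, pheno$subject_id)

  cohort <- merge(geno[c("subject_id", snp_ids)],
                  pheno[c("subject_id", pheno_cols)],
                  by = "subject_id", sort = TRUE)

  n_joined <- nrow(cohort)
  on_drug <- cohort$urate_lowering_drug %in% TRUE
  cohort <- cohort[!on_drug, , drop = FALSE]
  miss_xy <- is.na(cohort$su) | is.na(cohort$tbil)
  cohort <- cohort[!miss_xy, , drop = FALSE]

  if (any(cohort$su <= 0)) stop("non-positive serum urate in phenotype table")
  if (any(cohort$tbil <= 0)) stop("non-positive bilirubin in phenotype table")
  rownames(cohort) <- NULL

  as_cohort_table(
    cohort, snp_ids,
    join_report = list(n_genotype = nrow(geno), n_phenotype = nrow(pheno),
                       n_joined = n_joined,
                       n_drug_excluded = sum(on_drug),
                       n_missing_exposure_outcome = sum(miss_xy),
                       n_retained = nrow(cohort)))
}

parse_sex <- function(x, ids) {
  out <- c(male = "male", m = "male", female = "female", f = "female")[
    tolower(as.character(x))]
  if (anyNA(out)) {
    stop("unrecognised sex value '", x[which(is.na(out))[1L]],
         "' for subject ", ids[which(is.na(out))[1L]])
  }
  unname(out)
}

parse_flag <- function(x, ids) {
  out <- c(`0` = FALSE, `1` = TRUE, `true` = TRUE, `false` = FALSE)[
    tolower(as.character(x))]
  if (anyNA(out)) {
    stop("unrecognised urate_lowering_drug value '",
         x[which(is.na(out))[1L]], "' for subject ",
         ids[which(is.na(out))[1L]])
  }
  unname(out)
}

as_cohort_table <- function(df, snp_ids, join_report = NULL) {
  structure(df, class = c("cohort_table", "data.frame"),
            snp_ids = snp_ids, join_report = join_report)
}

#' @export
print.cohort_table <- function(x, ...) {
  snp_ids <- attr(x, "snp_ids")
  cat("Cohort table: ", nrow(x), " subjects, ", length(snp_ids),
      " instrument SNP(s) [", paste(snp_ids, collapse = ", "), "]\n", sep = "")
  rep <- attr(x, "join_report")
  if (!is.null(rep)) {
    cat("  joined ", rep$n_joined, "; excluded ", rep$n_drug_excluded,
        " on urate-lowering drugs, ", rep$n_missing_exposure_outcome,
        " missing exposure/outcome; retained ", rep$n_retained, "\n", sep = "")
  }
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Write a cohort table to TSV
#'
#' Serialises a `cohort_table` so that [read_cohort_table()] reproduces it
#' exactly: numeric columns are written with 17 significant digits (enough to
#' round-trip a double).
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "NA"
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#'
#' @param path Path to the TSV.
#' @param snp_ids Dosage column names; by default every column that is not a
#'   phenotype/covariate column.
#' @return A `cohort_table`.
#' @export
read_cohort_table <- function(path, snp_ids = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  pheno_cols <- c("subject_id", "age", "sex", "bmi", "fbg", "bun", "su",
                  "tbil", "urate_lowering_drug")
  if (is.null(snp_ids)) snp_ids <- setdiff(names(df), pheno_cols)
  for (s in snp_ids) df[[s]] <- as.integer(df[[s]])
  as_cohort_table(df, snp_ids)
}

#' Extract effect-allele dosages from a biallelic VCF
#'
#' Parses the GT field of a VCF (v4.x) and returns, for each instrument SNP
#' matched by rsID in the ID column, the per-subject dosage of the oriented
#' effect allele. Sites are matched against the weight table's alleles: if
#' the effect allele is the ALT allele the ALT count is the dosage, if it is
#' the REF allele the dosage is `2 - ALT count`. Missing genotypes (`./.`)
#' give missing dosages. Multiallelic sites, sites with unmatched rsIDs and
#' sites whose alleles do not match the weight table are skipped with a
#' warning count.
#'
#' @param vcf_path Path to the VCF.
#' @param weights A `snp_weights` table (oriented; see [read_weights()]).
#' @return A genotype data frame (`subject_id` plus one dosage column per
#'   matched SNP) suitable for [read_cohort()], with a `vcf_report` attribute
#'   counting matched and skipped sites.
#' @export
read_vcf_dosages <- function(vcf_path, weights) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  subjects <- colnames(gt)

  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  n_skipped <- 0L
  for (i in seq_len(nrow(weights))) {
    snp <- weights$snp_id[i]
    row <- which(fix$ID == snp)
    if (length(row) == 0L) next
    row <- row[1L]
    ref <- fix$REF[row]
    alt <- fix$ALT[row]
    if (is.na(alt) || grepl(",", alt) || nchar(ref) != 1L || nchar(alt) != 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    alt_count <- gt_alt_count(gt[row, ])
    ea <- weights$effect_allele[i]
    dosage <- if (identical(ea, alt)) {
      alt_count
    } else if (identical(ea, ref)) {
      2L - alt_count
    } else {
      n_skipped <- n_skipped + 1L
      next
    }
    out[[snp]] <- dosage
  }
  matched <- intersect(weights$snp_id, names(out))
  if (length(matched) == 0L) {
    stop("no instrument SNP found in VCF ", vcf_path)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " site(s) skipped (multiallelic or allele mismatch)")
  }
  structure(out, vcf_report = list(n_matched = length(matched),
                                   n_skipped = n_skipped))
}

gt_alt_count <- function(gt) {
  vapply(strsplit(gt, "[/|]"), function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == "." | a == "")) {
      return(NA_integer_)
    }
    sum(a != "0")
  }, integer(1L))
}

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  snp_ids <- attr(cohort, "snp_ids")
  if (is.null(snp_ids)) stop("cohort lacks a snp_ids attribute")
  if (anyDuplicated(cohort$subject_id)) stop("duplicate subject_id in cohort")
  for (s in snp_ids) {
    d <- cohort[[s]]
    if (any(!is.na(d) & !d %in% c(0L, 1L, 2L))) {
      stop("dosage outside {0,1,2,NA} for SNP ", s)
    }
  }
  if (any(cohort$su <= 0, na.rm = TRUE)) stop("non-positive serum urate")
  if (any(cohort$tbil <= 0, na.rm = TRUE)) stop("non-positive bilirubin")
  invisible(cohort)
}
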