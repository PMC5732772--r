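#' Read a SNP instrument weight table
#'
#' Loads per-SNP instrument weights (per-allele effects on serum urate,
#' umol/L) from a tab-separated file with header columns `snp_id`,
#' `effect_allele`, `weight` and, optionally, `other_allele`.
#'
#' By default every SNP is oriented to its urate-increasing allele: a row with
#' a negative weight has its effect and other alleles swapped and the absolute
#' weight taken, so the resulting risk score is monotone in genetic urate
#' burden. Signed weights can be kept as-is (`orient = FALSE`) for sensitivity
#' analyses that reproduce a literal signed-beta score.
#'
#' @param path Path to the weights TSV.
#' @param orient Orient all weights to the urate-increasing allele
#'   (default `TRUE`). Flipping a SNP requires an `other_allele` column so the
#'   oriented allele identity is known.
#' @return A `data.frame` of class `snp_weights` with columns `snp_id`,
#'   `effect_allele`, `other_allele` (`NA` if absent in the file), `weight`
#'   and `flipped`, plus a `load_report` attribute recording the number of
#'   SNPs loaded and flipped.
#' @seealso [default_weights()] for the weight set shipped with the package.
#' @export
read_weights <- function(path, orient = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("snp_id", "effect_allele", "weight")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("weights file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("weights file ", path, " has no rows")
  if (!"other_allele" %in% names(tab)) tab$other_allele <- NA_character_

  w <- suppressWarnings(as.numeric(tab$weight))
  if (anyNA(w)) {
    stop("non-numeric weight for SNP ", tab$snp_id[which(is.na(w))[1L]])
  }
  tab$weight <- w
  validate_weights(tab)

  tab$flipped <- FALSE
  if (orient) {
    flip <- tab$weight < 0
    if (any(flip)) {
      if (anyNA(tab$other_allele[flip])) {
        stop("cannot orient SNP(s) ",
             paste(tab$snp_id[flip & is.na(tab$other_allele)], collapse = ", "),
             ": negative weight but no other_allele column to flip to")
      }
      ea <- tab$effect_allele
      tab$effect_allele[flip] <- tab$other_allele[flip]
      tab$other_allele[flip] <- ea[flip]
      tab$weight[flip] <- abs(tab$weight[flip])
      tab$flipped <- flip
    }
  }

  structure(tab[c("snp_id", "effect_allele", "other_allele",
                  "weight", "flipped")],
            class = c("snp_weights", "data.frame"),
            load_report = list(n_loaded = nrow(tab),
                               n_flipped = sum(tab$flipped),
                               oriented = orient))
}

validate_weights <- function(tab) {
  if (anyDuplicated(tab$snp_id)) {
    stop("duplicate snp_id in weights: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
  }
  if (any(tab$weight == 0)) {
    stop("zero weight for SNP ",
         paste(tab$snp_id[tab$weight == 0], collapse = ", "),
         ": an uninformative instrument")
  }
  alleles <- c(tab$effect_allele, tab$other_allele[!is.na(tab$other_allele)])
  bad <- !grepl("^[ACGTacgt]$", alleles)
  if (any(bad)) {
    stop("invalid allele code(s): ", paste(unique(alleles[bad]), collapse = ", "),
         " (expected a single base A/C/G/T)")
  }
  invisible(tab)
}

#' Default urate-transporter instrument weights
#'
#' Returns the four-SNP urate-transporter weight set shipped with the package:
#' rs1481012 and rs2231137 (*ABCG2*), rs16890979 (*SLC2A9*) and rs3799352
#' (*SLC17A1*), with literature-reported per-allele effects on serum urate of
#' 27.555, -16.945, -24.654 and -7.456 umol/L. The file stores the signed
#' effects; loading orients each SNP to its urate-increasing allele by
#' default.
#'
#' The allele labels in the shipped file are nominal placeholders (the effect
#' sizes were published without allele annotations): they make orientation and
#' VCF matching well-defined for simulated data, but analyses of real
#' genotypes must supply a weight file carrying the study's actual effect
#' alleles.
#'
#' @inheritParams read_weights
#' @return A `snp_weights` data frame; see [read_weights()].
#' @examples
#' w <- default_weights()
#' # maximum attainable weighted score: every dosage at 2
#' 2 * sum(w$weight)
#' @export
default_weights <- function(orient = TRUE) {
  read_weights(system.file("extdata", "urate_snp_weights.tsv",
                           package = "uratemr", mustWork = TRUE),
               orient = orient)
}
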