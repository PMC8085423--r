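# Input/output: pedigrees, trio genotypes from VCF, exposure tables, and the
# tab-delimited per-SNP summary-statistics format.

#' Assemble a trio genotype matrix
#'
#' Container for effect-allele dosages of complete case-parent trios: three
#' integer matrices (SNP x trio) for child, mother and father, plus SNP and
#' trio annotation. Dosages are counts of the effect allele in 0/1/2 with `NA`
#' for missing calls.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `snp_id`,
#'   `effect_allele`, `other_allele` and optionally `imputation_r2`.
#' @param trios data.frame with columns `trio_id`, `child_id`, `mother_id`,
#'   `father_id` (see [read_pedigree()]).
#' @param child,mother,father Integer matrices, `nrow(snps)` x `nrow(trios)`.
#' @return An object of class `trio_matrix`.
#' @export
trio_matrix <- function(snps, trios, child, mother, father) {
  stopifnot(is.data.frame(snps), is.data.frame(trios))
  dims <- c(nrow(snps), nrow(trios))
  for (m in list(child, mother, father)) {
    stopifnot(identical(dim(m), as.integer(dims)))
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(snps$imputation_r2)) snps$imputation_r2 <- NA_real_
  structure(list(snps = snps, trios = trios, child = child, mother = mother,
                 father = father),
            class = "trio_matrix")
}

#' @export
print.trio_matrix <- function(x, ...) {
  cat(sprintf("trio_matrix: %d SNPs x %d complete trios\n",
              nrow(x$snps), nrow(x$trios)))
  invisible(x)
}

#' Read a 6-column pedigree file into case-parent trios
#'
#' Accepts the classic whitespace-delimited pre-MAKEPED pedigree dialect with
#' columns family, individual, father, mother, sex, phenotype. Each family
#' must describe one affected child (phenotype 2) with both parents present in
#' the file; families missing any member (parent ID "0" or absent individual)
#' are skipped with a message. Sex and phenotype are read but only used to
#' locate the affected child.
#'
#' @param path Pedigree file path.
#' @return data.frame with one row per complete trio: `trio_id`, `child_id`,
#'   `mother_id`, `father_id`, `n_skipped` attribute listing skipped families.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop(sprintf("malformed pedigree line %d: expected 6 fields, found %d",
                 which(nf != 6L)[1L], nf[nf != 6L][1L]))
  }
  ped <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(ped) <- c("family", "individual", "father", "mother", "sex", "phenotype")
  if (anyDuplicated(ped$individual)) {
    stop("duplicate individual ID in pedigree: ",
         ped$individual[duplicated(ped$individual)][1L])
  }
  skipped <- character(0)
  rows <- list()
  for (fam in unique(ped$family)) {
    p <- ped[ped$family == fam, , drop = FALSE]
    child <- p[p$father != "0" & p$mother != "0" & p$phenotype == "2", ,
               drop = FALSE]
    ok <- nrow(child) == 1L &&
      all(c(child$father, child$mother) %in% p$individual)
    if (!ok) {
      skipped <- c(skipped, fam)
      next
    }
    rows[[fam]] <- data.frame(trio_id = fam, child_id = child$individual,
                              mother_id = child$mother,
                              father_id = child$father,
                              stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " incomplete famil",
            if (length(skipped) == 1L) "y" else "ies", ": ",
            paste(skipped, collapse = ", "))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trio_id = character(0), child_id = character(0),
               mother_id = character(0), father_id = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_families") <- skipped
  out
}

.autosome_labels <- c(as.character(1:22), paste0("chr", 1:22))

.gt_to_dosage <- function(gt) {
  # "0/1", "0|1", "./." -> count of ALT alleles
  d <- rep(NA_integer_, length(gt))
  gt <- sub(":.*", "", gt)
  d[gt %in% c("0/0", "0|0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  d
}

#' Read trio genotypes from a VCF file
#'
#' Consumes biallelic autosomal records from a (plain or bgzipped) VCF and
#' returns effect-allele dosage matrices for child, mother and father of each
#' trio. Multiallelic and non-autosomal records are skipped and counted.
#' Genotypes `./.` become missing.
#'
#' @param path VCF path.
#' @param trios Pedigree data.frame from [read_pedigree()]; all member IDs
#'   must appear in the VCF sample header.
#' @param effect_allele_rule `"ALT"` (default) counts the ALT allele;
#'   `"minor-in-founders"` orients each SNP so the effect allele is the minor
#'   allele among parents (ALT kept on ties).
#' @return A [trio_matrix()]; attribute `skipped` carries counts of skipped
#'   records by reason.
#' @export
read_vcf_to_trios <- function(path, trios,
                              effect_allele_rule = c("ALT", "minor-in-founders")) {
  effect_allele_rule <- match.arg(effect_allele_rule)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)

  need <- unique(c(trios$child_id, trios$mother_id, trios$father_id))
  missing_ids <- setdiff(need, colnames(gt))
  if (length(missing_ids)) {
    stop("pedigree sample IDs absent from VCF header: ",
         paste(missing_ids, collapse = ", "))
  }

  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) & nzchar(fix$ALT) &
    fix$ALT != "."
  autosomal <- fix$CHROM %in% .autosome_labels
  keep <- biallelic & autosomal
  skipped <- c(multiallelic = sum(!biallelic),
               non_autosomal = sum(biallelic & !autosomal))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  dose <- function(ids) {
    m <- matrix(.gt_to_dosage(gt[, ids, drop = FALSE]),
                nrow = nrow(gt), ncol = length(ids))
    m
  }
  child <- dose(trios$child_id)
  mother <- dose(trios$mother_id)
  father <- dose(trios$father_id)

  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS), fix$ID),
                     effect_allele = fix$ALT, other_allele = fix$REF,
                     imputation_r2 = .info_r2(fix$INFO),
                     stringsAsFactors = FALSE)

  if (effect_allele_rule == "minor-in-founders") {
    eaf <- .parental_eaf(trio_matrix(snps, trios, child, mother, father))
    flip <- !is.na(eaf) & eaf > 0.5
    if (any(flip)) {
      tmp <- snps$effect_allele[flip]
      snps$effect_allele[flip] <- snps$other_allele[flip]
      snps$other_allele[flip] <- tmp
      child[flip, ] <- 2L - child[flip, ]
      mother[flip, ] <- 2L - mother[flip, ]
      father[flip, ] <- 2L - father[flip, ]
    }
  }

  out <- trio_matrix(snps, trios, child, mother, father)
  attr(out, "skipped") <- skipped
  out
}

# Parse R2= from a VCF INFO string (imputation quality), NA when absent.
.info_r2 <- function(info) {
  if (is.null(info)) return(NA_real_)
  r2 <- suppressWarnings(as.numeric(sub(".*(?:^|;)R2=([0-9.eE+-]+).*", "\\1",
                                        info, perl = TRUE)))
  r2[!grepl("(^|;)R2=", info)] <- NA_real_
  r2
}

#' Read a per-trio exposure table
#'
#' Expects a delimited file with columns `trio_id`, `exposure_name`,
#' `exposed` where exposed is 0, 1 or NA. Missing exposures are preserved:
#' such trios are excluded only from analyses of that exposure. Exposure
#' names outside smoking/alcohol/vitamin are retained and classed as "other".
#'
#' @param path TSV/whitespace-delimited file path.
#' @return data.frame `trio_id`, `exposure_name`, `exposed` (integer 0/1/NA),
#'   `exposure_class`.
#' @export
read_exposure_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "."), colClasses = "character")
  need <- c("trio_id", "exposure_name", "exposed")
  if (!all(need %in% names(tab))) {
    stop("exposure table must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(tab$trio_id, tab$exposure_name, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate exposure record for trio '%s', exposure '%s'",
                 d$trio_id, d$exposure_name))
  }
  exposed <- suppressWarnings(as.integer(tab$exposed))
  if (any(!is.na(exposed) & !exposed %in% 0:1)) {
    stop("exposed must be 0, 1 or NA")
  }
  data.frame(trio_id = tab$trio_id, exposure_name = tab$exposure_name,
             exposed = exposed,
             exposure_class = ifelse(tab$exposure_name %in%
                                       c("smoking", "alcohol", "vitamin"),
                                     tab$exposure_name, "other"),
             stringsAsFactors = FALSE)
}

#' Summarize exposure prevalence over a set of trios
#'
#' Counts trios with a non-missing record for the exposure and the exposed
#' subset, reporting the percentage rounded to the nearest integer the way
#' study descriptive tables print it.
#'
#' @param trios Pedigree data.frame (its `trio_id` column defines the
#'   denominator universe).
#' @param exposures Exposure table from [read_exposure_table()].
#' @param exposure_name Exposure to summarize.
#' @return list `n_nonmissing`, `n_exposed`, `pct_exposed` (NA with a warning
#'   when no trio has a non-missing record).
#' @export
summarize_exposure <- function(trios, exposures, exposure_name) {
  ex <- exposures[exposures$exposure_name == exposure_name &
                    exposures$trio_id %in% trios$trio_id, , drop = FALSE]
  e <- ex$exposed[!is.na(ex$exposed)]
  n_nonmissing <- length(e)
  n_exposed <- sum(e == 1L)
  if (n_nonmissing == 0L) {
    warning("no non-missing records for exposure '", exposure_name, "'")
    pct <- NA_real_
  } else {
    pct <- round(100 * n_exposed / n_nonmissing)
  }
  list(n_nonmissing = n_nonmissing, n_exposed = n_exposed, pct_exposed = pct)
}

.summary_cols <- c("CHR", "POS", "ID", "EA", "OA", "EAF_PARENTS",
                   "N_INFORMATIVE", "N_EXPOSED", "BETA_G", "SE_G", "BETA_GE",
                   "SE_GE", "COV_G_GE", "CHISQ_1DF", "P_1DF", "CHISQ_2DF",
                   "P_2DF", "FLAG_GENOMEWIDE", "FLAG_SUGGESTIVE")

#' Write per-SNP gTDT summary statistics
#'
#' Tab-delimited, one row per SNP, numeric fields rendered with 17 significant
#' digits so that a write/read round trip is lossless; missing values as "NA".
#'
#' @param results data.frame from [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_summary_stats()]
#' @export
write_summary_stats <- function(results, path) {
  miss <- setdiff(.summary_cols, names(results))
  if (length(miss)) stop("missing summary columns: ", paste(miss, collapse = ", "))
  out <- results[, .summary_cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1L))
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read per-SNP summary statistics written by [write_summary_stats()]
#'
#' @param path Summary-statistics TSV path.
#' @return data.frame with the canonical column set and types.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(CHR = "character", ID = "character",
                                          EA = "character", OA = "character"))
  miss <- setdiff(.summary_cols, names(tab))
  if (length(miss)) {
    stop("file ", path, " lacks summary columns: ", paste(miss, collapse = ", "))
  }
  tab
}
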