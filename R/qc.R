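# Per-SNP quality control: parental MAF, call missingness, Mendelian error
# rate, exact Hardy-Weinberg test among founders, imputation quality.

#' Default per-SNP QC thresholds
#'
#' All thresholds are applied with strict inequality in the failing direction:
#' a SNP fails when parental MAF < `maf_min`, missingness > `miss_max`,
#' Mendelian error rate > `mendel_max`, founder HWE exact p < `hwe_p_min`, or
#' (imputed SNPs only) imputation R2 < `r2_min`.
#'
#' @param maf_min,miss_max,mendel_max,hwe_p_min,r2_min Numeric thresholds.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(maf_min = 0.05, miss_max = 0.05, mendel_max = 0.05,
                          hwe_p_min = 1e-4, r2_min = 0.3) {
  list(maf_min = maf_min, miss_max = miss_max, mendel_max = mendel_max,
       hwe_p_min = hwe_p_min, r2_min = r2_min)
}

#' Mendelian consistency of a biallelic trio genotype
#'
#' A child dosage is consistent when it can be formed by one allele from each
#' parent. Vectorized over trios.
#'
#' @param gm,gf,gc Non-missing dosages in 0/1/2 (mother, father, child).
#' @return Logical vector.
#' @examples
#' mendelian_consistent(0, 0, 1) # FALSE
#' mendelian_consistent(2, 0, 1) # TRUE (obligate heterozygote)
#' @export
mendelian_consistent <- function(gm, gf, gc) {
  if (anyNA(c(gm, gf, gc))) stop("missing genotypes: drop before calling")
  stopifnot(all(gm %in% 0:2), all(gf %in% 0:2), all(gc %in% 0:2))
  lo <- (gm == 2) + (gf == 2)
  hi <- (gm >= 1) + (gf >= 1)
  gc >= lo & gc <= hi
}

#' Exact Hardy-Weinberg test among founders
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Well defined at low
#' counts where the chi-square approximation is not. Monomorphic SNPs return
#' p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Founder genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_founders <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one founder genotype required")
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  # P(het = h | n, allele counts) over h with the parity of `rare`
  h <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (rare + h) / 2) + h * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP quality-control report
#'
#' Computes for every SNP the parental minor-allele frequency (founders only,
#' each parent counted once), the genotype missingness over all trio members,
#' the Mendelian error rate among fully genotyped trios, the exact HWE p-value
#' among founders and, for imputed SNPs, the imputation R2 check.
#'
#' @param tm A [trio_matrix()].
#' @param thresholds List from [qc_thresholds()].
#' @return data.frame, one row per SNP: `snp_id`, `parental_maf`,
#'   `missing_rate`, `mendel_error_rate`, `hwe_p`, `imputation_r2`, `passed`,
#'   `fail_reasons` (comma-separated subset of MAF, MISS, MENDEL, HWE, INFO;
#'   empty when passed).
#' @export
snp_qc <- function(tm, thresholds = qc_thresholds()) {
  stopifnot(inherits(tm, "trio_matrix"))
  n_snps <- nrow(tm$snps)
  n_trios <- nrow(tm$trios)

  founder_n <- rowSums(!is.na(tm$mother)) + rowSums(!is.na(tm$father))
  eaf <- .parental_eaf(tm)
  maf <- pmin(eaf, 1 - eaf)

  n_miss <- rowSums(is.na(tm$child)) + rowSums(is.na(tm$mother)) +
    rowSums(is.na(tm$father))
  missing_rate <- n_miss / (3 * n_trios)

  complete <- !(is.na(tm$child) | is.na(tm$mother) | is.na(tm$father))
  lo <- (tm$mother == 2) + (tm$father == 2)
  hi <- (tm$mother >= 1) + (tm$father >= 1)
  inconsistent <- complete & !(tm$child >= lo & tm$child <= hi)
  n_complete <- rowSums(complete)
  mendel_rate <- ifelse(n_complete > 0,
                        rowSums(inconsistent, na.rm = TRUE) / n_complete, 0)

  hwe_p <- vapply(seq_len(n_snps), function(i) {
    g <- c(tm$mother[i, ], tm$father[i, ])
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    hwe_exact_founders(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1L))

  r2 <- tm$snps$imputation_r2
  if (is.null(r2)) r2 <- rep(NA_real_, n_snps)

  reasons <- character(n_snps)
  add <- function(reasons, bad, code) {
    ifelse(bad, ifelse(nzchar(reasons), paste(reasons, code, sep = ","), code),
           reasons)
  }
  no_founders <- founder_n == 0
  reasons <- add(reasons, no_founders | (!is.na(maf) & maf < thresholds$maf_min), "MAF")
  reasons <- add(reasons, no_founders | missing_rate > thresholds$miss_max, "MISS")
  reasons <- add(reasons, mendel_rate > thresholds$mendel_max, "MENDEL")
  reasons <- add(reasons, !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min, "HWE")
  reasons <- add(reasons, !is.na(r2) & r2 < thresholds$r2_min, "INFO")
  # a SNP with no genotyped founders fails MISS only (MAF undefined)
  reasons[no_founders] <- "MISS"

  data.frame(snp_id = tm$snps$snp_id, parental_maf = maf,
             missing_rate = missing_rate, mendel_error_rate = mendel_rate,
             hwe_p = hwe_p, imputation_r2 = r2,
             passed = !nzchar(reasons), fail_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Apply a QC report to a trio genotype matrix
#'
#' Retains passing SNPs in their original order. At retained SNPs, any
#' residual Mendelian-inconsistent trio has its three genotypes set missing at
#' that SNP (the trio is kept elsewhere), so downstream pseudo-control
#' construction is always defined.
#'
#' @param tm A [trio_matrix()].
#' @param reports QC report aligned with `tm$snps` (from [snp_qc()]).
#' @return list with `matrix` (filtered `trio_matrix`) and `log` (data.frame
#'   of per-reason removal counts plus the unique-SNP total and the number of
#'   trio-genotype sets masked for residual Mendelian inconsistency).
#' @export
apply_qc <- function(tm, reports) {
  stopifnot(inherits(tm, "trio_matrix"),
            identical(reports$snp_id, tm$snps$snp_id))
  keep <- reports$passed
  reason_list <- strsplit(reports$fail_reasons[!keep], ",", fixed = TRUE)
  per_reason <- table(factor(unlist(reason_list),
                             levels = c("MAF", "MISS", "MENDEL", "HWE", "INFO")))

  child <- tm$child[keep, , drop = FALSE]
  mother <- tm$mother[keep, , drop = FALSE]
  father <- tm$father[keep, , drop = FALSE]

  complete <- !(is.na(child) | is.na(mother) | is.na(father))
  lo <- (mother == 2) + (father == 2)
  hi <- (mother >= 1) + (father >= 1)
  mask <- complete & !(child >= lo & child <= hi)
  n_masked <- sum(mask, na.rm = TRUE)
  child[mask] <- NA_integer_
  mother[mask] <- NA_integer_
  father[mask] <- NA_integer_

  log <- data.frame(
    metric = c(paste0("removed_", names(per_reason)), "removed_unique_snps",
               "snps_retained", "trio_genotypes_masked_mendel"),
    count = c(as.integer(per_reason), sum(!keep), sum(keep), n_masked),
    stringsAsFactors = FALSE
  )
  list(matrix = trio_matrix(tm$snps[keep, , drop = FALSE], tm$trios,
                            child, mother, father),
       log = log)
}

#' Write a QC log/report to TSV
#'
#' One row per SNP mirroring the [snp_qc()] report; thresholds are echoed in a
#' leading comment line.
#'
#' @param reports data.frame from [snp_qc()].
#' @param path Output path.
#' @param thresholds Thresholds to echo.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(reports, path, thresholds = qc_thresholds()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# thresholds: ",
                    paste(names(thresholds), unlist(thresholds),
                          sep = "=", collapse = " ")), con)
  utils::write.table(reports, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
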