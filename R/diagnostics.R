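# Genomic-control diagnostics and plotting-ready QQ / Manhattan tables.

#' Genomic inflation factor (median-based)
#'
#' `lambda = median(chisq) / median of the null chi-square distribution`
#' (0.4549364 for 1 df, 2*log(2) for 2 df). Values near 1 indicate calibrated
#' tests; inflation above ~1.1 suggests confounding or technical artifacts.
#'
#' @param chisq Observed test statistics; `NA` dropped with their count
#'   recorded.
#' @param df Degrees of freedom of the test (1 or 2).
#' @return list `lambda`, `df`, `n_tests`, `n_dropped`.
#' @export
lambda_gc <- function(chisq, df = 1L) {
  stopifnot(df %in% c(1L, 2L))
  n_dropped <- sum(is.na(chisq))
  chisq <- chisq[!is.na(chisq)]
  if (length(chisq) == 0L) stop("no finite test statistics")
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = df)
  list(lambda = lambda, df = as.integer(df), n_tests = length(chisq),
       n_dropped = n_dropped)
}

#' Quantile-quantile table of p-values
#'
#' Expected quantile for rank k of n is `(k - 0.5)/n`; both axes on the
#' -log10 scale, sorted by the expected value. Duplicated p-values are kept.
#'
#' @param p P-values in (0, 1]; `NA` dropped.
#' @return data.frame `expected`, `observed` (-log10 scale).
#' @export
qq_table <- function(p) {
  p <- p[!is.na(p)]
  stopifnot(all(p > 0), all(p <= 1))
  n <- length(p)
  # rank k (ascending p) pairs with expected quantile (k - 0.5)/n
  d <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                  observed = -log10(sort(p)))
  d <- d[order(d$expected), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Manhattan-plot table with cumulative genome coordinates
#'
#' Lays SNPs on a single axis: the cumulative coordinate is the within-
#' chromosome position plus the summed observed lengths (maximum position) of
#' all preceding chromosomes. Flags use strict inequalities, so a p-value
#' exactly at a threshold is not flagged.
#'
#' @param results data.frame with columns CHR, POS and a p-value column.
#' @param p_col Name of the p-value column (default "P_1DF").
#' @param genomewide,suggestive Thresholds for the two flags.
#' @return data.frame `CHR`, `POS`, `cum_pos`, `neglog10p`, `genomewide`,
#'   `suggestive`, sorted by (chromosome, position).
#' @export
manhattan_table <- function(results, p_col = "P_1DF",
                            genomewide = 5e-8, suggestive = 1e-6) {
  stopifnot(all(c("CHR", "POS", p_col) %in% names(results)))
  d <- results[order(.chrom_rank(results$CHR), results$POS), , drop = FALSE]
  chrom <- as.character(d$CHR)
  chr_levels <- unique(chrom)
  chr_len <- vapply(chr_levels, function(cc) max(d$POS[chrom == cc]),
                    numeric(1L))
  offset <- c(0, cumsum(chr_len))[seq_along(chr_levels)]
  names(offset) <- chr_levels
  p <- d[[p_col]]
  data.frame(CHR = chrom, POS = d$POS, cum_pos = d$POS + offset[chrom],
             neglog10p = -log10(p),
             genomewide = as.integer(!is.na(p) & p < genomewide),
             suggestive = as.integer(!is.na(p) & p < suggestive),
             row.names = NULL, stringsAsFactors = FALSE)
}
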