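# Conditional-logistic gTDT: pseudo-control construction, exposure-stratified
# estimation of (beta_G, beta_GE), and 1 df / 2 df Wald tests.

# Lookup table over the 27 ordered (g_mother, g_father, g_child) dosage triples.
# Index k = 9*gm + 3*gf + gc + 1.  For Mendelian-consistent triples it stores the
# case dosage and the three pseudo-control dosages (the four ordered transmission
# combinations minus one instance equal to the case genotype).
.trio_cat <- local({
  G4 <- matrix(NA_real_, 27L, 4L)
  consistent <- logical(27L)
  informative <- logical(27L)
  for (gm in 0:2) {
    am <- switch(gm + 1L, c(0L, 0L), c(1L, 0L), c(1L, 1L))
    for (gf in 0:2) {
      af <- switch(gf + 1L, c(0L, 0L), c(1L, 0L), c(1L, 1L))
      combos <- as.vector(outer(am, af, "+")) # ordered: m1f1, m2f1, m1f2, m2f2
      for (gc in 0:2) {
        k <- 9L * gm + 3L * gf + gc + 1L
        if (!gc %in% combos) next
        consistent[k] <- TRUE
        pseudo <- combos[-match(gc, combos)]
        G4[k, ] <- c(gc, pseudo)
        informative[k] <- length(unique(combos)) > 1L
      }
    }
  }
  list(G4 = G4, consistent = consistent, informative = informative)
})

.cat_index <- function(gm, gf, gc) 9L * gm + 3L * gf + gc + 1L

#' Construct pseudo-controls for one trio at one SNP
#'
#' Enumerates the four ordered transmission combinations (each parent passes
#' each of its two alleles once) and removes one instance equal to the observed
#' case genotype; the remaining three dosages are the matched pseudo-controls
#' of the conditional logistic likelihood.
#'
#' @param gm,gf,gc Dosages of the effect allele (0, 1 or 2) for mother, father
#'   and affected child. Must be Mendelian-consistent and non-missing.
#' @return A list of class `pseudo_controls` with elements `g0` (case dosage),
#'   `pseudo` (three pseudo-control dosages) and `informative` (`FALSE` when
#'   all four transmission combinations give the same dosage, in which case the
#'   trio contributes nothing to the likelihood).
#' @examples
#' build_pseudo_controls(1, 1, 2) # pseudo-controls 0, 1, 1
#' @export
build_pseudo_controls <- function(gm, gf, gc) {
  stopifnot(length(gm) == 1L, length(gf) == 1L, length(gc) == 1L)
  if (anyNA(c(gm, gf, gc))) stop("missing genotype: pre-filter before calling")
  if (!all(c(gm, gf, gc) %in% 0:2)) stop("dosages must be 0, 1 or 2")
  k <- .cat_index(gm, gf, gc)
  if (!.trio_cat$consistent[k]) {
    stop(sprintf("Mendelian-inconsistent trio: gm=%d gf=%d gc=%d", gm, gf, gc))
  }
  structure(list(g0 = .trio_cat$G4[k, 1L], pseudo = .trio_cat$G4[k, 2:4],
                 informative = .trio_cat$informative[k]),
            class = "pseudo_controls")
}

#' Conditional probability of the case genotype within its matched set
#'
#' Probability that the affected child carries its observed genotype rather
#' than one of the three pseudo-control genotypes, under the conditional
#' logistic model with additive dosage coding:
#' exp(bG*g0 + bGE*g0*e) / sum_l exp(bG*gl + bGE*gl*e).
#'
#' @param g0 Case dosage.
#' @param pseudo A `pseudo_controls` object or a numeric vector of the three
#'   pseudo-control dosages.
#' @param e Binary exposure indicator (0/1).
#' @param beta_g,beta_ge Log relative-risk parameters.
#' @return A probability; the four probabilities over the matched set sum to 1.
#' @export
conditional_prob <- function(g0, pseudo, e, beta_g, beta_ge) {
  if (inherits(pseudo, "pseudo_controls")) pseudo <- pseudo$pseudo
  if (!all(is.finite(c(beta_g, beta_ge)))) stop("non-finite parameters")
  g <- c(g0, pseudo)
  eta <- beta_g * g + beta_ge * g * e
  eta <- eta - max(eta)
  exp(eta[1L]) / sum(exp(eta))
}

# Recode a matrix of additive dosages under a genetic model.
.recode_model <- function(G, model) {
  switch(model,
         additive = G,
         dominant = (G > 0) + 0,
         recessive = (G == 2) + 0,
         stop("unknown genetic model: ", model))
}

# Newton-Raphson maximizer of the conditional log-likelihood for one stratum,
# on category counts (length-27 tabulation of consistent (gm,gf,gc) triples).
# Start 0, |score| < 1e-10, max 50 iterations, step-halving, |beta| > 15 flags
# separation.
.fit_counts <- function(counts, model = "additive") {
  keep <- .trio_cat$consistent & counts > 0
  G <- .recode_model(.trio_cat$G4[keep, , drop = FALSE], model)
  w <- counts[keep]
  # informativeness under the *recoded* dosages
  inf <- rowSums(G != G[, 1L]) > 0
  G <- G[inf, , drop = FALSE]
  w <- w[inf]
  n_inf <- sum(w)
  out <- list(beta = NA_real_, se = NA_real_, loglik = 0,
              n_informative = as.integer(n_inf), converged = FALSE,
              separation = 0L, estimable = FALSE)
  if (n_inf == 0) return(out)

  ll_parts <- function(b) {
    eta <- b * G
    m <- apply(eta, 1L, max)
    W <- exp(eta - m)
    S <- rowSums(W)
    mu <- rowSums(W * G) / S
    v <- rowSums(W * G^2) / S - mu^2
    list(ll = sum(w * (eta[, 1L] - (m + log(S)))),
         score = sum(w * (G[, 1L] - mu)),
         info = sum(w * v))
  }

  beta <- 0
  cur <- ll_parts(beta)
  for (it in seq_len(50L)) {
    if (abs(cur$score) < 1e-10) {
      out$beta <- beta
      out$se <- 1 / sqrt(cur$info)
      out$loglik <- cur$ll
      out$converged <- TRUE
      out$estimable <- TRUE
      return(out)
    }
    step <- cur$score / cur$info
    new_beta <- beta + step
    nxt <- ll_parts(new_beta)
    # halve only on a genuine decrease; near the optimum the log-likelihood is
    # flat to rounding and the full Newton step must be accepted
    ll_tol <- 1e-10 * (abs(cur$ll) + 1)
    halvings <- 0L
    while (nxt$ll < cur$ll - ll_tol && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- ll_parts(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    cur <- nxt
    if (abs(beta) > 15) {
      out$beta <- sign(beta) * Inf
      out$loglik <- cur$ll
      out$separation <- as.integer(sign(beta))
      return(out)
    }
  }
  out$beta <- beta
  out$loglik <- cur$ll
  out
}

.counts_from_trios <- function(gm, gf, gc) {
  ok <- !(is.na(gm) | is.na(gf) | is.na(gc))
  gm <- gm[ok]; gf <- gf[ok]; gc <- gc[ok]
  k <- .cat_index(gm, gf, gc)
  bad <- !.trio_cat$consistent[k]
  if (any(bad)) {
    stop(sprintf("%d Mendelian-inconsistent trio(s); filter or set missing first",
                 sum(bad)))
  }
  tabulate(k, nbins = 27L)
}

#' Fit the gene-only conditional logistic model (gTDT) in one stratum
#'
#' Maximizes the conditional log-likelihood of the case versus its three
#' pseudo-controls with a single per-allele log relative risk, by
#' Newton-Raphson on the concave log-likelihood. In the classical limit where
#' every trio has exactly one heterozygous parent, the estimate reduces to
#' `log(b/c)` with `se^2 = 1/b + 1/c` for `b` transmissions and `c`
#' non-transmissions of the effect allele.
#'
#' @param gm,gf,gc Integer dosage vectors (one element per trio) for mother,
#'   father, child. Trios with any missing dosage are dropped;
#'   Mendelian-inconsistent trios are an error (pre-filter with
#'   [mendelian_consistent()] or [apply_qc()]).
#' @param model Genetic model used to recode dosages before likelihood
#'   evaluation: `"additive"` (default), `"dominant"` or `"recessive"`.
#' @return A list with `beta`, `se`, `loglik`, `n_informative`, `converged`,
#'   `separation` (-1/0/+1; nonzero when the estimate diverges, e.g. the effect
#'   allele is always or never transmitted from heterozygous parents) and
#'   `estimable`.
#' @export
fit_main_only <- function(gm, gf, gc, model = "additive") {
  .fit_counts(.counts_from_trios(gm, gf, gc), model = model)
}

#' Fit the gene plus gene-by-exposure conditional logistic model
#'
#' Because the exposure is binary and constant within a trio, the conditional
#' likelihood factorizes over exposure strata: the gene-only model fitted to
#' unexposed trios gives `beta_u`, to exposed trios gives `beta_e`, and the
#' model parameters are `beta_g = beta_u`, `beta_ge = beta_e - beta_u` with
#' `se_ge^2 = se_u^2 + se_e^2` and `cov(beta_g, beta_ge) = -se_u^2`. This
#' reproduces the closed-form efficiency of the stratified gTDT while
#' returning the full covariance needed by the 2 df joint test.
#'
#' @inheritParams fit_main_only
#' @param exposure Binary vector (0/1/NA), one element per trio; trios with
#'   missing exposure are excluded from this fit only.
#' @return An object of class `gxe_fit`: `beta_g`, `beta_ge`, `se_g`, `se_ge`,
#'   `cov_g_ge`, `loglik`, `n_informative_unexposed`, `n_informative_exposed`,
#'   `converged`, `estimable_ge`.
#' @export
fit_gxe <- function(gm, gf, gc, exposure, model = "additive") {
  stopifnot(length(exposure) == length(gm))
  keep <- !is.na(exposure)
  u <- keep & exposure == 0
  x <- keep & exposure == 1
  fit_u <- fit_main_only(gm[u], gf[u], gc[u], model = model)
  fit_x <- fit_main_only(gm[x], gf[x], gc[x], model = model)

  estimable_ge <- fit_u$estimable && fit_x$estimable
  structure(list(
    beta_g = fit_u$beta,
    beta_ge = if (estimable_ge) fit_x$beta - fit_u$beta else NA_real_,
    se_g = fit_u$se,
    se_ge = if (estimable_ge) sqrt(fit_u$se^2 + fit_x$se^2) else NA_real_,
    cov_g_ge = if (estimable_ge) -fit_u$se^2 else NA_real_,
    loglik = fit_u$loglik + fit_x$loglik,
    n_informative_unexposed = fit_u$n_informative,
    n_informative_exposed = fit_x$n_informative,
    converged = fit_u$converged && (fit_x$n_informative == 0L || fit_x$converged),
    estimable_ge = estimable_ge
  ), class = "gxe_fit")
}

.chisq_p <- function(chisq, df) stats::pchisq(chisq, df = df, lower.tail = FALSE)

#' 1 df Wald test of the gene-by-exposure interaction
#'
#' Tests H0: beta_GE = 0 with `chisq = (beta_ge/se_ge)^2` on 1 df. This is the
#' test used to focus exclusively on interaction, ignoring the genetic main
#' effect.
#'
#' @param fit A `gxe_fit` from [fit_gxe()].
#' @return A list of class `gtdt_test` with `chisq`, `df = 1` and `p`
#'   (upper-tail chi-square); `p` is `NA` when the interaction is not
#'   estimable or the fit did not converge.
#' @export
wald_1df <- function(fit) {
  stopifnot(inherits(fit, "gxe_fit"))
  if (!isTRUE(fit$converged) || !isTRUE(fit$estimable_ge)) {
    return(structure(list(chisq = NA_real_, df = 1L, p = NA_real_),
                     class = "gtdt_test"))
  }
  chisq <- (fit$beta_ge / fit$se_ge)^2
  structure(list(chisq = chisq, df = 1L, p = .chisq_p(chisq, 1L)),
            class = "gtdt_test")
}

#' 2 df Wald test of gene and gene-by-exposure effects jointly
#'
#' Tests H0: beta_G = 0 and beta_GE = 0 with
#' `chisq = b' V^{-1} b`, `V = [[se_g^2, cov], [cov, se_ge^2]]`, on 2 df.
#' Sensitive to a genetic main effect, an interaction, or both. Under the
#' stratified parameterization the statistic equals
#' `beta_u^2/se_u^2 + beta_e^2/se_e^2`.
#'
#' @param fit A `gxe_fit` from [fit_gxe()].
#' @return A `gtdt_test` list with `chisq`, `df = 2`, `p`; `NA` when the
#'   covariance matrix is unavailable or singular.
#' @export
wald_2df <- function(fit) {
  stopifnot(inherits(fit, "gxe_fit"))
  bad <- structure(list(chisq = NA_real_, df = 2L, p = NA_real_),
                   class = "gtdt_test")
  if (!isTRUE(fit$converged) || !isTRUE(fit$estimable_ge)) return(bad)
  V <- matrix(c(fit$se_g^2, fit$cov_g_ge, fit$cov_g_ge, fit$se_ge^2), 2L, 2L)
  if (!all(is.finite(V)) || det(V) <= 0) return(bad)
  b <- c(fit$beta_g, fit$beta_ge)
  chisq <- drop(t(b) %*% solve(V, b))
  structure(list(chisq = chisq, df = 2L, p = .chisq_p(chisq, 2L)),
            class = "gtdt_test")
}

#' Genome-wide gTDT scan for gene-by-exposure interaction
#'
#' Runs [fit_gxe()], [wald_1df()] and [wald_2df()] at every SNP of a trio
#' genotype matrix for one named exposure. Mendelian-inconsistent trios at a
#' SNP are treated as missing at that SNP (see [apply_qc()]); trios with
#' missing exposure are excluded throughout; SNPs where the fit is not
#' estimable are reported with `NA` statistics, never dropped.
#'
#' @param tm A `trio_matrix` (see [read_vcf_to_trios()] or [simulate_study()]).
#' @param exposures An exposure table as returned by [read_exposure_table()].
#' @param exposure_name Name of the exposure to analyze.
#' @param model Genetic model passed to the likelihood ("additive" default).
#' @param genomewide,suggestive Significance thresholds (strict `<`) used for
#'   the output flags, applied to the 1 df interaction p-value.
#' @return A data.frame with one row per SNP: CHR, POS, ID, EA, OA,
#'   EAF_PARENTS, N_INFORMATIVE, N_EXPOSED, BETA_G, SE_G, BETA_GE, SE_GE,
#'   COV_G_GE, CHISQ_1DF, P_1DF, CHISQ_2DF, P_2DF, FLAG_GENOMEWIDE,
#'   FLAG_SUGGESTIVE.
#' @export
scan_genome <- function(tm, exposures, exposure_name, model = "additive",
                        genomewide = 5e-8, suggestive = 1e-6) {
  stopifnot(inherits(tm, "trio_matrix"))
  ex <- exposures[exposures$exposure_name == exposure_name, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown exposure: ", exposure_name)
  e <- ex$exposed[match(tm$trios$trio_id, ex$trio_id)]

  n_snps <- nrow(tm$snps)
  idx <- .cat_index(tm$mother, tm$father, tm$child) # NA propagates
  idx[!is.na(idx) & !.trio_cat$consistent[pmax(idx, 1L)]] <- NA_integer_

  u_cols <- which(!is.na(e) & e == 0)
  x_cols <- which(!is.na(e) & e == 1)
  n_exposed <- length(x_cols)

  res <- vector("list", n_snps)
  for (i in seq_len(n_snps)) {
    row_idx <- idx[i, ]
    cu <- tabulate(row_idx[u_cols], nbins = 27L)
    cx <- tabulate(row_idx[x_cols], nbins = 27L)
    fit_u <- .fit_counts(cu, model = model)
    fit_x <- .fit_counts(cx, model = model)
    estimable_ge <- fit_u$estimable && fit_x$estimable
    fit <- structure(list(
      beta_g = fit_u$beta,
      beta_ge = if (estimable_ge) fit_x$beta - fit_u$beta else NA_real_,
      se_g = fit_u$se,
      se_ge = if (estimable_ge) sqrt(fit_u$se^2 + fit_x$se^2) else NA_real_,
      cov_g_ge = if (estimable_ge) -fit_u$se^2 else NA_real_,
      loglik = fit_u$loglik + fit_x$loglik,
      n_informative_unexposed = fit_u$n_informative,
      n_informative_exposed = fit_x$n_informative,
      converged = fit_u$converged && (fit_x$n_informative == 0L || fit_x$converged),
      estimable_ge = estimable_ge
    ), class = "gxe_fit")
    t1 <- wald_1df(fit)
    t2 <- wald_2df(fit)
    res[[i]] <- c(fit$n_informative_unexposed + fit$n_informative_exposed,
                  fit$beta_g, fit$se_g, fit$beta_ge, fit$se_ge, fit$cov_g_ge,
                  t1$chisq, t1$p, t2$chisq, t2$p)
  }
  m <- do.call(rbind, res)

  out <- data.frame(
    CHR = tm$snps$chrom,
    POS = tm$snps$pos,
    ID = tm$snps$snp_id,
    EA = tm$snps$effect_allele,
    OA = tm$snps$other_allele,
    EAF_PARENTS = .parental_eaf(tm),
    N_INFORMATIVE = as.integer(m[, 1L]),
    N_EXPOSED = n_exposed,
    BETA_G = m[, 2L], SE_G = m[, 3L],
    BETA_GE = m[, 4L], SE_GE = m[, 5L], COV_G_GE = m[, 6L],
    CHISQ_1DF = m[, 7L], P_1DF = m[, 8L],
    CHISQ_2DF = m[, 9L], P_2DF = m[, 10L],
    stringsAsFactors = FALSE
  )
  out$BETA_G[!is.finite(out$BETA_G)] <- NA_real_
  out$FLAG_GENOMEWIDE <- as.integer(!is.na(out$P_1DF) & out$P_1DF < genomewide)
  out$FLAG_SUGGESTIVE <- as.integer(!is.na(out$P_1DF) & out$P_1DF < suggestive)
  out
}

# Effect-allele frequency among founders (each parent counted once).
.parental_eaf <- function(tm) {
  num <- rowSums(tm$mother, na.rm = TRUE) + rowSums(tm$father, na.rm = TRUE)
  den <- 2 * (rowSums(!is.na(tm$mother)) + rowSums(!is.na(tm$father)))
  ifelse(den > 0, num / den, NA_real_)
}

#' Reconstruct a Wald test from a published relative risk and 95\% CI
#'
#' Back-computes the log relative risk, its standard error and a two-sided
#' normal p-value from a printed relative risk with 95\% confidence limits:
#' `beta = log(RR)`, `se = (log(U) - log(L)) / (2 * 1.959964)`. Useful for
#' checking published interaction results against their reported p-values.
#'
#' @param rr Relative risk estimate.
#' @param lower,upper 95\% confidence limits.
#' @return A list with `beta`, `se`, `z`, `chisq` and two-sided `p`.
#' @export
wald_from_rr_ci <- function(rr, lower, upper) {
  stopifnot(rr > 0, lower > 0, upper > lower)
  beta <- log(rr)
  se <- (log(upper) - log(lower)) / (2 * 1.959964)
  z <- beta / se
  list(beta = beta, se = se, z = z, chisq = z^2,
       p = 2 * stats::pnorm(-abs(z)))
}
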