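# Independent oracles used to validate the package implementation.
# These deliberately use different algorithms from the package code paths.

# Joint 2-parameter maximizer of the conditional gTDT likelihood by direct
# numerical optimization (BFGS on the negative log-likelihood), against which
# the exposure-stratified closed forms are checked.
oracle_fit_gxe <- function(gm, gf, gc, exposure) {
  keep <- !is.na(exposure)
  gm <- gm[keep]; gf <- gf[keep]; gc <- gc[keep]; e <- exposure[keep]
  sets <- lapply(seq_along(gm), function(i) {
    pc <- build_pseudo_controls(gm[i], gf[i], gc[i])
    if (!pc$informative) return(NULL)
    list(g = c(pc$g0, pc$pseudo), e = e[i])
  })
  sets <- Filter(Negate(is.null), sets)
  negll <- function(par) {
    -sum(vapply(sets, function(s) {
      eta <- par[1L] * s$g + par[2L] * s$g * s$e
      eta[1L] - (max(eta) + log(sum(exp(eta - max(eta)))))
    }, numeric(1L)))
  }
  neggrad <- function(par) {
    g2 <- vapply(sets, function(s) {
      eta <- par[1L] * s$g + par[2L] * s$g * s$e
      w <- exp(eta - max(eta))
      mu <- sum(w * s$g) / sum(w)
      c(s$g[1L] - mu, (s$g[1L] - mu) * s$e)
    }, numeric(2L))
    -rowSums(g2)
  }
  opt <- stats::optim(c(0, 0), negll, gr = neggrad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  # restart to polish: BFGS can stop early along flat directions
  for (k in 1:2) {
    opt <- stats::optim(opt$par, negll, gr = neggrad, method = "BFGS",
                        hessian = k == 2L,
                        control = list(reltol = 1e-15, maxit = 1000))
  }
  V <- solve(opt$hessian)
  list(beta_g = opt$par[1L], beta_ge = opt$par[2L], cov = V,
       loglik = -opt$value)
}

# Exact HWE conditional distribution by direct combinatorial enumeration with
# choose() and 2^h (no log-factorials); valid for founder totals <= 200.
oracle_hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  h_vals <- seq(rare %% 2, rare, by = 2)
  ways <- vapply(h_vals, function(h) {
    n_rare_hom <- (rare - h) / 2
    choose(n, n_rare_hom) * choose(n - n_rare_hom, h) * 2^h
  }, numeric(1L))
  p <- ways / sum(ways)
  p_obs <- p[match(n_het, h_vals)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# Mendelian consistency by exhaustive enumeration of the four transmission
# combinations.
oracle_mendel_consistent <- function(gm, gf, gc) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  any(outer(alleles(gm), alleles(gf), "+") == gc)
}

# Small deterministic synthetic SNP: parents HWE at `maf`, child by
# ascertained conditional sampling; returns dosage vectors.
random_trio_snp <- function(n, maf = 0.3, beta_g = 0, beta_ge = 0,
                            exposure_rate = 0.5) {
  e <- stats::rbinom(n, 1L, exposure_rate)
  gm <- stats::rbinom(n, 2L, maf)
  gf <- stats::rbinom(n, 2L, maf)
  gc <- sample_case_genotype(gm, gf, e, beta_g, beta_ge)
  list(gm = gm, gf = gf, gc = gc, e = e)
}

# Summary-stats row builder for meta/harmonization tests.
sumstats_row <- function(chr, pos, id, ea, oa, beta_g, se_g, beta_ge, se_ge,
                         cov = -se_g^2, eaf = 0.3) {
  z <- beta_ge / se_ge
  p1 <- stats::pchisq(z^2, 1, lower.tail = FALSE)
  data.frame(CHR = as.character(chr), POS = pos, ID = id, EA = ea, OA = oa,
             EAF_PARENTS = eaf, N_INFORMATIVE = 100L, N_EXPOSED = 30L,
             BETA_G = beta_g, SE_G = se_g, BETA_GE = beta_ge, SE_GE = se_ge,
             COV_G_GE = cov, CHISQ_1DF = z^2, P_1DF = p1,
             CHISQ_2DF = z^2 + (beta_g / se_g)^2,
             P_2DF = stats::pchisq(z^2 + (beta_g / se_g)^2, 2,
                                   lower.tail = FALSE),
             FLAG_GENOMEWIDE = as.integer(p1 < 5e-8),
             FLAG_SUGGESTIVE = as.integer(p1 < 1e-6),
             stringsAsFactors = FALSE)
}
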