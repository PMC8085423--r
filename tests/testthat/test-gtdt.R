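# Pseudo-control construction, conditional likelihood, stratified closed-form
# estimation and Wald tests.

test_that("pseudo-control multiset and sum rule hold for every consistent triple", {
  for (gm in 0:2) for (gf in 0:2) for (gc in 0:2) {
    if (!oracle_mendel_consistent(gm, gf, gc)) {
      expect_error(build_pseudo_controls(gm, gf, gc), "inconsistent")
      next
    }
    pc <- build_pseudo_controls(gm, gf, gc)
    all4 <- c(pc$g0, pc$pseudo)
    expect_equal(sum(all4), 2 * (gm + gf),
                 info = sprintf("gm=%d gf=%d gc=%d", gm, gf, gc))
    # multiset equals the 4 ordered transmission combinations
    alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    combos <- as.vector(outer(alleles(gm), alleles(gf), "+"))
    expect_equal(sort(all4), sort(combos))
    expect_equal(pc$informative, length(unique(combos)) > 1L)
  }
  expect_equal(sort(build_pseudo_controls(1, 1, 2)$pseudo), c(0, 1, 1))
  expect_equal(sort(build_pseudo_controls(2, 1, 1)$pseudo), c(1, 2, 2))
  expect_false(build_pseudo_controls(0, 0, 0)$informative)
})

test_that("conditional probabilities are correct and sum to one over the matched set", {
  # uniform at the null
  expect_equal(conditional_prob(2, c(0, 1, 1), 0, 0, 0), 0.25)
  # worked arithmetic: weights (2, 1, 4, 4) -> 2/11
  expect_equal(conditional_prob(1, c(0, 2, 2), 0, log(2), 0), 2 / 11)
  # exposure symmetry: beta_ge acts like beta_g in the exposed stratum
  expect_equal(conditional_prob(1, c(0, 2, 2), 1, 0, log(2)),
               conditional_prob(1, c(0, 2, 2), 0, log(2), 0))
  set.seed(1)
  for (i in 1:50) {
    gm <- sample(0:2, 1); gf <- sample(0:2, 1)
    alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    combos <- as.vector(outer(alleles(gm), alleles(gf), "+"))
    gc <- sample(combos, 1)
    pc <- build_pseudo_controls(gm, gf, gc)
    bg <- rnorm(1); bge <- rnorm(1); e <- rbinom(1, 1, 0.5)
    total <- conditional_prob(pc$g0, pc$pseudo, e, bg, bge)
    for (j in 1:3) {
      total <- total + conditional_prob(pc$pseudo[j], c(pc$g0, pc$pseudo[-j]),
                                        e, bg, bge)
    }
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("fit_main_only reproduces the single-heterozygous-parent TDT limit", {
  b <- 20L; c_ <- 10L
  gm <- rep(1L, b + c_); gf <- rep(0L, b + c_)
  gc <- c(rep(1L, b), rep(0L, c_))
  fit <- fit_main_only(gm, gf, gc)
  expect_true(fit$converged)
  expect_equal(fit$beta, log(b / c_), tolerance = 1e-9)
  expect_equal(fit$se, sqrt(1 / b + 1 / c_), tolerance = 1e-9)
  # symmetric transmissions give exactly zero
  fit0 <- fit_main_only(rep(1L, 20), rep(0L, 20), rep(c(1L, 0L), 10))
  expect_equal(fit0$beta, 0)
})

test_that("complete separation is flagged with the sign of divergence", {
  # single trio, both parents het, homozygous-effect child
  fit <- fit_main_only(1L, 1L, 2L)
  expect_false(fit$converged)
  expect_equal(fit$separation, 1L)
  expect_true(is.infinite(fit$beta) & fit$beta > 0)
  fit_dn <- fit_main_only(1L, 1L, 0L)
  expect_equal(fit_dn$separation, -1L)
})

test_that("stratified closed form matches the joint Newton/BFGS oracle", {
  set.seed(7)
  for (i in 1:25) {
    d <- random_trio_snp(400, maf = runif(1, 0.1, 0.5),
                         beta_g = runif(1, -0.4, 0.4),
                         beta_ge = runif(1, -0.5, 0.5))
    fit <- fit_gxe(d$gm, d$gf, d$gc, d$e)
    if (!fit$converged) next
    orc <- oracle_fit_gxe(d$gm, d$gf, d$gc, d$e)
    expect_lt(abs(fit$beta_g - orc$beta_g), 1e-6)
    expect_lt(abs(fit$beta_ge - orc$beta_ge), 1e-6)
    expect_lt(abs(fit$se_g - sqrt(orc$cov[1, 1])), 1e-5)
    expect_lt(abs(fit$se_ge - sqrt(orc$cov[2, 2])), 1e-5)
    expect_lt(abs(fit$cov_g_ge - orc$cov[1, 2]), 1e-5)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-8)
  }
})

test_that("fit_gxe recovers the stratum closed forms in the single-het design", {
  # unexposed b=30,c=30; exposed b=40,c=20
  gm <- rep(1L, 120); gf <- rep(0L, 120)
  gc <- c(rep(1L, 30), rep(0L, 30), rep(1L, 40), rep(0L, 20))
  e <- c(rep(0L, 60), rep(1L, 60))
  fit <- fit_gxe(gm, gf, gc, e)
  expect_equal(fit$beta_g, 0, tolerance = 1e-9)
  expect_equal(fit$beta_ge, log(2), tolerance = 1e-9)
  expect_equal(fit$se_g, sqrt(1 / 30 + 1 / 30), tolerance = 1e-9)
  expect_equal(fit$se_ge, sqrt(1 / 30 + 1 / 30 + 1 / 40 + 1 / 20),
               tolerance = 1e-9)
  expect_equal(fit$cov_g_ge, -(1 / 30 + 1 / 30), tolerance = 1e-9)
})

test_that("degenerate exposure strata are handled as specified", {
  d <- random_trio_snp(200, maf = 0.3)
  # all unexposed: interaction non-estimable, main effect over all trios
  fit <- fit_gxe(d$gm, d$gf, d$gc, rep(0L, 200))
  expect_false(fit$estimable_ge)
  expect_true(is.na(fit$beta_ge))
  ref <- fit_main_only(d$gm, d$gf, d$gc)
  expect_equal(fit$beta_g, ref$beta)
  expect_true(is.na(wald_1df(fit)$p))
  # missing exposure excludes trios from this fit
  e <- rep(c(0L, 1L), 100)
  e_na <- e; e_na[1:50] <- NA
  fit_na <- fit_gxe(d$gm, d$gf, d$gc, e_na)
  fit_sub <- fit_gxe(d$gm[-(1:50)], d$gf[-(1:50)], d$gc[-(1:50)], e[-(1:50)])
  expect_equal(fit_na$beta_ge, fit_sub$beta_ge)
})

test_that("Wald tests satisfy their algebraic identities", {
  gm <- rep(1L, 120); gf <- rep(0L, 120)
  gc <- c(rep(1L, 30), rep(0L, 30), rep(1L, 40), rep(0L, 20))
  e <- c(rep(0L, 60), rep(1L, 60))
  fit <- fit_gxe(gm, gf, gc, e)
  t1 <- wald_1df(fit)
  expect_equal(t1$chisq, (fit$beta_ge / fit$se_ge)^2)
  expect_equal(t1$p, pchisq(t1$chisq, 1, lower.tail = FALSE))
  # 2 df statistic equals the sum of squared stratum z-scores
  t2 <- wald_2df(fit)
  beta_u <- fit$beta_g
  beta_e <- fit$beta_g + fit$beta_ge
  se_u2 <- fit$se_g^2
  se_e2 <- fit$se_ge^2 - fit$se_g^2
  expect_equal(t2$chisq, beta_u^2 / se_u2 + beta_e^2 / se_e2,
               tolerance = 1e-10)
  # z = 1.959964 gives p = 0.05 on 1 df
  fit2 <- fit
  fit2$beta_ge <- 1.959964 * fit2$se_ge
  expect_equal(wald_1df(fit2)$p, 0.05, tolerance = 1e-6)
})

test_that("scan_genome is order-invariant, name-blind and keeps non-estimable SNPs", {
  cfg <- sim_config(n_trios = 150L, n_snps = 30L, maf = 0.3,
                    populations = data.frame(label = "pop", fraction = 1),
                    exposures = "smoking", exposure_rates = matrix(0.3, 1, 1),
                    seed = 3L)
  st <- simulate_study(cfg)
  # add a monomorphic SNP: uninformative everywhere -> NA row, not dropped
  st$matrix$child[5L, ] <- 0L
  st$matrix$mother[5L, ] <- 0L
  st$matrix$father[5L, ] <- 0L
  res <- scan_genome(st$matrix, st$exposures, "smoking")
  expect_equal(nrow(res), 30L)
  expect_true(is.na(res$P_1DF[5L]))
  expect_true(all(is.finite(res$P_1DF[-5L])))

  # permuting trio order leaves all estimates unchanged
  perm <- sample(nrow(st$matrix$trios))
  tm2 <- st$matrix
  tm2$trios <- tm2$trios[perm, ]
  tm2$child <- tm2$child[, perm]
  tm2$mother <- tm2$mother[, perm]
  tm2$father <- tm2$father[, perm]
  res2 <- scan_genome(tm2, st$exposures, "smoking")
  expect_equal(res2$BETA_GE, res$BETA_GE)
  expect_equal(res2$P_2DF, res$P_2DF)

  # same exposure under a different name gives identical statistics
  ex2 <- st$exposures
  ex2$exposure_name <- "renamed"
  res3 <- scan_genome(st$matrix, ex2, "renamed")
  expect_equal(res3$P_1DF, res$P_1DF)
  expect_error(scan_genome(st$matrix, st$exposures, "nope"),
               "unknown exposure")
})
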