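# Ascertained trio simulator: founders, conditional child sampling,
# contamination injection, determinism.

one_pop_cfg <- function(..., exposure_rates = matrix(0.3, 1, 1)) {
  sim_config(populations = data.frame(label = "pop", fraction = 1),
             exposures = "smoking", exposure_rates = exposure_rates, ...)
}

test_that("founder genotypes follow HWE proportions and are seed-reproducible", {
  cfg <- one_pop_cfg(n_trios = 4000L, n_snps = 5L, maf = 0.5, seed = 2L)
  par <- simulate_parents(cfg)
  g <- c(par$mother[1L, ], par$father[1L, ])
  freq <- c(mean(g == 0), mean(g == 1), mean(g == 2))
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / length(g))
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  par2 <- simulate_parents(cfg)
  expect_identical(par$mother, par2$mother)
  expect_identical(par$father, par2$father)

  cfg0 <- one_pop_cfg(n_trios = 50L, n_snps = 3L, maf = 0, seed = 2L)
  par0 <- simulate_parents(cfg0)
  expect_true(all(par0$mother == 0L) && all(par0$father == 0L))
})

test_that("null conditional sampling is exactly Mendelian", {
  set.seed(11)
  gc <- sample_case_genotype(rep(1L, 10000), rep(1L, 10000), 0L, 0, 0)
  counts <- table(factor(gc, levels = 0:2))
  gof <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
})

test_that("ascertainment tilts transmissions by the relative risk", {
  # beta_g = log 2, parents (1,1): probabilities (1/9, 4/9, 4/9)
  set.seed(12)
  gc <- sample_case_genotype(rep(1L, 30000), rep(1L, 30000), 0L, log(2), 0)
  p_hat <- as.numeric(table(factor(gc, levels = 0:2))) / 30000
  expect_true(all(abs(p_hat - c(1, 4, 4) / 9) <
                    3 * sqrt(c(1, 4, 4) / 9 * (1 - c(1, 4, 4) / 9) / 30000)))
  # single-het-parent transmission ratio approaches 2:1
  gm <- rep(1L, 10000); gf <- rep(0L, 10000)
  gc2 <- sample_case_genotype(gm, gf, 0L, log(2), 0)
  b <- sum(gc2 == 1L); c_ <- sum(gc2 == 0L)
  expect_equal(b / c_, 2, tolerance = 3 * sqrt(1 / b + 1 / c_))
})

test_that("conditional and rejection modes sample the same ascertained law", {
  set.seed(13)
  n <- 10000L
  gm <- rbinom(n, 2L, 0.4); gf <- rbinom(n, 2L, 0.4)
  e <- rbinom(n, 1L, 0.5)
  g_cond <- sample_case_genotype(gm, gf, e, 0.3, 0.5, mode = "conditional")
  g_rej <- sample_case_genotype(gm, gf, e, 0.3, 0.5, mode = "rejection",
                                penetrance_baseline = 0.05)
  tab <- rbind(table(factor(g_cond, levels = 0:2)),
               table(factor(g_rej, levels = 0:2)))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  expect_error(
    sample_case_genotype(1L, 1L, 1L, 2, 2, mode = "rejection",
                         penetrance_baseline = 0.5),
    "acceptance probability")
})

test_that("error injection matches its rates and the log restores the clean study", {
  cfg <- one_pop_cfg(n_trios = 500L, n_snps = 20L, maf = 0.3, seed = 4L,
                     genotype_missing_rate = 0.05, mendel_error_rate = 0.02)
  st <- simulate_study(cfg)
  n_calls <- 3 * 500 * 20
  n_missing <- sum(is.na(st$matrix$child)) + sum(is.na(st$matrix$mother)) +
    sum(is.na(st$matrix$father))
  ci <- qbinom(c(0.005, 0.995), n_calls, 0.05) / n_calls
  expect_gte(n_missing / n_calls, ci[1L])
  expect_lte(n_missing / n_calls, ci[2L])
  expect_gt(sum(st$truth$perturbations$kind == "mendel"), 0)

  clean <- revert_errors(st)
  cfg0 <- one_pop_cfg(n_trios = 500L, n_snps = 20L, maf = 0.3, seed = 4L)
  st0 <- simulate_study(cfg0)
  expect_identical(clean$matrix$child, st0$matrix$child)
  expect_identical(clean$matrix$mother, st0$matrix$mother)
  expect_identical(clean$matrix$father, st0$matrix$father)

  # zero rates are the identity
  st_id <- inject_errors(st0, cfg0)
  expect_identical(st_id$matrix$child, st0$matrix$child)
  expect_equal(nrow(st_id$truth$perturbations), 0L)
})

test_that("simulate_study has the configured shape, determinism and truth alignment", {
  cfg <- one_pop_cfg(n_trios = 100L, n_snps = 10L, seed = 6L,
                     causal = data.frame(snp = 3L, beta_g = 0.3, beta_ge = 0.5,
                                         exposure_name = "smoking"))
  st <- simulate_study(cfg)
  expect_equal(dim(st$matrix$child), c(10L, 100L))
  expect_equal(length(st$truth$beta_g), 10L)
  expect_equal(st$truth$beta_ge[3L], 0.5)
  expect_true(all(st$truth$beta_ge[-3L] == 0))
  expect_equal(nrow(st$exposures), 100L)

  st2 <- simulate_study(cfg)
  expect_identical(st$matrix$child, st2$matrix$child)
  cfg_b <- one_pop_cfg(n_trios = 100L, n_snps = 10L, seed = 7L,
                       causal = data.frame(snp = 3L, beta_g = 0.3,
                                           beta_ge = 0.5,
                                           exposure_name = "smoking"))
  st3 <- simulate_study(cfg_b)
  expect_false(identical(st$matrix$child, st3$matrix$child))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(populations = data.frame(label = c("a", "b"),
                                                   fraction = c(0.6, 0.6))),
               "sum to 1")
  expect_error(one_pop_cfg(n_trios = 10L, n_snps = 5L,
                           causal = data.frame(snp = 9L, beta_g = 0,
                                               beta_ge = 0,
                                               exposure_name = "smoking")))
  expect_error(one_pop_cfg(genotype_missing_rate = 1.2))
})

test_that("empirical power of the interaction test increases with effect size", {
  reps <- 60L
  power_at <- function(beta_ge, seed0) {
    rej <- vapply(seq_len(reps), function(r) {
      cfg <- one_pop_cfg(n_trios = 600L, n_snps = 1L, maf = 0.3,
                         exposure_rates = matrix(0.5, 1, 1),
                         seed = seed0 + r,
                         causal = data.frame(snp = 1L, beta_g = 0,
                                             beta_ge = beta_ge,
                                             exposure_name = "smoking"))
      st <- simulate_study(cfg)
      f <- fit_gxe(st$matrix$mother[1L, ], st$matrix$father[1L, ],
                   st$matrix$child[1L, ], st$exposures$exposed)
      p <- wald_1df(f)$p
      !is.na(p) && p < 0.05
    }, logical(1L))
    mean(rej)
  }
  pw <- vapply(c(0, 0.25, 0.5, 0.75), power_at, numeric(1L), seed0 = 900L)
  expect_true(all(diff(pw) >= -0.05)) # non-decreasing up to Monte-Carlo noise
  expect_lt(pw[1L], 0.15)
  expect_gt(pw[4L], 0.8)
})
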