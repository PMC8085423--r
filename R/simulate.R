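# Simulator of ascertained case-parent trio studies: multi-population founders
# in Hardy-Weinberg proportions, binary maternal exposures with population-
# specific rates, child genotypes drawn under ascertainment through an
# affected proband with multiplicative G + GxE relative risks, and optional
# genotype missingness / Mendelian-error contamination.

# Named sub-streams off one master seed so each component is independently
# reproducible.
.stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483563) + 1L
}

#' Configuration of a simulated trio study
#'
#' Defaults emulate a large two-population orofacial-cleft trio study:
#' ~2,000 trios with 40\% European / 60\% Asian ancestry and maternal exposure
#' rates that differ sharply between populations (smoking 30\%/3\%, alcohol
#' 40\%/3\%, multivitamin 60\%/19\%), the pattern that makes gene-exposure
#' correlation across strata a realistic confounding threat. Allele
#' frequencies default to Uniform(0.05, 0.5) draws shared across populations;
#' supply a matrix for population-specific frequencies.
#'
#' @param n_trios,n_snps Study dimensions.
#' @param populations data.frame with columns `label` and `fraction`
#'   (fractions sum to 1).
#' @param maf Effect-allele frequency: scalar, per-SNP vector, or
#'   `n_snps x n_populations` matrix. `NULL` draws Uniform(0.05, 0.5) per SNP.
#' @param exposure_rates `n_populations x length(exposures)` matrix of
#'   Bernoulli exposure rates (rows = populations).
#' @param exposures Exposure names simulated.
#' @param causal data.frame with columns `snp` (index), `beta_g`, `beta_ge`,
#'   `exposure_name`; all other SNPs are null.
#' @param genotype_missing_rate,mendel_error_rate Contamination rates in
#'   \[0, 1).
#' @param seed Master seed; all sub-streams derive from it.
#' @param mode Child sampling: `"conditional"` draws from the ascertained
#'   conditional law directly; `"rejection"` samples Mendelian children and
#'   accepts with probability `penetrance_baseline * RR(g, e)`.
#' @param penetrance_baseline Baseline penetrance for rejection mode.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 1939L, n_snps = 100L,
                       populations = data.frame(
                         label = c("European", "Asian"),
                         fraction = c(0.40, 0.60)),
                       maf = NULL,
                       exposure_rates = NULL,
                       exposures = c("smoking", "alcohol", "vitamin"),
                       causal = NULL,
                       genotype_missing_rate = 0,
                       mendel_error_rate = 0,
                       seed = 1L,
                       mode = c("conditional", "rejection"),
                       penetrance_baseline = 0.05) {
  mode <- match.arg(mode)
  stopifnot(n_trios >= 1L, n_snps >= 1L,
            is.data.frame(populations),
            all(c("label", "fraction") %in% names(populations)))
  if (abs(sum(populations$fraction) - 1) > 1e-8) {
    stop("population fractions must sum to 1")
  }
  n_pop <- nrow(populations)

  if (is.null(exposure_rates)) {
    default_rates <- rbind(European = c(smoking = 0.30, alcohol = 0.40,
                                        vitamin = 0.60),
                           Asian = c(smoking = 0.03, alcohol = 0.03,
                                     vitamin = 0.19))
    exposure_rates <- matrix(0.3, n_pop, length(exposures),
                             dimnames = list(populations$label, exposures))
    for (pl in intersect(populations$label, rownames(default_rates))) {
      for (ex in intersect(exposures, colnames(default_rates))) {
        exposure_rates[pl, ex] <- default_rates[pl, ex]
      }
    }
  }
  exposure_rates <- as.matrix(exposure_rates)
  stopifnot(nrow(exposure_rates) == n_pop,
            ncol(exposure_rates) == length(exposures),
            all(exposure_rates >= 0), all(exposure_rates <= 1))
  dimnames(exposure_rates) <- list(populations$label, exposures)

  if (!is.null(maf)) {
    if (is.matrix(maf)) {
      stopifnot(nrow(maf) == n_snps, ncol(maf) == n_pop)
    } else {
      stopifnot(length(maf) %in% c(1L, n_snps))
      maf <- matrix(maf, n_snps, n_pop)
    }
    stopifnot(all(maf >= 0), all(maf <= 1))
  }

  if (!is.null(causal)) {
    stopifnot(is.data.frame(causal),
              all(c("snp", "beta_g", "beta_ge", "exposure_name") %in%
                    names(causal)),
              all(causal$snp >= 1L), all(causal$snp <= n_snps),
              all(causal$exposure_name %in% exposures),
              !anyDuplicated(causal$snp))
  }
  stopifnot(genotype_missing_rate >= 0, genotype_missing_rate < 1,
            mendel_error_rate >= 0, mendel_error_rate < 1,
            penetrance_baseline > 0, penetrance_baseline <= 1)

  structure(list(n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
                 populations = populations, maf = maf,
                 exposure_rates = exposure_rates, exposures = exposures,
                 causal = causal,
                 genotype_missing_rate = genotype_missing_rate,
                 mendel_error_rate = mendel_error_rate,
                 seed = as.integer(seed), mode = mode,
                 penetrance_baseline = penetrance_baseline),
            class = "sim_config")
}

#' Simulate founder (parental) genotypes
#'
#' Each parent's dosage at each SNP is Binomial(2, maf) for the allele
#' frequency of that parent's population (Hardy-Weinberg proportions), with
#' linkage equilibrium across SNPs. Population assignment and allele
#' frequencies come from the config; the `parents` sub-stream of the master
#' seed drives all draws.
#'
#' @param config A [sim_config()].
#' @return list `mother`, `father` (integer `n_snps x n_trios` matrices),
#'   `population` (per-trio label), `maf` (the realized `n_snps x n_pop`
#'   frequency matrix).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed <- .stream_seed(config$seed, "parents")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(withr_seed)

  n_pop <- nrow(config$populations)
  maf <- config$maf
  if (is.null(maf)) {
    maf <- matrix(stats::runif(config$n_snps, 0.05, 0.5), config$n_snps, n_pop)
  }
  pop <- sample.int(n_pop, config$n_trios, replace = TRUE,
                    prob = config$populations$fraction)
  p_mat <- maf[, pop, drop = FALSE] # n_snps x n_trios
  draw <- function() {
    matrix(stats::rbinom(length(p_mat), 2L, p_mat),
           config$n_snps, config$n_trios)
  }
  list(mother = draw(), father = draw(),
       population = config$populations$label[pop], maf = maf)
}

# Mendelian transmission distribution over child dosage given parent dosages.
.mendel_probs <- function(gm, gf) {
  pm <- gm / 2
  pf <- gf / 2
  cbind(p0 = (1 - pm) * (1 - pf),
        p1 = pm * (1 - pf) + (1 - pm) * pf,
        p2 = pm * pf)
}

#' Sample an affected child's genotype under ascertainment
#'
#' Under the multiplicative relative-risk model, the genotype of a child
#' ascertained as affected follows the Mendelian transmission law tilted by
#' the relative risk: P(g | affected) is proportional to
#' `mendel(g | gm, gf) * exp(beta_g*g + beta_ge*g*e)`. Conditional mode
#' samples this law directly; rejection mode samples Mendelian children and
#' accepts with probability `penetrance_baseline * exp(beta_g*g + beta_ge*g*e)`
#' (the two agree; rejection mode demonstrates the mechanism and requires the
#' acceptance probability to stay below 1).
#'
#' @param gm,gf Parental dosage vectors.
#' @param e Binary exposure vector (recycled).
#' @param beta_g,beta_ge Log relative risks (scalars).
#' @param mode `"conditional"` or `"rejection"`.
#' @param penetrance_baseline Baseline penetrance (rejection mode).
#' @return Integer vector of child dosages.
#' @export
sample_case_genotype <- function(gm, gf, e, beta_g, beta_ge,
                                 mode = c("conditional", "rejection"),
                                 penetrance_baseline = 0.05) {
  mode <- match.arg(mode)
  n <- length(gm)
  e <- rep_len(e, n)
  P <- .mendel_probs(gm, gf)
  rr <- exp(outer(beta_g + beta_ge * e, 0:2)) # n x 3, tilt per dosage

  if (mode == "conditional") {
    W <- P * rr
    W <- W / rowSums(W)
    u <- stats::runif(n)
    return(as.integer((u > W[, 1L]) + (u > W[, 1L] + W[, 2L])))
  }

  acc <- penetrance_baseline * rr
  if (max(acc[P > 0]) > 1) {
    stop("acceptance probability exceeds 1; reduce penetrance_baseline")
  }
  child <- rep(NA_integer_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    u <- stats::runif(length(todo))
    g <- as.integer((u > P[todo, 1L]) + (u > P[todo, 1L] + P[todo, 2L]))
    keep <- stats::runif(length(todo)) < acc[cbind(todo, g + 1L)]
    child[todo[keep]] <- g[keep]
    todo <- todo[!keep]
  }
  child
}

#' Inject genotype missingness and Mendelian-error contamination
#'
#' Each genotype call is set missing independently with probability
#' `genotype_missing_rate`; independently, with probability
#' `mendel_error_rate` per (SNP, trio), one member chosen at random has its
#' genotype replaced by a uniform draw from the other two dosages. Every
#' perturbation is logged in the truth record so [revert_errors()] can restore
#' the clean study exactly.
#'
#' @param study A `simulated_study` from [simulate_study()].
#' @param config Its [sim_config()] (rates and seed are read from here).
#' @return The perturbed `simulated_study` with
#'   `truth$perturbations` populated.
#' @export
inject_errors <- function(study, config) {
  stopifnot(inherits(study, "simulated_study"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.stream_seed(config$seed, "errors"))

  members <- c("child", "mother", "father")
  logs <- list()
  n_cell <- config$n_snps * config$n_trios

  if (config$mendel_error_rate > 0) {
    hit <- which(stats::runif(n_cell) < config$mendel_error_rate)
    if (length(hit)) {
      snp <- ((hit - 1L) %% config$n_snps) + 1L
      trio <- ((hit - 1L) %/% config$n_snps) + 1L
      member <- sample(members, length(hit), replace = TRUE)
      old_g <- new_g <- integer(length(hit))
      for (i in seq_along(hit)) {
        g <- study$matrix[[member[i]]][snp[i], trio[i]]
        repl <- sample(setdiff(0:2, g), 1L)
        study$matrix[[member[i]]][snp[i], trio[i]] <- repl
        old_g[i] <- g
        new_g[i] <- repl
      }
      logs[["mendel"]] <- data.frame(kind = "mendel", snp = snp, trio = trio,
                                     member = member, old = old_g, new = new_g,
                                     stringsAsFactors = FALSE)
    }
  }
  if (config$genotype_missing_rate > 0) {
    for (m in members) {
      hit <- which(stats::runif(n_cell) < config$genotype_missing_rate)
      if (!length(hit)) next
      snp <- ((hit - 1L) %% config$n_snps) + 1L
      trio <- ((hit - 1L) %/% config$n_snps) + 1L
      old_g <- study$matrix[[m]][cbind(snp, trio)]
      study$matrix[[m]][cbind(snp, trio)] <- NA_integer_
      logs[[paste0("miss_", m)]] <- data.frame(
        kind = "missing", snp = snp, trio = trio, member = m, old = old_g,
        new = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  study$truth$perturbations <- if (length(logs)) {
    do.call(rbind, c(logs, make.row.names = FALSE))
  } else {
    data.frame(kind = character(0), snp = integer(0), trio = integer(0),
               member = character(0), old = integer(0), new = integer(0),
               stringsAsFactors = FALSE)
  }
  study
}

#' Undo logged perturbations, restoring the clean simulated study
#'
#' Replays the perturbation log of [inject_errors()] in reverse, writing the
#' recorded original genotype back into each perturbed cell.
#'
#' @param study A perturbed `simulated_study`.
#' @return The clean study (empty perturbation log).
#' @export
revert_errors <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  log <- study$truth$perturbations
  if (!is.null(log) && nrow(log)) {
    for (i in rev(seq_len(nrow(log)))) {
      study$matrix[[log$member[i]]][log$snp[i], log$trio[i]] <- log$old[i]
    }
  }
  study$truth$perturbations <- study$truth$perturbations[0, , drop = FALSE]
  study
}

#' Simulate a complete ascertained case-parent trio study
#'
#' Draws founders, per-trio population and maternal exposures, then an
#' affected child per trio under the multiplicative G + GxE relative-risk
#' model, and finally injects missingness/Mendelian contamination if
#' configured. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_study`: `matrix` ([trio_matrix()]),
#'   `exposures` (long exposure table), `truth` (per-SNP true `beta_g`,
#'   `beta_ge`, `exposure_name`, per-trio `population`, `maf`, perturbation
#'   log), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  par <- simulate_parents(config)

  old <- .save_rng()
  set.seed(.stream_seed(config$seed, "exposure"))
  pop_idx <- match(par$population, config$populations$label)
  exp_tabs <- lapply(config$exposures, function(ex) {
    rate <- config$exposure_rates[pop_idx, ex]
    data.frame(trio_id = sprintf("T%05d", seq_len(config$n_trios)),
               exposure_name = ex,
               exposed = stats::rbinom(config$n_trios, 1L, rate),
               stringsAsFactors = FALSE)
  })
  exposures <- do.call(rbind, exp_tabs)
  exposures$exposure_class <- ifelse(
    exposures$exposure_name %in% c("smoking", "alcohol", "vitamin"),
    exposures$exposure_name, "other")
  .restore_rng(old)

  beta_g <- beta_ge <- numeric(config$n_snps)
  causal_exposure <- rep(NA_character_, config$n_snps)
  if (!is.null(config$causal)) {
    beta_g[config$causal$snp] <- config$causal$beta_g
    beta_ge[config$causal$snp] <- config$causal$beta_ge
    causal_exposure[config$causal$snp] <- config$causal$exposure_name
  }

  old <- .save_rng()
  set.seed(.stream_seed(config$seed, "child"))
  child <- matrix(NA_integer_, config$n_snps, config$n_trios)
  e_by_exposure <- lapply(exp_tabs, function(d) d$exposed)
  names(e_by_exposure) <- config$exposures
  zero_e <- integer(config$n_trios)
  for (i in seq_len(config$n_snps)) {
    e <- if (is.na(causal_exposure[i])) zero_e else
      e_by_exposure[[causal_exposure[i]]]
    child[i, ] <- sample_case_genotype(
      par$mother[i, ], par$father[i, ], e, beta_g[i], beta_ge[i],
      mode = config$mode, penetrance_baseline = config$penetrance_baseline)
  }
  .restore_rng(old)

  trio_ids <- sprintf("T%05d", seq_len(config$n_trios))
  trios <- data.frame(trio_id = trio_ids,
                      child_id = paste0(trio_ids, "_c"),
                      mother_id = paste0(trio_ids, "_m"),
                      father_id = paste0(trio_ids, "_f"),
                      population = par$population,
                      stringsAsFactors = FALSE)

  per_chr <- ceiling(config$n_snps / 22)
  chrom <- as.character(((seq_len(config$n_snps) - 1L) %/% per_chr) + 1L)
  pos <- (((seq_len(config$n_snps) - 1L) %% per_chr) + 1L) * 10000L
  snps <- data.frame(chrom = chrom, pos = pos,
                     snp_id = sprintf("snp%06d", seq_len(config$n_snps)),
                     effect_allele = "G", other_allele = "A",
                     imputation_r2 = NA_real_, stringsAsFactors = FALSE)

  study <- structure(list(
    matrix = trio_matrix(snps, trios, child, par$mother, par$father),
    exposures = exposures,
    truth = list(beta_g = beta_g, beta_ge = beta_ge,
                 exposure_name = causal_exposure,
                 population = par$population, maf = par$maf,
                 perturbations = data.frame()),
    config = config
  ), class = "simulated_study")

  if (config$genotype_missing_rate > 0 || config$mendel_error_rate > 0) {
    study <- inject_errors(study, config)
  }
  study
}

#' Write a simulated study to standard file formats
#'
#' Emits a plain-text VCF (one sample per trio member), a 6-column pedigree,
#' the exposure TSV, a truth TSV (per-SNP true parameters) and a JSON manifest
#' echoing the configuration and seed, so the full pipeline can be exercised
#' through its public file interfaces.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_study_files <- function(study, dir, prefix = "study") {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- study$matrix
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             pedigree = file.path(dir, paste0(prefix, ".ped")),
             exposures = file.path(dir, paste0(prefix, "_exposures.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.json")))

  gt_code <- c("0/0", "0/1", "1/1")
  enc <- function(m) {
    out <- matrix("./.", nrow(m), ncol(m))
    out[!is.na(m)] <- gt_code[m[!is.na(m)] + 1L]
    out
  }
  gt <- matrix("", nrow(tm$snps), 3L * nrow(tm$trios))
  gt[, seq(1L, ncol(gt), by = 3L)] <- enc(tm$child)
  gt[, seq(2L, ncol(gt), by = 3L)] <- enc(tm$mother)
  gt[, seq(3L, ncol(gt), by = 3L)] <- enc(tm$father)
  samples <- as.vector(rbind(tm$trios$child_id, tm$trios$mother_id,
                             tm$trios$father_id))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(tm$snps$chrom, tm$snps$pos, tm$snps$snp_id,
                tm$snps$other_allele, tm$snps$effect_allele, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths["vcf"])

  ped <- rbind(
    data.frame(fam = tm$trios$trio_id, id = tm$trios$father_id, fa = "0",
               mo = "0", sex = 1L, phe = 1L, stringsAsFactors = FALSE),
    data.frame(fam = tm$trios$trio_id, id = tm$trios$mother_id, fa = "0",
               mo = "0", sex = 2L, phe = 1L, stringsAsFactors = FALSE),
    data.frame(fam = tm$trios$trio_id, id = tm$trios$child_id,
               fa = tm$trios$father_id, mo = tm$trios$mother_id, sex = 1L,
               phe = 2L, stringsAsFactors = FALSE))
  ped <- ped[order(ped$fam), ]
  utils::write.table(ped, paths["pedigree"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  utils::write.table(
    study$exposures[, c("trio_id", "exposure_name", "exposed")],
    paths["exposures"], sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- data.frame(snp_id = tm$snps$snp_id, beta_g = study$truth$beta_g,
                      beta_ge = study$truth$beta_ge,
                      exposure_name = study$truth$exposure_name,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  cfg <- study$config
  manifest <- list(seed = cfg$seed, n_trios = cfg$n_trios,
                   n_snps = cfg$n_snps, mode = cfg$mode,
                   populations = cfg$populations,
                   exposures = cfg$exposures,
                   exposure_rates = as.data.frame(cfg$exposure_rates),
                   genotype_missing_rate = cfg$genotype_missing_rate,
                   mendel_error_rate = cfg$mendel_error_rate,
                   package_version = as.character(utils::packageVersion("triogxe")))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
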