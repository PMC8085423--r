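# Fixed-effect inverse-variance meta-analysis across trio studies: allele
# harmonization of summary statistics, scalar combination of the interaction
# coefficient, and joint 2-parameter combination of (beta_G, beta_GE).

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(ea, oa) {
  !is.na(.complement[ea]) & .complement[ea] == oa
}

#' Harmonize per-study summary statistics to a common allele orientation
#'
#' Studies are matched on (chromosome, position). The first study carrying a
#' SNP defines the reference orientation. For each other study: matching
#' alleles are kept as-is; swapped effect/other alleles negate both `BETA_G`
#' and `BETA_GE` (standard errors and their covariance are unchanged, since
#' both coefficients change sign); alleles that match only after strand
#' complement are complemented and then the swap rule applied, unless the
#' allele pair is palindromic (A/T or C/G), in which case strand cannot be
#' resolved and the record is dropped; irreconcilable allele pairs are
#' dropped. SNPs present in a single study are carried through to the meta
#' stage as single-study results.
#'
#' @param studies Named list of summary-statistics data.frames in the
#'   [write_summary_stats()] column layout.
#' @return list with `studies` (aligned data.frames, dropped records removed)
#'   and `actions` (data.frame `key`, `study`, `action` in as-is /
#'   sign-flipped / strand-flipped / strand-flipped+sign-flipped / dropped).
#' @export
harmonize <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1L)
  if (is.null(names(studies)) || any(!nzchar(names(studies)))) {
    names(studies) <- paste0("study", seq_along(studies))
  }
  ref_ea <- ref_oa <- character(0)
  ref_key <- character(0)
  actions <- list()
  out <- studies

  for (s in names(studies)) {
    df <- studies[[s]]
    key <- paste(df$CHR, df$POS, sep = ":")
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate position within study '%s': %s",
                   s, key[duplicated(key)][1L]))
    }
    idx <- match(key, ref_key)
    new <- is.na(idx)
    action <- rep("as-is", nrow(df))
    drop <- logical(nrow(df))

    for (i in which(!new)) {
      ea <- df$EA[i]; oa <- df$OA[i]
      rea <- ref_ea[idx[i]]; roa <- ref_oa[idx[i]]
      if (ea == rea && oa == roa) next
      if (ea == roa && oa == rea) {
        if (.is_palindromic(ea, oa)) { # swap indistinguishable from strand flip
          action[i] <- "dropped"; drop[i] <- TRUE; next
        }
        action[i] <- "sign-flipped"
        df$BETA_G[i] <- -df$BETA_G[i]
        df$BETA_GE[i] <- -df$BETA_GE[i]
        tmp <- df$EA[i]; df$EA[i] <- df$OA[i]; df$OA[i] <- tmp
        next
      }
      cea <- unname(.complement[ea]); coa <- unname(.complement[oa])
      if (!is.na(cea) && !is.na(coa) && !.is_palindromic(ea, oa)) {
        if (cea == rea && coa == roa) {
          action[i] <- "strand-flipped"
          df$EA[i] <- cea; df$OA[i] <- coa
          next
        }
        if (cea == roa && coa == rea) {
          action[i] <- "strand-flipped+sign-flipped"
          df$BETA_G[i] <- -df$BETA_G[i]
          df$BETA_GE[i] <- -df$BETA_GE[i]
          df$EA[i] <- coa; df$OA[i] <- cea
          next
        }
      }
      action[i] <- "dropped"; drop[i] <- TRUE
    }

    add <- new & !drop
    ref_key <- c(ref_key, key[add])
    ref_ea <- c(ref_ea, df$EA[add])
    ref_oa <- c(ref_oa, df$OA[add])
    actions[[s]] <- data.frame(key = key, study = s, action = action,
                               stringsAsFactors = FALSE)
    out[[s]] <- df[!drop, , drop = FALSE]
  }
  list(studies = out, actions = do.call(rbind, c(actions, make.row.names = FALSE)))
}

#' Scalar fixed-effect inverse-variance meta-analysis
#'
#' Combines per-study estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w_i b_i)/sum(w_i)`, `se = 1/sqrt(sum(w_i))`, followed by a 1 df
#' Wald chi-square test of `beta = 0`. A single estimate passes through
#' unchanged. Cochran's Q is returned as a heterogeneity diagnostic only.
#'
#' @param beta,se Numeric vectors of per-study estimates and standard errors
#'   (all `se > 0`).
#' @return list `beta_meta`, `se_meta`, `chisq`, `df = 1`, `p`, `q_het`,
#'   `n_studies`.
#' @export
meta_scalar <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1L,
            all(is.finite(beta)), all(is.finite(se)), all(se > 0))
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  chisq <- (beta_meta / se_meta)^2
  list(beta_meta = beta_meta, se_meta = se_meta, chisq = chisq, df = 1L,
       p = .chisq_p(chisq, 1L), q_het = sum(w * (beta - beta_meta)^2),
       n_studies = length(beta))
}

#' Joint 2-parameter fixed-effect meta-analysis of (beta_G, beta_GE)
#'
#' Combines per-study coefficient vectors with matrix weights
#' `W_i = V_i^{-1}` (or `diag(V_i)^{-1}` when `use_within_study_cov = FALSE`):
#' `beta = (sum W_i)^{-1} sum(W_i b_i)`, `cov = (sum W_i)^{-1}`, and the 2 df
#' chi-square `beta' (sum W_i) beta` tests H0: beta_G = 0, beta_GE = 0 across
#' studies.
#'
#' @param betas List of length-2 numeric vectors `(beta_g, beta_ge)`.
#' @param covs List of 2x2 positive-definite covariance matrices.
#' @param use_within_study_cov Use the within-study covariance between the two
#'   coefficients (default) or only the diagonal (SEs alone).
#' @return list `beta_meta` (length 2), `cov_meta` (2x2), `chisq`, `df = 2`,
#'   `p`, `n_studies`; studies with singular weights are dropped with a
#'   warning.
#' @export
meta_joint_2df <- function(betas, covs, use_within_study_cov = TRUE) {
  stopifnot(is.list(betas), is.list(covs), length(betas) == length(covs),
            length(betas) >= 1L)
  Wsum <- matrix(0, 2L, 2L)
  Wb <- c(0, 0)
  used <- 0L
  for (i in seq_along(betas)) {
    V <- covs[[i]]
    if (!use_within_study_cov) V <- diag(diag(V), 2L)
    ok <- all(is.finite(V)) && all(is.finite(betas[[i]])) && det(V) > 0
    if (!ok) {
      warning("dropping study ", i, " with singular or non-finite covariance")
      next
    }
    W <- solve(V)
    Wsum <- Wsum + W
    Wb <- Wb + W %*% betas[[i]]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable study estimates")
  cov_meta <- solve(Wsum)
  beta_meta <- drop(cov_meta %*% Wb)
  chisq <- drop(t(beta_meta) %*% Wsum %*% beta_meta)
  list(beta_meta = beta_meta, cov_meta = cov_meta, chisq = chisq, df = 2L,
       p = .chisq_p(chisq, 2L), n_studies = used)
}

#' Meta-analyze gTDT summary statistics across studies
#'
#' Harmonizes the per-study summary files to a common allele orientation and
#' computes, SNP by SNP, the scalar fixed-effect meta-analysis of the
#' interaction coefficient (1 df test) and the joint 2-parameter meta-analysis
#' of gene and interaction effects (2 df test). SNPs present in a single study
#' are reported with `N_STUDIES = 1` (passthrough).
#'
#' @param studies Named list of summary-statistics data.frames
#'   ([read_summary_stats()] output).
#' @param use_within_study_cov Passed to [meta_joint_2df()].
#' @param genomewide,suggestive Flag thresholds (strict `<`) on the 1 df meta
#'   p-value.
#' @return data.frame, one row per harmonized SNP: CHR, POS, ID, EA, OA,
#'   N_STUDIES, BETA_GE_META, SE_GE_META, CHISQ_1DF, P_1DF, Q_HET, BETA_G_META,
#'   CHISQ_2DF, P_2DF, FLAG_GENOMEWIDE, FLAG_SUGGESTIVE.
#' @export
meta_studies <- function(studies, use_within_study_cov = TRUE,
                         genomewide = 5e-8, suggestive = 1e-6) {
  h <- harmonize(studies)
  studies <- h$studies
  all_keys <- unique(unlist(lapply(studies, function(d) {
    paste(d$CHR, d$POS, sep = ":")
  })))

  per_study <- lapply(studies, function(d) {
    d$key <- paste(d$CHR, d$POS, sep = ":")
    d
  })

  rows <- lapply(all_keys, function(k) {
    est <- lapply(per_study, function(d) d[d$key == k, , drop = FALSE])
    est <- est[vapply(est, nrow, integer(1L)) == 1L]
    ok <- vapply(est, function(d) {
      all(is.finite(c(d$BETA_G, d$BETA_GE, d$SE_G, d$SE_GE, d$COV_G_GE)))
    }, logical(1L))
    est <- est[ok]
    first <- per_study[[which(vapply(per_study, function(d) k %in% d$key,
                                     logical(1L)))[1L]]]
    ann <- first[first$key == k, c("CHR", "POS", "ID", "EA", "OA")]
    if (length(est) == 0L) {
      return(cbind(ann, N_STUDIES = 0L, BETA_GE_META = NA_real_,
                   SE_GE_META = NA_real_, CHISQ_1DF = NA_real_,
                   P_1DF = NA_real_, Q_HET = NA_real_, BETA_G_META = NA_real_,
                   CHISQ_2DF = NA_real_, P_2DF = NA_real_))
    }
    ms <- meta_scalar(vapply(est, function(d) d$BETA_GE, numeric(1L)),
                      vapply(est, function(d) d$SE_GE, numeric(1L)))
    mj <- meta_joint_2df(
      lapply(est, function(d) c(d$BETA_G, d$BETA_GE)),
      lapply(est, function(d) {
        matrix(c(d$SE_G^2, d$COV_G_GE, d$COV_G_GE, d$SE_GE^2), 2L, 2L)
      }),
      use_within_study_cov = use_within_study_cov)
    cbind(ann, N_STUDIES = ms$n_studies, BETA_GE_META = ms$beta_meta,
          SE_GE_META = ms$se_meta, CHISQ_1DF = ms$chisq, P_1DF = ms$p,
          Q_HET = ms$q_het, BETA_G_META = mj$beta_meta[1L],
          CHISQ_2DF = mj$chisq, P_2DF = mj$p)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$FLAG_GENOMEWIDE <- as.integer(!is.na(out$P_1DF) & out$P_1DF < genomewide)
  out$FLAG_SUGGESTIVE <- as.integer(!is.na(out$P_1DF) & out$P_1DF < suggestive)
  ord <- order(.chrom_rank(out$CHR), out$POS)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.integer(x))
  ifelse(is.na(r), 100L + as.integer(factor(x)), r)
}
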