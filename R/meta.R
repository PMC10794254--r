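#' Fixed-effect inverse-variance meta-analysis of one variant
#'
#' Pools estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = (\sum w_i)^{-1/2}}, two-sided Wald p from the normal
#' approximation. Heterogeneity: Cochran's
#' \eqn{Q = \sum w_i (\beta_i - \hat\beta)^2} and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \cdot 100} (0 for a single study or
#' Q = 0).
#'
#' @param beta,se numeric vectors of per-study estimates (all SE > 0).
#' @return list with `beta`, `se`, `p`, `q`, `i2` (percent), `k`.
#' @export
ivw_combine <- function(beta, se) {
  if (length(beta) == 0) stop("no estimates to combine")
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - b)^2)
  k <- length(beta)
  i2 <- if (k == 1 || q == 0) 0 else max(0, (q - (k - 1)) / q) * 100
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)), q = q, i2 = i2,
       k = k)
}

#' Combine male and female summary statistics within one study
#'
#' Inverse-variance combination of the two sex strata per study and
#' variant, after dosage harmonization and the sex-frequency concordance
#' filter. The combined sample size is the sum; EAF and info are
#' sample-size-weighted means. Variants present in only one sex yield no
#' overall record.
#'
#' @param male_records,female_records harmonized records of one study.
#' @param keep optional variant identifiers to combine (typically from
#'   [filter_sex_freq_discordance()]); default: all shared variants.
#' @return an overall-stratum data.frame in the same record format.
#' @export
combine_sexes <- function(male_records, female_records, keep = NULL) {
  shared <- intersect(male_records$rsid, female_records$rsid)
  if (!is.null(keep)) shared <- intersect(shared, keep)
  if (length(shared) == 0)
    return(male_records[0, , drop = FALSE])
  m <- male_records[match(shared, male_records$rsid), ]
  f <- female_records[match(shared, female_records$rsid), ]
  w_m <- 1 / m$se^2; w_f <- 1 / f$se^2
  b <- (w_m * m$beta + w_f * f$beta) / (w_m + w_f)
  s <- 1 / sqrt(w_m + w_f)
  n <- m$n + f$n
  data.frame(study = m$study, stratum = "overall", trait = m$trait,
             chrom = m$chrom, pos = m$pos, rsid = shared, ea = m$ea,
             oa = m$oa, eaf = (m$n * m$eaf + f$n * f$eaf) / n,
             beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)), n = n,
             info = (m$n * m$info + f$n * f$info) / n,
             stringsAsFactors = FALSE)
}

#' Genomic-control correction of one study-stratum
#'
#' The inflation factor is \eqn{\lambda_{GC} = \mathrm{median}(z^2)/0.4549364}
#' (the null median of a 1-df chi-square), determined on X-chromosome
#' variants only by default. When \eqn{\lambda > 1}, standard errors are
#' inflated by \eqn{\sqrt\lambda} (equivalent to dividing the chi-square
#' by \eqn{\lambda}) and p-values recomputed; otherwise the records are
#' returned unchanged.
#'
#' @param records summary-statistic data.frame of one study-stratum.
#' @param chrx_only estimate lambda on X-chromosome rows only (the
#'   correction is applied to those same rows).
#' @return list with `lambda` and `records`.
#' @export
genomic_control <- function(records, chrx_only = TRUE) {
  i <- if (chrx_only && "chrom" %in% names(records))
    records$chrom == "X" else rep(TRUE, nrow(records))
  z2 <- (records$beta[i] / records$se[i])^2
  z2 <- z2[is.finite(z2)]
  if (length(z2) == 0) stop("no finite z-scores to estimate lambda from")
  lambda <- stats::median(z2) / stats::qchisq(0.5, df = 1)
  if (lambda > 1) {
    records$se[i] <- records$se[i] * sqrt(lambda)
    records$p[i] <- 2 * stats::pnorm(-abs(records$beta[i] / records$se[i]))
  }
  list(lambda = lambda, records = records)
}

#' Cross-study fixed-effect meta-analysis with eligibility filters
#'
#' Pools harmonized, genomic-control-corrected per-study records per
#' variant with [ivw_combine()]. Weighted EAF and info use study sample
#' sizes as weights; the weighted MAF is min(weighted EAF, 1 - weighted
#' EAF). A variant is flagged `discovery_eligible` when it has at least
#' `min_studies` contributing studies, I-squared at most `i2_max` percent,
#' weighted MAF at least `wmaf_min` and weighted info at least `winfo_min`.
#' Ineligible variants are retained (for interaction and cross-trait
#' lookups) but excluded from locus discovery.
#'
#' @param records stacked per-study records of one stratum and trait.
#' @param min_studies,i2_max,wmaf_min,winfo_min eligibility thresholds.
#' @return data.frame with one row per variant: pooled `beta`, `se`, `p`,
#'   `n_total`, `n_studies`, `q`, `i2`, `weighted_eaf`, `weighted_maf`,
#'   `weighted_info`, `discovery_eligible`.
#' @export
meta_analyze <- function(records, min_studies = 10, i2_max = 95,
                         wmaf_min = 0.02, winfo_min = 0.8) {
  out <- lapply(split(records, records$rsid), function(r) {
    fit <- ivw_combine(r$beta, r$se)
    weaf <- sum(r$n * r$eaf) / sum(r$n)
    winfo <- sum(r$n * r$info) / sum(r$n)
    data.frame(rsid = r$rsid[1], chrom = r$chrom[1], pos = r$pos[1],
               ea = r$ea[1], oa = r$oa[1], stratum = r$stratum[1],
               trait = r$trait[1], beta = fit$beta, se = fit$se, p = fit$p,
               n_total = sum(r$n), n_studies = fit$k, q = fit$q, i2 = fit$i2,
               weighted_eaf = weaf, weighted_maf = min(weaf, 1 - weaf),
               weighted_info = winfo, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$pos), ]
  rownames(out) <- NULL
  out$discovery_eligible <- out$n_studies >= min_studies &
    out$i2 <= i2_max & out$weighted_maf >= wmaf_min &
    out$weighted_info >= winfo_min
  out
}

#' Phenotypic variance explained by a single variant
#'
#' \eqn{r^2 = \beta^2 / (\beta^2 + N \cdot se(\beta)^2)}, returned as a
#' fraction (multiply by 100 for percent). Invariant to the sign of beta.
#'
#' @param beta,se,n vectors of pooled estimate, its SE and sample size.
#' @return vector of fractions of variance explained.
#' @export
variance_explained <- function(beta, se, n) {
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(se <= 0)) stop("`se` must be positive")
  beta^2 / (beta^2 + n * se^2)
}

#' Cross-ancestry meta-regression of per-study effects on ancestry axes
#'
#' Weighted least squares of per-study betas on an intercept plus K axes
#' of genetic variation (supplied externally), with weights 1/se^2.
#' Ancestry-correlated heterogeneity is the Wald chi-square test that all
#' K axis coefficients are zero (df = K); the association test takes all
#' K+1 coefficients jointly (df = K+1); residual heterogeneity is the
#' weighted residual sum of squares on n - K - 1 df.
#'
#' @param beta,se per-study estimates for one variant.
#' @param axes numeric matrix (n_studies x K) of ancestry coordinates.
#' @return list with `coef`, `coef_se`, `p_association`, `p_het_anc`,
#'   `q_resid`, `df_resid`, `p_resid`.
#' @export
ancestry_meta_regression <- function(beta, se, axes) {
  axes <- as.matrix(axes)
  k <- ncol(axes)
  n <- length(beta)
  stopifnot(nrow(axes) == n, length(se) == n, all(se > 0))
  if (n <= k + 1)
    stop("need more studies than ancestry axes plus intercept")
  X <- cbind(intercept = 1, axes)
  if (qr(X)$rank < ncol(X))
    stop("singular design: studies are collinear on the ancestry axes")
  w <- 1 / se^2
  xtwx <- crossprod(X * sqrt(w))
  V <- solve(xtwx)
  gamma <- drop(V %*% crossprod(X, w * beta))
  resid <- beta - drop(X %*% gamma)
  q_resid <- sum(w * resid^2)
  df_resid <- n - k - 1
  # Wald chi-squares on the WLS coefficient vector
  chi_all <- drop(t(gamma) %*% xtwx %*% gamma)
  ax <- seq_len(k) + 1L
  chi_anc <- drop(t(gamma[ax]) %*% solve(V[ax, ax, drop = FALSE]) %*%
                    gamma[ax])
  list(coef = gamma, coef_se = sqrt(diag(V)),
       p_association = stats::pchisq(chi_all, df = k + 1, lower.tail = FALSE),
       p_het_anc = stats::pchisq(chi_anc, df = k, lower.tail = FALSE),
       q_resid = q_resid, df_resid = df_resid,
       p_resid = stats::pchisq(q_resid, df = df_resid, lower.tail = FALSE))
}
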