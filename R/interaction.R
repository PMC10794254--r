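#' Cross-sex correlation of effect estimates
#'
#' Male and female meta-analysis statistics are estimated on overlapping
#' study samples and correlated designs, so their test statistics are not
#' independent; the sex-difference test absorbs this through a
#' chromosome-wide correlation of the paired beta estimates, estimated as
#' a Spearman rank correlation over all shared variants.
#'
#' @param beta_m,beta_f paired effect estimates across variants.
#' @param min_pairs minimum number of shared variants.
#' @return Spearman rank correlation.
#' @seealso [cross_sex_rho_default()] for trait-typical defaults when no
#'   chromosome-wide estimate is possible.
#' @export
estimate_cross_sex_correlation <- function(beta_m, beta_f, min_pairs = 100) {
  ok <- is.finite(beta_m) & is.finite(beta_f)
  if (sum(ok) < min_pairs)
    stop("fewer than ", min_pairs, " shared variants; supply rho ",
         "explicitly (see cross_sex_rho_default())")
  stats::cor(beta_m[ok], beta_f[ok], method = "spearman")
}

#' Default cross-sex correlations by trait type
#'
#' Chromosome-wide cross-sex correlations of beta estimates typical for
#' large kidney-trait meta-analyses: 0.16 for an eGFR-like trait and 0.12
#' for a urate-like trait. Used when too few variants are available to
#' estimate rho from the data at hand.
#'
#' @param trait "eGFR" or "UA".
#' @return the default correlation.
#' @export
cross_sex_rho_default <- function(trait = c("eGFR", "UA")) {
  c(eGFR = 0.16, UA = 0.12)[[match.arg(trait)]]
}

#' Sex-difference (interaction) test for correlated estimates
#'
#' Tests the difference of the sex-specific effect estimates,
#' standardized with the correlation of the two test statistics:
#' \deqn{z = (\beta_m - \beta_f) / \sqrt{se_m^2 + se_f^2 -
#'   2\rho\, se_m se_f}}
#' with a two-sided normal p-value. Ignoring a positive rho is
#' conservative.
#'
#' @param beta_m,se_m,beta_f,se_f sex-specific estimates (vectorized).
#' @param rho cross-sex correlation of test statistics, |rho| < 1.
#' @return list with `z` and `p`.
#' @export
sex_difference_test <- function(beta_m, se_m, beta_f, se_f, rho = 0) {
  stopifnot(all(se_m > 0), all(se_f > 0))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  v <- se_m^2 + se_f^2 - 2 * rho * se_m * se_f
  if (any(v <= 0)) stop("non-positive variance of the difference")
  z <- (beta_m - beta_f) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' X-inactivation sensitivity rescaling of female effects
#'
#' The harmonized female 0/1/2 dosage coding assumes complete random
#' X-inactivation. Under the opposite extreme of complete escape (both
#' alleles expressed), female per-allele effects are over-estimated by a
#' factor 2; halving female betas and SEs before the interaction test
#' gives the sensitivity result under a no-inactivation model. z = beta/SE
#' per sex is unchanged, so only the sex comparison is affected.
#'
#' @param beta_f,se_f female effect estimates.
#' @return list with halved `beta` and `se`.
#' @export
xci_sensitivity <- function(beta_f, se_f) {
  list(beta = beta_f / 2, se = se_f / 2)
}

#' Classify the sex pattern of an association
#'
#' A variant is sex-specific when the interaction is significant, one sex
#' is genome-wide significant and the other is not even nominally
#' associated (labelled by the associated sex); sex-differential when the
#' interaction is significant and both sexes are nominally associated
#' (labelled by the sex with the larger absolute effect); otherwise
#' "none". Male/female colocalization evidence corroborates but does not
#' gate the label.
#'
#' @param p_int interaction p-value(s).
#' @param p_m,p_f,beta_m,beta_f sex-specific statistics (vectorized).
#' @param gw_alpha genome-wide threshold for the associated sex.
#' @param nominal_alpha nominal threshold for "associated at all".
#' @param interaction_alpha interaction significance threshold.
#' @return character vector of labels: "male-specific", "female-specific",
#'   "sex-differential-male-larger", "sex-differential-female-larger",
#'   "none".
#' @export
classify_sex_pattern <- function(p_int, p_m, p_f, beta_m, beta_f,
                                 gw_alpha = 5e-8, nominal_alpha = 0.05,
                                 interaction_alpha = 0.05) {
  n <- length(p_int)
  out <- rep("none", n)
  sig <- p_int < interaction_alpha
  male_spec <- sig & p_m < gw_alpha & p_f >= nominal_alpha
  female_spec <- sig & p_f < gw_alpha & p_m >= nominal_alpha
  diff_both <- sig & p_m < nominal_alpha & p_f < nominal_alpha
  out[diff_both & abs(beta_m) >= abs(beta_f)] <- "sex-differential-male-larger"
  out[diff_both & abs(beta_m) < abs(beta_f)] <- "sex-differential-female-larger"
  out[female_spec] <- "female-specific"
  out[male_spec] <- "male-specific"
  out
}

#' Sex-interaction analysis of index variants
#'
#' Joins male and female meta-analysis records on variant, runs the
#' sex-difference test with the supplied (or estimated) cross-sex
#' correlation, repeats it with female effects halved (the
#' no-X-inactivation sensitivity model) and classifies the sex pattern.
#'
#' @param male_meta,female_meta meta-analysis data.frames (columns `rsid`,
#'   `beta`, `se`, `p`).
#' @param rho cross-sex correlation; `NULL` estimates it from all shared
#'   variants via [estimate_cross_sex_correlation()].
#' @param variants optional variant subset to test (e.g. locus index
#'   SNPs); the correlation is still estimated chromosome-wide.
#' @param ... thresholds passed to [classify_sex_pattern()].
#' @return data.frame with per-variant sex-specific statistics, `rho`,
#'   `z_diff`, `p_interaction`, `p_interaction_no_xci`, `pattern` and
#'   `xci_dependent` (significant under the XCI model but not under the
#'   no-inactivation model).
#' @export
interaction_test <- function(male_meta, female_meta, rho = NULL,
                             variants = NULL,
                             interaction_alpha = 0.05, ...) {
  shared <- intersect(male_meta$rsid, female_meta$rsid)
  m <- male_meta[match(shared, male_meta$rsid), ]
  f <- female_meta[match(shared, female_meta$rsid), ]
  if (is.null(rho))
    rho <- estimate_cross_sex_correlation(m$beta, f$beta)
  if (!is.null(variants)) {
    keep <- shared %in% variants
    m <- m[keep, ]; f <- f[keep, ]; shared <- shared[keep]
  }
  main <- sex_difference_test(m$beta, m$se, f$beta, f$se, rho)
  half <- xci_sensitivity(f$beta, f$se)
  sens <- sex_difference_test(m$beta, m$se, half$beta, half$se, rho)
  pattern <- classify_sex_pattern(main$p, m$p, f$p, m$beta, f$beta,
                                  interaction_alpha = interaction_alpha, ...)
  data.frame(rsid = shared, beta_m = m$beta, se_m = m$se, p_m = m$p,
             beta_f = f$beta, se_f = f$se, p_f = f$p, rho = rho,
             z_diff = main$z, p_interaction = main$p,
             p_interaction_no_xci = sens$p, pattern = pattern,
             xci_dependent = main$p < interaction_alpha &
               sens$p >= interaction_alpha,
             stringsAsFactors = FALSE)
}
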