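#' Run the sex-stratified X-chromosome meta-analysis pipeline
#'
#' End-to-end driver over a panel of per-study, per-sex summary
#' statistics: per study, the X dosage coding is inferred from the
#' standard-error pattern (falling back to the declared convention when
#' no autosomal calibration variants are available or the pattern is
#' ambiguous) and harmonized to male 0/2 / female 0/1/2; per-study QC
#' filters are applied against the reference allele frequencies;
#' genomic-control correction is applied per sex stratum, the sexes are
#' combined per study (after the sex-frequency concordance filter) and
#' the combined results are genomic-control corrected again. Studies are
#' then meta-analyzed per stratum, loci are defined on the overall
#' results and supplemented with sex-stratified loci not covered by them,
#' and the locus index variants are tested for sex interaction (with the
#' no-X-inactivation sensitivity re-test) and classified.
#'
#' @param panel an `xwas_panel` from [simulate_panel()], or an equivalent
#'   list with `records`, `truth`, `coding`.
#' @param rho cross-sex correlation for the interaction test; `NULL`
#'   estimates it chromosome-wide from the sex-stratified meta results,
#'   falling back to [cross_sex_rho_default()] when too few variants are
#'   available.
#' @param trait trait type used for the rho fallback.
#' @param min_studies minimum contributing studies for locus discovery.
#' @param alpha genome-wide significance threshold.
#' @param qc apply per-study QC filters (reference frequencies taken from
#'   the panel's ancestral truth).
#' @param infer_coding infer the dosage coding per study rather than
#'   trusting the declared convention.
#' @return list of class `xwas_result` with elements `meta` (list
#'   `male`, `female`, `overall`), `loci` (with interaction columns
#'   joined at the index variants), `interaction`, `rho`, `lambda`
#'   (per study/stratum genomic-control factors) and `coding_inferred`.
#' @export
run_xwas_pipeline <- function(panel, rho = NULL, trait = "eGFR",
                              min_studies = 10, alpha = 5e-8, qc = TRUE,
                              infer_coding = TRUE) {
  reference <- data.frame(rsid = panel$truth$rsid, ea = "A",
                          eaf = panel$truth$ancestral_freq,
                          stringsAsFactors = FALSE)
  studies <- unique(panel$records$study)
  males <- females <- overalls <- vector("list", length(studies))
  lambdas <- list()
  codings <- list()
  for (i in seq_along(studies)) {
    s <- studies[i]
    recs <- panel$records[panel$records$study == s, ]
    x <- recs[recs$chrom == "X", ]
    auto <- recs[recs$chrom != "X", ]
    declared <- as.list(panel$coding[panel$coding$study == s,
                                     c("male", "female")])
    coding <- declared
    if (infer_coding && nrow(auto) > 0) {
      inferred <- tryCatch(infer_dosage_coding(x, auto),
                           error = function(e) NULL)
      if (!is.null(inferred)) {
        coding <- list(
          male = if (inferred$male == "ambiguous") declared$male
          else inferred$male,
          female = if (inferred$female == "ambiguous") declared$female
          else inferred$female)
        codings[[s]] <- inferred
      }
    }
    x <- harmonize_coding(x, coding)
    m <- x[x$stratum == "male", ]
    f <- x[x$stratum == "female", ]
    if (qc) {
      m <- qc_filter_study(m, reference)$records
      f <- qc_filter_study(f, reference)$records
    }
    gm <- genomic_control(m)
    gf <- genomic_control(f)
    m <- gm$records; f <- gf$records
    keep <- filter_sex_freq_discordance(m, f)
    o <- combine_sexes(m, f, keep)
    go <- genomic_control(o)
    o <- go$records
    lambdas[[s]] <- data.frame(study = s,
                               lambda_male = gm$lambda,
                               lambda_female = gf$lambda,
                               lambda_overall = go$lambda)
    males[[i]] <- m; females[[i]] <- f; overalls[[i]] <- o
  }
  meta <- list(
    male = meta_analyze(do.call(rbind, males), min_studies = min_studies),
    female = meta_analyze(do.call(rbind, females),
                          min_studies = min_studies),
    overall = meta_analyze(do.call(rbind, overalls),
                           min_studies = min_studies))

  loci <- define_loci(meta$overall, alpha = alpha)
  loci <- supplement_strata_loci(loci, define_loci(meta$male, alpha = alpha),
                                 "male")
  loci <- supplement_strata_loci(loci, define_loci(meta$female,
                                                   alpha = alpha), "female")

  if (is.null(rho))
    rho <- tryCatch(
      estimate_cross_sex_correlation(
        meta$male$beta[match(meta$female$rsid, meta$male$rsid)],
        meta$female$beta),
      error = function(e) cross_sex_rho_default(trait))

  interaction <- interaction_test(meta$male, meta$female, rho = rho,
                                  variants = loci$index_rsid)
  if (nrow(loci) > 0) {
    j <- match(loci$index_rsid, interaction$rsid)
    loci$p_interaction <- interaction$p_interaction[j]
    loci$p_interaction_no_xci <- interaction$p_interaction_no_xci[j]
    loci$pattern <- interaction$pattern[j]
    loci$xci_dependent <- interaction$xci_dependent[j]
  }
  structure(list(meta = meta, loci = loci, interaction = interaction,
                 rho = rho, lambda = do.call(rbind, lambdas),
                 coding_inferred = codings),
            class = "xwas_result")
}

#' @export
print.xwas_result <- function(x, ...) {
  cat("sex-stratified X-chromosome meta-analysis\n")
  cat(sprintf("  variants meta-analyzed: %d  rho: %.3f\n",
              nrow(x$meta$overall), x$rho))
  cat(sprintf("  loci: %d\n", nrow(x$loci)))
  if (nrow(x$loci) > 0)
    print(x$loci[, intersect(c("locus", "index_rsid", "index_p", "stratum",
                               "p_interaction", "pattern"), names(x$loci))])
  invisible(x)
}
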