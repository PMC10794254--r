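#' Default pseudoautosomal region intervals (hg19)
#'
#' PAR1 X:60,001-2,699,520 and PAR2 X:154,931,044-155,260,560 on build
#' GRCh37/hg19, 1-based inclusive. Variants inside these X/Y-shared
#' segments are excluded from X-specific analysis.
#'
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
par_intervals_hg19 <- function() {
  data.frame(name = c("PAR1", "PAR2"),
             start = c(60001, 154931044),
             end = c(2699520, 155260560))
}

# Align records to a reference keyed on (rsid, ea): returns records with
# beta/eaf flipped where effect and other allele are swapped relative to the
# reference, plus the matched reference frequency (NA when unmatched).
.align_alleles <- function(records, reference) {
  key <- paste(records$rsid, records$ea)
  ref_key <- paste(reference$rsid, reference$ea)
  hit <- match(key, ref_key)
  swap_key <- paste(records$rsid, records$oa)
  swap <- match(swap_key, ref_key)
  flip <- is.na(hit) & !is.na(swap)
  if (any(flip)) {
    tmp <- records$ea[flip]
    records$ea[flip] <- records$oa[flip]
    records$oa[flip] <- tmp
    records$beta[flip] <- -records$beta[flip]
    records$eaf[flip] <- 1 - records$eaf[flip]
    hit[flip] <- swap[flip]
  }
  records$ref_eaf <- reference$eaf[hit]
  records
}

#' Per-study quality-control filters for summary statistics
#'
#' Applies the standard per-study filters: effect-allele frequency deviating
#' from the reference by more than `af_tol` (after allele alignment: where
#' effect/other alleles are swapped relative to the reference, beta sign and
#' EAF are flipped first), imputation info below `info_min`, minor allele
#' count below `mac_min` (MAC computed as 2 N min(eaf, 1-eaf) on the 0/1/2
#' dosage scale), minor allele frequency below `maf_min`, and position
#' inside a pseudoautosomal region. Removal uses strict inequalities
#' (a variant with info exactly 0.5 or AF deviation exactly 0.20 is kept).
#' A variant failing several filters is counted once, under the first
#' filter in the order above; malformed records (non-positive SE) and
#' variants missing from the reference are dropped beforehand under
#' "malformed" and "unmatched".
#'
#' @param records summary-statistic data.frame for one study-stratum.
#' @param reference data.frame with columns `rsid`, `ea`, `eaf`: reference
#'   allele frequencies keyed on (variant, effect allele).
#' @param af_tol allowed absolute EAF deviation from the reference.
#' @param info_min,mac_min,maf_min lower thresholds (kept at threshold).
#' @param par_intervals data.frame of PAR intervals (1-based inclusive);
#'   applied to X-chromosome rows.
#' @return list with `records` (retained rows, with a `ref_eaf` column) and
#'   `report` (data.frame of per-filter removal counts, in application
#'   order).
#' @export
qc_filter_study <- function(records, reference, af_tol = 0.20,
                            info_min = 0.5, mac_min = 6, maf_min = 0.01,
                            par_intervals = par_intervals_hg19()) {
  records <- .align_alleles(records, reference)
  maf <- pmin(records$eaf, 1 - records$eaf)
  in_par <- rep(FALSE, nrow(records))
  if (!is.null(par_intervals) && nrow(par_intervals) > 0) {
    on_x <- records$chrom == "X"
    for (i in seq_len(nrow(par_intervals)))
      in_par <- in_par | (on_x & records$pos >= par_intervals$start[i] &
                            records$pos <= par_intervals$end[i])
  }
  fails <- cbind(
    malformed = !is.finite(records$se) | records$se <= 0,
    unmatched = is.na(records$ref_eaf),
    af_deviation = abs(records$eaf - records$ref_eaf) > af_tol,
    low_info = records$info < info_min,
    low_mac = 2 * records$n * maf < mac_min,
    low_maf = maf < maf_min,
    par = in_par)
  fails[is.na(fails)] <- FALSE
  first <- apply(fails, 1L, function(f) if (any(f)) which(f)[1] else 0L)
  report <- data.frame(reason = colnames(fails),
                       n_removed = tabulate(first, ncol(fails)))
  list(records = records[first == 0L, , drop = FALSE], report = report)
}

# Median residual-SD proxy from SEs under an assumed 0/1/2 dosage variance.
.median_sd_proxy <- function(records) {
  stats::median(records$se * sqrt(records$n * 2 * records$eaf *
                                    (1 - records$eaf)))
}

.classify_ratio <- function(log_ratio, lo, hi, label_lo, label_hi) {
  third <- (hi - lo) / 3
  if (log_ratio <= lo + third) label_lo
  else if (log_ratio >= hi - third) label_hi
  else "ambiguous"
}

#' Infer the X dosage coding of a study from its standard errors
#'
#' Imputation software differ in how X-chromosome allele dosages are coded
#' (male genotypes 0/1 vs 0/2; female 0/0.5/1 vs 0/1/2), which rescales
#' betas and SEs by a factor 2. The coding leaves a characteristic pattern
#' in the standard errors: for each sex, s = median(se * sqrt(N * 2f(1-f)))
#' estimates the residual SD under autosomal 0/1/2 coding. On the X, male
#' 0/2 coding has dosage variance 4f(1-f), so the ratio of s on X to s on
#' autosomes is 1/sqrt(2); under 0/1 coding it is sqrt(2). For females the
#' expected ratio is 1 under 0/1/2 and 2 under 0/0.5/1. Classification is
#' nearest-expected on the log scale, with the middle third of the log-gap
#' declared "ambiguous" (to be resolved with the study analysts rather than
#' guessed).
#'
#' @param x_records X-chromosome records of one study, both sexes
#'   (`stratum` column distinguishes them).
#' @param auto_records autosomal calibration records of the same study.
#' @param min_variants minimum variants per sex/chromosome group.
#' @return list of class `xwas_coding` with elements `male`, `female`
#'   (labels, possibly "ambiguous") and the diagnostics `ratio_male`,
#'   `ratio_female`.
#' @export
infer_dosage_coding <- function(x_records, auto_records, min_variants = 50) {
  groups <- list(
    male_x = x_records[x_records$stratum == "male", ],
    female_x = x_records[x_records$stratum == "female", ],
    male_auto = auto_records[auto_records$stratum == "male", ],
    female_auto = auto_records[auto_records$stratum == "female", ])
  n <- vapply(groups, nrow, 0L)
  if (any(n < min_variants))
    stop("need at least ", min_variants,
         " variants per sex on X and autosomes to infer the coding")
  s <- vapply(groups, .median_sd_proxy, 0)
  ratio_m <- s[["male_x"]] / s[["male_auto"]]
  ratio_f <- s[["female_x"]] / s[["female_auto"]]
  male <- .classify_ratio(log(ratio_m), log(1 / sqrt(2)), log(sqrt(2)),
                          "0/2", "0/1")
  female <- .classify_ratio(log(ratio_f), 0, log(2), "0/1/2", "0/0.5/1")
  structure(list(male = male, female = female,
                 ratio_male = unname(ratio_m), ratio_female = unname(ratio_f)),
            class = "xwas_coding")
}

#' Harmonize summary statistics to male 0/2 / female 0/1/2 dosage coding
#'
#' Inverse of [inject_coding_convention()]: male records coded 0/1 have
#' beta and SE divided by 2, female records coded 0/0.5/1 likewise.
#' z = beta/SE is unchanged and the operation is idempotent once the
#' records are on the harmonized scale. Refuses an "ambiguous" coding.
#'
#' @param records summary-statistic data.frame (one study, both sexes).
#' @param coding an `xwas_coding` or a list with elements `male`, `female`.
#' @return harmonized records.
#' @export
harmonize_coding <- function(records, coding) {
  if (identical(coding$male, "ambiguous") ||
      identical(coding$female, "ambiguous"))
    stop("coding is ambiguous; resolve with the study analysts first")
  scale_rows <- function(records, stratum) {
    i <- records$stratum == stratum & records$chrom == "X"
    records$beta[i] <- records$beta[i] / 2
    records$se[i] <- records$se[i] / 2
    records
  }
  if (identical(coding$male, "0/1")) records <- scale_rows(records, "male")
  if (identical(coding$female, "0/0.5/1"))
    records <- scale_rows(records, "female")
  records
}

#' Filter variants with discordant male/female allele frequencies
#'
#' For the sex-combined analysis, variants whose male and female
#' effect-allele frequencies differ by more than `tol` are excluded
#' (strict inequality: a difference of exactly `tol` is kept). Variants
#' present in only one sex are excluded from the sex-combined set but
#' remain usable in the sex-stratified analyses.
#'
#' @param male_records,female_records aligned records of one study.
#' @param tol allowed absolute EAF difference.
#' @return character vector of variant identifiers to keep for the
#'   sex-combined analysis.
#' @export
filter_sex_freq_discordance <- function(male_records, female_records,
                                        tol = 0.20) {
  shared <- intersect(male_records$rsid, female_records$rsid)
  em <- male_records$eaf[match(shared, male_records$rsid)]
  ef <- female_records$eaf[match(shared, female_records$rsid)]
  shared[!(abs(em - ef) > tol)]
}
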