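#' Iterative locus definition from meta-analysis results
#'
#' Repeatedly takes the genome-wide significant variant with the smallest
#' p-value as index SNP (ties broken by smaller position), assigns it the
#' 1-Mb segment centered on it, removes all variants inside the segment,
#' and iterates until no significant variant remains. Overlapping (or
#' exactly touching) intervals of the resulting loci are then merged to a
#' fixpoint, keeping the index SNP with the lower p-value for the merged
#' locus. Only discovery-eligible records are considered when the
#' `discovery_eligible` column is present.
#'
#' @param meta meta-analysis data.frame with columns `rsid`, `pos`, `p`
#'   (and optionally `beta`, `se`, `stratum`, `trait`,
#'   `discovery_eligible`).
#' @param alpha genome-wide significance threshold.
#' @param window locus window size in base pairs (centered on the index).
#' @return data.frame with one row per locus: `locus`, `index_rsid`,
#'   `index_pos`, `index_p`, `start`, `end`, `n_sig`, `merged_from`
#'   (comma-separated absorbed index SNPs). Zero rows when nothing is
#'   significant.
#' @export
define_loci <- function(meta, alpha = 5e-8, window = 1e6) {
  if ("discovery_eligible" %in% names(meta))
    meta <- meta[meta$discovery_eligible, , drop = FALSE]
  half <- window / 2
  pool <- meta[order(meta$p, meta$pos), c("rsid", "pos", "p")]
  loci <- list()
  while (nrow(pool) > 0 && pool$p[1] < alpha) {
    idx <- pool[1, ]
    covered <- pool$pos >= idx$pos - half & pool$pos <= idx$pos + half
    loci[[length(loci) + 1L]] <-
      data.frame(index_rsid = idx$rsid, index_pos = idx$pos, index_p = idx$p,
                 start = idx$pos - half, end = idx$pos + half,
                 n_sig = sum(pool$p[covered] < alpha),
                 merged_from = "", stringsAsFactors = FALSE)
    pool <- pool[!covered, , drop = FALSE]
  }
  if (length(loci) == 0)
    return(data.frame(locus = integer(), index_rsid = character(),
                      index_pos = numeric(), index_p = numeric(),
                      start = numeric(), end = numeric(), n_sig = integer(),
                      merged_from = character(), stringsAsFactors = FALSE))
  out <- merge_loci(do.call(rbind, loci))
  out$locus <- seq_len(nrow(out))
  out[, c("locus", setdiff(names(out), "locus"))]
}

#' Merge overlapping locus intervals to a fixpoint
#'
#' Intervals that overlap or touch are merged; the merged locus keeps the
#' index SNP with the lower p-value (ties broken by smaller position) and
#' records the absorbed index SNPs in `merged_from`. Repeated until no two
#' intervals of the trait overlap; idempotent.
#'
#' @param loci locus data.frame as produced by [define_loci()].
#' @return merged locus data.frame ordered by `start`.
#' @export
merge_loci <- function(loci) {
  repeat {
    loci <- loci[order(loci$start, loci$index_pos), , drop = FALSE]
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(loci)) {
      if (loci$start[i + 1L] <= loci$end[i]) {
        a <- loci[i, ]; b <- loci[i + 1L, ]
        win <- if (a$index_p < b$index_p ||
                   (a$index_p == b$index_p && a$index_pos <= b$index_pos))
          a else b
        lose <- if (identical(win, a)) b else a
        win$start <- min(a$start, b$start)
        win$end <- max(a$end, b$end)
        win$n_sig <- a$n_sig + b$n_sig
        win$merged_from <- paste(c(
          if (nzchar(win$merged_from)) win$merged_from,
          lose$index_rsid,
          if (nzchar(lose$merged_from)) lose$merged_from), collapse = ",")
        loci <- rbind(loci[seq_len(i - 1L), , drop = FALSE], win,
                      loci[-seq_len(i + 1L), , drop = FALSE])
        merged_any <- TRUE
      } else i <- i + 1L
    }
    if (!merged_any) break
  }
  rownames(loci) <- NULL
  loci
}

#' Supplement overall loci with sex-stratified loci
#'
#' A sex-stratified locus is added only if its index SNP does not fall
#' inside any locus interval already defined in the overall analysis of
#' the same trait (locus discovery is run primarily on the overall
#' stratum, which can miss hits confined to one sex).
#'
#' @param overall_loci loci from the overall analysis (gets
#'   `stratum = "overall"`).
#' @param strat_loci loci from a sex-stratified analysis.
#' @param stratum label for the supplemented loci.
#' @return combined locus data.frame with a `stratum` column.
#' @export
supplement_strata_loci <- function(overall_loci, strat_loci,
                                   stratum = "male") {
  if (!"stratum" %in% names(overall_loci))
    overall_loci$stratum <- rep("overall", nrow(overall_loci))
  if (nrow(strat_loci) == 0) return(overall_loci)
  inside <- vapply(strat_loci$index_pos, function(p)
    any(p >= overall_loci$start & p <= overall_loci$end), TRUE)
  add <- strat_loci[!inside, , drop = FALSE]
  if (nrow(add) == 0) return(overall_loci)
  add$stratum <- rep(stratum, nrow(add))
  out <- rbind(overall_loci, add)
  out$locus <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cross-trait locus overlap verdict
#'
#' Two loci of different traits are called overlapping when the LD between
#' their index variants is r^2 >= `r2_min` or the colocalization posterior
#' for a shared causal variant is PP(H4) >= `pp4_min` (the disjunctive,
#' deliberately conservative rule for claiming distinct loci). The effect
#' direction is compared at the index variants.
#'
#' @param ld_r2 r-squared between the two index variants (NA if the LD
#'   reference does not cover them; the verdict then rests on coloc alone).
#' @param pp_h4 colocalization PP(H4) between the two signals, in \[0, 1\].
#' @param beta1,beta2 index-variant effects on the shared effect allele.
#' @param r2_min,pp4_min decision thresholds.
#' @return list with `verdict` ("overlap"/"distinct"), `direction`
#'   ("same"/"opposite"/"undefined"), `ld_r2`, `pp_h4`.
#' @export
cross_trait_overlap <- function(ld_r2, pp_h4, beta1 = NA, beta2 = NA,
                                r2_min = 0.1, pp4_min = 0.5) {
  overlap <- (!is.na(ld_r2) && ld_r2 >= r2_min) ||
    (!is.na(pp_h4) && pp_h4 >= pp4_min)
  list(verdict = if (overlap) "overlap" else "distinct",
       direction = direction_concordance(beta1, beta2),
       ld_r2 = ld_r2, pp_h4 = pp_h4)
}

# One-sided p-value for an expected direction from a two-sided Wald p.
.one_sided_p <- function(beta, p_two, matches_expectation) {
  ifelse(matches_expectation, p_two / 2, 1 - p_two / 2)
}

#' Classify a locus' relevance for a secondary trait
#'
#' Looks up the discovery-trait index variant in a secondary trait and
#' tests one-sided in the expected direction (e.g. opposite direction for
#' BUN versus an eGFR hit, same direction for UA versus UA). Relevance is
#' "likely" when the observed direction matches the expectation at
#' one-sided p < `alpha`; "unlikely" when significance is reached in the
#' opposite-to-expected direction; otherwise "inconclusive". A missing
#' lookup record yields "not available".
#'
#' @param beta_disc discovery-trait index effect.
#' @param beta_lookup,p_lookup secondary-trait effect (same effect allele)
#'   and two-sided p-value; `NA` for missing.
#' @param expected_direction "opposite" or "same".
#' @param alpha one-sided significance level.
#' @return list with `label` and `p_one`.
#' @export
classify_secondary_trait <- function(beta_disc, beta_lookup, p_lookup,
                                     expected_direction = c("opposite",
                                                            "same"),
                                     alpha = 0.05) {
  expected_direction <- match.arg(expected_direction)
  if (is.na(beta_lookup) || is.na(p_lookup))
    return(list(label = "not available", p_one = NA_real_))
  same_sign <- sign(beta_disc) == sign(beta_lookup)
  matches <- if (expected_direction == "opposite") !same_sign else same_sign
  p_one <- .one_sided_p(beta_lookup, p_lookup, matches)
  label <- if (matches && p_one < alpha) "likely"
  else if (!matches && (1 - p_one) < alpha) "unlikely"
  else "inconclusive"
  list(label = label, p_one = p_one)
}

#' One-sided replication lookup in an independent study
#'
#' A discovery hit replicates when the replication effect has the same
#' direction and its one-sided p-value (half the two-sided one when the
#' directions agree) is below `alpha`.
#'
#' @param beta_disc discovery effect.
#' @param beta_rep,p_rep replication effect (same effect allele) and
#'   two-sided p-value.
#' @param alpha one-sided significance level.
#' @return list with `p_one`, `replicated`, `degenerate` (TRUE when the
#'   replication beta is exactly zero).
#' @export
replication_lookup <- function(beta_disc, beta_rep, p_rep, alpha = 0.05) {
  if (beta_rep == 0)
    return(list(p_one = NA_real_, replicated = FALSE, degenerate = TRUE))
  same <- sign(beta_rep) == sign(beta_disc)
  p_one <- .one_sided_p(beta_rep, p_rep, same)
  list(p_one = p_one, replicated = same && p_one < alpha,
       degenerate = FALSE)
}
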