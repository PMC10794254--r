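#' Empirical background rate of an annotation
#'
#' Fraction of randomly selected, annotated variants carrying the
#' annotation (e.g. an androgen response element of tier three or better
#' near the variant's gene), with its binomial standard error. Serves as
#' the null rate p0 of the enrichment test.
#'
#' @param annotated logical vector over the sampled variants.
#' @return list with `p0`, `se`, `n`.
#' @export
estimate_background_rate <- function(annotated) {
  annotated <- annotated[!is.na(annotated)]
  n <- length(annotated)
  if (n == 0) stop("empty annotation sample")
  p0 <- mean(annotated)
  list(p0 = p0, se = sqrt(p0 * (1 - p0) / n), n = n)
}

#' Exact binomial enrichment test
#'
#' One-sided exact upper tail P(X >= k) for X ~ Binomial(n, p0): the
#' probability of observing at least `k` annotated candidate genes among
#' `n` loci when the annotation occurs at background rate `p0`.
#'
#' @param k number of annotated loci (0 <= k <= n).
#' @param n number of loci tested.
#' @param p0 background annotation rate, in (0, 1).
#' @return one-sided p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie strictly in (0, 1)")
  if (k < 0 || k > n) stop("`k` must lie in [0, n]")
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

# Criterion helpers for the gene-prioritization rule engine ----------------

.near <- function(pos_a, pos_b, window) {
  !is.na(pos_a) & !is.na(pos_b) & abs(pos_a - pos_b) <= window
}

#' Ordered-criteria candidate-gene prioritization
#'
#' Evaluates, per gene, an ordered rule list and assigns the rank of the
#' first criterion met; the locus' candidate gene(s) are those with the
#' smallest rank (ties all reported). The criteria, in order:
#' \enumerate{
#'   \item missense variant with CADD > `cadd_min` in the credible set
#'     with posterior probability > `pp_min`, in the gene;
#'   \item eQTL colocalization (PP(H4) >= `pp4_min`) in a kidney tissue;
#'   \item eQTL colocalization of a known kidney-function gene in any
#'     tissue;
#'   \item (loci with a significant sex-interaction only) kidney-function
#'     gene near the index variant with an androgen response element of
#'     tier <= 3;
#'   \item kidney-function gene near a high-CADD credible-set variant;
#'   \item kidney-function gene near the index variant;
#'   \item eQTL colocalization of any gene in any tissue;
#'   \item any gene near a high-CADD credible-set variant;
#'   \item any gene near the index variant (fallback: nearest gene).
#' }
#' "Near" means within `window` base pairs of the gene's TSS.
#'
#' @param index_pos index-variant position.
#' @param credible data.frame of credible-set variants: `variant`, `pos`,
#'   `pp`.
#' @param variant_ann data.frame of variant annotations: `variant`,
#'   `gene`, `missense` (logical), `cadd`.
#' @param gene_ann data.frame of gene annotations: `gene`, `tss`,
#'   `are_tier` (integer, NA for none), `are_regulated` (logical),
#'   `kidney` (logical).
#' @param eqtl_coloc data.frame of eQTL colocalization results: `gene`,
#'   `tissue`, `kidney_tissue` (logical), `pp_h4`. May have zero rows.
#' @param has_sex_interaction whether the locus shows a significant
#'   sex-interaction (gates criterion 4).
#' @param window annotation window around TSS/variant, base pairs.
#' @param cadd_min,pp_min,pp4_min evidence thresholds.
#' @return data.frame `gene`, `rank` (9 = proximity fallback, NA = no
#'   criterion met and not nearest), ordered by rank; attribute
#'   `"winners"` holds the top-ranked gene(s).
#' @export
prioritize_genes <- function(index_pos, credible, variant_ann, gene_ann,
                             eqtl_coloc = NULL, has_sex_interaction = FALSE,
                             window = 250000, cadd_min = 10, pp_min = 0.01,
                             pp4_min = 0.75) {
  genes <- unique(gene_ann$gene)
  if (length(genes) == 0) stop("empty gene annotation table")
  if (is.null(eqtl_coloc))
    eqtl_coloc <- data.frame(gene = character(), tissue = character(),
                             kidney_tissue = logical(), pp_h4 = numeric())
  va <- merge(variant_ann, credible, by = "variant")
  high_cadd_pos <- va$pos[!is.na(va$cadd) & va$cadd > cadd_min]
  coloc_ok <- eqtl_coloc[eqtl_coloc$pp_h4 >= pp4_min, , drop = FALSE]

  rank_of <- function(g) {
    ga <- gene_ann[gene_ann$gene == g, ][1, ]
    kidney <- isTRUE(ga$kidney)
    near_idx <- .near(ga$tss, index_pos, window)
    near_cadd <- length(high_cadd_pos) > 0 &&
      any(.near(ga$tss, high_cadd_pos, window))
    crit <- c(
      any(va$gene == g & va$missense & !is.na(va$cadd) & va$cadd > cadd_min &
            va$pp > pp_min),
      any(coloc_ok$gene == g & coloc_ok$kidney_tissue),
      kidney && any(coloc_ok$gene == g),
      has_sex_interaction && kidney && near_idx &&
        !is.na(ga$are_tier) && ga$are_tier <= 3,
      kidney && near_cadd,
      kidney && near_idx,
      any(coloc_ok$gene == g),
      near_cadd,
      near_idx)
    if (any(crit)) which(crit)[1] else NA_integer_
  }
  rank <- vapply(genes, rank_of, 0L)
  if (all(is.na(rank))) {
    # no gene within the window: fall back to the nearest gene
    tss <- gene_ann$tss[match(genes, gene_ann$gene)]
    rank[which.min(abs(tss - index_pos))] <- 9L
  }
  out <- data.frame(gene = genes, rank = rank, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), ]
  rownames(out) <- NULL
  attr(out, "winners") <- out$gene[!is.na(out$rank) &
                                     out$rank == min(out$rank, na.rm = TRUE)]
  out
}
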