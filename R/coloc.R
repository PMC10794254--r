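# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows.
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalization of two association signals
#'
#' Enumerates the five hypotheses for a pair of traits at one locus --
#' H0 no association, H1/H2 association in trait 1/2 only, H3 two
#' distinct causal variants, H4 one shared causal variant -- from
#' per-variant Wakefield approximate Bayes factors. With per-variant
#' prior probabilities p1, p2 of being causal for each trait alone and
#' p12 for both, the (unnormalized) hypothesis weights are
#' H0 = 1, H1 = p1 * S1, H2 = p2 * S2, H3 = p1 p2 (S1 S2 - S12) and
#' H4 = p12 * S12, where S1, S2 sum each trait's ABFs over variants and
#' S12 sums the product of the two traits' ABFs at the same variant.
#' Sums are accumulated on the log scale (log-sum-exp). Both traits must
#' be aligned to the same effect alleles; the variant lists are
#' intersected first.
#'
#' @param stats1,stats2 data.frames with columns `rsid`, `beta`, `se`.
#' @param prior_sd1,prior_sd2 prior effect SDs for the two traits,
#'   typically [estimate_prior_sd()] of each.
#' @param p1,p2,p12 per-variant prior probabilities.
#' @return object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `priors`, `n_shared`, `index_variant` (variant with
#'   the largest joint ABF) and `direction` at that variant.
#' @export
coloc_abf <- function(stats1, stats2, prior_sd1, prior_sd2,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  shared <- intersect(stats1$rsid, stats2$rsid)
  if (length(shared) == 0) stop("no shared variants between the two traits")
  if (length(shared) < 10)
    warning("only ", length(shared), " shared variants; posterior ",
            "probabilities may be unstable")
  a <- stats1[match(shared, stats1$rsid), ]
  b <- stats2[match(shared, stats2$rsid), ]
  l1 <- log_abf(a$beta, a$se, prior_sd1)
  l2 <- log_abf(b$beta, b$se, prior_sd2)
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)
  h <- c(H0 = 0,
         H1 = log(p1) + s1,
         H2 = log(p2) + s2,
         H3 = log(p1) + log(p2) + .logdiffexp(s1 + s2, s12),
         H4 = log(p12) + s12)
  pp <- exp(h - .logsumexp(h))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  top <- which.max(l1 + l2)
  structure(list(pp = pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_shared = length(shared), index_variant = shared[top],
                 direction = direction_concordance(a$beta[top], b$beta[top])),
            class = "coloc_result")
}

#' Direction concordance of two effects at a shared variant
#'
#' "same" when the product of the two betas (on the same effect allele)
#' is positive, "opposite" when negative, "undefined" when either is
#' zero or missing.
#'
#' @param beta1,beta2 effects at the index variant.
#' @return one of "same", "opposite", "undefined".
#' @export
direction_concordance <- function(beta1, beta2) {
  if (is.na(beta1) || is.na(beta2) || beta1 == 0 || beta2 == 0)
    return("undefined")
  if (beta1 * beta2 > 0) "same" else "opposite"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalization posterior probabilities (n shared =",
      x$n_shared, ")\n")
  print(round(x$pp, 4))
  cat("top joint variant:", x$index_variant, "- directions",
      x$direction, "\n")
  invisible(x)
}
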