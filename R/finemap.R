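#' Conditional z-scores given a set of selected variants
#'
#' On the standardized scale, the z-score of variant i conditional on a
#' selected set S with LD matrix R is
#' \deqn{z_{c,i} = (z_i - R_{iS} R_{SS}^{-1} z_S) /
#'   \sqrt{1 - R_{iS} R_{SS}^{-1} R_{Si}}.}
#'
#' @param z named vector of marginal z-scores.
#' @param R LD correlation matrix covering all variants (dimnames match
#'   `names(z)`).
#' @param condition_on variant names to condition on.
#' @return named vector of conditional z-scores for the remaining
#'   variants (NA where the residual variance is numerically zero).
#' @export
conditional_z <- function(z, R, condition_on) {
  keep <- setdiff(names(z), condition_on)
  if (length(condition_on) == 0) return(z[keep])
  Rss <- R[condition_on, condition_on, drop = FALSE]
  A <- solve(Rss, cbind(z[condition_on],
                        t(R[keep, condition_on, drop = FALSE])))
  num <- z[keep] - drop(R[keep, condition_on, drop = FALSE] %*% A[, 1])
  resvar <- 1 - rowSums(R[keep, condition_on, drop = FALSE] *
                          t(A[, -1, drop = FALSE]))
  zc <- ifelse(resvar > 1e-10, num / sqrt(pmax(resvar, 1e-10)), NA_real_)
  stats::setNames(zc, keep)
}

#' Stepwise forward selection of independent signals
#'
#' Conditional-and-joint style selection from summary statistics and an
#' LD reference, on the standardized scale: start with the smallest-p
#' variant if genome-wide significant; at each step compute conditional
#' z-scores for every remaining variant whose maximum r-squared with the
#' selected set is below the collinearity cutoff, and add the variant
#' with the smallest conditional p if it is below `alpha`; iterate to a
#' fixpoint. Joint statistics come from the final multi-variant solve
#' \eqn{b = R_{SS}^{-1} z_S} with variance \eqn{R_{SS}^{-1}}. (A
#' frequency- and N-aware implementation would additionally weight by
#' per-variant dosage variance; on one locus with comparable N the
#' standardized form is equivalent up to scale.)
#'
#' @param z named vector of marginal z-scores for the locus.
#' @param R LD correlation matrix with matching dimnames.
#' @param alpha conditional significance threshold.
#' @param collinearity maximum r-squared between a candidate and any
#'   selected variant.
#' @return data.frame with one row per selected signal: `variant`,
#'   `order`, `z_marginal`, `p_marginal`, `z_conditional`,
#'   `p_conditional` (at selection), `z_joint`, `p_joint`. Zero rows when
#'   nothing is significant.
#' @export
stepwise_select <- function(z, R, alpha = 5e-8, collinearity = 0.9) {
  stopifnot(!is.null(names(z)), all(names(z) %in% rownames(R)))
  empty <- data.frame(variant = character(), order = integer(),
                      z_marginal = numeric(), p_marginal = numeric(),
                      z_conditional = numeric(), p_conditional = numeric(),
                      z_joint = numeric(), p_joint = numeric(),
                      stringsAsFactors = FALSE)
  p_marg <- 2 * stats::pnorm(-abs(z))
  first <- names(z)[order(p_marg, names(z))][1]
  if (p_marg[first] >= alpha) return(empty)
  sel <- first
  z_cond_at_sel <- stats::setNames(z[first], first)
  repeat {
    cand <- setdiff(names(z), sel)
    if (length(cand) == 0) break
    r2max <- apply(R[cand, sel, drop = FALSE]^2, 1L, max)
    cand <- cand[r2max < collinearity]
    if (length(cand) == 0) break
    zc <- conditional_z(z, R, sel)[cand]
    zc <- zc[!is.na(zc)]
    if (length(zc) == 0) break
    pc <- 2 * stats::pnorm(-abs(zc))
    best <- names(zc)[order(pc, names(zc))][1]
    if (pc[best] >= alpha) break
    z_cond_at_sel[best] <- zc[best]
    sel <- c(sel, best)
  }
  Rinv <- solve(R[sel, sel, drop = FALSE])
  b <- drop(Rinv %*% z[sel])
  zj <- b / sqrt(diag(Rinv))
  data.frame(variant = sel, order = seq_along(sel),
             z_marginal = unname(z[sel]), p_marginal = unname(p_marg[sel]),
             z_conditional = unname(z_cond_at_sel[sel]),
             p_conditional = unname(2 * stats::pnorm(-abs(z_cond_at_sel[sel]))),
             z_joint = unname(zj),
             p_joint = unname(2 * stats::pnorm(-abs(zj))),
             stringsAsFactors = FALSE)
}

#' Empirical prior effect SD for approximate Bayes factors
#'
#' The prior standard deviation of the true effect is estimated from the
#' spread of effect estimates within the locus: the difference of the
#' 97.5% and 2.5% percentiles divided by 2 * 1.959964, i.e. the
#' central-95%-range converted to a normal SD, floored at `floor`.
#'
#' @param betas effect estimates within the locus (>= `min_variants`).
#' @param floor lower bound on the returned SD.
#' @param min_variants minimum number of variants required.
#' @return the prior SD (W^0.5).
#' @export
estimate_prior_sd <- function(betas, floor = 1e-6, min_variants = 20) {
  betas <- betas[is.finite(betas)]
  if (length(betas) < min_variants)
    stop("fewer than ", min_variants,
         " variants; supply an explicit prior SD")
  q <- stats::quantile(betas, c(0.025, 0.975), names = FALSE)
  max((q[2] - q[1]) / (2 * stats::qnorm(0.975)), floor)
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For an estimate with sampling variance V = se^2, prior effect variance
#' W = prior_sd^2 and z = beta/se, the log ABF of association against the
#' null is
#' \deqn{\tfrac12 \log\frac{V}{V+W} + \frac{z^2}{2}\cdot\frac{W}{V+W}.}
#'
#' @param beta,se estimate and standard error (vectorized).
#' @param prior_sd prior SD of the true effect (W^0.5, >= 0).
#' @return vector of log approximate Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd >= 0)
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' 99% credible set from approximate Bayes factors
#'
#' Per-variant posterior probabilities are the normalized ABFs over the
#' locus (flat prior over variants, one causal variant assumed); the
#' credible set is the smallest prefix of the PP-descending order whose
#' cumulative PP reaches `coverage`, with ties at the boundary all
#' included. For secondary signals, pass statistics conditional on the
#' other selected signals.
#'
#' @param beta,se per-variant statistics of the locus (marginal, or
#'   conditional on other independent signals).
#' @param prior_sd prior effect SD, typically [estimate_prior_sd()].
#' @param coverage credibility level.
#' @param variants variant identifiers (defaults to names of `beta`).
#' @return object of class `credible_set`: list with `table` (variant,
#'   log_abf, pp, in_set, ordered by descending PP), `members`,
#'   `coverage`, `prior_sd`.
#' @export
credible_set <- function(beta, se, prior_sd, coverage = 0.99,
                         variants = names(beta)) {
  if (length(beta) == 0) stop("empty locus")
  if (is.null(variants)) variants <- paste0("v", seq_along(beta))
  labf <- log_abf(beta, se, prior_sd)
  pp <- exp(labf - .logsumexp(labf))
  ord <- order(pp, decreasing = TRUE)
  cum <- cumsum(pp[ord])
  k <- which(cum >= coverage)[1]
  if (is.na(k)) k <- length(pp)
  in_set <- logical(length(pp))
  in_set[ord[seq_len(k)]] <- TRUE
  in_set[pp == pp[ord[k]]] <- TRUE  # boundary ties all included
  tab <- data.frame(variant = variants, log_abf = labf, pp = pp,
                    in_set = in_set, stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, members = tab$variant[tab$in_set],
                 coverage = coverage, prior_sd = prior_sd),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%.0f%% credible set: %d of %d variants (prior SD %.3g)\n",
              100 * x$coverage, length(x$members), nrow(x$table),
              x$prior_sd))
  invisible(x)
}
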