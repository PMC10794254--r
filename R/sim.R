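#' Simulate an AR(1)-structured LD block
#'
#' Builds a signed correlation matrix with \eqn{r_{ij} = \rho^{|i-j|}}
#' for a decay parameter \eqn{\rho}. This first-order autoregressive
#' structure is a standard stand-in for local LD along a chromosome:
#' adjacent variants are most correlated and correlation decays
#' geometrically with marker distance. The matrix is symmetric, has unit
#' diagonal and is positive definite for any \eqn{0 < \rho \le 1}
#' (at \eqn{\rho = 1} it degenerates to the all-ones matrix of perfect LD).
#'
#' @param n_variants number of variants in the block (>= 1).
#' @param ld_decay decay parameter in (0, 1].
#' @param variants optional character vector of variant identifiers used
#'   as dimnames.
#' @return an `n_variants x n_variants` correlation matrix.
#' @export
#' @examples
#' simulate_ld_block(3, 0.5)
simulate_ld_block <- function(n_variants, ld_decay, variants = NULL) {
  if (length(n_variants) != 1L || is.na(n_variants) || n_variants < 1)
    stop("`n_variants` must be a positive integer")
  if (length(ld_decay) != 1L || is.na(ld_decay) || ld_decay <= 0 || ld_decay > 1)
    stop("`ld_decay` must lie in (0, 1]")
  n <- as.integer(n_variants)
  idx <- seq_len(n)
  R <- ld_decay^abs(outer(idx, idx, "-"))
  if (!is.null(variants)) {
    stopifnot(length(variants) == n)
    dimnames(R) <- list(variants, variants)
  }
  R
}

#' Configuration for the summary-statistic simulator
#'
#' Collects the study design of a simulated multi-study, multi-ancestry,
#' sex-stratified X-chromosome panel. Per-study scalars are recycled to
#' `n_studies`. Effects are specified on the harmonized dosage coding
#' (male 0/2, female 0/1/2); study-specific coding conventions are injected
#' into the emitted statistics afterwards and are part of the ground truth.
#'
#' @param n_studies number of studies.
#' @param n_male,n_female per-study sample sizes (recycled).
#' @param ancestry per-study ancestry label (recycled), e.g. "EUR".
#' @param freq_range range of the ancestral allele frequency (uniform draw).
#' @param fst Balding-Nichols divergence of each ancestry from the ancestral
#'   population; a single value or a named vector keyed by ancestry label.
#' @param n_variants number of X-chromosomal variants (>= 2).
#' @param n_auto_variants number of autosomal calibration variants simulated
#'   under 0/1/2 coding in both sexes (used by dosage-coding inference).
#' @param ld_decay AR(1) LD decay parameter for the X block.
#' @param causal_spec `NULL` or a data.frame with columns `index`,
#'   `beta_male`, `beta_female`: true per-dosage-unit effects on the
#'   harmonized coding.
#' @param xci_escape multiplier in \[1, 2\] applied to female effective
#'   effects: 1 is complete random X-inactivation, 2 complete escape.
#' @param residual_sd residual trait standard deviation.
#' @param coding per-study dosage coding convention: a list
#'   `list(male = "0/2"|"0/1", female = "0/1/2"|"0/0.5/1")` applied to all
#'   studies, or a data.frame with columns `study`, `male`, `female`.
#' @param info_range range of the uniform imputation-info distribution.
#' @param seed integer seed recorded in the output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 10, n_male = 1000, n_female = 1000,
                       ancestry = "EUR", freq_range = c(0.05, 0.95),
                       fst = 0.02, n_variants = 200, n_auto_variants = 0,
                       ld_decay = 0.9, causal_spec = NULL, xci_escape = 1,
                       residual_sd = 1,
                       coding = list(male = "0/2", female = "0/1/2"),
                       info_range = c(0.6, 1.0), seed = 1L) {
  n_studies <- as.integer(n_studies)
  stopifnot(n_studies >= 1, n_variants >= 2, n_auto_variants >= 0,
            residual_sd > 0)
  if (xci_escape < 1 || xci_escape > 2)
    stop("`xci_escape` must lie in [1, 2]")
  if (ld_decay <= 0 || ld_decay > 1) stop("`ld_decay` must lie in (0, 1]")
  if (any(freq_range <= 0) || any(freq_range >= 1) ||
      freq_range[1] > freq_range[2])
    stop("`freq_range` must be an increasing range inside (0, 1)")
  if (any(fst < 0) || any(fst >= 1)) stop("`fst` must lie in [0, 1)")
  n_male <- rep_len(as.integer(n_male), n_studies)
  n_female <- rep_len(as.integer(n_female), n_studies)
  ancestry <- rep_len(as.character(ancestry), n_studies)
  if (!is.null(causal_spec)) {
    causal_spec <- as.data.frame(causal_spec)
    stopifnot(all(c("index", "beta_male", "beta_female") %in%
                    names(causal_spec)))
    if (any(causal_spec$index < 1 | causal_spec$index > n_variants))
      stop("`causal_spec` references a variant index out of range")
  }
  if (is.data.frame(coding)) {
    stopifnot(all(c("study", "male", "female") %in% names(coding)),
              nrow(coding) == n_studies)
  } else {
    coding <- data.frame(study = paste0("study", seq_len(n_studies)),
                         male = coding$male, female = coding$female,
                         stringsAsFactors = FALSE)
  }
  bad <- !(coding$male %in% c("0/2", "0/1")) |
    !(coding$female %in% c("0/1/2", "0/0.5/1"))
  if (any(bad)) stop("unknown coding convention label")
  structure(list(n_studies = n_studies, n_male = n_male, n_female = n_female,
                 ancestry = ancestry, freq_range = freq_range, fst = fst,
                 n_variants = as.integer(n_variants),
                 n_auto_variants = as.integer(n_auto_variants),
                 ld_decay = ld_decay, causal_spec = causal_spec,
                 xci_escape = xci_escape, residual_sd = residual_sd,
                 coding = coding, info_range = info_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One MVN draw block: z ~ N(R %*% ncp, R), via a precomputed upper-triangular
# chol factor U with R = t(U) %*% U.
.draw_z <- function(U, ncp) {
  as.numeric(ncp + crossprod(U, stats::rnorm(nrow(U))))
}

# Balding-Nichols allele frequency draw around ancestral frequency f0.
.bn_freq <- function(f0, fst) {
  if (fst == 0) return(f0)
  a <- f0 * (1 - fst) / fst
  b <- (1 - f0) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(f0), a, b), 1e-3), 1 - 1e-3)
}

.sim_stratum <- function(study, stratum, chrom, pos, rsid, f, n, var_g,
                         ncp, U, residual_sd, info_range, trait) {
  z <- .draw_z(U, ncp)
  se <- residual_sd / sqrt(n * var_g)
  beta <- z * se
  n_alleles <- if (stratum == "male") n else 2 * n
  eaf <- pmin(pmax(f + stats::rnorm(length(f), 0,
                                    sqrt(f * (1 - f) / n_alleles)),
                   1e-4), 1 - 1e-4)
  data.frame(study = study, stratum = stratum, trait = trait, chrom = chrom,
             pos = pos, rsid = rsid, ea = "A", oa = "B", eaf = eaf,
             beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(z)), n = n,
             info = stats::runif(length(f), info_range[1], info_range[2]),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-study sex-stratified X-chromosome summary-statistic panel
#'
#' Summary statistics are simulated directly, without individual-level
#' genotypes: within the LD block, the per-study per-sex z-score vector is
#' drawn from a multivariate normal with mean \eqn{R \lambda} and covariance
#' \eqn{R}, where \eqn{R} is the LD correlation matrix and \eqn{\lambda} the
#' non-centrality vector. For variant j with allele frequency f, the male
#' non-centrality under 0/2 coding is
#' \eqn{\beta_{m,j}\sqrt{N_m \cdot 4f(1-f)}/\sigma} and the female one under
#' 0/1/2 coding is \eqn{\beta_{f,j} \cdot e \cdot \sqrt{N_f \cdot 2f(1-f)}/\sigma},
#' with \eqn{e} the X-inactivation escape multiplier. Standard errors are
#' \eqn{\sigma/\sqrt{N \mathrm{Var}(g)}} and betas recovered as z * SE, so
#' null z-scores are exactly standard normal. Ancestry allele frequencies
#' follow a Balding-Nichols draw around the ancestral frequency. Study-wise
#' dosage coding conventions are then injected with
#' [inject_coding_convention()]. Autosomal calibration variants (all null,
#' LD-free, 0/1/2 coding in both sexes) are appended when requested.
#'
#' @param config a [sim_config()].
#' @return a list of class `xwas_panel` with elements `records` (per-study
#'   per-sex summary statistics), `truth` (per-variant ground truth),
#'   `ld` (X-block correlation matrix), `coding` (per-study convention) and
#'   `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nv <- config$n_variants
  rsid <- sprintf("vX%04d", seq_len(nv))
  pos <- 3e6 + (seq_len(nv) - 1L) * 5000L
  f0 <- stats::runif(nv, config$freq_range[1], config$freq_range[2])
  ancestries <- unique(config$ancestry)
  fst <- config$fst
  if (is.null(names(fst))) fst <- stats::setNames(rep_len(fst,
    length(ancestries)), ancestries)
  freq <- sapply(ancestries, function(a) .bn_freq(f0, fst[[a]]))
  freq <- matrix(freq, nrow = nv, dimnames = list(rsid, ancestries))

  beta_m <- beta_f <- numeric(nv)
  causal <- logical(nv)
  if (!is.null(config$causal_spec)) {
    cs <- config$causal_spec
    beta_m[cs$index] <- cs$beta_male
    beta_f[cs$index] <- cs$beta_female
    causal[cs$index] <- TRUE
  }
  beta_f_eff <- beta_f * config$xci_escape

  R <- simulate_ld_block(nv, config$ld_decay, rsid)
  U <- chol(R)

  na <- config$n_auto_variants
  if (na > 0) {
    rsid_a <- sprintf("vA%04d", seq_len(na))
    pos_a <- 1e6 + (seq_len(na) - 1L) * 5000L
    f0_a <- stats::runif(na, config$freq_range[1], config$freq_range[2])
    freq_a <- sapply(ancestries, function(a) .bn_freq(f0_a, fst[[a]]))
    freq_a <- matrix(freq_a, nrow = na, dimnames = list(rsid_a, ancestries))
    U_a <- diag(na)
  }

  sd0 <- config$residual_sd
  recs <- vector("list", config$n_studies * 2L)
  k <- 0L
  for (s in seq_len(config$n_studies)) {
    sid <- config$coding$study[s]
    anc <- config$ancestry[s]
    f <- freq[, anc]
    nm <- config$n_male[s]; nf <- config$n_female[s]
    var_m <- 4 * f * (1 - f)
    var_f <- 2 * f * (1 - f)
    ncp_m <- R %*% (beta_m * sqrt(nm * var_m) / sd0)
    ncp_f <- R %*% (beta_f_eff * sqrt(nf * var_f) / sd0)
    xm <- .sim_stratum(sid, "male", "X", pos, rsid, f, nm, var_m, ncp_m, U,
                       sd0, config$info_range, "sim")
    xf <- .sim_stratum(sid, "female", "X", pos, rsid, f, nf, var_f, ncp_f, U,
                       sd0, config$info_range, "sim")
    if (na > 0) {
      fa <- freq_a[, anc]
      var_a <- 2 * fa * (1 - fa)
      am <- .sim_stratum(sid, "male", "AUTO", pos_a, rsid_a, fa, nm, var_a,
                         rep(0, na), U_a, sd0, config$info_range, "sim")
      af <- .sim_stratum(sid, "female", "AUTO", pos_a, rsid_a, fa, nf, var_a,
                         rep(0, na), U_a, sd0, config$info_range, "sim")
      xm <- rbind(xm, am); xf <- rbind(xf, af)
    }
    xm <- inject_coding_convention(xm, male = config$coding$male[s])
    xf <- inject_coding_convention(xf, female = config$coding$female[s])
    recs[[k <- k + 1L]] <- xm
    recs[[k <- k + 1L]] <- xf
  }

  truth <- data.frame(rsid = rsid, chrom = "X", pos = pos,
                      causal = causal, beta_male = beta_m,
                      beta_female = beta_f_eff, ancestral_freq = f0,
                      stringsAsFactors = FALSE)
  for (a in ancestries) truth[[paste0("freq_", a)]] <- freq[, a]

  structure(list(records = do.call(rbind, recs), truth = truth, ld = R,
                 coding = config$coding, config = config),
            class = "xwas_panel")
}

#' Inject a study-specific X dosage coding convention
#'
#' Rescales harmonized X-chromosomal effect estimates to an alternative
#' dosage coding. When male genotypes are coded 0/1 instead of 0/2 the
#' dosage range halves, so the per-unit effect and its standard error
#' double; likewise for female 0/0.5/1 versus 0/1/2. Allele frequency,
#' p-value and sample size are unchanged, and z = beta/SE is invariant.
#' Only X-chromosomal rows of the matching stratum are touched; autosomal
#' calibration records keep the common 0/1/2 coding.
#'
#' @param records summary-statistic data.frame on the harmonized coding.
#' @param male,female target convention label: `"0/2"` or `"0/1"` for males,
#'   `"0/1/2"` or `"0/0.5/1"` for females. `NULL` leaves the stratum alone.
#' @return the rescaled records.
#' @export
inject_coding_convention <- function(records, male = NULL, female = NULL) {
  scale_rows <- function(records, stratum, fac) {
    i <- records$stratum == stratum & records$chrom == "X"
    records$beta[i] <- records$beta[i] * fac
    records$se[i] <- records$se[i] * fac
    records
  }
  if (!is.null(male)) {
    if (!male %in% c("0/2", "0/1")) stop("unknown male coding: ", male)
    if (male == "0/1") records <- scale_rows(records, "male", 2)
  }
  if (!is.null(female)) {
    if (!female %in% c("0/1/2", "0/0.5/1"))
      stop("unknown female coding: ", female)
    if (female == "0/0.5/1") records <- scale_rows(records, "female", 2)
  }
  records
}

#' @export
print.xwas_panel <- function(x, ...) {
  cat("X-chromosome summary-statistic panel\n")
  cat(sprintf("  studies: %d  X variants: %d  autosomal: %d  seed: %d\n",
              x$config$n_studies, x$config$n_variants,
              x$config$n_auto_variants, x$config$seed))
  cat(sprintf("  causal variants: %d  xci escape: %.2f\n",
              sum(x$truth$causal), x$config$xci_escape))
  invisible(x)
}
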