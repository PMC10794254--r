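test_that("inverse-variance combination matches direct arithmetic", {
  one <- ivw_combine(0.1, 0.1)
  expect_equal(one$beta, 0.1)
  expect_equal(one$se, 0.1)
  expect_equal(one$q, 0)
  expect_equal(one$i2, 0)

  two <- ivw_combine(c(0.1, 0.3), c(0.1, 0.2))
  expect_equal(two$beta, 0.14)                    # w = (100, 25)
  expect_equal(two$se, 1 / sqrt(125))
  expect_equal(two$q, 100 * 0.04^2 + 25 * 0.16^2) # 0.8
  expect_equal(two$p, 2 * pnorm(-abs(0.14 / two$se)))

  same <- ivw_combine(c(0.2, 0.2), c(0.05, 0.05))
  expect_equal(same$beta, 0.2)
  expect_equal(same$se, 0.05 / sqrt(2))
  expect_equal(same$q, 0)
  expect_error(ivw_combine(numeric(), numeric()), "no estimates")
})

test_that("pooled estimates agree with an independent meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:12, 1)
    beta <- rnorm(k, 0.05, 0.1)
    se <- runif(k, 0.02, 0.2)
    ours <- ivw_combine(beta, se)
    ref <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$se, ref$se, tolerance = 1e-10)
    expect_equal(ours$q, ref$QE, tolerance = 1e-10)
  }
})

test_that("IVW precision never decreases and huge-SE studies are inert", {
  set.seed(4)
  for (i in 1:50) {
    k <- sample(1:10, 1)
    beta <- rnorm(k); se <- runif(k, 0.01, 1)
    fit <- ivw_combine(beta, se)
    expect_lte(fit$se, min(se))
    expect_gte(fit$q, 0)
    expect_true(fit$i2 >= 0 && fit$i2 <= 100)
    inflated <- ivw_combine(c(beta, 5), c(se, max(se) * 1e6))
    expect_equal(inflated$beta, fit$beta, tolerance = 1e-6)
  }
})

test_that("sexes combine by inverse variance with summed sample size", {
  rec <- function(stratum, beta, se, rsid = "v1", eaf = 0.3, n = 1000L)
    data.frame(study = "s1", stratum = stratum, trait = "t", chrom = "X",
               pos = 3e6, rsid = rsid, ea = "A", oa = "B", eaf = eaf,
               beta = beta, se = se, p = 0.5, n = n, info = 0.9)
  eq <- combine_sexes(rec("male", 0.1, 0.05), rec("female", 0.1, 0.05))
  expect_equal(eq$beta, 0.1)
  expect_equal(eq$se, 0.05 / sqrt(2))
  expect_equal(eq$n, 2000)
  expect_equal(eq$stratum, "overall")

  uneq <- combine_sexes(rec("male", 0.2, 0.05), rec("female", 0.0, 0.05))
  expect_equal(uneq$beta, 0.1)
  expect_equal(uneq$se, 0.05 / sqrt(2), tolerance = 1e-12)

  none <- combine_sexes(rec("male", 0.2, 0.05),
                        rec("female", 0.1, 0.05, rsid = "v2"))
  expect_equal(nrow(none), 0)
})

test_that("genomic control corrects only when lambda exceeds one", {
  rec <- function(z, n = length(z))
    data.frame(study = "s", stratum = "male", trait = "t", chrom = "X",
               pos = seq_len(n), rsid = paste0("v", seq_len(n)), ea = "A",
               oa = "B", eaf = 0.3, beta = z * 0.01, se = 0.01,
               p = 2 * pnorm(-abs(z)), n = 1000L, info = 0.9)
  m <- qchisq(0.5, 1)
  null_rec <- rec(rep(sqrt(m), 5))
  out <- genomic_control(null_rec)
  expect_equal(out$lambda, 1)
  expect_equal(out$records, null_rec)

  infl <- rec(c(sqrt(2 * m), sqrt(2 * m), sqrt(2 * m), 2, 0.1))
  out2 <- genomic_control(infl)
  expect_equal(out2$lambda, 2)
  z_corr <- out2$records$beta / out2$records$se
  expect_equal(z_corr[4], 2 / sqrt(2))  # chi-square divided by lambda

  defl <- rec(rep(sqrt(0.9 * m), 5))
  out3 <- genomic_control(defl)
  expect_equal(out3$lambda, 0.9)
  expect_equal(out3$records, defl)
})

test_that("recomputed lambda equals one after correction", {
  set.seed(5)
  for (i in 1:20) {
    z <- rnorm(501, 0, runif(1, 1.05, 2))
    rec <- data.frame(study = "s", stratum = "male", trait = "t",
                      chrom = "X", pos = seq_along(z),
                      rsid = paste0("v", seq_along(z)), ea = "A", oa = "B",
                      eaf = 0.3, beta = z * 0.01, se = 0.01,
                      p = 2 * pnorm(-abs(z)), n = 1000L, info = 0.9)
    out <- genomic_control(rec)
    if (out$lambda > 1)
      expect_equal(genomic_control(out$records)$lambda, 1,
                   tolerance = 1e-6)
  }
})

test_that("meta-analysis flags discovery eligibility without dropping rows", {
  mk <- function(k, rsid, beta = 0.05, se = 0.01, eaf = 0.3, info = 0.95)
    do.call(rbind, lapply(seq_len(k), function(i)
      data.frame(study = paste0("s", i), stratum = "overall", trait = "t",
                 chrom = "X", pos = 3e6, rsid = rsid, ea = "A", oa = "B",
                 eaf = eaf, beta = beta, se = se, p = 0.5, n = 1000L,
                 info = info)))
  good <- mk(12, "v_good")
  few <- mk(8, "v_few")
  rare <- mk(12, "v_rare", eaf = 0.01)
  badinfo <- mk(12, "v_badinfo", info = 0.5)
  het <- mk(12, "v_het")
  set.seed(6)
  het$beta <- rnorm(12, 0, 0.5)  # massive heterogeneity
  out <- meta_analyze(rbind(good, few, rare, badinfo, het))
  expect_equal(nrow(out), 5)  # ineligible variants retained for lookups
  flag <- setNames(out$discovery_eligible, out$rsid)
  expect_true(flag[["v_good"]])
  expect_false(flag[["v_few"]])
  expect_false(flag[["v_rare"]])     # weighted MAF 0.01 < 0.02
  expect_false(flag[["v_badinfo"]])  # weighted info 0.5 < 0.8
  expect_gt(out$i2[out$rsid == "v_het"], 95)
  expect_false(flag[["v_het"]])
  expect_equal(out$n_studies[out$rsid == "v_good"], 12)
  expect_equal(out$n_total[out$rsid == "v_good"], 12000)
})

test_that("variance explained follows the Wald-based formula", {
  expect_equal(variance_explained(0, 0.01, 1000), 0)
  expect_equal(variance_explained(0.1, 0.01, 1000), 0.01 / 0.11)
  expect_equal(variance_explained(-0.1, 0.01, 1000),
               variance_explained(0.1, 0.01, 1000))
  expect_error(variance_explained(0.1, 0.01, 0), "positive")
})

test_that("ancestry meta-regression detects axis-correlated heterogeneity", {
  set.seed(7)
  k <- 3
  n_stud <- 20
  axes <- matrix(rnorm(n_stud * k), n_stud, k)
  se <- runif(n_stud, 0.02, 0.05)

  expect_error(ancestry_meta_regression(rnorm(n_stud), se,
                                        matrix(1, n_stud, k)),
               "singular")

  # null calibration: p_het_anc uniform across replicates
  p_null <- replicate(400, {
    beta <- rnorm(n_stud, 0.02, 0) + rnorm(n_stud, 0, se)
    ancestry_meta_regression(beta, se, axes)$p_het_anc
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)

  # planted effect flipping sign along one axis is detected
  hits <- replicate(100, {
    ax <- matrix(rnorm(n_stud * k, sd = 0.5), n_stud, k)
    ax[, 1] <- rep(c(1, -1), length.out = n_stud)  # EUR/EAS vs AFR contrast
    beta <- 0.05 * ax[, 1] + rnorm(n_stud, 0, se)
    ancestry_meta_regression(beta, se, ax)$p_het_anc < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
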