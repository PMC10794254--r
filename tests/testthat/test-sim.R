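test_that("AR(1) LD block has the stated structure", {
  expect_equal(simulate_ld_block(1, 0.9), matrix(1, 1, 1))
  expect_equal(simulate_ld_block(3, 1.0), matrix(1, 3, 3))
  R <- simulate_ld_block(3, 0.5)
  expect_equal(R[1, 2], 0.5)
  expect_equal(R[2, 3], 0.5)
  expect_equal(R[1, 3], 0.25)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 3))
  expect_true(all(eigen(simulate_ld_block(50, 0.95))$values > 0))
  expect_error(simulate_ld_block(0, 0.5), "positive")
  expect_error(simulate_ld_block(3, 0), "0, 1")
  expect_error(simulate_ld_block(3, 1.2), "0, 1")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(xci_escape = 2.5), "xci_escape")
  expect_error(sim_config(ld_decay = 0), "ld_decay")
  expect_error(sim_config(freq_range = c(0.9, 0.1)), "freq_range")
  expect_error(sim_config(n_variants = 100,
                          causal_spec = data.frame(index = 200,
                                                   beta_male = 1,
                                                   beta_female = 1)),
               "out of range")
  expect_error(sim_config(coding = list(male = "0/3", female = "0/1/2")),
               "coding")
})

test_that("null panel yields standard-normal z and calibrated p-values", {
  cfg <- sim_config(n_studies = 1, n_variants = 2000, ld_decay = 0.001,
                    seed = 7)
  panel <- simulate_panel(cfg)
  for (s in c("male", "female")) {
    r <- panel$records[panel$records$stratum == s, ]
    z <- r$beta / r$se
    expect_lt(abs(mean(z)), 0.1)
    expect_lt(abs(var(z) - 1), 0.1)
    expect_lt(abs(mean(r$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  }
})

test_that("panels are byte-identical under a fixed seed", {
  cfg <- sim_config(n_studies = 2, n_variants = 50, n_auto_variants = 60,
                    seed = 42)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  cfg2 <- sim_config(n_studies = 2, n_variants = 50, n_auto_variants = 60,
                     seed = 43)
  expect_false(identical(simulate_panel(cfg)$records,
                         simulate_panel(cfg2)$records))
})

test_that("planted effects are recovered without bias in both sexes", {
  # equal male/female effects under full XCI: harmonized estimates agree
  # with the truth and with each other across replicates
  b <- 0.08
  est <- t(sapply(1:200, function(i) {
    cfg <- sim_config(n_studies = 1, n_male = 2000, n_female = 2000,
                      n_variants = 20, ld_decay = 0.5,
                      freq_range = c(0.2, 0.8), seed = 1000 + i,
                      causal_spec = data.frame(index = 10, beta_male = b,
                                               beta_female = b))
    r <- simulate_panel(cfg)$records
    r <- r[r$rsid == "vX0010", ]
    c(m = r$beta[r$stratum == "male"], f = r$beta[r$stratum == "female"])
  }))
  for (s in c("m", "f"))
    expect_lt(abs(mean(est[, s]) - b), 3 * sd(est[, s]) / sqrt(nrow(est)))
})

test_that("X-inactivation escape doubles apparent female effects", {
  b <- 0.08
  est <- sapply(1:200, function(i) {
    cfg <- sim_config(n_studies = 1, n_female = 2000, n_variants = 20,
                      ld_decay = 0.5, freq_range = c(0.2, 0.8),
                      xci_escape = 2, seed = 2000 + i,
                      causal_spec = data.frame(index = 10, beta_male = 0,
                                               beta_female = b))
    r <- simulate_panel(cfg)$records
    r$beta[r$rsid == "vX0010" & r$stratum == "female"]
  })
  expect_lt(abs(mean(est) - 2 * b), 3 * sd(est) / sqrt(length(est)))
})

test_that("coding-convention injection rescales beta and SE, not z", {
  rec <- data.frame(study = "s", stratum = c("male", "female"), trait = "t",
                    chrom = "X", pos = 1:2, rsid = c("a", "b"),
                    ea = "A", oa = "B", eaf = 0.3, beta = 0.10, se = 0.02,
                    p = 0.5, n = 100L, info = 0.9)
  same <- inject_coding_convention(rec, male = "0/2", female = "0/1/2")
  expect_identical(same, rec)
  out <- inject_coding_convention(rec, male = "0/1", female = "0/0.5/1")
  expect_equal(out$beta, c(0.20, 0.20))
  expect_equal(out$se, c(0.04, 0.04))
  expect_equal(out$beta / out$se, rec$beta / rec$se)
  expect_equal(out[c("eaf", "p", "n")], rec[c("eaf", "p", "n")])
  # round trip through harmonization restores the original values
  back <- harmonize_coding(out, list(male = "0/1", female = "0/0.5/1"))
  expect_equal(back, rec)
  expect_error(inject_coding_convention(rec, male = "0/3"), "unknown")
})

test_that("panel round-trips through the tab-separated on-disk format", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_studies = 2, n_variants = 30, seed = 5)
  panel <- simulate_panel(cfg)
  write_panel(panel, dir)
  expect_setequal(list.files(dir),
                  c("study1.tsv", "study2.tsv", "truth.tsv", "ld.tsv",
                    "manifest.tsv"))
  r1 <- read_summary_stats(file.path(dir, "study1.tsv"))
  orig <- panel$records[panel$records$study == "study1", ]
  rownames(orig) <- NULL
  expect_equal(r1[, c("rsid", "beta", "se", "p", "eaf")],
               orig[, c("rsid", "beta", "se", "p", "eaf")])
  ld <- read_ld_matrix(file.path(dir, "ld.tsv"))
  expect_equal(unname(ld), unname(panel$ld))
  manifest <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                         sep = "\t")
  expect_equal(manifest$value[manifest$key == "seed"], 5)
})
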