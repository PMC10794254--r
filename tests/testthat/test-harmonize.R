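make_records <- function(n = 10, pos = seq(3e6, by = 5000, length.out = n),
                         eaf = rep(0.3, n), se = rep(0.02, n),
                         info = rep(0.9, n), n_samp = rep(1000L, n),
                         stratum = "male") {
  data.frame(study = "s1", stratum = stratum, trait = "t", chrom = "X",
             pos = pos, rsid = sprintf("v%03d", seq_len(n)), ea = "A",
             oa = "B", eaf = eaf, beta = rep(0.01, n), se = se, p = 0.5,
             n = n_samp, info = info, stringsAsFactors = FALSE)
}

ref_for <- function(records) {
  data.frame(rsid = records$rsid, ea = records$ea, eaf = records$eaf,
             stringsAsFactors = FALSE)
}

test_that("QC filters apply the stated thresholds with strict boundaries", {
  rec <- make_records(6)
  rec$info[3] <- 0.5                            # exactly at threshold: keep
  rec$info[4] <- 0.49                           # below: remove
  rec$eaf[5] <- 0.005                           # MAF < 0.01 and MAC = 10
  ref <- ref_for(rec)
  ref$eaf[1] <- 0.80                            # deviates by 0.5: remove
  ref$eaf[2] <- 0.50                            # deviates by exactly 0.2: keep
  out <- qc_filter_study(rec, ref)
  expect_setequal(out$records$rsid, c("v002", "v003", "v006"))
  rep <- setNames(out$report$n_removed, out$report$reason)
  expect_equal(unname(rep["af_deviation"]), 1)
  expect_equal(unname(rep["low_info"]), 1)
  # v005: MAC = 2*1000*0.005 = 10 >= 6 passes MAC, fails MAF
  expect_equal(unname(rep["low_maf"]), 1)
  expect_equal(sum(out$report$n_removed), nrow(rec) - nrow(out$records))
})

test_that("PAR variants and malformed/unmatched records are removed", {
  rec <- make_records(4, pos = c(60500, 2e6, 3e6, 155e6))
  ref <- ref_for(rec)[-4, ]  # last variant missing from reference
  rec$se[3] <- 0
  out <- qc_filter_study(rec, ref)
  expect_equal(nrow(out$records), 0)
  rep <- setNames(out$report$n_removed, out$report$reason)
  expect_equal(unname(rep["par"]), 2)        # PAR1 at 60,500 and 2 Mb
  expect_equal(unname(rep["malformed"]), 1)
  expect_equal(unname(rep["unmatched"]), 1)
})

test_that("allele alignment flips beta and EAF for swapped alleles", {
  rec <- make_records(2, eaf = c(0.3, 0.25))
  rec$ea[2] <- "B"; rec$oa[2] <- "A"  # swapped relative to reference
  ref <- data.frame(rsid = rec$rsid, ea = "A", eaf = c(0.3, 0.75))
  out <- qc_filter_study(rec, ref)
  expect_equal(nrow(out$records), 2)
  v2 <- out$records[out$records$rsid == "v002", ]
  expect_equal(v2$ea, "A")
  expect_equal(v2$eaf, 0.75)
  expect_equal(v2$beta, -0.01)
})

test_that("the retained set is insensitive to filter order", {
  set.seed(1)
  rec <- make_records(200, eaf = runif(200, 0.005, 0.995),
                      info = runif(200, 0.3, 1),
                      pos = sample(c(6e4, seq(3e6, 4e6, length.out = 199))))
  ref <- ref_for(rec)
  ref$eaf <- pmin(pmax(ref$eaf + rnorm(200, 0, 0.15), 0.01), 0.99)
  out <- qc_filter_study(rec, ref)
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  pass <- abs(rec$eaf - ref$eaf) <= 0.2 & rec$info >= 0.5 &
    2 * rec$n * maf >= 6 & maf >= 0.01 &
    !(rec$pos >= 60001 & rec$pos <= 2699520)
  expect_setequal(out$records$rsid, rec$rsid[pass])
})

test_that("dosage coding is inferred from the SE ratio pattern", {
  conventions <- expand.grid(male = c("0/2", "0/1"),
                             female = c("0/1/2", "0/0.5/1"),
                             stringsAsFactors = FALSE)
  for (i in seq_len(nrow(conventions))) {
    cfg <- sim_config(n_studies = 1, n_male = 1000, n_female = 1000,
                      n_variants = 200, n_auto_variants = 200,
                      ld_decay = 0.5, seed = 100 + i,
                      coding = list(male = conventions$male[i],
                                    female = conventions$female[i]))
    panel <- simulate_panel(cfg)
    r <- panel$records
    coding <- infer_dosage_coding(r[r$chrom == "X", ], r[r$chrom != "X", ])
    expect_equal(coding$male, conventions$male[i])
    expect_equal(coding$female, conventions$female[i])
    if (conventions$male[i] == "0/2")
      expect_true(coding$ratio_male > 0.6 && coding$ratio_male < 0.85)
    else
      expect_true(coding$ratio_male > 1.2 && coding$ratio_male < 1.7)
  }
})

test_that("identical X and autosomal SE patterns give female 0/1/2", {
  rec_x <- rbind(make_records(60, stratum = "male"),
                 make_records(60, stratum = "female"))
  rec_a <- rec_x
  rec_a$chrom <- "AUTO"
  coding <- infer_dosage_coding(rec_x, rec_a)
  expect_equal(coding$female, "0/1/2")
  expect_equal(coding$ratio_female, 1)
  # ratio 1 for males falls in the ambiguous middle third
  expect_equal(coding$male, "ambiguous")
  expect_error(harmonize_coding(rec_x, coding), "ambiguous")
})

test_that("harmonization inverts injection and is idempotent", {
  set.seed(2)
  for (i in 1:20) {
    rec <- make_records(4, se = runif(4, 0.01, 0.1),
                        stratum = sample(c("male", "female"), 4,
                                         replace = TRUE))
    rec$beta <- rnorm(4, 0, 0.05)
    male <- sample(c("0/2", "0/1"), 1)
    female <- sample(c("0/1/2", "0/0.5/1"), 1)
    coded <- inject_coding_convention(rec, male = male, female = female)
    back <- harmonize_coding(coded, list(male = male, female = female))
    expect_equal(back, rec)
    expect_equal(harmonize_coding(back, list(male = "0/2",
                                             female = "0/1/2")), back)
    expect_equal(coded$beta / coded$se, rec$beta / rec$se)
  }
})

test_that("sex frequency discordance filter uses a strict 20% rule", {
  m <- make_records(4, eaf = c(0.30, 0.10, 0.40, 0.5), stratum = "male")
  f <- make_records(4, eaf = c(0.35, 0.35, 0.60, 0.5), stratum = "female")
  keep <- filter_sex_freq_discordance(m, f)
  expect_setequal(keep, c("v001", "v003", "v004"))  # 0.20 exactly is kept
  # variant present in one sex only is excluded from the combined set
  keep2 <- filter_sex_freq_discordance(m[1:2, ], f)
  expect_setequal(keep2, "v001")
})
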