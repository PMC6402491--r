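test_that("summary statistics round-trip through the TSV dialect", {
  df <- make_sumstats(3)
  path <- write_sumstats_file(df)
  rec <- read_summary_stats(path, quiet = TRUE)
  expect_s3_class(rec, "gwas_sumstats")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$snp_id, df$snp_id)
  expect_equal(rec$beta, df$beta)
  expect_equal(nrow(attr(rec, "rejected")), 0)

  # gz round trip
  gz <- tempfile(fileext = ".tsv.gz")
  write_summary_stats(rec, gz)
  rec2 <- read_summary_stats(gz, quiet = TRUE)
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("column mapping gives records identical to the canonical header", {
  df <- make_sumstats(3)
  canonical <- read_summary_stats(write_sumstats_file(df), quiet = TRUE)
  names(df)[names(df) == "beta"] <- "logOR"
  names(df)[names(df) == "snp_id"] <- "MarkerName"
  mapped <- read_summary_stats(write_sumstats_file(df),
                               column_map = c(beta = "logOR",
                                              snp_id = "MarkerName"),
                               quiet = TRUE)
  expect_equal(as.data.frame(mapped), as.data.frame(canonical))
})

test_that("invalid rows are rejected with reasons, valid rows kept in order", {
  df <- make_sumstats(5)
  df$se[2] <- 0                  # non-positive SE
  df$effect_allele[4] <- "AT"    # indel-like allele
  rec <- suppressMessages(read_summary_stats(write_sumstats_file(df)))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$snp_id, df$snp_id[c(1, 3, 5)])
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$snp_id, c("rs2", "rs4"))
  expect_match(rej$reason[rej$snp_id == "rs2"], "SE")
})

test_that("missing mapped column and unparseable numerics are format errors", {
  df <- make_sumstats(2)
  df$pvalue <- NULL
  expect_error(read_summary_stats(write_sumstats_file(df)), "pvalue")
  df2 <- make_sumstats(2)
  df2$beta <- c("0.05", "not-a-number")
  expect_error(read_summary_stats(write_sumstats_file(df2)), "line 3")
})

test_that("harmonization aligns swapped alleles and reorients the exposure", {
  # outcome stored on the swapped allele pair: beta negated
  exp1 <- make_sumstats(1, beta = 0.05, ea = "A", oa = "G")
  out1 <- make_sumstats(1, beta = 0.01, ea = "G", oa = "A", eaf = 0.7)
  h1 <- harmonize(exp1, out1)
  expect_equal(h1$gamma, 0.05)
  expect_equal(h1$beta, -0.01)

  # negative exposure effect: both flipped so gamma > 0
  exp2 <- make_sumstats(1, beta = -0.05, ea = "A", oa = "G")
  out2 <- make_sumstats(1, beta = 0.01, ea = "A", oa = "G")
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$gamma, 0.05)
  expect_equal(h2$beta, -0.01)

  # strand-flipped outcome (A/G recorded as T/C): aligned without sign change
  exp3 <- make_sumstats(1, beta = 0.05, ea = "A", oa = "G")
  out3 <- make_sumstats(1, beta = 0.01, ea = "T", oa = "C")
  h3 <- harmonize(exp3, out3)
  expect_equal(h3$beta, 0.01)

  # incompatible alleles dropped with reason
  out4 <- make_sumstats(1, beta = 0.01, ea = "A", oa = "C")
  h4 <- harmonize(exp3, out4)
  expect_equal(nrow(h4), 0)
  expect_equal(attr(h4, "drops")$reason, "allele-mismatch")
})

test_that("palindromic SNPs follow the configured policy", {
  expp <- make_sumstats(1, beta = 0.05, ea = "A", oa = "T", eaf = 0.50)
  outp <- make_sumstats(1, beta = 0.01, ea = "A", oa = "T", eaf = 0.50)

  # ambiguous frequency inside the window -> dropped
  expect_error(harmonize(expp, outp, palindrome_policy = "infer_by_eaf",
                         eaf_ambiguity_window = 0.08), NA)
  h <- harmonize(expp, outp)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "drops")$reason, "palindromic-ambiguous")

  # informative frequencies, concordant -> retained unflipped
  expi <- make_sumstats(1, beta = 0.05, ea = "A", oa = "T", eaf = 0.2)
  outi <- make_sumstats(1, beta = 0.01, ea = "A", oa = "T", eaf = 0.25)
  hi <- harmonize(expi, outi)
  expect_equal(hi$beta, 0.01)

  # informative but discordant -> interpreted as other strand, flipped
  outd <- make_sumstats(1, beta = 0.01, ea = "A", oa = "T", eaf = 0.75)
  hd <- harmonize(expi, outd)
  expect_equal(hd$beta, -0.01)

  # drop_ambiguous drops every palindromic SNP regardless of frequency
  hda <- harmonize(expi, outi, palindrome_policy = "drop_ambiguous")
  expect_equal(nrow(hda), 0)
  expect_equal(attr(hda, "drops")$reason, "palindromic")

  # keep aligns by labels alone
  hk <- harmonize(expi, outd, palindrome_policy = "keep")
  expect_equal(hk$beta, 0.01)

  # missing eaf under infer_by_eaf -> dropped
  expm <- make_sumstats(1, beta = 0.05, ea = "A", oa = "T", eaf = NA)
  hm <- harmonize(expm, outi)
  expect_equal(nrow(hm), 0)
})

test_that("harmonization bookkeeping: duplicates, no overlap, set arithmetic", {
  exp5 <- make_sumstats(4)
  out5 <- make_sumstats(4)
  dup <- rbind(exp5, exp5[1, ])
  expect_error(harmonize(dup, out5), "rs1")
  expect_error(harmonize(exp5, make_sumstats(2, ids = c("rsX", "rsY"))),
               "no shared instruments")

  # retained + dropped = id intersection; unmatched logged
  out6 <- make_sumstats(3, ids = c("rs2", "rs3", "rs99"))
  h <- harmonize(exp5, out6)
  drops <- attr(h, "drops")
  shared <- intersect(exp5$snp_id, out6$snp_id)
  dropped_shared <- drops$snp_id[drops$reason != "unmatched"]
  expect_equal(nrow(h) + length(dropped_shared), length(shared))
  expect_setequal(drops$snp_id[drops$reason == "unmatched"],
                  c("rs1", "rs4", "rs99"))
})

test_that("harmonized sets round-trip through write_mr_data/read_mr_data", {
  exp1 <- make_sumstats(5, beta = c(0.05, -0.02, 0.03, 0.04, 0.06))
  out1 <- make_sumstats(5, beta = c(0.01, 0.02, -0.01, 0.005, 0.012),
                        ea = c("G", "A", "A", "A", "A"),
                        oa = c("A", "G", "G", "G", "G"))
  h <- harmonize(exp1, out1)
  path <- tempfile(fileext = ".tsv")
  write_mr_data(h, path)
  h2 <- read_mr_data(path)
  expect_equal(h2$gamma, h$gamma)
  expect_equal(h2$se_gamma, h$se_gamma)
  expect_equal(h2$beta, h$beta)
  expect_equal(h2$se_beta, h$se_beta)
  expect_equal(attr(h2, "drops")$snp_id, attr(h, "drops")$snp_id)
})

test_that("orientation invariance: flipping labels and sign of any input record leaves results unchanged", {
  set.seed(11)
  n <- 20
  exp0 <- make_sumstats(n, beta = rnorm(n, 0.08, 0.03),
                        se = rep(0.01, n),
                        ea = rep("A", n), oa = rep("G", n),
                        eaf = runif(n, 0.1, 0.4))
  out0 <- make_sumstats(n, beta = rnorm(n, 0.003, 0.01),
                        se = rep(0.008, n),
                        ea = rep("A", n), oa = rep("G", n),
                        eaf = runif(n, 0.1, 0.4))
  h0 <- harmonize(exp0, out0)

  flip <- sample(n, 8)
  exp1 <- exp0
  exp1$beta[flip] <- -exp1$beta[flip]
  exp1$eaf[flip] <- 1 - exp1$eaf[flip]
  exp1$effect_allele[flip] <- "G"
  exp1$other_allele[flip] <- "A"
  h1 <- harmonize(exp1, out0)
  expect_equal(h1$gamma, h0$gamma)
  expect_equal(h1$beta, h0$beta)

  # downstream estimate identical too
  f0 <- mr_fit(h0, "ivw_fixed")
  f1 <- mr_fit(h1, "ivw_fixed")
  expect_equal(f1$alpha, f0$alpha)
  expect_equal(f1$se_alpha, f0$se_alpha)
})
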