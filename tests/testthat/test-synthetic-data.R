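test_that("degenerate truths produce the forced latent states", {
  des <- design_params(n_pairs = 10, samples_per_site = c(3, 3))
  off <- generate_dataset(des, truth_params(beta = c(-10, -10)), seed = 5)
  expect_true(all(off$truth$z == 0))
  expect_true(all(off$truth$a == 0))

  on <- generate_dataset(des, truth_params(beta = c(10, 10), alpha = 10,
                                           delta = c(0.4, -0.3),
                                           false_amp_rate = 0), seed = 5)
  expect_true(all(on$truth$z == 1))
  expect_true(all(on$truth$a == 1))
})

test_that("the seed contract holds: same seed identical, new seed differs", {
  des <- design_params(n_pairs = 6)
  tru <- truth_params()
  g1 <- generate_dataset(des, tru, seed = 42)
  g2 <- generate_dataset(des, tru, seed = 42)
  g3 <- generate_dataset(des, tru, seed = 43)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$tables$replicates$m_pos,
                         g3$tables$replicates$m_pos))
})

test_that("replicate positivity matches the logistic detection model (Monte Carlo)", {
  # 400 fully occupied samples x 5 replicates = 2000 Bernoulli trials whose
  # success probabilities are logit^-1(v'delta)
  des <- design_params(n_pairs = 100, samples_per_site = c(2, 2))
  tru <- truth_params(beta = c(10, 10), alpha = 10, delta = c(0.45, -0.33),
                      false_amp_rate = 0)
  g <- generate_dataset(des, tru, seed = 99)
  p <- g$truth$p_rep
  expect_equal(length(g$dataset$y), 2000)
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(g$dataset$y) - mean(p)), 3 * se)
})

test_that("site occupancy rates converge to logit^-1(x'beta) (Monte Carlo)", {
  des <- design_params(n_pairs = 1000, samples_per_site = c(1, 1),
                       n_replicates = 1)
  tru <- truth_params(beta = c(colony = 0.8, control = -0.6), alpha = 0,
                      delta = 0, false_amp_rate = 0)
  g <- generate_dataset(des, tru, seed = 7)
  for (tp in c("colony", "control")) {
    z <- g$truth$z[g$dataset$sites$island_type == tp]
    pr <- plogis(tru$beta[[tp]])
    expect_lt(abs(mean(z) - pr), 3 * sqrt(pr * (1 - pr) / length(z)))
  }
})

test_that("no detection arises without occurrence when false amplification is off", {
  des <- design_params(n_pairs = 40)
  tru <- truth_params(false_amp_rate = 0)
  g <- generate_dataset(des, tru, seed = 13)
  a_rep <- g$truth$a[g$dataset$sample_of_rep]
  expect_true(all(g$dataset$y[a_rep == 0] == 0))
  expect_true(all(g$truth$a <= g$truth$z[g$dataset$site_of_sample]))
  expect_true(all(g$truth$lambda_true[g$truth$a == 0] == 0))
  expect_true(all(g$truth$lambda_true[g$truth$a == 1] > 0))

  # with the false-amplification channel on, spurious positives exist but are
  # recorded at droplet level only, never in lambda_true
  g2 <- generate_dataset(des, truth_params(false_amp_rate = 0.05), seed = 13)
  expect_true(all(g2$truth$lambda_true[g2$truth$a == 0] == 0))
})

test_that("truth_report equals an independent recount of the stored states", {
  g <- generate_dataset(design_params(n_pairs = 12), truth_params(), seed = 7)
  rep_tab <- truth_report(g$truth, g$dataset)
  sites <- g$dataset$sites
  for (tp in c("colony", "control")) {
    z <- g$truth$z[sites$island_type == tp]
    expect_equal(rep_tab$true_occupancy[rep_tab$island_type == tp], mean(z))
    samp_sites <- sites$island_type[g$dataset$site_of_sample]
    in_occ <- samp_sites == tp & g$truth$z[g$dataset$site_of_sample] == 1
    if (any(in_occ))
      expect_equal(rep_tab$true_occurrence[rep_tab$island_type == tp],
                   sum(g$truth$a[in_occ]) / sum(in_occ))
  }
  # all-occupied / half-occurrence arithmetic
  half <- g$truth
  half$z[] <- 1L
  half$a[] <- rep_len(c(0L, 1L), length(half$a))
  rt <- truth_report(half, g$dataset)
  expect_equal(rt$true_occupancy, c(1, 1))
  expect_equal(mean(rt$true_occurrence),
               mean(tapply(half$a, g$dataset$sites$island_type[
                 g$dataset$site_of_sample], mean)))
  bad <- g$truth
  names(bad$z)[1] <- "nonsense"
  expect_error(truth_report(bad, g$dataset), "consistency error")
})

test_that("generator rejects inconsistent configurations", {
  expect_error(design_params(n_pairs = 0), "configuration error")
  expect_error(design_params(droplets_per_reaction = c(10, 2e6)),
               "configuration error")
  expect_error(design_params(droplet_volume = 0), "configuration error")
  expect_error(truth_params(beta = 1:3), "dimension error")
  expect_error(truth_params(delta = numeric(0)), "dimension error")
  expect_error(truth_params(false_amp_rate = 0.2), "configuration error")
})

test_that("the deterministic fixture satisfies every count constraint at once", {
  fp <- fixture_products()
  fx <- fp$fx
  # design shape
  expect_equal(nrow(fx$sites), 30)
  n_by_type <- table(fx$sites$island_type[match(fx$samples$site_id,
                                                fx$sites$site_id)])
  expect_equal(unname(n_by_type[c("colony", "control")]), c(137L, 128L),
               ignore_attr = TRUE)
  # LOB comes out at the NTC value
  expect_equal(round(fp$lob$value, 3), 0.258)
  expect_identical(fp$lob$source_control_id, "NC09")

  conc <- fp$samples$concentration
  type <- fx$sites$island_type[match(fp$samples$site_id, fx$sites$site_id)]
  # positives: 19 colony over 10 sites as (2x9, 1); 5 control over 4 as (2,1,1,1)
  pos_col <- fp$samples$site_id[type == "colony" & conc > 0]
  pos_ctl <- fp$samples$site_id[type == "control" & conc > 0]
  expect_equal(length(pos_col), 19)
  expect_equal(sort(as.integer(table(pos_col)), decreasing = TRUE),
               c(rep(2L, 9), 1L))
  expect_equal(length(pos_ctl), 5)
  expect_equal(sort(as.integer(table(pos_ctl)), decreasing = TRUE),
               c(2L, 1L, 1L, 1L))
  # printed concentration endpoints
  expect_equal(round(range(conc[type == "colony" & conc > 0]), 2),
               c(0.26, 38.29))
  expect_equal(round(range(conc[type == "control" & conc > 0]), 2),
               c(0.26, 0.39))
  # site totals: mean prints 3.20 / 0.11, max site total prints 38.6
  tot <- tapply(conc, fp$samples$site_id, sum)
  col_tot <- tot[grep("^C", names(tot))]
  ctl_tot <- tot[grep("^X", names(tot))]
  expect_equal(round(mean(col_tot), 2), 3.20)
  expect_equal(round(mean(ctl_tot), 2), 0.11)
  expect_equal(round(max(col_tot), 1), 38.6)
  # clock and temperature design counts
  dc <- design_counts(fp$samples, fx$sites)
  expect_equal(dc$by_type$before_cutoff[dc$by_type$island_type == "colony"], 97)
  expect_equal(dc$by_type$before_cutoff[dc$by_type$island_type == "control"], 91)
  expect_equal(dc$temperature$in_range, 218)
  # exactly three pairs fail the 8 degree rule
  pc <- exclude_pairs(fp$samples, fx$sites)
  expect_equal(sum(pc$excluded), 3)
  expect_equal(sum(!pc$excluded), 12)
  # temperatures are complete, so imputation must not change anything
  imp <- impute_temperature(fx$samples)
  expect_equal(imp$water_temp_c, fx$samples$water_temp_c)
  expect_false(any(imp$temp_imputed))
})

test_that("fixture regeneration is byte-identical and matches the shipped CSVs", {
  fx1 <- survey_fixture()
  fx2 <- survey_fixture()
  expect_identical(fx1, fx2)
  shipped <- system.file("extdata", "fixture", package = "ednaocc")
  expect_true(nzchar(shipped))
  tmp <- withr::local_tempdir()
  write_tables(fx1, tmp)
  for (f in c("sites.csv", "samples.csv", "replicates.csv",
              "neg_controls.csv")) {
    expect_identical(readLines(file.path(tmp, f)),
                     readLines(file.path(shipped, f)),
                     label = f)
  }
})

test_that("pooled droplet counts of fixture positives reproduce the stated concentrations", {
  fp <- fixture_products()
  v <- 0.00085
  # invert each positive sample's pooled counts independently
  pos <- fp$quant[fp$quant$lambda_hat > 0, ]
  for (i in seq_len(nrow(pos))) {
    lam <- invert_partition(pos$m_total[i], pos$m_pos[i], v)
    expect_lt(abs(lam - pos$lambda_hat[i]) / lam, 1e-10)
  }
  expect_equal(round(max(pos$lambda_hat), 2), 38.29)
  expect_equal(round(min(pos$lambda_hat), 2), 0.26)
})
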