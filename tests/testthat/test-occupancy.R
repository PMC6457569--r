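test_that("model strings parse to the right covariate assignment", {
  m1 <- parse_model_string("psi(type)theta(.)p(time)")
  expect_equal(m1$psi, "type")
  expect_equal(m1$theta, character(0))
  expect_equal(m1$p, "time")
  m3 <- parse_model_string("psi(.)theta(.)p(.)")
  expect_equal(lengths(m3[c("psi", "theta", "p")]),
               c(psi = 0L, theta = 0L, p = 0L))
  m6 <- parse_model_string("psi(type)theta(.)p(time + depth)")
  expect_equal(m6$p, c("time", "depth"))
  # Greek notation is accepted too
  expect_equal(format(parse_model_string("ψ(type)θ(date)p(time)")),
               "psi(type)theta(date)p(time)")
  expect_error(parse_model_string("psi(type)theta(.)p(elevation)"),
               "unknown.*elevation")
  expect_error(parse_model_string("psi(type)p(time)"), "position")
})

test_that("design matrices standardize at the unit level and cell-means code type", {
  sites <- data.frame(site_id = c("A", "B"), pair_id = 1,
                      island_type = c("colony", "control"))
  samples <- data.frame(sample_id = c("A-1", "B-1"),
                        site_id = c("A", "B"), date = "2017-04-01",
                        time = c(600, 660), water_temp_c = c(20, 24),
                        depth_cm = c(30, 40))
  det <- data.frame(sample_id = c("A-1", "B-1"), rep1 = c(1L, 0L),
                    rep2 = c(0L, 0L))
  d <- build_design_matrices(sites, samples, det, "psi(type)theta(time)p(time)")
  # {600, 660} standardized with sd denominator n-1
  expect_equal(unname(d$W[, "time"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(d$scaling$theta$center[["time"]], 630)
  expect_equal(d$scaling$theta$scale[["time"]], sd(c(600, 660)))
  # p-level standardization is over replicate units (the same value repeated)
  expect_equal(unname(d$V[, "time"]),
               scale(c(600, 600, 660, 660))[, 1], tolerance = 1e-12)
  # cell-means: one indicator per row
  expect_true(all(rowSums(d$X) == 1))
  expect_equal(dim(d$X), c(2, 2))

  # 15 + 15 fixture sites: X is 30 x 2 with exactly one 1 per row
  fp <- fixture_products()
  dfx <- build_design_matrices(fp$fx$sites, fp$fx$samples,
                               fp$filt$detections, "psi(type)theta(.)p(.)")
  expect_equal(dim(dfx$X), c(30, 2))
  expect_true(all(rowSums(dfx$X == 1) == 1))
  # null model: all three design matrices are columns of ones
  dnull <- build_design_matrices(fp$fx$sites, fp$fx$samples,
                                 fp$filt$detections, "psi(.)theta(.)p(.)")
  expect_true(all(dnull$X == 1) && ncol(dnull$X) == 1)
  expect_true(all(dnull$W == 1) && ncol(dnull$W) == 1)
  expect_true(all(dnull$V == 1) && ncol(dnull$V) == 1)
  expect_error(build_design_matrices(sites,
                                     transform(samples, depth_cm = 10),
                                     det, "psi(type)theta(.)p(depth)"),
               "scaling error")
})

test_that("latent conditionals match exhaustive enumeration", {
  # spec anchors
  lc <- latent_conditionals(0.4, 0.5, list(c(0.8, 0.8)), list(c(0, 0)))
  expect_equal(lc$a_prob, 0.02 / 0.52, tolerance = 1e-12)
  expect_equal(latent_conditionals(0.4, 0.5, list(c(0.8, 0.8)),
                                   list(c(0, 1)))$a_prob, 1)
  expect_equal(latent_conditionals(0.5, 0.5, list(0.5), list(0))$z_prob,
               1 / 3, tolerance = 1e-12)
  # property: random instances, every detection configuration
  set.seed(2024)
  for (rep_i in 1:25) {
    inst <- random_instance()
    for (y in all_y_configs(inst$Kj)) {
      got <- latent_conditionals(inst$psi, inst$theta, inst$p, y)
      want <- enum_site(inst$psi, inst$theta, inst$p, y)
      expect_equal(got$a_prob, want$a_prob, tolerance = 1e-12)
      if (all(unlist(y) == 0))
        expect_equal(got$z_prob, want$z_prob, tolerance = 1e-12)
    }
  }
  expect_error(latent_conditionals(1.2, 0.5, list(0.5), list(0)),
               "domain error")
})

test_that("posterior summaries use interpolated percentiles", {
  set.seed(8)
  chain <- sample(1:1000)
  tab <- summarize_posterior(fake_fit(chain = chain))
  row <- tab[tab$parameter == "beta[colony]", ]
  expect_equal(row$median, 500.5)
  expect_equal(row$cri_low, 25.975)
  expect_equal(row$cri_high, 975.025)
  const <- summarize_posterior(fake_fit(chain = rep(0.42, 200)))
  expect_true(all(const$median == 0.42 & const$cri_low == 0.42 &
                    const$cri_high == 0.42))
})

test_that("detection curve follows the logistic closed form and is monotone", {
  V <- matrix(c(1, 1, 0, 1), 2, 2,
              dimnames = list(NULL, c("(Intercept)", "time")))
  flat <- fake_fit(delta = matrix(0, 2, 2,
                                  dimnames = list(NULL, c("(Intercept)", "time"))),
                   V = V)
  dc <- detection_curve(flat, grid = c(-1, 0, 1))
  expect_equal(dc$mean, rep(0.5, 3))
  slope <- fake_fit(delta = matrix(c(0, -1), 1, 2, byrow = TRUE,
                                   dimnames = list(NULL, c("(Intercept)", "time"))),
                    V = V)
  dc2 <- detection_curve(slope, grid = c(0, 1))
  expect_equal(dc2$mean, c(0.5, plogis(-1)), tolerance = 1e-12)
  expect_true(all(diff(dc2$mean) <= 0))
  expect_warning(detection_curve(slope, grid = c(0, 6)), "5 SD")
})

test_that("a fully positive dataset drives psi, theta and p toward one", {
  sites <- data.frame(site_id = sprintf("S%02d", 1:8), pair_id = rep(1:4, 2),
                      island_type = rep(c("colony", "control"), 4))
  samples <- do.call(rbind, lapply(sites$site_id, function(s)
    data.frame(sample_id = paste0(s, "-", 1:3), site_id = s,
               date = "2017-04-01", time = 600, water_temp_c = 25,
               depth_cm = 30)))
  det <- data.frame(sample_id = samples$sample_id, rep1 = 1L, rep2 = 1L,
                    rep3 = 1L)
  fit <- occu_ms(list(sites = sites, samples = samples, detections = det),
                 model = "psi(.)theta(.)p(.)", n_iter = 5000, burn_in = 1000,
                 seed = 3)
  tab <- summarize_posterior(fit)
  for (par in c("psi[colony]", "theta_bar", "p_bar"))
    expect_gt(tab$median[tab$parameter == par], 0.9)
  # hierarchy invariant on the retained latent draws
  z_rep <- fit$draws$z[, fit$data$site_of_sample, drop = FALSE]
  expect_true(all(fit$draws$a <= z_rep))
  y_pos <- which(fit$data$y == 1)
  expect_true(all(fit$draws$a[, fit$data$sample_of_rep[y_pos]] == 1))
})

test_that("identical seeds give identical chains", {
  g <- generate_dataset(design_params(n_pairs = 8), truth_params(), seed = 21)
  f1 <- occu_ms(g$dataset, n_iter = 1500, burn_in = 300, seed = 77)
  f2 <- occu_ms(g$dataset, n_iter = 1500, burn_in = 300, seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- occu_ms(g$dataset, n_iter = 1500, burn_in = 300, seed = 78)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("with no informative units the coefficient posterior is the prior", {
  # sites without samples: beta is fit to latent z drawn from its prior
  # predictive, and alpha/delta have no active units at all, so every
  # coefficient chain must match its Normal(0, prior_sd^2) prior moments
  sites <- data.frame(site_id = sprintf("S%02d", 1:30), pair_id = rep(1:15, 2),
                      island_type = rep(c("colony", "control"), 15))
  empty_samples <- data.frame(sample_id = character(), site_id = character(),
                              date = character(), time = numeric(),
                              water_temp_c = numeric(), depth_cm = numeric())
  det <- data.frame(sample_id = character(), rep1 = integer())
  dat <- build_design_matrices(sites, empty_samples, det, "psi(.)theta(.)p(.)")
  fit <- occu_ms(dat, n_iter = 12000, burn_in = 2000, prior_sd = 2, seed = 5)
  # alpha and delta have no active units ever: their draws are iid prior
  for (block in c("alpha", "delta")) {
    ch <- fit$draws[[block]][, 1]
    expect_lt(abs(mean(ch)), 0.1)
    expect_lt(abs(sd(ch) - 2), 0.1)
  }
  # beta is refit each sweep to latent z drawn from its own prior predictive;
  # marginally still the prior, but autocorrelated, so wider MC bounds
  chb <- fit$draws$beta[, 1]
  expect_lt(abs(mean(chb)), 0.3)
  expect_lt(abs(sd(chb) - 2), 0.3)
})

test_that("the Metropolis fallback agrees with the Polya-Gamma sampler", {
  g <- generate_dataset(design_params(n_pairs = 25, samples_per_site = c(4, 4)),
                        truth_params(false_amp_rate = 0), seed = 31)
  fpg <- occu_ms(g$dataset, n_iter = 8000, burn_in = 2000, seed = 1,
                 sampler = "pg", store_latent = FALSE)
  frw <- occu_ms(g$dataset, n_iter = 8000, burn_in = 2000, seed = 1,
                 sampler = "rw", store_latent = FALSE)
  spg <- summarize_posterior(fpg)
  srw <- summarize_posterior(frw)
  expect_equal(spg$median, srw$median, tolerance = 0.25)
})

test_that("simulated occupancy ordering is recovered across refits", {
  ok <- 0
  for (i in 1:5) {
    g <- generate_dataset(design_params(n_pairs = 30, samples_per_site = c(5, 5)),
                          truth_params(beta = c(colony = 1.2, control = -0.4),
                                       alpha = -0.3, delta = c(0.8, -0.4),
                                       false_amp_rate = 0),
                          seed = 400 + i)
    fit <- occu_ms(g$dataset, n_iter = 3000, burn_in = 600, seed = 500 + i,
                   store_latent = FALSE)
    ps <- apply(fit$draws$psi, 2, median)
    ok <- ok + as.integer(ps["colony"] > ps["control"])
  }
  expect_gte(ok, 4)
})

test_that("diagnostics report ACF and batch-means MCSE correctly", {
  set.seed(15)
  n <- 10000
  iid <- fake_fit(chain = rnorm(n))
  dg <- occu_diagnostics(iid)
  expect_lt(abs(dg$acf["lag1", "beta[colony]"]), 0.03)
  expect_equal(dim(dg$acf), c(50, 6))
  # constant chain: zero Monte Carlo error
  const <- fake_fit(chain = rep(1.3, n))
  expect_equal(unname(occu_diagnostics(const)$mcse["beta[colony]"]), 0)
  # AR(1) with rho = 0.9
  ar <- numeric(n); ar[1] <- 0
  eps <- rnorm(n)
  for (i in 2:n) ar[i] <- 0.9 * ar[i - 1] + eps[i]
  dga <- occu_diagnostics(fake_fit(chain = ar))
  expect_gt(dga$acf["lag1", "beta[colony]"], 0.85)
  expect_lt(dga$acf["lag1", "beta[colony]"], 0.95)
  expect_error(occu_diagnostics(fake_fit(chain = rnorm(100))),
               "diagnostics error")
  # trace export round-trips
  tf <- withr::local_tempfile(fileext = ".csv")
  occu_diagnostics(iid, trace_file = tf)
  expect_equal(nrow(read.csv(tf)), n)
})

test_that("fit methods print, coef, predict and simulate coherently", {
  g <- generate_dataset(design_params(n_pairs = 10), truth_params(), seed = 2)
  fit <- occu_ms(g$dataset, n_iter = 1200, burn_in = 200, seed = 9)
  expect_output(print(fit), "Multi-scale eDNA occupancy")
  expect_named(coef(fit), c("psi.colony", "psi.control",
                            "theta.(Intercept)", "p.(Intercept)", "p.time"))
  pr <- predict(fit, "psi")
  expect_equal(pr$unit, c("colony", "control"))
  expect_true(all(pr$cri_low <= pr$median & pr$median <= pr$cri_high))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_true(all(vapply(sims, length, 1L) == length(g$dataset$y)))
  expect_true(all(unlist(sims) %in% 0:1))
})
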