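#' Design parameters for a simulated paired eDNA survey
#'
#' Describes the sampling design of a paired colony/control survey: how many
#' island pairs, how many 1-L water samples per site, how many PCR replicates
#' per sample, and the droplet partition of each ddPCR reaction.
#'
#' @param n_pairs number of colony-control island pairs (default 15).
#' @param samples_per_site inclusive integer range (length 2) of samples per
#'   site; each site draws its count uniformly from the range (default
#'   `c(8, 10)`, bracketing the 8-10 samples per island typical of such
#'   surveys).
#' @param n_replicates PCR replicates per sample (default 5).
#' @param droplets_per_reaction inclusive range of droplets per reaction
#'   (default `c(15000, 20000)`, the nanofluidic partition of the QX200
#'   platform).
#' @param droplet_volume droplet volume in uL (default 0.00085).
#' @param prop_missing_temp fraction of samples whose temperature measurement
#'   is dropped (to exercise imputation; default 0).
#' @return object of class `design_params`.
#' @export
design_params <- function(n_pairs = 15, samples_per_site = c(8, 10),
                          n_replicates = 5,
                          droplets_per_reaction = c(15000, 20000),
                          droplet_volume = 0.00085,
                          prop_missing_temp = 0) {
  samples_per_site <- as.integer(round(samples_per_site))
  if (length(samples_per_site) == 1)
    samples_per_site <- rep(samples_per_site, 2)
  droplets_per_reaction <- as.integer(round(droplets_per_reaction))
  if (length(droplets_per_reaction) == 1)
    droplets_per_reaction <- rep(droplets_per_reaction, 2)
  if (n_pairs < 1 || n_replicates < 1 || any(samples_per_site < 1))
    stop("configuration error: all counts must be >= 1")
  if (samples_per_site[1] > samples_per_site[2] ||
      droplets_per_reaction[1] > droplets_per_reaction[2])
    stop("configuration error: ranges must be increasing")
  if (droplets_per_reaction[1] < 1 || droplets_per_reaction[2] > 1e6)
    stop("configuration error: droplet range must lie in [1, 1e6]")
  if (droplet_volume <= 0)
    stop("configuration error: droplet_volume must be > 0")
  if (prop_missing_temp < 0 || prop_missing_temp >= 1)
    stop("configuration error: prop_missing_temp must be in [0, 1)")
  structure(list(n_pairs = as.integer(n_pairs),
                 samples_per_site = samples_per_site,
                 n_replicates = as.integer(n_replicates),
                 droplets_per_reaction = droplets_per_reaction,
                 droplet_volume = droplet_volume,
                 prop_missing_temp = prop_missing_temp),
            class = "design_params")
}

#' True parameter values for the synthetic-data generator
#'
#' Logit-scale coefficients of the generating hierarchy. Coefficient length
#' selects the covariates: `beta` of length 2 is cell-means by island type
#' (`colony`, `control`), length 1 is a common intercept; `alpha` is
#' `(intercept)` or `(intercept, date)`; `delta` is `(intercept)`,
#' `(intercept, time)` or `(intercept, time, depth)`, all on standardized
#' covariates.
#'
#' Defaults are the coefficient scale reported for python eDNA surveys of
#' Everglades tree islands: occupancy cell means 1.17 (colony) and -0.19
#' (control), occurrence intercept `qlogis(0.14)`, detection intercept
#' `qlogis(0.61)` with a time slope of -0.33.
#'
#' @param beta site-level coefficients (see above).
#' @param alpha sample-level coefficients.
#' @param delta replicate-level coefficients.
#' @param conc_meanlog,conc_sdlog log-normal location/scale of the true
#'   concentration (copies/uL) of eDNA-positive samples.
#' @param false_amp_rate per-replicate probability of a spurious
#'   amplification burst in eDNA-free material (in `[0, 0.05]`).
#' @param spurious_conc concentration scale (copies/uL) of a spurious burst;
#'   kept below a typical limit of blank so the LOB filter removes most
#'   false positives.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(beta = c(colony = 1.17, control = -0.19),
                         alpha = qlogis(0.14),
                         delta = c(qlogis(0.61), -0.33),
                         conc_meanlog = log(0.8), conc_sdlog = 1.2,
                         false_amp_rate = 0.002, spurious_conc = 0.15) {
  if (!length(beta) %in% 1:2) stop("dimension error: beta must have length 1 or 2")
  if (length(beta) == 2 && is.null(names(beta)))
    names(beta) <- c("colony", "control")
  if (!length(alpha) %in% 1:2) stop("dimension error: alpha must have length 1 or 2")
  if (!length(delta) %in% 1:3) stop("dimension error: delta must have length 1, 2 or 3")
  if (conc_sdlog <= 0) stop("configuration error: conc_sdlog must be > 0")
  if (false_amp_rate < 0 || false_amp_rate > 0.05)
    stop("configuration error: false_amp_rate must lie in [0, 0.05]")
  if (spurious_conc <= 0) stop("configuration error: spurious_conc must be > 0")
  structure(list(beta = beta, alpha = alpha, delta = delta,
                 conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
                 false_amp_rate = false_amp_rate,
                 spurious_conc = spurious_conc),
            class = "truth_params")
}

.spec_from_truth <- function(truth, prior_sd = 2) {
  model_spec(
    psi = if (length(truth$beta) == 2) "type" else character(),
    theta = if (length(truth$alpha) == 2) "date" else character(),
    p = c("time", "depth")[seq_len(length(truth$delta) - 1)],
    prior_sd = prior_sd
  )
}

#' Simulate a paired colony/control eDNA survey down to droplet counts
#'
#' Generates a complete synthetic survey with known truth: latent site
#' occupancy `z_i ~ Bern(logit^-1(x_i' beta))`, latent sample occurrence
#' `a_ij | z_i = 1 ~ Bern(logit^-1(w_ij' alpha))`, a log-normal true
#' concentration for occupied samples, and droplet counts per PCR replicate.
#' Collection times are drawn per site visit within 08:00-13:00, water
#' temperature is a linear function of time plus Gaussian noise, depth is a
#' site-level value, and the collection date is shared within a pair.
#'
#' Detection heterogeneity is induced through the droplet channel: for each
#' replicate of an occupied sample the effective amplifiable concentration is
#' attenuated to `lambda_eff = -log(1 - p_ijk) / (v m)` with
#' `p_ijk = logit^-1(v_ijk' delta)`, and the positive droplet count is
#' `m1 ~ Binomial(m, 1 - exp(-lambda_eff v))`, so replicate-level positivity
#' (`m1 >= 1`) has probability exactly `p_ijk` while droplet counts remain
#' the single source of detections. Replicates of eDNA-free samples receive a
#' spurious burst (`1 + Binomial(m - 1, 1 - exp(-spurious_conc * v))`
#' positives) with probability `false_amp_rate`, exercising the limit of
#' blank; with `false_amp_rate = 0` no detection can occur without
#' occurrence.
#'
#' @param design a [design_params()] object.
#' @param truth a [truth_params()] object.
#' @param seed integer seed; identical seeds give bit-identical output
#'   (default 20190410).
#' @return list with `dataset` (an `occu_data` whose `y` marks replicates
#'   with at least one positive droplet), `truth` (class `synthetic_truth`:
#'   `z`, `a`, `lambda_true`, the generating parameters and the true
#'   unit-level probabilities), and `tables` (the four raw CSV-schema data
#'   frames: `sites`, `samples`, `replicates`, `neg_controls`).
#' @export
generate_dataset <- function(design = design_params(),
                             truth = truth_params(), seed = 20190410) {
  stopifnot(inherits(design, "design_params"), inherits(truth, "truth_params"))
  if (is.null(seed)) stop("configuration error: a seed is required")
  set.seed(as.integer(seed))
  np <- design$n_pairs
  v <- design$droplet_volume
  K <- design$n_replicates

  wd <- max(2, nchar(np))
  sites <- data.frame(
    site_id = c(sprintf("C%0*d", wd, seq_len(np)),
                sprintf("X%0*d", wd, seq_len(np))),
    pair_id = rep(seq_len(np), 2),
    island_type = rep(c("colony", "control"), each = np),
    area_m2 = round(runif(2 * np, 200, 4000)),
    stringsAsFactors = FALSE
  )
  nsite <- nrow(sites)

  pair_date <- as.Date("2017-04-01") + sample.int(60, np, replace = TRUE)
  J <- sample.int(design$samples_per_site[2] - design$samples_per_site[1] + 1,
                  nsite, replace = TRUE) + design$samples_per_site[1] - 1L
  base_time <- runif(nsite, 480, 780 - 3 * max(J))
  site_depth <- runif(nsite, 20, 80)

  samples <- do.call(rbind, lapply(seq_len(nsite), function(i) {
    tm <- round(base_time[i] + 3 * (seq_len(J[i]) - 1))
    data.frame(
      sample_id = sprintf("%s-%02d", sites$site_id[i], seq_len(J[i])),
      site_id = sites$site_id[i],
      date = as.character(pair_date[sites$pair_id[i]]),
      time = .fmt_minutes(tm),
      water_temp_c = round(14 + 0.015 * tm + rnorm(J[i], 0, 1.5), 1),
      depth_cm = round(pmax(5, site_depth[i] + rnorm(J[i], 0, 2))),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL
  nsamp <- nrow(samples)

  # latent truth on standardized covariates (sd with denominator n-1, the
  # same standardization build_design_matrices() applies)
  std <- function(x) (x - mean(x)) / sd(x)
  type_col <- as.numeric(samples$site_id %in% sites$site_id[sites$island_type == "colony"])
  if (length(truth$beta) == 2) {
    eta_z <- ifelse(sites$island_type == "colony", truth$beta[["colony"]],
                    truth$beta[["control"]])
  } else {
    eta_z <- rep(truth$beta[[1]], nsite)
  }
  z <- rbinom(nsite, 1, plogis(.clip_eta(eta_z)))

  date_num <- .as_num_date(samples$date)
  eta_a <- rep(truth$alpha[[1]], nsamp)
  if (length(truth$alpha) == 2) eta_a <- eta_a + truth$alpha[[2]] * std(date_num)
  site_of_sample <- match(samples$site_id, sites$site_id)
  a <- rbinom(nsamp, 1, plogis(.clip_eta(eta_a))) * z[site_of_sample]
  lambda_true <- ifelse(a == 1,
                        rlnorm(nsamp, truth$conc_meanlog, truth$conc_sdlog), 0)

  # replicate-level detection probabilities (covariates standardized over
  # replicate units)
  time_num <- .as_minutes(samples$time)
  sample_of_rep <- rep(seq_len(nsamp), each = K)
  eta_p <- rep(truth$delta[[1]], nsamp * K)
  if (length(truth$delta) >= 2)
    eta_p <- eta_p + truth$delta[[2]] * std(time_num[sample_of_rep])
  if (length(truth$delta) >= 3)
    eta_p <- eta_p + truth$delta[[3]] * std(samples$depth_cm[sample_of_rep])
  p_rep <- plogis(.clip_eta(eta_p))

  m <- sample.int(design$droplets_per_reaction[2] -
                    design$droplets_per_reaction[1] + 1,
                  nsamp * K, replace = TRUE) +
    design$droplets_per_reaction[1] - 1L
  a_rep <- a[sample_of_rep]
  # occupied: attenuate so P(m1 >= 1) = p_rep exactly
  q_occ <- 1 - (1 - p_rep)^(1 / m)
  q0 <- 1 - exp(-truth$spurious_conc * v)
  burst <- runif(nsamp * K) < truth$false_amp_rate
  m1 <- integer(nsamp * K)
  occ <- a_rep == 1
  m1[occ] <- rbinom(sum(occ), m[occ], q_occ[occ])
  fp <- !occ & burst
  m1[fp] <- 1L + rbinom(sum(fp), m[fp] - 1L, q0)

  replicates <- data.frame(
    sample_id = samples$sample_id[sample_of_rep],
    replicate_id = rep(seq_len(K), times = nsamp),
    run_id = 1L,
    m_total = m, m_pos = m1,
    ipc_conc = round(100 * (1 - plogis(rnorm(nsamp * K,
      ifelse(type_col[sample_of_rep] == 1, 1.5, -1.5), 1))), 2),
    stringsAsFactors = FALSE
  )

  nc_m <- sample.int(design$droplets_per_reaction[2] -
                       design$droplets_per_reaction[1] + 1, 12,
                     replace = TRUE) + design$droplets_per_reaction[1] - 1L
  nc_burst <- runif(12) < truth$false_amp_rate
  nc_pos <- ifelse(nc_burst, 1L + rbinom(12, nc_m - 1L, q0), 0L)
  neg_controls <- data.frame(
    control_id = sprintf("NC%02d", 1:12),
    control_type = rep(c("field", "filtration", "extraction", "NTC"), each = 3),
    m_total = nc_m, m_pos = as.integer(nc_pos),
    stringsAsFactors = FALSE
  )

  # observed detections: at least one positive droplet in the replicate
  det <- matrix(NA_integer_, nsamp, K,
                dimnames = list(NULL, paste0("rep", seq_len(K))))
  det[cbind(sample_of_rep, replicates$replicate_id)] <- as.integer(m1 >= 1)
  detections <- cbind(data.frame(sample_id = samples$sample_id,
                                 stringsAsFactors = FALSE),
                      as.data.frame(det))

  if (design$prop_missing_temp > 0) {
    nmiss <- floor(design$prop_missing_temp * nsamp)
    samples$water_temp_c[sample.int(nsamp, nmiss)] <- NA
  }

  dataset <- build_design_matrices(sites, samples, detections,
                                   .spec_from_truth(truth))

  truth_out <- structure(list(
    z = setNames(z, sites$site_id),
    a = setNames(a, samples$sample_id),
    lambda_true = setNames(lambda_true, samples$sample_id),
    p_rep = p_rep, theta = plogis(.clip_eta(eta_a)),
    psi = plogis(.clip_eta(eta_z)),
    params = truth, seed = seed
  ), class = "synthetic_truth")

  list(dataset = dataset, truth = truth_out,
       tables = list(sites = sites, samples = samples,
                     replicates = replicates, neg_controls = neg_controls))
}

#' True summary fractions of a synthetic dataset
#'
#' Recounts the stored truth of a [generate_dataset()] draw: per island type,
#' the true occupancy fraction (mean of `z`), the true sample-occurrence
#' fraction among samples of occupied sites (mean of `a | z = 1`), and the
#' true mean replicate positivity among replicates of occupied samples
#' (mean of `y | a = 1`). These are the quantities parameter-recovery checks
#' compare against.
#'
#' @param truth a `synthetic_truth` object.
#' @param dataset the matching `occu_data` from the same
#'   [generate_dataset()] call.
#' @return data frame, one row per island type.
#' @export
truth_report <- function(truth, dataset) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(dataset, "occu_data"))
  if (!identical(names(truth$z), dataset$sites$site_id) ||
      !identical(names(truth$a), dataset$samples$sample_id))
    stop("consistency error: truth and dataset unit ids do not match")
  type_site <- dataset$sites$island_type
  type_samp <- type_site[dataset$site_of_sample]
  type_rep <- type_samp[dataset$sample_of_rep]
  a_rep <- truth$a[dataset$sample_of_rep]
  z_samp <- truth$z[dataset$site_of_sample]
  out <- lapply(unique(type_site), function(tp) {
    s_occ <- type_samp == tp & z_samp == 1
    r_occ <- type_rep == tp & a_rep == 1
    data.frame(
      island_type = tp,
      true_occupancy = mean(truth$z[type_site == tp]),
      true_occurrence = if (any(s_occ)) mean(truth$a[s_occ]) else NA_real_,
      true_positivity = if (any(r_occ)) mean(dataset$y[r_occ]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
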