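# Strict CSV schemas of the pipeline. All files are UTF-8, comma-separated,
# with a header row; times are HH:MM, dates ISO-8601.
.SCHEMAS <- list(
  sites = c("site_id", "pair_id", "island_type", "area_m2"),
  samples = c("sample_id", "site_id", "date", "time", "water_temp_c",
              "depth_cm"),
  replicates = c("sample_id", "replicate_id", "run_id", "m_total", "m_pos",
                 "ipc_conc"),
  neg_controls = c("control_id", "control_type", "m_total", "m_pos")
)

#' Read one of the pipeline input tables
#'
#' @param path CSV file path.
#' @param what table name: `"sites"`, `"samples"`, `"replicates"` or
#'   `"neg_controls"`.
#' @return data frame validated against the schema.
#' @export
read_table <- function(path, what = names(.SCHEMAS)) {
  what <- match.arg(what)
  if (!file.exists(path))
    stop("schema violation: missing input file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- .SCHEMAS[[what]]
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (what == "replicates") {
    bad <- which(d$m_pos > d$m_total | d$m_total < 1 | d$m_pos < 0)
    if (length(bad))
      stop("schema violation in ", path, ": row ", bad[1],
           ": need 0 <= m_pos <= m_total and m_total >= 1")
  }
  if (what == "sites" && !all(d$island_type %in% c("colony", "control")))
    stop("schema violation in ", path,
         ": island_type must be 'colony' or 'control'")
  d
}

#' Write the four pipeline tables to a directory
#'
#' @param tables named list with `sites`, `samples`, `replicates`,
#'   `neg_controls` (e.g. from [generate_dataset()] or [survey_fixture()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(.SCHEMAS)) {
    if (is.null(tables[[nm]])) stop("missing table: ", nm)
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]][intersect(c(.SCHEMAS[[nm]],
                                       names(tables[[nm]])),
                                     names(tables[[nm]]))],
              p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' Collects every knob of the analysis pipeline. Defaults follow the survey
#' protocol this package models: 100,000 MCMC iterations with burn-in 5000,
#' the seven candidate occupancy models, LOB from the negative controls.
#'
#' @param input_dir directory holding `sites.csv`, `samples.csv`,
#'   `replicates.csv`, `neg_controls.csv`.
#' @param output_dir directory for artifacts.
#' @param droplet_volume droplet volume in uL.
#' @param lob `"auto"` (compute from the negative controls) or a numeric
#'   threshold in copies/uL.
#' @param models character vector of model strings (see
#'   [parse_model_string()]).
#' @param n_iter,burn_in MCMC control.
#' @param prior_sd coefficient prior SD.
#' @param sampler `"pg"` or `"rw"`.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            droplet_volume = 0.00085, lob = "auto",
                            models = c("psi(type)theta(.)p(time)",
                                       "psi(type)theta(.)p(.)",
                                       "psi(.)theta(.)p(.)",
                                       "psi(type)theta(date)p(.)",
                                       "psi(type)theta(date)p(time)",
                                       "psi(type)theta(.)p(time + depth)",
                                       "psi(type)theta(.)p(depth)"),
                            n_iter = 100000, burn_in = 5000, prior_sd = 2,
                            sampler = c("pg", "rw"), seed = 1L) {
  sampler <- match.arg(sampler)
  if (burn_in >= n_iter) stop("configuration error: need n_iter > burn_in")
  if (!identical(lob, "auto") && (!is.numeric(lob) || lob < 0))
    stop("configuration error: lob must be \"auto\" or a value >= 0")
  for (m in models) parse_model_string(m) # fail fast on malformed strings
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 droplet_volume = droplet_volume, lob = lob, models = models,
                 n_iter = n_iter, burn_in = burn_in, prior_sd = prior_sd,
                 sampler = sampler, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config()] may be set in the file; missing fields
#' take their defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: quantify (pool droplet counts per sample and run,
#' select the highest-concentration run), lob (limit of blank from the
#' negative controls), detections (zero filtered samples, score replicate
#' detections), impute (fill missing water temperatures from collection
#' time), fit (every configured occupancy model), waic-rank, summaries
#' (count-level table, pair comparison, design counts, detection curve).
#' Every output is a CSV under `config$output_dir`, and `manifest.csv`
#' records the configuration, seed, per-stage row counts and an MD5 checksum
#' of every artifact.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default all). Model fitting
#'   requires the quantification stages in the same call.
#' @return invisibly, a list with the fit objects, the WAIC table and the
#'   artifact paths.
#' @export
run_pipeline <- function(config, stages = c("quantify", "fit", "summarize")) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[%s] %s",
                                           format(Sys.time(), "%H:%M:%S"),
                                           sprintf(...)))
  artifacts <- character(0)
  counts <- list()
  put <- function(d, name) {
    p <- file.path(outdir, name)
    write.csv(d, p, row.names = FALSE)
    artifacts[[name]] <<- p
    counts[[name]] <<- nrow(d)
    p
  }

  sites <- read_table(file.path(config$input_dir, "sites.csv"), "sites")
  samples <- read_table(file.path(config$input_dir, "samples.csv"), "samples")
  replicates <- read_table(file.path(config$input_dir, "replicates.csv"),
                           "replicates")
  neg_controls <- read_table(file.path(config$input_dir, "neg_controls.csv"),
                             "neg_controls")

  # --- quantify / lob / detections / impute -------------------------------
  log_msg("quantify: %d replicate rows", nrow(replicates))
  quant <- pool_and_select(replicates, config$droplet_volume)
  lob <- if (identical(config$lob, "auto"))
    compute_lob(quantify_controls(neg_controls, config$droplet_volume))
  else config$lob
  lobval <- if (inherits(lob, "lob_threshold")) lob$value else lob
  filt <- apply_lob(quant, replicates, lob)
  ipc <- tapply(replicates$ipc_conc, replicates$sample_id, mean)
  quant_out <- filt$concentrations
  quant_out$inhibition <- inhibition_ratio(
    as.numeric(ipc[quant_out$sample_id]), 100)
  put(quant_out, "quantification.csv")
  put(filt$detections, "detections.csv")
  log_msg("lob %.4g copies/uL: %d of %d samples zeroed", lobval,
          sum(quant_out$lob_applied), nrow(quant_out))

  samples <- impute_temperature(samples)
  samples$concentration <- quant_out$lambda_hat[
    match(samples$sample_id, quant_out$sample_id)]
  put(samples, "samples_imputed.csv")

  fits <- list()
  waic_tab <- NULL
  if ("fit" %in% stages) {
    seeds <- config$seed + seq_along(config$models) - 1L
    waics <- list()
    for (k in seq_along(config$models)) {
      m <- config$models[k]
      log_msg("fit %s (n_iter %d)", m, config$n_iter)
      dat <- build_design_matrices(sites, samples, filt$detections,
                                   parse_model_string(m, config$prior_sd))
      fit <- occu_ms(dat, n_iter = config$n_iter, burn_in = config$burn_in,
                     seed = seeds[k], sampler = config$sampler,
                     store_latent = FALSE)
      fits[[m]] <- fit
      waics[[m]] <- compute_waic(fit)
      put(summarize_posterior(fit),
          sprintf("posterior_model%d.csv", k))
    }
    waic_tab <- rank_models(waics)
    put(waic_tab, "model_ranking.csv")
    best <- fits[[waic_tab$model[1]]]
    put(summarize_posterior(best), "posterior_best.csv")
    # detection-vs-time curve from the best-ranked model that carries time
    with_time <- waic_tab$model[vapply(waic_tab$model, function(m)
      "time" %in% colnames(fits[[m]]$data$V), logical(1))]
    if (length(with_time))
      put(detection_curve(fits[[with_time[1]]]), "detection_curve.csv")
    diag_fit <- tryCatch(occu_diagnostics(best), error = function(e) NULL)
    if (!is.null(diag_fit))
      put(data.frame(parameter = names(diag_fit$mcse), mcse = diag_fit$mcse,
                     lag1_acf = diag_fit$acf[1, ]), "diagnostics.csv")
  }

  if ("summarize" %in% stages) {
    put(naive_summary(samples, sites), "table_naive.csv")
    pc <- exclude_pairs(samples, sites)
    put(pc, "pair_comparison.csv")
    tst <- paired_concentration_test(samples, sites,
                                     pc$pair_id[!pc$excluded])
    put(as.data.frame(tst), "paired_test.csv")
    dc <- design_counts(samples, sites)
    put(dc$by_type, "design_counts.csv")
    ctt <- correlation_time_temp(samples)
    put(data.frame(r = ctt$r, t_stat = ctt$t_stat, df = ctt$df, p = ctt$p,
                   temp_in_range = dc$temperature$in_range,
                   temp_total = dc$temperature$total,
                   temp_percent = dc$temperature$percent),
        "field_stats.csv")
  }

  manifest <- data.frame(
    file = names(artifacts),
    rows = unlist(counts[names(artifacts)]),
    md5 = unname(tools::md5sum(unlist(artifacts))),
    stringsAsFactors = FALSE
  )
  cfg_row <- data.frame(file = "(config)", rows = NA,
                        md5 = paste0("seed=", config$seed, ";n_iter=",
                                     config$n_iter, ";burn_in=",
                                     config$burn_in, ";lob=", lobval,
                                     ";sampler=", config$sampler,
                                     ";version=",
                                     as.character(utils::packageVersion("ednaocc"))))
  write.csv(rbind(manifest, cfg_row), file.path(outdir, "manifest.csv"),
            row.names = FALSE)
  log_msg("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(fits = fits, waic = waic_tab, artifacts = artifacts,
                 lob = lobval))
}
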