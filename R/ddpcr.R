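#' Absolute concentration from droplet counts
#'
#' Estimates target concentration from a droplet digital PCR reaction under
#' the Poisson partition model. With `m_total` droplets of volume `v` and
#' `m_pos` of them positive, the estimator is
#' \deqn{\hat\lambda = -\log(1 - m_{pos}/m_{total}) / v}
#' with delta-method standard error
#' \eqn{\sqrt{m_{pos} / (m_{total}(m_{total}-m_{pos}))} / v}. The 95%
#' confidence interval is a Wald interval on \eqn{\log\hat\lambda}
#' back-transformed (`ci_method = "log"`, the default, which respects
#' positivity) or a plain Wald interval (`ci_method = "wald"`).
#'
#' @param m_total total droplet count (>= 1).
#' @param m_pos positive droplet count; must be strictly less than `m_total`
#'   (a saturated reaction leaves the estimator undefined).
#' @param droplet_volume droplet volume in microlitres (platform nominal
#'   0.00085 uL by default).
#' @param ci_method `"log"` or `"wald"`.
#' @return object of class `concentration_estimate`: list with `lambda_hat`,
#'   `se`, `ci_low`, `ci_high` (copies/uL) and the pooled `m_total`, `m_pos`.
#'   `m_pos = 0` returns an all-zero estimate.
#' @seealso [pool_and_select()], [compute_lob()], [apply_lob()]
#' @export
estimate_concentration <- function(m_total, m_pos, droplet_volume = 0.00085,
                                   ci_method = c("log", "wald")) {
  ci_method <- match.arg(ci_method)
  if (length(m_total) != 1 || length(m_pos) != 1)
    stop("estimate_concentration() takes scalar counts; see pool_and_select()")
  if (!is.finite(m_total) || !is.finite(m_pos) || m_total < 1)
    stop("m_total must be a positive count")
  if (m_pos < 0 || m_pos > m_total)
    stop("data error: m_pos must lie in [0, m_total]")
  if (droplet_volume <= 0) stop("droplet_volume must be > 0")
  if (m_pos == m_total)
    stop("saturation error: all droplets positive, concentration estimator undefined")
  m_total <- as.numeric(m_total)
  m_pos <- as.numeric(m_pos)
  if (m_pos == 0) {
    est <- list(lambda_hat = 0, se = 0, ci_low = 0, ci_high = 0,
                m_total = m_total, m_pos = m_pos)
    class(est) <- "concentration_estimate"
    return(est)
  }
  v <- droplet_volume
  lam <- -log(1 - m_pos / m_total) / v
  se <- sqrt(m_pos / (m_total * (m_total - m_pos))) / v
  zq <- qnorm(0.975)
  if (ci_method == "log") {
    half <- zq * se / lam
    ci <- lam * exp(c(-half, half))
  } else {
    ci <- pmax(0, lam + c(-zq, zq) * se)
  }
  est <- list(lambda_hat = lam, se = se, ci_low = ci[1], ci_high = ci[2],
              m_total = m_total, m_pos = m_pos)
  class(est) <- "concentration_estimate"
  est
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("[eDNA] %.4g copies/uL (se %.3g, 95%% CI %.4g-%.4g; %d/%d droplets)\n",
              x$lambda_hat, x$se, x$ci_low, x$ci_high,
              as.integer(x$m_pos), as.integer(x$m_total)))
  invisible(x)
}

#' Pool replicate runs and select the run with the highest concentration
#'
#' Within one ddPCR run of a sample, droplet counts are pooled across PCR
#' replicates (sums of `m_total` and `m_pos`) and a single concentration is
#' estimated. Samples re-run after additional inhibitor-removal treatments
#' have several runs; the run with the highest pooled concentration is kept,
#' ties broken in favour of the latest `run_id`.
#'
#' @param runs data frame with columns `sample_id`, `replicate_id`, `run_id`,
#'   `m_total`, `m_pos` (one row per PCR replicate).
#' @param droplet_volume,ci_method passed to [estimate_concentration()].
#' @return data frame, one row per sample: `sample_id`, `run_id` (selected),
#'   `lambda_hat`, `se`, `ci_low`, `ci_high`, pooled `m_total`, `m_pos`.
#' @export
pool_and_select <- function(runs, droplet_volume = 0.00085,
                            ci_method = c("log", "wald")) {
  ci_method <- match.arg(ci_method)
  need <- c("sample_id", "replicate_id", "run_id", "m_total", "m_pos")
  if (!is.data.frame(runs) || !all(need %in% names(runs)))
    stop("data error: `runs` must contain columns ",
         paste(need, collapse = ", "))
  if (nrow(runs) == 0) stop("data error: empty run list")
  out <- lapply(split(runs, runs$sample_id, drop = TRUE), function(d) {
    per_run <- lapply(split(d, d$run_id, drop = TRUE), function(r) {
      est <- estimate_concentration(sum(r$m_total), sum(r$m_pos),
                                    droplet_volume, ci_method)
      data.frame(run_id = r$run_id[1], lambda_hat = est$lambda_hat,
                 se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
                 m_total = est$m_total, m_pos = est$m_pos,
                 stringsAsFactors = FALSE)
    })
    per_run <- do.call(rbind, per_run)
    # highest concentration wins; ties go to the latest run
    ord <- order(per_run$lambda_hat, per_run$run_id, decreasing = TRUE)
    best <- per_run[ord[1], , drop = FALSE]
    cbind(data.frame(sample_id = d$sample_id[1], stringsAsFactors = FALSE),
          best)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Limit of blank from negative controls
#'
#' The limit of blank (LOB) is the maximum pooled concentration observed in
#' any negative control (field, filtration, extraction, or no-template
#' controls); sample concentrations at or below it are treated as
#' false-positive risk and zeroed by [apply_lob()].
#'
#' @param controls data frame of per-control pooled estimates with columns
#'   `control_id` and `lambda_hat` (e.g. from [pool_and_select()] on the
#'   control droplet counts, with `control_id` as `sample_id`).
#' @return object of class `lob_threshold`: list with `value` (copies/uL) and
#'   `source_control_id` (the control attaining the maximum; `NA` when all
#'   controls are clean, in which case `value` is 0).
#' @export
compute_lob <- function(controls) {
  if (!is.data.frame(controls) || nrow(controls) == 0)
    stop("configuration error: need at least one negative control")
  id_col <- if ("control_id" %in% names(controls)) "control_id" else "sample_id"
  if (!all(c(id_col, "lambda_hat") %in% names(controls)))
    stop("configuration error: controls need `control_id` and `lambda_hat`")
  i <- which.max(controls$lambda_hat)
  val <- controls$lambda_hat[i]
  out <- list(value = max(0, val),
              source_control_id = if (val > 0) controls[[id_col]][i] else NA_character_)
  class(out) <- "lob_threshold"
  out
}

#' @export
print.lob_threshold <- function(x, ...) {
  cat(sprintf("limit of blank: %.4g copies/uL (source: %s)\n", x$value,
              ifelse(is.na(x$source_control_id), "all controls clean",
                     x$source_control_id)))
  invisible(x)
}

#' Apply the limit of blank to sample concentrations and detections
#'
#' Samples whose pooled concentration is at or below the LOB are zeroed:
#' concentration set to 0 and all replicate detections set to 0. Retained
#' samples keep their concentration, and a replicate is scored as a detection
#' (`y = 1`) iff it has at least one positive droplet in the selected run.
#'
#' @param samples per-sample estimates from [pool_and_select()] (columns
#'   `sample_id`, `run_id`, `lambda_hat`, ...).
#' @param runs the per-replicate droplet counts (as given to
#'   [pool_and_select()]); only the selected run of each sample is scored.
#' @param lob a [compute_lob()] result, or a numeric threshold in copies/uL
#'   (default 0.258).
#' @param level `"sample"` (default): the threshold gates the pooled sample
#'   concentration only. `"replicate"`: additionally, a replicate within a
#'   retained sample only scores a detection when its own single-replicate
#'   estimate exceeds the threshold.
#' @param droplet_volume droplet volume in uL (used for the single-replicate
#'   estimates of `level = "replicate"`).
#' @return list with `concentrations` (the `samples` frame plus `lob_applied`
#'   flag and zeroed `lambda_hat`) and `detections` (data frame `sample_id`,
#'   `rep1` ... in replicate order, values 0/1). Applying the filter twice is
#'   a no-op.
#' @export
apply_lob <- function(samples, runs, lob = 0.258,
                      level = c("sample", "replicate"),
                      droplet_volume = 0.00085) {
  level <- match.arg(level)
  thr <- if (inherits(lob, "lob_threshold")) lob$value else as.numeric(lob)
  if (length(thr) != 1 || is.na(thr) || thr < 0)
    stop("configuration error: lob threshold must be a single value >= 0")
  conc <- samples
  conc$lob_applied <- conc$lambda_hat <= thr
  conc$lambda_hat[conc$lob_applied] <- 0
  # zero the interval/SE columns too where present: a zeroed sample is a
  # declared non-detection, not an estimate
  for (col in c("se", "ci_low", "ci_high"))
    if (col %in% names(conc)) conc[[col]][conc$lob_applied] <- 0

  kmax <- max(table(paste(runs$sample_id, runs$run_id)))
  det <- matrix(0L, nrow(conc), kmax,
                dimnames = list(NULL, paste0("rep", seq_len(kmax))))
  for (i in seq_len(nrow(conc))) {
    if (conc$lob_applied[i]) next
    r <- runs[runs$sample_id == conc$sample_id[i] &
                runs$run_id == conc$run_id[i], , drop = FALSE]
    r <- r[order(r$replicate_id), , drop = FALSE]
    hit <- r$m_pos >= 1
    if (level == "replicate" && any(hit)) {
      lam_k <- -log(1 - r$m_pos / r$m_total) / droplet_volume
      hit <- hit & lam_k > thr
    }
    det[i, seq_len(nrow(r))] <- as.integer(hit)
  }
  detections <- cbind(data.frame(sample_id = conc$sample_id,
                                 stringsAsFactors = FALSE),
                      as.data.frame(det))
  list(concentrations = conc, detections = detections)
}

#' Pool negative-control droplet counts per control
#'
#' Convenience wrapper: pools the droplet counts of each negative control
#' (across its wells) and estimates its concentration, yielding the input
#' expected by [compute_lob()].
#'
#' @param neg_controls data frame `control_id`, `control_type`, `m_total`,
#'   `m_pos` (one row per control well).
#' @param droplet_volume droplet volume in uL.
#' @return data frame `control_id`, `control_type`, `lambda_hat`.
#' @export
quantify_controls <- function(neg_controls, droplet_volume = 0.00085) {
  need <- c("control_id", "m_total", "m_pos")
  if (!is.data.frame(neg_controls) || !all(need %in% names(neg_controls)) ||
      nrow(neg_controls) == 0)
    stop("configuration error: need a non-empty neg_controls table with ",
         paste(need, collapse = ", "))
  out <- lapply(split(neg_controls, neg_controls$control_id, drop = TRUE),
                function(d) {
    est <- estimate_concentration(sum(d$m_total), sum(d$m_pos), droplet_volume)
    data.frame(control_id = d$control_id[1],
               control_type = if ("control_type" %in% names(d))
                 d$control_type[1] else NA_character_,
               lambda_hat = est$lambda_hat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' PCR inhibition from the internal positive control
#'
#' Scores inhibition of a reaction as the fractional loss of the exogenous
#' internal positive control (IPC) relative to the uninhibited standards:
#' `clamp(1 - ipc_sample / ipc_standard, 0, 1)`. Reported as QC metadata
#' only; inhibited samples can still yield target detections.
#'
#' @param ipc_sample IPC concentration measured in the sample well
#'   (copies/uL, >= 0). Vectorized.
#' @param ipc_standard IPC concentration of the standards (> 0).
#' @return inhibition fraction(s) in `[0, 1]`.
#' @export
inhibition_ratio <- function(ipc_sample, ipc_standard) {
  if (any(!is.finite(ipc_standard)) || any(ipc_standard <= 0))
    stop("configuration error: ipc_standard must be > 0")
  if (any(ipc_sample < 0, na.rm = TRUE))
    stop("data error: ipc_sample must be >= 0")
  pmin(pmax(1 - ipc_sample / ipc_standard, 0), 1)
}
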