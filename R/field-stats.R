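#' Impute missing water temperatures from collection time
#'
#' Fits an ordinary-least-squares regression of water temperature on
#' collection time over the samples with measured temperatures and replaces
#' missing temperatures by the fitted values. Measured values are never
#' touched; imputed rows are flagged so they can be excluded from analyses
#' that require measured temperatures.
#'
#' @param samples data frame with `water_temp_c` (NA where missing) and
#'   `time` (minutes since midnight or `"HH:MM"`).
#' @return `samples` with `water_temp_c` completed and a logical
#'   `temp_imputed` column.
#' @export
impute_temperature <- function(samples) {
  tm <- .as_minutes(samples$time)
  temp <- as.numeric(samples$water_temp_c)
  miss <- is.na(temp)
  if (all(miss)) stop("imputation error: no measured temperatures")
  if (sum(!miss) < 10)
    stop("imputation error: need at least 10 measured temperatures")
  if (any(miss)) {
    fit <- lm(temp ~ tm, subset = !miss)
    temp[miss] <- predict(fit, newdata = data.frame(tm = tm[miss]))
  }
  samples$water_temp_c <- temp
  samples$temp_imputed <- miss
  samples
}

#' Pearson correlation between collection time and water temperature
#'
#' @param samples data frame with `time`, `water_temp_c` and (optionally) a
#'   `temp_imputed` flag.
#' @param exclude_imputed drop rows with imputed temperatures (default TRUE).
#' @return list with `r`, `t_stat` (equal to `t = r*sqrt(n-2)/sqrt(1-r^2)`), `df`
#'   (`n - 2`) and the two-sided `p` from the t distribution. A perfect
#'   correlation reports an infinite t and p = 0.
#' @export
correlation_time_temp <- function(samples, exclude_imputed = TRUE) {
  keep <- rep(TRUE, nrow(samples))
  if (exclude_imputed && "temp_imputed" %in% names(samples))
    keep <- !samples$temp_imputed
  tm <- .as_minutes(samples$time)[keep]
  temp <- as.numeric(samples$water_temp_c)[keep]
  ok <- !is.na(tm) & !is.na(temp)
  tm <- tm[ok]; temp <- temp[ok]
  n <- length(tm)
  if (n < 3) stop("data error: need at least 3 usable samples")
  if (sd(tm) == 0 || sd(temp) == 0)
    stop("undefined-correlation error: zero variance")
  r <- cor(tm, temp)
  df <- n - 2
  t_stat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- if (is.infinite(t_stat)) 0 else 2 * pt(-abs(t_stat), df)
  list(r = r, t_stat = t_stat, df = df, p = p, n = n)
}

#' Partition colony-control pairs by temperature mismatch
#'
#' A pair is excluded when the median water temperature of its control
#' samples is at least `threshold_c` degrees Celsius higher than the median
#' of its colony samples ("at least": the boundary case is excluded).
#' Medians are order-free, so the partition does not depend on sample order.
#'
#' @param samples data frame with `site_id`, `water_temp_c`.
#' @param sites data frame with `site_id`, `pair_id`, `island_type`
#'   (values `colony` / `control`).
#' @param threshold_c exclusion threshold in degrees Celsius (default 8).
#' @return data frame per pair: `pair_id`, `colony_median`, `control_median`,
#'   `temp_median_diff` (control minus colony) and `excluded`.
#' @export
exclude_pairs <- function(samples, sites, threshold_c = 8) {
  stopifnot(all(c("pair_id", "island_type", "site_id") %in% names(sites)))
  merged <- merge(samples, sites[c("site_id", "pair_id", "island_type")],
                  by = "site_id")
  out <- lapply(split(merged, merged$pair_id), function(d) {
    col <- d$water_temp_c[d$island_type == "colony"]
    ctl <- d$water_temp_c[d$island_type == "control"]
    if (length(col) == 0 || length(ctl) == 0)
      stop("pairing error: pair ", d$pair_id[1], " is missing one side")
    diff <- median(ctl, na.rm = TRUE) - median(col, na.rm = TRUE)
    data.frame(pair_id = d$pair_id[1], colony_median = median(col, na.rm = TRUE),
               control_median = median(ctl, na.rm = TRUE),
               temp_median_diff = diff, excluded = diff >= threshold_c)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive occupancy and concentration summary by island type
#'
#' The count-level summary of a paired eDNA survey: per island type, positive
#' and total samples (with percent, rounded half-to-even to 1 decimal),
#' positive and total sites, mean site-total concentration (a site total is
#' the sum of its post-LOB sample concentrations; zero sites included in the
#' mean), and the min/max positive sample concentration (NA when a type has
#' no positives).
#'
#' @param samples data frame with `site_id` and post-LOB `concentration`
#'   (copies/uL).
#' @param sites data frame with `site_id`, `island_type`.
#' @return data frame, one row per island type.
#' @export
naive_summary <- function(samples, sites) {
  merged <- merge(samples, sites[c("site_id", "island_type")], by = "site_id")
  if (!"concentration" %in% names(merged))
    stop("data error: samples need a post-LOB `concentration` column")
  out <- lapply(split(merged, merged$island_type), function(d) {
    pos <- d$concentration > 0
    if (nrow(d) == 0) stop("summary error: empty island-type stratum")
    site_tot <- tapply(d$concentration, d$site_id, sum)
    all_sites <- unique(sites$site_id[sites$island_type == d$island_type[1]])
    # sites with no positive sample still count (total 0)
    tot <- setNames(numeric(length(all_sites)), all_sites)
    tot[names(site_tot)] <- site_tot
    data.frame(
      island_type = d$island_type[1],
      positive_samples = sum(pos), total_samples = nrow(d),
      percent_positive = round(100 * sum(pos) / nrow(d), 1),
      positive_sites = sum(tot > 0), total_sites = length(tot),
      mean_site_total = mean(tot),
      min_positive = if (any(pos)) min(d$concentration[pos]) else NA_real_,
      max_positive = if (any(pos)) max(d$concentration[pos]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired t-test of site-total concentrations (colony minus control)
#'
#' Classical paired t statistic on per-pair differences of site-total
#' concentrations, `d = colony_total - control_total`, over the retained
#' pairs: `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1` and a two-sided
#' p-value. (The subtraction direction is fixed as colony minus control; only
#' the sign of `t` depends on it.)
#'
#' @param samples data frame with `site_id`, `concentration`.
#' @param sites data frame with `site_id`, `pair_id`, `island_type`.
#' @param retain_pairs optional vector of `pair_id` to keep (e.g. the
#'   non-excluded pairs from [exclude_pairs()]); default all.
#' @return list `mean_diff`, `sd_diff`, `t_stat`, `df`, `p`, `n_pairs`.
#' @export
paired_concentration_test <- function(samples, sites, retain_pairs = NULL) {
  merged <- merge(samples, sites[c("site_id", "pair_id", "island_type")],
                  by = "site_id")
  if (!is.null(retain_pairs))
    merged <- merged[merged$pair_id %in% retain_pairs, , drop = FALSE]
  pairs <- split(merged, merged$pair_id)
  if (length(pairs) < 2) stop("test error: need at least 2 retained pairs")
  d <- vapply(pairs, function(x) {
    sum(x$concentration[x$island_type == "colony"]) -
      sum(x$concentration[x$island_type == "control"])
  }, numeric(1))
  n <- length(d)
  m <- mean(d); s <- sd(d)
  # no variation in the differences: a mean of zero is exactly no effect
  t_stat <- if (s == 0 && m == 0) 0 else m / (s / sqrt(n))
  df <- n - 1
  p <- 2 * pt(-abs(t_stat), df)
  list(mean_diff = m, sd_diff = s, t_stat = t_stat, df = df, p = p,
       n_pairs = n)
}

#' Survey design counts: clock cutoff and temperature range
#'
#' Per island type, the count and percent (1 decimal, half-to-even) of
#' samples collected strictly before a clock cutoff, and overall the count
#' and percent of samples whose water temperature lies in a closed interval.
#'
#' @param samples data frame with `site_id`, `time`, `water_temp_c`.
#' @param sites data frame with `site_id`, `island_type`.
#' @param cutoff_minutes clock cutoff in minutes since midnight (default 660,
#'   i.e. 11AM).
#' @param temp_range closed temperature interval in Celsius (default
#'   `c(20.3, 27.8)`).
#' @return list with `by_type` (data frame `island_type`, `before_cutoff`,
#'   `total`, `percent`) and `temperature` (list `in_range`, `total`,
#'   `percent`).
#' @export
design_counts <- function(samples, sites, cutoff_minutes = 660,
                          temp_range = c(20.3, 27.8)) {
  merged <- merge(samples, sites[c("site_id", "island_type")], by = "site_id")
  tm <- .as_minutes(merged$time)
  by_type <- lapply(split(seq_len(nrow(merged)), merged$island_type),
                    function(ix) {
    before <- sum(tm[ix] < cutoff_minutes)
    data.frame(island_type = merged$island_type[ix[1]],
               before_cutoff = before, total = length(ix),
               percent = round(100 * before / length(ix), 1),
               stringsAsFactors = FALSE)
  })
  by_type <- do.call(rbind, by_type)
  rownames(by_type) <- NULL
  temp <- as.numeric(merged$water_temp_c)
  inr <- sum(temp >= temp_range[1] & temp <= temp_range[2], na.rm = TRUE)
  list(by_type = by_type,
       temperature = list(in_range = inr, total = nrow(merged),
                          percent = round(100 * inr / nrow(merged), 1)))
}
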