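#' Deterministic demonstration survey with known count-level summaries
#'
#' A fully deterministic synthetic survey of 15 colony-control island pairs
#' (265 water samples, 5 ddPCR replicates each) whose count-level summaries
#' are fixed by construction: 19 of 137 colony samples positive across 10 of
#' 15 colony sites, 5 of 128 control samples positive across 4 of 15 control
#' sites, positive sample concentrations spanning 0.26-38.29 copies/uL at
#' colonies and 0.26-0.39 copies/uL at controls, mean site-total
#' concentrations of 3.20 (colonies) and 0.11 (controls) copies/uL, a
#' no-template control at the 0.258 copies/uL limit of blank, 97/137 colony
#' and 91/128 control samples collected before 11AM, 218 of 265 samples in
#' the 20.3-27.8 degrees C range, and exactly 3 pairs whose control median
#' temperature is at least 8 degrees C above the paired colony median.
#'
#' Positive samples carry pooled droplet counts (mostly 16,000 droplets per
#' replicate at 0.00085 uL) chosen by inverting the Poisson partition mean,
#' so re-quantifying the droplet counts reproduces the stated concentrations
#' at their printed precision. The same tables ship as frozen CSVs under
#' `system.file("extdata", "fixture", package = "ednaocc")`.
#'
#' @return list of the four raw tables: `sites`, `samples`, `replicates`,
#'   `neg_controls`. Regeneration is byte-identical (no randomness).
#' @export
survey_fixture <- function() {
  np <- 15
  sites <- data.frame(
    site_id = c(sprintf("C%02d", 1:np), sprintf("X%02d", 1:np)),
    pair_id = rep(1:np, 2),
    island_type = rep(c("colony", "control"), each = np),
    area_m2 = c(seq(300, 3100, length.out = np),
                seq(280, 3000, length.out = np)),
    stringsAsFactors = FALSE
  )

  n_col <- c(10, 10, rep(9, 13))      # 137 colony samples
  n_ctl <- c(rep(9, 8), rep(8, 7))    # 128 control samples

  mk_samples <- function(prefix, nper) {
    do.call(rbind, lapply(seq_len(np), function(i) {
      data.frame(
        sample_id = sprintf("%s%02d-%02d", prefix, i, seq_len(nper[i])),
        site_id = sprintf("%s%02d", prefix, i),
        date = as.character(as.Date("2017-04-03") + 3 * (i - 1)),
        stringsAsFactors = FALSE
      )
    }))
  }
  col_s <- mk_samples("C", n_col)
  ctl_s <- mk_samples("X", n_ctl)

  # collection times: exactly 97 colony and 91 control samples before 11:00
  assign_times <- function(n, n_early) {
    idx <- seq_len(n)
    ifelse(idx <= n_early,
           480 + ((idx - 1) %% 36) * 5,    # 08:00-10:55
           660 + ((idx - n_early - 1) %% 24) * 5)  # 11:00-12:55
  }
  col_s$time <- .fmt_minutes(assign_times(nrow(col_s), 97))
  ctl_s$time <- .fmt_minutes(assign_times(nrow(ctl_s), 91))

  # temperatures: 47 of 265 outside [20.3, 27.8]; pairs 13-15 get a
  # control-minus-colony median gap >= 8 C, all other pairs stay below 8
  temp_of <- function(site, within_site_idx) {
    i <- as.integer(substr(site, 2, 3))
    colony <- substr(site, 1, 1) == "C"
    if (colony) {
      if (i >= 13) return(18.0)                           # 27 outside
      if (i == 12) return(21.0)
      if (i == 11) return(20.5)
      if (i == 1 && within_site_idx <= 4) return(19.5)    # 4 outside
      return(23.0)
    }
    if (i >= 13) return(26.5)
    if (i == 12) return(28.4)                             # 8 outside
    if (i == 11) return(28.2)                             # 8 outside
    24.0
  }
  for (s in c("col_s", "ctl_s")) {
    d <- get(s)
    widx <- as.integer(substr(d$sample_id, 5, 6))
    d$water_temp_c <- mapply(temp_of, d$site_id, widx)
    d$depth_cm <- ifelse(substr(d$site_id, 1, 1) == "C", 30, 40) +
      (as.integer(substr(d$site_id, 2, 3)) %% 5)
    assign(s, d)
  }
  samples <- rbind(col_s, ctl_s)
  rownames(samples) <- NULL

  # positive samples: pooled positive-droplet totals inverted from the target
  # concentrations (m droplets per replicate, v = 0.00085 uL)
  # C01-01 38.29, C01-02 0.26, seventeen colony fillers ~0.556 (so the colony
  # site-total mean prints 3.20); X01 0.26 & 0.39, three control fillers
  # ~0.338 (control mean prints 0.11)
  pos <- rbind(
    data.frame(sample_id = "C01-01", m = 16000L, m1_pool = 2562L),
    data.frame(sample_id = "C01-02", m = 16000L, m1_pool = 18L),
    data.frame(sample_id = sprintf("C%02d-%02d", rep(2:9, each = 2),
                                   rep(1:2, 8)),
               m = 16000L, m1_pool = 38L),
    data.frame(sample_id = "C10-01", m = 16000L, m1_pool = 38L),
    data.frame(sample_id = "X01-01", m = 16000L, m1_pool = 18L),
    data.frame(sample_id = "X01-02", m = 20000L, m1_pool = 33L),
    data.frame(sample_id = c("X02-01", "X03-01", "X04-01"),
               m = 16000L, m1_pool = 23L)
  )

  spread5 <- function(total) { # distribute a pooled count over 5 replicates
    base <- total %/% 5L
    extra <- total %% 5L
    base + as.integer(seq_len(5) <= extra)
  }
  replicates <- do.call(rbind, lapply(seq_len(nrow(samples)), function(j) {
    sid <- samples$sample_id[j]
    k <- match(sid, pos$sample_id)
    m <- if (is.na(k)) 16000L else pos$m[k]
    m1 <- if (is.na(k)) rep(0L, 5) else spread5(pos$m1_pool[k])
    data.frame(sample_id = sid, replicate_id = 1:5, run_id = 1L,
               m_total = m, m_pos = m1,
               ipc_conc = if (substr(sid, 1, 1) == "C") 15 else 80,
               stringsAsFactors = FALSE)
  }))
  rownames(replicates) <- NULL

  # negative controls: all clean except one NTC whose pooled concentration is
  # 0.258 copies/uL, the limit of blank
  neg_controls <- data.frame(
    control_id = sprintf("NC%02d", 1:9),
    control_type = c(rep("field", 3), "filtration", "extraction",
                     rep("NTC", 4)),
    m_total = c(rep(17000L, 8), 18241L),
    m_pos = c(rep(0L, 8), 4L),
    stringsAsFactors = FALSE
  )

  list(sites = sites, samples = samples, replicates = replicates,
       neg_controls = neg_controls)
}
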