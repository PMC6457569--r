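# Covariates understood at each level of the hierarchy. `type` is the
# categorical island type (cell-means coded at the site level); the numeric
# covariates live on the samples table and are inherited by their replicates.
.SITE_COVARS <- "type"
.NUM_COVARS <- c("date", "time", "depth", "temp")

#' Specify a three-level occupancy model
#'
#' A model specification names the covariates entering each level of the
#' hierarchy on the logit scale: site occupancy (psi), sample occurrence
#' (theta) and replicate detection (p). `type` is cell-means coded (one
#' coefficient per island type, no global intercept); the theta and p levels
#' always carry an intercept, plus centered/scaled numeric covariates.
#'
#' @param psi character vector of site covariates (`"type"` or empty for
#'   intercept-only).
#' @param theta character vector of sample covariates (subset of `date`,
#'   `time`, `depth`, `temp`).
#' @param p character vector of replicate covariates (same choices).
#' @param prior_sd prior standard deviation of every coefficient on the logit
#'   scale (Normal(0, prior_sd^2), default 2: weakly informative, keeps the
#'   implied occupancy probabilities near-uniform).
#' @return object of class `occu_model_spec`.
#' @seealso [parse_model_string()] for the compact `"psi(type)theta(.)p(time)"`
#'   notation.
#' @export
model_spec <- function(psi = character(), theta = character(),
                       p = character(), prior_sd = 2) {
  psi <- psi[psi != "."]; theta <- theta[theta != "."]; p <- p[p != "."]
  bad <- setdiff(psi, .SITE_COVARS)
  if (length(bad)) stop("parse error: unknown site covariate '", bad[1], "'")
  bad <- setdiff(theta, .NUM_COVARS)
  if (length(bad)) stop("parse error: unknown sample covariate '", bad[1], "'")
  bad <- setdiff(p, .NUM_COVARS)
  if (length(bad)) stop("parse error: unknown replicate covariate '", bad[1], "'")
  if (!is.numeric(prior_sd) || prior_sd <= 0) stop("prior_sd must be > 0")
  out <- list(psi = psi, theta = theta, p = p, prior_sd = prior_sd)
  class(out) <- "occu_model_spec"
  out
}

#' @export
format.occu_model_spec <- function(x, ...) {
  lab <- function(v) if (length(v) == 0) "." else paste(v, collapse = " + ")
  sprintf("psi(%s)theta(%s)p(%s)", lab(x$psi), lab(x$theta), lab(x$p))
}

#' @export
print.occu_model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse compact model notation
#'
#' Parses strings like `"psi(type)theta(.)p(time + depth)"` into a
#' [model_spec()]. `.` denotes an intercept-only level; covariate names are
#' separated by `+`. The Greek spellings are also accepted.
#'
#' @param s model string.
#' @param prior_sd passed to [model_spec()].
#' @return an `occu_model_spec`.
#' @export
parse_model_string <- function(s, prior_sd = 2) {
  if (!is.character(s) || length(s) != 1)
    stop("parse error: model string must be a single character value")
  s0 <- s
  s <- gsub("ψ", "psi", s)
  s <- gsub("θ", "theta", s)
  s <- gsub("\\s", "", s)
  m <- regmatches(s, regexec("^psi\\(([^)]*)\\)theta\\(([^)]*)\\)p\\(([^)]*)\\)$", s))[[1]]
  if (length(m) != 4) {
    stop(sprintf("parse error in model string '%s': expected psi(...)theta(...)p(...) at position %d",
                 s0, .first_mismatch(s)))
  }
  split1 <- function(txt) {
    if (txt == "" || txt == ".") return(character())
    trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  }
  model_spec(psi = split1(m[2]), theta = split1(m[3]), p = split1(m[4]),
             prior_sd = prior_sd)
}

.first_mismatch <- function(s) {
  # walk the grammar psi(<args>)theta(<args>)p(<args>) and report the first
  # character at which the input departs from it
  pos <- 1L
  for (kw in c("psi", "theta", "p")) {
    for (ch in strsplit(kw, "")[[1]]) {
      if (substr(s, pos, pos) != ch) return(pos)
      pos <- pos + 1L
    }
    if (substr(s, pos, pos) != "(") return(pos)
    pos <- pos + 1L
    while (pos <= nchar(s) && substr(s, pos, pos) != ")") pos <- pos + 1L
    if (substr(s, pos, pos) != ")") return(pos)
    pos <- pos + 1L
  }
  pos # trailing garbage after the closing parenthesis
}

#' Assemble detection data and design matrices for model fitting
#'
#' Builds the ragged site/sample/replicate detection structure
#' \eqn{y_{ijk}} together with the design matrices for each level of a
#' [model_spec()]. Numeric covariates are centered and scaled (sd with
#' denominator n-1) using the units at their own level: sample covariates
#' over samples for the theta level, and over replicates for the p level.
#' Island type is cell-means coded. Scaling metadata is stored so fitted
#' coefficients can be mapped back to natural units.
#'
#' @param sites data frame with `site_id`, `island_type` (and optionally
#'   `pair_id`). Sites with no samples are allowed (they contribute only
#'   their occupancy prior).
#' @param samples data frame with `sample_id`, `site_id`, `date` (ISO-8601 or
#'   `Date`), `time` (minutes since midnight or `"HH:MM"`), `water_temp_c`,
#'   `depth_cm`. Temperatures must be complete (impute first; see
#'   [impute_temperature()]).
#' @param detections data frame `sample_id`, `rep1`..`repK` with 0/1 entries
#'   (ragged rows may use `NA` for absent replicates), e.g. from
#'   [apply_lob()].
#' @param spec an `occu_model_spec` (or a model string).
#' @return object of class `occu_data`: list with element data frames
#'   (`sites`, `samples`), vectors `y`, `site_of_sample`, `sample_of_rep`
#'   (1-based), design matrices `X`, `W`, `V`, the cell-means rows `Xtype`,
#'   type labels, and `scaling` metadata.
#' @export
build_design_matrices <- function(sites, samples, detections, spec) {
  if (is.character(spec)) spec <- parse_model_string(spec)
  stopifnot(inherits(spec, "occu_model_spec"))
  if (!all(c("site_id", "island_type") %in% names(sites)))
    stop("data error: sites needs site_id and island_type")
  if (!all(c("sample_id", "site_id") %in% names(samples)))
    stop("data error: samples needs sample_id and site_id")
  if (!all(samples$site_id %in% sites$site_id))
    stop("data error: samples reference unknown site_id")
  if (anyDuplicated(sites$site_id)) stop("data error: duplicate site_id")
  if (anyDuplicated(samples$sample_id)) stop("data error: duplicate sample_id")

  samples <- samples[order(match(samples$site_id, sites$site_id)), ,
                     drop = FALSE]
  rownames(samples) <- NULL

  # raw numeric covariates at the sample level
  num <- data.frame(
    date = .as_num_date(samples$date),
    time = .as_minutes(samples$time),
    depth = as.numeric(samples$depth_cm),
    temp = as.numeric(samples$water_temp_c)
  )
  used <- union(spec$theta, spec$p)
  if (length(used) && any(!complete.cases(num[used])))
    stop("data error: missing covariate values (impute temperatures first)")

  # ragged detection array
  det <- detections[match(samples$sample_id, detections$sample_id), ,
                    drop = FALSE]
  if (any(is.na(det$sample_id)))
    stop("data error: detections missing for some samples")
  repcols <- grep("^rep[0-9]+$", names(det), value = TRUE)
  ymat <- as.matrix(det[repcols])
  y <- integer(0); sample_of_rep <- integer(0)
  for (j in seq_len(nrow(ymat))) {
    yj <- ymat[j, !is.na(ymat[j, ])]
    if (length(yj) == 0) stop("data error: sample without replicates: ",
                              samples$sample_id[j])
    if (!all(yj %in% c(0, 1))) stop("data error: detections must be 0/1")
    y <- c(y, as.integer(yj))
    sample_of_rep <- c(sample_of_rep, rep.int(j, length(yj)))
  }
  site_of_sample <- match(samples$site_id, sites$site_id)

  scale_at <- function(xraw, rows, covars) {
    # center/scale over the units at this level; record the metadata
    out <- list(mat = matrix(1, length(rows), 1,
                             dimnames = list(NULL, "(Intercept)")),
                center = numeric(0), scale = numeric(0))
    for (cv in covars) {
      v <- xraw[[cv]][rows]
      mu <- mean(v); sdv <- sd(v)
      if (!is.finite(sdv) || sdv == 0)
        stop("scaling error: covariate '", cv, "' is constant")
      out$mat <- cbind(out$mat, (v - mu) / sdv)
      colnames(out$mat)[ncol(out$mat)] <- cv
      out$center[cv] <- mu; out$scale[cv] <- sdv
    }
    out
  }

  types <- sort(unique(as.character(sites$island_type)))
  if ("type" %in% spec$psi) {
    X <- sapply(types, function(tp) as.numeric(sites$island_type == tp))
    X <- matrix(X, nrow = nrow(sites), dimnames = list(NULL, types))
    Xtype <- diag(length(types))
    dimnames(Xtype) <- list(types, types)
  } else {
    X <- matrix(1, nrow(sites), 1, dimnames = list(NULL, "(Intercept)"))
    Xtype <- matrix(1, length(types), 1, dimnames = list(types, "(Intercept)"))
  }

  Wsc <- scale_at(num, seq_len(nrow(samples)), spec$theta)
  Vsc <- scale_at(num, sample_of_rep, spec$p)

  out <- list(
    sites = sites, samples = samples, y = y,
    site_of_sample = site_of_sample, sample_of_rep = sample_of_rep,
    X = X, W = Wsc$mat, V = Vsc$mat, Xtype = Xtype, types = types,
    spec = spec, covariates = num,
    scaling = list(theta = Wsc[c("center", "scale")],
                   p = Vsc[c("center", "scale")])
  )
  class(out) <- "occu_data"
  out
}

#' @export
print.occu_data <- function(x, ...) {
  cat(sprintf("occupancy dataset: %d sites, %d samples, %d PCR replicates (%d detections)\n",
              nrow(x$sites), nrow(x$samples), length(x$y), sum(x$y)))
  cat("model:", format(x$spec), "\n")
  invisible(x)
}

.as_num_date <- function(d) {
  if (inherits(d, "Date")) return(as.numeric(d))
  if (is.numeric(d)) return(as.numeric(d))
  as.numeric(as.Date(as.character(d)))
}

.as_minutes <- function(tm) {
  if (is.numeric(tm)) return(as.numeric(tm))
  tm <- as.character(tm)
  ok <- grepl("^[0-9]{1,2}:[0-9]{2}$", tm)
  if (!all(ok | is.na(tm))) stop("data error: times must be HH:MM or minutes")
  hh <- as.numeric(sub(":.*", "", tm)); mm <- as.numeric(sub(".*:", "", tm))
  hh * 60 + mm
}

.fmt_minutes <- function(mins) sprintf("%02d:%02d", mins %/% 60, mins %% 60)
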