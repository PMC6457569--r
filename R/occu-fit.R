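#' Fit a multi-scale eDNA occupancy model by Gibbs sampling
#'
#' Fits the three-level Bayesian occupancy model for replicated eDNA surveys:
#' a latent site-level occupancy state \eqn{z_i \sim Bern(\psi_i)}, a latent
#' sample-level occurrence state \eqn{a_{ij} | z_i = 1 \sim Bern(\theta_{ij})}
#' and observed replicate detections
#' \eqn{y_{ijk} | a_{ij} = 1 \sim Bern(p_{ijk})}, each probability
#' logit-linear in its covariates. Coefficients carry independent
#' Normal(0, `prior_sd`^2) priors and are updated by conjugate Polya-Gamma
#' augmentation (or adaptive random-walk Metropolis); latent states are
#' updated from their full conditionals (see [latent_conditionals()]).
#'
#' Each post-burn-in draw also records the derived quantities reported for
#' such surveys: psi per island type (inverse logit at the type's design
#' row), theta-bar (mean over all samples of the occurrence probability) and
#' p-bar (mean over all replicates of the detection probability).
#'
#' @param data an `occu_data` object from [build_design_matrices()], or a
#'   list/environment with `sites`, `samples`, `detections` data frames from
#'   which one is built using `model`.
#' @param model an `occu_model_spec` or model string such as
#'   `"psi(type)theta(.)p(time)"`; ignored (with a warning) when `data` is
#'   already an `occu_data`.
#' @param n_iter total MCMC iterations (default 100000).
#' @param burn_in iterations discarded (default 5000).
#' @param prior_sd coefficient prior SD on the logit scale (default taken
#'   from the spec, itself defaulting to 2).
#' @param seed integer seed; every run with the same seed and inputs yields
#'   identical chains.
#' @param sampler `"pg"` (Polya-Gamma Gibbs, default) or `"rw"` (adaptive
#'   random-walk Metropolis fallback).
#' @param store_latent keep the per-draw latent `z` and `a` chains (default
#'   TRUE; turn off to save memory on large runs).
#' @return object of class `occu_ms` with elements `draws` (matrices `beta`,
#'   `alpha`, `delta`, `psi`, vectors `theta_bar`, `p_bar`, and latent `z`,
#'   `a` chains), `data`, `spec`, `n_iter`, `burn_in`, `seed`, `call`.
#' @examples
#' fx <- survey_fixture()
#' quant <- pool_and_select(fx$replicates)
#' lob <- compute_lob(quantify_controls(fx$neg_controls))
#' det <- apply_lob(quant, fx$replicates, lob)
#' fit <- occu_ms(list(sites = fx$sites, samples = fx$samples,
#'                     detections = det$detections),
#'                model = "psi(type)theta(.)p(time)",
#'                n_iter = 2000, burn_in = 500, seed = 1)
#' summary(fit)
#' @export
occu_ms <- function(data, model = "psi(type)theta(.)p(time)",
                    n_iter = 100000, burn_in = 5000, prior_sd = NULL,
                    seed = NULL, sampler = c("pg", "rw"),
                    store_latent = TRUE) {
  sampler <- match.arg(sampler)
  cl <- match.call()
  if (!inherits(data, "occu_data")) {
    spec <- if (inherits(model, "occu_model_spec")) model
            else parse_model_string(model)
    data <- build_design_matrices(data$sites, data$samples, data$detections,
                                  spec)
  }
  spec <- data$spec
  if (is.null(prior_sd)) prior_sd <- spec$prior_sd
  if (!is.numeric(n_iter) || !is.numeric(burn_in) || burn_in >= n_iter)
    stop("configuration error: need burn_in < n_iter")
  if (prior_sd <= 0) stop("configuration error: prior_sd must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  res <- .occu_gibbs_cpp(
    y = as.integer(data$y),
    site_of_sample = as.integer(data$site_of_sample - 1L),
    sample_of_rep = as.integer(data$sample_of_rep - 1L),
    X = data$X, W = data$W, V = data$V, Xtype = data$Xtype,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    prior_sd = prior_sd, sampler = if (sampler == "pg") 0L else 1L,
    store_latent = store_latent, clip = .CLIP
  )
  colnames(res$beta) <- colnames(data$X)
  colnames(res$alpha) <- colnames(data$W)
  colnames(res$delta) <- colnames(data$V)
  colnames(res$psi) <- rownames(data$Xtype)
  if (!store_latent) res$z <- res$a <- NULL

  out <- list(draws = res, data = data, spec = spec, n_iter = n_iter,
              burn_in = burn_in, prior_sd = prior_sd, seed = seed,
              sampler = sampler, call = cl)
  class(out) <- "occu_ms"
  out
}

#' Full-conditional probabilities of the latent occupancy states
#'
#' For one site with fixed parameters, returns the conditional probabilities
#' used by the Gibbs sampler:
#' \itemize{
#' \item `a_prob[j]`: \eqn{P(a_{ij} = 1 | z_i = 1, y_{ij.})}. Equal to 1 when
#'   any replicate of sample j is positive; otherwise
#'   \eqn{\theta q / (\theta q + 1 - \theta)} with
#'   \eqn{q = \prod_k (1 - p_{ijk})}. (Under \eqn{z_i = 0}, \eqn{a_{ij} = 0}
#'   with certainty.)
#' \item `z_prob`: \eqn{P(z_i = 1 | \mathrm{all}\ a_{ij} = 0)}
#'   \eqn{= \psi r / (\psi r + 1 - \psi)} with
#'   \eqn{r = \prod_j (1 - \theta_{ij})}; equal to 1 when any
#'   \eqn{a_{ij} = 1}.
#' }
#'
#' @param psi site occupancy probability (scalar in `[0,1]`).
#' @param theta sample occurrence probabilities (length J).
#' @param p replicate detection probabilities: list of length J of numeric
#'   vectors (ragged), or a J x K matrix.
#' @param y observed detections, same shape as `p`, values 0/1.
#' @param a optional current occurrence states (length J, 0/1) used for
#'   `z_prob`; defaults to "all zero", matching the definition above.
#' @return list with `a_prob` (length J) and `z_prob` (scalar).
#' @export
latent_conditionals <- function(psi, theta, p, y, a = NULL) {
  if (is.matrix(p)) p <- lapply(seq_len(nrow(p)), function(i) p[i, !is.na(p[i, ])])
  if (is.matrix(y)) y <- lapply(seq_len(nrow(y)), function(i) y[i, !is.na(y[i, ])])
  J <- length(theta)
  stopifnot(length(p) == J, length(y) == J, length(psi) == 1)
  allp <- c(psi, theta, unlist(p))
  if (any(allp < 0 | allp > 1)) stop("domain error: probabilities outside [0,1]")
  if (!all(unlist(y) %in% c(0, 1))) stop("domain error: y must be 0/1")
  a_prob <- vapply(seq_len(J), function(j) {
    if (any(y[[j]] == 1)) return(1)
    q <- prod(1 - p[[j]])
    th <- theta[j]
    (th * q) / (th * q + 1 - th)
  }, numeric(1))
  if (is.null(a)) a <- rep(0, J)
  if (any(a == 1)) {
    z_prob <- 1
  } else {
    r <- prod(1 - theta)
    z_prob <- (psi * r) / (psi * r + 1 - psi)
  }
  list(a_prob = a_prob, z_prob = z_prob)
}

#' Posterior summary table
#'
#' Per-quantity posterior median and equal-tailed 95% credible interval
#' (percentiles by linear interpolation between order statistics) for the
#' regression coefficients and the derived psi (by island type), theta-bar
#' and p-bar.
#'
#' @param fit an `occu_ms` fit.
#' @param prob credible mass (default 0.95).
#' @return data frame with columns `parameter`, `median`, `cri_low`,
#'   `cri_high`.
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "occu_ms"))
  d <- fit$draws
  if (nrow(d$beta) == 0) stop("state error: no post-burn-in draws")
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  one <- function(x, name) {
    data.frame(parameter = name, median = median(x),
               cri_low = unname(quantile(x, qs[1], type = 7)),
               cri_high = unname(quantile(x, qs[2], type = 7)),
               stringsAsFactors = FALSE)
  }
  blocks <- list(beta = d$beta, alpha = d$alpha, delta = d$delta, psi = d$psi)
  rows <- list()
  for (b in names(blocks)) {
    m <- blocks[[b]]
    for (j in seq_len(ncol(m)))
      rows[[length(rows) + 1]] <- one(m[, j], paste0(b, "[", colnames(m)[j], "]"))
  }
  if (!all(is.na(d$theta_bar)))
    rows[[length(rows) + 1]] <- one(d$theta_bar, "theta_bar")
  if (!all(is.na(d$p_bar)))
    rows[[length(rows) + 1]] <- one(d$p_bar, "p_bar")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection probability over a covariate grid
#'
#' Posterior mean and credible band of the replicate detection probability
#' \eqn{logit^{-1}(v'\delta)} along a grid of one standardized covariate
#' (other covariates held at 0, their standardized mean).
#'
#' @param fit an `occu_ms` fit whose p-level includes `covariate`.
#' @param grid standardized covariate values (default an equally spaced grid
#'   over the observed standardized range). Values beyond +-5 SD trigger a
#'   warning.
#' @param covariate name of the p-level covariate (default `"time"`).
#' @param prob credible mass.
#' @return data frame `grid`, `natural` (covariate back-transformed to its
#'   measurement units), `mean`, `cri_low`, `cri_high`.
#' @export
detection_curve <- function(fit, grid = NULL, covariate = "time",
                            prob = 0.95) {
  stopifnot(inherits(fit, "occu_ms"))
  V <- fit$data$V
  if (!covariate %in% colnames(V))
    stop("model did not include '", covariate, "' in the detection level")
  if (is.null(grid)) {
    rg <- range(V[, covariate])
    grid <- seq(rg[1], rg[2], length.out = 50)
  }
  if (any(abs(grid) > 5))
    warning("grid extends beyond 5 SD of the observed covariate")
  del <- fit$draws$delta
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  vrow <- matrix(0, length(grid), ncol(del),
                 dimnames = list(NULL, colnames(del)))
  vrow[, "(Intercept)"] <- 1
  vrow[, covariate] <- grid
  eta <- vrow %*% t(del)              # grid x draws
  pmatr <- plogis(.clip_eta(eta))
  sc <- fit$data$scaling$p
  natural <- if (covariate %in% names(sc$center))
    grid * sc$scale[[covariate]] + sc$center[[covariate]] else grid
  data.frame(grid = grid, natural = natural,
             mean = rowMeans(pmatr),
             cri_low = apply(pmatr, 1, quantile, qs[1], type = 7),
             cri_high = apply(pmatr, 1, quantile, qs[2], type = 7))
}

#' Chain diagnostics: autocorrelation and Monte Carlo standard errors
#'
#' Computes, for every coefficient chain and the derived quantities, the
#' autocorrelation function on the centered chain at lags 1..`max_lag` and
#' the batch-means Monte Carlo standard error
#' (`sd(batch means) / sqrt(n_batches)`).
#'
#' @param fit an `occu_ms` fit with at least 2500 post-burn-in draws (and at
#'   least `n_batches` draws for the batch means).
#' @param max_lag largest autocorrelation lag (default 50).
#' @param n_batches number of batches for the MCSE (default 50).
#' @param trace_file optional path; when given, all chains are written there
#'   as CSV for trace plotting.
#' @return list with `acf` (matrix lag x parameter), `mcse` (named vector)
#'   and `n_draws`.
#' @export
occu_diagnostics <- function(fit, max_lag = 50, n_batches = 50,
                             trace_file = NULL) {
  stopifnot(inherits(fit, "occu_ms"))
  ch <- .chain_matrix(fit)
  n <- nrow(ch)
  if (n < 2500)
    stop("diagnostics error: need at least 2500 post-burn-in draws")
  if (n < n_batches)
    stop("diagnostics error: chain shorter than the batch requirement")
  acfm <- sapply(colnames(ch), function(nm) .acf_lags(ch[, nm], max_lag))
  rownames(acfm) <- paste0("lag", seq_len(max_lag))
  bsize <- floor(n / n_batches)
  use <- seq_len(bsize * n_batches)
  mcse <- vapply(colnames(ch), function(nm) {
    bm <- colMeans(matrix(ch[use, nm], nrow = bsize))
    sd(bm) / sqrt(n_batches)
  }, numeric(1))
  if (!is.null(trace_file))
    write.csv(cbind(iteration = seq_len(n) + fit$burn_in, ch), trace_file,
              row.names = FALSE)
  list(acf = acfm, mcse = mcse, n_draws = n)
}

.acf_lags <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(rep(NA_real_, max_lag))
  vapply(seq_len(max_lag), function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom
  }, numeric(1))
}

.chain_matrix <- function(fit) {
  d <- fit$draws
  ch <- cbind(d$beta, d$alpha, d$delta, d$psi)
  colnames(ch) <- c(paste0("beta[", colnames(d$beta), "]"),
                    paste0("alpha[", colnames(d$alpha), "]"),
                    paste0("delta[", colnames(d$delta), "]"),
                    paste0("psi[", colnames(d$psi), "]"))
  if (!all(is.na(d$theta_bar))) ch <- cbind(ch, theta_bar = d$theta_bar)
  if (!all(is.na(d$p_bar))) ch <- cbind(ch, p_bar = d$p_bar)
  ch
}
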