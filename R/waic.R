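#' Site-level marginal likelihood of the occupancy model
#'
#' Likelihood of one site's detection history with the latent occupancy and
#' occurrence states integrated out:
#' \deqn{L_i = \psi_i \prod_j B_{ij} + (1 - \psi_i) I(\mathrm{all}\ y_{i..} = 0)}
#' \deqn{B_{ij} = \theta_{ij} \prod_k p_{ijk}^{y_{ijk}} (1-p_{ijk})^{1-y_{ijk}}
#'   + (1 - \theta_{ij}) I(\mathrm{all}\ y_{ij.} = 0)}
#' Sites are the exchangeable unit of the design, so this is the per-unit
#' predictive density entering [compute_waic()].
#'
#' @inheritParams latent_conditionals
#' @param log return the log likelihood (default FALSE).
#' @return the (log) likelihood value.
#' @export
site_marginal_likelihood <- function(psi, theta, p, y, log = FALSE) {
  if (is.matrix(p)) p <- lapply(seq_len(nrow(p)), function(i) p[i, !is.na(p[i, ])])
  if (is.matrix(y)) y <- lapply(seq_len(nrow(y)), function(i) y[i, !is.na(y[i, ])])
  J <- length(theta)
  stopifnot(length(p) == J, length(y) == J, length(psi) == 1)
  allp <- c(psi, theta, unlist(p))
  if (any(allp < 0 | allp > 1)) stop("domain error: probabilities outside [0,1]")
  logB <- vapply(seq_len(J), function(j) {
    yk <- y[[j]]; pk <- p[[j]]
    cond <- exp(sum(yk * log(pk) + (1 - yk) * log1p(-pk)))
    log(theta[j] * cond + (1 - theta[j]) * as.numeric(all(yk == 0)))
  }, numeric(1))
  all0 <- all(unlist(y) == 0)
  # log(psi * prod B + (1 - psi) * I(all zero)), stabilized
  terms <- c(log(psi) + sum(logB),
             if (all0) log1p(-psi) else -Inf)
  ll <- .logsumexp(terms)
  if (log) ll else exp(ll)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' WAIC of a fitted occupancy model
#'
#' Computes the widely applicable information criterion from the site-level
#' marginal likelihood evaluated at every retained posterior draw. Per site,
#' `lppd_i = log(mean over draws of L_i)` and
#' `penalty_i = var over draws of log L_i`; then
#' `lack_of_fit = -2 * sum(lppd_i)`, `predictive_variance = 2 * sum(penalty_i)`
#' and `waic = lack_of_fit + predictive_variance` (exactly, by construction).
#' Means over draws are stabilized by log-sum-exp.
#'
#' @param fit an `occu_ms` fit with at least 100 post-burn-in draws.
#' @param chunk number of draws processed per block (memory control).
#' @return object of class `waic_result`: list with `waic`,
#'   `predictive_variance`, `lack_of_fit`, per-site vectors `lppd` and
#'   `penalty`, and `n_draws`.
#' @export
compute_waic <- function(fit, chunk = 500) {
  stopifnot(inherits(fit, "occu_ms"))
  d <- fit$draws
  n_draws <- nrow(d$beta)
  if (n_draws < 100) stop("state error: need at least 100 post-burn-in draws")
  dat <- fit$data
  nsite <- nrow(dat$X)
  nsamp <- nrow(dat$W)
  sos <- dat$site_of_sample
  sor <- dat$sample_of_rep
  y <- dat$y
  allzero_samp <- as.numeric(rowsum(y, sor)[, 1] == 0)
  pos_per_site <- numeric(nsite)
  pos_per_site[sort(unique(sos))] <- rowsum(1 - allzero_samp, sos)[, 1]
  allzero_site <- as.numeric(pos_per_site == 0)

  logL <- matrix(NA_real_, nsite, n_draws)
  for (start in seq(1, n_draws, by = chunk)) {
    ix <- start:min(start + chunk - 1, n_draws)
    eta_p <- .clip_eta(dat$V %*% t(d$delta[ix, , drop = FALSE]))
    eta_t <- .clip_eta(dat$W %*% t(d$alpha[ix, , drop = FALSE]))
    eta_s <- .clip_eta(dat$X %*% t(d$beta[ix, , drop = FALSE]))
    # per-replicate Bernoulli log density, summed within samples
    logdens <- y * stats::plogis(eta_p, log.p = TRUE) +
      (1 - y) * stats::plogis(-eta_p, log.p = TRUE)
    logcond <- rowsum(logdens, sor)                      # nsamp x |ix|
    theta <- plogis(eta_t)
    logB <- log(theta * exp(logcond) + (1 - theta) * allzero_samp)
    sumlogB <- rowsum(logB, sos)                         # per-site
    if (nrow(sumlogB) < nsite) { # sites with no samples contribute log(1)=0
      full <- matrix(0, nsite, length(ix))
      full[sort(unique(sos)), ] <- sumlogB
      sumlogB <- full
    }
    psi <- plogis(eta_s)
    t1 <- log(psi) + sumlogB
    t2 <- log1p(-psi)
    t2[allzero_site == 0, ] <- -Inf
    m <- pmax(t1, t2)
    logL[, ix] <- m + log(exp(t1 - m) + exp(t2 - m))
  }
  if (any(!is.finite(logL))) {
    bad <- which(apply(!is.finite(logL), 1, all))
    if (length(bad))
      stop("log-domain error: site(s) with zero likelihood across all draws: ",
           paste(dat$sites$site_id[bad], collapse = ", "))
  }
  lppd <- apply(logL, 1, .logsumexp) - log(n_draws)
  penalty <- apply(logL, 1, var)
  out <- list(
    lack_of_fit = -2 * sum(lppd),
    predictive_variance = 2 * sum(penalty),
    lppd = lppd, penalty = penalty, n_draws = n_draws
  )
  out$waic <- out$lack_of_fit + out$predictive_variance
  class(out) <- "waic_result"
  out
}

#' @export
print.waic_result <- function(x, digits = 2, ...) {
  cat(sprintf("WAIC %.*f = lack of fit %.*f + predictive variance %.*f (%d draws)\n",
              digits, x$waic, digits, x$lack_of_fit, digits,
              x$predictive_variance, x$n_draws))
  invisible(x)
}

#' Rank candidate models by WAIC
#'
#' Orders a named set of [compute_waic()] results by increasing WAIC (lower
#' is better). The sort is stable: tied models keep their input order.
#'
#' @param results named list of `waic_result` objects (names are the model
#'   labels, e.g. the model strings).
#' @return data frame `model`, `waic`, `predictive_variance`, `lack_of_fit`,
#'   `rank`, sorted by `waic`.
#' @export
rank_models <- function(results) {
  if (length(results) == 0) stop("configuration error: no models to rank")
  if (is.null(names(results)) || anyDuplicated(names(results)) ||
      any(names(results) == ""))
    stop("configuration error: results must have unique, non-empty names")
  stopifnot(all(vapply(results, inherits, logical(1), "waic_result")))
  tab <- data.frame(
    model = names(results),
    waic = vapply(results, `[[`, numeric(1), "waic"),
    predictive_variance = vapply(results, `[[`, numeric(1),
                                 "predictive_variance"),
    lack_of_fit = vapply(results, `[[`, numeric(1), "lack_of_fit"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$waic)            # radix order: stable on ties
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
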