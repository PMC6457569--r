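#' @export
print.occu_ms <- function(x, ...) {
  cat("Multi-scale eDNA occupancy model (Bayesian,",
      if (x$sampler == "pg") "Polya-Gamma Gibbs)" else "random-walk Metropolis)",
      "\n")
  cat("model: ", format(x$spec), "\n", sep = "")
  cat(sprintf("data:  %d sites, %d samples, %d PCR replicates\n",
              nrow(x$data$sites), nrow(x$data$samples), length(x$data$y)))
  cat(sprintf("chains: %d iterations, burn-in %d (%d draws kept)\n",
              x$n_iter, x$burn_in, nrow(x$draws$beta)))
  cat("\nPosterior medians:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.occu_ms <- function(object, ...) {
  d <- object$draws
  out <- c(apply(d$beta, 2, median), apply(d$alpha, 2, median),
           apply(d$delta, 2, median))
  names(out) <- c(paste0("psi.", colnames(d$beta)),
                  paste0("theta.", colnames(d$alpha)),
                  paste0("p.", colnames(d$delta)))
  out
}

#' @export
summary.occu_ms <- function(object, prob = 0.95, ...) {
  out <- list(table = summarize_posterior(object, prob), spec = object$spec,
              n_iter = object$n_iter, burn_in = object$burn_in, prob = prob)
  class(out) <- "summary.occu_ms"
  out
}

#' @export
print.summary.occu_ms <- function(x, digits = 3, ...) {
  cat("model:", format(x$spec), "\n")
  cat(sprintf("%d iterations, burn-in %d; %.0f%% equal-tailed credible intervals\n\n",
              x$n_iter, x$burn_in, 100 * x$prob))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Posterior predictions from a fitted occupancy model
#'
#' `level = "psi"` returns the posterior of site occupancy per island type;
#' `level = "theta"` / `level = "p"` return posterior summaries of the
#' occurrence / detection probability for each observed unit (or, for
#' `level = "p"` with `grid`, along a covariate grid via
#' [detection_curve()]).
#'
#' @param object an `occu_ms` fit.
#' @param level one of `"psi"`, `"theta"`, `"p"`.
#' @param grid optional standardized covariate grid (detection level only).
#' @param covariate covariate for `grid` (default `"time"`).
#' @param prob credible mass.
#' @param ... unused.
#' @return data frame of posterior means/medians and credible bounds.
#' @export
predict.occu_ms <- function(object, level = c("psi", "theta", "p"),
                            grid = NULL, covariate = "time", prob = 0.95,
                            ...) {
  level <- match.arg(level)
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  summar <- function(m, labels) {
    data.frame(unit = labels, mean = colMeans(m),
               median = apply(m, 2, median),
               cri_low = apply(m, 2, quantile, qs[1], type = 7),
               cri_high = apply(m, 2, quantile, qs[2], type = 7),
               row.names = NULL)
  }
  d <- object$draws
  if (level == "psi") return(summar(d$psi, colnames(d$psi)))
  if (level == "p" && !is.null(grid))
    return(detection_curve(object, grid, covariate, prob))
  if (level == "theta") {
    eta <- object$data$W %*% t(d$alpha)
    return(summar(t(plogis(.clip_eta(eta))), object$data$samples$sample_id))
  }
  eta <- object$data$V %*% t(d$delta)
  summar(t(plogis(.clip_eta(eta))),
         paste0(object$data$samples$sample_id[object$data$sample_of_rep],
                ":k", sequence(tabulate(object$data$sample_of_rep))))
}

#' Plot a fitted occupancy model
#'
#' `which = "traces"` draws trace plots of the coefficient chains;
#' `which = "detection"` draws the posterior detection-probability curve
#' against the time-of-day covariate (requires `time` in the p level);
#' `which = "psi"` draws posterior densities of occupancy by island type.
#'
#' @param x an `occu_ms` fit.
#' @param which `"traces"`, `"detection"` or `"psi"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.occu_ms <- function(x, which = c("traces", "detection", "psi"), ...) {
  which <- match.arg(which)
  if (which == "detection") {
    dc <- detection_curve(x)
    plot(dc$natural, dc$mean, type = "l", ylim = c(0, 1),
         xlab = "collection time (minutes since midnight)",
         ylab = "detection probability p", ...)
    graphics::lines(dc$natural, dc$cri_low, lty = 2)
    graphics::lines(dc$natural, dc$cri_high, lty = 2)
    return(invisible(x))
  }
  if (which == "psi") {
    d <- x$draws$psi
    dens <- apply(d, 2, stats::density, from = 0, to = 1)
    ylim <- c(0, max(vapply(dens, function(z) max(z$y), numeric(1))))
    plot(dens[[1]], main = "posterior site occupancy", xlim = c(0, 1),
         ylim = ylim, xlab = expression(psi), ...)
    if (length(dens) > 1)
      for (j in 2:length(dens)) graphics::lines(dens[[j]], lty = j)
    graphics::legend("topleft", legend = colnames(d), lty = seq_len(ncol(d)),
                     bty = "n")
    return(invisible(x))
  }
  ch <- .chain_matrix(x)
  k <- min(ncol(ch), 9)
  op <- graphics::par(mfrow = c(ceiling(k / 3), min(k, 3)),
                      mar = c(2, 2, 2, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_len(k))
    plot(ch[, j], type = "l", main = colnames(ch)[j], xlab = "", ylab = "")
  invisible(x)
}

#' Simulate detection data from a fitted occupancy model
#'
#' Draws new latent states and detection histories on the fitted survey
#' design, one replicate dataset per posterior draw (sampled at random from
#' the retained draws).
#'
#' @param object an `occu_ms` fit.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a 0/1 vector of simulated
#'   detections aligned with `object$data$y`.
#' @export
simulate.occu_ms <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  dat <- object$data
  idx <- sample.int(nrow(d$beta), nsim, replace = TRUE)
  out <- lapply(idx, function(i) {
    psi <- plogis(.clip_eta(dat$X %*% d$beta[i, ]))
    theta <- plogis(.clip_eta(dat$W %*% d$alpha[i, ]))
    p <- plogis(.clip_eta(dat$V %*% d$delta[i, ]))
    z <- rbinom(nrow(dat$X), 1, psi)
    a <- rbinom(nrow(dat$W), 1, theta) * z[dat$site_of_sample]
    rbinom(length(dat$y), 1, p) * a[dat$sample_of_rep]
  })
  attr(out, "seed") <- seed
  out
}
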