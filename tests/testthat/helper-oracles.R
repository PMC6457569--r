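# Independent brute-force oracles used across the suite.

# Exhaustive enumeration of the single-site joint P(z, a, y): returns the
# marginal likelihood of y and the latent conditionals, computed without any
# algebraic simplification.
enum_site <- function(psi, theta, p, y) {
  J <- length(theta)
  grid <- expand.grid(rep(list(0:1), J + 1))
  names(grid) <- c("z", paste0("a", seq_len(J)))
  w <- apply(grid, 1, function(st) {
    z <- st[1]; a <- st[-1]
    pr <- if (z) psi else 1 - psi
    for (j in seq_len(J)) {
      pr <- pr * if (z) (if (a[j]) theta[j] else 1 - theta[j])
                 else (if (a[j]) 0 else 1)
      pr <- pr * if (a[j]) prod(ifelse(y[[j]] == 1, p[[j]], 1 - p[[j]]))
                 else as.numeric(all(y[[j]] == 0))
    }
    pr
  })
  lik <- sum(w)
  a_prob <- vapply(seq_len(J), function(j) {
    keep <- grid$z == 1
    sum(w[keep & grid[[paste0("a", j)]] == 1]) / sum(w[keep])
  }, numeric(1))
  z_prob_given_a0 <- {
    a0 <- rowSums(grid[paste0("a", seq_len(J))]) == 0
    # conditional on all a = 0 (only well-defined when y is all zero)
    sum(w[a0 & grid$z == 1]) / sum(w[a0])
  }
  list(lik = lik, a_prob = a_prob, z_prob = z_prob_given_a0)
}

# all 0/1 detection configurations for a ragged (J, K_j) layout
all_y_configs <- function(Kj) {
  tot <- sum(Kj)
  lapply(0:(2^tot - 1), function(cfg) {
    bits <- as.integer(intToBits(cfg))[seq_len(tot)]
    split(bits, rep(seq_along(Kj), Kj))
  })
}

# random single-site instance (<= 3 samples x <= 2 replicates)
random_instance <- function() {
  J <- sample(1:3, 1)
  Kj <- sample(1:2, J, replace = TRUE)
  list(psi = runif(1, 0.05, 0.95),
       theta = runif(J, 0.05, 0.95),
       p = lapply(Kj, function(k) runif(k, 0.05, 0.95)),
       Kj = Kj)
}

# numeric inversion of the Poisson partition mean E[m1] = m (1 - e^{-lambda v})
invert_partition <- function(m, m1, v) {
  if (m1 == 0) return(0)
  f <- function(lam) m * (1 - exp(-lam * v)) - m1
  stats::uniroot(f, c(1e-12, -log(1 - (m1 + 0.5) / m) / v * 2),
                 tol = 1e-14)$root
}

# textbook paired t-test on per-pair differences
paired_t_oracle <- function(d) {
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t_stat = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1))
}

# shared fixture pipeline products (quantified, LOB-filtered)
fixture_products <- function() {
  fx <- survey_fixture()
  quant <- pool_and_select(fx$replicates)
  lob <- compute_lob(quantify_controls(fx$neg_controls))
  filt <- apply_lob(quant, fx$replicates, lob)
  samples <- fx$samples
  samples$concentration <- filt$concentrations$lambda_hat[
    match(samples$sample_id, filt$concentrations$sample_id)]
  list(fx = fx, quant = quant, lob = lob, filt = filt, samples = samples)
}

# rebuild a detections data frame from an occu_data object (no LOB)
detections_from_dataset <- function(dataset) {
  K <- max(tabulate(dataset$sample_of_rep))
  det <- matrix(NA_integer_, nrow(dataset$samples), K,
                dimnames = list(NULL, paste0("rep", seq_len(K))))
  k_within <- sequence(tabulate(dataset$sample_of_rep))
  det[cbind(dataset$sample_of_rep, k_within)] <- dataset$y
  cbind(data.frame(sample_id = dataset$samples$sample_id,
                   stringsAsFactors = FALSE),
        as.data.frame(det))
}

# minimal fit-shaped object for testing posterior summarizers in isolation
fake_fit <- function(delta = NULL, chain = NULL, V = NULL,
                     scaling = list(center = numeric(0), scale = numeric(0))) {
  if (is.null(chain)) chain <- rnorm(100)
  onecol <- function(nm) matrix(chain, ncol = 1, dimnames = list(NULL, nm))
  draws <- list(beta = onecol("colony"), alpha = onecol("(Intercept)"),
                delta = if (is.null(delta)) onecol("(Intercept)") else delta,
                psi = onecol("colony"), theta_bar = chain, p_bar = chain)
  structure(list(draws = draws,
                 data = list(V = V, scaling = list(p = scaling)),
                 burn_in = 0),
            class = "occu_ms")
}
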