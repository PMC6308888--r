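# Independent brute-force oracles and tiny fixtures used across tests.
# These re-derive likelihood values from first principles, never through the
# package's own evaluation path.

# Direct zero-inflated binomial NLL for intercept-only models, written as a
# plain double loop over sites and visits.
occu_nll_direct <- function(y, psi, p) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    det <- 1
    allzero <- TRUE
    for (j in seq_len(ncol(y))) {
      if (is.na(y[i, j])) next
      det <- det * (if (y[i, j] == 1) p else 1 - p)
      if (y[i, j] == 1) allzero <- FALSE
    }
    total <- total - log(psi * det + (1 - psi) * as.numeric(allzero))
  }
  total
}

# Direct N-mixture NLL by explicit summation over latent abundance.
nmix_nll_direct <- function(y, lambda, p, K) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    lik <- 0
    for (N in 0:K) {
      term <- dpois(N, lambda)
      for (j in seq_len(ncol(y))) {
        if (is.na(y[i, j])) next
        term <- term * dbinom(y[i, j], N, p)
      }
      lik <- lik + term
    }
    total <- total - log(lik)
  }
  total
}

# Direct two-species NLL over the four latent joint states, intercept-only,
# no detection interaction.
twosp_nll_direct <- function(yA, yB, psiA, psiBA, psiBa, pA, pB) {
  bern <- function(row, p) {
    out <- 1
    for (v in row) {
      if (is.na(v)) next
      out <- out * (if (v == 1) p else 1 - p)
    }
    out
  }
  zero <- function(row) all(row[!is.na(row)] == 0)
  total <- 0
  for (i in seq_len(nrow(yA))) {
    lik <- psiA * psiBA * bern(yA[i, ], pA) * bern(yB[i, ], pB) +
      psiA * (1 - psiBA) * bern(yA[i, ], pA) * as.numeric(zero(yB[i, ])) +
      (1 - psiA) * psiBa * as.numeric(zero(yA[i, ])) * bern(yB[i, ], pB) +
      (1 - psiA) * (1 - psiBa) *
        as.numeric(zero(yA[i, ]) && zero(yB[i, ]))
    total <- total - log(lik)
  }
  total
}

# Two-stage brute-force grid minimization over named probability axes.
# f takes a named list of probabilities; returns the argmin to a resolution
# of roughly span * (1/ (points-1))^stages.
grid_minimize <- function(f, axes, points = 15L, stages = 4L) {
  lo <- vapply(axes, function(a) a[1], numeric(1))
  hi <- vapply(axes, function(a) a[2], numeric(1))
  best <- NULL
  for (s in seq_len(stages)) {
    grids <- Map(function(l, h) seq(l, h, length.out = points), lo, hi)
    combos <- do.call(expand.grid, grids)
    vals <- apply(combos, 1, function(row) f(as.list(row)))
    k <- which.min(vals)
    best <- list(par = unlist(combos[k, ]), value = vals[k])
    span <- (hi - lo) / (points - 1)
    lo <- pmax(vapply(axes, function(a) a[1], numeric(1)), best$par - span)
    hi <- pmin(vapply(axes, function(a) a[2], numeric(1)), best$par + span)
  }
  best
}

# Coarse global grid followed by coordinate-wise brute-force scans: an
# optimizer-free minimizer for likelihood surfaces with more than two
# parameters.
coord_grid_minimize <- function(f, axes, points = 9L, sweeps = 30L,
                                scan_points = 41L) {
  best <- grid_minimize(f, axes, points = points, stages = 1L)
  par <- best$par
  lo_all <- vapply(axes, function(a) a[1], numeric(1))
  hi_all <- vapply(axes, function(a) a[2], numeric(1))
  width <- (hi_all - lo_all) / 2
  for (s in seq_len(sweeps)) {
    for (k in seq_along(par)) {
      grid_k <- seq(max(lo_all[k], par[k] - width[k]),
                    min(hi_all[k], par[k] + width[k]),
                    length.out = scan_points)
      vals <- vapply(grid_k, function(v) {
        q <- par; q[k] <- v
        f(as.list(q))
      }, numeric(1))
      par[k] <- grid_k[which.min(vals)]
    }
    width <- width * 0.7
  }
  list(par = par, value = f(as.list(par)))
}

# Round half away from zero (the convention behind printed values such as
# 25/40 -> 0.63), unlike base round()'s half-to-even.
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

make_binary_data <- function(y, site_covs = NULL, visit_covs = list()) {
  survey_data(y, site_covs = site_covs, visit_covs = visit_covs,
              mode = "binary")
}

make_count_data <- function(y, site_covs = NULL, visit_covs = list()) {
  survey_data(y, site_covs = site_covs, visit_covs = visit_covs,
              mode = "count")
}

# Hand-built occupancy fit object with known parameters (for prediction and
# GoF statistic tests that need exact probabilities, not estimates).
manual_occu_fit <- function(psi_coef, p_coef, dataset, vcov = NULL,
                            spec = model_spec(~1, ~1, "occupancy")) {
  est <- c(psi_coef, p_coef)
  structure(list(spec = spec,
                 estimates = est, vcov = vcov, loglik = NA_real_,
                 K = length(est), n_sites = nrow(dataset$y),
                 converged = TRUE, boundary = FALSE,
                 dataset = dataset,
                 n_state = length(psi_coef), n_det = length(p_coef)),
            class = c("occu_fit", "salocc_fit"))
}
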