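#' Chi-square goodness-of-fit statistic for an occupancy fit
#'
#' MacKenzie–Bailey-style statistic on detection-history frequencies.
#' Within each missingness cohort (sites sharing the same pattern of
#' surveyed visits) every possible history over the observed visits is
#' enumerated; expected frequencies come from the fitted \eqn{\hat\psi_i},
#' \eqn{\hat p_{ij}} summed over the cohort's sites. The statistic is
#' \eqn{\sum_h (O_h - E_h)^2 / E_h} over histories that were observed, plus
#' one pooled cell for all never-observed histories.
#'
#' @param fit a converged \code{occu_fit}.
#' @param dataset the data to score; defaults to the training data.
#' @return The nonnegative statistic.
#' @export
occupancy_gof_statistic <- function(fit, dataset = fit$dataset) {
  stopifnot(inherits(fit, "occu_fit"))
  cf <- split_coefs(fit)
  X <- state_design(dataset, fit$spec$formulas$state)
  W <- detection_design(dataset, fit$spec$formulas$detection)
  n <- nrow(dataset$y); J <- ncol(dataset$y)
  psi <- .plogis(drop(X %*% cf$state))
  p <- matrix(.plogis(drop(W %*% cf$det)), n, J)
  y <- dataset$y

  pattern <- apply(!is.na(y), 1, function(r) paste(as.integer(r), collapse = ""))
  stat <- 0
  for (pat in unique(pattern)) {
    sites <- which(pattern == pat)
    vis <- which(strsplit(pat, "")[[1]] == "1")
    if (!length(vis)) next
    histories <- as.matrix(expand.grid(rep(list(c(0, 1)), length(vis))))
    # expected count of each history in this cohort
    E <- numeric(nrow(histories))
    for (h in seq_len(nrow(histories))) {
      hv <- histories[h, ]
      ph <- vapply(sites, function(i) {
        pij <- p[i, vis]
        det <- prod(ifelse(hv == 1, pij, 1 - pij))
        psi[i] * det + (1 - psi[i]) * as.numeric(all(hv == 0))
      }, numeric(1))
      E[h] <- sum(ph)
    }
    key <- apply(histories, 1, paste, collapse = "")
    obs_key <- apply(y[sites, vis, drop = FALSE], 1, paste, collapse = "")
    O <- as.numeric(table(factor(obs_key, levels = key)))
    seen <- O > 0
    if (any(seen & E <= 0))
      stop("expected frequency 0 for an observed history")
    stat <- stat + sum((O[seen] - E[seen])^2 / E[seen])
    if (any(!seen)) {
      E0 <- sum(E[!seen])
      if (E0 > 0) stat <- stat + E0      # (0 - E0)^2 / E0
    }
  }
  stat
}

#' Pearson residual goodness-of-fit statistic for an N-mixture fit
#'
#' Sum of squared Pearson residuals of the counts against the marginal
#' mean and variance of each site-visit count, computed by finite mixture
#' over latent abundance up to \code{K_trunc}.
#'
#' @param fit a converged \code{nmix_fit}.
#' @param dataset the data to score; defaults to the training data.
#' @return The nonnegative statistic.
#' @export
nmixture_gof_statistic <- function(fit, dataset = fit$dataset) {
  stopifnot(inherits(fit, "nmix_fit"))
  cf <- split_coefs(fit)
  X <- state_design(dataset, fit$spec$formulas$state)
  W <- detection_design(dataset, fit$spec$formulas$detection)
  n <- nrow(dataset$y); J <- ncol(dataset$y)
  lambda <- exp(drop(X %*% cf$state))
  p <- matrix(.plogis(drop(W %*% cf$det)), n, J)
  y <- dataset$y
  stat <- 0
  for (i in seq_len(n)) {
    mm <- nmix_moments(lambda[i], p[i, ], fit$K_trunc)
    r2 <- (y[i, ] - mm$mean)^2 / mm$var
    stat <- stat + sum(r2[!is.na(y[i, ])])
  }
  stat
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates \code{B} datasets from the fitted model on its own covariates,
#' refits the same model to each (starting from the fitted parameters), and
#' recomputes the fit statistic, giving the statistic's null distribution.
#' Reports \code{p} (proportion of bootstrap statistics at or above the
#' observed one) and the overdispersion ratio
#' \eqn{\hat c = observed / mean(bootstrap)}. Replicates whose refit fails
#' are dropped and counted, with a warning if more than 5\% drop. Fully
#' reproducible from \code{seed}.
#'
#' @param fit a converged \code{occu_fit} or \code{nmix_fit}.
#' @param dataset data to score; defaults to the training data.
#' @param B number of bootstrap iterations (the study scale is 10,000;
#'   the default 1000 is a desk scale).
#' @param seed integer seed.
#' @param statistic \code{"auto"} picks the history chi-square for occupancy
#'   fits and the Pearson sum for N-mixture fits.
#' @return An object of class \code{gof_result}: \code{observed},
#'   \code{boot} (the bootstrap sample), \code{p_value}, \code{c_hat},
#'   \code{B}, \code{n_failed}, \code{seed}, \code{statistic}.
#' @export
parametric_bootstrap_gof <- function(fit, dataset = fit$dataset, B = 1000L,
                                     seed = 1L, statistic = c("auto",
                                                              "occupancy_chisq",
                                                              "nmixture_pearson")) {
  stopifnot(inherits(fit, "salocc_fit"), B >= 1)
  statistic <- match.arg(statistic)
  if (statistic == "auto")
    statistic <- if (inherits(fit, "occu_fit")) "occupancy_chisq" else "nmixture_pearson"
  stat_fun <- if (statistic == "occupancy_chisq") occupancy_gof_statistic else
    nmixture_gof_statistic
  refit <- function(d) {
    if (inherits(fit, "occu_fit"))
      fit_occupancy(d, fit$spec, n_starts = 1L, seed = 1L)
    else
      fit_nmixture(d, fit$spec, K_trunc = fit$K_trunc, n_starts = 1L, seed = 1L)
  }
  observed <- stat_fun(fit, dataset)
  set.seed(seed)
  sims <- stats::simulate(fit, nsim = B)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    boot[b] <- tryCatch({
      fb <- suppressWarnings(refit(sims[[b]]))
      stat_fun(fb, sims[[b]])
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(boot))
  if (failed > 0.05 * B)
    warning(failed, " of ", B, " bootstrap refits failed and were dropped")
  boot_ok <- boot[!is.na(boot)]
  structure(list(observed = observed, boot = boot_ok,
                 p_value = mean(boot_ok >= observed),
                 c_hat = observed / mean(boot_ok),
                 B = B, n_failed = failed, seed = seed,
                 statistic = statistic),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Parametric bootstrap goodness-of-fit (", x$statistic, ")\n", sep = "")
  cat(sprintf("  observed statistic %.4f, B = %d (%d failed)\n",
              x$observed, x$B, x$n_failed))
  cat(sprintf("  p = %.4f, c-hat = %.4f\n", x$p_value, x$c_hat))
  invisible(x)
}

#' Serialize a goodness-of-fit result to JSON
#'
#' @param gof a \code{gof_result}.
#' @param path optional file path.
#' @param include_sample include the full bootstrap sample.
#' @return The JSON string (invisibly when written).
#' @export
gof_to_json <- function(gof, path = NULL, include_sample = FALSE) {
  obj <- list(statistic = gof$statistic, observed = gof$observed,
              p_value = gof$p_value, c_hat = gof$c_hat, B = gof$B,
              n_failed = gof$n_failed, seed = gof$seed)
  if (include_sample) obj$boot <- gof$boot
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
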