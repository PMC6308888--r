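#' Negative log-likelihood of the N-mixture abundance model
#'
#' Repeated-count likelihood with latent site abundance
#' \eqn{N_i \sim Poisson(\lambda_i)}, \eqn{\lambda_i = \exp(x_i' \beta_\lambda)},
#' and counts \eqn{y_{ij} \sim Binomial(N_i, p_{ij})},
#' \eqn{p_{ij} = logit^{-1}(w_{ij}' \beta_p)}. The latent sum is truncated at
#' \code{K_trunc}:
#' \deqn{-\sum_i \log \sum_{N=0}^{K} Pois(N; \lambda_i)
#'       \prod_j Bin(y_{ij}; N, p_{ij}).}
#' Missing visits are dropped from the product.
#'
#' @param params coefficient vector: abundance coefficients then detection
#'   coefficients.
#' @param dataset a count-mode [survey_data] object.
#' @param spec a [model_spec] with \code{family = "nmixture"}.
#' @param K_trunc upper bound on latent abundance; must be at least the
#'   maximum observed count.
#' @return The negative log-likelihood.
#' @export
nmix_negloglik <- function(params, dataset, spec, K_trunc) {
  stopifnot(inherits(dataset, "survey_data"))
  if (dataset$mode != "count") stop("N-mixture models need count-mode data")
  X <- state_design(dataset, spec$formulas$state)
  W <- detection_design(dataset, spec$formulas$detection)
  nmix_negloglik_ll(params, dataset$y, X, W, K_trunc)
}

nmix_negloglik_ll <- function(params, y, X, W, K_trunc) {
  n <- nrow(y); J <- ncol(y)
  maxy <- suppressWarnings(max(y, na.rm = TRUE))
  if (is.finite(maxy) && K_trunc < maxy)
    stop("K_trunc (", K_trunc, ") below the maximum observed count (", maxy, ")")
  if (any(y[!is.na(y)] < 0)) stop("negative counts")
  pX <- ncol(X); pW <- ncol(W)
  if (length(params) != pX + pW)
    stop("expected ", pX + pW, " parameters, got ", length(params))
  lambda <- exp(drop(X %*% params[seq_len(pX)]))
  p <- matrix(.plogis(drop(W %*% params[pX + seq_len(pW)])), n, J)
  # site x (K+1) matrix of log Poisson(N; lambda_i) + log P(y_i. | N)
  Ns <- 0:K_trunc
  lmat <- matrix(NA_real_, n, K_trunc + 1L)
  for (k in seq_along(Ns)) {
    N <- Ns[k]
    lb <- stats::dbinom(y, N, p, log = TRUE)
    lb[is.na(y)] <- 0
    lmat[, k] <- stats::dpois(N, lambda, log = TRUE) + rowSums(lb)
  }
  m <- apply(lmat, 1, max)
  ll <- m + log(rowSums(exp(lmat - m)))
  -sum(ll)
}

#' Fit an N-mixture abundance model by maximum likelihood
#'
#' Minimizes [nmix_negloglik] by multi-start BFGS. After fitting, the
#' likelihood is re-evaluated with the truncation bound doubled; the fit
#' records whether the log-likelihood moved by less than \code{1e-6}
#' (\code{K_trunc_stable}), the check that the finite sum has converged.
#'
#' @inheritParams fit_occupancy
#' @param dataset a count-mode [survey_data] object.
#' @param K_trunc upper bound on latent abundance; default
#'   \code{max(y) + 100}.
#' @return An object of classes \code{nmix_fit}, \code{salocc_fit}; estimate
#'   names carry prefixes \code{lambda_} (log link) and \code{p_} (logit
#'   link). Extra fields: \code{K_trunc}, \code{K_trunc_stable}.
#' @export
fit_nmixture <- function(dataset, spec = model_spec(~1, ~1, "nmixture"),
                         K_trunc = NULL, n_starts = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "survey_data"))
  if (dataset$mode != "count") stop("N-mixture models need count-mode data")
  if (spec$family != "nmixture") stop("spec family must be 'nmixture'")
  y <- dataset$y
  maxy <- max(0, y[!is.na(y)])
  if (is.null(K_trunc)) K_trunc <- maxy + 100L
  X <- state_design(dataset, spec$formulas$state)
  W <- detection_design(dataset, spec$formulas$detection)
  nll <- function(par) nmix_negloglik_ll(par, y, X, W, K_trunc)
  opt <- multistart_optim(nll, ncol(X) + ncol(W), n_starts = n_starts,
                          seed = seed)
  nll2 <- nmix_negloglik_ll(opt$par, y, X, W, 2L * K_trunc)
  stable <- abs(nll2 - opt$value) < 1e-6
  if (!stable)
    warning("log-likelihood changed by ", signif(abs(nll2 - opt$value), 3),
            " when K_trunc doubled; increase K_trunc")
  nms <- c(paste0("lambda_", colnames(X)), paste0("p_", colnames(W)))
  est <- stats::setNames(opt$par, nms)
  vcov <- opt$vcov
  if (!is.null(vcov)) dimnames(vcov) <- list(nms, nms)
  new_salocc_fit("nmix_fit", spec, est, vcov, -opt$value, nrow(y),
                 opt$converged, opt$boundary, opt$grad_norm,
                 extra = list(dataset = dataset, K_trunc = K_trunc,
                              K_trunc_stable = stable,
                              n_state = ncol(X), n_det = ncol(W)))
}

#' @rdname predict.occu_fit
#' @export
predict.nmix_fit <- function(object, grid = NULL, record = NULL,
                             type = c("state", "detection"), level = 0.95,
                             ...) {
  type <- match.arg(type)
  link <- if (type == "state") "log" else "logit"
  predict_link(object, grid, record, type, link, level)
}

# Fitted lambda_i and p_ij on the training data.
fitted_rates <- function(fit) {
  cf <- split_coefs(fit)
  X <- state_design(fit$dataset, fit$spec$formulas$state)
  W <- detection_design(fit$dataset, fit$spec$formulas$detection)
  n <- nrow(fit$dataset$y); J <- ncol(fit$dataset$y)
  list(lambda = exp(drop(X %*% cf$state)),
       p = matrix(.plogis(drop(W %*% cf$det)), n, J))
}

#' Simulate count matrices from a fitted N-mixture model
#'
#' Draws \eqn{N_i \sim Poisson(\hat\lambda_i)} then
#' \eqn{y_{ij} \sim Binomial(N_i, \hat p_{ij})} on the training covariates,
#' preserving the original missingness pattern.
#'
#' @param object a fitted \code{nmix_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of [survey_data] objects.
#' @export
simulate.nmix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- fitted_rates(object)
  y0 <- object$dataset$y
  n <- nrow(y0); J <- ncol(y0)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    N <- stats::rpois(n, pr$lambda)
    y <- matrix(stats::rbinom(n * J, rep(N, J), pr$p), n, J)
    y[is.na(y0)] <- NA
    d <- object$dataset
    d$y <- y
    dimnames(d$y) <- dimnames(y0)
    out[[s]] <- d
  }
  out
}

# Marginal mean and variance of y_ij by finite mixture over N <= K_trunc
# (used by the Pearson GoF statistic; for Poisson N these equal lambda*p
# analytically, which the tests exploit as an oracle).
nmix_moments <- function(lambda, p, K_trunc) {
  Ns <- 0:K_trunc
  w <- stats::dpois(Ns, lambda)
  w <- w / sum(w)
  mN <- outer(Ns, p)                   # E[y | N] = N p
  vN <- outer(Ns, p * (1 - p))         # Var[y | N]
  mu <- colSums(w * mN)
  v <- colSums(w * (vN + mN^2)) - mu^2
  list(mean = mu, var = v)
}

#' @export
residuals.nmix_fit <- function(object, ...) {
  pr <- fitted_rates(object)
  n <- nrow(object$dataset$y); J <- ncol(object$dataset$y)
  mu <- matrix(NA_real_, n, J); v <- matrix(NA_real_, n, J)
  for (i in seq_len(n)) {
    mm <- nmix_moments(pr$lambda[i], pr$p[i, ], object$K_trunc)
    mu[i, ] <- mm$mean; v[i, ] <- mm$var
  }
  (object$dataset$y - mu) / sqrt(v)
}

#' Occupancy probability implied by a Poisson abundance rate
#'
#' Under the N-mixture model a site is occupied iff its latent abundance is
#' positive, so \eqn{\psi = 1 - e^{-\lambda}}. Links the two state models
#' for cross-checks.
#'
#' @param lambda_hat nonnegative expected abundance per site.
#' @return Probability in \eqn{[0, 1)}.
#' @export
implied_occupancy <- function(lambda_hat) {
  if (any(lambda_hat < 0)) stop("lambda must be nonnegative")
  1 - exp(-lambda_hat)
}

#' Extrapolate a per-transect abundance rate to a study area
#'
#' Converts a per-sampling-unit expected abundance into an expected total
#' over a larger area: \code{(lambda / transect_area) * total_area_ha *
#' 10000}.
#'
#' @param lambda_per_transect expected abundance per sampling unit.
#' @param transect_area sampling-unit area in square metres (the study's
#'   transects are 96 m2).
#' @param total_area_ha total area in hectares.
#' @return Expected total abundance over \code{total_area_ha}.
#' @export
#' @examples
#' extrapolate_density(0.06 * 96, 96, 44.25) # density 0.06 / m2 over 44.25 ha
extrapolate_density <- function(lambda_per_transect, transect_area = 96,
                                total_area_ha) {
  if (transect_area <= 0) stop("transect_area must be positive")
  if (any(total_area_ha < 0)) stop("total_area_ha must be nonnegative")
  (lambda_per_transect / transect_area) * total_area_ha * 1e4
}
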