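#' Negative log-likelihood of the single-season occupancy model
#'
#' Zero-inflated binomial likelihood for detection/non-detection histories
#' under imperfect detection. Site i is occupied with probability
#' \eqn{\psi_i = logit^{-1}(x_i' \beta_\psi)} and, if occupied, detected on
#' visit j with probability \eqn{p_{ij} = logit^{-1}(w_{ij}' \beta_p)}. The
#' site likelihood is
#' \deqn{\psi_i \prod_j p_{ij}^{y_{ij}} (1-p_{ij})^{1-y_{ij}}
#'       + (1-\psi_i) I(\sum_j y_{ij} = 0),}
#' with missing visits dropped from the product.
#'
#' @param params coefficient vector: state coefficients first (in the order
#'   of \code{model.matrix(state_formula)}), then detection coefficients.
#' @param dataset a binary-mode [survey_data] object with covariates already
#'   standardized if the spec's formulas expect that.
#' @param spec a [model_spec] with \code{family = "occupancy"}.
#' @return The negative log-likelihood (nonnegative up to round-off).
#' @export
occu_negloglik <- function(params, dataset, spec) {
  stopifnot(inherits(dataset, "survey_data"))
  if (dataset$mode != "binary") stop("occupancy models need binary-mode data")
  X <- state_design(dataset, spec$formulas$state)
  W <- detection_design(dataset, spec$formulas$detection)
  occu_negloglik_ll(params, dataset$y, X, W)
}

# Core evaluation against prebuilt design matrices (used by the fitter so
# matrices are built once, not per optimizer step).
occu_negloglik_ll <- function(params, y, X, W) {
  n <- nrow(y); J <- ncol(y)
  pX <- ncol(X); pW <- ncol(W)
  if (length(params) != pX + pW)
    stop("expected ", pX + pW, " parameters, got ", length(params))
  beta_psi <- params[seq_len(pX)]
  beta_p <- params[pX + seq_len(pW)]
  psi <- .plogis(drop(X %*% beta_psi))
  eta <- matrix(drop(W %*% beta_p), n, J)
  # log Bernoulli terms, stable at extreme eta:
  # y=1 -> log plogis(eta) = -log1p(exp(-eta)); y=0 -> -log1p(exp(eta))
  lterm <- ifelse(y == 1, .plogis(eta, log.p = TRUE),
                  .plogis(-eta, log.p = TRUE))
  lterm[is.na(y)] <- 0
  lp_det <- rowSums(lterm)                      # log P(history | occupied)
  all_zero <- rowSums(y == 1, na.rm = TRUE) == 0
  lik <- psi * exp(lp_det) + (1 - psi) * as.numeric(all_zero)
  -sum(log(pmax(lik, .Machine$double.xmin)))
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Minimizes [occu_negloglik] by multi-start BFGS; the covariance matrix
#' comes from the inverse numerical Hessian at the optimum. Estimates with
#' absolute value above 10 on the logit scale are flagged as boundary
#' estimates (near 0/1 probabilities).
#'
#' @param dataset a binary-mode [survey_data] object.
#' @param spec a [model_spec]; default intercept-only on both levels.
#' @param n_starts number of optimizer starts (first at 0, the rest
#'   jittered).
#' @param seed integer seed for the start jitter.
#' @return An object of classes \code{occu_fit}, \code{salocc_fit} with
#'   named \code{estimates} (prefixes \code{psi_} and \code{p_}),
#'   \code{vcov}, \code{loglik}, \code{aic}, \code{aicc}, \code{converged},
#'   \code{boundary} and the dataset/design bookkeeping used by
#'   \code{predict} and \code{simulate} methods.
#' @export
#' @examples
#' set.seed(1)
#' covs <- simulate_covariates(60, 4, seed = 1)
#' sim <- simulate_occupancy_data(
#'   state_coefs = c(`(Intercept)` = 0.5), detection_coefs = c(`(Intercept)` = -0.5),
#'   covariates = covs, seed = 2)
#' fit <- fit_occupancy(sim$dataset, model_spec(~1, ~1, "occupancy"), seed = 3)
#' coef(fit)
fit_occupancy <- function(dataset, spec = model_spec(~1, ~1, "occupancy"),
                          n_starts = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "survey_data"))
  if (dataset$mode != "binary") stop("occupancy models need binary-mode data")
  if (ncol(dataset$y) < 2) stop("need at least two visits")
  if (spec$family != "occupancy") stop("spec family must be 'occupancy'")
  X <- state_design(dataset, spec$formulas$state)
  W <- detection_design(dataset, spec$formulas$detection)
  y <- dataset$y
  nll <- function(par) occu_negloglik_ll(par, y, X, W)
  opt <- multistart_optim(nll, ncol(X) + ncol(W), n_starts = n_starts,
                          seed = seed)
  nms <- c(paste0("psi_", colnames(X)), paste0("p_", colnames(W)))
  est <- stats::setNames(opt$par, nms)
  vcov <- opt$vcov
  if (!is.null(vcov)) dimnames(vcov) <- list(nms, nms)
  new_salocc_fit("occu_fit", spec, est, vcov, -opt$value, nrow(y),
                 opt$converged, opt$boundary, opt$grad_norm,
                 extra = list(dataset = dataset,
                              n_state = ncol(X), n_det = ncol(W)))
}

# Split a fit's coefficient vector into state and detection parts.
split_coefs <- function(fit) {
  list(state = fit$estimates[seq_len(fit$n_state)],
       det = fit$estimates[fit$n_state + seq_len(fit$n_det)])
}

#' Predict occupancy (or abundance) over a covariate grid
#'
#' Builds the linear predictor on the link scale, attaches pointwise
#' Wald 95\% intervals via the delta method (\eqn{x' V x}), and
#' back-transforms. Grid values are given on the raw scale when a
#' standardization record is supplied; covariates in the formula but absent
#' from the grid sit at their standardized mean, 0.
#'
#' @param object a fitted \code{occu_fit} or \code{nmix_fit}.
#' @param grid data frame of covariate values.
#' @param record optional \code{standardization_record}; when supplied the
#'   grid is z-scored with the training means/sds first.
#' @param type \code{"state"} (occupancy probability \eqn{\psi} or expected
#'   abundance \eqn{\lambda}) or \code{"detection"} (per-visit detection
#'   probability).
#' @param level confidence level for the pointwise interval.
#' @param ... unused.
#' @return A \code{prediction_grid} data frame: the grid columns plus
#'   \code{estimate}, \code{se_link}, \code{lower}, \code{upper}.
#' @export
predict.occu_fit <- function(object, grid = NULL, record = NULL,
                             type = c("state", "detection"), level = 0.95,
                             ...) {
  type <- match.arg(type)
  link <- if (type == "state") "logit" else "logit"
  predict_link(object, grid, record, type, link, level)
}

predict_link <- function(fit, grid, record, type, link, level = 0.95) {
  formula <- if (type == "state") fit$spec$formulas$state else fit$spec$formulas$detection
  cf <- split_coefs(fit)
  beta <- if (type == "state") cf$state else cf$det
  idx <- if (type == "state") seq_len(fit$n_state) else fit$n_state + seq_len(fit$n_det)
  vars <- all.vars(formula)
  if (is.null(grid)) grid <- data.frame(row.names = 1)
  extraneous <- setdiff(names(grid), vars)
  if (length(extraneous))
    stop("grid names covariate(s) absent from the formula: ",
         paste(extraneous, collapse = ", "))
  grid_std <- apply_standardization(grid, record)
  for (v in setdiff(vars, names(grid_std))) grid_std[[v]] <- 0
  X <- stats::model.matrix(formula, grid_std)
  eta <- drop(X %*% beta)
  se <- rep(NA_real_, length(eta))
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[idx, idx, drop = FALSE]
    se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  inv <- if (link == "logit") .plogis else exp
  out <- cbind(grid, data.frame(
    estimate = inv(eta),
    se_link = se,
    lower = inv(eta - z * se),
    upper = inv(eta + z * se)))
  class(out) <- c("prediction_grid", "data.frame")
  attr(out, "link") <- link
  attr(out, "eta") <- eta
  out
}

#' @rdname predict.occu_fit
#' @param fit a fitted \code{occu_fit}.
#' @export
predict_occupancy <- function(fit, grid = NULL, record = NULL,
                              type = c("state", "detection"), level = 0.95) {
  stopifnot(inherits(fit, "occu_fit"))
  predict(fit, grid = grid, record = record, type = match.arg(type),
          level = level)
}

# Fitted psi_i and p_ij on the training data.
fitted_probs <- function(fit) {
  cf <- split_coefs(fit)
  X <- state_design(fit$dataset, fit$spec$formulas$state)
  W <- detection_design(fit$dataset, fit$spec$formulas$detection)
  n <- nrow(fit$dataset$y); J <- ncol(fit$dataset$y)
  list(psi = .plogis(drop(X %*% cf$state)),
       p = matrix(.plogis(drop(W %*% cf$det)), n, J))
}

#' Simulate detection histories from a fitted occupancy model
#'
#' Draws latent occupancy states and visit-level detections from the fitted
#' \eqn{\hat\psi_i}, \eqn{\hat p_{ij}} on the training covariates; the
#' missingness pattern of the original data is preserved.
#'
#' @param object a fitted \code{occu_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of [survey_data] objects of length \code{nsim}.
#' @export
simulate.occu_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- fitted_probs(object)
  y0 <- object$dataset$y
  n <- nrow(y0); J <- ncol(y0)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    z <- stats::rbinom(n, 1, pr$psi)
    y <- matrix(stats::rbinom(n * J, 1, rep(z, J) * pr$p), n, J)
    y[is.na(y0)] <- NA
    d <- object$dataset
    d$y <- y
    dimnames(d$y) <- dimnames(y0)
    out[[s]] <- d
  }
  out
}

#' @export
residuals.occu_fit <- function(object, ...) {
  pr <- fitted_probs(object)
  mu <- pr$psi * pr$p            # marginal P(y_ij = 1)
  (object$dataset$y - mu) / sqrt(mu * (1 - mu))
}
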