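.plogis <- stats::plogis
.qlogis <- stats::qlogis

# Design matrix for a state formula over site covariates: n_sites x p.
state_design <- function(dataset, formula) {
  df <- dataset$site_covs
  if (is.null(df)) df <- data.frame(row.names = dataset$site_ids)
  check_formula_covs(formula, c(names(df)))
  X <- stats::model.matrix(formula, stats::model.frame(formula, df,
                                                       na.action = stats::na.pass))
  if (anyNA(X)) stop("NaN/NA in state design matrix")
  X
}

# Design matrix for a detection formula over site and/or visit covariates:
# (n_sites * n_visits) x q, visits stacked column-major (site fastest), so
# row (j - 1) * n + i is site i, visit j.
detection_design <- function(dataset, formula) {
  n <- nrow(dataset$y); J <- ncol(dataset$y)
  site_df <- dataset$site_covs
  if (is.null(site_df)) site_df <- data.frame(row.names = dataset$site_ids)
  check_formula_covs(formula, c(names(site_df), names(dataset$visit_covs)))
  long <- site_df[rep(seq_len(n), times = J), , drop = FALSE]
  for (nm in names(dataset$visit_covs))
    long[[nm]] <- as.vector(dataset$visit_covs[[nm]])
  rownames(long) <- NULL
  W <- stats::model.matrix(formula, stats::model.frame(formula, long,
                                                       na.action = stats::na.pass))
  if (anyNA(W)) stop("NaN/NA in detection design matrix")
  W
}

check_formula_covs <- function(formula, available) {
  vars <- all.vars(formula)
  missing <- setdiff(vars, available)
  if (length(missing))
    stop("formula references covariate(s) not in the dataset: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# Central-difference gradient.
num_gradient <- function(f, x, step = 1e-6) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    h <- step * max(1, abs(x[k]))
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Central-difference Hessian on the link scale.
num_hessian <- function(f, x, step = 1e-5) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  h <- step * pmax(1, abs(x))
  for (i in seq_len(p)) {
    for (j in i:p) {
      xpp <- x; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm <- x; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp <- x; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm <- x; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

# Multi-start quasi-Newton minimization. Starts at zero plus Normal(0, 0.5)
# jitter for the remaining starts; returns the best optimum found with a
# convergence flag based on the gradient norm at the optimum.
multistart_optim <- function(negloglik, n_params, n_starts = 5L, seed = NULL,
                             start = NULL, grad_tol = 1e-4) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  starts <- vector("list", n_starts)
  starts[[1]] <- if (is.null(start)) rep(0, n_params) else start
  if (n_starts > 1L)
    for (s in 2:n_starts)
      starts[[s]] <- starts[[1]] + stats::rnorm(n_params, 0, 0.5)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negloglik, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  g <- tryCatch(num_gradient(negloglik, best$par), error = function(e) rep(NA_real_, n_params))
  gnorm <- sqrt(sum(g^2))
  boundary <- any(abs(best$par) > 10)
  converged <- isTRUE(best$convergence == 0) &&
    is.finite(gnorm) && (gnorm <= grad_tol || boundary)
  H <- tryCatch(num_hessian(negloglik, best$par), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(H) && all(is.finite(H))) {
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov) && any(!is.finite(vcov))) vcov <- NULL
  }
  list(par = best$par, value = best$value, converged = converged,
       boundary = boundary, grad_norm = gnorm, vcov = vcov)
}

aic_of <- function(loglik, K) -2 * loglik + 2 * K
aicc_of <- function(loglik, K, n) {
  aic <- aic_of(loglik, K)
  if (n - K - 1 <= 0) return(Inf)
  aic + 2 * K * (K + 1) / (n - K - 1)
}

new_salocc_fit <- function(subclass, spec, estimates, vcov, loglik, n_sites,
                           converged, boundary, grad_norm, extra = list()) {
  K <- length(estimates)
  obj <- c(list(
    spec = spec,
    estimates = estimates,
    vcov = vcov,
    loglik = loglik,
    K = K,
    n_sites = n_sites,
    aic = aic_of(loglik, K),
    aicc = aicc_of(loglik, K, n_sites),
    converged = converged,
    boundary = boundary,
    grad_norm = grad_norm
  ), extra)
  structure(obj, class = c(subclass, "salocc_fit"))
}

#' @export
coef.salocc_fit <- function(object, ...) object$estimates

#' @export
vcov.salocc_fit <- function(object, ...) object$vcov

#' @export
logLik.salocc_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n_sites,
            class = "logLik")
}

#' @export
print.salocc_fit <- function(x, ...) {
  cat(fit_label(x), "\n", sep = "")
  cat("  formula(s): ", format_spec(x$spec), "\n", sep = "")
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, x$K)
  tab <- data.frame(Estimate = x$estimates, `Std. Error` = se,
                    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("  logLik %.4f  K %d  AIC %.3f  AICc %.3f  %s\n",
              x$loglik, x$K, x$aic, x$aicc,
              if (x$converged) "converged" else "NOT converged"))
  if (x$boundary) cat("  note: boundary estimate(s), |coef| > 10 on link scale\n")
  invisible(x)
}

#' @export
summary.salocc_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$vcov)) {
    se <- sqrt(pmax(diag(object$vcov), 0))
    z <- object$estimates / se
    cat("\n  Wald z and 95% CI (link scale):\n")
    tab <- data.frame(z = z,
                      lower = object$estimates - 1.96 * se,
                      upper = object$estimates + 1.96 * se)
    rownames(tab) <- names(object$estimates)
    print(round(tab, 4))
  }
  invisible(object)
}

fit_label <- function(x) {
  if (inherits(x, "occu_fit")) "Single-season occupancy model (zero-inflated binomial)"
  else if (inherits(x, "nmix_fit")) "N-mixture abundance model (Poisson latent abundance)"
  else if (inherits(x, "twosp_fit")) "Two-species co-occurrence occupancy model (psi_Ba parameterization)"
  else "Hierarchical detection model"
}

format_spec <- function(spec) {
  paste(vapply(names(spec$formulas), function(nm)
    paste0(nm, ": ", deparse(spec$formulas[[nm]])), character(1)),
    collapse = "; ")
}

#' Define a hierarchical detection model
#'
#' Couples a state formula (occupancy or abundance, over site covariates)
#' with a detection formula (over site and/or visit covariates). Intercepts
#' are always included.
#'
#' @param state_formula right-hand-side formula for the state process,
#'   e.g. \code{~ MST + VEG}.
#' @param detection_formula right-hand-side formula for detection,
#'   e.g. \code{~ CWD}.
#' @param family one of \code{"occupancy"}, \code{"nmixture"}.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(state_formula = ~1, detection_formula = ~1,
                       family = c("occupancy", "nmixture")) {
  family <- match.arg(family)
  structure(list(formulas = list(state = state_formula,
                                 detection = detection_formula),
                 family = family),
            class = "model_spec")
}

#' Serialize a fitted model to JSON
#'
#' @param fit a fitted model object.
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to \code{path}.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "salocc_fit"))
  obj <- list(
    class = class(fit)[1],
    formulas = lapply(fit$spec$formulas, deparse),
    estimates = as.list(fit$estimates),
    vcov = fit$vcov,
    loglik = fit$loglik,
    K = fit$K,
    n_sites = fit$n_sites,
    aic = fit$aic,
    aicc = fit$aicc,
    converged = fit$converged,
    boundary = fit$boundary
  )
  if (!is.null(fit$K_trunc)) {
    obj$K_trunc <- fit$K_trunc
    obj$K_trunc_stable <- fit$K_trunc_stable
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
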