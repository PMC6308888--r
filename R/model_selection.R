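#' Akaike weights from information-criterion values
#'
#' \eqn{w_i = \exp(-\Delta_i / 2) / \sum_k \exp(-\Delta_k / 2)} with
#' \eqn{\Delta_i} the difference from the smallest value; subtracting the
#' minimum first keeps the exponentials finite for arbitrarily large spreads.
#'
#' @param criterion_values numeric vector of AIC or AICc values, all finite.
#' @return A probability vector summing to 1.
#' @export
#' @examples
#' akaike_weights(c(100, 102)) # 0.731, 0.269
akaike_weights <- function(criterion_values) {
  if (!length(criterion_values)) stop("no criterion values")
  if (any(!is.finite(criterion_values)))
    stop("criterion values must be finite")
  d <- criterion_values - min(criterion_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Assemble fitted models into a ranked candidate set
#'
#' All fits must share the same data (same number of sites) and model
#' family. Weights are Akaike weights under the chosen criterion.
#'
#' @param fits list of \code{salocc_fit} objects (optionally named; unnamed
#'   models are labelled by their formulas).
#' @param criterion \code{"AICc"} (default, small-sample corrected) or
#'   \code{"AIC"}.
#' @return An object of class \code{model_set}.
#' @export
model_set <- function(fits, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("empty model set")
  if (!all(vapply(fits, inherits, logical(1), "salocc_fit")))
    stop("all elements must be fitted models")
  fam <- vapply(fits, function(f) class(f)[1], character(1))
  if (length(unique(fam)) != 1) stop("mixed model families in one set")
  ns <- vapply(fits, function(f) f$n_sites, numeric(1))
  if (length(unique(ns)) != 1) stop("models fitted to different data")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) format_spec(f$spec), character(1))
  crit <- vapply(fits, function(f)
    if (criterion == "AICc") f$aicc else f$aic, numeric(1))
  structure(list(fits = fits, criterion = criterion, criterion_values = crit,
                 weights = akaike_weights(crit)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("Model set (", length(x$fits), " models, ranked by ", x$criterion,
      ")\n", sep = "")
  print(rank_table(x), row.names = FALSE)
  invisible(x)
}

#' Ranking table for a model set
#'
#' @param set a [model_set].
#' @return Data frame sorted by the criterion: model label, K, criterion
#'   value, delta, weight, cumulative weight, convergence flag. Ties keep
#'   insertion order.
#' @export
rank_table <- function(set) {
  stopifnot(inherits(set, "model_set"))
  ord <- order(set$criterion_values)   # stable in R
  K <- vapply(set$fits, function(f) f$K, numeric(1))
  conv <- vapply(set$fits, function(f) f$converged, logical(1))
  data.frame(model = names(set$fits)[ord],
             K = K[ord],
             criterion = set$criterion_values[ord],
             delta = set$criterion_values[ord] - min(set$criterion_values),
             weight = set$weights[ord],
             cum_weight = cumsum(set$weights[ord]),
             converged = conv[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative Akaike weight of a model subset
#'
#' Sums the weights of the models satisfying a predicate — e.g. the evidence
#' for covariate (environmental) models against intercept-only (null)
#' models. Subset and complement weights add to 1.
#'
#' @param set a [model_set].
#' @param predicate function taking a fit and returning \code{TRUE}/\code{FALSE},
#'   or a logical/character/integer index into the set.
#' @return A probability.
#' @export
cumulative_weight <- function(set, predicate) {
  stopifnot(inherits(set, "model_set"))
  sel <- if (is.function(predicate))
    vapply(set$fits, predicate, logical(1))
  else if (is.character(predicate)) names(set$fits) %in% predicate
  else predicate
  sum(set$weights[sel])
}

# Pull a named coefficient and its conditional variance out of a fit,
# matching on the suffix after the component prefix (psi_/p_/lambda_).
find_coef <- function(fit, covariate) {
  nms <- names(fit$estimates)
  hit <- which(endsWith(nms, paste0("_", covariate)) | nms == covariate)
  if (!length(hit)) return(NULL)
  if (length(hit) > 1)
    stop("covariate '", covariate, "' matches several coefficients in one ",
         "model (", paste(nms[hit], collapse = ", "), "); pass the full name")
  v <- if (!is.null(fit$vcov)) fit$vcov[hit, hit] else NA_real_
  list(beta = unname(fit$estimates[hit]), var = v, name = nms[hit])
}

#' Model-averaged effect size with unconditional uncertainty
#'
#' Computes \eqn{\bar\beta = \sum_i \tilde w_i \beta_i} and the
#' unconditional standard error
#' \eqn{\sqrt{\sum_i \tilde w_i (var_i + (\beta_i - \bar\beta)^2)}}
#' (the revised multi-model estimator), with weights renormalized over the
#' models that contain the covariate (\code{scope = "containing_models"}) or
#' taken over all models with \eqn{\beta_i = 0, var_i = 0} where the
#' covariate is absent (\code{scope = "all_models_shrinkage"}). 50\% and
#' 95\% unconditional intervals use z = 0.674 and 1.96; the covariate is
#' flagged important when the 95\% interval excludes 0.
#'
#' @param set a [model_set].
#' @param covariate coefficient name; matched against full names
#'   (\code{"p_CWD"}) or bare covariate suffixes (\code{"CWD"}).
#' @param scope averaging scope (see above).
#' @return An object of class \code{averaged_effect}: covariate, beta_bar,
#'   unconditional SE, the two CIs, important flag, scope, the per-model
#'   table.
#' @export
model_average_beta <- function(set, covariate,
                               scope = c("containing_models",
                                         "all_models_shrinkage")) {
  stopifnot(inherits(set, "model_set"))
  scope <- match.arg(scope)
  rows <- lapply(set$fits, find_coef, covariate = covariate)
  has <- !vapply(rows, is.null, logical(1))
  if (!any(has)) stop("covariate '", covariate, "' appears in no model")
  if (scope == "containing_models") {
    w <- set$weights[has] / sum(set$weights[has])
    beta <- vapply(rows[has], `[[`, numeric(1), "beta")
    v <- vapply(rows[has], `[[`, numeric(1), "var")
  } else {
    w <- set$weights
    beta <- ifelse(has, vapply(rows, function(r) if (is.null(r)) 0 else r$beta,
                               numeric(1)), 0)
    v <- ifelse(has, vapply(rows, function(r) if (is.null(r)) 0 else r$var,
                            numeric(1)), 0)
  }
  beta_bar <- sum(w * beta)
  se <- sqrt(sum(w * (v + (beta - beta_bar)^2)))
  ci50 <- beta_bar + c(-1, 1) * 0.674 * se
  ci95 <- beta_bar + c(-1, 1) * 1.96 * se
  structure(list(covariate = covariate, beta_bar = beta_bar, se = se,
                 ci50 = ci50, ci95 = ci95,
                 important = ci95[1] > 0 || ci95[2] < 0,
                 scope = scope,
                 models = data.frame(model = names(set$fits)[if (scope == "containing_models") has else TRUE],
                                     weight = w, beta = beta, var = v,
                                     row.names = NULL)),
            class = "averaged_effect")
}

#' @export
print.averaged_effect <- function(x, ...) {
  cat(sprintf("%s: beta_bar = %.4f, unconditional SE = %.4f%s\n",
              x$covariate, x$beta_bar, x$se, if (x$important) " *" else ""))
  cat(sprintf("  50%% CI [%.4f, %.4f]  95%% CI [%.4f, %.4f]  (scope: %s)\n",
              x$ci50[1], x$ci50[2], x$ci95[1], x$ci95[2], x$scope))
  invisible(x)
}

#' Model-averaged predictions over a covariate grid
#'
#' Averages per-model predictions pointwise with Akaike weights on the link
#' scale (default), combining within- and between-model variance into an
#' unconditional SE as in [model_average_beta], then back-transforms; the
#' averaged curve always lies inside the per-model envelope on the link
#' scale. Covariates a model's formula lacks enter at their standardized
#' mean, 0.
#'
#' @param set a [model_set].
#' @param grid data frame of covariate values.
#' @param record optional \code{standardization_record} (raw-scale grids).
#' @param type \code{"state"} or \code{"detection"}.
#' @param response_scale_average also average on the response scale
#'   (labelled \code{estimate_response_avg}), for comparison.
#' @return A \code{prediction_grid} data frame with \code{estimate},
#'   \code{se_link}, \code{lower}, \code{upper} (95\%, unconditional).
#' @export
model_average_predictions <- function(set, grid = NULL, record = NULL,
                                      type = c("state", "detection"),
                                      response_scale_average = FALSE) {
  stopifnot(inherits(set, "model_set"))
  type <- match.arg(type)
  preds <- lapply(set$fits, function(f) {
    vars <- all.vars(if (type == "state") f$spec$formulas$state else
      f$spec$formulas$detection)
    g <- grid
    if (!is.null(g)) g <- g[intersect(names(g), vars)]
    if (!is.null(g) && !ncol(g)) g <- NULL
    stats::predict(f, grid = g, record = record, type = type)
  })
  R <- if (is.null(grid)) 1L else nrow(grid)
  # models whose formula ignores every grid covariate predict one constant
  # row; replicate it across the grid
  preds <- lapply(preds, function(p) {
    if (nrow(p) == R) return(p)
    q <- p[rep(1L, R), , drop = FALSE]
    attr(q, "eta") <- rep(attr(p, "eta"), R)
    attr(q, "link") <- attr(p, "link")
    q
  })
  eta <- vapply(preds, function(p) attr(p, "eta"), numeric(R))
  se <- vapply(preds, function(p) p$se_link, numeric(R))
  eta <- matrix(eta, ncol = length(preds))
  se <- matrix(se, ncol = length(preds))
  w <- set$weights
  eta_bar <- drop(eta %*% w)
  se_unc <- sqrt(drop((se^2 + (eta - eta_bar)^2) %*% w))
  link <- attr(preds[[1]], "link")
  inv <- if (link == "logit") .plogis else exp
  out <- data.frame(estimate = inv(eta_bar), se_link = se_unc,
                    lower = inv(eta_bar - 1.96 * se_unc),
                    upper = inv(eta_bar + 1.96 * se_unc))
  if (response_scale_average) {
    resp <- vapply(preds, function(p) p$estimate, numeric(nrow(preds[[1]])))
    out$estimate_response_avg <- drop(matrix(resp, ncol = length(preds)) %*% w)
  }
  if (!is.null(grid)) out <- cbind(grid, out)
  class(out) <- c("prediction_grid", "data.frame")
  attr(out, "link") <- link
  out
}

#' Effect-size plot for model-averaged coefficients
#'
#' Dot-and-bar display: point at \eqn{\bar\beta}, thick bar for the 50\%
#' unconditional interval, thin bar for the 95\% interval, asterisk where
#' the 95\% interval excludes zero.
#'
#' @param x a list of \code{averaged_effect} objects (or a single one).
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return Invisibly, the data frame behind the plot.
#' @export
plot_averaged_effects <- function(x, main = "Model-averaged effect sizes",
                                  ...) {
  if (inherits(x, "averaged_effect")) x <- list(x)
  df <- data.frame(
    covariate = vapply(x, `[[`, character(1), "covariate"),
    beta = vapply(x, `[[`, numeric(1), "beta_bar"),
    lo50 = vapply(x, function(e) e$ci50[1], numeric(1)),
    hi50 = vapply(x, function(e) e$ci50[2], numeric(1)),
    lo95 = vapply(x, function(e) e$ci95[1], numeric(1)),
    hi95 = vapply(x, function(e) e$ci95[2], numeric(1)),
    important = vapply(x, `[[`, logical(1), "important"))
  k <- nrow(df)
  graphics::plot(df$beta, seq_len(k), xlim = range(c(df$lo95, df$hi95, 0)),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                 xlab = expression(bar(beta)), ylab = "", main = main, ...)
  graphics::axis(2, at = seq_len(k),
                 labels = paste0(df$covariate, ifelse(df$important, " *", "")),
                 las = 1)
  graphics::abline(v = 0, lty = 3)
  graphics::segments(df$lo95, seq_len(k), df$hi95, seq_len(k), lwd = 1)
  graphics::segments(df$lo50, seq_len(k), df$hi50, seq_len(k), lwd = 3)
  invisible(df)
}
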