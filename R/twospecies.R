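#' Define a two-species co-occurrence model
#'
#' Conditional (psi_Ba) parameterization: species A occupies a site with
#' probability \eqn{\psi_A}; species B occupies it with probability
#' \eqn{\psi_{BA}} where A is present and \eqn{\psi_{Ba}} where A is absent.
#' Each component (and each detection probability) may be linked to
#' covariates through its own additive logit-scale formula. Occupancy
#' components use site covariates; detection components may also use visit
#' covariates.
#'
#' @param psiA,psiBA,psiBa right-hand-side formulas for the three occupancy
#'   components.
#' @param pA,pB formulas for the detection probabilities of A and B when the
#'   other species' presence is not allowed to matter.
#' @param rA,rBA,rBa formulas for the detection-interaction parameters, used
#'   only when fitting with \code{interaction_detection = TRUE}: rA is
#'   detection of A where both species are present, rBA/rBa detection of B
#'   where both are present and A was/was not detected on that visit.
#' @return An object of class \code{twosp_spec}.
#' @export
twosp_spec <- function(psiA = ~1, psiBA = ~1, psiBa = ~1,
                       pA = ~1, pB = ~1, rA = ~1, rBA = ~1, rBa = ~1) {
  structure(list(formulas = list(psiA = psiA, psiBA = psiBA, psiBa = psiBa,
                                 pA = pA, pB = pB,
                                 rA = rA, rBA = rBA, rBa = rBa),
                 family = "two_species"),
            class = "twosp_spec")
}

twosp_designs <- function(dataset_A, dataset_B, spec, interaction_detection) {
  if (!all(dim(dataset_A$y) == dim(dataset_B$y)) ||
      !identical(dataset_A$site_ids, dataset_B$site_ids))
    stop("species datasets misaligned: same sites and visits required")
  comps <- c("psiA", "psiBA", "psiBa", "pA", "pB")
  if (interaction_detection) comps <- c(comps, "rA", "rBA", "rBa")
  des <- list()
  for (cm in comps) {
    f <- spec$formulas[[cm]]
    des[[cm]] <- if (cm %in% c("psiA", "psiBA", "psiBa"))
      state_design(dataset_A, f) else detection_design(dataset_A, f)
  }
  des
}

twosp_par_index <- function(designs) {
  sizes <- vapply(designs, ncol, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Map(function(s, e) s:e, starts, ends)
}

#' Negative log-likelihood of the two-species occupancy model
#'
#' Mixture over the four latent joint-occupancy states \{both, A only,
#' B only, neither\} with probabilities \eqn{\psi_A \psi_{BA}},
#' \eqn{\psi_A (1-\psi_{BA})}, \eqn{(1-\psi_A) \psi_{Ba}},
#' \eqn{(1-\psi_A)(1-\psi_{Ba})}. Given the latent state, detection
#' histories of the two species are products of Bernoulli terms over
#' non-missing visits; a species that is absent cannot be detected, so any
#' detection of it zeroes that state's weight. With
#' \code{interaction_detection = FALSE} detection uses \eqn{p_A},
#' \eqn{p_B} regardless of the other species; otherwise the
#' \eqn{r} parameters apply where both species are present.
#'
#' @param params coefficient vector, components concatenated in the order
#'   psiA, psiBA, psiBa, pA, pB (then rA, rBA, rBa if interaction is on).
#' @param dataset_A,dataset_B binary-mode [survey_data] objects on the same
#'   sites and visits.
#' @param spec a [twosp_spec].
#' @param interaction_detection logical flag.
#' @return The negative log-likelihood.
#' @export
twosp_negloglik <- function(params, dataset_A, dataset_B, spec = twosp_spec(),
                            interaction_detection = FALSE) {
  stopifnot(inherits(dataset_A, "survey_data"), inherits(dataset_B, "survey_data"))
  if (dataset_A$mode != "binary" || dataset_B$mode != "binary")
    stop("two-species models need binary-mode data")
  des <- twosp_designs(dataset_A, dataset_B, spec, interaction_detection)
  twosp_negloglik_ll(params, dataset_A$y, dataset_B$y, des,
                     interaction_detection)
}

twosp_negloglik_ll <- function(params, yA, yB, designs, interaction_detection) {
  idx <- twosp_par_index(designs)
  npar <- max(unlist(idx))
  if (length(params) != npar)
    stop("expected ", npar, " parameters, got ", length(params))
  n <- nrow(yA); J <- ncol(yA)
  lin <- function(cm) drop(designs[[cm]] %*% params[idx[[cm]]])
  psiA <- .plogis(lin("psiA"))
  psiBA <- .plogis(lin("psiBA"))
  psiBa <- .plogis(lin("psiBa"))
  pA <- matrix(.plogis(lin("pA")), n, J)
  pB <- matrix(.plogis(lin("pB")), n, J)
  if (interaction_detection) {
    rA <- matrix(.plogis(lin("rA")), n, J)
    rBA <- matrix(.plogis(lin("rBA")), n, J)
    rBa <- matrix(.plogis(lin("rBa")), n, J)
  } else {
    rA <- pA; rBA <- pB; rBa <- pB
  }

  lbern <- function(y, p) {
    out <- ifelse(y == 1, log(p), log1p(-p))
    out[is.na(y)] <- 0
    out
  }
  zeroA <- rowSums(yA == 1, na.rm = TRUE) == 0
  zeroB <- rowSums(yB == 1, na.rm = TRUE) == 0

  # state both present: A det with rA; B det with rBA where A detected that
  # visit, rBa where A present-but-undetected
  pB_both <- ifelse(!is.na(yA) & yA == 1, rBA, rBa)
  l_both <- rowSums(lbern(yA, rA)) + rowSums(lbern(yB, pB_both))
  l_Aonly <- rowSums(lbern(yA, pA)) + log(as.numeric(zeroB))
  l_Bonly <- log(as.numeric(zeroA)) + rowSums(lbern(yB, pB))
  l_none <- log(as.numeric(zeroA & zeroB))

  lik <- psiA * psiBA * exp(l_both) +
    psiA * (1 - psiBA) * exp(l_Aonly) +
    (1 - psiA) * psiBa * exp(l_Bonly) +
    (1 - psiA) * (1 - psiBa) * exp(l_none)
  -sum(log(pmax(lik, .Machine$double.xmin)))
}

#' Fit a two-species co-occurrence occupancy model
#'
#' Maximum likelihood with multi-start BFGS on [twosp_negloglik]. The fit
#' carries derived quantities evaluated at the covariate means (all
#' standardized covariates at 0): the marginal occupancy of B,
#' \eqn{\psi_B = \psi_A \psi_{BA} + (1-\psi_A)\psi_{Ba}}, the co-occurrence
#' probability \eqn{\psi_{AB} = \psi_A \psi_{BA}}, and the Species
#' Interaction Factor \eqn{\phi = \psi_{AB} / (\psi_A \psi_B)} with a
#' delta-method interval computed on the log scale and exponentiated (so it
#' stays positive). Species A should be the more ubiquitous species, B the
#' one conditioned on it.
#'
#' @inheritParams twosp_negloglik
#' @param n_starts,seed optimizer controls as in [fit_occupancy].
#' @return An object of classes \code{twosp_fit}, \code{salocc_fit} with a
#'   \code{derived} data frame (psi_A, psi_BA, psi_Ba, psi_B, psi_AB, phi
#'   with SEs and 95\% intervals) and a \code{derived_site_mean} row
#'   (psi_BA averaged over site-level predictions, labelled separately from
#'   the intercept-scale value).
#' @export
fit_twospecies <- function(dataset_A, dataset_B, spec = twosp_spec(),
                           interaction_detection = FALSE, n_starts = 5L,
                           seed = 1L) {
  stopifnot(inherits(dataset_A, "survey_data"), inherits(dataset_B, "survey_data"))
  if (dataset_A$mode != "binary" || dataset_B$mode != "binary")
    stop("two-species models need binary-mode data")
  des <- twosp_designs(dataset_A, dataset_B, spec, interaction_detection)
  idx <- twosp_par_index(des)
  npar <- max(unlist(idx))
  yA <- dataset_A$y; yB <- dataset_B$y
  nll <- function(par) twosp_negloglik_ll(par, yA, yB, des, interaction_detection)
  opt <- multistart_optim(nll, npar, n_starts = n_starts, seed = seed)
  nms <- unlist(lapply(names(des), function(cm)
    paste0(cm, "_", colnames(des[[cm]]))))
  est <- stats::setNames(opt$par, nms)
  vcov <- opt$vcov
  if (!is.null(vcov)) dimnames(vcov) <- list(nms, nms)
  fit <- new_salocc_fit("twosp_fit", spec, est, vcov, -opt$value, nrow(yA),
                        opt$converged, opt$boundary, opt$grad_norm,
                        extra = list(dataset_A = dataset_A,
                                     dataset_B = dataset_B,
                                     interaction_detection = interaction_detection,
                                     designs_ncol = vapply(des, ncol, integer(1)),
                                     par_index = idx))
  fit$derived <- twosp_derived(fit)
  fit$derived_site_mean <- twosp_site_mean(fit, des)
  fit
}

# Derived occupancy quantities at standardized-covariate means (intercepts),
# with delta-method SEs; phi interval on the log scale.
twosp_derived <- function(fit) {
  idx <- fit$par_index
  at0 <- function(par, cm) {
    # intercept-scale linear predictor: covariates at standardized mean 0
    .plogis(par[idx[[cm]][1]])
  }
  quantities <- list(
    psi_A = function(par) at0(par, "psiA"),
    psi_BA = function(par) at0(par, "psiBA"),
    psi_Ba = function(par) at0(par, "psiBa"),
    psi_B = function(par) {
      a <- at0(par, "psiA")
      a * at0(par, "psiBA") + (1 - a) * at0(par, "psiBa")
    },
    psi_AB = function(par) at0(par, "psiA") * at0(par, "psiBA"),
    phi = function(par) {
      a <- at0(par, "psiA"); ba <- at0(par, "psiBA"); bA <- at0(par, "psiBa")
      b <- a * ba + (1 - a) * bA
      (a * ba) / (a * b)
    })
  out <- data.frame(quantity = names(quantities), estimate = NA_real_,
                    se = NA_real_, lower = NA_real_, upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(quantities)) {
    f <- quantities[[i]]
    est <- f(fit$estimates)
    out$estimate[i] <- est
    if (is.null(fit$vcov)) next
    if (names(quantities)[i] == "phi") {
      g <- num_gradient(function(p) log(f(p)), fit$estimates)
      se_log <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
      out$se[i] <- est * se_log           # delta back to phi scale
      out$lower[i] <- est * exp(-1.96 * se_log)
      out$upper[i] <- est * exp(1.96 * se_log)
    } else {
      g <- num_gradient(f, fit$estimates)
      se <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
      out$se[i] <- se
      out$lower[i] <- max(0, est - 1.96 * se)
      out$upper[i] <- min(1, est + 1.96 * se)
    }
  }
  out
}

# psi_BA averaged over the sites' covariate values (the "overall" conditional
# occupancy as a mean of site-level predictions).
twosp_site_mean <- function(fit, designs) {
  idx <- fit$par_index
  mean(.plogis(drop(designs$psiBA %*% fit$estimates[idx$psiBA])))
}

#' @export
print.twosp_fit <- function(x, ...) {
  cat(fit_label(x), "\n", sep = "")
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, x$K)
  print(round(data.frame(Estimate = x$estimates, `Std. Error` = se,
                         check.names = FALSE), 4))
  cat(sprintf("  logLik %.4f  K %d  AIC %.3f  %s\n", x$loglik, x$K, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  cat("  derived (at covariate means):\n")
  print(transform(x$derived, estimate = round(estimate, 4),
                  se = round(se, 4), lower = round(lower, 4),
                  upper = round(upper, 4)), row.names = FALSE)
  cat(sprintf("  psi_BA averaged over sites: %.4f\n", x$derived_site_mean))
  invisible(x)
}

#' Species Interaction Factor
#'
#' \eqn{\phi = \psi_{AB} / (\psi_A \psi_B)}: 1 means the two species occupy
#' sites independently, above 1 they co-occur more often than chance
#' (aggregation), below 1 less often (segregation).
#'
#' @param psi_A,psi_B marginal occupancy probabilities in (0, 1].
#' @param psi_AB joint co-occurrence probability; cannot exceed either
#'   marginal.
#' @return A positive real.
#' @export
#' @examples
#' species_interaction_factor(0.6, 0.8, 0.48) # independence: 1
species_interaction_factor <- function(psi_A, psi_B, psi_AB) {
  if (any(psi_A <= 0 | psi_A > 1) || any(psi_B <= 0 | psi_B > 1))
    stop("marginal occupancy probabilities must be in (0, 1]")
  if (any(psi_AB < 0))
    stop("psi_AB must be nonnegative")
  if (any(psi_AB > pmin(psi_A, psi_B) + 1e-12))
    stop("psi_AB exceeds min(psi_A, psi_B): impossible joint probability")
  psi_AB / (psi_A * psi_B)
}

#' Conditional occupancy of species B given species A over a grid
#'
#' Predicts \eqn{\psi_{BA}} (occupancy of the conditioned species where the
#' dominant species is present) across covariate values, with pointwise
#' delta-method 95\% intervals on the logit scale.
#'
#' @param fit a converged \code{twosp_fit}.
#' @param grid data frame of covariate values (raw scale when \code{record}
#'   supplied).
#' @param record optional \code{standardization_record}.
#' @param level confidence level.
#' @return A \code{prediction_grid} data frame.
#' @export
conditional_occupancy <- function(fit, grid = NULL, record = NULL,
                                  level = 0.95) {
  stopifnot(inherits(fit, "twosp_fit"))
  formula <- fit$spec$formulas$psiBA
  vars <- all.vars(formula)
  if (is.null(grid)) grid <- data.frame(row.names = 1)
  extraneous <- setdiff(names(grid), vars)
  if (length(extraneous))
    stop("grid names covariate(s) absent from the psiBA formula: ",
         paste(extraneous, collapse = ", "))
  grid_std <- apply_standardization(grid, record)
  for (v in setdiff(vars, names(grid_std))) grid_std[[v]] <- 0
  X <- stats::model.matrix(formula, grid_std)
  idx <- fit$par_index$psiBA
  beta <- fit$estimates[idx]
  eta <- drop(X %*% beta)
  se <- rep(NA_real_, length(eta))
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[idx, idx, drop = FALSE]
    se <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(grid, data.frame(estimate = .plogis(eta), se_link = se,
                                lower = .plogis(eta - z * se),
                                upper = .plogis(eta + z * se)))
  class(out) <- c("prediction_grid", "data.frame")
  attr(out, "link") <- "logit"
  out
}
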