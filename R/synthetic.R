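# Covariate generator targets: marginal mean and spread taken from the
# survey's covariate summary (spread backed out of the interquartile range,
# sd = IQR / 1.349), with draws clipped to each covariate's natural range.
# CWD and ROC are small counts and are drawn Poisson at the stated mean.
site_cov_targets <- data.frame(
  name = c("ASP", "CAN", "ELV", "MST", "RAD", "TPI", "VEG"),
  mean = c(1.19, 26, 407.40, 14, 746.12, 14.20, 126.60),
  sd = c((1.87 - 0.33), (28 - 20), (436.40 - 375.40), (17 - 11),
         (846.91 - 677.92), (23.55 - 4.05), (130.40 - 123.80)) / 1.349,
  lo = c(0, 0, 0, 0, 0, -Inf, -Inf),
  hi = c(2, 100, Inf, 100, Inf, Inf, Inf),
  stringsAsFactors = FALSE)

visit_cov_targets <- list(
  CWD = list(family = "poisson", mean = 3),
  DAY = list(family = "normal", mean = 306.50,
             sd = (312.20 - 300.80) / 1.349, lo = -Inf, hi = Inf),
  LLD = list(family = "normal", mean = 5.45, sd = (6.75 - 4.45) / 1.349,
             lo = 0, hi = Inf),
  LUX = list(family = "normal", mean = 510.40, sd = (740 - 175) / 1.349,
             lo = 0, hi = Inf),
  ROC = list(family = "poisson", mean = 5),
  TOD = list(family = "normal", mean = 1310, sd = (1518 - 1102) / 1.349,
             lo = 800, hi = 2000))

#' Simulate site and visit covariates emulating the study design
#'
#' Draws the seven site covariates (ASP, CAN, ELV, MST, RAD, TPI, VEG) and
#' six visit covariates (CWD, DAY, LLD, LUX, ROC, TOD) with the means and
#' IQR-implied spreads of the survey's covariate table: normal draws with
#' sd = IQR/1.349 clipped to natural ranges, except the cover counts CWD and
#' ROC which are Poisson. Marginals are independent unless a correlation
#' matrix is supplied for the site covariates (applied to the underlying
#' normal draws before clipping).
#'
#' @param n_sites,n_visits positive integers (the emulated design is 40
#'   sites by 4 visits).
#' @param seed integer seed; identical seeds reproduce identical tables.
#' @param site_correlation optional 7x7 correlation matrix (rows/columns in
#'   the order ASP, CAN, ELV, MST, RAD, TPI, VEG).
#' @return A list with \code{site_covs} (data frame) and \code{visit_covs}
#'   (named list of n_sites x n_visits matrices).
#' @export
simulate_covariates <- function(n_sites, n_visits, seed = 1L,
                                site_correlation = NULL) {
  if (n_sites < 1 || n_visits < 1) stop("dimensions must be positive")
  set.seed(seed)
  k <- nrow(site_cov_targets)
  Z <- matrix(stats::rnorm(n_sites * k), n_sites, k)
  if (!is.null(site_correlation)) {
    if (!all(dim(site_correlation) == c(k, k)))
      stop("site_correlation must be ", k, "x", k)
    Z <- Z %*% chol(site_correlation)
  }
  site_covs <- as.data.frame(stats::setNames(lapply(seq_len(k), function(j) {
    t <- site_cov_targets[j, ]
    pmin(pmax(t$mean + t$sd * Z[, j], t$lo), t$hi)
  }), site_cov_targets$name))
  visit_covs <- lapply(visit_cov_targets, function(t) {
    if (t$family == "poisson")
      matrix(stats::rpois(n_sites * n_visits, t$mean), n_sites, n_visits)
    else
      matrix(pmin(pmax(stats::rnorm(n_sites * n_visits, t$mean, t$sd),
                       t$lo), t$hi), n_sites, n_visits)
  })
  list(site_covs = site_covs, visit_covs = visit_covs)
}

# Standardize a covariate table in place (z-scores) for the generators: the
# generating links act on standardized covariates, mirroring how the models
# are fitted, while the returned dataset keeps the raw scale.
std_covs <- function(covariates) {
  sc <- covariates$site_covs
  for (nm in names(sc)) {
    s <- stats::sd(sc[[nm]])
    sc[[nm]] <- if (s > 0) (sc[[nm]] - mean(sc[[nm]])) / s else sc[[nm]] * 0
  }
  vc <- lapply(covariates$visit_covs, function(m) {
    s <- stats::sd(as.vector(m))
    if (s > 0) (m - mean(m)) / s else m * 0
  })
  list(site_covs = sc, visit_covs = vc)
}

# Linear predictor for named coefficients over (standardized) covariates.
# Site-level: returns length-n vector; with visit = TRUE returns n x J.
coef_linpred <- function(coefs, covs, n, J, visit = FALSE) {
  out <- if (visit) matrix(0, n, J) else numeric(n)
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") {
      out <- out + coefs[[nm]]
    } else if (nm %in% names(covs$site_covs)) {
      v <- covs$site_covs[[nm]]
      out <- out + coefs[[nm]] * (if (visit) matrix(v, n, J) else v)
    } else if (visit && nm %in% names(covs$visit_covs)) {
      out <- out + coefs[[nm]] * covs$visit_covs[[nm]]
    } else {
      stop("coefficient names unknown covariate: ", nm)
    }
  }
  out
}

check_coefs <- function(coefs, label) {
  if (is.null(names(coefs)) || any(!nzchar(names(coefs))))
    stop(label, " must be a named vector (use '(Intercept)')")
  if (any(!is.finite(unlist(coefs)))) stop(label, " must be finite")
  as.list(coefs)
}

#' Simulate detection/non-detection data from the occupancy model
#'
#' Latent occupancy \eqn{z_i \sim Bernoulli(\psi_i)} with
#' \eqn{logit(\psi_i)} linear in standardized site covariates, and
#' detections \eqn{y_{ij} \sim Bernoulli(z_i p_{ij})} with
#' \eqn{logit(p_{ij})} linear in standardized site/visit covariates.
#'
#' @param state_coefs named numeric vector of logit-scale occupancy
#'   coefficients (name \code{"(Intercept)"} plus site covariates).
#' @param detection_coefs named numeric vector of logit-scale detection
#'   coefficients (intercept plus site or visit covariates).
#' @param covariates list from [simulate_covariates] (raw scale).
#' @param seed integer seed.
#' @return A list of class \code{synthetic_truth}: \code{dataset} (a binary
#'   [survey_data] carrying the raw covariates), \code{z} (latent occupancy
#'   indicators), \code{psi}, \code{p}, the coefficients and the seed.
#' @export
simulate_occupancy_data <- function(state_coefs, detection_coefs, covariates,
                                    seed = 1L) {
  state_coefs <- check_coefs(state_coefs, "state_coefs")
  detection_coefs <- check_coefs(detection_coefs, "detection_coefs")
  n <- nrow(covariates$site_covs)
  J <- ncol(covariates$visit_covs[[1]])
  zc <- std_covs(covariates)
  psi <- .plogis(coef_linpred(state_coefs, zc, n, J))
  p <- .plogis(coef_linpred(detection_coefs, zc, n, J, visit = TRUE))
  set.seed(seed)
  z <- stats::rbinom(n, 1, psi)
  y <- matrix(stats::rbinom(n * J, 1, rep(z, J) * p), n, J)
  dataset <- survey_data(y, site_covs = covariates$site_covs,
                         visit_covs = covariates$visit_covs, mode = "binary")
  structure(list(dataset = dataset, z = z, psi = psi, p = p,
                 state_coefs = state_coefs,
                 detection_coefs = detection_coefs, seed = seed),
            class = "synthetic_truth")
}

#' Simulate repeated counts from the N-mixture model with availability
#'
#' Latent abundance \eqn{N_i \sim Poisson(\lambda_i)} with
#' \eqn{\log(\lambda_i)} linear in standardized site covariates; counts
#' \eqn{y_{ij} \sim Binomial(N_i,\ availability \times p_{ij})}. Random
#' temporary emigration thus scales conditional capture down to the
#' effective detection probability the model identifies.
#'
#' @param state_coefs named log-scale abundance coefficients.
#' @param detection_coefs named logit-scale conditional-capture
#'   coefficients.
#' @param covariates list from [simulate_covariates].
#' @param availability probability in (0, 1] that an individual is at the
#'   surface during a visit.
#' @param seed integer seed.
#' @return A list of class \code{synthetic_truth}: \code{dataset} (count
#'   [survey_data]), \code{N} (latent abundances), \code{lambda},
#'   \code{p_psi}, \code{p_lambda}, coefficients, availability, seed.
#' @export
simulate_count_data <- function(state_coefs, detection_coefs, covariates,
                                availability = 1, seed = 1L) {
  if (availability <= 0 || availability > 1)
    stop("availability must be in (0, 1]")
  state_coefs <- check_coefs(state_coefs, "state_coefs")
  detection_coefs <- check_coefs(detection_coefs, "detection_coefs")
  n <- nrow(covariates$site_covs)
  J <- ncol(covariates$visit_covs[[1]])
  zc <- std_covs(covariates)
  lambda <- exp(coef_linpred(state_coefs, zc, n, J))
  p_psi <- .plogis(coef_linpred(detection_coefs, zc, n, J, visit = TRUE))
  p_eff <- availability * p_psi
  set.seed(seed)
  N <- stats::rpois(n, lambda)
  y <- matrix(stats::rbinom(n * J, rep(N, J), p_eff), n, J)
  dataset <- survey_data(y, site_covs = covariates$site_covs,
                         visit_covs = covariates$visit_covs, mode = "count")
  structure(list(dataset = dataset, N = N, lambda = lambda, p_psi = p_psi,
                 p_lambda = p_eff, availability = availability,
                 state_coefs = state_coefs,
                 detection_coefs = detection_coefs, seed = seed),
            class = "synthetic_truth")
}

# Accept either a bare probability or a named logit-scale coefficient
# vector for a two-species component.
twosp_component <- function(x, label, zc, n, J, visit = FALSE) {
  if (is.numeric(x) && length(x) == 1 && is.null(names(x))) {
    if (x < 0 || x > 1) stop(label, " probability must be in [0, 1]")
    if (visit) return(matrix(x, n, J)) else return(rep(x, n))
  }
  .plogis(coef_linpred(check_coefs(x, label), zc, n, J, visit = visit))
}

#' Simulate paired detection histories for two interacting species
#'
#' Species A occupies sites with probability \eqn{\psi_A}; species B with
#' probability \eqn{\psi_{BA}} where A is present and \eqn{\psi_{Ba}} where
#' absent. Detections are independent Bernoulli given presence. Components
#' may be bare probabilities (intercept-only) or named logit-scale
#' coefficient vectors over standardized covariates.
#'
#' @param psi_A,psi_BA,psi_Ba occupancy components.
#' @param p_A,p_B detection components.
#' @param covariates list from [simulate_covariates].
#' @param seed integer seed.
#' @return A list of class \code{synthetic_truth}: \code{dataset_A},
#'   \code{dataset_B} (binary [survey_data] on shared covariates),
#'   \code{zA}, \code{zB}, the component probabilities and the seed.
#' @export
simulate_two_species <- function(psi_A, psi_BA, psi_Ba, p_A, p_B,
                                 covariates, seed = 1L) {
  n <- nrow(covariates$site_covs)
  J <- ncol(covariates$visit_covs[[1]])
  zc <- std_covs(covariates)
  vA <- twosp_component(psi_A, "psi_A", zc, n, J)
  vBA <- twosp_component(psi_BA, "psi_BA", zc, n, J)
  vBa <- twosp_component(psi_Ba, "psi_Ba", zc, n, J)
  mA <- twosp_component(p_A, "p_A", zc, n, J, visit = TRUE)
  mB <- twosp_component(p_B, "p_B", zc, n, J, visit = TRUE)
  set.seed(seed)
  zA <- stats::rbinom(n, 1, vA)
  zB <- stats::rbinom(n, 1, ifelse(zA == 1, vBA, vBa))
  yA <- matrix(stats::rbinom(n * J, 1, rep(zA, J) * mA), n, J)
  yB <- matrix(stats::rbinom(n * J, 1, rep(zB, J) * mB), n, J)
  mk <- function(y) survey_data(y, site_covs = covariates$site_covs,
                                visit_covs = covariates$visit_covs,
                                mode = "binary")
  structure(list(dataset_A = mk(yA), dataset_B = mk(yB), zA = zA, zB = zB,
                 psi_A = vA, psi_BA = vBA, psi_Ba = vBa, seed = seed),
            class = "synthetic_truth")
}

#' Load a simulation scenario from YAML
#'
#' The packaged scenario \code{lcw_like.yaml} encodes the emulated study
#' conditions: 40 sites, 4 visits, the covariate moments, and link-scale
#' effect sizes comparable to the study's model-averaged estimates
#' (detection declining with time of day for one species, increasing with
#' coarse woody debris for the other; availability well below 1).
#'
#' @param path YAML file; default is the packaged \code{lcw_like.yaml}.
#' @return A named list (scenario).
#' @export
load_scenario <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lcw_like.yaml", package = "salocc")
  yaml::read_yaml(path)
}

#' Simulate a dataset from a scenario
#'
#' @param scenario list from [load_scenario].
#' @param which one of \code{"occupancy"}, \code{"nmixture"},
#'   \code{"cooccurrence"}.
#' @param seed integer seed (covariates use \code{seed}, the state/detection
#'   draws \code{seed + 1}).
#' @param n_sites,n_visits optional overrides of the scenario dimensions.
#' @return A \code{synthetic_truth} list (see the simulator functions).
#' @export
simulate_scenario <- function(scenario, which = c("occupancy", "nmixture",
                                                  "cooccurrence"),
                              seed = 1L, n_sites = NULL, n_visits = NULL) {
  which <- match.arg(which)
  n <- if (is.null(n_sites)) scenario$n_sites else n_sites
  J <- if (is.null(n_visits)) scenario$n_visits else n_visits
  covs <- simulate_covariates(n, J, seed = seed)
  cfg <- scenario[[which]]
  if (is.null(cfg)) stop("scenario lacks a '", which, "' block")
  num <- function(x) stats::setNames(as.numeric(unlist(x)), names(unlist(x)))
  if (which == "occupancy") {
    simulate_occupancy_data(num(cfg$state), num(cfg$detection), covs,
                            seed = seed + 1L)
  } else if (which == "nmixture") {
    simulate_count_data(num(cfg$state), num(cfg$detection), covs,
                        availability = cfg$availability, seed = seed + 1L)
  } else {
    comp <- function(x) if (is.list(x) || !is.null(names(x))) num(x) else x
    simulate_two_species(comp(cfg$psi_A), comp(cfg$psi_BA), comp(cfg$psi_Ba),
                         comp(cfg$p_A), comp(cfg$p_B), covs,
                         seed = seed + 1L)
  }
}

#' Write a synthetic truth bundle to disk
#'
#' Writes the dataset CSVs (via [write_survey]) and the generating
#' parameters as JSON alongside.
#'
#' @param truth a \code{synthetic_truth}.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(truth$dataset))
    paths <- write_survey(truth$dataset, dir)
  if (!is.null(truth$dataset_A)) {
    paths <- c(paths, write_survey(truth$dataset_A, file.path(dir, "species_A")))
    paths <- c(paths, write_survey(truth$dataset_B, file.path(dir, "species_B")))
  }
  meta <- truth[setdiff(names(truth),
                        c("dataset", "dataset_A", "dataset_B"))]
  pj <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), pj)
  invisible(c(paths, truth = pj))
}
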