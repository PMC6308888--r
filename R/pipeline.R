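#' Stepwise detection-then-state inference pipeline
#'
#' The full single-species workflow: (a) fit one model per candidate
#' detection covariate (plus an intercept-only model) holding the state
#' process constant; (b) model-average each detection covariate's effect
#' size and flag the important ones (95\% unconditional CI excluding 0);
#' (c) carry the selected detection structure into one state model per
#' candidate state covariate (plus intercept-only); (d) model-average the
#' state effect sizes; (e) produce model-averaged prediction curves over
#' each state covariate's observed range. Covariates are standardized up
#' front and predictions are reported on the raw covariate scale.
#'
#' @param dataset a [survey_data] object (binary for occupancy, counts for
#'   N-mixture).
#' @param detection_candidates character vector of candidate detection
#'   covariates.
#' @param state_candidates character vector of candidate state covariates.
#' @param family \code{"occupancy"} or \code{"nmixture"}.
#' @param criterion ranking criterion; default AICc.
#' @param seed integer seed (optimizer starts).
#' @param selected_detection optional override of the step-(b) selection
#'   rule: the detection covariates to carry forward.
#' @param grid_length points per prediction curve.
#' @param out_dir optional directory; when given, rank tables, effect
#'   tables, predictions and a manifest are written as CSV/JSON.
#' @param verbose log one line per fit.
#' @return A list (class \code{stepwise_result}) with
#'   \code{detection_set}, \code{detection_effects},
#'   \code{selected_detection}, \code{state_set}, \code{state_effects},
#'   \code{predictions} (one prediction grid per state candidate),
#'   \code{record} (standardization), and \code{manifest}.
#' @export
run_stepwise <- function(dataset, detection_candidates, state_candidates,
                         family = c("occupancy", "nmixture"),
                         criterion = c("AICc", "AIC"), seed = 1L,
                         selected_detection = NULL, grid_length = 50L,
                         out_dir = NULL, verbose = FALSE) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  std <- standardize_covariates(dataset)
  data_std <- std$data
  record <- std$record
  fitter <- if (family == "occupancy") fit_occupancy else fit_nmixture
  fit_one <- function(state_f, det_f, label) {
    f <- tryCatch(
      suppressWarnings(fitter(data_std, model_spec(state_f, det_f, family),
                              seed = seed)),
      error = function(e) NULL)
    if (verbose && !is.null(f))
      message(sprintf("fit %-28s K=%d %s=%.3f %s", label, f$K, criterion,
                      if (criterion == "AICc") f$aicc else f$aic,
                      if (f$converged) "converged" else "NOT converged"))
    if (verbose && is.null(f)) message("fit ", label, " FAILED")
    f
  }

  # (a) detection models, state held constant
  det_forms <- c(list(`p(.)` = ~1),
                 stats::setNames(lapply(detection_candidates, function(v)
                   stats::as.formula(paste("~", v))),
                   sprintf("p(%s)", detection_candidates)))
  det_fits <- Map(fit_one, list(~1), det_forms, names(det_forms))
  det_fits <- Filter(Negate(is.null), det_fits)
  dropped <- Filter(function(f) !f$converged, det_fits)
  if (length(dropped))
    warning(length(dropped), " detection fit(s) flagged non-converged")
  if (!length(det_fits)) stop("all detection fits failed")
  det_set <- model_set(det_fits, criterion = criterion)

  # (b) model-averaged detection effects
  det_effects <- lapply(stats::setNames(nm = detection_candidates),
                        function(v)
                          tryCatch(model_average_beta(det_set, v),
                                   error = function(e) NULL))
  det_effects <- Filter(Negate(is.null), det_effects)
  if (is.null(selected_detection))
    selected_detection <- names(Filter(function(e) e$important, det_effects))

  # (c) state models with the selected detection structure
  det_formula <- if (length(selected_detection))
    stats::as.formula(paste("~", paste(selected_detection, collapse = "+")))
  else ~1
  state_forms <- c(list(`state(.)` = ~1),
                   stats::setNames(lapply(state_candidates, function(v)
                     stats::as.formula(paste("~", v))),
                     sprintf("state(%s)", state_candidates)))
  state_fits <- Map(fit_one, state_forms, list(det_formula),
                    names(state_forms))
  state_fits <- Filter(Negate(is.null), state_fits)
  if (!length(state_fits)) stop("all state fits failed")
  state_set <- model_set(state_fits, criterion = criterion)

  # (d) model-averaged state effects
  state_effects <- lapply(stats::setNames(nm = state_candidates), function(v)
    tryCatch(model_average_beta(state_set, v), error = function(e) NULL))
  state_effects <- Filter(Negate(is.null), state_effects)

  # (e) model-averaged prediction curves on the raw covariate scale
  predictions <- lapply(stats::setNames(nm = state_candidates), function(v) {
    i <- match(v, record$covariate)
    raw <- record$mean[i] + record$sd[i] *
      seq(-2, 2, length.out = grid_length)
    grid <- stats::setNames(data.frame(raw), v)
    model_average_predictions(state_set, grid, record = record,
                              type = "state")
  })

  manifest <- rbind(
    data.frame(step = "detection", rank_table(det_set)),
    data.frame(step = "state", rank_table(state_set)))

  res <- structure(list(detection_set = det_set,
                        detection_effects = det_effects,
                        selected_detection = selected_detection,
                        state_set = state_set,
                        state_effects = state_effects,
                        predictions = predictions,
                        record = record,
                        manifest = manifest,
                        family = family, criterion = criterion, seed = seed),
                   class = "stepwise_result")
  if (!is.null(out_dir)) write_stepwise(res, out_dir)
  res
}

effects_frame <- function(effects) {
  do.call(rbind, lapply(effects, function(e)
    data.frame(covariate = e$covariate, beta_bar = e$beta_bar, se = e$se,
               lo50 = e$ci50[1], hi50 = e$ci50[2],
               lo95 = e$ci95[1], hi95 = e$ci95[2],
               important = e$important, row.names = NULL)))
}

write_stepwise <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(rank_table(res$detection_set),
                   file.path(out_dir, "detection_rank.csv"), row.names = FALSE)
  utils::write.csv(rank_table(res$state_set),
                   file.path(out_dir, "state_rank.csv"), row.names = FALSE)
  if (length(res$detection_effects))
    utils::write.csv(effects_frame(res$detection_effects),
                     file.path(out_dir, "detection_effects.csv"),
                     row.names = FALSE)
  if (length(res$state_effects)) {
    utils::write.csv(effects_frame(res$state_effects),
                     file.path(out_dir, "state_effects.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "state_effects.png"), width = 600,
                   height = 400)
    plot_averaged_effects(res$state_effects)
    grDevices::dev.off()
  }
  for (nm in names(res$predictions))
    utils::write.csv(res$predictions[[nm]],
                     file.path(out_dir, paste0("prediction_", nm, ".csv")),
                     row.names = FALSE)
  writeLines(jsonlite::toJSON(list(
    family = res$family, criterion = res$criterion, seed = res$seed,
    selected_detection = res$selected_detection),
    auto_unbox = TRUE), file.path(out_dir, "config_echo.json"))
  invisible(out_dir)
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise", x$family, "pipeline (criterion ", x$criterion, ")\n")
  cat("\nDetection model ranking:\n")
  print(rank_table(x$detection_set), row.names = FALSE)
  cat("\nSelected detection covariates:",
      if (length(x$selected_detection))
        paste(x$selected_detection, collapse = ", ") else "(none)", "\n")
  cat("\nState model ranking:\n")
  print(rank_table(x$state_set), row.names = FALSE)
  if (length(x$state_effects)) {
    cat("\nModel-averaged state effects:\n")
    print(effects_frame(x$state_effects), row.names = FALSE)
  }
  invisible(x)
}

#' Two-species co-occurrence pipeline
#'
#' Fits the null co-occurrence model (all components intercept-only) and one
#' environmental model per candidate covariate (the covariate entering both
#' conditional-occupancy components, \eqn{\psi_{BA}} and \eqn{\psi_{Ba}}),
#' ranks them by AIC, reports the cumulative Akaike weight of the
#' environmental subset against the null subset, the Species Interaction
#' Factor of the top-ranked model with its delta-method interval, and a
#' conditional-occupancy prediction curve per covariate from the top-ranked
#' model containing it.
#'
#' @param dataset_A,dataset_B aligned binary [survey_data] objects; A should
#'   be the more ubiquitous species.
#' @param cooccurrence_candidates character vector of site covariates.
#' @param detection_formula_A,detection_formula_B detection formulas shared
#'   across the candidate set.
#' @param criterion ranking criterion; two-species sets default to AIC.
#' @param seed integer seed.
#' @param grid_length points per prediction curve.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param verbose log one line per fit.
#' @return A list (class \code{cooccurrence_result}) with \code{set},
#'   \code{null_weight}, \code{environmental_weight}, \code{top_fit},
#'   \code{phi} (row of the top fit's derived table), \code{predictions},
#'   \code{record}, \code{manifest}.
#' @export
run_cooccurrence <- function(dataset_A, dataset_B, cooccurrence_candidates,
                             detection_formula_A = ~1,
                             detection_formula_B = ~1,
                             criterion = c("AIC", "AICc"), seed = 1L,
                             grid_length = 50L, out_dir = NULL,
                             verbose = FALSE) {
  criterion <- match.arg(criterion)
  stdA <- standardize_covariates(dataset_A)
  stdB <- standardize_covariates(dataset_B)
  record <- stdA$record
  specs <- c(list(null = twosp_spec(pA = detection_formula_A,
                                    pB = detection_formula_B)),
             stats::setNames(lapply(cooccurrence_candidates, function(v) {
               f <- stats::as.formula(paste("~", v))
               twosp_spec(psiBA = f, psiBa = f,
                          pA = detection_formula_A, pB = detection_formula_B)
             }), sprintf("env(%s)", cooccurrence_candidates)))
  fits <- lapply(stats::setNames(nm = names(specs)), function(nm) {
    f <- tryCatch(
      suppressWarnings(fit_twospecies(stdA$data, stdB$data, specs[[nm]],
                                      seed = seed)),
      error = function(e) NULL)
    if (verbose && !is.null(f))
      message(sprintf("fit %-16s K=%d AIC=%.3f %s", nm, f$K, f$aic,
                      if (f$converged) "converged" else "NOT converged"))
    f
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all co-occurrence fits failed")
  set <- model_set(fits, criterion = criterion)
  null_w <- cumulative_weight(set, function(f)
    identical(deparse(f$spec$formulas$psiBA), "~1") &&
      identical(deparse(f$spec$formulas$psiBa), "~1"))
  tab <- rank_table(set)
  top <- set$fits[[tab$model[1]]]
  predictions <- lapply(stats::setNames(nm = cooccurrence_candidates),
                        function(v) {
    holder <- set$fits[[paste0("env(", v, ")")]]
    if (is.null(holder)) return(NULL)
    i <- match(v, record$covariate)
    raw <- record$mean[i] + record$sd[i] * seq(-2, 2, length.out = grid_length)
    conditional_occupancy(holder, stats::setNames(data.frame(raw), v),
                          record = record)
  })
  res <- structure(list(set = set, null_weight = null_w,
                        environmental_weight = 1 - null_w,
                        top_fit = top,
                        phi = top$derived[top$derived$quantity == "phi", ],
                        derived = top$derived,
                        predictions = Filter(Negate(is.null), predictions),
                        record = record, manifest = tab,
                        criterion = criterion, seed = seed),
                   class = "cooccurrence_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "cooccurrence_rank.csv"),
                     row.names = FALSE)
    utils::write.csv(top$derived, file.path(out_dir, "derived.csv"),
                     row.names = FALSE)
    for (nm in names(res$predictions))
      utils::write.csv(res$predictions[[nm]],
                       file.path(out_dir, paste0("cond_occupancy_", nm, ".csv")),
                       row.names = FALSE)
    writeLines(jsonlite::toJSON(list(
      criterion = criterion, seed = seed, null_weight = null_w,
      environmental_weight = 1 - null_w), auto_unbox = TRUE, digits = NA),
      file.path(out_dir, "cooccurrence_weights.json"))
  }
  res
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat("Two-species co-occurrence pipeline (criterion ", x$criterion, ")\n",
      sep = "")
  print(x$manifest, row.names = FALSE)
  cat(sprintf("\ncumulative weight: environmental %.3f vs null %.3f\n",
              x$environmental_weight, x$null_weight))
  cat(sprintf("Species Interaction Factor (top model): %.3f [%.3f, %.3f]\n",
              x$phi$estimate, x$phi$lower, x$phi$upper))
  invisible(x)
}
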