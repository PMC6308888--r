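#' Decompose detection into availability and temporary emigration
#'
#' Occupancy models estimate the conditional capture probability
#' \eqn{p_\psi} (capture given presence and surface availability), while
#' N-mixture models estimate an effective detection probability
#' \eqn{p_\lambda =} availability \eqn{\times p_\psi}. Their ratio therefore
#' recovers availability — the probability an individual is alive and at
#' the surface during a survey — and its complement, the temporary
#' emigration probability (e.g. into subterranean refugia).
#'
#' @param p_psi conditional capture probability, in (0, 1].
#' @param p_lambda effective detection probability, in \eqn{[0,} \code{p_psi}\eqn{]}.
#' @return An object of class \code{detection_decomposition}: \code{p_psi},
#'   \code{p_lambda}, \code{availability}, \code{temporary_emigration}, and
#'   a \code{note} recording the convention used.
#' @export
#' @examples
#' decompose_detection(p_psi = 0.24, p_lambda = 0.05) # availability ~ 0.21
decompose_detection <- function(p_psi, p_lambda) {
  if (any(p_psi <= 0) || any(p_psi > 1))
    stop("p_psi must be in (0, 1]")
  if (any(p_lambda < 0))
    stop("p_lambda must be nonnegative")
  if (any(p_lambda > p_psi + 1e-12))
    stop("p_lambda exceeds p_psi: inconsistent estimates ",
         "(effective detection cannot exceed conditional capture)")
  availability <- p_lambda / p_psi
  structure(list(p_psi = p_psi, p_lambda = p_lambda,
                 availability = availability,
                 temporary_emigration = 1 - availability,
                 note = paste("availability computed as p_lambda / p_psi;",
                              "temporary emigration as its complement")),
            class = "detection_decomposition")
}

#' @export
print.detection_decomposition <- function(x, ...) {
  cat("Detection decomposition\n")
  cat(sprintf("  conditional capture p_psi   %.4f\n", x$p_psi))
  cat(sprintf("  effective detection p_lambda %.4f\n", x$p_lambda))
  cat(sprintf("  availability                 %.4f\n", x$availability))
  cat(sprintf("  temporary emigration         %.4f\n", x$temporary_emigration))
  invisible(x)
}

summary_row <- function(parameter, estimate, lower = NA_real_,
                        upper = NA_real_, available = TRUE) {
  data.frame(parameter = parameter,
             estimate = if (available) estimate else NA_real_,
             lower = lower, upper = upper, available = available,
             stringsAsFactors = FALSE)
}

#' Assemble a species summary table of site and sampling parameters
#'
#' Six rows in the layout of a model-averaged parameter table: occupancy
#' probability, density, conditional capture probability, effective
#' detection probability, availability, and emigration probability, each
#' with a 95\% interval where one exists. Components passed as \code{NULL}
#' yield rows marked unavailable.
#'
#' @param occupancy list with \code{estimate}, \code{lower}, \code{upper}
#'   (probability scale), or \code{NULL}.
#' @param density list with \code{estimate}, \code{lower}, \code{upper}
#'   (per square metre), or \code{NULL}.
#' @param p_psi,p_lambda lists with \code{estimate}, \code{lower},
#'   \code{upper}, or \code{NULL}.
#' @param decomposition a \code{detection_decomposition}, or \code{NULL}.
#' @return A data frame of class \code{species_summary} with columns
#'   parameter, estimate, lower, upper, available.
#' @export
summary_table <- function(occupancy = NULL, density = NULL, p_psi = NULL,
                          p_lambda = NULL, decomposition = NULL) {
  grab <- function(comp, name) {
    if (is.null(comp)) return(summary_row(name, NA, available = FALSE))
    summary_row(name, comp$estimate,
                if (!is.null(comp$lower)) comp$lower else NA_real_,
                if (!is.null(comp$upper)) comp$upper else NA_real_)
  }
  rows <- rbind(
    grab(occupancy, "Occupancy Probability"),
    grab(density, "Estimated Density (N/m2)"),
    grab(p_psi, "Conditional Capture Probability"),
    grab(p_lambda, "Effective Detection Probability"),
    if (is.null(decomposition))
      summary_row("Availability", NA, available = FALSE)
    else summary_row("Availability", decomposition$availability),
    if (is.null(decomposition))
      summary_row("Emigration Probability", NA, available = FALSE)
    else summary_row("Emigration Probability",
                     decomposition$temporary_emigration))
  class(rows) <- c("species_summary", "data.frame")
  rows
}

#' Write a species summary table as CSV and Markdown
#'
#' @param table a \code{species_summary} from [summary_table].
#' @param path_csv,path_md optional output paths.
#' @return The Markdown string, invisibly.
#' @export
write_summary_table <- function(table, path_csv = NULL, path_md = NULL) {
  if (!is.null(path_csv))
    utils::write.csv(table, path_csv, row.names = FALSE)
  fmt <- function(r) {
    if (!r$available) return(sprintf("| %s | — | |", r$parameter))
    ci <- if (is.finite(r$lower)) sprintf("(%.2f, %.2f)", r$lower, r$upper) else ""
    sprintf("| %s | %.2f | %s |", r$parameter, r$estimate, ci)
  }
  md <- c("| Parameter | Estimate | 95% CI |", "|---|---|---|",
          vapply(seq_len(nrow(table)), function(i) fmt(table[i, ]),
                 character(1)))
  md <- paste(md, collapse = "\n")
  if (!is.null(path_md)) writeLines(md, path_md)
  invisible(md)
}
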