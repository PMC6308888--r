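#' Construct a survey dataset
#'
#' Bundles a detection-history or count matrix from temporally replicated
#' surveys with its site-level and visit-level covariates. This is the input
#' container for all model-fitting functions in the package.
#'
#' @param y numeric matrix, sites in rows and visits in columns. In
#'   \code{"binary"} mode entries must be 0, 1 or \code{NA}; in
#'   \code{"count"} mode nonnegative integers or \code{NA}. \code{NA} marks a
#'   visit that did not happen (or yielded no usable record) and is dropped
#'   from per-site likelihood products, never treated as a zero.
#' @param site_covs data frame of site covariates, one row per site, or
#'   \code{NULL}.
#' @param visit_covs named list of numeric matrices shaped like \code{y},
#'   one per visit-level covariate.
#' @param mode \code{"binary"} for detection/non-detection data,
#'   \code{"count"} for repeated counts.
#' @param site_ids character vector of site labels; defaults to the row
#'   names of \code{y} or \code{"site_1"}, \code{"site_2"}, ...
#'
#' @return An object of class \code{survey_data}: a list with elements
#'   \code{y}, \code{site_covs}, \code{visit_covs}, \code{mode},
#'   \code{site_ids}.
#' @export
#' @examples
#' y <- matrix(rbinom(40, 1, 0.3), nrow = 10, ncol = 4)
#' sd1 <- survey_data(y, site_covs = data.frame(MST = rnorm(10)))
#' naive_poa(sd1)
survey_data <- function(y, site_covs = NULL, visit_covs = list(),
                        mode = c("binary", "count"), site_ids = NULL) {
  mode <- match.arg(mode)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y)
  J <- ncol(y)
  if (n < 1L || J < 1L) stop("y must have at least one site and one visit")
  if (is.null(site_ids)) {
    site_ids <- if (!is.null(rownames(y))) rownames(y) else paste0("site_", seq_len(n))
  }
  site_ids <- as.character(site_ids)
  if (length(site_ids) != n) stop("site_ids length must equal nrow(y)")
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  dimnames(y) <- list(site_ids, paste0("v", seq_len(J)))

  obs <- y[!is.na(y)]
  if (mode == "binary") {
    if (!all(obs %in% c(0, 1)))
      stop("binary mode: entries must be 0, 1 or NA")
  } else {
    if (any(obs < 0) || any(obs != round(obs)))
      stop("count mode: entries must be nonnegative integers or NA")
  }

  if (!is.null(site_covs)) {
    site_covs <- as.data.frame(site_covs)
    if (nrow(site_covs) != n)
      stop("site_covs must have one row per site (", n, "), got ", nrow(site_covs))
    rownames(site_covs) <- site_ids
  }
  if (length(visit_covs)) {
    if (is.null(names(visit_covs)) || any(!nzchar(names(visit_covs))))
      stop("visit_covs must be a named list")
    visit_covs <- lapply(visit_covs, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      m
    })
    bad <- vapply(visit_covs, function(m) !all(dim(m) == c(n, J)), logical(1))
    if (any(bad))
      stop("visit covariate(s) not shaped n_sites x n_visits: ",
           paste(names(visit_covs)[bad], collapse = ", "))
  }

  structure(list(y = y, site_covs = site_covs, visit_covs = visit_covs,
                 mode = mode, site_ids = site_ids),
            class = "survey_data")
}

#' @export
print.survey_data <- function(x, ...) {
  cat("Survey dataset (", x$mode, " mode): ", nrow(x$y), " sites x ",
      ncol(x$y), " visits\n", sep = "")
  if (!is.null(x$site_covs))
    cat("  site covariates: ", paste(names(x$site_covs), collapse = ", "), "\n", sep = "")
  if (length(x$visit_covs))
    cat("  visit covariates: ", paste(names(x$visit_covs), collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$y))
  if (nmiss) cat("  missing site-visits: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
summary.survey_data <- function(object, ...) {
  print(object)
  if (object$mode == "binary") {
    cat("  naive POA:", round(naive_poa(object), 3), "\n")
  } else {
    cat("  total count:", sum(object$y, na.rm = TRUE),
        " max count:", max(object$y, na.rm = TRUE), "\n")
  }
  invisible(object)
}

n_sites <- function(x) nrow(x$y)
n_visits <- function(x) ncol(x$y)

#' Read a survey dataset from delimited text files
#'
#' All files are comma-separated with a header row; the site-identifier
#' column is named \code{site_id}. The detection/count file has one column
#' per visit after \code{site_id}; each visit-covariate file is shaped the
#' same way. Blank cells become \code{NA} and stay missing.
#'
#' @param detections_path path to the detection/count CSV.
#' @param site_covs_path optional path to the site-covariate CSV
#'   (\code{site_id} plus one column per covariate).
#' @param visit_covs_paths named character vector of paths, one per
#'   visit-level covariate.
#' @param mode \code{"binary"} or \code{"count"}.
#' @return A [survey_data] object.
#' @export
read_survey <- function(detections_path, site_covs_path = NULL,
                        visit_covs_paths = character(),
                        mode = c("binary", "count")) {
  mode <- match.arg(mode)
  det <- utils::read.csv(detections_path, check.names = FALSE)
  if (!"site_id" %in% names(det))
    stop("detections file must have a 'site_id' column: ", detections_path)
  ids <- as.character(det$site_id)
  y <- as.matrix(det[setdiff(names(det), "site_id")])
  if (mode == "count" && any(y[!is.na(y)] != round(y[!is.na(y)])))
    stop("non-integer counts in ", detections_path)

  site_covs <- NULL
  if (!is.null(site_covs_path)) {
    sc <- utils::read.csv(site_covs_path, check.names = FALSE)
    if (!"site_id" %in% names(sc))
      stop("site covariate file must have a 'site_id' column")
    scids <- as.character(sc$site_id)
    unknown <- setdiff(scids, ids)
    if (length(unknown))
      stop("unknown site ids in site covariate file: ",
           paste(unknown, collapse = ", "))
    if (!setequal(scids, ids))
      stop("site covariate file missing sites: ",
           paste(setdiff(ids, scids), collapse = ", "))
    sc <- sc[match(ids, scids), , drop = FALSE]
    site_covs <- sc[setdiff(names(sc), "site_id")]
  }

  visit_covs <- list()
  if (length(visit_covs_paths)) {
    if (is.null(names(visit_covs_paths)))
      stop("visit_covs_paths must be named by covariate")
    visit_covs <- lapply(visit_covs_paths, function(p) {
      vc <- utils::read.csv(p, check.names = FALSE)
      if (!"site_id" %in% names(vc))
        stop("visit covariate file must have a 'site_id' column: ", p)
      vcids <- as.character(vc$site_id)
      unknown <- setdiff(vcids, ids)
      if (length(unknown))
        stop("unknown site ids in ", p, ": ", paste(unknown, collapse = ", "))
      m <- as.matrix(vc[match(ids, vcids), setdiff(names(vc), "site_id")])
      if (!all(dim(m) == dim(y)))
        stop("dimension mismatch between ", p, " and detections file")
      m
    })
  }

  survey_data(y, site_covs = site_covs, visit_covs = visit_covs,
              mode = mode, site_ids = ids)
}

#' Write a survey dataset to delimited text files
#'
#' Inverse of [read_survey]: writes \code{detections.csv},
#' \code{site_covs.csv} and one \code{visit_<name>.csv} per visit covariate
#' into \code{dir}.
#'
#' @param dataset a [survey_data] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(detections = file.path(dir, "detections.csv"))
  det <- data.frame(site_id = dataset$site_ids, dataset$y,
                    check.names = FALSE)
  utils::write.csv(det, paths[["detections"]], row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$site_covs)) {
    p <- file.path(dir, "site_covs.csv")
    utils::write.csv(data.frame(site_id = dataset$site_ids, dataset$site_covs,
                                check.names = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, site_covs = p)
  }
  for (nm in names(dataset$visit_covs)) {
    p <- file.path(dir, paste0("visit_", nm, ".csv"))
    m <- dataset$visit_covs[[nm]]
    utils::write.csv(data.frame(site_id = dataset$site_ids, m,
                                check.names = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, stats::setNames(p, nm))
  }
  invisible(paths)
}

#' Standardize covariates to zero mean and unit variance
#'
#' Centers and scales the named covariates (site- or visit-level) by their
#' sample mean and standard deviation, as is conventional before fitting
#' detection models so that coefficients are comparable effect sizes. The
#' returned record allows raw-scale prediction grids to be mapped onto the
#' fitted scale.
#'
#' @param dataset a [survey_data] object.
#' @param covariate_names character vector; defaults to every numeric site
#'   and visit covariate.
#' @return A list with \code{data} (the dataset with covariates replaced by
#'   z-scores) and \code{record} (a data frame of per-covariate means and
#'   standard deviations, class \code{standardization_record}).
#' @export
standardize_covariates <- function(dataset, covariate_names = NULL) {
  stopifnot(inherits(dataset, "survey_data"))
  site_names <- names(dataset$site_covs)
  visit_names <- names(dataset$visit_covs)
  if (is.null(covariate_names))
    covariate_names <- c(site_names[vapply(dataset$site_covs, is.numeric, logical(1))],
                         visit_names)
  rec <- data.frame(covariate = character(0), mean = numeric(0), sd = numeric(0),
                    stringsAsFactors = FALSE)
  for (nm in covariate_names) {
    if (nm %in% site_names) {
      v <- dataset$site_covs[[nm]]
      if (!is.numeric(v)) stop("covariate not numeric: ", nm)
      m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s <= 0) stop("zero-variance covariate: ", nm)
      dataset$site_covs[[nm]] <- (v - m) / s
    } else if (nm %in% visit_names) {
      v <- dataset$visit_covs[[nm]]
      m <- mean(v, na.rm = TRUE); s <- stats::sd(as.vector(v), na.rm = TRUE)
      if (!is.finite(s) || s <= 0) stop("zero-variance covariate: ", nm)
      dataset$visit_covs[[nm]] <- (v - m) / s
    } else {
      stop("unknown covariate: ", nm)
    }
    rec <- rbind(rec, data.frame(covariate = nm, mean = m, sd = s,
                                 stringsAsFactors = FALSE))
  }
  class(rec) <- c("standardization_record", "data.frame")
  list(data = dataset, record = rec)
}

#' Apply a standardization record to a raw-scale covariate table
#'
#' @param grid data frame of covariate values on the raw scale.
#' @param record a \code{standardization_record} from
#'   [standardize_covariates]; \code{NULL} leaves \code{grid} unchanged.
#' @return \code{grid} with every recorded covariate z-scored.
#' @export
apply_standardization <- function(grid, record) {
  if (is.null(record)) return(grid)
  for (i in seq_len(nrow(record))) {
    nm <- record$covariate[i]
    if (nm %in% names(grid))
      grid[[nm]] <- (grid[[nm]] - record$mean[i]) / record$sd[i]
  }
  grid
}

#' Naive proportion of area occupied
#'
#' The fraction of sites with at least one detection across non-missing
#' visits, uncorrected for imperfect detection. Always at or below the
#' detection-corrected occupancy estimate in expectation.
#'
#' @param dataset a binary-mode [survey_data] object.
#' @return A proportion in \eqn{[0, 1]}.
#' @export
naive_poa <- function(dataset) {
  stopifnot(inherits(dataset, "survey_data"))
  if (dataset$mode != "binary")
    stop("naive_poa requires binary-mode data; binarize counts first ",
         "(e.g. survey_data(pmin(y, 1), ..., mode = 'binary'))")
  detected <- apply(dataset$y, 1, function(r) any(r == 1, na.rm = TRUE))
  mean(detected)
}

#' Beers aspect transformation
#'
#' Linearizes compass aspect into a moisture-exposure index
#' \eqn{\cos(45^\circ - A) + 1}, ranging from 0 on xeric southwest-facing
#' slopes to 2 on mesic northeast-facing slopes.
#'
#' @param aspect_degrees compass aspect in degrees (0 = north). Values
#'   outside \eqn{[0, 360)} are wrapped modulo 360 with a warning.
#' @return Values in \eqn{[0, 2]}.
#' @export
#' @examples
#' beers_aspect(c(45, 135, 225)) # 2, 1, 0
beers_aspect <- function(aspect_degrees) {
  if (any(aspect_degrees < 0 | aspect_degrees >= 360, na.rm = TRUE)) {
    warning("aspect outside [0, 360) wrapped modulo 360")
    aspect_degrees <- aspect_degrees %% 360
  }
  cos((45 - aspect_degrees) * pi / 180) + 1
}

#' Select the TPI neighborhood scale most correlated with counts
#'
#' Given Topographic Position Index values computed at several candidate
#' neighborhood scales, picks the scale whose TPI vector has the largest
#' absolute Pearson correlation with per-site mean counts. Ties break toward
#' the smallest scale; scales with zero variance are excluded with a warning.
#'
#' @param tpi_by_scale data frame or named list of numeric vectors, one per
#'   candidate scale, each of length \code{length(mean_counts)}. Names are
#'   parsed as numeric scales where possible (for the tie-break ordering).
#' @param mean_counts numeric vector of per-site mean counts.
#' @return A list with \code{scale} (the chosen name), \code{correlations}
#'   (the full table: scale, r, abs_r), and \code{r} (the winning
#'   correlation).
#' @export
select_tpi_scale <- function(tpi_by_scale, mean_counts) {
  tpi_by_scale <- as.list(tpi_by_scale)
  if (!length(tpi_by_scale)) stop("no candidate scales")
  if (is.null(names(tpi_by_scale)))
    names(tpi_by_scale) <- as.character(seq_along(tpi_by_scale))
  lens <- vapply(tpi_by_scale, length, integer(1))
  if (any(lens != length(mean_counts)))
    stop("every TPI vector must match length(mean_counts)")
  if (stats::sd(mean_counts) == 0)
    stop("mean_counts is constant; correlation undefined")
  r <- vapply(tpi_by_scale, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, mean_counts)
  }, numeric(1))
  if (anyNA(r))
    warning("constant TPI vector(s) excluded: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  tab <- data.frame(scale = names(r), r = r, abs_r = abs(r),
                    row.names = NULL, stringsAsFactors = FALSE)
  ok <- which(!is.na(r))
  if (!length(ok)) stop("all candidate scales excluded")
  num <- suppressWarnings(as.numeric(tab$scale))
  ord <- if (anyNA(num)) ok[order(-tab$abs_r[ok], ok)] else
    ok[order(-tab$abs_r[ok], num[ok])]
  best <- ord[1]
  list(scale = tab$scale[best], correlations = tab, r = tab$r[best])
}
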