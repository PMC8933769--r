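# SUVR computation and conversion to the Centiloid (CL) scale.
#
# The CL scale anchors amyloid burden across tracers and pipelines: 0 is the
# young amyloid-negative mean and 100 the typical AD level; individual values
# may fall outside [0, 100]. Conversion from SUVR is a published
# tracer-by-reference-region linear map, CL = intercept + slope * SUVR. The
# shipped calibration table holds the 14 published (tracer, reference)
# pairs; the remaining 6 combinations have no published conversion and
# requesting one is an explicit error.

TRACER_NAMES <- c("PiB", "florbetapir", "flutemetamol", "florbetaben", "NAV4694")

# CLI-facing short codes
TRACER_CODES <- c(pib = "PiB", fbp = "florbetapir", flute = "flutemetamol",
                  fbb = "florbetaben", nav = "NAV4694")
REFERENCE_CODES <- c(whlcbl = "WhlCbl", cerebgry = "CerebGry",
                     whlcblbrnstm = "WhlCblBrnStm", pons = "Pons")

#' The SUVR-to-Centiloid calibration table
#'
#' Published linear conversion coefficients per (tracer, reference region)
#' pair, shipped as a versioned CSV. Only the 14 published pairs are present.
#'
#' @param path Optional path to an alternative calibration CSV with columns
#'   `tracer,reference,intercept,slope`.
#' @return A tibble with those four columns.
#' @export
calibration_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "centiloid_calibration.csv",
                        package = "amypet", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tracer", "reference", "intercept", "slope") %in% names(tab)))
  if (any(tab$slope <= 0)) stop("calibration slopes must be positive")
  tibble::as_tibble(tab)
}

#' Look up one calibration
#' @param tracer Tracer name (`r paste(TRACER_NAMES, collapse = ", ")`) or
#'   short code (`pib`, `fbp`, `flute`, `fbb`, `nav`).
#' @param reference Reference region name or short code.
#' @param table Calibration table (default the shipped one).
#' @return List with `tracer`, `reference`, `intercept`, `slope`.
#' @export
get_calibration <- function(tracer, reference, table = calibration_table()) {
  tracer <- canon_tracer(tracer)
  reference <- canon_reference(reference)
  hit <- table$tracer == tracer & table$reference == reference
  if (!any(hit)) {
    stop(sprintf("no published conversion for tracer '%s' with reference '%s'",
                 tracer, reference))
  }
  row <- table[which(hit)[1], ]
  list(tracer = tracer, reference = reference,
       intercept = row$intercept, slope = row$slope)
}

canon_tracer <- function(x) {
  if (x %in% TRACER_NAMES) return(x)
  lx <- tolower(x)
  if (lx %in% names(TRACER_CODES)) return(unname(TRACER_CODES[lx]))
  hit <- match(lx, tolower(TRACER_NAMES))
  if (!is.na(hit)) return(TRACER_NAMES[hit])
  stop(sprintf("unknown tracer '%s'", x))
}

canon_reference <- function(x) {
  if (x %in% REFERENCE_NAMES) return(x)
  lx <- tolower(x)
  if (lx %in% names(REFERENCE_CODES)) return(unname(REFERENCE_CODES[lx]))
  hit <- match(lx, tolower(REFERENCE_NAMES))
  if (!is.na(hit)) return(REFERENCE_NAMES[hit])
  stop(sprintf("unknown reference region '%s'", x))
}

#' Compute the SUVR of a spatially standardized PET volume
#'
#' SUVR = mean count in the global cortical+striatal target VOI divided by
#' the mean count in the chosen reference VOI. The PET volume must already be
#' on the VOI grid (spatially standardized).
#'
#' @param pet_std `aq_vol` on the VOI grid.
#' @param vs An `aq_voiset`.
#' @param reference Reference region name.
#' @return A tibble row (class `aq_suvr`) with `target_name`,
#'   `reference_name`, `target_mean`, `reference_mean`, `suvr`.
#' @export
compute_suvr <- function(pet_std, vs, reference) {
  reference <- canon_reference(reference)
  stop_if_grid_mismatch(pet_std$grid, vs$grid, "PET and VOI set")
  tm <- mask_mean(pet_std, vs$target_mask)
  rm_ <- mask_mean(pet_std, vs$reference_masks[[reference]])
  if (rm_ <= 0) {
    stop(sprintf("non-positive reference mean (%.4g) in '%s': upstream normalization or masking failed",
                 rm_, reference))
  }
  out <- tibble::tibble(target_name = "ctx", reference_name = reference,
                        target_mean = tm, reference_mean = rm_,
                        suvr = tm / rm_)
  class(out) <- c("aq_suvr", class(out))
  out
}

#' Convert an SUVR to the Centiloid scale
#'
#' @param suvr SUVR value(s).
#' @param tracer,reference Tracer and reference region (a published pair).
#' @param table Calibration table.
#' @return A tibble (class `aq_cl`) with `tracer`, `reference`, `suvr`,
#'   `intercept`, `slope`, `cl`. CL is stored unrounded; round for display.
#' @export
suvr_to_centiloid <- function(suvr, tracer, reference,
                              table = calibration_table()) {
  cal <- get_calibration(tracer, reference, table)
  out <- tibble::tibble(tracer = cal$tracer, reference = cal$reference,
                        suvr = as.numeric(suvr),
                        intercept = cal$intercept, slope = cal$slope,
                        cl = cal$intercept + cal$slope * as.numeric(suvr))
  class(out) <- c("aq_cl", class(out))
  out
}

#' Invert the Centiloid conversion
#' @param cl CL value(s).
#' @inheritParams suvr_to_centiloid
#' @return SUVR value(s).
#' @export
centiloid_to_suvr <- function(cl, tracer, reference,
                              table = calibration_table()) {
  cal <- get_calibration(tracer, reference, table)
  (as.numeric(cl) - cal$intercept) / cal$slope
}

#' Validate computed CL values against reference CL values
#'
#' Ordinary least squares of computed on reference
#' (computed = intercept + slope * reference) with the squared Pearson
#' correlation, judged against the standard acceptance bands for a Centiloid
#' pipeline: slope in [0.98, 1.02], intercept in [-2, 2] CL, R^2 > 0.98.
#'
#' @param cl_computed,cl_reference Numeric vectors (>= 3 pairs; reference
#'   values must not be all equal).
#' @return An `aq_validation` list with `slope`, `intercept`, `r2`, the three
#'   pass flags, `n`, and the fitted `lm` object. Has [tidy()]/[glance()]
#'   methods and an [autoplot()].
#' @export
validate_against_reference <- function(cl_computed, cl_reference) {
  stopifnot(length(cl_computed) == length(cl_reference))
  ok <- is.finite(cl_computed) & is.finite(cl_reference)
  x <- cl_reference[ok]; y <- cl_computed[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("reference values are all equal; regression is degenerate")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- stats::cor(x, y)^2
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
    pass_slope = co[2] >= 0.98 && co[2] <= 1.02,
    pass_intercept = abs(co[1]) <= 2,
    pass_r2 = r2 > 0.98,
    n = length(x), fit = fit,
    data = tibble::tibble(reference = x, computed = y)
  ), class = "aq_validation")
}

#' @export
print.aq_validation <- function(x, ...) {
  cat(sprintf("<aq_validation> n=%d  slope=%.4f [%s]  intercept=%.3f CL [%s]  R2=%.4f [%s]\n",
              x$n, x$slope, if (x$pass_slope) "pass" else "FAIL",
              x$intercept, if (x$pass_intercept) "pass" else "FAIL",
              x$r2, if (x$pass_r2) "pass" else "FAIL"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy aq_validation
#' @export
tidy.aq_validation <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 band_low = c(-2, 0.98), band_high = c(2, 1.02),
                 pass = c(x$pass_intercept, x$pass_slope))
}

#' @method glance aq_validation
#' @export
glance.aq_validation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 pass_slope = x$pass_slope, pass_intercept = x$pass_intercept,
                 pass_r2 = x$pass_r2, n = x$n,
                 pass_all = x$pass_slope && x$pass_intercept && x$pass_r2)
}

#' @method autoplot aq_validation
#' @export
autoplot.aq_validation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$reference, y = .data$computed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Reference CL", y = "Computed CL",
                  title = sprintf("slope %.3f, intercept %.2f CL, R² %.4f",
                                  object$slope, object$intercept, object$r2)) +
    ggplot2::theme_minimal()
}
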