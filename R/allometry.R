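#' Leaf-area allometry model
#'
#' Linear model \code{area = intercept + slope * width * length} relating
#' planimeter-measured leaf area to the product of caliper width and
#' length measurements. Units are carried as given (the published
#' coefficients fix the scale) and never converted.
#'
#' \code{leaf_area_model()} constructs a model from known coefficients;
#' the published fit is \code{leaf_area_model(86, 0.63224)}.
#'
#' @param intercept area at width x length = 0.
#' @param slope coefficient on width x length; > 0 for a sensible fit.
#' @param r_squared optional goodness of fit in [0, 1].
#' @return object of class \code{leaf_area_model}.
#' @export
leaf_area_model <- function(intercept, slope, r_squared = NA_real_) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(intercept = intercept, slope = slope,
                 r_squared = r_squared),
            class = "leaf_area_model")
}

#' Fit the leaf-area allometry by ordinary least squares
#'
#' Regresses measured area on the single regressor width x length with an
#' intercept, using leaves measured with a leaf-area meter.
#'
#' @param leaves data.frame with columns \code{width}, \code{length},
#'   \code{area}; at least 3 rows, positive dimensions.
#' @return a [leaf_area_model()] with \code{r_squared}; the underlying
#'   \code{lm} fit is kept as attribute \code{"fit"}.
#' @export
#' @examples
#' wl <- expand.grid(width = 1:4, length = 10:14)
#' wl$area <- 86 + 0.63224 * wl$width * wl$length
#' fit_leaf_area(wl)  # recovers the generating coefficients
fit_leaf_area <- function(leaves) {
  stopifnot(is.data.frame(leaves),
            all(c("width", "length", "area") %in% names(leaves)))
  if (nrow(leaves) < 3) stop("need at least 3 leaves")
  if (any(leaves$width <= 0) || any(leaves$length <= 0))
    stop("widths and lengths must be positive")
  wl <- leaves$width * leaves$length
  if (stats::var(wl) == 0)
    stop("degenerate regressor: width x length is constant")
  fit <- stats::lm(area ~ wl, data = data.frame(area = leaves$area, wl = wl))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((leaves$area - mean(leaves$area))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0
  m <- leaf_area_model(unname(stats::coef(fit)[1]),
                       unname(stats::coef(fit)[2]), r2)
  attr(m, "fit") <- fit
  m
}

#' @export
print.leaf_area_model <- function(x, ...) {
  cat(sprintf("Leaf-area allometry: area = %.5g + %.5g * width * length",
              x$intercept, x$slope))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.leaf_area_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict leaf area from width and length
#'
#' @param model a [leaf_area_model()].
#' @param width,length non-negative leaf dimensions (vectors recycle).
#' @return predicted area(s).
#' @export
predict_leaf_area <- function(model, width, length) {
  stopifnot(inherits(model, "leaf_area_model"))
  if (any(width < 0) || any(length < 0))
    stop("leaf dimensions must be non-negative")
  model$intercept + model$slope * width * length
}

#' @export
predict.leaf_area_model <- function(object, newdata, ...) {
  predict_leaf_area(object, newdata$width, newdata$length)
}

#' Persist / restore a leaf-area model as JSON
#'
#' @param model a [leaf_area_model()].
#' @param path JSON file path.
#' @return \code{write_leaf_area_model} returns \code{path} invisibly;
#'   \code{read_leaf_area_model} returns the model.
#' @export
write_leaf_area_model <- function(model, path) {
  jsonlite::write_json(list(intercept = model$intercept, slope = model$slope,
                            r_squared = model$r_squared),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_leaf_area_model
#' @export
read_leaf_area_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  leaf_area_model(j$intercept, j$slope,
                  if (is.null(j$r_squared)) NA_real_ else j$r_squared)
}
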