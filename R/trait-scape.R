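#' Impute missing trait values by regularized iterative PCA
#'
#' Completes a replicate x trait matrix by alternating a low-rank PCA
#' reconstruction with re-imputation: missing cells are initialized at the
#' column means, the current completed matrix is centered (and optionally
#' scaled), its leading \code{n_components} singular values are shrunk by
#' the estimated noise variance (the mean of the discarded eigenvalues),
#' and the reconstruction re-fills the missing cells. Iteration stops when
#' successive imputations change by less than \code{tol} in Frobenius norm.
#' The shrinkage step keeps the fitted values away from overfitting the
#' observed cells, which plain iterative PCA is prone to.
#'
#' Observed entries are never modified.
#'
#' @param x numeric matrix (or data.frame of numerics) with NAs.
#' @param n_components rank of the reconstruction; 1 <= n_components <
#'   ncol(x). Default 2, the number of interpretable trait-scape
#'   dimensions.
#' @param max_iter iteration cap; non-convergence raises a warning and
#'   returns the last iterate.
#' @param tol Frobenius-norm convergence threshold on the imputed cells.
#' @param scale standardize columns to unit variance inside the iteration
#'   (recommended when traits are on different scales).
#' @return the completed numeric matrix.
#' @export
#' @examples
#' x <- outer(1:6, c(1, 2, 4))      # rank-1
#' x[2, 3] <- NA
#' impute_missing(x, n_components = 1)[2, 3]  # recovers 8
impute_missing <- function(x, n_components = 2, max_iter = 1000,
                           tol = 1e-8, scale = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  n <- nrow(x); p <- ncol(x)
  if (n_components < 1 || n_components >= p)
    stop("n_components must satisfy 1 <= n_components < ncol(x)")
  obs <- !is.na(x)
  if (any(colSums(obs) == 0))
    stop("column(s) entirely missing: ",
         paste(colnames(x)[colSums(obs) == 0], collapse = ", "))
  if (any(colSums(obs) < 2))
    stop("every trait column needs at least 2 observed values")
  if (all(obs)) return(x)

  mu0 <- colMeans(x, na.rm = TRUE)
  xc <- x
  xc[!obs] <- mu0[col(x)[!obs]]

  q <- min(n - 1, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- colMeans(xc)
    sg <- if (scale) apply(xc, 2, stats::sd) else rep(1, p)
    if (any(sg == 0)) sg[sg == 0] <- 1
    z <- sweep(sweep(xc, 2, mu), 2, sg, "/")
    sv <- svd(z, nu = q, nv = q)
    lambda <- sv$d[seq_len(q)]^2 / (n - 1)
    sigma2 <- if (n_components < q)
      mean(lambda[(n_components + 1):q]) else 0
    shrink <- pmax(lambda[seq_len(n_components)] - sigma2, 0) /
      lambda[seq_len(n_components)]
    shrink[!is.finite(shrink)] <- 0
    dstar <- sv$d[seq_len(n_components)] * shrink
    fit <- sv$u[, seq_len(n_components), drop = FALSE] %*%
      (dstar * t(sv$v[, seq_len(n_components), drop = FALSE]))
    fit <- sweep(sweep(fit, 2, sg, "*"), 2, mu, "+")
    new_imp <- fit[!obs]
    delta <- sqrt(sum((new_imp - xc[!obs])^2))
    xc[!obs] <- new_imp
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("imputation did not converge in ", max_iter,
            " iterations (last change ", format(delta), ")")
  xc
}

#' Fit the trait-scape ordination
#'
#' Principal component analysis of a completed replicate x trait matrix:
#' the score space ("trait-scape") in which the Euclidean-distance
#' plasticity indices are computed. Columns are centered and, by default,
#' scaled to unit variance (the traits mix micrometres, grams, square
#' millimetres, centimetres and counts, so correlation-matrix PCA is
#' used). All k = ncol(x) dimensions are retained: with all components
#' the score-space Euclidean distance equals the distance in
#' centered/scaled trait space, which is what makes the plasticity
#' indices well-defined. Loading signs are fixed by making each column's
#' largest-magnitude element positive, so scores are reproducible.
#'
#' @param x complete numeric matrix/data.frame, >= ncol(x) + 1 rows.
#' @param scale logical; standardize traits to unit variance (default).
#' @return object of class \code{trait_scape} with elements
#'   \code{scores} (n x k), \code{loadings} (p x k), \code{explained_variance},
#'   \code{sdev}, \code{center}, \code{scale}, \code{k}, \code{traits}.
#' @seealso [predict.trait_scape()] to project new rows,
#'   [plot.trait_scape()] for the biplot.
#' @export
trait_scape <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains missing values; run impute_missing() first")
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 replicates")
  if (n - 1 < p)
    stop("need at least ncol(x) + 1 rows to span all ", p, " dimensions")
  if (is.null(colnames(x))) colnames(x) <- paste0("trait", seq_len(p))
  sds <- apply(x, 2, stats::sd)
  if (scale && any(sds == 0))
    stop("zero-variance trait(s) cannot be scaled: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  rot <- pc$rotation
  sc <- pc$x
  # deterministic sign convention
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = sc, loadings = rot,
                 explained_variance = ev, sdev = pc$sdev,
                 center = pc$center,
                 scale = if (scale) pc$scale else FALSE,
                 k = ncol(sc), traits = colnames(x)),
            class = "trait_scape")
}

#' @export
print.trait_scape <- function(x, ...) {
  cat(sprintf("Trait-scape ordination: %d replicates x %d traits\n",
              nrow(x$scores), length(x$traits)))
  cat("Explained variance (%):",
      paste(sprintf("%s %.1f", colnames(x$scores),
                    100 * x$explained_variance), collapse = ", "), "\n")
  cat(sprintf("First two dimensions explain %.1f%% of trait variation\n",
              100 * sum(x$explained_variance[1:min(2, x$k)])))
  invisible(x)
}

#' @export
summary.trait_scape <- function(object, ...) {
  tab <- rbind(`Standard deviation` = object$sdev,
               `Proportion of Variance` = object$explained_variance,
               `Cumulative Proportion` = cumsum(object$explained_variance))
  colnames(tab) <- colnames(object$scores)
  cat("Trait-scape ordination of", length(object$traits), "traits\n")
  print(round(tab, 4))
  cat("\nLoadings:\n")
  print(round(object$loadings, 3))
  invisible(tab)
}

#' Project new trait rows into a fitted trait-scape
#'
#' Applies the stored centering/scaling and rotation; projecting the
#' training rows returns the training scores, projecting the column-mean
#' row returns the origin.
#'
#' @param object a [trait_scape()] fit.
#' @param newdata matrix/data.frame with the same trait columns, complete.
#' @param ... unused.
#' @return score matrix with \code{k} columns.
#' @export
predict.trait_scape <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  if (is.null(colnames(nd))) {
    if (ncol(nd) != length(object$traits))
      stop("newdata must have the ", length(object$traits), " trait columns")
    colnames(nd) <- object$traits
  }
  if (!all(object$traits %in% colnames(nd)))
    stop("newdata is missing trait(s): ",
         paste(setdiff(object$traits, colnames(nd)), collapse = ", "))
  nd <- nd[, object$traits, drop = FALSE]
  if (anyNA(nd)) stop("newdata contains missing values")
  z <- sweep(nd, 2, object$center)
  if (!identical(object$scale, FALSE)) z <- sweep(z, 2, object$scale, "/")
  z %*% object$loadings
}

#' Trait-scape biplot
#'
#' Scores on two ordination dimensions with trait-loading arrows; points
#' can be coloured by an experimental grouping (e.g. individual x
#' treatment).
#'
#' @param x a [trait_scape()] fit.
#' @param dims two dimensions to display.
#' @param groups optional factor colouring the replicates.
#' @param arrow_scale multiplier for the loading arrows.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.trait_scape <- function(x, dims = c(1, 2), groups = NULL,
                             arrow_scale = NULL, ...) {
  sc <- x$scores[, dims, drop = FALSE]
  ld <- x$loadings[, dims, drop = FALSE]
  if (is.null(arrow_scale))
    arrow_scale <- 0.8 * min(apply(abs(sc), 2, max) / apply(abs(ld), 2, max))
  col <- if (is.null(groups)) "grey30" else
    grDevices::hcl.colors(nlevels(as.factor(groups)), "Dark 3")[as.factor(groups)]
  lab <- sprintf("Dim %d (%.1f%%)", dims, 100 * x$explained_variance[dims])
  graphics::plot(sc, col = col, pch = 16, xlab = lab[1], ylab = lab[2], ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::arrows(0, 0, arrow_scale * ld[, 1], arrow_scale * ld[, 2],
                   length = 0.08, col = "grey40")
  graphics::text(1.08 * arrow_scale * ld[, 1], 1.08 * arrow_scale * ld[, 2],
                 rownames(ld), cex = 0.8, col = "grey20")
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(as.factor(groups)),
                     col = grDevices::hcl.colors(nlevels(as.factor(groups)), "Dark 3"),
                     pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}

#' Assemble the trait matrix used for the ordination
#'
#' Extracts the six functional traits (stomatal length, root:shoot ratio,
#' leaf area, stem height, stem diameter, stem density) from a trait
#' record table, restricted to surviving pots.
#'
#' @param records trait record table (see [generate_greenhouse()]).
#' @param traits trait columns to use.
#' @return list with \code{x} (numeric matrix, possibly with NAs) and
#'   \code{records} (the matching surviving rows).
#' @export
trait_matrix <- function(records,
                         traits = c("stomatal_length", "root_shoot_ratio",
                                    "leaf_area", "stem_height",
                                    "stem_diameter", "stem_density")) {
  if (!nrow(records)) stop("empty trait table")
  if ("survived" %in% names(records))
    records <- records[records$survived, , drop = FALSE]
  if (!nrow(records)) stop("no surviving pots in the trait table")
  miss <- setdiff(traits, names(records))
  if (length(miss)) stop("trait column(s) not found: ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(records[, traits, drop = FALSE])
  rownames(x) <- records$pot_id
  list(x = x, records = records)
}
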