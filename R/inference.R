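#' Box-Cox power transformation with profile-likelihood lambda
#'
#' Applies (y^lambda - 1)/lambda, with the lambda -> 0 limit log(y).
#' When \code{lambda} is not supplied it is chosen to maximize the
#' profile log-likelihood of the normal model for the transformed
#' responses, evaluated on a grid (default [-2, 2] in steps of 0.01)
#' followed by one quadratic refinement through the three points around
#' the grid maximum.
#'
#' @param y strictly positive numeric responses.
#' @param lambda fixed exponent; \code{NULL} (default) estimates it.
#' @param grid candidate lambda grid for the profile search.
#' @return object of class \code{boxcox_transform}: \code{lambda},
#'   \code{y}, \code{transformed}, \code{method}.
#' @seealso [inv_boxcox()] for the inverse transform.
#' @export
#' @examples
#' bc <- boxcox_transform(rlnorm(500))
#' bc$lambda  # near 0 for lognormal data
boxcox_transform <- function(y, lambda = NULL, grid = seq(-2, 2, by = 0.01)) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("Box-Cox requires strictly positive responses")
  apply_bc <- function(y, l)
    if (abs(l) < 1e-6) log(y) else (y^l - 1) / l
  if (is.null(lambda)) {
    n <- length(y)
    slog <- sum(log(y))
    prof <- function(l) {
      z <- apply_bc(y, l)
      s2 <- mean((z - mean(z))^2)
      -n / 2 * log(s2) + (l - 1) * slog
    }
    ll <- vapply(grid, prof, numeric(1))
    i <- which.max(ll)
    lambda <- grid[i]
    if (i > 1 && i < length(grid)) {
      # quadratic refinement through the three points around the maximum
      x3 <- grid[(i - 1):(i + 1)]; y3 <- ll[(i - 1):(i + 1)]
      denom <- (y3[1] - 2 * y3[2] + y3[3])
      if (denom < 0) {
        cand <- x3[2] - (x3[2] - x3[1]) * (y3[3] - y3[1]) / (2 * denom)
        if (is.finite(cand) && prof(cand) >= ll[i]) lambda <- cand
      }
    }
  }
  structure(list(lambda = lambda, y = y,
                 transformed = apply_bc(y, lambda),
                 method = "profile-likelihood ML"),
            class = "boxcox_transform")
}

#' Inverse Box-Cox transform
#'
#' @param z transformed values.
#' @param lambda the exponent used in the forward transform.
#' @return the original-scale values.
#' @export
inv_boxcox <- function(z, lambda) {
  if (abs(lambda) < 1e-6) exp(z) else (lambda * z + 1)^(1 / lambda)
}

#' @export
print.boxcox_transform <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.4f (%s), n = %d\n",
              x$lambda, x$method, length(x$y)))
  invisible(x)
}

#' Three-way factorial ANOVA of a trait response
#'
#' Evaluates the cytotype response to drought and elevated CO2 with the
#' full-factorial fixed-effects model
#' \code{response ~ cytotype * (water * co2)} and sequential (type I)
#' sums of squares in that term order. Pot-level measurements are first
#' averaged to one value per individual x treatment combination among
#' surviving pots (the unit of replication is the individual replicate),
#' the response is Box-Cox transformed unless \code{transform = FALSE} or
#' a fixed lambda is given, and Tukey HSD post hoc comparisons plus
#' Shapiro-Wilk / Brown-Forsythe Levene assumption checks are attached.
#'
#' @param records trait record table (see [generate_greenhouse()]).
#' @param response name of the response column.
#' @param transform \code{TRUE} (estimate lambda), \code{FALSE} (raw
#'   response), or a numeric lambda.
#' @param aggregate average pots to individual x treatment means first
#'   (default); set \code{FALSE} to analyse pot-level data.
#' @return object of class \code{anova_result}.
#' @export
factorial_anova <- function(records, response, transform = TRUE,
                            aggregate = TRUE) {
  if (!response %in% names(records)) stop("unknown response: ", response)
  if ("survived" %in% names(records))
    records <- records[records$survived, , drop = FALSE]
  records <- records[!is.na(records[[response]]), , drop = FALSE]
  if (!nrow(records)) stop("no usable records for response ", response)
  for (f in c("cytotype", "water", "co2"))
    if (length(unique(records[[f]])) < 2)
      stop("factor ", f, " needs 2 levels in the data")

  if (aggregate) {
    agg <- stats::aggregate(records[[response]],
                            by = list(individual = records$individual,
                                      cytotype = records$cytotype,
                                      water = records$water,
                                      co2 = records$co2),
                            FUN = mean)
    names(agg)[5] <- "y"
    d <- agg
  } else {
    d <- data.frame(individual = records$individual,
                    cytotype = records$cytotype, water = records$water,
                    co2 = records$co2, y = records[[response]],
                    stringsAsFactors = FALSE)
  }
  n_cells <- with(d, table(cytotype, water, co2))
  if (any(n_cells == 0))
    warning("empty design cell(s); sequential sums of squares retained")

  bc <- NULL
  if (isTRUE(transform)) {
    bc <- boxcox_transform(d$y)
    d$y <- bc$transformed
  } else if (is.numeric(transform)) {
    bc <- boxcox_transform(d$y, lambda = transform)
    d$y <- bc$transformed
  }
  d$cytotype <- factor(d$cytotype, levels = c("hybrid", "allopolyploid"))
  d$water <- factor(d$water, levels = c("well-watered", "drought"))
  d$co2 <- factor(d$co2, levels = c("ambient", "elevated"))

  fit <- stats::aov(y ~ cytotype * (water * co2), data = d)
  if (stats::df.residual(fit) < 1)
    stop("zero residual degrees of freedom")
  st <- summary(fit)[[1]]
  terms <- trimws(rownames(st))
  tab <- data.frame(term = terms, df = st$Df, sumsq = st$`Sum Sq`,
                    meansq = st$`Mean Sq`, F = st$`F value`,
                    p = st$`Pr(>F)`, stringsAsFactors = FALSE)
  groups <- interaction(d$cytotype, d$water, d$co2, drop = TRUE)
  checks <- assumption_checks(stats::residuals(fit), groups)
  structure(list(terms = tab[tab$term != "Residuals", ],
                 residual = tab[tab$term == "Residuals", ],
                 posthoc = stats::TukeyHSD(fit),
                 assumption_checks = checks,
                 transform = bc, response = response,
                 data = d, fit = fit),
            class = "anova_result")
}

#' One-way ANOVA with Tukey HSD
#'
#' Compares index values (e.g. trait-variation index across individuals,
#' MVPi across cytotypes) across groups.
#'
#' @param values numeric response values.
#' @param group factor/character group labels, >= 2 groups.
#' @return an \code{anova_result}.
#' @export
one_way_anova <- function(values, group) {
  group <- as.factor(group)
  keep <- !is.na(values)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2) stop("need at least 2 groups")
  d <- data.frame(y = values, group = group)
  fit <- stats::aov(y ~ group, data = d)
  st <- summary(fit)[[1]]
  terms <- trimws(rownames(st))
  tab <- data.frame(term = terms, df = st$Df, sumsq = st$`Sum Sq`,
                    meansq = st$`Mean Sq`, F = st$`F value`,
                    p = st$`Pr(>F)`, stringsAsFactors = FALSE)
  checks <- if (min(table(group)) >= 3 && length(values) >= 3 &&
                stats::var(values) > 0)
    tryCatch(assumption_checks(stats::residuals(fit), group),
             error = function(e) NULL) else NULL
  structure(list(terms = tab[tab$term != "Residuals", ],
                 residual = tab[tab$term == "Residuals", ],
                 posthoc = stats::TukeyHSD(fit),
                 assumption_checks = checks,
                 transform = NULL, response = deparse(substitute(values)),
                 data = d, fit = fit),
            class = "anova_result")
}

#' Tukey HSD pairwise table
#'
#' Studentized-range-adjusted pairwise comparisons from a fitted ANOVA.
#'
#' @param x an \code{anova_result} (or \code{aov} fit).
#' @param which model term(s); default all.
#' @return data.frame with term, pair, difference, CI bounds and adjusted
#'   p value.
#' @export
tukey_hsd <- function(x, which = NULL) {
  fit <- if (inherits(x, "anova_result")) x$fit else x
  tk <- if (is.null(which)) stats::TukeyHSD(fit) else
    stats::TukeyHSD(fit, which = which)
  do.call(rbind, lapply(names(tk), function(term) {
    m <- tk[[term]]
    data.frame(term = term, pair = rownames(m), diff = m[, "diff"],
               lwr = m[, "lwr"], upr = m[, "upr"], p_adj = m[, "p adj"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk on the residuals and Levene's test on absolute deviations
#' from group medians (the robust Brown-Forsythe variant).
#'
#' @param residuals model residuals (3 <= n <= 5000 for Shapiro-Wilk).
#' @param groups factor of group membership for the Levene test.
#' @return data.frame with one row per check: statistic, df, p value.
#' @export
assumption_checks <- function(residuals, groups) {
  n <- length(residuals)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk supports 3 <= n <= 5000 (n = ", n, ")")
  sw <- stats::shapiro.test(residuals)
  lv <- car::leveneTest(residuals ~ as.factor(groups), center = stats::median)
  data.frame(check = c("shapiro_wilk", "levene_brown_forsythe"),
             statistic = c(unname(sw$statistic), lv$`F value`[1]),
             df = c(NA, lv$Df[1]),
             p = c(sw$p.value, lv$`Pr(>F)`[1]),
             stringsAsFactors = FALSE)
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA (sequential sums of squares)")
  if (!is.null(x$transform))
    cat(sprintf(", Box-Cox lambda = %.3f", x$transform$lambda))
  cat("\nResponse:", x$response, "\n\n")
  tab <- rbind(x$terms, x$residual)
  tab$sumsq <- signif(tab$sumsq, 5); tab$meansq <- signif(tab$meansq, 5)
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$assumption_checks)) {
    cat("\nAssumption checks:\n")
    print(transform(x$assumption_checks, statistic = round(statistic, 4),
                    p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Relative change of a treatment mean against a reference mean
#'
#' Percent change of (for example) drought biomass against the
#' well-watered reference taken as 100%, rounded to the nearest integer
#' percent for reporting; the unrounded value is kept as attribute
#' \code{"raw"}.
#'
#' @param reference_mean reference (100%) mean; must be > 0.
#' @param treatment_mean treatment mean.
#' @param digits decimals of the reported percentage.
#' @return signed percent change (negative = decrease).
#' @export
#' @examples
#' relative_decrease(13.8, 5.9)  # -57
relative_decrease <- function(reference_mean, treatment_mean, digits = 0) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference mean must be positive")
  raw <- 100 * (treatment_mean - reference_mean) / reference_mean
  structure(round_half_up(raw, digits), raw = raw)
}

#' Interaction plot of cell means
#'
#' Cell means with standard-error whiskers by cytotype across the water x
#' CO2 treatment combinations, one panel style line per cytotype.
#'
#' @param records trait record table.
#' @param response trait column to plot.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the cell-mean table.
#' @export
interaction_plot <- function(records, response, ...) {
  if ("survived" %in% names(records))
    records <- records[records$survived, , drop = FALSE]
  records <- records[!is.na(records[[response]]), , drop = FALSE]
  cell <- interaction(records$water, records$co2, sep = " x ")
  mtab <- tapply(records[[response]], list(records$cytotype, cell), mean)
  setab <- tapply(records[[response]], list(records$cytotype, cell), function(v)
    stats::sd(v) / sqrt(length(v)))
  xs <- seq_len(ncol(mtab))
  graphics::plot(range(xs), range(c(mtab - setab, mtab + setab), na.rm = TRUE),
                 type = "n", xaxt = "n", xlab = "treatment combination",
                 ylab = response, ...)
  graphics::axis(1, at = xs, labels = colnames(mtab), cex.axis = 0.8)
  for (r in seq_len(nrow(mtab))) {
    off <- (r - mean(seq_len(nrow(mtab)))) * 0.05
    graphics::lines(xs + off, mtab[r, ], type = "b", pch = 15 + r, lty = r)
    graphics::arrows(xs + off, mtab[r, ] - setab[r, ], xs + off,
                     mtab[r, ] + setab[r, ], angle = 90, code = 3,
                     length = 0.04)
  }
  graphics::legend("topright", legend = rownames(mtab), pch = 15 + seq_len(nrow(mtab)),
                   lty = seq_len(nrow(mtab)), bty = "n", cex = 0.8)
  invisible(mtab)
}
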