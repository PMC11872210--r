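#' Euclidean distance between two score vectors
#'
#' The elementary distance of the plasticity indices: all k ordination
#' dimensions enter (k = number of evaluated traits), so the distance
#' equals the distance in centered/scaled trait space.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("score vectors differ in length (", length(x), " vs ", length(y), ")")
  sqrt(sum((x - y)^2))
}

#' Multivariate plasticity index (MVPi)
#'
#' Mean Euclidean distance over all cross-environment pairs of technical
#' replicates of the same genotype: n ambient replicates x m treatment
#' replicates give n*m distances whose arithmetic mean is the index.
#' Within-environment pairs never enter.
#'
#' @param ambient_scores numeric matrix, one row per ambient replicate.
#' @param treatment_scores numeric matrix, one row per treatment
#'   replicate (same number of columns).
#' @return scalar mean distance with attributes \code{n} and \code{m}.
#' @export
#' @examples
#' mvpi(rbind(c(0, 0), c(0, 2)), rbind(c(3, 0), c(3, 2)))  # 3.3028
mvpi <- function(ambient_scores, treatment_scores) {
  a <- rbind(ambient_scores)
  b <- rbind(treatment_scores)
  if (!nrow(a) || !nrow(b))
    stop("both environments need at least one replicate")
  if (ncol(a) != ncol(b)) stop("score dimensions differ")
  ed <- vapply(seq_len(nrow(a)), function(i)
    vapply(seq_len(nrow(b)), function(j)
      euclidean_distance(a[i, ], b[j, ]), numeric(1)),
    numeric(nrow(b)))
  structure(mean(ed), n = nrow(a), m = nrow(b))
}

#' Plant trait-variation index
#'
#' Similarity of trait expression among replicates grown in the ambient
#' environment: for each individual, the mean Euclidean distance of its
#' ambient replicates to the centroid of all ambient replicates pooled
#' across individuals (the centre of the ordination).
#'
#' @param ambient_scores numeric matrix of ambient-environment score rows.
#' @param individual factor/character vector assigning each row to an
#'   individual.
#' @return named numeric vector, one index per individual.
#' @export
trait_variation_index <- function(ambient_scores, individual) {
  a <- rbind(ambient_scores)
  if (!nrow(a)) stop("no ambient replicates supplied")
  individual <- as.character(individual)
  if (length(individual) != nrow(a))
    stop("individual must label every score row")
  centroid <- colMeans(a)
  dists <- vapply(seq_len(nrow(a)), function(i)
    euclidean_distance(a[i, ], centroid), numeric(1))
  vapply(split(dists, individual), mean, numeric(1))
}

#' Default treatment contrasts of the experiment
#'
#' Each treatment combination against the ambient reference cell
#' (well-watered x ambient CO2), plus the CO2-level contrast within the
#' drought treatment (the elevated-vs-ambient CO2 contrast within
#' well-watered water supply is the \code{WW.eCO2} row).
#'
#' @return named list of \code{list(treatment =, reference =)} cells,
#'   each cell a named character vector \code{c(water =, co2 =)}.
#' @export
default_contrasts <- function() {
  ww_a <- c(water = "well-watered", co2 = "ambient")
  list(
    "DR.aCO2 vs WW.aCO2" = list(treatment = c(water = "drought", co2 = "ambient"),
                                reference = ww_a),
    "WW.eCO2 vs WW.aCO2" = list(treatment = c(water = "well-watered", co2 = "elevated"),
                                reference = ww_a),
    "DR.eCO2 vs WW.aCO2" = list(treatment = c(water = "drought", co2 = "elevated"),
                                reference = ww_a),
    "DR.eCO2 vs DR.aCO2" = list(treatment = c(water = "drought", co2 = "elevated"),
                                reference = c(water = "drought", co2 = "ambient"))
  )
}

#' Plasticity indices per individual and cytotype for a set of contrasts
#'
#' Assembles, for every grouping unit and requested treatment contrast,
#' the cross-environment replicate distances and their mean (the MVPi).
#' Per-individual indices are always computed; cytotype-level indices are
#' reported in both defensible aggregations: pooling all replicates of a
#' cytotype (\code{mvpi_pooled}) and averaging the per-individual indices
#' (\code{mvpi_mean_individual}). Non-surviving pots are excluded; a group
#' with no replicates in the reference cell yields NA (missing, not zero).
#'
#' @param scape a [trait_scape()] fit, or a score matrix.
#' @param records data.frame aligned row-by-row with the score rows,
#'   providing \code{individual}, \code{cytotype}, \code{water},
#'   \code{co2} and optionally \code{survived}.
#' @param contrasts list as returned by [default_contrasts()].
#' @return object of class \code{plasticity_result}: \code{ed_pairs},
#'   \code{mvpi_individual}, \code{mvpi_cytotype}.
#' @export
plasticity_by_contrast <- function(scape, records,
                                   contrasts = default_contrasts()) {
  scores <- if (inherits(scape, "trait_scape")) scape$scores else as.matrix(scape)
  if (nrow(scores) != nrow(records))
    stop("records must align with the score rows")
  need <- c("individual", "cytotype", "water", "co2")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if ("survived" %in% names(records)) {
    keep <- records$survived
    scores <- scores[keep, , drop = FALSE]
    records <- records[keep, , drop = FALSE]
  }
  if (!nrow(records)) stop("no surviving records to analyse")

  cell_rows <- function(sub, cell)
    which(sub$water == cell[["water"]] & sub$co2 == cell[["co2"]])

  ed_pairs <- list(); ind_rows <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    for (ind in unique(records$individual)) {
      sub_i <- which(records$individual == ind)
      sub <- records[sub_i, , drop = FALSE]
      ref <- sub_i[cell_rows(sub, ct$reference)]
      trt <- sub_i[cell_rows(sub, ct$treatment)]
      cy <- sub$cytotype[1]
      if (!length(ref) || !length(trt)) {
        ind_rows[[length(ind_rows) + 1]] <- data.frame(
          individual = ind, cytotype = cy, contrast = cn,
          mvpi = NA_real_, n = length(ref), m = length(trt),
          stringsAsFactors = FALSE)
        next
      }
      pair <- expand.grid(x = ref, y = trt)
      pair$ed <- vapply(seq_len(nrow(pair)), function(r)
        euclidean_distance(scores[pair$x[r], ], scores[pair$y[r], ]),
        numeric(1))
      ed_pairs[[length(ed_pairs) + 1]] <- data.frame(
        individual = ind, cytotype = cy, contrast = cn,
        ambient_pot = rownames(scores)[pair$x] %||% pair$x,
        treatment_pot = rownames(scores)[pair$y] %||% pair$y,
        ed = pair$ed, stringsAsFactors = FALSE)
      ind_rows[[length(ind_rows) + 1]] <- data.frame(
        individual = ind, cytotype = cy, contrast = cn,
        mvpi = mean(pair$ed), n = length(ref), m = length(trt),
        stringsAsFactors = FALSE)
    }
  }
  ed_pairs <- do.call(rbind, ed_pairs)
  mvpi_ind <- do.call(rbind, ind_rows)
  rownames(mvpi_ind) <- NULL

  cyt_rows <- list()
  for (cn in names(contrasts)) {
    for (cy in unique(records$cytotype)) {
      sel <- ed_pairs$contrast == cn & ed_pairs$cytotype == cy
      ii <- mvpi_ind$contrast == cn & mvpi_ind$cytotype == cy
      cyt_rows[[length(cyt_rows) + 1]] <- data.frame(
        cytotype = cy, contrast = cn,
        mvpi_pooled = if (any(sel)) mean(ed_pairs$ed[sel]) else NA_real_,
        mvpi_mean_individual = mean(mvpi_ind$mvpi[ii], na.rm = TRUE),
        n_pairs = sum(sel), stringsAsFactors = FALSE)
    }
  }
  mvpi_cyt <- do.call(rbind, cyt_rows)
  rownames(mvpi_cyt) <- NULL
  structure(list(ed_pairs = ed_pairs, mvpi_individual = mvpi_ind,
                 mvpi_cytotype = mvpi_cyt),
            class = "plasticity_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plasticity_result <- function(x, ...) {
  cat("Multivariate plasticity indices (mean cross-environment Euclidean distance)\n")
  cat("\nPer cytotype:\n")
  print(transform(x$mvpi_cytotype,
                  mvpi_pooled = round(mvpi_pooled, 3),
                  mvpi_mean_individual = round(mvpi_mean_individual, 3)),
        row.names = FALSE)
  cat("\nPer individual (first rows):\n")
  print(utils::head(transform(x$mvpi_individual, mvpi = round(mvpi, 3)), 12),
        row.names = FALSE)
  invisible(x)
}

#' Bar chart of plasticity indices
#'
#' Mean index per group with standard-error whiskers, one bar group per
#' treatment contrast.
#'
#' @param x a \code{plasticity_result}.
#' @param level \code{"cytotype"} (per-individual MVPi averaged within
#'   cytotype, SE across individuals) or \code{"individual"}.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted mean matrix.
#' @export
plot.plasticity_result <- function(x, level = c("cytotype", "individual"), ...) {
  level <- match.arg(level)
  d <- x$mvpi_individual
  g <- if (level == "cytotype") d$cytotype else d$individual
  mtab <- tapply(d$mvpi, list(g, d$contrast), mean, na.rm = TRUE)
  setab <- tapply(d$mvpi, list(g, d$contrast), function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  top <- max(c(mtab + setab, mtab)[is.finite(c(mtab + setab, mtab))])
  bp <- graphics::barplot(mtab, beside = TRUE, ylab = "MVPi (mean ED)",
                          legend.text = rownames(mtab),
                          ylim = c(0, 1.25 * top),
                          las = 2, cex.names = 0.7, ...)
  ok <- is.finite(mtab) & is.finite(setab) & setab > 0
  graphics::arrows(bp[ok], (mtab - setab)[ok], bp[ok], (mtab + setab)[ok],
                   angle = 90, code = 3, length = 0.04)
  invisible(mtab)
}
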