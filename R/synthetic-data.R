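#' Greenhouse design specification
#'
#' Describes the full-factorial greenhouse design: clonal donor individuals
#' (each with a cytotype), two water-availability levels, two atmospheric
#' CO2 levels, a fixed number of ramets (pots, technical replicates) per
#' individual x treatment cell, and end-of-experiment dropout counts.
#' The default reproduces the study design: 6 individuals (H1-H3 hybrid,
#' A1-A3 allopolyploid) x 2 x 2 x 6 replicates = 144 pots, of which 21
#' died or senesced and 9 were removed for other experiments, leaving
#' n = 114 for analysis.
#'
#' @param individuals data.frame with columns \code{id} and \code{cytotype}
#'   (\code{"hybrid"} or \code{"allopolyploid"}).
#' @param replicates_per_cell pots per individual x water x CO2 cell.
#' @param dropout integer vector \code{c(dead = , removed = )}: pots flagged
#'   dead/senescent and pots removed from the experiment.
#' @param seed integer seed driving all randomness of the generator.
#' @return an object of class \code{design_spec}.
#' @export
#' @examples
#' d <- design_spec()
#' d$n_pots  # 144
design_spec <- function(individuals = data.frame(
                          id = c("H1", "H2", "H3", "A1", "A2", "A3"),
                          cytotype = rep(c("hybrid", "allopolyploid"), each = 3),
                          stringsAsFactors = FALSE
                        ),
                        replicates_per_cell = 6,
                        dropout = c(dead = 21, removed = 9),
                        seed = 1L) {
  stopifnot(is.data.frame(individuals),
            all(c("id", "cytotype") %in% names(individuals)),
            nrow(individuals) >= 1,
            replicates_per_cell >= 1)
  if (!all(individuals$cytotype %in% c("hybrid", "allopolyploid")))
    stop("cytotype must be 'hybrid' or 'allopolyploid'")
  dropout <- as.integer(dropout)
  if (length(dropout) != 2 || any(dropout < 0))
    stop("dropout must be two non-negative counts c(dead, removed)")
  n_pots <- nrow(individuals) * 2L * 2L * as.integer(replicates_per_cell)
  if (sum(dropout) > n_pots)
    stop("dropout counts exceed the total number of pots")
  structure(list(individuals = individuals,
                 water_levels = c("well-watered", "drought"),
                 co2_levels = c("ambient", "elevated"),
                 replicates_per_cell = as.integer(replicates_per_cell),
                 dropout = c(dead = dropout[1], removed = dropout[2]),
                 n_pots = n_pots,
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Trait distribution model for the synthetic generator
#'
#' Holds, for every (cytotype, water, CO2) cell and trait, the mean and SD
#' from which pot-level values are drawn, plus a per-trait missingness rate
#' (missing completely at random, injected among surviving pots only).
#'
#' @param cells data.frame with columns \code{cytotype}, \code{water},
#'   \code{co2}, \code{trait}, \code{mean}, \code{sd}.
#' @param missingness named numeric vector of per-trait missingness rates
#'   in [0, 1); traits absent from the vector default to 0.
#' @return an object of class \code{trait_model}.
#' @seealso [spartina_trait_model()] for the calibrated default.
#' @export
trait_model <- function(cells, missingness = numeric(0)) {
  stopifnot(is.data.frame(cells),
            all(c("cytotype", "water", "co2", "trait", "mean", "sd") %in% names(cells)))
  if (any(cells$sd < 0)) stop("SDs must be non-negative")
  if (any(cells$mean < 0)) stop("trait means must be non-negative")
  if (length(missingness) &&
      (any(missingness < 0) || any(missingness >= 1)))
    stop("missingness rates must lie in [0, 1)")
  structure(list(cells = cells, missingness = missingness),
            class = "trait_model")
}

#' The calibrated Spartina trait model
#'
#' Cell means and SDs anchored to the reported greenhouse results:
#' stomatal length 27.5 +/- 2.1 um (hybrid) vs 38.2 +/- 3.0 um
#' (allopolyploid), treatment-independent; total biomass 13.8 +/- 6.3 g
#' (hybrid, well-watered) dropping under drought, and 9.5 +/- 4.4 g
#' (allopolyploid, well-watered) dropping to 5.0 +/- 1.8 g; drought cell
#' means split by CO2 level so that the pooled drought decrease and the
#' control-vs-full-treatment decrease match the reported -57%/-52%
#' (hybrid) and -47%/-36% (allopolyploid). The remaining traits (root:shoot
#' ratio, leaf area, stem height, stem diameter, stem density) are given
#' field-realistic means with the reported qualitative structure: the
#' hybrid's root:shoot ratio peaks under well-watered x elevated CO2 and
#' drops under drought x elevated CO2 while the allopolyploid's is
#' treatment-insensitive, and the allopolyploid responds to elevated CO2
#' in size-related traits while the hybrid does not.
#'
#' @param missingness per-trait MCAR rates; the default leaves biomass
#'   complete and makes stomatal length (measured on a subset of stems)
#'   the most incomplete trait.
#' @return a [trait_model()].
#' @export
spartina_trait_model <- function(missingness = c(
                                   stomatal_length = 0.05,
                                   root_shoot_ratio = 0.02,
                                   leaf_area = 0.02,
                                   stem_height = 0.02,
                                   stem_diameter = 0.02,
                                   stem_density = 0.02,
                                   biomass = 0
                                 )) {
  grid <- expand.grid(cytotype = c("hybrid", "allopolyploid"),
                      water = c("well-watered", "drought"),
                      co2 = c("ambient", "elevated"),
                      stringsAsFactors = FALSE)
  cell_mean <- function(cy, wa, co, trait) {
    hy <- cy == "hybrid"; dr <- wa == "drought"; el <- co == "elevated"
    switch(trait,
      stomatal_length = if (hy) c(27.5, 2.1) else c(38.2, 3.0),
      biomass = if (hy) {
        if (!dr) c(13.8, 6.3) else if (el) c(6.6, 2.4) else c(5.2, 2.4)
      } else {
        if (!dr) c(9.5, 4.4) else if (el) c(6.1, 1.8) else c(3.9, 1.8)
      },
      root_shoot_ratio = if (hy) {
        if (!dr && el) c(1.4, 0.35) else if (dr && el) c(0.8, 0.25) else c(1.0, 0.3)
      } else c(0.9, 0.3),
      leaf_area = if (hy) {
        if (dr) c(1400, 450) else c(2600, 800)
      } else {
        if (dr) c(1300 + 400 * el, 450) else c(2200 + 400 * el, 700)
      },
      stem_height = if (hy) {
        if (dr) c(40, 8) else c(55, 10)
      } else {
        if (dr) c(45 + 5 * el, 9) else c(65 + 5 * el, 12)
      },
      stem_diameter = if (hy) c(3.0 - 0.5 * dr, 0.5) else c(4.5 - 0.5 * dr, 0.7),
      stem_density = if (hy) {
        if (dr) c(15, 5) else c(25, 8)
      } else {
        if (dr) c(8 + 3 * el, 3) else c(12 + 3 * el, 4)
      },
      stop("unknown trait: ", trait))
  }
  traits <- c("stomatal_length", "root_shoot_ratio", "leaf_area",
              "stem_height", "stem_diameter", "stem_density", "biomass")
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ms <- t(vapply(traits, function(tr)
      cell_mean(grid$cytotype[i], grid$water[i], grid$co2[i], tr), numeric(2)))
    data.frame(cytotype = grid$cytotype[i], water = grid$water[i],
               co2 = grid$co2[i], trait = traits,
               mean = ms[, 1], sd = ms[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  trait_model(cells, missingness)
}

#' Generate a synthetic greenhouse trait table
#'
#' Draws one record per pot of the full-factorial design, flags the
#' seeded dropout (dead/senescent and removed pots, chosen uniformly at
#' random), and injects missing trait values completely at random among
#' surviving pots. Positive-valued traits are drawn from a normal
#' truncated at zero; stem density is additionally rounded to a
#' non-negative integer.
#'
#' @param design a [design_spec()].
#' @param model a [trait_model()] covering every (cytotype, water, co2)
#'   cell of the design; missing cells raise a configuration error.
#' @return data.frame with one row per pot: \code{pot_id},
#'   \code{individual}, \code{cytotype}, \code{water}, \code{co2},
#'   \code{replicate}, \code{status} (\code{"survived"}, \code{"dead"},
#'   \code{"removed"}), logical \code{survived}, and the seven traits.
#' @export
#' @examples
#' rec <- generate_greenhouse(design_spec(seed = 7), spartina_trait_model())
#' table(rec$status)
generate_greenhouse <- function(design, model = spartina_trait_model()) {
  stopifnot(inherits(design, "design_spec"), inherits(model, "trait_model"))
  traits <- unique(model$cells$trait)
  # every design cell must be present in the model
  need <- expand.grid(cytotype = unique(design$individuals$cytotype),
                      water = design$water_levels, co2 = design$co2_levels,
                      stringsAsFactors = FALSE)
  have <- unique(model$cells[c("cytotype", "water", "co2")])
  key <- function(d) paste(d$cytotype, d$water, d$co2, sep = "|")
  missing_cells <- setdiff(key(need), key(have))
  if (length(missing_cells))
    stop("trait model does not cover design cell(s): ",
         paste(missing_cells, collapse = ", "))

  set.seed(design$seed)
  grid <- expand.grid(replicate = seq_len(design$replicates_per_cell),
                      co2 = design$co2_levels,
                      water = design$water_levels,
                      individual = design$individuals$id,
                      stringsAsFactors = FALSE)[, 4:1]
  grid$cytotype <- design$individuals$cytotype[
    match(grid$individual, design$individuals$id)]
  n <- nrow(grid)
  abbr <- c("well-watered" = "WW", "drought" = "DR",
            "ambient" = "aCO2", "elevated" = "eCO2")
  rec <- data.frame(
    pot_id = sprintf("%s_%s_%s_r%d", grid$individual, abbr[grid$water],
                     abbr[grid$co2], grid$replicate),
    individual = grid$individual, cytotype = grid$cytotype,
    water = grid$water, co2 = grid$co2, replicate = grid$replicate,
    stringsAsFactors = FALSE)

  # dropout: dead/senescent first, then removed, uniform among pots
  status <- rep("survived", n)
  drop_idx <- sample.int(n, sum(design$dropout))
  status[drop_idx[seq_len(design$dropout["dead"])]] <- "dead"
  if (design$dropout["removed"] > 0)
    status[drop_idx[design$dropout["dead"] + seq_len(design$dropout["removed"])]] <-
      "removed"
  rec$status <- status
  rec$survived <- status == "survived"

  cellkey <- paste(rec$cytotype, rec$water, rec$co2, sep = "|")
  mkey <- paste(model$cells$cytotype, model$cells$water, model$cells$co2,
                model$cells$trait, sep = "|")
  for (tr in traits) {
    mu <- model$cells$mean[match(paste(cellkey, tr, sep = "|"), mkey)]
    sg <- model$cells$sd[match(paste(cellkey, tr, sep = "|"), mkey)]
    val <- numeric(n)
    for (ck in unique(cellkey)) {
      idx <- which(cellkey == ck)
      val[idx] <- rtrunc0(length(idx), mu[idx[1]], sg[idx[1]])
    }
    if (tr == "stem_density") val <- pmax(0, round(val))
    rec[[tr]] <- val
  }
  # MCAR missingness among survivors only
  for (tr in traits) {
    rate <- if (tr %in% names(model$missingness)) model$missingness[[tr]] else 0
    if (rate > 0) {
      surv <- which(rec$survived)
      rec[[tr]][surv[stats::runif(length(surv)) < rate]] <- NA_real_
    }
  }
  rec
}

#' SSR locus definitions of the modal Wadden Sea genotype
#'
#' The eight microsatellite loci (MS02, MS07, MS13-MS18) with the allele
#' complement of the modal multilocus genotype (16 alleles in total) and,
#' per locus, the pool of low-frequency ("rare") allele sizes observed in
#' the population survey from which variant genotypes gain alleles.
#'
#' @return named list; each element has integer vectors \code{modal} and
#'   \code{pool}.
#' @export
spartina_loci <- function() {
  list(
    MS02 = list(modal = 268L,                   pool = 257L),
    MS07 = list(modal = c(257L, 273L),          pool = integer(0)),
    MS13 = list(modal = c(248L, 264L),          pool = 238L),
    MS14 = list(modal = 271L,                   pool = c(260L, 268L)),
    MS15 = list(modal = c(223L, 250L, 258L, 261L), pool = 242L),
    MS16 = list(modal = c(204L, 251L, 260L),    pool = integer(0)),
    MS17 = list(modal = c(264L, 273L),          pool = integer(0)),
    MS18 = list(modal = 260L,                   pool = c(245L, 250L, 280L, 288L))
  )
}

#' Generate a synthetic SSR genotype population
#'
#' Emulates a clonal population dominated by one multilocus genotype:
#' \code{round(dominant_fraction * n_samples)} samples carry the modal
#' allele complement exactly; each remaining sample, with probability
#' \code{rare_allele_rate}, differs from it by gaining 1-4 rare alleles
#' (drawn from the per-locus pools) or by losing 1-3 modal alleles.
#' \code{rare_allele_rate = 0} therefore yields a single multilocus
#' genotype.
#'
#' @param n_samples number of samples.
#' @param loci named list of locus specs as in [spartina_loci()].
#' @param dominant_fraction fraction of samples carrying the modal
#'   genotype, in (0, 1].
#' @param rare_allele_rate probability that a non-modal sample actually
#'   mutates away from the modal genotype.
#' @param cytotype cytotype label(s), recycled to \code{n_samples}.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample_id}, \code{cytotype},
#'   \code{origin}, and one slash-separated allele-size column per locus.
#' @export
#' @examples
#' pop <- generate_ssr(79, dominant_fraction = 0.557, seed = 3)
#' head(pop)
generate_ssr <- function(n_samples, loci = spartina_loci(),
                         dominant_fraction = 0.557, rare_allele_rate = 1,
                         cytotype = "allopolyploid", seed = 1L) {
  if (!length(loci)) stop("locus list must not be empty")
  stopifnot(n_samples >= 1, dominant_fraction > 0, dominant_fraction <= 1,
            rare_allele_rate >= 0, rare_allele_rate <= 1)
  set.seed(as.integer(seed))
  n_modal <- round(dominant_fraction * n_samples)
  variant <- rep(FALSE, n_samples)
  if (n_samples > n_modal)
    variant[sample.int(n_samples, n_samples - n_modal)] <- TRUE

  modal_tbl <- do.call(rbind, lapply(names(loci), function(lc)
    data.frame(locus = lc, size = loci[[lc]]$modal, stringsAsFactors = FALSE)))
  pool_tbl <- do.call(rbind, lapply(names(loci), function(lc)
    if (length(loci[[lc]]$pool))
      data.frame(locus = lc, size = loci[[lc]]$pool, stringsAsFactors = FALSE)))

  sets <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    g <- split(modal_tbl$size, modal_tbl$locus)
    if (variant[i] && stats::runif(1) < rare_allele_rate) {
      gain <- !is.null(pool_tbl) && stats::runif(1) < 0.5
      if (gain) {
        k <- min(sample.int(4L, 1), nrow(pool_tbl))
        add <- pool_tbl[sample.int(nrow(pool_tbl), k), , drop = FALSE]
        for (j in seq_len(nrow(add)))
          g[[add$locus[j]]] <- sort(unique(c(g[[add$locus[j]]], add$size[j])))
      } else {
        k <- min(sample.int(3L, 1), nrow(modal_tbl) - 1L)
        rm_idx <- sample.int(nrow(modal_tbl), k)
        for (j in rm_idx)
          g[[modal_tbl$locus[j]]] <-
            setdiff(g[[modal_tbl$locus[j]]], modal_tbl$size[j])
      }
    }
    sets[[i]] <- g
  }
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
                    cytotype = rep_len(cytotype, n_samples),
                    origin = NA_character_, stringsAsFactors = FALSE)
  for (lc in names(loci))
    out[[lc]] <- vapply(sets, function(g) format_alleles(g[[lc]]), character(1))
  out
}

#' Read / write the CSV interchange formats
#'
#' Trait tables are plain CSV, one row per pot; SSR tables serialize each
#' locus as slash-separated fragment sizes (e.g. \code{"223/250/258/261"}).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{read_*} return a data.frame; \code{write_*} return
#'   \code{path} invisibly.
#' @name traitscape-io
NULL

#' @rdname traitscape-io
#' @export
write_traits_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname traitscape-io
#' @export
read_traits_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("survived" %in% names(x)) x$survived <- as.logical(x$survived)
  x
}

#' @rdname traitscape-io
#' @export
write_ssr_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname traitscape-io
#' @export
read_ssr_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  x
}
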