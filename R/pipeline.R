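#' Pipeline configuration
#'
#' Assembles (or reads from YAML/JSON) the configuration driving
#' [run_pipeline()]: the design and seed for synthesis, stage toggles and
#' method parameters. Any field omitted falls back to the study defaults.
#'
#' @param seed integer seed for all stochastic stages (mandatory).
#' @param stages character subset of
#'   \code{c("synth", "ssr", "scape", "plasticity", "anova", "allometry")}.
#' @param design a [design_spec()] (its seed is overridden by \code{seed}).
#' @param model a [trait_model()].
#' @param ssr list of [generate_ssr()] arguments.
#' @param impute list of [impute_missing()] arguments (n_components,
#'   max_iter, tol, scale).
#' @param anova_responses trait columns to test with [factorial_anova()].
#' @param traits_csv,ssr_csv optional paths to existing input tables;
#'   required when \code{"synth"} is not among the stages.
#' @param figures write PNG figures alongside the tables.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("synth", "ssr", "scape", "plasticity",
                                       "anova", "allometry"),
                            design = design_spec(seed = seed),
                            model = spartina_trait_model(),
                            ssr = list(n_samples = 79, dominant_fraction = 0.557),
                            impute = list(n_components = 2),
                            anova_responses = c("stomatal_length",
                                                "root_shoot_ratio", "biomass"),
                            traits_csv = NULL, ssr_csv = NULL,
                            figures = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!length(seed)) stop("a seed is mandatory")
  if (!("synth" %in% stages)) {
    if (any(c("scape", "plasticity", "anova") %in% stages) &&
        (is.null(traits_csv) || !file.exists(traits_csv)))
      stop("traits_csv must exist when synthesis is disabled")
    if ("ssr" %in% stages && (is.null(ssr_csv) || !file.exists(ssr_csv)))
      stop("ssr_csv must exist when synthesis is disabled")
  }
  design$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), stages = stages, design = design,
                 model = model, ssr = ssr, impute = impute,
                 anova_responses = anova_responses,
                 traits_csv = traits_csv, ssr_csv = ssr_csv,
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The document mirrors the [pipeline_config()] arguments; unknown fields
#' are rejected.
#'
#' @param path path to a .yaml/.yml or .json document.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  args <- doc
  if (!is.null(args$design) && !inherits(args$design, "design_spec"))
    args$design <- do.call(design_spec, args$design)
  do.call(pipeline_config, args)
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[traitscape] ", fmt), ...))

#' Run the full analysis pipeline
#'
#' Chains the enabled stages -- synthesis, SSR genotype analysis,
#' imputation + trait-scape ordination, plasticity indices, factorial
#' ANOVA and the leaf-area allometry -- writing every intermediate table
#' as CSV into \code{out_dir} together with a machine-readable manifest
#' (seed, config hash, file checksums, record counts, versions). Re-runs
#' with the same configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()] or path to a YAML/JSON config.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- list()
  emit <- function(x, name, writer = utils::write.csv) {
    path <- file.path(out_dir, name)
    if (identical(writer, utils::write.csv)) writer(x, path, row.names = FALSE)
    else writer(x, path)
    files <<- c(files, name)
    path
  }

  # config snapshot + hash
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files <- c(files, "config.json")

  records <- ssr_tab <- NULL
  if ("synth" %in% config$stages) {
    t0 <- Sys.time()
    records <- generate_greenhouse(config$design, config$model)
    ssr_args <- config$ssr
    ssr_args$seed <- config$seed + 1L
    ssr_tab <- do.call(generate_ssr, ssr_args)
    emit(records, "traits.csv")
    emit(ssr_tab, "ssr_genotypes.csv")
    counts$pots_generated <- nrow(records)
    counts$pots_analyzed <- sum(records$survived)
    counts$ssr_samples <- nrow(ssr_tab)
    stage_log("synth: %d pots (%d surviving), %d SSR samples [%.2fs]",
              nrow(records), sum(records$survived), nrow(ssr_tab),
              as.numeric(Sys.time() - t0, units = "secs"))
  } else {
    if (!is.null(config$traits_csv)) {
      records <- read_traits_csv(config$traits_csv)
      counts$pots_generated <- nrow(records)
      counts$pots_analyzed <- if ("survived" %in% names(records))
        sum(records$survived) else nrow(records)
    }
    if (!is.null(config$ssr_csv)) ssr_tab <- read_ssr_csv(config$ssr_csv)
  }

  if ("ssr" %in% config$stages) {
    t0 <- Sys.time()
    if (is.null(ssr_tab)) stop("ssr stage: no SSR table available")
    binned <- bin_alleles(ssr_tab)
    gt <- call_multilocus_genotypes(binned)
    emit(gt$table, "genotype_table.csv")
    freq <- do.call(rbind, lapply(ssr_locus_columns(binned), function(lc)
      frequency_table(binned, lc)))
    emit(freq, "locus_frequencies.csv")
    reps <- genotype_representatives(binned, gt)
    d <- dissimilarity_matrix(reps)
    msn <- minimum_spanning_network(
      d, node_counts = stats::setNames(gt$table$n, gt$table$label))
    emit(msn, "msn_edges.csv", write_msn_edges)
    emit(msn, "msn.graphml", write_msn_graphml)
    counts$genotypes <- gt$n_genotypes
    stage_log("ssr: %d genotypes, MST weight %g [%.2fs]", gt$n_genotypes,
              msn$mst_weight, as.numeric(Sys.time() - t0, units = "secs"))
  }

  scape <- NULL; surv <- NULL
  if (any(c("scape", "plasticity") %in% config$stages)) {
    t0 <- Sys.time()
    if (is.null(records)) stop("scape stage: no trait table available")
    tm <- trait_matrix(records)
    surv <- tm$records
    imp_args <- c(list(x = tm$x), config$impute)
    completed <- do.call(impute_missing, imp_args)
    scape <- trait_scape(completed)
    emit(cbind(surv[c("pot_id", "individual", "cytotype", "water", "co2")],
               as.data.frame(scape$scores)), "scape_scores.csv")
    emit(data.frame(trait = rownames(scape$loadings),
                    as.data.frame(scape$loadings)), "scape_loadings.csv")
    emit(data.frame(dimension = colnames(scape$scores),
                    explained_variance = scape$explained_variance),
         "scape_variance.csv")
    counts$replicates_ordinated <- nrow(scape$scores)
    stage_log("scape: %d replicates, dims 1-2 explain %.1f%% [%.2fs]",
              nrow(scape$scores), 100 * sum(scape$explained_variance[1:2]),
              as.numeric(Sys.time() - t0, units = "secs"))
    if (config$figures &&
        write_figure(file.path(out_dir, "trait_scape.png"), function() {
          plot(scape, groups = interaction(surv$cytotype, surv$water, surv$co2))
        }))
      files <- c(files, "trait_scape.png")
  }

  if ("plasticity" %in% config$stages) {
    t0 <- Sys.time()
    pr <- plasticity_by_contrast(scape, surv)
    emit(pr$ed_pairs, "ed_pairs.csv")
    emit(pr$mvpi_individual, "mvpi_individual.csv")
    emit(pr$mvpi_cytotype, "mvpi_cytotype.csv")
    amb <- surv$water == "well-watered" & surv$co2 == "ambient"
    tvi <- trait_variation_index(scape$scores[amb, , drop = FALSE],
                                 surv$individual[amb])
    emit(data.frame(individual = names(tvi), trait_variation = unname(tvi)),
         "trait_variation.csv")
    # one-way comparison of per-individual MVPi between cytotypes
    mv <- pr$mvpi_individual[!is.na(pr$mvpi_individual$mvpi), ]
    aov_mvpi <- one_way_anova(mv$mvpi, mv$cytotype)
    emit(rbind(aov_mvpi$terms, aov_mvpi$residual), "mvpi_anova.csv")
    counts$mvpi_rows <- nrow(pr$mvpi_individual)
    stage_log("plasticity: %d MVPi values, %d ED pairs [%.2fs]",
              nrow(pr$mvpi_individual), nrow(pr$ed_pairs),
              as.numeric(Sys.time() - t0, units = "secs"))
    if (config$figures &&
        write_figure(file.path(out_dir, "mvpi.png"), function() plot(pr)))
      files <- c(files, "mvpi.png")
  }

  if ("anova" %in% config$stages) {
    t0 <- Sys.time()
    if (is.null(records)) stop("anova stage: no trait table available")
    tabs <- lapply(config$anova_responses, function(resp) {
      a <- factorial_anova(records, resp)
      cbind(response = resp, rbind(a$terms, a$residual),
            lambda = a$transform$lambda)
    })
    emit(do.call(rbind, tabs), "anova_tables.csv")
    stage_log("anova: %d responses [%.2fs]", length(config$anova_responses),
              as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("allometry" %in% config$stages) {
    t0 <- Sys.time()
    set.seed(config$seed + 2L)
    leaves <- data.frame(width = stats::runif(20, 0.3, 1.2),
                         length = stats::runif(20, 10, 45))
    published <- leaf_area_model(86, 0.63224)
    leaves$area <- predict_leaf_area(published, leaves$width, leaves$length)
    refit <- fit_leaf_area(leaves)
    emit(leaves, "allometry_leaves.csv")
    write_leaf_area_model(refit, file.path(out_dir, "allometry_model.json"))
    files <- c(files, "allometry_model.json")
    stage_log("allometry: slope %.5f, R^2 %.4f [%.2fs]", refit$slope,
              refit$r_squared, as.numeric(Sys.time() - t0, units = "secs"))
  }

  manifest <- list(
    package = "traitscape",
    version = as.character(utils::packageVersion("traitscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    config_md5 = unname(tools::md5sum(cfg_json)),
    counts = counts,
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("manifest: %d files in %s", length(files), out_dir)
  invisible(manifest)
}

# config -> plain list for the JSON snapshot
serialize_config <- function(config) {
  list(seed = config$seed, stages = config$stages,
       design = list(individuals = config$design$individuals,
                     replicates_per_cell = config$design$replicates_per_cell,
                     dropout = as.list(config$design$dropout),
                     seed = config$design$seed),
       model_cells = config$model$cells,
       missingness = as.list(config$model$missingness),
       ssr = config$ssr, impute = config$impute,
       anova_responses = config$anova_responses)
}

write_figure <- function(path, draw) {
  ok <- tryCatch({
    grDevices::png(path, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    TRUE
  }, error = function(e) {
    warning("figure skipped (", conditionMessage(e), ")")
    FALSE
  })
  invisible(ok)
}
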