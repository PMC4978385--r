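# End-to-end pipeline: orchestrates every analysis stage from a single
# configuration with per-stage child seeds, and writes the full set of
# output tables plus a JSON run manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the study-style settings: 25% missing-data ceiling,
#' minimum analyzable population size 10, Pcrit 0.02, total-Ne infinity cap
#' 10,000, 10,000 permutations for matrix tests, 1,000 bottleneck
#' iterations and Monte Carlo assignment genotypes. Any entry can be
#' overridden; permutation-heavy stages are routinely scaled down for
#' desk-size runs.
#'
#' @param genotypes GenePop path, or a [genotype_dataset()]
#' @param stages stage sidecar CSV path (`individual,stage`), or NULL
#' @param sites site CSV path (`site,x,y`) or data frame, or NULL to skip
#'   the landscape stages
#' @param layers named list of [raster_grid()] layers (`slope`, `canopy`,
#'   `stream`) or paths to ASCII grids; NULL skips those surfaces
#' @param out_dir output directory, or NULL for in-memory results only
#' @param seed master seed; each stochastic stage gets a derived child seed
#' @param max_missing,min_pop_n,pcrit,ne_cap,permutations,bootstraps,
#'   bottleneck_reps,mc_individuals,mantel_permutations stage parameters
#' @param run_stages character vector of stages to run (default all):
#'   `"filter"`, `"sibship"`, `"diversity"`, `"differentiation"`, `"ne"`,
#'   `"bottleneck"`, `"assignment"`, `"landscape"`, `"inference"`
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genotypes, stages = NULL, sites = NULL,
                            layers = NULL, out_dir = NULL, seed = 1,
                            max_missing = 0.25, min_pop_n = 10,
                            pcrit = 0.02, ne_cap = 10000,
                            permutations = 10000, bootstraps = 10000,
                            bottleneck_reps = 1000, mc_individuals = 1000,
                            mantel_permutations = 9999,
                            run_stages = c("filter", "sibship", "diversity",
                                           "differentiation", "ne",
                                           "bottleneck", "assignment",
                                           "landscape", "inference")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Deterministic child seed from a master seed
#' @param master master seed (integer)
#' @param i stage counter
#' @return integer seed below 2^31
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 69069 + i * 12345) %% 2147483647L) + 1L
}

.write_table <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages execute in dependency order: read/filter genotypes, sibling
#' pruning, diversity, differentiation (global + pairwise + AMOVA),
#' LD-based Ne with hierarchical total, bottleneck tests, individual
#' assignment, landscape resistance surfaces, and matrix inference
#' (causal-model Mantel grid and the MLPE candidate suite for both Dps and
#' linearized FST). A stage failure halts with a stage-named error;
#' results of completed stages are kept.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result` with one element per completed
#'   stage plus `manifest`
#' @export
run_pipeline <- function(config) {
  cfg <- config
  res <- list()
  stage_on <- function(s) s %in% cfg$run_stages
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- step("input", {
    d <- if (inherits(cfg$genotypes, "genotype_dataset")) cfg$genotypes
         else read_genepop(cfg$genotypes)
    if (!is.null(cfg$stages) && is.character(cfg$stages))
      d <- read_stage_csv(cfg$stages, d)
    d
  })
  sites <- if (is.null(cfg$sites)) NULL
           else if (is.data.frame(cfg$sites)) cfg$sites
           else step("input", read_sites_csv(cfg$sites))

  if (stage_on("filter")) {
    ds <- step("filter", filter_missing(ds, cfg$max_missing))
    res$filter_report <- attr(ds, "report")
    .write_table(res$filter_report, cfg$out_dir, "filtered_individuals")
  }
  if (stage_on("sibship")) {
    ds <- step("sibship", prune_siblings(ds, derive_seed(cfg$seed, 1)))
    res$family_table <- attr(ds, "family_table")
    res$family_summary <- attr(ds, "family_summary")
    .write_table(res$family_table, cfg$out_dir, "families")
  }
  res$counts <- data.frame(pop = pop_names(ds),
                           n = as.integer(table(ds$pop)[pop_names(ds)]))
  keep <- step("exclude", exclude_small_pops(ds, cfg$min_pop_n))
  res$excluded_pops <- attr(keep, "report")
  ds_main <- keep

  if (stage_on("diversity")) {
    res$diversity <- step("diversity", diversity_table(ds_main))
    .write_table(res$diversity, cfg$out_dir, "diversity")
  }
  if (stage_on("differentiation")) {
    res$global <- step("differentiation",
                       c(fst = global_fst(ds_main),
                         gst_prime = hedrick_gst(ds_main)))
    res$pairwise_fst <- step("differentiation",
                             pairwise_fst(ds_main, cfg$bootstraps,
                                          derive_seed(cfg$seed, 2)))
    res$linfst <- linearize_fst(res$pairwise_fst)
    res$dps <- step("differentiation", dps_matrix(ds_main))
    res$amova <- step("differentiation",
                      amova(ds_main, min(cfg$permutations, 999),
                            derive_seed(cfg$seed, 3)))
    if (!is.null(cfg$out_dir)) {
      write_pairwise_csv(res$pairwise_fst, file.path(cfg$out_dir, "fst.csv"))
      write_pairwise_csv(res$linfst, file.path(cfg$out_dir, "linfst.csv"))
      write_pairwise_csv(res$dps, file.path(cfg$out_dir, "dps.csv"))
    }
  }
  if (stage_on("ne")) {
    res$ne <- step("ne", lapply(pop_names(ds_main), function(p)
      ldne(ds_main, p, cfg$pcrit)))
    names(res$ne) <- pop_names(ds_main)
    fst_for_total <- if (!is.null(res$global)) res$global["fst"]
                     else global_fst(ds_main)
    res$total_ne <- total_ne(res$ne, unname(fst_for_total), cfg$ne_cap)
    ne_tab <- data.frame(pop = names(res$ne),
                         ne = vapply(res$ne, `[[`, numeric(1), "ne"),
                         ne_low = vapply(res$ne, `[[`, numeric(1), "ci_low"),
                         ne_high = vapply(res$ne, `[[`, numeric(1), "ci_high"))
    .write_table(ne_tab, cfg$out_dir, "ne")
  }
  if (stage_on("bottleneck")) {
    res$bottleneck <- step("bottleneck",
                           bottleneck_table(ds_main, cfg$bottleneck_reps,
                                            derive_seed(cfg$seed, 4)))
    .write_table(res$bottleneck, cfg$out_dir, "bottleneck")
  }
  if (stage_on("assignment")) {
    res$assignment <- step("assignment",
                           assign_all(ds_main, cfg$mc_individuals,
                                      seed = derive_seed(cfg$seed, 5)))
    res$assignment_summary <- assignment_summary(res$assignment)
    .write_table(res$assignment_summary, cfg$out_dir, "assignment_summary")
  }
  if (stage_on("landscape") && !is.null(sites)) {
    surfaces <- step("landscape", {
      s <- list()
      lay <- cfg$layers
      if (!is.null(lay)) {
        lay <- lapply(lay, function(x)
          if (is.character(x)) read_ascii_grid(x) else x)
      }
      base_layer <- if (!is.null(lay)) lay[[1]]
        else raster_grid(matrix(0, 50, 50),
                         cellsize = max(dist(sites[, c("x", "y")])) / 40)
      s$distance <- build_surface(base_layer, "distance")
      if (!is.null(lay$slope)) s$slope <- build_surface(lay$slope, "slope")
      if (!is.null(lay$canopy)) s$canopy <- build_surface(lay$canopy, "canopy")
      if (!is.null(lay$stream)) s$stream <- build_surface(lay$stream, "stream")
      s
    })
    sites_use <- sites[match(pop_names(ds_main), sites$site), ]
    res$resistance <- step("landscape", lapply(surfaces, function(sf)
      effective_resistance(sf, sites_use)))
    res$collinearity <- step("landscape",
                             screen_collinearity(res$resistance))
    if (!is.null(cfg$out_dir))
      for (nm in names(res$resistance))
        write_pairwise_csv(res$resistance[[nm]],
                           file.path(cfg$out_dir,
                                     paste0("resistance_", nm, ".csv")))
    .write_table(res$collinearity, cfg$out_dir, "collinearity")
  }
  if (stage_on("inference") && !is.null(res$resistance) &&
      !is.null(res$dps)) {
    preds <- res$resistance
    res$causal <- step("inference", {
      rbind(cbind(response = "dps",
                  causal_model_table(res$dps, preds,
                                     cfg$mantel_permutations,
                                     derive_seed(cfg$seed, 6))),
            cbind(response = "linfst",
                  causal_model_table(res$linfst, preds,
                                     cfg$mantel_permutations,
                                     derive_seed(cfg$seed, 7))))
    })
    .write_table(res$causal, cfg$out_dir, "causal_model")
    res$mlpe <- step("inference", {
      drop_collinear <- function(suite) {
        Filter(function(v) {
          sub <- res$collinearity
          !any(sub$collinear & sub$a %in% v & sub$b %in% v)
        }, suite)
      }
      suite <- drop_collinear(mlpe_candidate_suite(names(preds)))
      lapply(stats::setNames(c("dps", "linfst"), c("dps", "linfst")),
             function(rtag) {
        resp <- if (rtag == "dps") res$dps else res$linfst
        fits <- lapply(suite, function(v) mlpe_fit(resp, preds[v]))
        names(fits) <- vapply(suite, paste, character(1), collapse = " + ")
        rank_models(fits)
      })
    })
    if (!is.null(cfg$out_dir)) {
      .write_table(res$mlpe$dps, cfg$out_dir, "mlpe_dps")
      .write_table(res$mlpe$linfst, cfg$out_dir, "mlpe_linfst")
    }
  }
  res$manifest <- list(seed = cfg$seed,
                       parameters = cfg[!(names(cfg) %in%
                                            c("genotypes", "layers"))],
                       stages_run = cfg$run_stages,
                       n_individuals = length(ds$individuals),
                       n_loci = length(ds$loci),
                       timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$out_dir)) {
    man <- res$manifest
    man$parameters <- man$parameters[!vapply(man$parameters, is.null,
                                             logical(1))]
    man$parameters$sites <- NULL
    jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(res) <- "pipeline_result"
  res
}

#' The standard nine-model MLPE candidate suite
#'
#' Univariate models for each hypothesis plus the additive combinations
#' that exclude collinear pairs by construction (canopy and distance are
#' never combined downstream; the pipeline also drops any combination its
#' collinearity screen flags).
#'
#' @param predictors available predictor names (subset of `distance`,
#'   `slope`, `canopy`, `stream`)
#' @return list of character vectors of predictor names
#' @export
mlpe_candidate_suite <- function(predictors = c("distance", "slope",
                                                "canopy", "stream")) {
  full <- list("distance", "slope", "canopy", "stream",
               c("distance", "slope"), c("canopy", "slope"),
               c("stream", "slope"), c("distance", "slope", "stream"),
               c("canopy", "slope", "stream"))
  Filter(function(v) all(v %in% predictors), full)
}
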