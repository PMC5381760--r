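#' Pipeline configuration
#'
#' Bundles every stage's tunables with the classic defaults: filtering
#' (age 20 y, NDVI cutoff 0.7, camera-trap dedup 25 km), CSR (200 km buffer,
#' 500 simulations), SDM (70/30 split, 10000 background points, convergence
#' 1e-5, 500 iterations), equivalency (100 null replicates per direction),
#' and a single global seed from which each stage derives its own.
#'
#' @param records_csv,env_dir,biomes_asc,ndvi_asc input paths (unused in
#'   synthetic mode).
#' @param synthetic logical: generate inputs from `synthetic_args`.
#' @param synthetic_args list of overrides for [synthetic_config()].
#' @param max_age,ndvi_cutoff,dedup_km filtering parameters.
#' @param csr_buffer_km,csr_n_sim CSR parameters.
#' @param train_frac,n_background,tol,max_iter,sdm_replicates SDM parameters.
#' @param null_replicates equivalency null replicates per direction.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(records_csv = NULL, env_dir = NULL,
                            biomes_asc = NULL, ndvi_asc = NULL,
                            synthetic = is.null(records_csv),
                            synthetic_args = list(),
                            max_age = 20, ndvi_cutoff = 0.7, dedup_km = 25,
                            csr_buffer_km = 200, csr_n_sim = 500,
                            train_frac = 0.7, n_background = 10000,
                            tol = 1e-5, max_iter = 500, sdm_replicates = 10,
                            null_replicates = 100, seed = 1L) {
  stopifnot(max_age > 0, ndvi_cutoff > 0, dedup_km > 0, csr_buffer_km > 0,
            csr_n_sim > 0, n_background > 0, tol > 0, max_iter > 0,
            sdm_replicates > 0, null_replicates > 0,
            train_frac > 0, train_frac < 1)
  structure(list(
    records_csv = records_csv, env_dir = env_dir, biomes_asc = biomes_asc,
    ndvi_asc = ndvi_asc, synthetic = synthetic,
    synthetic_args = synthetic_args,
    max_age = max_age, ndvi_cutoff = ndvi_cutoff, dedup_km = dedup_km,
    csr_buffer_km = csr_buffer_km, csr_n_sim = csr_n_sim,
    train_frac = train_frac, n_background = n_background, tol = tol,
    max_iter = max_iter, sdm_replicates = sdm_replicates,
    null_replicates = null_replicates, seed = as.integer(seed)),
    class = "pipeline_config")
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[melaniche] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes records -> association -> CSR -> predictor selection ->
#' per-phenotype SDM -> equivalency -> driver contrasts, writing every
#' stage's outputs plus a machine-readable manifest (parameter echo, derived
#' stage seeds, record counts, headline statistics). In synthetic mode the
#' chain runs on generated ground truth. Any stage failure halts with the
#' stage name; already-written outputs are retained. The manifest contains
#' no timestamps, so identical configs give byte-identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress progress logging.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  stage <- function(name, expr) {
    log_stage(quiet, "stage %s", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  inputs <- stage("inputs", {
    if (config$synthetic) {
      sargs <- c(config$synthetic_args,
                 list(seed = stage_seed(config$seed, "synth")))
      sargs <- sargs[!duplicated(names(sargs))]
      cfg <- do.call(synthetic_config, sargs)
      truth <- generate_records(cfg)
      write_synthetic_truth(truth, file.path(out_dir, "synthetic"))
      list(records = truth$records, env = truth$env, biomes = truth$biomes,
           biome_levels = truth$biome_levels,
           ndvi = truth$ndvi_change, truth = truth)
    } else {
      for (p in c(config$records_csv, config$biomes_asc))
        if (is.null(p) || !file.exists(p))
          stop("missing input: ", if (is.null(p)) "unset path" else p)
      if (is.null(config$env_dir) || !dir.exists(config$env_dir))
        stop("missing input: env_dir ", config$env_dir)
      env <- read_env_stack(config$env_dir)
      bio <- read_esri_ascii(config$biomes_asc)
      ndvi <- if (!is.null(config$ndvi_asc)) read_esri_ascii(config$ndvi_asc)
      list(records = read_records(config$records_csv), env = env,
           biomes = bio$values, biome_levels = NULL,
           ndvi = if (!is.null(ndvi)) ndvi$values, truth = NULL)
    }
  })
  env <- inputs$env

  filtered <- stage("records", {
    rec <- read_records(inputs$records)
    rec <- dedup_camera_traps(rec, config$dedup_km)
    ref_year <- max(rec$year, na.rm = TRUE)
    fr <- filter_records(rec, ref_year,
                         ndvi_change = inputs$ndvi, ndvi_grid = env$grid,
                         ndvi_cutoff = config$ndvi_cutoff,
                         max_age = config$max_age)
    fr$records <- assign_biomes(fr$records, inputs$biomes, env$grid,
                                levels = inputs$biome_levels)
    utils::write.csv(fr$records, file.path(out_dir, "records_filtered.csv"),
                     row.names = FALSE)
    filter_report_json(fr$report, file.path(out_dir, "filter_report.json"))
    fr
  })
  rec <- modelling_records(filtered$records)
  manifest$stages$records <- list(
    n_input = filtered$report$n_input, n_output = filtered$report$n_output,
    n_eligible = nrow(rec))

  assoc <- stage("association", {
    ct <- contingency_table(rec)
    write_contingency_csv(ct, file.path(out_dir, "contingency.csv"))
    ct
  })
  manifest$stages$association <- list(
    chi_square = assoc$chi_square, likelihood_ratio = assoc$likelihood_ratio,
    dof = assoc$dof,
    frequency_pct = phenotype_frequency(rec)$frequency_pct)

  csr_results <- stage("csr", {
    poly <- build_study_polygon(rec, buffer_km = config$csr_buffer_km)
    out <- lapply(c(melanistic = "melanistic",
                    non_melanistic = "non_melanistic"), function(ph) {
      sub <- rec[rec$phenotype == ph, , drop = FALSE]
      if (nrow(sub) < 3) return(NULL)
      csr_test(sub, poly, n_sim = config$csr_n_sim,
               seed = stage_seed(config$seed, paste0("csr_", ph)),
               effort_records = rec)
    })
    out
  })
  manifest$stages$csr <- lapply(csr_results, function(x)
    if (is.null(x)) NULL else list(p_value = x$p_value, n = x$n))

  sel <- stage("predictors", {
    if (length(env$layers) >= 2)
      select_predictors(env, n_points = min(10000, sum(env$mask)),
                        seed = stage_seed(config$seed, "pearson"))
    else names(env$layers)
  })
  env_sel <- env_stack(env$layers[as.character(sel)], env$grid, env$mask)
  manifest$stages$predictors <- as.character(sel)

  sdm <- stage("sdm", {
    out <- list()
    for (ph in c("melanistic", "non_melanistic")) {
      sub <- rec[rec$phenotype == ph, , drop = FALSE]
      if (nrow(sub) < 4) stop("phenotype '", ph, "' has <4 records")
      rr <- run_replicates(sub, env_sel, train_fraction = config$train_frac,
                           n_replicates = config$sdm_replicates,
                           seed = stage_seed(config$seed, paste0("sdm_", ph)),
                           n_background = config$n_background,
                           max_iter = config$max_iter, tol = config$tol)
      write_esri_ascii(rr$mean_suitability, env$grid,
                       file.path(out_dir, paste0("suitability_", ph, ".asc")),
                       env$mask)
      out[[ph]] <- rr
    }
    out
  })
  manifest$stages$sdm <- lapply(sdm, function(rr) list(
    auc_mean = rr$evaluation$auc_mean, auc_se = rr$evaluation$auc_se,
    n_presence = rr$evaluation$n_presence,
    variable_importance = as.list(rr$evaluation$variable_importance)))

  cmp <- stage("comparison", {
    mel <- rec[rec$phenotype == "melanistic", , drop = FALSE]
    nonmel <- rec[rec$phenotype == "non_melanistic", , drop = FALSE]
    eq <- equivalency_test(
      mel, nonmel, env_sel, n_replicates = config$null_replicates,
      protocol = maxent_protocol(n_background = min(2000, config$n_background),
                                 max_iter = config$max_iter, tol = config$tol),
      seed = stage_seed(config$seed, "equivalency"),
      observed = list(minor = sdm$melanistic$mean_suitability,
                      major = sdm$non_melanistic$mean_suitability))
    overlap_result_json(eq, file.path(out_dir, "equivalency.json"))
    pt <- paired_suitability_test(rec, sdm$melanistic$mean_suitability,
                                  sdm$non_melanistic$mean_suitability,
                                  env$grid)
    list(equivalency = eq, paired = pt)
  })
  manifest$stages$comparison <- list(
    D = cmp$equivalency$D, I = cmp$equivalency$I, RR = cmp$equivalency$RR,
    p_D = cmp$equivalency$p_D, p_I = cmp$equivalency$p_I,
    p_RR = cmp$equivalency$p_RR,
    paired_t = cmp$paired$t, paired_p = cmp$paired$p,
    mean_suitability_minor = cmp$paired$mean_A,
    mean_suitability_major = cmp$paired$mean_B)

  drivers <- stage("drivers", {
    g <- env$grid
    full <- scale_definition("full_range",
                             extent = c(g$xmin, g$xmin + g$ncol * g$cellsize,
                                        g$ymin, g$ymin + g$nrow * g$cellsize))
    dc <- driver_contrast(rec, env_sel, sdm$melanistic$mean_suitability,
                          sdm$non_melanistic$mean_suitability, list(full),
                          ndvi = inputs$ndvi)
    utils::write.csv(dc$contrasts, file.path(out_dir, "driver_contrasts.csv"),
                     row.names = FALSE)
    dc
  })
  manifest$stages$drivers <- list(
    n_significant = sum(drivers$contrasts$significant),
    threshold = drivers$threshold)

  manifest$niche_difference_flagged <-
    cmp$equivalency$p_D <= 0.05 || cmp$equivalency$p_I <= 0.05
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log_stage(quiet, "done: %s", out_dir)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin argument-vector interface used by the `inst/cli/melaniche.R` script
#' (flags are parsed by hand; no CLI framework dependency):
#' `melaniche_cli(c("all", "--synthetic", "--seed", "7", "--out", "run1"))`.
#' Subcommands: `synth` (write a synthetic truth set), `all` (full
#' pipeline), `records`, `assoc`, `csr`, `sdm`, `compare`, `barrier` (each a
#' focused slice of the pipeline on a config JSON).
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
melaniche_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: melaniche <synth|all|...> [--flags]")
  cmd <- args[1]
  flags <- parse_flags(args[-1])
  seed <- as.integer(flags$seed %||% 1)
  out <- flags$out %||% "melaniche_run"
  cfg <- if (!is.null(flags$config)) {
    raw <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    do.call(pipeline_config, raw)
  } else {
    pipeline_config(synthetic = isTRUE(flags$synthetic), seed = seed,
                    csr_n_sim = as.integer(flags$nsim %||% 500),
                    null_replicates = as.integer(flags$`null-replicates` %||% 100))
  }
  switch(cmd,
    synth = {
      sargs <- list(seed = seed)
      if (!is.null(flags$`n-records`))
        sargs$n_records <- as.integer(flags$`n-records`)
      truth <- generate_records(do.call(synthetic_config, sargs))
      write_synthetic_truth(truth, out)
      invisible(truth)
    },
    all = invisible(run_pipeline(cfg, out)),
    stop("unknown or unimplemented subcommand '", cmd,
         "'; use the package functions directly for fine-grained stages"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      out[[key]] <- args[i + 1]; i <- i + 2
    } else {
      out[[key]] <- TRUE; i <- i + 1
    }
  }
  out
}
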