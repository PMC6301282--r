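# End-to-end workflows: the carbon-source study (engineer -> scan -> sweep
# -> mixed substrates -> flux-matrix PCA) and the omics study (normalise ->
# condition-specific models -> batch geometric FBA -> DARs -> elastic net).
# Every run directory is self-describing: config, seed and log suffice to
# reproduce all outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param model `"toy"` (default) or a path readable by [read_model()].
#' @param engineering_specs optional TSV of reaction specs to graft
#'   ([load_reaction_specs()]).
#' @param sources carbon sources to scan (default: the toy sources).
#' @param rate control uptake rate, mmol/gDW/h (default 10).
#' @param objectives objective reaction ids for the scan (default
#'   rhamnolipid export and biomass for the toy).
#' @param sweep_source source used for the uptake sweep (default: first of
#'   `sources`).
#' @param omics_source single carbon source for the omics study (default:
#'   first of `sources`).
#' @param gamma expression-integration weight (default 1).
#' @param alpha_threshold DAR adjusted-p cutoff (default 0.05).
#' @param enet_alpha elastic-net ridge weight (default 0.5).
#' @param folds CV folds (default 10).
#' @param top_k genes reported per DAR (default 10).
#' @param seed integer seed (default 1).
#' @param output_dir where artifacts are written.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(model = "toy", engineering_specs = NULL,
                            sources = c("glucose", "fructose", "glycerol",
                                        "3-hydroxydecanoate"),
                            rate = 10,
                            objectives = c("EX_rl", "EX_bio"),
                            sweep_source = sources[1],
                            omics_source = sources[1],
                            gamma = 1, alpha_threshold = 0.05,
                            enet_alpha = 0.5, folds = 10, top_k = 10,
                            seed = 1, output_dir = tempfile("rlflux_run_")) {
  cfg <- list(model = model, engineering_specs = engineering_specs,
              sources = sources, rate = rate, objectives = objectives,
              sweep_source = sweep_source, omics_source = omics_source,
              gamma = gamma, alpha_threshold = alpha_threshold,
              enet_alpha = enet_alpha, folds = folds, top_k = top_k,
              seed = seed, output_dir = output_dir)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!identical(cfg$model, "toy") && !file.exists(cfg$model) &&
      !dir.exists(cfg$model))
    stop("model path does not exist: ", cfg$model, call. = FALSE)
  if (!is.null(cfg$engineering_specs) && !file.exists(cfg$engineering_specs))
    stop("engineering spec path does not exist: ", cfg$engineering_specs,
         call. = FALSE)
  if (cfg$rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (cfg$alpha_threshold <= 0 || cfg$alpha_threshold >= 1)
    stop("alpha_threshold must be in (0, 1)", call. = FALSE)
  if (cfg$enet_alpha < 0 || cfg$enet_alpha > 1)
    stop("enet_alpha must be in [0, 1]", call. = FALSE)
  if (cfg$folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (cfg$gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

load_pipeline_model <- function(cfg) {
  model <- if (identical(cfg$model, "toy")) toy_model()
           else read_model(cfg$model)
  if (!is.null(cfg$engineering_specs))
    model <- engineer_model(model, load_reaction_specs(cfg$engineering_specs))
  model
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

open_run_log <- function(cfg, study) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logf("rlflux ", as.character(utils::packageVersion("rlflux")),
       " | R ", getRversion(), " | study: ", study,
       " | seed: ", cfg$seed, " | solver tolerance: 1e-6")
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config.yaml"))
  logf
}

run_stage <- function(name, logf, expr) {
  logf("stage '", name, "' started")
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  logf("stage '", name, "' done")
  res
}

#' Run the carbon-source study
#'
#' Engineer (optional) -> single-source scan over all sources for each
#' objective -> uptake sweep (rates 1..rate) -> mixed substrates (every
#' source simultaneously at the control rate) -> PCA of the reactions x
#' sources flux matrix from the production-objective scan. All tables are
#' written as TSV into `config$output_dir` together with `run.log` and the
#' resolved `config.yaml`.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return list with `scan`, `sweep`, `mixed`, `pca` (invisible).
#' @export
run_carbon_study <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  logf <- open_run_log(cfg, "carbon")
  model <- run_stage("load_model", logf, load_pipeline_model(cfg))

  scans <- run_stage("scan", logf, {
    out <- list()
    for (obj in cfg$objectives)
      out[[obj]] <- carbon_source_scan(model, cfg$sources, cfg$rate,
                                       objective = obj)
    scan_tab <- do.call(rbind, out)
    rownames(scan_tab) <- NULL
    write_tsv(scan_tab, file.path(cfg$output_dir, "scan.tsv"))
    out
  })

  sweep <- run_stage("sweep", logf, {
    sw <- uptake_sweep(model, cfg$sweep_source, seq_len(cfg$rate),
                       objective = cfg$objectives[1])
    write_tsv(sw$scan, file.path(cfg$output_dir, "sweep.tsv"))
    logf("sweep slope ", format(sw$slope), ", max relative deviation ",
         format(sw$max_rel_deviation))
    sw
  })

  mixed <- run_stage("mixed", logf, {
    rates <- setNames(rep(cfg$rate, length(cfg$sources)), cfg$sources)
    mx <- mixed_substrate(model, rates, objective = cfg$objectives[1])
    write_tsv(data.frame(sources = paste(cfg$sources, collapse = "+"),
                         rate = cfg$rate, flux = as.numeric(mx)),
              file.path(cfg$output_dir, "mixed.tsv"))
    mx
  })

  pca <- run_stage("pca", logf, {
    sols <- attr(scans[[cfg$objectives[1]]], "solutions")
    flux_matrix <- vapply(sols, function(s) s$fluxes,
                          numeric(n_reactions(model)))
    p <- pca_flux(flux_matrix, scale = TRUE)
    write_tsv(data.frame(component = names(p$eigenvalues),
                         eigenvalue = p$eigenvalues,
                         variance_fraction = p$variance_fraction),
              file.path(cfg$output_dir, "pca_eigenvalues.tsv"))
    write_tsv(data.frame(variable = rownames(p$var_contrib),
                         p$var_contrib, check.names = FALSE),
              file.path(cfg$output_dir, "pca_var_contrib.tsv"))
    write_tsv(data.frame(reaction = rownames(p$ind_contrib),
                         p$ind_contrib, check.names = FALSE),
              file.path(cfg$output_dir, "pca_ind_contrib.tsv"))
    p
  })
  logf("carbon study complete")
  invisible(list(scan = scans, sweep = sweep, mixed = mixed, pca = pca))
}

#' Run the omics study
#'
#' Normalise the expression matrix -> one condition-specific model per
#' sample -> batch geometric FBA under a single-carbon-source medium ->
#' differentially active reactions -> elastic net per DAR -> top-|beta|
#' gene table per DAR.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param expression_path TSV (genes x samples) or an
#'   [expression_matrix()].
#' @param groups_path TSV `sample<TAB>group`, or a named group vector;
#'   ignored when `expression_path` is already an `expression_matrix`.
#' @param model optional pre-configured model (default: per config, with
#'   the omics medium applied).
#' @return list with `batch`, `dars`, `enet`, `top` (invisible).
#' @export
run_omics_study <- function(config, expression_path, groups_path = NULL,
                            model = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  logf <- open_run_log(cfg, "omics")

  expr <- run_stage("load_expression", logf, {
    if (inherits(expression_path, "expression_matrix")) expression_path
    else {
      groups <- if (is.character(groups_path) && length(groups_path) == 1 &&
                    is.null(names(groups_path)))
        read_groups(groups_path) else groups_path
      values <- read_expression(expression_path)
      missing <- setdiff(colnames(values), names(groups))
      if (length(missing))
        stop("sample '", missing[1], "' has no group label", call. = FALSE)
      expression_matrix(values, groups)
    }
  })

  if (is.null(model))
    model <- run_stage("load_model", logf, {
      m <- load_pipeline_model(cfg)
      set_medium(m, medium_spec(setNames(cfg$rate, cfg$omics_source),
                                closed_sources = setdiff(cfg$sources,
                                                         cfg$omics_source)))
    })

  batch <- run_stage("batch_fba", logf, {
    b <- batch_condition_fba(model, expr, gamma = cfg$gamma,
                             objective = cfg$objectives[1])
    write_tsv(data.frame(reaction = rownames(b$fluxes), b$fluxes,
                         check.names = FALSE),
              file.path(cfg$output_dir, "flux_matrix.tsv"))
    n_bad <- sum(b$status != "optimal")
    if (n_bad) logf(n_bad, " sample(s) failed; see status column")
    b
  })

  dars <- run_stage("dars", logf, {
    d <- identify_dars(batch$fluxes, batch$groups,
                       alpha_threshold = cfg$alpha_threshold, model = model)
    write_tsv(as.data.frame(d), file.path(cfg$output_dir, "dars.tsv"))
    logf(nrow(d), " differentially active reaction(s)")
    d
  })

  enet <- list(); top <- list()
  if (nrow(dars)) {
    fits <- run_stage("elastic_net", logf, {
      X <- t(normalize_expression(expr)$values)
      for (rid in dars$reaction) {
        fit <- elastic_net_select(X, batch$fluxes[rid, ],
                                  alpha = cfg$enet_alpha,
                                  folds = cfg$folds, seed = cfg$seed)
        enet[[rid]] <- fit
        tg <- top_genes(fit, cfg$top_k)
        top[[rid]] <- tg
        write_tsv(tg, file.path(cfg$output_dir,
                                paste0("top_genes_", rid, ".tsv")))
      }
      list(enet = enet, top = top)
    })
    enet <- fits$enet; top <- fits$top
  }
  logf("omics study complete")
  invisible(list(batch = batch, dars = dars, enet = enet, top = top))
}
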