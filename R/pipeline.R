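#' Pipeline run configuration
#'
#' Collects every stage parameter in one serializable object. Defaults are
#' the analysis constants the pipeline is built around: 7-fold stratified
#' cross-validation, 1000 surrogate maps, alpha 0.05 for multiple-testing
#' flags, a p < 0.5 retention filter for the path-model table, and fit-index
#' cutoffs CFI/TLI > 0.95 and RMSEA < 0.05. The synthetic cohort defaults
#' emulate the study conditions: three groups of 30/19/22 subjects, 400
#' timepoints (a 10-minute scan sampled every 1.5 s), 25 components of which
#' 16 are retained.
#'
#' @param ... Overrides of the defaults listed in the function definition.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "features", "train", "signature", "genes", "sem"),
    master_seed = 1,
    grid_shape = c(24, 24, 24),
    voxel_size_mm = 2,
    n_components = 25,
    ic_inclusion = setdiff(1:25, c(4, 15, 16, 18, 20, 21, 24)),
    smoothness_mm = 8,
    groups = list(groupA = 30, groupB = 19, groupC = 22),
    planted_edges = list(groupC = data.frame(i = 1, j = 2, r = 0.6)),
    base_r = 0.15,
    n_timepoints = 400,
    noise_sd = 0.5,
    contrasts = list(c("groupA", "groupC")),
    C_grid = 10^seq(-2, 2, length.out = 25),
    l1_ratio_grid = seq(0.05, 1, by = 0.05),
    k_folds = 7,
    class_weight = "none",
    n_genes = 20,
    gene_length_mm = 10,
    n_regions = 30,
    n_surrogates = 1000,
    alpha = 0.05,
    sem_p_threshold = 0.5,
    sem_model = NULL,          # path to a model file; NULL = default chain
    cutoffs = list(cfi = 0.95, tli = 0.95, rmsea = 0.05))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$k_folds >= 2, cfg$n_surrogates >= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$sem_p_threshold > 0, cfg$sem_p_threshold <= 1,
            all(cfg$C_grid > 0),
            all(cfg$l1_ratio_grid >= 0 & cfg$l1_ratio_grid <= 1),
            length(cfg$ic_inclusion) >= 2)
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$planted_edges <- lapply(raw$planted_edges, as.data.frame)
  raw$contrasts <- lapply(raw$contrasts, unlist)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg),
                                              digits.d = 12)),
             collapse = "\n")
  chars <- utf8ToInt(s)
  sprintf("%08x", as.integer(sum(chars * (seq_along(chars) %% 97 + 1)) %%
                               2^31))
}

#' Run the pipeline end to end
#'
#' Executes the selected stages in order — simulate, features, train,
#' signature, genes, sem — writing every table as TSV and every volume as
#' NIfTI under `out_dir`, with per-stage seeds derived from the master seed
#' by stable hashing (rerunning one stage reproduces it without rerunning
#' its predecessors). A manifest recording parameters, seeds and output
#' hashes is written last; a stage failure halts the run with the manifest
#' up to that point.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   stages = list())
  state <- new.env(parent = emptyenv())
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  finish_stage <- function(stage, seed, outputs, t0) {
    manifest$stages[[stage]] <<- list(
      seed = seed, outputs = outputs,
      hashes = vapply(outputs, content_hash, ""),
      wall_s = round(as.numeric(Sys.time()) - t0, 2))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  want <- function(stage) stage %in% cfg$stages

  if (want("simulate")) {
    t0 <- as.numeric(Sys.time()); seed <- stage_seed(cfg$master_seed,
                                                     "simulate")
    log_stage("simulate", "grid ", paste(cfg$grid_shape, collapse = "x"),
              ", K = ", cfg$n_components, ", seed ", seed)
    grid <- sphere_grid(cfg$grid_shape, voxel_size_mm = cfg$voxel_size_mm)
    state$grid <- grid
    state$basis <- make_ic_basis(cfg$n_components, grid, cfg$smoothness_mm,
                                 seed = seed)
    covs <- lapply(names(cfg$groups), function(g) {
      group_covariance(cfg$n_components, base_r = cfg$base_r,
                       edges = cfg$planted_edges[[g]])
    })
    names(covs) <- names(cfg$groups)
    state$cohort <- simulate_cohort(state$basis, covs,
                                    unlist(cfg$groups),
                                    n_timepoints = cfg$n_timepoints,
                                    noise_sd = cfg$noise_sd,
                                    seed = seed + 1L)
    state$genes <- lapply(seq_len(cfg$n_genes), function(g) {
      make_gene_map(grid, gene_symbol = sprintf("GENE%02d", g),
                    correlation_length_mm = cfg$gene_length_mm,
                    seed = seed + 100L + g)
    })
    names(state$genes) <- vapply(state$genes, `[[`, "", "gene_symbol")
    state$parcellation <- make_parcellation(grid, cfg$n_regions,
                                            seed = seed + 2L)
    outs <- character(0)
    dir.create(file.path(out_dir, "simulate"), showWarnings = FALSE)
    p <- file.path(out_dir, "simulate", "parcellation.nii.gz")
    save_volume(unmask(state$parcellation$labels, grid, fill = 0), p,
                grid = grid)
    outs <- c(outs, p)
    p <- file.path(out_dir, "simulate", "cohort_labels.tsv")
    write_tsv_table(state$cohort$subjects, p); outs <- c(outs, p)
    write_provenance(list(seed = seed, k = cfg$n_components,
                          groups = names(cfg$groups),
                          n_per_group = unlist(cfg$groups),
                          n_timepoints = cfg$n_timepoints,
                          noise_sd = cfg$noise_sd),
                     file.path(out_dir, "simulate", "cohort.prov"))
    finish_stage("simulate", seed, outs, t0)
  }

  if (want("features")) {
    if (is.null(state$cohort)) {
      stop("features stage requires the simulate stage output", call. = FALSE)
    }
    t0 <- as.numeric(Sys.time()); seed <- stage_seed(cfg$master_seed,
                                                     "features")
    log_stage("features", length(cfg$ic_inclusion), " retained components")
    state$features <- build_feature_table(state$cohort, cfg$ic_inclusion)
    p1 <- file.path(out_dir, "features.tsv")
    write_tsv_table(state$features, p1)
    p2 <- file.path(out_dir, "edge_map.tsv")
    write_tsv_table(edge_map(state$features), p2)
    finish_stage("features", seed, c(p1, p2), t0)
  }

  if (want("train")) {
    if (is.null(state$features)) {
      stop("train stage requires the features stage output", call. = FALSE)
    }
    t0 <- as.numeric(Sys.time()); seed <- stage_seed(cfg$master_seed, "train")
    state$fits <- lapply(cfg$contrasts, function(ct) {
      log_stage("train", "contrast ", paste(ct, collapse = " vs "))
      tune_and_fit_cv(state$features, ct,
                      enet_config(C_grid = cfg$C_grid,
                                  l1_ratio_grid = cfg$l1_ratio_grid,
                                  k_folds = cfg$k_folds,
                                  class_weight = cfg$class_weight,
                                  seed = seed))
    })
    names(state$fits) <- vapply(cfg$contrasts, paste, "", collapse = "-vs-")
    outs <- character(0)
    for (nm in names(state$fits)) {
      p <- file.path(out_dir, paste0("weights_", nm, ".tsv"))
      write_tsv_table(tidy(state$fits[[nm]]), p); outs <- c(outs, p)
      p <- file.path(out_dir, paste0("metrics_", nm, ".tsv"))
      write_tsv_table(state$fits[[nm]]$metric_summary, p); outs <- c(outs, p)
    }
    finish_stage("train", seed, outs, t0)
  }

  if (want("signature")) {
    if (is.null(state$fits)) {
      stop("signature stage requires the train stage output", call. = FALSE)
    }
    t0 <- as.numeric(Sys.time()); seed <- stage_seed(cfg$master_seed,
                                                     "signature")
    state$signatures <- lapply(state$fits, backproject_signature,
                               ic_basis = state$basis)
    outs <- character(0)
    for (nm in names(state$signatures)) {
      p <- file.path(out_dir, paste0("signature_", nm, ".nii.gz"))
      save_volume(state$signatures[[nm]], p); outs <- c(outs, p)
    }
    finish_stage("signature", seed, outs, t0)
  }

  if (want("genes")) {
    if (is.null(state$signatures)) {
      stop("genes stage requires the signature stage output", call. = FALSE)
    }
    t0 <- as.numeric(Sys.time()); seed <- stage_seed(cfg$master_seed, "genes")
    log_stage("genes", cfg$n_surrogates, " surrogates, ",
              length(state$genes), " gene maps")
    outs <- character(0)
    state$similarity <- list()
    for (nm in names(state$signatures)) {
      surr <- generate_surrogates(state$signatures[[nm]], state$grid,
                                  n = cfg$n_surrogates, seed = seed)
      cort <- similarity_table(state$signatures[[nm]], state$genes, surr,
                               alpha = cfg$alpha)
      regl <- similarity_table(state$signatures[[nm]], state$genes, surr,
                               parcellation = state$parcellation,
                               alpha = cfg$alpha)
      state$similarity[[nm]] <- dplyr::bind_rows(cort, regl)
      p <- file.path(out_dir, paste0("similarity_", nm, ".tsv"))
      write_tsv_table(state$similarity[[nm]], p); outs <- c(outs, p)
    }
    finish_stage("genes", seed, outs, t0)
  }

  if (want("sem")) {
    if (is.null(state$similarity)) {
      stop("sem stage requires the genes stage output", call. = FALSE)
    }
    t0 <- as.numeric(Sys.time()); seed <- stage_seed(cfg$master_seed, "sem")
    model <- if (!is.null(cfg$sem_model)) read_path_model(cfg$sem_model)
             else {
               gs <- names(state$genes)[1:min(4, length(state$genes))]
               path_model(paste(gs[-length(gs)], "->", gs[-1]))
             }
    outs <- character(0)
    for (nm in names(state$similarity)) {
      tab <- assemble_sem_table(state$similarity[[nm]],
                                genes = model$variables,
                                p_threshold = cfg$sem_p_threshold)
      fit <- fit_path_model(model, tab)
      p <- file.path(out_dir, paste0("sem_estimates_", nm, ".tsv"))
      write_tsv_table(tidy(fit), p); outs <- c(outs, p)
      p <- file.path(out_dir, paste0("sem_summary_", nm, ".txt"))
      write_provenance(c(glance(fit),
                         list(p_threshold = cfg$sem_p_threshold)), p)
      outs <- c(outs, p)
    }
    finish_stage("sem", seed, outs, t0)
  }

  manifest <- yaml::read_yaml(file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
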