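#' Pipeline configuration
#'
#' Bundles every stage parameter of the full analysis, defaulting to the
#' full-scale settings (subsample 288, 1000 bootstrap attempts, 0.95
#' consensus, 1000 shuffles, K range 2..15, 20 reps x 5 folds, 100 random
#' removal replicates). For desk-size runs pass smaller values; the seed is
#' the single source of randomness for the whole run.
#'
#' @param mode `"simulate"` (generate a planted network), `"networks"` (read
#'   edge lists from `network_dir`) or `"expression"` (build layers from the
#'   expression matrices in `expression_paths`, a named vector layer -> CSV).
#' @param seed master seed; every stage derives its own substream from it.
#' @param simulate list of arguments for [generate_sbm_multilayer()] (used in
#'   simulate mode).
#' @param network_dir directory for [read_network_layers()] (networks mode).
#' @param expression_paths named character vector of CSV paths (expression
#'   mode).
#' @param chaperone_ids,client_ids gene sets for the coexpression stage
#'   (expression mode).
#' @param n_subsample,n_boot,consensus_threshold,alpha coexpression stage.
#' @param n_shuffles nestedness / null-ensemble stage.
#' @param K_min,K_max,n_restarts SBM model-selection stage.
#' @param n_reps,n_folds link-prediction stage.
#' @param n_random_reps robustness stage.
#' @param run_prediction run the (costly) full prediction grid (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "networks", "expression"),
                            seed = 1L,
                            simulate = list(
                              n_chaperones = 15, n_clients = 200, n_layers = 4,
                              K = 2, affinity_contrast = 10,
                              membership_concentration = 0
                            ),
                            network_dir = NULL,
                            expression_paths = NULL,
                            chaperone_ids = NULL, client_ids = NULL,
                            n_subsample = 288, n_boot = 1000,
                            consensus_threshold = 0.95, alpha = 0.05,
                            n_shuffles = 1000,
                            K_min = 2, K_max = 15, n_restarts = 10,
                            n_reps = 20, n_folds = 5,
                            n_random_reps = 100,
                            run_prediction = TRUE) {
  structure(
    list(
      mode = match.arg(mode), seed = as.integer(seed), simulate = simulate,
      network_dir = network_dir, expression_paths = expression_paths,
      chaperone_ids = chaperone_ids, client_ids = client_ids,
      n_subsample = n_subsample, n_boot = n_boot,
      consensus_threshold = consensus_threshold, alpha = alpha,
      n_shuffles = n_shuffles, K_min = K_min, K_max = K_max,
      n_restarts = n_restarts, n_reps = n_reps, n_folds = n_folds,
      n_random_reps = n_random_reps, run_prediction = run_prediction
    ),
    class = "pipeline_config"
  )
}

#' Deterministic per-stage seed from a master seed
#'
#' Hashes the stage label into the master seed so that inserting a stage does
#' not perturb the seeds of the others. Result stays below 2^31.
#'
#' @param master integer master seed.
#' @param label stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 131 + h) %% 2147483629)
}

#' Run the full CCI analysis pipeline
#'
#' Executes build -> niche -> nestedness -> null z-scores -> SBM -> link
#' prediction -> robustness, writing tidy CSVs, the fitted model as JSON, the
#' network edge lists and a run manifest into `out_dir`. Identical
#' configuration and seed reproduce the bundle byte-for-byte. With
#' `resume = TRUE`, stages whose outputs already exist are skipped and their
#' outputs re-read.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param resume skip stages whose output files already exist.
#' @return invisibly, a list with the main in-memory results (`network`,
#'   `niche`, `nestedness`, `fidelity_z`, `model`, `prediction`,
#'   `robustness`, `correlations`).
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(out_dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  stage_msg <- function(s) message("[ccinet] stage: ", s)
  done <- function(path) resume && file.exists(path)

  # -- build ------------------------------------------------------------
  stage_msg("build")
  net_dir <- file.path(out_dir, "networks")
  if (done(file.path(net_dir, "manifest.yml"))) {
    net <- read_network_layers(net_dir)
  } else {
    net <- switch(config$mode,
      simulate = {
        args <- config$simulate
        args$seed <- derive_seed(config$seed, "simulate")
        do.call(generate_sbm_multilayer, args)$network
      },
      networks = read_network_layers(config$network_dir),
      expression = {
        expr_list <- purrr::imap(
          config$expression_paths,
          function(p, id) read_expression_csv(p, id)
        )
        build_consensus_network(
          expr_list, config$chaperone_ids, config$client_ids,
          n_subsample = config$n_subsample, n_boot = config$n_boot,
          consensus_threshold = config$consensus_threshold,
          alpha = config$alpha, seed = derive_seed(config$seed, "build")
        )
      }
    )
    write_network_layers(net, net_dir)
  }

  # -- niche ------------------------------------------------------------
  stage_msg("niche")
  niche <- niche_table(net)
  fidelity <- partner_fidelity(net)
  fidelity_scores <- partner_fidelity_scores(net)
  overlap <- within_layer_overlap(net)
  lsim <- layer_similarity(net)
  fid_niche <- fidelity_niche_correlation(net)
  readr::write_csv(niche, file.path(tdir, "niche.csv"), progress = FALSE)
  readr::write_csv(fidelity, file.path(tdir, "partner_fidelity.csv"), progress = FALSE)
  readr::write_csv(fidelity_scores, file.path(tdir, "partner_fidelity_scores.csv"), progress = FALSE)
  readr::write_csv(overlap, file.path(tdir, "within_layer_overlap.csv"), progress = FALSE)
  readr::write_csv(lsim, file.path(tdir, "layer_similarity.csv"), progress = FALSE)
  readr::write_csv(fid_niche, file.path(tdir, "fidelity_niche_correlation.csv"), progress = FALSE)

  # -- nestedness -------------------------------------------------------
  stage_msg("nestedness")
  nest <- nestedness_test(
    net,
    n_shuffles = config$n_shuffles,
    seed = derive_seed(config$seed, "nestedness")
  )
  jsonlite::write_json(
    list(
      rho_observed = nest$rho_observed, p_value = nest$p_value,
      n_shuffles = nest$n_shuffles, null_mean = mean(nest$null_samples)
    ),
    file.path(tdir, "nestedness.json"),
    auto_unbox = TRUE, digits = NA
  )

  # -- null z-scores for partner fidelity --------------------------------
  stage_msg("nulls")
  ens <- shuffle_ensemble(
    net,
    n_replicates = config$n_shuffles,
    seed = derive_seed(config$seed, "nulls"),
    statistic = function(mats) {
      stats::median(partner_fidelity(as_cci_network(mats))$jaccard, na.rm = TRUE)
    },
    keep_replicates = FALSE
  )
  obs_fid <- stats::median(fidelity$jaccard, na.rm = TRUE)
  fid_z <- zscore(obs_fid, ens$statistic_samples)
  fid_z$observed <- obs_fid
  readr::write_csv(fid_z, file.path(tdir, "fidelity_zscore.csv"), progress = FALSE)

  # -- sbm ---------------------------------------------------------------
  stage_msg("sbm")
  model_path <- file.path(out_dir, "model.json")
  sel <- select_K(
    net,
    K_min = config$K_min, K_max = config$K_max,
    n_restarts = config$n_restarts, seed = derive_seed(config$seed, "sbm")
  )
  model <- sel$best_model
  readr::write_csv(sel$bic_trace, file.path(tdir, "bic_trace.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      K = model$K, log_likelihood = model$log_likelihood, BIC = model$BIC,
      converged = model$converged,
      u = model$u, v = model$v, w = lapply(model$w, identity),
      chaperones = model$chaperones, clients = model$clients, layers = model$layers
    ),
    model_path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  assignments <- hard_assignments(model)
  readr::write_csv(assignments, file.path(tdir, "assignments.csv"), progress = FALSE)

  # -- prediction --------------------------------------------------------
  prediction <- NULL
  if (config$run_prediction) {
    stage_msg("prediction")
    prediction <- prediction_grid(
      net,
      K = 2, n_reps = config$n_reps, n_folds = config$n_folds,
      seed = derive_seed(config$seed, "prediction")
    )
    readr::write_csv(prediction$auc, file.path(tdir, "auc.csv"), progress = FALSE)
  }

  # -- robustness --------------------------------------------------------
  stage_msg("robustness")
  modules <- module_numbers(assignments)
  T_table <- robustness_suite(
    net,
    group_labels = modules,
    n_random_reps = config$n_random_reps,
    seed = derive_seed(config$seed, "robustness")
  )
  readr::write_csv(T_table, file.path(tdir, "robustness.csv"), progress = FALSE)
  T_niche <- suppressWarnings(correlate_T_with_niche(T_table, niche))
  readr::write_csv(T_niche, file.path(tdir, "robustness_niche_correlation.csv"), progress = FALSE)

  # -- manifest ----------------------------------------------------------
  manifest <- list(
    package = "ccinet",
    version = as.character(utils::packageVersion("ccinet")),
    seed = config$seed,
    mode = config$mode,
    stage_seeds = list(
      simulate = derive_seed(config$seed, "simulate"),
      build = derive_seed(config$seed, "build"),
      nestedness = derive_seed(config$seed, "nestedness"),
      nulls = derive_seed(config$seed, "nulls"),
      sbm = derive_seed(config$seed, "sbm"),
      prediction = derive_seed(config$seed, "prediction"),
      robustness = derive_seed(config$seed, "robustness")
    ),
    parameters = config[!(names(config) %in% c("expression_paths", "network_dir"))]
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )

  invisible(list(
    network = net, niche = niche, nestedness = nest, fidelity_z = fid_z,
    model = model, bic_trace = sel$bic_trace, prediction = prediction,
    robustness = T_table, correlations = list(
      fidelity_niche = fid_niche, robustness_niche = T_niche
    )
  ))
}
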