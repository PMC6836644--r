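#' Configuration of an end-to-end screening run
#'
#' Bundles every tunable of the pipeline with defaults matching the
#' reference workflow: four row groups, three feature clusters, majority
#' voting, an AND (false-positive-minimizing) meta-rule, a 0.35 Tanimoto
#' leader-clustering cap, and a 21-compound final selection.
#'
#' Group usage mirrors the reference split: groups 1-2 drive feature
#' clustering, groups 2-3 train the two measure-guided models (group 2
#' is deliberately reused), and the last group is held out for
#' evaluation.
#'
#' @param out_dir artifact directory (created if needed).
#' @param input path to a labeled TSV compound table (with schema
#'   sidecar), or `NULL` to generate synthetic data.
#' @param synthetic a [synthetic_spec()] used when `input` is `NULL` and
#'   for the synthetic screening library.
#' @param screening_prevalence Active prevalence of the synthetic
#'   screening library (`NULL` skips screening).
#' @param screening_n synthetic library size (default: training size).
#' @param seed master seed for partitioning and model selection.
#' @param n_groups number of row groups.
#' @param k_features number of feature clusters.
#' @param roster classifier roster (list of [classifier_spec()]).
#' @param cv_folds cross-validation folds for classifier selection.
#' @param voting `"majority"` or `"weighted"`.
#' @param meta_rule `"minimize_fp"` or `"minimize_fn"` — rule used for
#'   the screening stage.
#' @param chem_threshold Tanimoto distance cap for leader clustering.
#' @param selection_size number of representatives to purchase.
#' @param reuse_group2 reuse group 2 for both feature clustering and
#'   model building (reference behaviour); `FALSE` gives disjoint roles.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL,
                            synthetic = synthetic_spec(),
                            screening_prevalence = 0.05,
                            screening_n = NULL, seed = 1,
                            n_groups = 4, k_features = 3,
                            roster = default_roster(), cv_folds = 5,
                            voting = "majority",
                            meta_rule = c("minimize_fp", "minimize_fn"),
                            chem_threshold = 0.35, selection_size = 21,
                            reuse_group2 = TRUE) {
  meta_rule <- match.arg(meta_rule)
  if (n_groups < 3) abort("n_groups must be >= 3 (cluster/train/test roles)")
  structure(list(out_dir = out_dir, input = input, synthetic = synthetic,
                 screening_prevalence = screening_prevalence,
                 screening_n = screening_n, seed = as.integer(seed),
                 n_groups = as.integer(n_groups),
                 k_features = as.integer(k_features), roster = roster,
                 cv_folds = as.integer(cv_folds), voting = voting,
                 meta_rule = meta_rule, chem_threshold = chem_threshold,
                 selection_size = as.integer(selection_size),
                 reuse_group2 = isTRUE(reuse_group2)),
            class = "pipeline_config")
}

config_as_json <- function(config) {
  x <- unclass(config)
  x$synthetic <- unclass(x$synthetic)
  x$roster <- lapply(x$roster, unclass)
  x
}

#' Run the full virtual-screening pipeline
#'
#' Executes the complete workflow: ingest or generate a labeled table;
#' partition rows; cluster features by Fisher score; train the MCC- and
#' PPV-optimized models; evaluate both models and both meta-models on
#' the held-out group; screen a library with the configured meta-rule;
#' rank predicted actives by global relevance; leader-cluster them; and
#' select one top-ranked representative per cluster up to
#' `selection_size` compounds.
#'
#' Every artifact is written under `config$out_dir` (TSV/JSON) together
#' with the resolved configuration and a run log, and is regenerable
#' from (input, resolved config, seed) alone.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory objects: `table`,
#'   `assignment`, `clustering`, `model_mcc`, `model_ppv`, `report`
#'   (held-out evaluation for both models and both meta-models),
#'   `screen` (prediction, `ranked` table, `clusters`, `selection`) and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logf <- function(stage, fmt, ...) {
    writeLines(sprintf("[%s] %s", stage, sprintf(fmt, ...)), log_con)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  paths <- list(log = log_path)

  logf("init", "mcscreen %s, seed %d",
       as.character(utils::packageVersion("mcscreen")), config$seed)

  # -- data -----------------------------------------------------------------
  tab <- run_stage("data", {
    if (!is.null(config$input)) {
      read_compound_table(config$input)
    } else {
      generate_dataset(config$synthetic)$table
    }
  })
  logf("data", "%d compounds, %d features in", n_compounds(tab),
       length(feature_names(tab)))

  # -- partition ------------------------------------------------------------
  assignment <- run_stage("partition",
                          partition_rows(tab, config$n_groups, config$seed))
  paths$groups <- file.path(config$out_dir, "group_assignment.tsv")
  utils::write.table(
    data.frame(id = names(assignment$groups), group = assignment$groups),
    paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  logf("partition", "%d groups, sizes %s", config$n_groups,
       paste(as.integer(table(assignment$groups)), collapse = "/"))

  cluster_groups <- 1:2
  train_groups <- if (config$reuse_group2) 2:3 else c(3L)
  test_group <- config$n_groups

  # -- feature clustering ---------------------------------------------------
  clustering <- run_stage("cluster-features", {
    sub <- subset_rows(tab, group_ids(assignment, cluster_groups))
    cluster_features(sub, k = config$k_features)
  })
  paths$clustering <- file.path(config$out_dir, "feature_clustering.json")
  write_feature_clustering(clustering, paths$clustering)
  logf("cluster-features", "k=%d, sizes %s", clustering$k,
       paste(vapply(clustering$clusters, length, 1L), collapse = "/"))

  # -- training -------------------------------------------------------------
  train_tab <- subset_rows(tab, group_ids(assignment, train_groups))
  models <- list()
  for (obj in c("mcc", "ppv")) {
    models[[obj]] <- run_stage(paste0("train-", obj), {
      build_mcs(train_tab, clustering, objective = obj,
                roster = config$roster, cv_folds = config$cv_folds,
                seed = config$seed, voting = config$voting)
    })
    paths[[paste0("model_", obj)]] <-
      file.path(config$out_dir, sprintf("model_%s.rds", obj))
    save_mcs(models[[obj]], paths[[paste0("model_", obj)]])
    logf(paste0("train-", obj), "families %s",
         paste(vapply(models[[obj]]$classifiers, function(x) x$family, ""),
               collapse = "/"))
  }

  # -- held-out evaluation --------------------------------------------------
  report <- run_stage("evaluate", {
    test_tab <- subset_rows(tab, group_ids(assignment, test_group))
    truth <- compound_labels(test_tab)
    pred_mcc <- predict(models$mcc, test_tab)
    pred_ppv <- predict(models$ppv, test_tab)
    evals <- list(
      mcc_model = evaluate_predictions(pred_mcc, truth),
      ppv_model = evaluate_predictions(pred_ppv, truth),
      minimize_fp = evaluate_predictions(
        combine_meta(pred_mcc, pred_ppv, "minimize_fp"), truth),
      minimize_fn = evaluate_predictions(
        combine_meta(pred_mcc, pred_ppv, "minimize_fn"), truth)
    )
    lapply(evals, function(e) {
      c(unclass(e$confusion),
        list(mcc = e$mcc, ppv = e$ppv, accuracy = e$accuracy,
             errors = e$errors))
    })
  })
  paths$report <- file.path(config$out_dir, "evaluation.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
  logf("evaluate", "minimize_fp errors=%d, minimize_fn errors=%d",
       report$minimize_fp$errors, report$minimize_fn$errors)

  # -- screening ------------------------------------------------------------
  screen <- NULL
  if (!is.null(config$screening_prevalence)) {
    screen <- run_stage("screen", {
      lib <- generate_screening_library(
        config$synthetic, config$screening_prevalence,
        n = config$screening_n %||% (config$synthetic$n_active +
                                       config$synthetic$n_inactive))
      pred <- combine_meta(predict(models$mcc, lib$table),
                           predict(models$ppv, lib$table),
                           config$meta_rule)
      list(library = lib, prediction = pred)
    })
    logf("screen", "%d library compounds, %d predicted Active",
         n_compounds(screen$library$table),
         sum(screen$prediction$labels == "Active"))

    screen$ranked <- run_stage("rank", rank_screen(screen$prediction))
    paths$ranked <- file.path(config$out_dir, "ranked_candidates.tsv")
    utils::write.table(screen$ranked, paths$ranked, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    logf("rank", "%d ranked candidates", nrow(screen$ranked))

    screen$clusters <- run_stage("chem-cluster", {
      if (nrow(screen$ranked) == 0) list() else {
        fps <- screen$library$table$bits
        rownames(fps) <- screen$library$table$ids
        leader_cluster(fps[screen$ranked$id, , drop = FALSE],
                       config$chem_threshold,
                       ordering = screen$ranked$id)
      }
    })
    logf("chem-cluster", "%d clusters at threshold %.2f",
         length(screen$clusters), config$chem_threshold)

    screen$selection <- run_stage("select", {
      if (length(screen$clusters) == 0) character(0) else {
        theta <- stats::setNames(screen$ranked$theta, screen$ranked$id)
        reps <- select_representatives(screen$clusters, theta)
        reps[order(-theta[reps], reps)][
          seq_len(min(config$selection_size, length(reps)))]
      }
    })
    paths$selection <- file.path(config$out_dir, "selection.tsv")
    sel_df <- screen$ranked[match(screen$selection, screen$ranked$id),
                            c("rank", "id", "theta", "theta_trunc")]
    utils::write.table(sel_df, paths$selection, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    logf("select", "%d representatives selected", length(screen$selection))
  }

  # -- resolved config ------------------------------------------------------
  paths$config <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_as_json(config), paths$config,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  invisible(list(table = tab, assignment = assignment,
                 clustering = clustering, model_mcc = models$mcc,
                 model_ppv = models$ppv, report = report, screen = screen,
                 paths = paths))
}
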