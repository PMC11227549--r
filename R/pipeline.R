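#' Default pipeline configuration
#'
#' Every tunable of the analysis stack surfaced as one nested list, suitable
#' for serialisation to YAML. Unknown keys passed to [run_pipeline()] are
#' rejected by name.
#'
#' @return A named list of parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out = "forage_out",
    cohort = list(
      rats = paste0("rat", sprintf("%02d", 1:6)),
      n_sessions = 10,
      tracking = FALSE,
      conditions = list(
        baseline = list(policy = list(a_R = 2, b_R = 3, a_C = 1, b_C = -1,
                                      curvature = 0)),
        challenge = list(policy = list(a_R = 2, b_R = 6, a_C = 1, b_C = -1,
                                       curvature = 0))
      )
    ),
    schedule = list(n_trials = 40, cost_lux = c(15, 320),
                    cost_probs = c(0.5, 0.5)),
    features = list(k_sd = 2, stop_eps = 0.1, stop_window = 3,
                    rot_window = 1.5, grid_n = 64, eps_move = 0.05),
    shapes = list(feature = "choice", threshold = 0.4),
    clustering = list(axes = c("shift", "max"), c_range = 2:6, m = 2,
                      n_restarts = 10, standardize = TRUE)
  )
}

validate_config <- function(config) {
  ref <- default_config()
  check <- function(cfg, tmpl, path = "") {
    extra <- setdiff(names(cfg), names(tmpl))
    if (length(extra)) {
      stopf("unknown config key%s: %s", if (length(extra) > 1) "s" else "",
            paste0(path, extra, collapse = ", "),
            class = "foragedm_config_error")
    }
    for (k in names(cfg)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) &&
          k != "conditions" && is.list(cfg[[k]])) {
        check(cfg[[k]], tmpl[[k]], paste0(path, k, "$"))
      }
    }
  }
  check(config, ref)
  modifyList(ref, config)
}

#' Run the full simulate-to-compare pipeline
#'
#' Simulates a cohort under each configured condition, derives per-session
#' psychometric curves, classifies their shapes, clusters the sigmoid
#' descriptors of the first condition (baseline), projects the other
#' conditions onto the baseline partition, builds per-rat strategy profiles
#' and computes shift statistics (per-rat Euclidean distances, the
#' Kolmogorov-Smirnov comparison and per-cluster migration chi-squared
#' tests). All outputs are deterministic in `config$seed`; a machine-readable
#' manifest (config hash, per-stage counts, file hashes) is written alongside
#' the artifacts.
#'
#' @param config A config list ([default_config()] documents the keys) or a
#'   path to a YAML file with the same structure.
#' @return The output directory, invisibly; the manifest as the
#'   `manifest` attribute.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out_dir <- cfg$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("foragedm")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out")]),
    seed = cfg$seed,
    stages = list()
  )
  stage <- function(name, n) {
    manifest$stages[[name]] <<- list(n = n, status = "ok")
  }
  on_fail <- function(name, e) {
    manifest$stages[[name]] <<- list(status = "failed",
                                     message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  }

  # -- simulate ---------------------------------------------------------------
  cohort <- tryCatch({
    conds <- purrr::map(cfg$cohort$conditions, function(cc) {
      list(policy = do.call(decision_policy, cc$policy),
           schedule = do.call(task_schedule, cfg$schedule))
    })
    simulate_cohort(cfg$cohort$rats, conds,
                    n_sessions = cfg$cohort$n_sessions,
                    seed = cfg$seed, tracking = isTRUE(cfg$cohort$tracking))
  }, error = function(e) on_fail("simulate", e))
  stage("simulate", nrow(cohort))

  # -- features ---------------------------------------------------------------
  features <- tryCatch({
    purrr::map_dfr(cohort$session_obj, function(s) {
      if (nrow(s$tracking) > 0) {
        do.call(extract_features, c(list(s), cfg$features))
      } else {
        trials_as_features(s)
      }
    })
  }, error = function(e) on_fail("features", e))
  readr::write_csv(features, file.path(out_dir, "features.csv"))
  stage("features", nrow(features))

  # -- shape classification ---------------------------------------------------
  shapes <- tryCatch({
    classify_sessions(features, feature = cfg$shapes$feature,
                      threshold = cfg$shapes$threshold)
  }, error = function(e) on_fail("shapes", e))
  readr::write_csv(shapes, file.path(out_dir, "shapes.csv"))
  stage("shapes", nrow(shapes))

  # -- clustering on baseline, projection of other conditions -----------------
  comparison <- tryCatch({
    conds <- names(cfg$cohort$conditions)
    base_label <- conds[1]
    axes <- cfg$clustering$axes
    sig <- dplyr::filter(shapes, .data$label == "sigmoidal",
                         .data$identified,
                         dplyr::if_all(dplyr::all_of(axes), is.finite))
    base <- dplyr::filter(sig, .data$condition == base_label)
    if (nrow(base) < max(cfg$clustering$c_range) + 1) {
      stopf("too few sigmoidal baseline sessions (%d) to cluster", nrow(base))
    }
    model <- select_cluster_count(
      base[, axes], c_range = cfg$clustering$c_range,
      m = cfg$clustering$m, n_restarts = cfg$clustering$n_restarts,
      seed = cfg$seed, standardize = isTRUE(cfg$clustering$standardize)
    )
    profs <- list()
    dists <- list()
    counts <- list()
    base_prof <- strategy_profiles(list(choice = model),
                                   list(choice = base[, "rat_id"]))
    counts[[base_label]] <- tabulate(model$cluster, model$c)
    profs[[base_label]] <- base_prof
    for (cond in conds[-1]) {
      dat <- dplyr::filter(sig, .data$condition == cond)
      U <- fcm_project(model, dat[, axes])
      cl <- attr(U, "cluster")
      prof <- strategy_profiles(list(choice = model),
                                list(choice = dat[, "rat_id"]),
                                assignments = list(choice = cl))
      profs[[cond]] <- prof
      counts[[cond]] <- tabulate(cl, model$c)
      rats <- intersect(unique(base$rat_id), unique(dat$rat_id))
      dists[[cond]] <- tibble::tibble(
        rat_id = rats,
        distance = vapply(rats, function(r) {
          euclidean_shift(profile_vector(base_prof, r),
                          profile_vector(prof, r))
        }, numeric(1))
      )
    }
    ks <- NULL; migration <- NULL
    if (length(conds) >= 2) {
      # null-style reference: baseline split-half distances vs condition ones
      cond1 <- conds[2]
      migration <- cluster_migration_test(counts[[base_label]],
                                          counts[[cond1]])
      if (length(conds) >= 3) {
        ks <- population_shift_test(dists[[conds[2]]]$distance,
                                    dists[[conds[3]]]$distance)
      }
    }
    list(model = model, profiles = profs, distances = dists,
         migration = migration, ks = ks)
  }, error = function(e) on_fail("cluster", e))
  stage("cluster", comparison$model$c)

  jsonlite::write_json(
    list(
      mpc_table = comparison$model$mpc_table,
      selected_c = comparison$model$c,
      mpc = comparison$model$mpc,
      centers = as.data.frame(comparison$model$centers),
      migration = comparison$migration,
      ks = comparison$ks,
      distances = purrr::map(comparison$distances, as.data.frame)
    ),
    file.path(out_dir, "clusters.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- lapply(setNames(tools::md5sum(files), basename(files)),
                           unname)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(invisible(out_dir), manifest = manifest)
}
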