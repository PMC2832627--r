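#' Configuration of a full pipeline run
#'
#' Collects the stage toggles and parameters of [run_pipeline()] into a
#' single validated object that can be serialized to JSON and restored,
#' so a run is fully described by one file plus a seed. Unknown keys in a
#' config file are rejected.
#'
#' @param sim A [sim_config()] describing the synthetic panel (or `NULL`
#'   when `profiles_path` supplies precomputed profiles).
#' @param profiles_path,labels_path Optional paths to a precomputed
#'   profile matrix and labels TSV, used instead of simulation.
#' @param render_images Render and re-quantify scan images per serum
#'   (exercises the image stage; slower) instead of using simulated
#'   profiles directly.
#' @param se_side Structuring-element side for quantification (`NULL` =
#'   layout default).
#' @param adjust Grow spot areas during quantification.
#' @param folds,repetitions,cost,n_permutations Classifier evaluation
#'   parameters (see [cross_validate()] and [permutation_test()]).
#' @param classify,permute Stage toggles for classification and the
#'   permutation test.
#' @param seed Master seed of the run.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), profiles_path = NULL,
                       labels_path = NULL, render_images = FALSE,
                       se_side = NULL, adjust = TRUE, folds = 10L,
                       repetitions = 10L, cost = 1, n_permutations = 0L,
                       classify = TRUE, permute = n_permutations > 0L,
                       seed = 1L, out_dir = ".") {
  cfg <- list(sim = sim, profiles_path = profiles_path,
              labels_path = labels_path, render_images = render_images,
              se_side = se_side, adjust = adjust, folds = as.integer(folds),
              repetitions = as.integer(repetitions), cost = cost,
              n_permutations = as.integer(n_permutations),
              classify = classify, permute = permute,
              seed = as.integer(seed), out_dir = out_dir)
  if (is.null(cfg$sim) && is.null(cfg$profiles_path)) {
    stop("either a simulation config or a profiles path is required",
         call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$sim <- if (!is.null(x$sim)) unclass(x$sim) else NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$sim)) {
    sim_known <- names(formals(sim_config))
    sim_unknown <- setdiff(names(x$sim), sim_known)
    if (length(sim_unknown)) {
      stop("unknown simulation config keys: ",
           paste(sim_unknown, collapse = ", "), call. = FALSE)
    }
    x$sim <- do.call(sim_config, x$sim)
  }
  do.call(run_config, x)
}

#' Run the full analysis pipeline
#'
#' Composes the stages — simulate (or load) profiles, optionally render
#' and re-quantify scan images, quantile normalize, score antigens by
#' AUC, classify with the cross-validated SVM and permutation test — and
#' writes all artifacts plus a run manifest (config snapshot, output
#' checksums, package version, collected warnings) to `out_dir`.
#' Identical config and seed produce identical outputs. A failing stage
#' aborts with the stage name; files already written by the failing stage
#' keep a `.partial` suffix.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  warns <- character()
  note <- function(w) warns[[length(warns) + 1L]] <<- conditionMessage(w)

  stage <- function(name, paths, expr) {
    partial <- paste0(paths, ".partial")
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        note(w)
        invokeRestart("muffleWarning")
      }
    )
    for (i in seq_along(paths)) {
      if (file.exists(partial[i])) file.rename(partial[i], paths[i])
    }
    files <<- c(files, paths)
    res
  }

  out <- function(name) file.path(cfg$out_dir, name)

  # --- profiles -------------------------------------------------------
  if (!is.null(cfg$profiles_path)) {
    profiles <- stage("load", character(), read_profile_matrix(cfg$profiles_path))
    groups <- stage("load", character(), {
      g <- read_labels(cfg$labels_path)
      g[rownames(profiles)]
    })
    layout <- NULL
  } else {
    p_prof <- out("profiles.tsv")
    p_lab <- out("labels.tsv")
    p_lay <- out("layout.json")
    sim <- stage("simulate", c(p_prof, p_lab, p_lay), {
      s <- simulate_profiles(cfg$sim)
      write_profile_matrix(s$profiles, paste0(p_prof, ".partial"))
      write_labels(rownames(s$profiles), s$groups, paste0(p_lab, ".partial"))
      write_layout_json(s$truth$layout, paste0(p_lay, ".partial"))
      s
    })
    profiles <- sim$profiles
    groups <- sim$groups
    layout <- sim$truth$layout
    if (cfg$render_images) {
      p_q <- out("quantified_profiles.tsv")
      profiles <- stage("quantify", p_q, {
        q <- quantify_simulation(sim, se_side = cfg$se_side,
                                 adjust = cfg$adjust)
        write_profile_matrix(q, paste0(p_q, ".partial"))
        q
      })
    }
  }

  # --- normalization and AUC -----------------------------------------
  p_norm <- out("normalized_profiles.tsv")
  normalized <- stage("normalize", p_norm, {
    nm <- quantile_normalize(profiles)
    write_profile_matrix(nm, paste0(p_norm, ".partial"))
    nm
  })

  p_auc <- out("auc.tsv")
  stage("auc", p_auc, {
    tab <- auc_table(normalized, groups)
    write_auc_table(tab, paste0(p_auc, ".partial"))
    tab
  })

  # --- classification -------------------------------------------------
  report <- NULL
  if (isTRUE(cfg$classify)) {
    p_rep <- out("classification.json")
    p_met <- out("metrics.tsv")
    p_sc <- out("scores.tsv")
    report <- stage("classify", c(p_rep, p_met, p_sc), {
      rep <- cross_validate(profiles, groups, folds = cfg$folds,
                            repetitions = cfg$repetitions, cost = cfg$cost,
                            seed = cfg$seed)
      jsonlite::write_json(
        list(median = as.list(rep$median),
             ci = as.data.frame(t(rep$ci)),
             per_repetition = rep$metrics,
             positive = rep$positive, folds = rep$folds,
             repetitions = rep$repetitions, cost = rep$cost),
        paste0(p_rep, ".partial"), auto_unbox = TRUE, digits = NA)
      m <- data.frame(
        task = paste(levels(groups), collapse = " vs "),
        accuracy = rep$median["accuracy"],
        accuracy_ci = sprintf("%.3f-%.3f", rep$ci["lower", "accuracy"],
                              rep$ci["upper", "accuracy"]),
        sensitivity = rep$median["sensitivity"],
        sensitivity_ci = sprintf("%.3f-%.3f", rep$ci["lower", "sensitivity"],
                                 rep$ci["upper", "sensitivity"]),
        specificity = rep$median["specificity"],
        specificity_ci = sprintf("%.3f-%.3f", rep$ci["lower", "specificity"],
                                 rep$ci["upper", "specificity"])
      )
      utils::write.table(m, paste0(p_met, ".partial"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(decision_scores(rep), paste0(p_sc, ".partial"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    })
  }

  if (isTRUE(cfg$permute) && cfg$n_permutations > 0L) {
    p_perm <- out("permutations.json")
    stage("permute", p_perm, {
      pt <- permutation_test(profiles, groups,
                             n_permutations = cfg$n_permutations,
                             folds = cfg$folds, cost = cfg$cost,
                             seed = cfg$seed, observed = report)
      jsonlite::write_json(
        list(accuracies = pt$accuracies, median = pt$median,
             mean = pt$mean, p_value = pt$p_value),
        paste0(p_perm, ".partial"), auto_unbox = TRUE, digits = NA)
      pt
    })
  }

  # --- manifest -------------------------------------------------------
  p_cfg <- out("config.json")
  write_run_config(cfg, p_cfg)
  files <- c(files, p_cfg)
  manifest <- list(
    package = "seroarray",
    version = as.character(utils::packageVersion("seroarray")),
    seed = cfg$seed,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    warnings = warns
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
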