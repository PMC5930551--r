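#' Read and validate a subject manifest
#'
#' Tab-delimited manifest with required columns \code{subject_id},
#' \code{site}, \code{group}, \code{bdi}, \code{gender}. Ids must be
#' unique; sites must come from the allowed set; groups must be
#' \code{patient} / \code{control}.
#'
#' @param path manifest file path.
#' @param allowed_sites permitted site labels.
#' @return validated data frame.
#' @export
read_manifest <- function(path, allowed_sites = c("A", "B", "C")) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "site", "group", "bdi", "gender")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  }
  bad_site <- setdiff(unique(df$site), allowed_sites)
  if (length(bad_site)) {
    stop("unknown site label(s): ", paste(bad_site, collapse = ", "),
         " (allowed: ", paste(allowed_sites, collapse = ", "), ")")
  }
  if (!all(df$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'")
  }
  df
}

#' Assemble a pipeline run configuration
#'
#' Bundles every stage's parameters with explicit seeds and stage
#' toggles. The configuration round-trips through the key-value text
#' format (\code{\link{write_run_config}} / \code{\link{read_run_config}}).
#'
#' @param seed master seed (every stage derives its own stream).
#' @param stages character vector of stages to run, a subset of
#'   \code{c("preproc", "connectivity", "hdi", "reorg", "svm", "cvae")}.
#' @param density link density for thresholding.
#' @param hdi_metric nodal metric for the HDI stage.
#' @param gamma,omega,n_subsample,n_reps,n_perms multislice parameters.
#' @param svm_n_boot,svm_n_perm SVM machinery sizes.
#' @param cvae_n_ensemble ensemble size.
#' @param profile \code{"desk"} or \code{"full"} scale.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L,
                       stages = c("preproc", "connectivity", "hdi", "reorg",
                                  "svm", "cvae"),
                       density = 0.10, hdi_metric = "degree",
                       gamma = 1.5, omega = 0.1,
                       n_subsample = 70, n_reps = NULL, n_perms = NULL,
                       svm_n_boot = 5, svm_n_perm = 0,
                       cvae_n_ensemble = 3,
                       profile = c("desk", "full")) {
  profile <- match.arg(profile)
  structure(list(seed = as.integer(seed), stages = stages,
                 density = density, hdi_metric = hdi_metric,
                 gamma = gamma, omega = omega,
                 n_subsample = as.integer(n_subsample),
                 n_reps = n_reps, n_perms = n_perms,
                 svm_n_boot = as.integer(svm_n_boot),
                 svm_n_perm = as.integer(svm_n_perm),
                 cvae_n_ensemble = as.integer(cvae_n_ensemble),
                 profile = profile),
            class = "run_config")
}

#' Write / read a run configuration as key-value text
#' @param config a \code{\link{run_config}}.
#' @param path file path.
#' @return \code{path} / the re-read \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  enc <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    paste0(nm, "=", if (is.null(v)) "NULL" else paste(v, collapse = ","))
  }, character(1))
  writeLines(enc, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    val <- if (p[2] == "NULL") NULL else strsplit(p[2], ",", fixed = TRUE)[[1]]
    if (!is.null(val) && !anyNA(suppressWarnings(as.numeric(val))) &&
        p[1] != "hdi_metric") {
      val <- as.numeric(val)
      if (all(val == round(val))) val <- as.integer(val)
    }
    out[[p[1]]] <- val
  }
  structure(out, class = "run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes preprocessing, connectivity, hub disruption, modular
#' reorganisation and classification on an in-memory cohort, per the
#' stage toggles of the configuration; each stage derives its seed from
#' the master seed, so a rerun with the same config reproduces every
#' table. Stage failures halt with a stage-named error; completed
#' results are preserved in the returned bundle.
#'
#' @param cohort a \code{\link{simulate_cohort}}-shaped list.
#' @param config a \code{\link{run_config}}.
#' @return named list of stage result bundles plus a \code{log}
#'   data frame of stage/parameter records.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  res <- list(config = config)
  logs <- list()
  note <- function(stage, msg) {
    logs[[length(logs) + 1]] <<- data.frame(stage = stage, message = msg,
                                            stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- cohort$manifest

  if ("preproc" %in% config$stages) {
    res$preproc <- run_stage("preproc", preprocess_cohort(cohort))
    excluded <- res$preproc$qc$subject_id[res$preproc$qc$excluded_flag]
    note("preproc", paste0("fd_threshold=0.5;excluded=",
                           paste(excluded, collapse = ",")))
    manifest <- manifest[!manifest$subject_id %in% excluded, , drop = FALSE]
  }

  if ("connectivity" %in% config$stages) {
    res$connectivity <- run_stage("connectivity", {
      adj <- list(); corr <- list()
      for (id in manifest$subject_id) {
        pp <- res$preproc$subjects[[id]]
        cm <- if (!is.null(pp)) correlation_matrix(pp$ts, pp$mask)
              else correlation_matrix(cohort$timeseries[[id]])
        corr[[id]] <- cm
        adj[[id]] <- threshold_to_density(cm, config$density)
      }
      list(correlations = corr, adjacencies = adj)
    })
    note("connectivity", paste0("density=", config$density))
  }

  if ("hdi" %in% config$stages) {
    res$hdi <- run_stage("hdi", {
      profiles <- lapply(res$connectivity$adjacencies, nodal_metric,
                         metric_name = config$hdi_metric)
      cohort_hdi(profiles, manifest)
    })
    note("hdi", paste0("metric=", config$hdi_metric, ";welch=TRUE"))
  }

  if ("reorg" %in% config$stages) {
    res$reorg <- run_stage("reorg", {
      mc <- modularity_config(gamma = config$gamma, omega = config$omega,
                              n_subsample = config$n_subsample,
                              n_reps = config$n_reps,
                              n_perms = config$n_perms,
                              seed = child_seed(config$seed, 4),
                              profile = config$profile)
      reorg_permutation_test(res$connectivity$adjacencies[manifest$subject_id],
                             manifest, mc)
    })
    note("reorg", paste0("gamma=", config$gamma, ";omega=", config$omega,
                         ";subsample=", config$n_subsample))
  }

  if ("svm" %in% config$stages) {
    res$svm <- run_stage("svm", {
      feats <- do.call(rbind, lapply(
        res$connectivity$correlations[manifest$subject_id],
        connectivity_features))
      svm_validate(feats, manifest, scheme = "model2", labelling = "pain",
                   n_boot = config$svm_n_boot, n_perm = config$svm_n_perm,
                   seed = child_seed(config$seed, 5))
    })
    note("svm", paste0("n_boot=", config$svm_n_boot))
  }

  if ("cvae" %in% config$stages) {
    res$cvae <- run_stage("cvae", {
      holdout <- max(manifest$site)
      train_ids <- manifest$subject_id[manifest$site != holdout]
      test_ids <- manifest$subject_id[manifest$site == holdout]
      ts <- lapply(manifest$subject_id, function(id) {
        pp <- res$preproc$subjects[[id]]
        if (!is.null(pp)) pp$ts$data[pp$mask, , drop = FALSE]
        else cohort$timeseries[[id]]$data
      })
      names(ts) <- manifest$subject_id
      cfg <- cvae_config(n_rois = ncol(ts[[1]]),
                         n_ensemble = config$cvae_n_ensemble,
                         seed = child_seed(config$seed, 6),
                         profile = config$profile)
      cvae_validate(ts, manifest, train_ids, test_ids, cfg)
    })
    note("cvae", paste0("ensemble=", config$cvae_n_ensemble))
  }

  res$log <- do.call(rbind, logs)
  res
}
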