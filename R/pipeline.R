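# End-to-end experiment orchestration: one config object describes a
# (representation, mode) cell of the experiment grid; run_experiment()
# executes it on synthetic data and persists a self-describing run directory.

#' Experiment run configuration
#'
#' @param representation One of `"handcrafted"`, `"ddtw"`, `"cnn"`.
#' @param mode One of `"template"` (medoids fixed to the four class
#'   templates), `"baseline"` (free medoids at `k`), `"optimal"` (k selected
#'   by scanning `k_range`).
#' @param k Cluster count for template/baseline modes (default 4).
#' @param k_range Grid scanned in optimal mode (default 1:15).
#' @param synth Synthetic dataset config ([synthetic_config()]).
#' @param ae Autoencoder config ([ae_config()]), used when
#'   `representation = "cnn"`.
#' @param ddtw_w Sakoe-Chiba half-width for DDTW (default 20).
#' @param compute_ps Compute prediction strength during the optimal-mode
#'   scan. Defaults to TRUE for the feature representations and FALSE for
#'   DDTW, whose prediction strength is markedly more expensive; set TRUE to
#'   opt in.
#' @param ps_threshold Prediction-strength threshold for [choose_k()].
#' @param seed Seed for the split and the scan.
#' @param out_dir Output directory for run artifacts (`NULL`: nothing
#'   written).
#' @return List of class `dvp_run_config`.
#' @export
run_config <- function(representation = c("handcrafted", "ddtw", "cnn"),
                       mode = c("baseline", "template", "optimal"),
                       k = 4L, k_range = 1:15,
                       synth = synthetic_config(),
                       ae = ae_config(),
                       ddtw_w = 20L,
                       compute_ps = NULL,
                       ps_threshold = 0.7,
                       seed = 1L,
                       out_dir = NULL) {
  representation <- match.arg(representation)
  mode <- match.arg(mode)
  if (is.null(compute_ps)) compute_ps <- representation != "ddtw"
  structure(list(representation = representation, mode = mode,
                 k = as.integer(k), k_range = as.integer(k_range),
                 synth = synth, ae = ae, ddtw_w = ddtw_w,
                 compute_ps = compute_ps, ps_threshold = ps_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "dvp_run_config")
}

#' Prepare shared experiment inputs
#'
#' Generates the synthetic dataset, normalizes all pulses onto the canonical
#' grid, draws the train/val/test split, and renders the four normalized
#' class templates. The same prepared object can be shared by every cell of
#' the experiment grid, so data, split and templates are identical across
#' representations and modes.
#'
#' @param synth A [synthetic_config()].
#' @param seed Seed of the split.
#' @return List of class `dvp_prepared` with `dataset`, `pulses` (normalized
#'   matrix), `split` (factor), `templates` (4 x 100 matrix) and `clinical`.
#' @export
prepare_experiment <- function(synth = synthetic_config(), seed = 1L) {
  dataset <- generate_dataset(synth)
  pulses <- normalize_pulses(dataset$pulses)
  split <- split_dataset(nrow(pulses), seed = seed)
  templates <- normalize_pulses(lapply(make_class_templates(),
                                       render_template))
  structure(list(dataset = dataset, pulses = pulses, split = split,
                 templates = templates, clinical = dataset$clinical,
                 labels = dataset$labels, synth = synth, seed = seed),
            class = "dvp_prepared")
}

# Representation-specific inputs for clustering the test partition:
# either a feature matrix plus template features, or a dissimilarity matrix
# plus pulse-to-template dissimilarities.
compute_representation <- function(prepared, config) {
  te <- prepared$split == "test"
  tr <- prepared$split == "train"
  va <- prepared$split == "val"
  switch(config$representation,
    handcrafted = {
      feats <- extract_feature_matrix(prepared$pulses)
      sc <- fit_feature_scaler(feats[tr, , drop = FALSE],
                               drop_constant = TRUE)
      list(kind = "features",
           x = predict(sc, feats[te, , drop = FALSE]),
           templates = predict(sc, extract_feature_matrix(prepared$templates)),
           scaler = sc)
    },
    cnn = {
      model <- build_autoencoder(config$ae)
      model <- train_autoencoder(model, prepared$pulses[tr, , drop = FALSE],
                                 prepared$pulses[va, , drop = FALSE])
      list(kind = "features",
           x = encode_pulses(model, prepared$pulses[te, , drop = FALSE]),
           templates = encode_pulses(model, prepared$templates),
           model = model)
    },
    ddtw = {
      list(kind = "diss",
           x = pairwise_ddtw(prepared$pulses[te, , drop = FALSE],
                             w = config$ddtw_w),
           cross = cross_ddtw(prepared$pulses[te, , drop = FALSE],
                              prepared$templates, w = config$ddtw_w))
    })
}

#' Run one experiment configuration
#'
#' Executes a single (representation, mode) cell end-to-end on synthetic
#' data: generate and normalize pulses, split, compute the representation on
#' the clustering (test) partition, cluster in the requested mode, and score
#' the clusters against the clinical covariates (per-cluster normalized
#' means, Kruskal-Wallis + Welch tests, and the weighted quantile-distance
#' `d` per covariate). All stages are seeded, so a rerun of the same config
#' reproduces every artifact.
#'
#' @param config A [run_config()].
#' @param prepared Optional [prepare_experiment()] output to share data
#'   across configs; built from `config$synth` when NULL.
#' @param representation_cache Optional result of a previous internal
#'   representation computation for the same prepared data (as found in a
#'   previous run's `$representation`), reused to avoid recomputation.
#' @return List of class `dvp_experiment`: the `config`, the cluster
#'   `result` (`dvp_kmedoids`), `counts` (size and percentage per cluster),
#'   `inertia`, selection `curves` and `chosen_k` (optimal mode), clinical
#'   `csm` (data.frame of `d` per covariate), `tests`
#'   (`dvp_test_report`), `cluster_means`, and the test-row indices.
#' @export
run_experiment <- function(config, prepared = NULL,
                           representation_cache = NULL) {
  stopifnot(inherits(config, "dvp_run_config"))
  if (is.null(prepared)) {
    prepared <- prepare_experiment(config$synth, seed = config$seed)
  }
  rep_data <- if (is.null(representation_cache)) {
    compute_representation(prepared, config)
  } else representation_cache
  te_idx <- which(prepared$split == "test")

  curves <- NULL
  chosen_k <- NULL
  if (config$mode == "template") {
    cross <- if (rep_data$kind == "diss") {
      rep_data$cross
    } else {
      pracma::distmat(rep_data$x, rep_data$templates)
    }
    result <- assign_fixed_medoids(cross)
    inertia <- cluster_inertia(result, cross)
  } else if (config$mode == "baseline") {
    result <- kmedoids_fit(rep_data$x, config$k,
                           diss = rep_data$kind == "diss")
    inertia <- cluster_inertia(result, rep_data$x)
  } else {
    curves <- scan_k(rep_data$x, k_range = config$k_range,
                     compute_ps = config$compute_ps, seed = config$seed,
                     method = paste(config$representation, config$mode))
    chosen_k <- choose_k(curves, ps_threshold = config$ps_threshold)
    result <- attr(curves, "fits")[[match(chosen_k, curves$k)]]
    result$mode <- "optimal"
    inertia <- cluster_inertia(result, rep_data$x)
  }

  clin_te <- prepared$clinical[te_idx, , drop = FALSE]
  covars <- setdiff(names(clin_te), c("subject_id", "true_class"))
  csm <- do.call(rbind, lapply(covars, function(v) {
    rep_ <- csm_weighted_distance(result$labels, clin_te[[v]], variable = v)
    data.frame(variable = v, d = rep_$d)
  }))
  tests <- kruskal_then_welch(result$labels, clin_te[covars])
  cmeans <- cluster_means_normalized(result$labels, clin_te[covars])
  sizes <- tabulate(result$labels, result$k)
  counts <- data.frame(cluster = seq_len(result$k), size = sizes,
                       percent = 100 * sizes / length(result$labels))

  out <- structure(list(config = config, result = result, counts = counts,
                        inertia = inertia, curves = curves,
                        chosen_k = chosen_k, csm = csm, tests = tests,
                        cluster_means = cmeans, test_idx = te_idx,
                        representation = rep_data),
                   class = "dvp_experiment")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(pulse_index = x$test_idx, label = x$result$labels),
            file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(x$counts, file.path(dir, "counts.csv"), row.names = FALSE)
  write.csv(x$csm, file.path(dir, "csm_distances.csv"), row.names = FALSE)
  write.csv(x$tests$kruskal, file.path(dir, "kruskal.csv"), row.names = FALSE)
  write.csv(x$tests$welch, file.path(dir, "welch.csv"), row.names = FALSE)
  write.csv(data.frame(cluster = rownames(x$cluster_means), x$cluster_means),
            file.path(dir, "cluster_means.csv"), row.names = FALSE)
  if (!is.null(x$curves)) {
    write.csv(as.data.frame(x$curves), file.path(dir, "curves.csv"),
              row.names = FALSE)
  }
  sidecar <- list(representation = x$config$representation,
                  mode = x$config$mode, k = x$result$k,
                  chosen_k = x$chosen_k,
                  medoid_idx = x$result$medoid_idx,
                  objective = x$result$objective, inertia = x$inertia,
                  seed = x$config$seed,
                  synth_seed = x$config$synth$seed,
                  n_test = length(x$test_idx))
  jsonlite::write_json(sidecar, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.dvp_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %s / %s on %d test pulses\n",
              x$config$representation, x$config$mode, length(x$test_idx)))
  if (!is.null(x$chosen_k)) cat("Selected k:", x$chosen_k, "\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("Mean squared inertia: %.4g\n", x$inertia))
  cat("Covariate separation d:\n")
  print(x$csm, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full experiment grid
#'
#' All representation x mode combinations (3 x 3 = 9 by default) on one
#' shared synthetic dataset and split. Each representation is computed once
#' and reused across its three modes.
#'
#' @param synth A [synthetic_config()].
#' @param representations,modes Subsets of the grid axes.
#' @param out_dir Optional root directory; each cell writes to
#'   `<out_dir>/<representation>_<mode>/`.
#' @param seed Split/scan seed.
#' @param ... Passed on to [run_config()] (e.g. `ae`, `k_range`,
#'   `compute_ps`).
#' @return Named list of `dvp_experiment` objects
#'   (`"<representation>_<mode>"`).
#' @export
run_experiment_grid <- function(synth = synthetic_config(),
                                representations = c("handcrafted", "ddtw",
                                                    "cnn"),
                                modes = c("template", "baseline", "optimal"),
                                out_dir = NULL, seed = 1L, ...) {
  prepared <- prepare_experiment(synth, seed = seed)
  out <- list()
  for (rep_ in representations) {
    cache <- NULL
    for (mode in modes) {
      cfg <- run_config(representation = rep_, mode = mode, synth = synth,
                        seed = seed,
                        out_dir = if (is.null(out_dir)) NULL else
                          file.path(out_dir, paste0(rep_, "_", mode)), ...)
      if (is.null(cache)) cache <- compute_representation(prepared, cfg)
      out[[paste0(rep_, "_", mode)]] <-
        run_experiment(cfg, prepared = prepared, representation_cache = cache)
    }
  }
  out
}
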