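#' Validate a pipeline configuration
#'
#' Schema-checks a run configuration (YAML path or list) without doing
#' any computation: required sections, known keys, positive numeric
#' parameters, valid phantom topologies, and existence of any referenced
#' input files.
#'
#' @param config path to a YAML file, or a configuration list.
#' @return List with `ok` (logical) and `errors` (character vector).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) {
      return(list(ok = FALSE, errors = sprintf("Config file not found: %s", config)))
    }
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      NULL
    })
    if (is.null(config)) {
      return(list(ok = FALSE, errors = "Malformed YAML."))
    }
  }
  allowed_top <- c("seed", "output_dir", "conditions", "preprocess", "skeleton", "stats")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown) > 0) {
    errors <- c(errors, sprintf(
      "Unknown top-level key(s): %s (allowed: %s)",
      paste(unknown, collapse = ", "), paste(allowed_top, collapse = ", ")
    ))
  }
  if (is.null(config$conditions) || length(config$conditions) < 1) {
    errors <- c(errors, "At least one condition is required.")
  } else {
    nms <- vapply(config$conditions, function(cn) cn$name %||% "", character(1))
    if (any(nms == "")) errors <- c(errors, "Every condition needs a `name`.")
    if (anyDuplicated(nms)) errors <- c(errors, "Condition names must be unique.")
    for (cn in config$conditions) {
      has_phantom <- !is.null(cn$phantom)
      has_files <- !is.null(cn$masks)
      if (!has_phantom && !has_files) {
        errors <- c(errors, sprintf(
          "Condition '%s' needs either a `phantom` spec or `masks` file list.",
          cn$name %||% "?"
        ))
      }
      if (has_phantom) {
        topo <- cn$phantom$topology %||% ""
        if (!topo %in% c("straight_tube", "y_junction", "random_tree")) {
          errors <- c(errors, sprintf(
            "Condition '%s': unknown topology '%s'.", cn$name %||% "?", topo
          ))
        }
        for (key in c("tube_radius_um", "n_segments", "length_um")) {
          val <- cn$phantom[[key]]
          if (!is.null(val) && (!is.numeric(val) || val <= 0)) {
            errors <- c(errors, sprintf(
              "Condition '%s': `%s` must be positive.", cn$name %||% "?", key
            ))
          }
        }
      }
      if (has_files) {
        missing <- cn$masks[!file.exists(unlist(cn$masks))]
        if (length(missing) > 0) {
          errors <- c(errors, sprintf("Missing input file(s): %s",
                                      paste(unlist(missing), collapse = ", ")))
        }
      }
      ng <- cn$n_gels %||% 3
      if (!is.numeric(ng) || ng < 1) {
        errors <- c(errors, sprintf("Condition '%s': `n_gels` must be >= 1.", cn$name %||% "?"))
      }
    }
  }
  pp <- config$preprocess %||% list()
  if (!is.null(pp$sigma_um) && pp$sigma_um < 0) {
    errors <- c(errors, "`preprocess.sigma_um` must be >= 0.")
  }
  if (!is.null(pp$min_object_voxels) && pp$min_object_voxels < 0) {
    errors <- c(errors, "`preprocess.min_object_voxels` must be >= 0.")
  }
  sk <- config$skeleton %||% list()
  if (!is.null(sk$prune_um) && sk$prune_um < 0) {
    errors <- c(errors, "`skeleton.prune_um` must be >= 0.")
  }
  st <- config$stats %||% list()
  metrics_allowed <- c(
    "total_length_um", "total_length_per_mm3", "n_vessels", "n_branch_points",
    "n_endpoints", "n_branches", "avg_branch_length_um"
  )
  if (!is.null(st$metric) && !st$metric %in% metrics_allowed) {
    errors <- c(errors, sprintf(
      "`stats.metric` must be one of: %s", paste(metrics_allowed, collapse = ", ")
    ))
  }
  list(ok = length(errors) == 0, errors = errors)
}

derive_seed <- function(root, i, j = 0L) {
  as.integer((as.numeric(root) * 101 + i * 7919 + j * 104729) %% 2147483647)
}

#' Run the phantom-to-statistics pipeline
#'
#' Config-driven orchestration: for every condition, generate (or load)
#' each gel's vessel data, segment it, skeletonize, measure the network,
#' then route the chosen metric across conditions through the
#' statistical battery. All randomness flows from the single root
#' `seed` via per-gel derived seeds, so reruns with the same config are
#' identical and individual gels can be regenerated independently.
#'
#' @param config YAML path or configuration list; see
#'   [validate_config()] and the bundled demo config
#'   (`system.file("extdata", "demo_config.yaml", package = "angiometry")`).
#' @return List of class `angiometry_run`: `metrics` (per-gel tibble),
#'   `truth` (per-gel phantom ground truth where applicable), `stats`
#'   (a [route_and_test()] result or `NULL`), `provenance` (every
#'   parameter that was applied, defaults included), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    path <- config
    config <- yaml::read_yaml(path)
  }
  chk <- validate_config(config)
  if (!chk$ok) {
    abort(paste0("Invalid config:\n", paste("-", chk$errors, collapse = "\n")))
  }
  seed <- config$seed %||% 1L
  pp <- config$preprocess %||% list()
  pp_args <- list(
    sigma_um = pp$sigma_um %||% 2,
    filter = pp$filter %||% "median",
    threshold = pp$threshold %||% "otsu_global",
    min_object_voxels = pp$min_object_voxels %||% 27
  )
  prune_um <- (config$skeleton %||% list())$prune_um %||% 3
  st <- config$stats %||% list()
  metric <- st$metric %||% "n_vessels"
  alpha <- st$alpha %||% 0.05

  metrics <- list()
  truths <- list()
  for (ci in seq_along(config$conditions)) {
    cn <- config$conditions[[ci]]
    ng <- cn$n_gels %||% 3
    for (gi in seq_len(ng)) {
      if (!is.null(cn$phantom)) {
        spec_args <- cn$phantom
        spec_args$seed <- derive_seed(seed, ci, gi)
        spec <- do.call(vessel_phantom_spec, spec_args)
        ph <- generate_vessel_phantom(spec)
        mask <- do.call(preprocess_stack, c(list(ph$stack), pp_args))
        vol <- stack_volume_mm3(ph$stack)
        truths[[length(truths) + 1]] <- tibble(
          condition = cn$name, gel = gi,
          true_n_segments = ph$truth$n_segments,
          true_total_length_um = ph$truth$total_length_um,
          true_n_junctions = ph$truth$n_junctions,
          true_n_endpoints = ph$truth$n_endpoints
        )
      } else {
        mask_path <- unlist(cn$masks)[gi]
        if (is.na(mask_path)) abort(sprintf("Condition '%s' gel %d: no mask file.", cn$name, gi))
        ms <- read_stack(mask_path)
        mask <- image_stack(ms$voxels > 0.5, ms$voxel_size_um, ms$channel)
        vol <- stack_volume_mm3(mask)
      }
      m <- measure_mask(mask, prune_um = prune_um, volume_mm3 = vol)
      metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
        tibble(condition = cn$name, gel = gi), m
      )
    }
  }
  metrics <- purrr::list_rbind(metrics)
  truth <- if (length(truths) > 0) purrr::list_rbind(truths) else NULL

  fit <- NULL
  if (length(config$conditions) >= 2) {
    d <- data.frame(value = metrics[[metric]], group = metrics$condition)
    fit <- route_and_test(d, alpha = alpha, quiet = TRUE)
  }

  provenance <- list(
    seed = seed, preprocess = pp_args, prune_um = prune_um,
    stats = list(metric = metric, alpha = alpha),
    package_version = as.character(utils::packageVersion("angiometry")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(truth)) {
      utils::write.csv(truth, file.path(out_dir, "phantom_truth.csv"), row.names = FALSE)
    }
    if (!is.null(fit)) {
      utils::write.csv(tidy(fit), file.path(out_dir, "posthoc.csv"), row.names = FALSE)
      jsonlite::write_json(
        c(glance(fit), list()), file.path(out_dir, "stat_routing.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  structure(
    list(metrics = metrics, truth = truth, stats = fit,
         provenance = provenance, config = config),
    class = "angiometry_run"
  )
}

#' @export
print.angiometry_run <- function(x, ...) {
  cat(sprintf(
    "<angiometry_run> %d gels across %d condition(s)\n",
    nrow(x$metrics), length(unique(x$metrics$condition))
  ))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}
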