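#' Write and read the dataset container
#'
#' The container is a single-file named-object archive (a serialized R list,
#' portable and compressed) holding arrays (trials, labels, codes, templates,
#' model parameters), scalar metadata, and a version tag, with a JSON sidecar
#' of the originating configuration when one is attached. Round trips are
#' lossless: every array is restored bit-for-bit.
#'
#' @param container Named list to store. For `type = "dataset"` the fields
#'   `trials`, `labels`, `codes`, `sample_rate` are mandatory.
#' @param path Destination file path (`.rds`; the sidecar is `path` + `.json`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` the
#'   restored container.
#' @export
write_dataset <- function(container, path) {
  if (!is.list(container)) stop_invalid("`container` must be a list")
  container$container_version <- container$container_version %||% "1.0"
  validate_container(container)
  saveRDS(container, path)
  cfg <- container$config
  if (!is.null(cfg)) {
    jsonlite::write_json(
      unclass(cfg)[!vapply(unclass(cfg), is.function, TRUE)],
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  container <- readRDS(path)
  validate_container(container)
  container
}

validate_container <- function(container) {
  type <- container$type %||% "dataset"
  mandatory <- switch(type,
    dataset = c("trials", "labels", "codes", "sample_rate"),
    model = c("w", "r", "templates", "sample_rate"),
    character(0)
  )
  missing <- setdiff(mandatory, names(container))
  if (length(missing) > 0L) {
    abort(
      sprintf(
        "container of type '%s' is missing mandatory field(s): %s",
        type, paste(missing, collapse = ", ")
      ),
      class = "bdstop_schema_error"
    )
  }
  invisible(container)
}

#' Default run configuration
#'
#' All module defaults in one validated list: decision-grid step, cost ratio,
#' targeted accuracy, similarity kind, response length, simulation settings,
#' and seed. Unknown keys are rejected on validation so typos cannot pass
#' silently.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    grid_step_s = 0.1,
    zeta = 1,
    theta = 0.9,
    similarity = "inner",
    response_len_s = 0.3,
    n_classes = 36L,
    n_reps = 3L,
    n_channels = 8L,
    sample_rate = 120,
    n_cycles = 4L,
    alpha = 1,
    sigma = 1.1,
    frame_rate = 60,
    degree = 6L,
    n_folds = 5L,
    overhead_s = 0,
    seed = 1L
  )
}

#' Validate and merge a run configuration
#'
#' @param config Named list of overrides (e.g. parsed from a YAML file).
#' @return The merged configuration (defaults overridden by `config`).
#' @export
validate_run_config <- function(config = list()) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(
      sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
      class = "bdstop_schema_error"
    )
  }
  utils::modifyList(defaults, config)
}

read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path) %||% list())
}

#' Command-line entry point
#'
#' Dispatches the subcommands `codes`, `simulate`, `calibrate`, `decode`,
#' `sweep`, and `evaluate` over the package's functions; the thin executable
#' shipped at `inst/cli/bdstop` forwards `commandArgs(TRUE)` here. Every run
#' logs the resolved configuration (JSON, one line) so deterministic paths
#' can be reproduced exactly from the log.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success, 2 on usage error,
#'   1 on runtime failure).
#' @export
run_command <- function(argv) {
  usage <- paste(
    "usage: bdstop <codes|simulate|calibrate|decode|sweep|evaluate> [--key value ...]",
    "  codes     --degree 6 --n-classes 36 --out codes.txt [--modulate]",
    "  simulate  --seed 1 --out data.rds [--config run.yaml]",
    "  calibrate --input data.rds --out model.rds [--zeta 1]",
    "  decode    --input data.rds --model model.rds --method bds --out log.csv",
    "  sweep     --input data.rds --method bds --hyper 0.01,1,100 --out sweep.csv",
    "  evaluate  --log log.csv --out metrics.json",
    sep = "\n"
  )
  if (length(argv) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- argv[1L]
  opts <- tryCatch(parse_cli_options(argv[-1L]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", usage)
    return(invisible(2L))
  }
  status <- tryCatch(
    {
      switch(cmd,
        codes = cli_codes(opts),
        simulate = cli_simulate(opts),
        calibrate = cli_calibrate(opts),
        decode = cli_decode(opts),
        sweep = cli_sweep(opts),
        evaluate = cli_evaluate(opts),
        {
          message(sprintf("unknown subcommand '%s'\n%s", cmd, usage))
          return(invisible(2L))
        }
      )
      0L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  flags <- c("modulate") # boolean flags take no value
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- gsub("-", "_", substring(a, 3L))
    if (key %in% flags) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i + 1L > length(args)) stop(sprintf("missing value for '%s'", a))
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

resolve_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else validate_run_config()
  numeric_keys <- c(
    "zeta", "theta", "sigma", "alpha", "grid_step_s", "overhead_s",
    "sample_rate", "frame_rate", "response_len_s"
  )
  int_keys <- c("seed", "n_classes", "n_reps", "n_channels", "n_cycles", "n_folds", "degree")
  for (k in intersect(names(opts), names(cfg))) {
    cfg[[k]] <- if (k %in% numeric_keys) {
      as.numeric(opts[[k]])
    } else if (k %in% int_keys) {
      as.integer(opts[[k]])
    } else {
      opts[[k]]
    }
  }
  inform(paste0(
    "resolved config: ",
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  ))
  cfg
}

cli_codes <- function(opts) {
  cfg <- resolve_config(opts)
  pair <- default_preferred_pair()
  fam <- gold_code_family(pair$u, pair$v, frame_rate = cfg$frame_rate)
  if (isTRUE(opts$modulate)) fam <- modulate(fam)
  n <- min(as.integer(opts$n_classes %||% cfg$n_classes), nrow(fam))
  out <- opts$out %||% stop("--out is required")
  writeLines(apply(fam[seq_len(n), , drop = FALSE], 1L, paste, collapse = ""), out)
  inform(sprintf("wrote %d codes x %d frames to %s", n, ncol(fam), out))
}

cli_simulate <- function(opts) {
  cfg <- resolve_config(opts)
  ds <- simulate_dataset(sim_config(
    n_classes = cfg$n_classes, n_reps = cfg$n_reps,
    n_channels = cfg$n_channels, sample_rate = cfg$sample_rate,
    n_cycles = cfg$n_cycles, alpha = cfg$alpha, sigma = cfg$sigma,
    response_len_s = cfg$response_len_s, frame_rate = cfg$frame_rate,
    seed = cfg$seed
  ))
  out <- opts$out %||% stop("--out is required")
  write_dataset(
    list(
      type = "dataset", trials = ds$trials, labels = ds$labels,
      codes = unclass(ds$codes), sample_rate = ds$sample_rate,
      structures = ds$structures, ground_truth = ds$ground_truth,
      config = cfg
    ),
    out
  )
  inform(sprintf("wrote dataset to %s", out))
}

load_sim_dataset <- function(path) {
  cont <- read_dataset(path)
  structure(
    list(
      trials = cont$trials, labels = cont$labels, codes = cont$codes,
      structures = cont$structures, sample_rate = cont$sample_rate,
      config = cont$config, ground_truth = cont$ground_truth
    ),
    class = "sim_dataset"
  )
}

cli_calibrate <- function(opts) {
  cfg <- resolve_config(opts)
  ds <- load_sim_dataset(opts$input %||% stop("--input is required"))
  fit <- fit_rcca(ds$trials, ds$labels, ds$structures)
  model <- calibrate_bds(ds$trials, ds$labels, fit, zeta = cfg$zeta)
  write_dataset(
    list(
      type = "model", w = fit$w, r = fit$r, templates = fit$templates,
      sample_rate = ds$sample_rate, bds = model, config = cfg
    ),
    opts$out %||% stop("--out is required")
  )
  inform(sprintf("wrote model to %s", opts$out))
}

cli_decode <- function(opts) {
  cfg <- resolve_config(opts)
  ds <- load_sim_dataset(opts$input %||% stop("--input is required"))
  method <- opts$method %||% "bds"
  spec <- method_spec(method,
    zeta = cfg$zeta, theta = cfg$theta,
    similarity = cfg$similarity, overhead_s = cfg$overhead_s
  )
  fit <- fit_rcca(ds$trials, ds$labels, ds$structures)
  fit$structures <- ds$structures
  grid <- default_grid(dim(ds$trials)[3], ds$sample_rate, cfg$grid_step_s)
  rule <- build_rule(spec, ds$trials, ds$labels, fit, grid, seed = cfg$seed)
  log <- decode_trials(ds$trials, ds$labels, fit, rule, grid, spec$similarity)
  utils::write.csv(log, opts$out %||% stop("--out is required"), row.names = FALSE)
  inform(sprintf("wrote decision log (%d rows) to %s", nrow(log), opts$out))
}

cli_sweep <- function(opts) {
  cfg <- resolve_config(opts)
  ds <- load_sim_dataset(opts$input %||% stop("--input is required"))
  method <- opts$method %||% "bds"
  hyper <- as.numeric(strsplit(opts$hyper %||% "1", ",")[[1]])
  tab <- sweep_stopping(ds, method, hyper,
    n_folds = cfg$n_folds, seed = cfg$seed, similarity = cfg$similarity
  )
  utils::write.csv(tab, opts$out %||% stop("--out is required"), row.names = FALSE)
  inform(sprintf("wrote sweep table (%d rows) to %s", nrow(tab), opts$out))
}

cli_evaluate <- function(opts) {
  log <- utils::read.csv(opts$log %||% stop("--log is required"))
  counts <- confusion_counts(tibble::as_tibble(log))
  stops <- log[log$accepted, ]
  out <- list(
    tp = counts$tp, fp = counts$fp, tn = counts$tn, fn = counts$fn,
    accuracy = mean(stops$predicted == stops$true_label),
    mean_stop_time = mean(stops$time_s),
    precision = suppressMessages(precision(counts)),
    recall = suppressMessages(recall(counts)),
    specificity = suppressMessages(specificity(counts)),
    f_score = suppressMessages(f_score(counts))
  )
  jsonlite::write_json(out, opts$out %||% stop("--out is required"),
    auto_unbox = TRUE, digits = NA
  )
  inform(sprintf("wrote metrics to %s", opts$out))
}
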