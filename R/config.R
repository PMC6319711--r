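#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing one reproducible experiment run.
#' Required key: `experiment` (one of `"meanfield"`, `"abm"`,
#' `"equilibria"`, `"compare"`, `"sweep"`, `"agreement"`). Optional keys
#' with defaults mirroring the package's standard study settings:
#' `params` (a11/a12/a21/a22, default all 0.2), `case` (case_id/m/d,
#' default case 1), `graph` (type/N/p/K/rewire_p/min_degree, default
#' Erdős–Rényi N = 1000, p = 0.2), `T` (200), `seed` (1), `out_dir`
#' (`"."`), `scale` (`"full"` or `"test"`), `threshold` (0.5), plus the
#' experiment-specific keys `initial`, `replicates`, `ratio_xz`,
#' `ratio_yz`, `base_a11`, `base_a22`, `m`, `j_values`, `rewire_p`,
#' `replications`, `grid_resolution`. Unknown keys are rejected, and all
#' referenced values are validated against their module constructors
#' before any run starts.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated config object of class `ci_config`.
#' @examples
#' cfg_file <- tempfile(fileext = ".json")
#' writeLines('{"experiment": "meanfield", "T": 50, "seed": 1}', cfg_file)
#' load_config(cfg_file)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

config_defaults <- function() {
  list(
    params = list(a11 = 0.2, a12 = 0.2, a21 = 0.2, a22 = 0.2),
    case = list(case_id = 1, m = 1),
    graph = list(type = "er", N = 1000, p = 0.2),
    T = 200, seed = 1, out_dir = ".", scale = "full", threshold = 0.5,
    initial = NULL, replicates = NULL, ratio_xz = NULL, ratio_yz = NULL,
    base_a11 = 0.5, base_a22 = 0.5, m = 3, j_values = NULL,
    rewire_p = 0.1, replications = NULL, grid_resolution = 21
  )
}

#' @rdname load_config
#' @param config A named list with the same keys as the JSON schema.
#' @export
validate_config <- function(config) {
  allowed <- c("experiment", names(config_defaults()))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$experiment)) abort("config key 'experiment' is required")
  experiments <- c("meanfield", "abm", "equilibria", "compare", "sweep", "agreement")
  if (!config$experiment %in% experiments) {
    abort(sprintf("experiment must be one of: %s", paste(experiments, collapse = ", ")))
  }
  cfg <- utils::modifyList(config_defaults(), config, keep.null = TRUE)
  cfg$experiment <- config$experiment
  if (!cfg$scale %in% c("test", "full")) abort("scale must be 'test' or 'full'")

  # construct module objects now: constructor errors name the offending key
  cfg$params_obj <- do.call(payoff_params, as.list(cfg$params))
  cfg$case_obj <- do.call(case_spec, as.list(cfg$case))
  if (!is.numeric(cfg$T) || cfg$T < 0) abort("T must be a nonnegative number")
  if (!is.numeric(cfg$seed)) abort("seed must be numeric")

  # cross-field check: the graph must be able to supply the sample sets
  card <- case_cardinalities(cfg$case_obj)
  need <- max(card$M, card$D)
  if (!is.null(cfg$graph$min_degree) && cfg$graph$min_degree < need) {
    abort(sprintf(
      "graph min_degree %d is below the %d neighbours case %d requires",
      cfg$graph$min_degree, need, cfg$case_obj$case_id
    ))
  }
  if (!is.null(cfg$graph$N) && cfg$graph$N <= need) {
    abort("graph N is too small for the case's sample sets")
  }
  if (!is.null(cfg$initial)) {
    validate_state(as.numeric(cfg$initial))
  }
  structure(cfg, class = "ci_config")
}

#' @export
print.ci_config <- function(x, ...) {
  cat(sprintf("<ci_config> experiment = %s, case %d, seed %d, scale = %s\n",
              x$experiment, x$case_obj$case_id, x$seed, x$scale))
  invisible(x)
}

# scale = "test" shrinks problem sizes for quick desk runs
apply_scale <- function(cfg) {
  if (cfg$scale != "test") {
    cfg$replicates <- cfg$replicates %||% 10
    cfg$replications <- cfg$replications %||% 100
    cfg$j_values <- cfg$j_values %||% c(1:10, 15, 20)
    cfg$ratio_xz <- cfg$ratio_xz %||% seq(0.1, 2, length.out = 21)
    cfg$ratio_yz <- cfg$ratio_yz %||% seq(0.1, 2, length.out = 21)
    return(cfg)
  }
  cfg$graph$N <- min(cfg$graph$N %||% 200, 200)
  cfg$T <- min(cfg$T, 100)
  cfg$replicates <- cfg$replicates %||% 3
  cfg$replications <- cfg$replications %||% 20
  cfg$j_values <- cfg$j_values %||% c(2, 10)
  cfg$ratio_xz <- cfg$ratio_xz %||% seq(0.25, 2, length.out = 5)
  cfg$ratio_yz <- cfg$ratio_yz %||% seq(0.25, 2, length.out = 5)
  cfg
}

#' Run a configured experiment
#'
#' Executes the experiment described by a [load_config()] object, writing
#' tidy CSV results plus a JSON manifest (full configuration, seed,
#' package and R versions) into the output directory. Reruns with the same
#' configuration reproduce the CSVs exactly.
#'
#' @param config A `ci_config` (or a path to a JSON config file).
#' @param out_dir Output directory override; defaults to the config's
#'   `out_dir`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "ci_config")) abort("config must be a ci_config or a file path")
  cfg <- apply_scale(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  p_file <- function(name) file.path(out_dir, name)
  params <- cfg$params_obj
  case <- cfg$case_obj
  seed <- as.integer(cfg$seed)
  message(sprintf("running experiment '%s' (case %d, seed %d, scale %s)",
                  cfg$experiment, case$case_id, seed, cfg$scale))

  if (cfg$experiment == "meanfield") {
    init <- if (!is.null(cfg$initial)) {
      as.numeric(cfg$initial)
    } else {
      with_seed_if(seed, {
        u <- stats::runif(3)
        u / sum(u)
      })
    }
    tr <- iterate_mean_field(c(x = init[1], y = init[2], z = init[3]),
                             cfg$T, params, case)
    paths$trajectory <- write_trajectory_csv(tr, p_file("meanfield_trajectory.csv"))
    pp <- phase_portrait(params, case, cfg$grid_resolution)
    paths$phase_portrait <- write_phase_portrait_csv(pp, p_file("phase_portrait.csv"))
  } else if (cfg$experiment == "abm") {
    card <- case_cardinalities(case)
    graph <- build_graph(cfg$graph, min_degree = max(card$M, card$D),
                         seed = child_seed(seed, 1))
    message(sprintf("graph generated after %s attempt(s)",
                    graph$descriptor$attempts %||% NA))
    w0 <- init_opinions(graph$n, seed = child_seed(seed, 2))
    tr <- run_abm(graph, w0, params, case, cfg$T, seed = child_seed(seed, 3))
    paths$trajectory <- write_abm_trajectory_csv(tr, p_file("abm_trajectory.csv"))
    paths$graph <- write_graph_edgelist(graph, p_file("graph.edgelist"))
  } else if (cfg$experiment == "equilibria") {
    eq <- equilibrium_analysis(params, case)
    paths$equilibria <- write_equilibrium_csv(eq, p_file("equilibria.csv"))
  } else if (cfg$experiment == "compare") {
    blocks <- purrr::imap_dfr(study_payoffs(), function(pp, id) {
      cmp <- compare_processes(pp, case, graph_spec = cfg$graph,
                               T_steps = cfg$T,
                               seed = child_seed(seed, match(id, names(study_payoffs()))),
                               threshold = cfg$threshold)
      dplyr::mutate(cmp$trajectories, matrix_id = id, case = case$case_id)
    })
    blocks <- blocks[, c("matrix_id", "case", "t", "source", "x", "y", "z")]
    utils::write.csv(as.data.frame(blocks), p_file("compare.csv"),
                     row.names = FALSE, quote = FALSE)
    paths$compare <- p_file("compare.csv")
  } else if (cfg$experiment == "sweep") {
    sw <- ratio_sweep(
      ratio_xz = cfg$ratio_xz, ratio_yz = cfg$ratio_yz,
      base_a11 = cfg$base_a11, base_a22 = cfg$base_a22,
      case = case, graph_spec = cfg$graph, T_steps = cfg$T,
      replicates = cfg$replicates, seed = seed
    )
    utils::write.csv(
      as.data.frame(sw)[, c("ratio_xz", "ratio_yz", "final_x_fraction", "n_reps")],
      p_file("sweep.csv"), row.names = FALSE, quote = FALSE
    )
    paths$sweep <- p_file("sweep.csv")
  } else if (cfg$experiment == "agreement") {
    ag <- smallworld_agreement(
      case_id = case$case_id, m = cfg$m, j_values = cfg$j_values,
      rewire_p = cfg$rewire_p, N = cfg$graph$N %||% 100, T_steps = cfg$T,
      replications = cfg$replications, seed = seed, threshold = cfg$threshold
    )
    utils::write.csv(as.data.frame(ag), p_file("agreement.csv"),
                     row.names = FALSE, quote = FALSE)
    paths$agreement <- p_file("agreement.csv")
  }

  manifest <- list(
    experiment = cfg$experiment,
    config = cfg[setdiff(names(cfg), c("params_obj", "case_obj"))],
    seed = seed,
    package_version = as.character(utils::packageVersion("crossinhib")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, p_file("manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  paths$manifest <- p_file("manifest.json")
  invisible(paths)
}
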