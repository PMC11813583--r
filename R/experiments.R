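#' Built-in experiment presets
#'
#' Each preset bundles the reference beta-lactamase parameter set with the
#' geometry and grids of one standard computational experiment:
#'
#' * `droplet_trajectories`: single 100 pl droplet, `a_init` = 15 ug/ml,
#'   deterministic trajectories for inocula of 3..9 cells (the inoculum
#'   effect in miniature: 5 cells is the survival threshold).
#' * `phase_boundary`: critical-density curve over an `a_init` grid for
#'   `K_M` in \{1, 6.7, 15\} ug/ml.
#' * `outcome_scan`: single-draw stochastic outcome per (a_init, rho) cell,
#'   100 pl sub-volume.
#' * `survival_scan`: as `outcome_scan` but replicate-averaged mean ps.
#' * `survival_curve`: whole-population survival `Ps` versus fragmentation
#'   at rho = 5e7 cells/ml in V = 1e-4 ml, `a_init` in \{15, 35, 55, 75\}.
#' * `nonlethal_curve`: conditional sub-volume survival versus `m` for
#'   `a_init` in \{10, 15, 20, 30\} at the same density.
#' * `foraging_lag`: growth-onset lag versus `m` in \{1, 10, 100, 1000\}.
#'
#' @param preset preset name.
#' @param n_replicates replicate count (presets default to 1000, the usual
#'   figure-quality value; pass something smaller for quick runs).
#' @param seed master seed.
#' @return An `"experiment_config"` list with resolved parameters.
#' @export
experiment_config <- function(preset = c("droplet_trajectories",
                                         "phase_boundary", "outcome_scan",
                                         "survival_scan", "survival_curve",
                                         "nonlethal_curve", "foraging_lag"),
                              n_replicates = 1000L, seed = 1L) {
  preset <- match.arg(preset)
  base <- list(preset = preset, params = model_params(),
               n_replicates = as.integer(n_replicates),
               seed = as.integer(seed))
  extra <- switch(preset,
    droplet_trajectories = list(volume_pl = 100, a_init = 15,
                                n_init_grid = 3:9, t_max = 2000),
    phase_boundary = list(a_grid = seq(1, 80, by = 0.5),
                          K_M_grid = c(1, 6.7, 15)),
    outcome_scan = list(a_grid = c(5, 15, 30, 55, 80),
                        rho_grid = 10^seq(7, 8.5, length.out = 5),
                        volume_pl = 100, n_replicates = 1L),
    survival_scan = list(a_grid = c(5, 15, 30, 55, 80),
                         rho_grid = 10^seq(7, 8.5, length.out = 5),
                         volume_pl = 100),
    survival_curve = list(rho = 5e7, total_volume_ml = 1e-4,
                          a_grid = c(15, 35, 55, 75),
                          lambda_grid = 10^seq(log10(200), log10(0.5),
                                               length.out = 9)),
    nonlethal_curve = list(rho = 5e7, total_volume_ml = 1e-4,
                           a_grid = c(10, 15, 20, 30),
                           m_grid = c(1, 10, 100, 1000)),
    foraging_lag = list(fparams = foraging_params(), rho = 5e7,
                        total_volume_ml = 1e-4,
                        m_grid = c(1, 10, 100, 1000)))
  cfg <- utils::modifyList(base, extra)
  class(cfg) <- "experiment_config"
  cfg
}

.config_lines <- function(config) {
  flat <- function(x) paste(format(x, digits = 15, trim = TRUE),
                            collapse = ";")
  items <- c(preset = config$preset, seed = flat(config$seed),
             n_replicates = flat(config$n_replicates))
  p <- config$params
  items <- c(items, mu_per_min = flat(p$mu), gamma_per_min = flat(p$gamma),
             enzyme_rate_ug_per_cell_min = flat(p$enzyme_rate),
             K_M_ug_per_ml = flat(p$K_M), a_th_ug_per_ml = flat(p$a_th))
  for (nm in setdiff(names(config),
                     c("preset", "params", "seed", "n_replicates", "fparams")))
    items[nm] <- flat(config[[nm]])
  if (!is.null(config$fparams)) {
    f <- config$fparams
    items <- c(items, foraging_n_th = flat(f$n_th),
               foraging_s_init = flat(f$s_init))
  }
  paste0("# ", names(items), "=", unname(items))
}

.write_csv_with_header <- function(df, file, config) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.config_lines(config), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Run a preset experiment and write its outputs
#'
#' Executes the computation a preset describes and writes a results CSV
#' (prefixed with `#`-comment lines embedding the fully resolved
#' configuration and seed) plus a JSON run summary. Outputs are
#' deterministic: the same configuration and seed reproduce identical files.
#'
#' @param config an [experiment_config()].
#' @param output_dir writable output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
run_experiment <- function(config, output_dir) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  p <- config$params
  files <- c()
  summary <- list(preset = config$preset, seed = config$seed)

  result <- switch(config$preset,
    droplet_trajectories = {
      v <- convert_volume(config$volume_pl, "pl")
      outcomes <- character(0)
      for (n0 in config$n_init_grid) {
        tr <- simulate_deterministic(p, initial_condition(n0, config$a_init, v),
                                     t_max = config$t_max)
        f <- file.path(output_dir,
                       sprintf("trajectory_ninit%02d_%s.csv", n0,
                               tolower(tr$outcome)))
        write_trajectory_csv(tr, f)
        files <- c(files, f)
        outcomes[as.character(n0)] <- tr$outcome
      }
      summary$outcomes <- as.list(outcomes)
      summary$critical_count <-
        critical_count(p, config$a_init, v)
      NULL
    },
    phase_boundary = {
      tabs <- lapply(config$K_M_grid, function(km) {
        pk <- model_params(mu = p$mu, gamma = p$gamma,
                           enzyme_rate = p$enzyme_rate, K_M = km,
                           a_th = p$a_th)
        cbind(K_M = km,
              phase_boundary_table(pk, config$a_grid[config$a_grid >= pk$a_th]))
      })
      do.call(rbind, tabs)
    },
    outcome_scan = ,
    survival_scan = {
      phase_scan(p, config$a_grid, config$rho_grid,
                 convert_volume(config$volume_pl, "pl"),
                 n_replicates = config$n_replicates, seed = config$seed)
    },
    survival_curve = {
      survival_curve(p, config$rho, config$a_grid, config$total_volume_ml,
                     lambda_grid = config$lambda_grid,
                     n_replicates = config$n_replicates, seed = config$seed)
    },
    nonlethal_curve = {
      conditional_survival_curve(p, config$rho, config$a_grid,
                                 config$total_volume_ml,
                                 m_grid = config$m_grid,
                                 n_replicates = config$n_replicates,
                                 seed = config$seed)
    },
    foraging_lag = {
      foraging_lag_curve(config$fparams, config$rho, config$total_volume_ml,
                         m_grid = config$m_grid,
                         n_replicates = config$n_replicates,
                         seed = config$seed)
    })

  if (!is.null(result)) {
    f <- file.path(output_dir, paste0(config$preset, ".csv"))
    .write_csv_with_header(result, f, config)
    files <- c(files, f)
    num <- vapply(result, is.numeric, logical(1))
    summary$n_rows <- nrow(result)
    summary$column_means <- as.list(colMeans(result[num], na.rm = TRUE))
  }
  fj <- file.path(output_dir, paste0(config$preset, "_summary.json"))
  summary$resolved_config <- sub("^# ", "", .config_lines(config))
  jsonlite::write_json(summary, fj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, fj)
  invisible(files)
}

#' Read a flat key=value configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments ignored.
#' Keys carry unit suffixes (`volume_pl`, `total_volume_ml`, ...) so that a
#' mis-specified unit is a visible key mismatch rather than a silent
#' thousand-fold error. Values containing `;` are split into numeric
#' vectors.
#'
#' @param path file path.
#' @return Named list of parsed values (numeric where possible).
#' @export
read_config_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: ", ln, call. = FALSE)
    val <- strsplit(trimws(kv[2]), ";", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(kv[1])]] <- if (anyNA(num)) val else num
  }
  out
}
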