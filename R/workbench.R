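#' Read a run configuration file
#'
#' Configurations are YAML with blocks `substrate` (or `substrates`),
#' `clutch`, `motors`, `genotype`, `sim` and `grid`; every block is
#' optional and missing keys take package defaults. Unknown keys within a
#' block are reported with their key path.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg named list as produced by [read_run_config].
#' @return The validated list, classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping")
  known <- c("substrate", "substrates", "clutch", "motors", "genotype",
             "genotypes", "sim", "grid", "relaxometry", "seed", "outdir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  check_block <- function(block, allowed, path) {
    if (is.null(block)) return(invisible(NULL))
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop("unknown config keys: ",
           paste(paste0(path, ".", extra), collapse = ", "))
  }
  check_block(cfg$substrate, c("k1", "k2", "eta"), "substrate")
  check_block(cfg$clutch, names(formals(clutch_params)), "clutch")
  check_block(cfg$motors, names(formals(motor_params)), "motors")
  check_block(cfg$genotype, c("label", "koff_factor"), "genotype")
  check_block(cfg$sim, names(formals(sim_config)), "sim")
  check_block(cfg$grid, names(formals(make_default_grid)), "grid")
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration list to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
}

config_substrate <- function(cfg) {
  s <- cfg$substrate
  if (is.null(s)) return(make_default_grid()$substrates$soft_Vplus)
  sls_params(k1 = s$k1, k2 = s$k2, eta = s$eta)
}

config_block <- function(block, constructor) {
  if (is.null(block)) return(constructor())
  do.call(constructor, block)
}

config_genotype <- function(cfg) {
  g <- cfg$genotype
  if (is.null(g)) return(genotype("scRNA"))
  genotype(g$label, koff_factor = g$koff_factor)
}

# FNV-1a hash of a string, reported as 8 hex digits; used to fingerprint
# the configuration in run manifests.
config_hash <- function(x) {
  s <- utf8ToInt(yaml::as.yaml(x))
  h <- 2166136261
  for (b in s) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

write_manifest <- function(outdir, cfg, seed, extra = list()) {
  manifest <- c(list(package = "viscoclutch",
                     version = as.character(packageVersion("viscoclutch")),
                     seed = seed,
                     config_hash = config_hash(cfg),
                     config = cfg), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# All outputs are staged in a temporary directory and moved into place
# only on success, so a failing run leaves no partial outputs.
with_staging <- function(outdir, body) {
  stage <- tempfile("viscoclutch_stage_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  body(stage)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, recursive = TRUE)) {
    dest <- file.path(outdir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(stage, f), dest, overwrite = TRUE)
  }
  invisible(outdir)
}

#' Run a single simulation job from a configuration
#'
#' Runs [run_simulation] under the configured parameters and writes
#' `trajectory.tsv` (one row per recorded step), `summary.json` and a
#' provenance manifest (`manifest.json` with the echoed config, seed and
#' config hash) into `outdir`. Outputs are written atomically: a failing
#' run leaves no partial files.
#'
#' @param cfg a `run_config` (list) or path to a YAML config.
#' @param outdir output directory.
#' @param seed root seed; overrides `cfg$seed` / `sim$seed`.
#' @return The [run_simulation] result, invisibly.
#' @export
run_simulate_job <- function(cfg = list(), outdir, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  sls <- config_substrate(cfg)
  clutch <- config_block(cfg$clutch, clutch_params)
  motors <- config_block(cfg$motors, motor_params)
  gt <- config_genotype(cfg)
  sim <- config_block(cfg$sim, sim_config)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  else if (!is.null(cfg$seed)) sim$seed <- as.integer(cfg$seed)
  res <- run_simulation(clutch, motors, sls, gt, sim)
  with_staging(outdir, function(stage) {
    write.table(res$trajectory, file.path(stage, "trajectory.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$summary, file.path(stage, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_manifest(stage, cfg, sim$seed)
  })
  invisible(res)
}

#' Run the condition grid and trend report from a configuration
#'
#' Runs [run_condition_grid] (default: the full 8-condition grid at 26
#' replicates) and [trend_check], writing `condition_summary.tsv`,
#' `replicates.tsv`, `trend_report.tsv` and a manifest into `outdir`.
#'
#' @param cfg a `run_config` list or YAML path; its `grid` block is passed
#'   to [make_default_grid].
#' @param outdir output directory.
#' @param seed root seed; overrides the grid's `root_seed`.
#' @return List with `grid` ([run_condition_grid] result) and `trends`
#'   ([trend_check] report), invisibly.
#' @export
run_grid_job <- function(cfg = list(), outdir, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  grid_args <- if (is.null(cfg$grid)) list() else cfg$grid
  if (!is.null(seed)) grid_args$root_seed <- as.integer(seed)
  grid_spec <- do.call(make_default_grid, grid_args)
  if (!is.null(cfg$genotypes)) grid_spec$genotypes <- cfg$genotypes
  if (!is.null(cfg$clutch))
    grid_spec$clutch <- config_block(cfg$clutch, clutch_params)
  if (!is.null(cfg$motors))
    grid_spec$motors <- config_block(cfg$motors, motor_params)
  if (!is.null(cfg$sim)) grid_spec$sim <- config_block(cfg$sim, sim_config)
  if (grid_spec$n_replicates < 6)
    warning("fewer than 6 replicates per condition: trend assertions are ",
            "underpowered")
  res <- run_condition_grid(grid_spec)
  trends <- trend_check(res)
  with_staging(outdir, function(stage) {
    write.table(res$summary, file.path(stage, "condition_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(res$replicates, file.path(stage, "replicates.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(trends, file.path(stage, "trend_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(stage, cfg, grid_spec$root_seed)
  })
  invisible(list(grid = res, trends = trends))
}

#' Analyse a directory of stress-relaxation curves
#'
#' Reads every `*.tsv` curve file in `input_dir`, groups curves by their
#' `group` header field (falling back to the file-name prefix before
#' `_rep`), runs the full relaxation pipeline per group (preprocess,
#' average, t80, energy dissipation) and writes `relaxation_summary.tsv`
#' plus one averaged curve (`avg_<group>.tsv`, with the SD band) per group.
#' Unparseable files are reported and skipped, not silently dropped.
#'
#' @param input_dir directory of curve files in the [write_curve] format.
#' @param outdir output directory.
#' @param ed_method energy-dissipation definition (see
#'   [energy_dissipation_pct]).
#' @return The summary data.frame, invisibly.
#' @export
run_relax_analyze_job <- function(input_dir, outdir,
                                  ed_method = "amplitude") {
  files <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[!grepl("^avg_", basename(files))]
  if (length(files) == 0) stop("no curves found in ", input_dir)
  curves <- list()
  for (f in files) {
    cv <- tryCatch(read_curve(f), error = function(e) {
      warning("skipping unparseable curve file ", basename(f), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(cv)) next
    grp <- if (!is.na(cv$group)) cv$group else sub("_rep.*$", "", basename(f))
    curves[[grp]] <- c(curves[[grp]], list(cv))
  }
  if (length(curves) == 0) stop("no parseable curves found in ", input_dir)
  summaries <- list()
  avgs <- list()
  for (grp in names(curves)) {
    s <- summarise_relaxation(curves[[grp]], ed_method = ed_method)
    avgs[[grp]] <- attr(s, "avg_curve")
    summaries[[grp]] <- s
  }
  summary <- do.call(rbind, c(summaries, make.row.names = FALSE))
  with_staging(outdir, function(stage) {
    write.table(summary, file.path(stage, "relaxation_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    for (grp in names(avgs)) {
      av <- avgs[[grp]]
      lines <- c(sprintf("# group: %s", grp),
                 sprintf("# n_curves: %d", attr(av, "n_curves")),
                 "t\tF_mean\tF_sd",
                 sprintf("%.6g\t%.6g\t%.6g", av$t, av$F, attr(av, "sd")))
      writeLines(lines, file.path(stage, paste0("avg_", grp, ".tsv")))
    }
  })
  invisible(summary)
}

#' Materialise a synthetic fixture set
#'
#' Writes, into `outdir`: `n_curves` noisy stress-relaxation curves for
#' each substrate condition of the grid (in the [write_curve] text format),
#' one Hertzian indentation curve per stiffness class, and the grid
#' configuration as YAML — everything the analysis stages need, with known
#' ground truth.
#'
#' @param outdir output directory.
#' @param grid a grid specification ([make_default_grid] by default).
#' @param n_curves relaxation curves per condition.
#' @param noise_sd force noise as a fraction of F0.
#' @param seed root seed.
#' @return Invisibly, the output directory.
#' @export
run_synth_job <- function(outdir, grid = make_default_grid(),
                          n_curves = 20, noise_sd = 0.02, seed = 1L) {
  with_staging(outdir, function(stage) {
    idx <- 0L
    for (sub_name in names(grid$substrates)) {
      idx <- idx + 1L
      for (i in seq_len(n_curves)) {
        spec <- curve_gen_spec(grid$substrates[[sub_name]],
                               noise_sd = noise_sd,
                               seed = replicate_seed(seed, idx, i),
                               group = sub_name)
        write_curve(make_relaxation_curve(spec),
                    file.path(stage, sprintf("%s_rep%02d.tsv", sub_name, i)))
      }
    }
    e_truth <- c(soft = 400, stiff = 25000)
    for (nm in names(e_truth)) {
      cv <- make_indentation_curve(e_truth[[nm]], noise_sd = 0.01,
                                   seed = replicate_seed(seed, 99L,
                                                         match(nm, names(e_truth))))
      writeLines(c(sprintf("# youngs_modulus_pa_truth: %g", e_truth[[nm]]),
                   sprintf("# probe_radius_um: %g", cv$R),
                   "depth\tF",
                   sprintf("%.6g\t%.6g", cv$depth, cv$F)),
                 file.path(stage, sprintf("indentation_%s.txt", nm)))
    }
    grid_cfg <- list(grid = list(n_replicates = grid$n_replicates,
                                 root_seed = grid$root_seed))
    write_run_config(grid_cfg, file.path(stage, "grid_config.yaml"))
  })
  invisible(outdir)
}
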