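# End-to-end orchestration: cohort -> montages -> solve -> metrics -> sweep
# -> CV -> stats, behind a serializable configuration with a master seed.

#' Default experiment configuration
#'
#' One solve per (head, montage) at that montage's reference amplitude, with
#' the 1-4 mA sweep obtained by linear scaling (`resolve_each_amplitude =
#' TRUE` re-solves every amplitude instead, for validating the linearity
#' shortcut).
#'
#' @param n_heads Number of phantom heads in the cohort.
#' @param grid_shape,voxel_size Phantom grid (see [phantom_spec()]).
#' @param montages Character vector of preset names.
#' @param reference_mA Reference (anode) amplitude per montage, mA.
#' @param amplitudes Sweep amplitudes, mA.
#' @param e_th Modulation threshold, V/m.
#' @param conductivities Optional named conductivity overrides (S/m), passed
#'   to [default_conductivities()].
#' @param seed Master seed.
#' @param tol,maxit Solver controls.
#' @param save_fields Write per-solve NIfTI field maps.
#' @param resolve_each_amplitude Re-solve at every sweep amplitude.
#' @return A list of class `run_config`.
#' @export
default_config <- function(n_heads = 5, grid_shape = 64, voxel_size = 3,
                           montages = c("LUL", "BL", "TWO_BY_ONE"),
                           reference_mA = 2,
                           amplitudes = seq(1, 4, by = 0.5),
                           e_th = 0.2, conductivities = NULL, seed = 1L,
                           tol = 1e-8, maxit = 50000L,
                           save_fields = FALSE,
                           resolve_each_amplitude = FALSE) {
  structure(list(
    n_heads = n_heads, grid_shape = grid_shape, voxel_size = voxel_size,
    shell_radii = c(skin = 88, skull = 82, csf = 78, gray = 75, white = 60),
    perturbation = list(radius_frac = 0.05, roi_jitter_mm = 3),
    conductivities = conductivities,
    montages = montages, reference_mA = reference_mA,
    amplitudes = amplitudes, e_th = e_th, seed = as.integer(seed),
    tol = tol, maxit = as.integer(maxit), save_fields = save_fields,
    resolve_each_amplitude = resolve_each_amplitude),
    class = "run_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file; keys as in [default_config()].
#' @return A `run_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(y)) {
    val <- y[[nm]]
    if (nm %in% c("shell_radii", "perturbation", "amplitudes",
                  "montages", "grid_shape"))
      val <- if (nm %in% c("shell_radii", "perturbation"))
        utils::modifyList(as.list(cfg[[nm]]), as.list(val)) else unlist(val)
    if (nm == "shell_radii") val <- unlist(val)
    cfg[[nm]] <- val
  }
  cfg
}

#' Run the full montage-comparison experiment
#'
#' Generates (or accepts) a cohort of head models, voxelizes each montage,
#' solves the volume-conduction problem once per (head, montage) at the
#' reference amplitude, sweeps the amplitude range by linear scaling,
#' summarizes inter-individual variability (CV across heads) and montage
#' differences (ANOVA, Bonferroni pairwise, Cohen's d), and writes the
#' bundle to `out_dir`: `metrics.csv`, `cv.csv`, `stats_peak_field.csv`,
#' `stats_modulated_volume.csv`, `stats.json`, `config.yaml`, `run.log`.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param cohort Optional pre-built cohort (list of `list(volume, rois)`),
#'   bypassing phantom generation.
#' @return List with `metrics`, `cv`, `report` (`NULL` if fewer than 2
#'   heads), `diagnostics`, `config`, invisibly when writing.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("run_experiment: %d head(s), montages: %s, seed %d",
      config$n_heads, paste(config$montages, collapse = ", "), config$seed)
  say("defaults in effect: peak = max over ROI voxels; network denominator = side union; LUL cathode T3-P3; E_th = %g V/m", config$e_th)

  if (is.null(cohort)) {
    spec <- phantom_spec(
      grid_shape = config$grid_shape, voxel_size = config$voxel_size,
      shell_radii = config$shell_radii, perturbation = config$perturbation,
      seed = config$seed)
    cohort <- make_cohort(config$n_heads, spec)
  }
  sigma_table <- default_conductivities(unlist(config$conductivities))

  metrics <- list()
  diags <- list()
  for (h in seq_along(cohort)) {
    head_id <- sprintf("S%d", h)
    vol <- cohort[[h]]$volume
    rois <- cohort[[h]]$rois
    for (mn in config$montages) {
      mont <- preset_montage(mn, config$reference_mA)
      volp <- voxelize_pads(vol, mont)
      sigma <- assign_conductivity(volp, sigma_table)
      tsolve <- system.time(
        sol <- solve_potential(sigma, attr(volp, "pads"), vol$voxel_size,
                               tol = config$tol, maxit = config$maxit))
      sol <- compute_field(sol)
      say("%s %-10s solved: %d iters, relres %.2e, %.1f s",
          head_id, mn, sol$diagnostics$iterations, sol$diagnostics$relres,
          tsolve[["elapsed"]])
      diags[[paste(head_id, mn)]] <- c(
        iterations = sol$diagnostics$iterations,
        relres = sol$diagnostics$relres, seconds = tsolve[["elapsed"]])
      if (config$resolve_each_amplitude) {
        sw <- do.call(rbind, lapply(config$amplitudes, function(a) {
          monta <- preset_montage(mn, a)
          volpa <- voxelize_pads(vol, monta)
          sigmaa <- assign_conductivity(volpa, sigma_table)
          sola <- compute_field(
            solve_potential(sigmaa, attr(volpa, "pads"), vol$voxel_size,
                            tol = config$tol, maxit = config$maxit))
          sweep_currents(sola, a, rois, amplitudes = a, e_th = config$e_th)
        }))
      } else {
        sw <- sweep_currents(sol, config$reference_mA, rois,
                             amplitudes = config$amplitudes,
                             e_th = config$e_th)
      }
      sw$head <- head_id
      sw$montage <- mn
      metrics[[paste(head_id, mn)]] <- sw
      if (config$save_fields && !is.null(out_dir))
        write_field_nifti(sol, file.path(out_dir, "fields",
                                         paste0(head_id, "_", mn)))
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  metrics <- metrics[, c("head", "montage", "amplitude", "measure",
                         "target", "value")]

  cv <- cv_across_heads(metrics)

  report <- NULL
  if (length(cohort) >= 2) {
    report <- build_report(metrics, montages = config$montages,
                           peak_amplitude = config$reference_mA)
  } else {
    say("WARNING: stats stage skipped — fewer than 2 heads (no replicates)")
  }
  say("run_experiment finished in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(metrics = metrics, cv = cv, report = report,
              diagnostics = diags, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(cv, file.path(out_dir, "cv.csv"), row.names = FALSE)
    if (!is.null(report)) {
      write.csv(report$peak_field,
                file.path(out_dir, "stats_peak_field.csv"), row.names = FALSE)
      write.csv(report$modulated_volume,
                file.path(out_dir, "stats_modulated_volume.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(peak_field = report$peak_field,
             modulated_volume = report$modulated_volume),
        file.path(out_dir, "stats.json"), dataframe = "rows", digits = NA)
    }
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(out))
  }
  out
}

#' Coefficient of variation of each metric across heads
#'
#' @param metrics Tidy metrics table from [run_experiment()] /
#'   [sweep_currents()] with a `head` column.
#' @return Data frame `montage`, `amplitude`, `measure`, `target`, `mean`,
#'   `sd`, `cv` (NA where the mean is zero).
#' @export
cv_across_heads <- function(metrics) {
  key <- interaction(metrics$montage, metrics$amplitude, metrics$measure,
                     metrics$target, drop = TRUE)
  rows <- lapply(split(metrics, key), function(sub) {
    m <- mean(sub$value)
    data.frame(montage = sub$montage[1], amplitude = sub$amplitude[1],
               measure = sub$measure[1], target = sub$target[1],
               mean = m, sd = sd(sub$value),
               cv = if (length(sub$value) >= 2 && m != 0) sd(sub$value) / m
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$measure, out$target, out$montage, out$amplitude), ]
  rownames(out) <- NULL
  out
}
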