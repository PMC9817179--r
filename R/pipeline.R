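default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("kinetics", "images", "spt"),
    out_dir = NULL,
    kinetics = list(
      start_pp_step = 2,
      n_ratios = 41L,
      t_end = 100, n_points = 201L),
    images = list(
      n_cells = 4L,
      noise_tolerance = 2e-4,
      effect = list(puncta_count_factor = 1.5, amplitude_factor = 1.25),
      spec = list(min_separation = 14)),
    spt = list(
      tau_H2B = 100,
      frame_interval = 0.5,
      n_cells = 6L,
      n_per_cell = 1500L,
      conditions = list(
        list(name = "fast", A = 0.5, tau_ns = 2, tau_s = 10),
        list(name = "slow", A = 0.5, tau_ns = 2, tau_s = 60))),
    alpha = 0.05)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the synthetic end-to-end study pipeline
#'
#' Orchestrates the three analysis stages on seeded synthetic data and
#' collects every per-cell measurement into one long-format study table:
#'
#' * `kinetics` — both phase-diagram sweeps (in-puncta fixation-rate ratio
#'   at constant overall rates; relative overall fixation rate at constant
#'   k3, k4) plus one example time course.
#' * `images` — paired live/fixed nuclei with a planted effect, the three
#'   LLPS parameters per image, per-cell percent changes, and a Wilcoxon
#'   signed-rank test per parameter.
#' * `spt` — per-cell dwell-time sets per condition, two-exponential
#'   survival fits, photobleaching correction against `tau_H2B`, and a
#'   Wilcoxon rank-sum comparison between two conditions.
#'
#' @param config Named list, or path to a YAML file, overriding the
#'   defaults (see `llpsfix:::default_pipeline_config()`); unknown stage
#'   names are an error. `config$out_dir`, when set, receives CSV/JSON
#'   outputs.
#' @return List with `study_table` (data.frame: `cell_id`, `condition`,
#'   `parameter`, `value`), `summary` (per-stage results incl. p-values),
#'   and `provenance` (seed and full config).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  known <- c("kinetics", "images", "spt")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; known stages: ", paste(known, collapse = ", "), call. = FALSE)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  table_rows <- list()
  summary <- list()

  if ("kinetics" %in% cfg$stages) {
    kc <- cfg$kinetics
    grids <- list(
      start_pp = seq(0, 100, by = kc$start_pp_step),
      ratio = 10 ^ seq(-2, 2, length.out = kc$n_ratios))
    pd_in <- sweep_phase_diagram("relative-in-puncta", grids$start_pp,
                                 grids$ratio)
    pd_ov <- sweep_phase_diagram("relative-overall", grids$start_pp,
                                 grids$ratio)
    tc <- simulate_time_course(rate_set(0.5, 0.5, 0.1, 0.1), 50,
                               t_end = kc$t_end, n_points = kc$n_points)
    summary$kinetics <- list(
      max_abs_delta_in_puncta = max(abs(pd_in$delta)),
      max_abs_delta_overall = max(abs(pd_ov$delta)),
      conservation_error = max(abs(rowSums(
        tc[, c("s1", "s2", "s3", "s4")]) - 1)))
    if (!is.null(out_dir)) {
      write_phase_diagram(pd_in, file.path(out_dir,
                                           "sweep_in_puncta_ratio.csv"))
      write_phase_diagram(pd_ov, file.path(out_dir,
                                           "sweep_overall_ratio.csv"))
      write_time_course(tc, file.path(out_dir, "time_course.csv"))
    }
  }

  if ("images" %in% cfg$stages) {
    ic <- cfg$images
    changes <- list()
    for (i in seq_len(ic$n_cells)) {
      spec <- do.call(synthetic_image_spec,
                      c(ic$spec, list(seed = cfg$seed + i)))
      pair <- make_live_fixed_pair(spec, ic$effect)
      ql <- quantify_puncta(pair$live$stack, pair$live$mask,
                            ic$noise_tolerance)
      qf <- quantify_puncta(pair$fixed$stack, pair$fixed$mask,
                            ic$noise_tolerance)
      ch <- compare_live_fixed(ql, qf)
      cell <- sprintf("cell%02d", i)
      changes[[i]] <- cbind(cell_id = cell, ch)
      for (cond in c("live", "fixed")) {
        q <- if (cond == "live") ql else qf
        table_rows[[length(table_rows) + 1L]] <- data.frame(
          cell_id = cell, condition = cond,
          parameter = c("n_puncta", "surface_roughness",
                        "punctate_percentage"),
          value = c(q$n_puncta, q$surface_roughness,
                    q$punctate_percentage))
      }
    }
    changes <- do.call(rbind, changes)
    tests <- lapply(split(changes, changes$parameter), function(df) {
      d <- df$percent_change[df$percent_valid]
      if (length(d) == 0L || all(d == 0)) return(NULL)
      wilcoxon_signed_rank(d)
    })
    summary$images <- list(
      paired_changes = changes,
      mean_percent_change = vapply(
        split(changes, changes$parameter),
        function(df) mean(df$percent_change[df$percent_valid]),
        numeric(1)),
      signed_rank = tests)
    if (!is.null(out_dir))
      utils::write.csv(changes,
                       file.path(out_dir, "paired_changes.csv"),
                       row.names = FALSE)
  }

  if ("spt" %in% cfg$stages) {
    sc <- cfg$spt
    per_cond <- list()
    fit_rows <- list()
    for (ci in seq_along(sc$conditions)) {
      cond <- sc$conditions[[ci]]
      taus <- numeric(sc$n_cells)
      for (i in seq_len(sc$n_cells)) {
        spec <- synthetic_dwell_spec(
          A = cond$A, tau_ns = cond$tau_ns, tau_s = cond$tau_s,
          tau_bleach = sc$tau_H2B, n = sc$n_per_cell,
          frame_interval = sc$frame_interval,
          seed = cfg$seed + 1000L * ci + i)
        dw <- make_dwell_times(spec)
        fit <- fit_two_exponential(survival_curve(dw$dwells))
        corr <- photobleach_correct(fit$tau_s, sc$tau_H2B)
        taus[i] <- corr$tau_corrected
        cell <- sprintf("%s_cell%02d", cond$name, i)
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          cell_id = cell, condition = cond$name,
          A = fit$A, tau_ns = fit$tau_ns, tau_s = fit$tau_s,
          tau_corrected = corr$tau_corrected)
        table_rows[[length(table_rows) + 1L]] <- data.frame(
          cell_id = cell, condition = cond$name,
          parameter = "tau_corrected", value = corr$tau_corrected)
      }
      per_cond[[cond$name]] <- taus
    }
    summary$spt <- summarize_residence(per_cond)
    summary$spt$fits <- do.call(rbind, fit_rows)
    if (!is.null(out_dir))
      utils::write.csv(summary$spt$fits,
                       file.path(out_dir, "residence_fits.csv"),
                       row.names = FALSE)
  }

  study_table <- if (length(table_rows) > 0L) do.call(rbind, table_rows)
  else data.frame(cell_id = character(0), condition = character(0),
                  parameter = character(0), value = numeric(0))
  result <- list(study_table = study_table, summary = summary,
                 provenance = list(seed = cfg$seed, config = cfg,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "llpsfix"))))
  if (!is.null(out_dir)) {
    utils::write.csv(study_table, file.path(out_dir, "study_table.csv"),
                     row.names = FALSE)
    writeable <- summary
    writeable$images$paired_changes <- NULL
    writeable$spt$fits <- NULL
    jsonlite::write_json(
      list(summary = writeable, seed = cfg$seed),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  result
}
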