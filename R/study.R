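# Study orchestration: the twenty predictive simulations (four
# locomotion conditions x {unassisted reference + four impedance
# parameter combinations}), summary metrics, and table export.

#' Summary metrics of a solved scenario
#'
#' Spatiotemporal, kinetic and effort metrics of a solution. Forces and
#' joint moments are reported per side (the bilateral totals of the
#' lumped planar model divided by two), matching the convention of
#' experimental pushrim studies; angles are in degrees.
#'
#' @param sol A `paw_solution`.
#' @param dt Sampling interval for peak extraction (s).
#' @return A `paw_metrics` list.
#' @export
summarize_solution <- function(sol, dt = 0.002) {
  out <- solution_outputs(sol, dt = dt)
  durs <- vapply(sol$phases, function(p) p$tf, numeric(1))
  types <- vapply(sol$phases, function(p) p$type, character(1))
  steady <- sol$scenario$kind == "steady"
  push_time <- sum(durs[types == "propulsion"])
  rec_time <- sum(durs[types == "recovery"])
  pr <- out[out$type == "propulsion", ]
  first_push <- out[out$phase == 1, ]
  contact <- first_push$theta[1]
  release <- first_push$theta[nrow(first_push)]
  m <- list(
    condition = sol$scenario$condition,
    assist = sol$scenario$assist,
    speed = sol$scenario$v_avg,
    cadence = if (steady) 1 / sum(durs) else NA_real_,
    push_time = if (steady) push_time else push_time /
      sum(types == "propulsion"),
    recovery_time = if (steady) rec_time else rec_time /
      sum(types == "recovery"),
    push_recovery_ratio = push_time / rec_time,
    contact_angle = contact * 180 / pi,
    release_angle = release * 180 / pi,
    push_angle = (release - contact) * 180 / pi,
    max_rim_tangential_force = max(pr$Ft),
    max_shoulder_flexion_moment = max(-out$tau_shoulder) / 2,
    max_shoulder_extension_moment = max(out$tau_shoulder) / 2,
    max_elbow_flexion_moment = max(out$tau_elbow) / 2,
    max_elbow_extension_moment = max(-out$tau_elbow) / 2,
    peak_activation = c(se = max(out$a_se), sf = max(out$a_sf),
                        ee = max(out$a_ee), ef = max(out$a_ef)),
    Wp = sol$Wp, Wm = sol$Wm,
    status = sol$status)
  class(m) <- "paw_metrics"
  m
}

#' @export
summary.paw_solution <- function(object, ...) summarize_solution(object, ...)

#' @export
print.paw_metrics <- function(x, ...) {
  cat(sprintf("Metrics: %s / %s\n", x$condition, x$assist))
  if (!is.na(x$cadence)) {
    cat(sprintf("  cadence %.2f 1/s; push %.3f s, recovery %.3f s (ratio %.2f)\n",
                x$cadence, x$push_time, x$recovery_time,
                x$push_recovery_ratio))
  }
  cat(sprintf("  contact %.1f deg, release %.1f deg, push angle %.1f deg\n",
              x$contact_angle, x$release_angle, x$push_angle))
  cat(sprintf("  peak tangential force %.1f N (per hand)\n",
              x$max_rim_tangential_force))
  cat(sprintf("  peak moments (N m, per side): shoulder flex %.2f / ext %.2f, elbow flex %.2f / ext %.2f\n",
              x$max_shoulder_flexion_moment, x$max_shoulder_extension_moment,
              x$max_elbow_flexion_moment, x$max_elbow_extension_moment))
  cat(sprintf("  Wp = %.4f s (%.3f in 1e-1 s)", x$Wp, 10 * x$Wp))
  if (x$assist != "off") cat(sprintf(", Wm = %.2f N^2 m^2 s", x$Wm))
  cat("\n")
  invisible(x)
}

#' Identification record from a startup solution
#'
#' Extracts the bilateral pushrim-torque / wheel-speed record of a
#' startup simulation (uniformly resampled), the open-loop input-output
#' data used to identify the first-order reference model.
#'
#' @param sol A `paw_solution` of a startup scenario.
#' @param dt Sampling interval (s).
#' @return Data frame with `time`, `tau_p`, `v`.
#' @export
identification_record <- function(sol, dt = 0.002) {
  out <- solution_outputs(sol, dt = dt)
  keep <- c(TRUE, diff(out$time) > dt / 4)   # drop duplicated phase edges
  data.frame(time = out$time[keep], tau_p = out$tau_p[keep],
             v = out$v[keep])
}

#' Run the full simulation study
#'
#' Solves the reference (unassisted) scenarios for the four locomotion
#' conditions, identifies the first-order reference model from the
#' unassisted level-ground startup record, then solves the four assisted
#' parameter combinations per condition with continuation seeding
#' (references seed the nominal combination; single-parameter reductions
#' are seeded from the nominal; the double reduction from the nearest
#' single reduction). Solutions flagged as clearly unrealistic (contact
#' angle below -150 degrees or push angle above 120 degrees) are re-run
#' from the alternative neighbouring seed.
#'
#' @param conditions Subset of the four conditions to run.
#' @param assists Subset of assistance settings.
#' @param params,muscles Model parameter objects.
#' @param mesh Mesh profile (see [scenario_mesh()]).
#' @param impedance Optional fixed `paw_impedance`; when `NULL` the
#'   nominal model is identified from the unassisted level startup run
#'   (requires `"level-startup"` among the conditions).
#' @param out_dir Optional directory: tables are exported there.
#' @param control Solver options.
#' @param progress Print progress lines.
#' @return A `paw_study` list: `solutions` (condition -> assist),
#'   `impedance_fit`, `table_effort` (user/motor effort per scenario),
#'   `table_reference` (steady-state reference metrics with literature
#'   columns), `log`.
#' @export
run_study <- function(conditions = c("level-steady", "ramp-steady",
                                     "level-startup", "ramp-startup"),
                      assists = c("off", "m100-c100", "m50-c100",
                                  "m100-c50", "m50-c50"),
                      params = default_parameters(),
                      muscles = default_muscles(),
                      mesh = "default", impedance = NULL,
                      out_dir = NULL, control = list(),
                      progress = interactive()) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (progress) message(msg)
  }
  sols <- list()
  solve_one <- function(cond, assist, imp, guess = NULL) {
    sc <- build_scenario(cond, assist)
    t0 <- Sys.time()
    sol <- tryCatch(
      solve_scenario(sc, params = params, muscles = muscles,
                     impedance = if (is.null(imp)) impedance_params() else imp,
                     mesh = mesh, guess = guess, control = control),
      error = function(e) structure(list(error = conditionMessage(e),
                                         scenario = sc),
                                    class = "paw_failed_solution"))
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(sol, "paw_failed_solution")) {
      note("%s / %s: FAILED (%s)", cond, assist, sol$error)
    } else {
      note("%s / %s: %s, Wp %.4f, %d it, %.0f s", cond, assist,
           sol$status, sol$Wp, sol$iterations, el)
    }
    sol
  }
  ok <- function(s) inherits(s, "paw_solution") &&
    s$status %in% c("success")
  # 1. references
  refs_first <- intersect(conditions,
                          c("level-steady", "level-startup"))
  ramp_of <- c("level-steady" = "ramp-steady",
               "level-startup" = "ramp-startup")
  if ("off" %in% assists) {
    for (cond in refs_first) {
      sols[[cond]] <- list()
      sols[[cond]][["off"]] <- solve_one(cond, "off", NULL)
    }
    for (cond in intersect(conditions, unname(ramp_of))) {
      sols[[cond]] <- list()
      level_cond <- names(ramp_of)[ramp_of == cond]
      seed <- if (length(level_cond) && !is.null(sols[[level_cond]]) &&
                    ok(sols[[level_cond]][["off"]]))
        sols[[level_cond]][["off"]] else NULL
      sols[[cond]][["off"]] <- solve_one(cond, "off", NULL, guess = seed)
    }
  }
  # 2. identification of the nominal reference model
  fit <- NULL
  if (is.null(impedance)) {
    if (!is.null(sols[["level-startup"]]) &&
          ok(sols[["level-startup"]][["off"]])) {
      rec <- identification_record(sols[["level-startup"]][["off"]])
      fit <- identify_first_order(rec$time, rec$tau_p, rec$v,
                                  Rw = params$wheel_radius)
      impedance <- impedance_params(coef(fit)[["Mi"]], coef(fit)[["Ci"]])
      note("identified reference model: Mi %.2f kg, Ci %.2f N s/m",
           impedance$Mi, impedance$Ci)
    } else {
      impedance <- impedance_params()
      note("identification unavailable; using stored nominal (Mi %.2f, Ci %.2f)",
           impedance$Mi, impedance$Ci)
    }
  }
  # 3. assisted scenarios with continuation seeding
  assist_order <- intersect(c("m100-c100", "m50-c100", "m100-c50",
                              "m50-c50"), assists)
  seed_of <- list("m100-c100" = "off",
                  "m50-c100" = c("m100-c100", "off"),
                  "m100-c50" = c("m100-c100", "off"),
                  "m50-c50" = c("m50-c100", "m100-c50", "off"))
  for (cond in conditions) {
    if (is.null(sols[[cond]])) sols[[cond]] <- list()
    for (assist in assist_order) {
      seeds <- seed_of[[assist]]
      avail <- Filter(function(s) !is.null(sols[[cond]][[s]]) &&
                        ok(sols[[cond]][[s]]), seeds)
      sol <- solve_one(cond, assist, impedance,
                       guess = if (length(avail))
                         sols[[cond]][[avail[1]]] else NULL)
      # on solver failure, fall back through the remaining seeds
      k <- 2L
      while (!ok(sol) && k <= length(avail)) {
        note("%s / %s: retrying from %s seed", cond, assist, avail[k])
        sol <- solve_one(cond, assist, impedance,
                         guess = sols[[cond]][[avail[k]]])
        k <- k + 1L
      }
      # clearly-unrealistic-pattern detector: re-seed from the
      # alternative neighbour
      if (ok(sol)) {
        mt <- summarize_solution(sol, dt = 0.01)
        if (mt$contact_angle < -150 || mt$push_angle > 120) {
          note("%s / %s: unrealistic pattern (contact %.1f, push %.1f); reseeding",
               cond, assist, mt$contact_angle, mt$push_angle)
          alt <- setdiff(seeds, character(0))
          for (s in rev(alt)) {
            if (!is.null(sols[[cond]][[s]]) && ok(sols[[cond]][[s]])) {
              sol2 <- solve_one(cond, assist, impedance,
                                guess = sols[[cond]][[s]])
              if (ok(sol2)) {
                mt2 <- summarize_solution(sol2, dt = 0.01)
                if (mt2$contact_angle >= -150 && mt2$push_angle <= 120) {
                  sol <- sol2
                  break
                }
              }
            }
          }
        }
      }
      sols[[cond]][[assist]] <- sol
    }
  }
  study <- structure(list(solutions = sols, impedance_fit = fit,
                          impedance = impedance,
                          table_effort = effort_table(sols),
                          table_reference = reference_table(sols),
                          log = log), class = "paw_study")
  if (!is.null(out_dir)) export_tables(study, out_dir)
  study
}

# user/motor effort per scenario, in the reporting units
# (Wp in 1e-1 s; Wm in N^2 m^2 s, absent for references)
effort_table <- function(sols) {
  rows <- list()
  for (cond in names(sols)) {
    for (assist in names(sols[[cond]])) {
      s <- sols[[cond]][[assist]]
      rows[[length(rows) + 1]] <- if (inherits(s, "paw_solution")) {
        data.frame(condition = cond, assist = assist,
                   Wp_tenths = 10 * s$Wp,
                   Wm = if (assist == "off") NA_real_ else s$Wm,
                   status = s$status)
      } else {
        data.frame(condition = cond, assist = assist,
                   Wp_tenths = NA_real_, Wm = NA_real_,
                   status = "failed")
      }
    }
  }
  do.call(rbind, rows)
}

reference_table <- function(sols) {
  s <- sols[["level-steady"]][["off"]]
  if (!inherits(s, "paw_solution")) return(NULL)
  m <- summarize_solution(s)
  pred <- c(speed = m$speed,
            max_rim_tangential_force = m$max_rim_tangential_force,
            cadence = m$cadence, push_time = m$push_time,
            recovery_time = m$recovery_time,
            push_recovery_ratio = m$push_recovery_ratio,
            push_angle = m$push_angle, contact_angle = m$contact_angle,
            release_angle = m$release_angle,
            max_shoulder_flexion_moment = m$max_shoulder_flexion_moment,
            max_shoulder_extension_moment = m$max_shoulder_extension_moment,
            max_elbow_flexion_moment = m$max_elbow_flexion_moment,
            max_elbow_extension_moment = m$max_elbow_extension_moment)
  lit <- literature_reference()
  cbind(data.frame(metric = names(pred), predicted = unname(pred)),
        lit[match(names(pred), lit$metric), -1, drop = FALSE])
}

#' Literature comparison values for steady-state propulsion
#'
#' Static reference constants from published experimental studies of
#' manual wheelchair propulsion at comparable speeds (treadmill
#' kinematics/kinetics group medians and overground means), shipped for
#' report tables.
#'
#' @return Data frame keyed by `metric`.
#' @export
literature_reference <- function() {
  data.frame(
    metric = c("speed", "max_rim_tangential_force", "cadence",
               "push_time", "recovery_time", "push_recovery_ratio",
               "push_angle", "contact_angle", "release_angle",
               "max_shoulder_flexion_moment",
               "max_shoulder_extension_moment",
               "max_elbow_flexion_moment", "max_elbow_extension_moment"),
    gil_agudo_g1 = c(0.83, NA, 0.9, 0.6, 0.5, 1.3, 62.5, -108.2, -51.3,
                     10.7, 3.9, 4.6, 1.6),
    gil_agudo_g2 = c(0.83, NA, 1.1, 0.5, 0.5, 1.1, 58.6, -111.3, -52.2,
                     8.0, 4.8, 4.9, 0.9),
    gil_agudo_g3 = c(0.83, NA, 1.1, 0.4, 0.5, 0.8, 64.5, -115.7, -54.0,
                     7.7, 6.9, 6.0, 0.5),
    gil_agudo_g4 = c(0.83, NA, 1.2, 0.4, 0.5, 0.8, 57.5, -110.4, -48.1,
                     6.4, 4.9, 4.6, 0.6),
    boninger_arc = c(0.9, 45.8, 1.13, NA, NA, 1.12, 94.4, NA, NA,
                     NA, NA, NA, NA),
    boninger_sc = c(0.9, 38.3, 0.88, NA, NA, 1.21, 114.0, NA, NA,
                    NA, NA, NA, NA),
    boninger_slop = c(0.9, 47.0, 1.03, NA, NA, 1.03, 91.7, NA, NA,
                      NA, NA, NA, NA),
    boninger_dlop = c(0.9, 65.8, 0.81, NA, NA, 0.78, 110.0, NA, NA,
                      NA, NA, NA, NA))
}

#' Export study tables
#'
#' Writes the effort table (user effort in 1e-1 s, motor effort in
#' N^2 m^2 s, dashes for the unassisted references) and the steady-state
#' reference metric table with literature columns, as CSV and JSON with
#' four significant digits.
#'
#' @param study A `paw_study`.
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the written file paths.
#' @export
export_tables <- function(study, out_dir, formats = c("csv", "json")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fmt4 <- function(df) {
    for (cc in names(df)) if (is.numeric(df[[cc]]))
      df[[cc]] <- signif(df[[cc]], 4)
    df
  }
  eff <- fmt4(study$table_effort)
  if ("csv" %in% formats) {
    p1 <- file.path(out_dir, "effort_table.csv")
    eff_csv <- eff
    eff_csv$Wm <- ifelse(is.na(eff$Wm), "-", format(eff$Wm))
    utils::write.csv(eff_csv, p1, row.names = FALSE)
    paths <- c(paths, p1)
    if (!is.null(study$table_reference)) {
      p2 <- file.path(out_dir, "reference_metrics.csv")
      utils::write.csv(fmt4(study$table_reference), p2, row.names = FALSE)
      paths <- c(paths, p2)
    }
  }
  if ("json" %in% formats) {
    p3 <- file.path(out_dir, "study_tables.json")
    jsonlite::write_json(
      list(effort = eff,
           reference_metrics = if (is.null(study$table_reference))
             NULL else fmt4(study$table_reference),
           impedance = if (!is.null(study$impedance))
             list(Mi = study$impedance$Mi, Ci = study$impedance$Ci)
           else NULL),
      p3, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' @export
print.paw_study <- function(x, ...) {
  cat("Predictive simulation study\n")
  if (!is.null(x$impedance)) {
    cat(sprintf("  reference model: Mi = %.2f kg, Ci = %.2f N s/m\n",
                x$impedance$Mi, x$impedance$Ci))
  }
  print(x$table_effort, row.names = FALSE)
  invisible(x)
}
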