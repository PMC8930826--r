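test_that("the scenario matrix enumerates the full study", {
  sc <- build_scenario("level-startup", "off")
  expect_length(sc$phase_types, 5)
  expect_equal(sc$displacement, 1.6)
  expect_equal(sc$ramp_angle, 0)
  expect_equal(sc$phase_types[c(1, 3, 5)], rep("propulsion", 3))
  sc2 <- build_scenario("ramp-steady", "m50-c50")
  expect_length(sc2$phase_types, 2)
  expect_equal(sc2$ramp_angle, 3 * pi / 180)
  expect_equal(c(sc2$mi_scale, sc2$ci_scale), c(0.5, 0.5))
  expect_true(is.na(sc2$displacement))
  combos <- expand.grid(
    condition = c("level-steady", "ramp-steady", "level-startup",
                  "ramp-startup"),
    assist = c("off", "m100-c100", "m50-c100", "m100-c50", "m50-c50"),
    stringsAsFactors = FALSE)
  cfgs <- mapply(function(cd, as) build_scenario(cd, as),
                 combos$condition, combos$assist, SIMPLIFY = FALSE)
  expect_length(cfgs, 20)
  keys <- vapply(cfgs, function(s) paste(s$condition, s$assist), "")
  expect_length(unique(keys), 20)
  expect_error(build_scenario("flat"), "arg")
})

test_that("scenario scales feed the reference model, PI uses the nominal", {
  imp_nom <- impedance_params(92.5, 14.88)
  imp_ref <- impedance_params(92.5, 14.88, mi_scale = 0.5, ci_scale = 0.5)
  expect_equal(imp_ref$Mi, 46.25)
  expect_equal(imp_ref$Ci, 7.44)
  expect_error(impedance_params(-1, 2), "Mi")
  pi_c <- design_pi(imp_nom, 0.2988, 0.02)
  expect_equal(pi_c$Kp, 0.2988^2 * 92.5 / 0.02, tolerance = 1e-12)
})

test_that("summary metrics satisfy their internal identities", {
  sol <- cached_solve("level-steady", "off")
  m <- summarize_solution(sol)
  expect_equal(m$push_angle, m$release_angle - m$contact_angle,
               tolerance = 1e-9)
  expect_equal(m$cadence, 1 / (m$push_time + m$recovery_time),
               tolerance = 1e-9)
  expect_equal(m$push_recovery_ratio, m$push_time / m$recovery_time,
               tolerance = 1e-9)
  # all reported fields populated for a steady-state solution
  num <- unlist(m[c("cadence", "push_time", "recovery_time",
                    "push_recovery_ratio", "contact_angle",
                    "release_angle", "push_angle",
                    "max_rim_tangential_force",
                    "max_shoulder_flexion_moment",
                    "max_shoulder_extension_moment",
                    "max_elbow_flexion_moment",
                    "max_elbow_extension_moment", "Wp")])
  expect_true(all(is.finite(num)))
  # peak force is stable under interpolation refinement
  out1 <- solution_outputs(sol, dt = 0.004)
  out2 <- solution_outputs(sol, dt = 0.0004)
  f1 <- max(out1$Ft); f2 <- max(out2$Ft)
  expect_lt(abs(f2 - f1) / f1, 0.01)
})

test_that("study tables export and round-trip", {
  sol <- cached_solve("level-steady", "off")
  sols <- list("level-steady" = list("off" = sol))
  study <- structure(list(solutions = sols,
                          impedance = impedance_params(),
                          impedance_fit = NULL,
                          table_effort = pawsim:::effort_table(sols),
                          table_reference = pawsim:::reference_table(sols),
                          log = character(0)), class = "paw_study")
  expect_equal(study$table_effort$Wp_tenths, 10 * sol$Wp, tolerance = 1e-9)
  expect_true(is.na(study$table_effort$Wm[1]))   # dash for references
  dir <- tempfile()
  paths <- export_tables(study, dir)
  eff <- utils::read.csv(file.path(dir, "effort_table.csv"))
  expect_equal(eff$Wp_tenths, signif(10 * sol$Wp, 4))
  expect_equal(trimws(eff$Wm), "-")
  ref <- utils::read.csv(file.path(dir, "reference_metrics.csv"))
  expect_true(all(c("metric", "predicted", "gil_agudo_g1",
                    "boninger_arc") %in% names(ref)))
  js <- jsonlite::read_json(file.path(dir, "study_tables.json"),
                            simplifyVector = TRUE)
  expect_equal(js$effort$Wp_tenths, signif(10 * sol$Wp, 4))
  unlink(dir, recursive = TRUE)
})

test_that("literature comparison constants cover the report metrics", {
  lit <- literature_reference()
  expect_true(all(c("cadence", "push_angle", "contact_angle",
                    "max_shoulder_flexion_moment") %in% lit$metric))
  expect_equal(lit$gil_agudo_g1[lit$metric == "cadence"], 0.9)
  expect_equal(lit$boninger_sc[lit$metric == "max_rim_tangential_force"],
               38.3)
})
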