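# Orchestration of the four standard analyses over synthetic or provided
# trajectories: fingerprint tables + classification, electric-field
# detachment assay, umbrella energetics, and sliding tracks. Each runner
# optionally writes a report bundle (TSV/JSON plus the resolved settings and
# a run log) under an output directory; reruns with the same settings and
# seed produce byte-identical deterministic outputs.

toy_frame_dt_ns <- function(config) config$stride * config$dt / 1000

write_run_log <- function(out_dir, what, seed, settings_json) {
  log <- c(sprintf("analysis: %s", what),
           sprintf("package: habind %s",
                   as.character(utils::packageVersion("habind"))),
           sprintf("seed: %s", seed),
           sprintf("settings_checksum: %d",
                   sum(utf8ToInt(settings_json)) %% 1000000007))
  writeLines(log, file.path(out_dir, paste0(what, "_run.log")))
}

bundle_init <- function(out_dir, what, seed, settings) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  writeLines(js, file.path(out_dir, paste0(what, "_config.json")))
  write_run_log(out_dir, what, seed, as.character(js))
}

#' Fingerprint analysis over planted-mode replicas
#'
#' Simulates `n_replicas` toy trajectories per requested mode (or consumes a
#' caller-provided list of trajectories), builds the per-mode replica binding
#' table and classifies each replica's fingerprint against the reference
#' modes.
#'
#' @param config a `habind_toy_config` (ignored when `trajs` given).
#' @param modes binding modes to run.
#' @param n_replicas replicas per mode.
#' @param n_steps integration steps per replica.
#' @param seed top-level seed; replica seeds derive from it.
#' @param params contact parameters.
#' @param threshold classification threshold.
#' @param trajs optional named list (mode -> list of `habind_traj`) replacing
#'   simulation.
#' @param out_dir optional report directory.
#' @return list with `tables` (mode -> `habind_binding_table`),
#'   `assignments` (data.frame: mode, replica, label, similarities).
#' @export
run_fingerprint <- function(config = toy_config(),
                            modes = c("crystallographic", "parallel",
                                      "upright"),
                            n_replicas = 3L, n_steps = 50000L, seed = 1L,
                            params = contact_params(), threshold = 0.80,
                            trajs = NULL, out_dir = NULL) {
  if (is.null(trajs) && n_replicas < 1L) stop("need at least one replica")
  if (!is.null(trajs) && !length(trajs)) stop("empty trajectory list")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(modes) * max(1L, n_replicas)),
                  nrow = length(modes))
  refs <- reference_fingerprints()
  tables <- list(); rows <- list()
  for (mi in seq_along(modes)) {
    m <- modes[mi]
    series <- list()
    reps <- if (is.null(trajs)) seq_len(n_replicas) else seq_along(trajs[[m]])
    for (r in reps) {
      tr <- if (is.null(trajs))
        simulate_toy(plant_mode(config, m), n_steps, seed = seeds[mi, r])
      else trajs[[m]][[r]]
      s <- residue_contact_series(tr, reference_residues(),
                                  selection_spec("ligand", role = "polymer"),
                                  params)
      series[[r]] <- s
      fp <- structure(setNames(100 * colSums(s) / nrow(s), colnames(s)),
                      class = "habind_fingerprint")
      cl <- classify(fp, refs, threshold)
      rows[[length(rows) + 1]] <- data.frame(
        mode = m, replica = r, label = cl$label,
        t(cl$similarity), stringsAsFactors = FALSE)
    }
    tables[[m]] <- replica_binding_table(series)
  }
  assignments <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    bundle_init(out_dir, "fingerprint", seed,
                list(modes = modes, n_replicas = n_replicas,
                     n_steps = n_steps, seed = seed,
                     cutoff = params$cutoff, threshold = threshold))
    write_binding_table(tables, file.path(out_dir, "fingerprint_table.tsv"))
    write.table(assignments, file.path(out_dir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(labels = setNames(as.list(assignments$label),
                             paste(assignments$mode, assignments$replica,
                                   sep = "_"))),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE)
  }
  list(tables = tables, assignments = assignments)
}

#' Electric-field detachment assay
#'
#' Runs `n_replicas` field-on detachment simulations per mode (receptor
#' fixed, charged polymer pulled by the field), detects first-zero-contact
#' detachment against the censoring time, and summarises per mode in the
#' detachment-table layout.
#'
#' @param config base `habind_toy_config`.
#' @param modes binding modes to assay.
#' @param n_replicas replicas per mode.
#' @param efield field vector (force per unit charge, kJ mol^-1 nm^-1 e^-1).
#' @param t_end censoring time in ns (required).
#' @param seed top-level seed.
#' @param params contact parameters.
#' @param field_tag label for the field condition.
#' @param out_dir optional report directory.
#' @return list with `summaries` (mode -> `habind_detachment_summary`),
#'   `records` (stacked data.frame), `table` (layout data.frame).
#' @export
run_efield_assay <- function(config = toy_config(),
                             modes = c("crystallographic", "parallel",
                                       "upright"),
                             n_replicas = 20L, efield = c(0, 0, 6),
                             t_end = NULL, seed = 1L,
                             params = contact_params(),
                             field_tag = "E-field", out_dir = NULL) {
  if (is.null(t_end)) stop("censoring time t_end (ns) is required")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(modes) * n_replicas),
                  nrow = length(modes))
  dt_ns <- toy_frame_dt_ns(config)
  n_steps <- round(t_end * 1000 / config$dt)
  records <- list(); summaries <- list()
  for (mi in seq_along(modes)) {
    m <- modes[mi]
    cfg <- plant_mode(config, m)
    cfg$scenario <- "efield"
    cfg$field <- efield
    recs <- list()
    for (r in seq_len(n_replicas)) {
      tr <- simulate_toy(cfg, n_steps, seed = seeds[mi, r])
      counts <- contact_count_series(
        tr, selection_spec("protein", role = "protein"),
        selection_spec("ligand", role = "polymer"), params)
      recs[[r]] <- detect_detachment(counts, dt = dt_ns, t_end = t_end,
                                     field_tag = field_tag, replica = r)
    }
    rec <- do.call(rbind, recs)
    rec$mode <- m
    records[[m]] <- rec
    summaries[[m]] <- summarize_detachments(rec)
  }
  records <- do.call(rbind, records)
  tab <- data.frame(
    mode = modes, field = field_tag,
    detachments_percent = vapply(summaries, `[[`, numeric(1), "fraction"),
    mean_time_ns = vapply(summaries, `[[`, numeric(1), "mean_time"),
    se_time_ns = vapply(summaries, `[[`, numeric(1), "se_time"),
    n = n_replicas, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    bundle_init(out_dir, "efield", seed,
                list(modes = modes, n_replicas = n_replicas, efield = efield,
                     t_end = t_end, seed = seed, cutoff = params$cutoff))
    write.table(tab, file.path(out_dir, "detachment_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summaries = summaries, records = records, table = tab)
}

#' Umbrella energetics analysis
#'
#' Either post-processes umbrella windows (synthetic scans per mode or
#' caller-provided window lists) through WHAM into PMFs with minimum and
#' population free energies, or - when `dg_inputs` is given - produces the
#' unit-conversion report (thermal units and pairwise preference factor)
#' directly from stated free-energy values.
#'
#' @param config a planted-capable `habind_toy_config`.
#' @param modes modes to scan (>= 1; preference factor uses the first two).
#' @param centers,k,steps_per_window umbrella scan settings.
#' @param seed top-level seed.
#' @param windows optional named list (mode -> list of `habind_window`).
#' @param dg_inputs optional named numeric of free energies (kJ/mol) to
#'   convert without any sampling.
#' @param thermo a `habind_thermo` for conversions.
#' @param n_boot bootstrap resamples for WHAM uncertainties.
#' @param out_dir optional report directory.
#' @return list with `pmf` (mode -> `habind_pmf`), `dg_min`, `dg_pop`,
#'   `dg_kbt`, `preference` (factor between the first two modes), `thermo`.
#' @export
run_energetics <- function(config = toy_config(),
                           modes = c("crystallographic", "parallel"),
                           centers = seq(1.1, 3.3, by = 0.15), k = 500,
                           steps_per_window = 20000L, seed = 1L,
                           windows = NULL, dg_inputs = NULL,
                           thermo = thermo_params(), n_boot = 50,
                           out_dir = NULL) {
  if (!is.null(dg_inputs)) {
    kbt_vals <- vapply(dg_inputs, function(v) as.numeric(to_kbt(v, thermo)),
                       numeric(1))
    pref <- if (length(dg_inputs) >= 2)
      preference_factor(dg_inputs[[1]], dg_inputs[[2]], thermo) else NA_real_
    out <- list(pmf = NULL, dg_min = dg_inputs, dg_pop = NULL,
                dg_kbt = kbt_vals, preference = pref, thermo = thermo)
    if (!is.null(out_dir)) {
      bundle_init(out_dir, "energetics", seed,
                  list(dg_inputs = dg_inputs, kbt = thermo$kbt,
                       convention = thermo$convention))
      jsonlite::write_json(
        list(dg_kJ_mol = as.list(dg_inputs), dg_kbt = as.list(kbt_vals),
             preference_factor = pref, kbt_kJ_mol = thermo$kbt,
             convention = thermo$convention),
        file.path(out_dir, "energetics.json"), auto_unbox = TRUE, digits = NA)
    }
    return(out)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(modes))
  pmfs <- list(); dg_min <- dg_pop <- numeric(0)
  for (mi in seq_along(modes)) {
    m <- modes[mi]
    win <- if (!is.null(windows)) windows[[m]]
    else umbrella_scan(plant_mode(config, m), centers, k,
                       steps_per_window, seed = seeds[mi])
    pmfs[[m]] <- wham(win, n_boot = n_boot, seed = seeds[mi])
    dg_min[m] <- delta_g_min(pmfs[[m]])
    dg_pop[m] <- delta_g_population(pmfs[[m]])
  }
  pref <- if (length(modes) >= 2)
    preference_factor(dg_min[[1]], dg_min[[2]], thermo) else NA_real_
  out <- list(pmf = pmfs, dg_min = dg_min, dg_pop = dg_pop,
              dg_kbt = vapply(dg_min, function(v) as.numeric(to_kbt(v, thermo)),
                              numeric(1)),
              preference = pref, thermo = thermo)
  if (!is.null(out_dir)) {
    bundle_init(out_dir, "energetics", seed,
                list(modes = modes, centers = centers, k = k,
                     steps_per_window = steps_per_window, seed = seed,
                     kbt = thermo$kbt, convention = thermo$convention))
    for (m in names(pmfs))
      write_pmf(pmfs[[m]], file.path(out_dir, paste0("pmf_", m, ".tsv")))
    jsonlite::write_json(
      list(dg_min_kJ_mol = as.list(dg_min), dg_pop_kJ_mol = as.list(dg_pop),
           dg_min_kbt = as.list(out$dg_kbt), preference_factor = pref,
           kbt_kJ_mol = thermo$kbt, convention = thermo$convention),
      file.path(out_dir, "energetics.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Sliding analysis of one planted mode
#'
#' Simulates the receptor diffusing along a restrained polymer, builds the
#' contact contour and returns the sliding track.
#'
#' @param config base `habind_toy_config`.
#' @param mode planted binding mode.
#' @param n_steps integration steps.
#' @param seed seed.
#' @param params contact parameters.
#' @param max_gap gap bridging for the track (frames).
#' @param out_dir optional report directory.
#' @return list with `track` (`habind_sliding_track`), `contour`, `traj`.
#' @export
run_sliding <- function(config = toy_config(polymer_beads = 64L),
                        mode = "parallel", n_steps = 200000L, seed = 1L,
                        params = contact_params(), max_gap = 20L,
                        out_dir = NULL) {
  cfg <- plant_mode(config, mode)
  cfg$scenario <- "sliding"
  tr <- simulate_toy(cfg, n_steps, seed = seed)
  map <- assign_ha_numbering(tr$model, coords = frame_coords(tr, 1))
  contour <- contact_contour(tr, map, params = params)
  track <- sliding_track(contour, dt = toy_frame_dt_ns(cfg), max_gap = max_gap)
  if (!is.null(out_dir)) {
    bundle_init(out_dir, paste0("sliding_", mode), seed,
                list(mode = mode, n_steps = n_steps, seed = seed,
                     polymer_beads = cfg$polymer_beads))
    write_sliding_track(track, file.path(out_dir,
                                         paste0("sliding_", mode, ".tsv")))
  }
  list(track = track, contour = contour, traj = tr)
}
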