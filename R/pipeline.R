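#' Replicate aggregation (mean +/- SD)
#'
#' Sample mean and sample SD (n - 1 denominator) over replicate runs, the
#' convention used for every reported metric.  A single replicate gets SD 0
#' with a warning flag.
#'
#' @param values per-run values (n >= 1).
#' @param metric,condition labels stored in the summary.
#' @return one-row data frame `metric, condition, n, mean, sd, flag`.
#' @export
aggregate_replicates <- function(values, metric = NA_character_,
                                 condition = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("aggregate_replicates: no values")
  flag <- if (length(values) == 1L) "single-replicate" else ""
  data.frame(metric = metric, condition = condition, n = length(values),
             mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else 0,
             flag = flag, stringsAsFactors = FALSE)
}

#' Two-condition comparison with star codes
#'
#' Two-tailed two-sample t test between replicate sets, Welch
#' (unequal-variance) by default, classical pooled-variance Student's by
#' request.  Stars follow the usual caption convention: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `ns` otherwise.
#'
#' @param a,b numeric replicate vectors, each n >= 2.
#' @param test `"welch"` or `"student"`.
#' @return list `p_value`, `stars`, `estimate` (mean difference b - a).
#' @export
compare_conditions <- function(a, b, test = c("welch", "student")) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L) {
    stop("compare_conditions: need >= 2 replicates per condition")
  }
  p <- if (stats::var(a) + stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = (test == "student"))$p.value
  }
  list(p_value = p, stars = star_code(p), estimate = mean(b) - mean(a))
}

#' @rdname compare_conditions
#' @param p p-value(s).
#' @export
star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' End-to-end trajectory analysis
#'
#' Runs the whole static-analysis battery over one or more replicate
#' trajectories of a two-chain complex: per-frame Ca-RMSD and Rgyr,
#' interfacial H-bond series with N_HB, the residue-pair occupancy table,
#' dissociation probabilities (both estimators), and optionally buried SASA,
#' binding energy and the pocket descriptors H/alpha/theta.  All tables use
#' one tidy schema and the manifest records seeds, configuration hash and
#' package version so any number is reproducible.
#'
#' @param trajectories list of [md_trajectory] replicates (or a single one).
#' @param chains_a,chains_b interface chain partition.
#' @param condition label for the replicate summaries.
#' @param hbond_mode `"angle"` or `"distance"` (structures without
#'   hydrogens); distance mode is flagged in the manifest warnings.
#' @param d_cut,ang_cut H-bond cutoffs (A, degrees).
#' @param sasa compute per-replicate mean buried SASA (slower).
#' @param energy_params optional parameter data frame enabling the
#'   binding-energy stage.
#' @param energy_stride frame stride for the energy stage.
#' @param geometry optional list with elements `loop_a`, `loop_b` (selection
#'   strings for the H metric), `strand_a`, `strand_b` (theta), `alpha_strand`,
#'   `alpha_atoms` (length-2 selection resolving to the two reference atoms).
#' @return list of class `analysis_report`: `metrics` (tidy per-frame data
#'   frame: run, frame, time_ns, metric, value), `occupancy`
#'   ([occupancy_table]), `summaries` (replicate mean +/- SD rows),
#'   `dissociation`, `manifest`.
#' @export
analyze_trajectory <- function(trajectories, chains_a, chains_b,
                               condition = "static",
                               hbond_mode = c("angle", "distance"),
                               d_cut = 3.5, ang_cut = 30,
                               sasa = FALSE, energy_params = NULL,
                               energy_stride = 1L, geometry = NULL) {
  hbond_mode <- match.arg(hbond_mode)
  if (inherits(trajectories, "md_trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1L)
  warnings_out <- character(0)
  if (hbond_mode == "distance") {
    warnings_out <- c(warnings_out, "hbond detection in distance-only fallback mode")
  }
  metrics <- list(); occ_runs <- list(); per_run <- list()
  for (r in seq_along(trajectories)) {
    traj <- trajectories[[r]]
    s <- traj$structure
    ca <- tryCatch(suppressWarnings(select_atoms(s, "name CA")), error = function(e) integer(0))
    tidy <- function(metric, value) {
      data.frame(run = r, frame = seq_len(n_frames(traj)), time_ns = traj$times,
                 metric = metric, value = value, stringsAsFactors = FALSE)
    }
    if (length(ca) >= 3L) {
      metrics[[length(metrics) + 1L]] <- tidy("rmsd_ca", rmsd_series(traj, ca))
    }
    metrics[[length(metrics) + 1L]] <- tidy("rgyr", rgyr_series(traj))
    hbs <- hbond_series(traj, chains_a = chains_a, chains_b = chains_b,
                        d_cut = d_cut, ang_cut = ang_cut, mode = hbond_mode)
    nhb <- nhb_series(hbs)
    metrics[[length(metrics) + 1L]] <- tidy("nhb", nhb)
    occ_runs[[r]] <- occupancy(hbs)
    run_stats <- list(nhb_mean = mean(nhb),
                      f_d_independence = dissociation_probability(
                        occ_runs[[r]], "independence_product"),
                      f_d_empirical = as.numeric(dissociation_probability(
                        nhb, "empirical_all_broken")))
    if (sasa) {
      run_stats$buried_sasa_nm2 <- mean(
        buried_sasa_series(traj, chains_a, chains_b, n_points = 240L))
    }
    if (!is.null(energy_params)) {
      eb <- binding_energy(traj, chains_a, chains_b, params = energy_params,
                           stride = energy_stride)
      run_stats$e_binding <- attr(eb, "summary")[["mean"]]
    }
    if (!is.null(geometry)) {
      g <- geometry
      if (!is.null(g$loop_a) && !is.null(g$loop_b)) {
        hv <- metric_H(traj, select_atoms(s, g$loop_a), select_atoms(s, g$loop_b))
        metrics[[length(metrics) + 1L]] <- tidy("H", hv)
        run_stats$H_mean <- mean(hv)
      }
      if (!is.null(g$strand_a) && !is.null(g$strand_b)) {
        th <- metric_theta(traj, select_atoms(s, g$strand_a),
                           select_atoms(s, g$strand_b))
        metrics[[length(metrics) + 1L]] <- tidy("theta", th)
        run_stats$theta_mean <- mean(th)
      }
      if (!is.null(g$alpha_strand) && !is.null(g$alpha_atoms)) {
        aa <- select_atoms(s, g$alpha_atoms)
        if (length(aa) != 2L) stop("analyze_trajectory: alpha_atoms must resolve to 2 atoms")
        al <- metric_alpha(traj, select_atoms(s, g$alpha_strand), aa[1], aa[2])
        metrics[[length(metrics) + 1L]] <- tidy("alpha", al)
        run_stats$alpha_mean <- mean(al)
      }
    }
    per_run[[r]] <- run_stats
  }
  metric_names <- names(per_run[[1]])
  summaries <- do.call(rbind, lapply(metric_names, function(m) {
    aggregate_replicates(vapply(per_run, function(x) x[[m]], numeric(1)),
                         metric = m, condition = condition)
  }))
  occ_tab <- occupancy_table(occ_runs, condition = condition)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rampclamp")),
    n_replicates = length(trajectories),
    condition = condition,
    chains = list(a = chains_a, b = chains_b),
    hbond = list(mode = hbond_mode, d_cut = d_cut, ang_cut = ang_cut),
    config_hash = config_hash(list(condition, chains_a, chains_b, hbond_mode,
                                   d_cut, ang_cut, sasa,
                                   !is.null(energy_params), geometry)),
    warnings = warnings_out)
  structure(list(metrics = do.call(rbind, metrics), occupancy = occ_tab,
                 summaries = summaries,
                 per_run = per_run, manifest = manifest),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d replicates, condition '%s'\n",
              x$manifest$n_replicates, x$manifest$condition))
  print(x$summaries)
  invisible(x)
}

#' Deterministic configuration hash
#'
#' MD5 of the deparsed configuration object, used in run manifests.
#' @param config any R object.
#' @return hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Seeded pulling experiment with replicates
#'
#' Runs the ramp-clamp protocol (or ramp only) for each listed condition with
#' `n_rep` seeded replicates, collecting force traces, rupture forces and the
#' clamp-phase trigger bookkeeping; the replicate-ensemble analogue of a
#' rupture-force scatter.  Replicate seeds are `seed + 0:(n_rep-1)` offsets
#' of the protocol seed, so the whole experiment is reproducible.
#'
#' @param systems named list of [set_loading] outputs (one per condition,
#'   e.g. `list(mode1 = ..., mode2 = ...)`).
#' @param protocol base [smd_protocol]; its `mode` field is ignored in favour
#'   of each system's own mode.
#' @param n_rep replicates per condition (default 3).
#' @param clamp run the full ramp-clamp protocol (default) or ramp only.
#' @param smooth_window_ns rupture-force smoothing window.
#' @return list of class `smd_experiment`: `ruptures` (condition, replicate,
#'   seed, rupture_force_pN, rupture_time_ns, complete, trigger_time_ns),
#'   `traces` (nested list), `summaries`, `manifest`.
#' @export
smd_experiment <- function(systems, protocol, n_rep = 3L, clamp = TRUE,
                           smooth_window_ns = 0.05) {
  stopifnot(is.list(systems), length(systems) >= 1L,
            inherits(protocol, "smd_protocol"))
  if (is.null(names(systems)) || any(!nzchar(names(systems)))) {
    stop("smd_experiment: systems must be a named list of conditions")
  }
  rows <- list(); traces <- list()
  for (cond in names(systems)) {
    traces[[cond]] <- list()
    for (r in seq_len(n_rep)) {
      prot <- protocol
      prot$seed <- protocol$seed + (r - 1L)
      if (clamp) {
        run <- run_ramp_clamp(systems[[cond]], prot)
        trace <- run$trace
        complete <- run$complete
        trig <- run$trigger_time
      } else {
        run <- run_ramp(systems[[cond]], prot)
        trace <- run$trace
        complete <- NA
        trig <- NA_real_
      }
      rup <- rupture_force(trace, smooth_window_ns)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, replicate = r, seed = prot$seed,
        rupture_force_pN = rup$rupture_force,
        rupture_time_ns = rup$rupture_time,
        complete = complete, trigger_time_ns = trig,
        stringsAsFactors = FALSE)
      traces[[cond]][[r]] <- trace
    }
  }
  ruptures <- do.call(rbind, rows)
  summaries <- do.call(rbind, lapply(names(systems), function(cond) {
    aggregate_replicates(ruptures$rupture_force_pN[ruptures$condition == cond],
                         metric = "rupture_force_pN", condition = cond)
  }))
  incomplete <- ruptures$condition[!is.na(ruptures$complete) & !ruptures$complete]
  manifest <- list(
    package_version = as.character(utils::packageVersion("rampclamp")),
    base_seed = protocol$seed, n_rep = n_rep,
    clamp_force_pN = protocol$clamp_force_pN,
    protocol_incomplete = unique(incomplete),
    config_hash = config_hash(list(names(systems), unclass(protocol), n_rep, clamp)))
  structure(list(ruptures = ruptures, traces = traces, summaries = summaries,
                 manifest = manifest),
            class = "smd_experiment")
}

#' Write report tables as CSV
#'
#' Emits the tidy metric series, occupancy table and replicate summaries of
#' an [analyze_trajectory] report to `<dir>/metrics.csv`, `occupancy.csv`,
#' `summaries.csv` and the manifest to `manifest.json`-like plain text.
#'
#' @param report `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$occupancy),
                   file.path(dir, "occupancy.csv"), row.names = FALSE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"), row.names = FALSE)
  mf <- report$manifest
  writeLines(c(sprintf("package_version: %s", mf$package_version),
               sprintf("condition: %s", mf$condition),
               sprintf("n_replicates: %d", mf$n_replicates),
               sprintf("config_hash: %s", mf$config_hash),
               if (length(mf$warnings)) paste("warning:", mf$warnings)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
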