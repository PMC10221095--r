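#' Build an elastic-network model
#'
#' Coarse-grained bead model: one bead per selected atom (Ca by default),
#' harmonic springs between all bead pairs within `cutoff` at their native
#' distance.  Springs crossing the chain interface get a (typically weaker)
#' stiffness `k_interface` and are marked breakable so that pull-induced
#' rupture exists in the model; intra-chain springs are permanent.
#'
#' @param structure [md_structure].
#' @param selection selection string or atom indices; default `"name CA"`.
#' @param cutoff spring cutoff (A).
#' @param k_intra intra-chain stiffness (kcal/mol/A^2).
#' @param k_interface inter-chain stiffness (kcal/mol/A^2).
#' @param breakable_interface mark inter-chain springs breakable.
#' @return object of class `enm_model`: bead table, coordinates, masses and a
#'   spring data frame (`i, j, r0, k, breakable`).  Beads with no spring
#'   trigger a connectivity warning.
#' @export
build_enm <- function(structure, selection = "name CA", cutoff = 10,
                      k_intra = 1.0, k_interface = 0.2,
                      breakable_interface = TRUE) {
  stopifnot(inherits(structure, "md_structure"))
  idx <- if (is.character(selection)) select_atoms(structure, selection) else as.integer(selection)
  if (length(idx) < 2L) stop("build_enm: need >= 2 beads")
  beads <- structure$atoms[idx, ]
  rownames(beads) <- NULL
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  pr <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(pr) == 0L) {
    warning("build_enm: no springs within cutoff; all beads isolated")
    springs <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                          k = numeric(0), breakable = logical(0))
  } else {
    inter <- beads$chain_id[pr[, 1]] != beads$chain_id[pr[, 2]]
    springs <- data.frame(i = pr[, 1], j = pr[, 2],
                          r0 = d[pr],
                          k = ifelse(inter, k_interface, k_intra),
                          breakable = inter & breakable_interface)
    lonely <- setdiff(seq_len(n), unique(c(springs$i, springs$j)))
    if (length(lonely)) {
      warning("build_enm: bead(s) without any spring: ",
              paste(utils::head(lonely, 5), collapse = ","))
    }
  }
  structure(list(beads = beads, xyz = xyz, masses = beads$mass,
                 springs = springs, cutoff = cutoff),
            class = "enm_model")
}

#' Pulling protocol
#'
#' Parameters of the ramp-clamp loading protocol.  Defaults follow the
#' standard constant-velocity setup: virtual-spring stiffness 34.74 pN/nm,
#' pulling velocity 5 A/ns, and a 25 pN setpoint at which the run switches
#' from force-ramp to force-clamp.
#'
#' @param mode loading mode, 1 (one anchor) or 2 (two anchors, midpoint rule).
#' @param k_spring_pN_nm virtual-spring stiffness (pN/nm).
#' @param v_pull_A_ns dummy-atom velocity (A/ns).
#' @param clamp_force_pN clamp setpoint (pN).
#' @param temperature_K bath temperature (K).
#' @param friction bead friction gamma (kcal mol^-1 ns A^-2); the overdamped
#'   update is `dx = F/gamma dt + sqrt(2 kBT dt/gamma) xi`.
#' @param dt_ns integration step (ns; default 1e-5 = 10 fs).
#' @param ramp_ns,clamp_ns phase durations (ns).
#' @param sample_every store every k-th step.
#' @param break_factor breakable springs are removed past
#'   `break_factor * r0` (engine-specific rupture rule); <= 0 disables.
#' @param seed RNG seed (mandatory for stochastic runs).
#' @return list of class `smd_protocol`.
#' @export
smd_protocol <- function(mode = 2L, k_spring_pN_nm = 34.74, v_pull_A_ns = 5,
                         clamp_force_pN = 25, temperature_K = 300,
                         friction = 0.05, dt_ns = 1e-5,
                         ramp_ns = 1, clamp_ns = 1, sample_every = 100L,
                         break_factor = 2, seed = 1L) {
  stopifnot(mode %in% c(1L, 2L), k_spring_pN_nm > 0, v_pull_A_ns > 0,
            clamp_force_pN > 0, temperature_K >= 0, friction > 0, dt_ns > 0)
  structure(list(mode = as.integer(mode), k_spring_pN_nm = k_spring_pN_nm,
                 v_pull_A_ns = v_pull_A_ns, clamp_force_pN = clamp_force_pN,
                 temperature_K = temperature_K, friction = friction,
                 dt_ns = dt_ns, ramp_ns = ramp_ns, clamp_ns = clamp_ns,
                 sample_every = as.integer(sample_every),
                 break_factor = break_factor, seed = as.integer(seed)),
            class = "smd_protocol")
}

#' Configure anchors and pulling direction
#'
#' Registers the fixed and steered beads and computes the pulling direction
#' from the t = 0 geometry, after which it is held constant for the whole
#' run.  Mode 1 uses one fixed bead and pulls along fixed -> steered; mode 2
#' uses two fixed beads and pulls along the line from the midpoint between
#' them to the steered bead (the two-anchor geometry modelling a
#' membrane-proximal disulfide constraint).
#'
#' @param model [build_enm] output.
#' @param mode 1 or 2.
#' @param fixed bead indices (1 for mode 1, 2 for mode 2) or a selection
#'   string resolved against the bead table.
#' @param steered single bead index or selection string.
#' @param direction optional explicit pulling direction (3-vector, normalised
#'   internally), overriding the geometric rule; useful when the anchor and
#'   steered bead coincide (e.g. a zero-rest-length tether).
#' @return object of class `smd_system`.
#' @export
set_loading <- function(model, mode, fixed, steered, direction = NULL) {
  stopifnot(inherits(model, "enm_model"), mode %in% c(1L, 2L))
  bead_struct <- md_structure(model$beads)
  resolve <- function(x) if (is.character(x)) select_atoms(bead_struct, x) else as.integer(x)
  fixed <- resolve(fixed); steered <- resolve(steered)
  if (length(steered) != 1L) stop("set_loading: exactly one steered bead required")
  if (mode == 1L && length(fixed) != 1L) stop("set_loading: mode 1 uses one fixed bead")
  if (mode == 2L && length(fixed) != 2L) stop("set_loading: mode 2 uses two fixed beads")
  if (steered %in% fixed) stop("set_loading: steered bead cannot be fixed")
  anchor <- unname(if (mode == 1L) model$xyz[fixed, ] else
                   colMeans(model$xyz[fixed, , drop = FALSE]))
  dir <- if (is.null(direction)) unname(model$xyz[steered, ]) - anchor else direction
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) {
    stop("set_loading: steered bead coincides with the anchor point; give an explicit direction")
  }
  structure(list(model = model, mode = as.integer(mode), fixed = fixed,
                 steered = steered, direction = dir / nd, anchor = anchor),
            class = "smd_system")
}

.check_dt <- function(system, protocol, rigid_steered) {
  sp <- system$model$springs
  n <- nrow(system$model$xyz)
  ksum <- numeric(n)
  if (nrow(sp)) {
    for (r in seq_len(nrow(sp))) {
      ksum[sp$i[r]] <- ksum[sp$i[r]] + sp$k[r]
      ksum[sp$j[r]] <- ksum[sp$j[r]] + sp$k[r]
    }
  }
  if (!rigid_steered) {
    ksum[system$steered] <- ksum[system$steered] +
      spring_pN_nm_to_kcal(protocol$k_spring_pN_nm)
  }
  ratio <- max(ksum) * protocol$dt_ns / protocol$friction
  if (ratio > 0.1) {
    stop(sprintf(paste0("smd: dt too large for stability (k dt / gamma = %.3g > 0.1); ",
                        "use dt <= %.3g ns"),
                 ratio, 0.1 * protocol$friction / max(ksum)))
  }
  invisible(ratio)
}

.run_engine <- function(system, protocol, load_mode, duration_ns,
                        start_xyz = NULL, t_offset = 0, phase = "ramp",
                        rigid_steered = FALSE, stop_at_force = FALSE,
                        springs_alive = NULL, set_rng = TRUE) {
  .check_dt(system, protocol, rigid_steered)
  model <- system$model
  xyz <- if (is.null(start_xyz)) model$xyz else start_xyz
  sp <- model$springs
  if (!is.null(springs_alive)) sp <- sp[springs_alive, , drop = FALSE]
  n_steps <- max(1L, round(duration_ns / protocol$dt_ns))
  if (set_rng) set.seed(protocol$seed)
  res <- cpp_langevin(
    coords = xyz,
    spring_ij = if (nrow(sp)) as.matrix(sp[, c("i", "j")]) - 1L else matrix(0L, 0, 2),
    spring_r0 = sp$r0, spring_k = sp$k,
    spring_breakable = sp$breakable,
    break_factor = protocol$break_factor,
    fixed = system$fixed - 1L,
    steered = system$steered - 1L,
    direction = system$direction,
    load_mode = load_mode,
    k_spring = spring_pN_nm_to_kcal(protocol$k_spring_pN_nm),
    v_pull = protocol$v_pull_A_ns,
    clamp_force = force_pN_to_kcal(protocol$clamp_force_pN),
    gamma = protocol$friction,
    kBT = kBT_kcal(protocol$temperature_K),
    dt = protocol$dt_ns,
    n_steps = n_steps,
    sample_every = protocol$sample_every,
    rigid_steered = rigid_steered,
    stop_at_force = stop_at_force,
    stop_force = force_pN_to_kcal(protocol$clamp_force_pN))
  ns <- res$n_sampled
  nb <- nrow(xyz)
  arr <- array(NA_real_, dim = c(ns, nb, 3))
  for (d in 1:3) arr[, , d] <- res$xyz[seq_len(ns), (d - 1L) * nb + seq_len(nb)]
  traj <- md_trajectory(md_structure(model$beads), arr,
                        times = res$times[seq_len(ns)] + t_offset)
  trace <- force_trace(time_ns = res$times[seq_len(ns)] + t_offset,
                       force_pN = force_kcal_to_pN(res$force[seq_len(ns)]),
                       dummy_A = res$dummy[seq_len(ns)],
                       steered_A = res$steered_proj[seq_len(ns)],
                       phase = rep(phase, ns))
  list(trajectory = traj, trace = trace,
       triggered = res$triggered,
       trigger_time = if (res$triggered) res$trigger_step * protocol$dt_ns + t_offset else NA_real_,
       final_xyz = res$final_xyz,
       springs_alive = res$spring_alive,
       steps_done = res$steps_done)
}

#' Free (unloaded) Langevin dynamics
#'
#' Runs the elastic network at the protocol temperature with no pulling
#' force; the equilibrium counterpart of the loaded phases, used e.g. to
#' check equipartition statistics.
#'
#' @param model [build_enm] output.
#' @param protocol [smd_protocol]; `ramp_ns` sets the duration.
#' @param fixed bead indices held immobile.
#' @return list as [run_ramp] (force channel all zero).
#' @export
run_free <- function(model, protocol, fixed = integer(0)) {
  stopifnot(inherits(model, "enm_model"), inherits(protocol, "smd_protocol"))
  system <- structure(list(model = model, mode = 1L,
                           fixed = as.integer(fixed), steered = 0L,
                           direction = c(0, 0, 1)),
                      class = "smd_system")
  .run_engine(system, protocol, load_mode = 0L,
              duration_ns = protocol$ramp_ns, phase = "ramp",
              rigid_steered = TRUE)
}

#' Run the force-ramp (constant-velocity) phase
#'
#' A dummy atom starts at the steered bead's projection on the pulling axis
#' and moves at `v_pull`; the virtual spring applies
#' `F = k_spring (x_dummy - x_steered)` along the fixed direction.  Free
#' beads follow overdamped Langevin dynamics; fixed beads never move.  With
#' identical seed and protocol the trace is bitwise reproducible.
#'
#' @param system [set_loading] output.
#' @param protocol [smd_protocol].
#' @param rigid_steered hold the steered bead immobile (test mode: the force
#'   then grows exactly as `k_spring * v_pull * t`).
#' @param stop_at_clamp_force stop at the first crossing of the clamp
#'   setpoint (the ramp-to-clamp trigger).
#' @return list: `trajectory` ([md_trajectory] of the beads), `trace`
#'   ([force_trace]), `triggered`, `trigger_time`, `final_xyz`,
#'   `springs_alive`.
#' @export
run_ramp <- function(system, protocol, rigid_steered = FALSE,
                     stop_at_clamp_force = FALSE) {
  stopifnot(inherits(system, "smd_system"), inherits(protocol, "smd_protocol"))
  .run_engine(system, protocol, load_mode = 1L, duration_ns = protocol$ramp_ns,
              phase = "ramp", rigid_steered = rigid_steered,
              stop_at_force = stop_at_clamp_force)
}

#' Run the force-clamp phase
#'
#' Applies the constant clamp force to the steered bead along the stored
#' pulling direction; the applied-force channel is constant by construction.
#'
#' @inheritParams run_ramp
#' @param start_xyz starting coordinates (defaults to the model's native
#'   coordinates; pass `final_xyz` of a ramp run to continue it).
#' @param t_offset time origin for the trace (ns).
#' @param springs_alive logical vector of surviving springs from a previous
#'   phase.
#' @export
run_clamp <- function(system, protocol, start_xyz = NULL, t_offset = 0,
                      springs_alive = NULL) {
  stopifnot(inherits(system, "smd_system"), inherits(protocol, "smd_protocol"))
  .run_engine(system, protocol, load_mode = 2L, duration_ns = protocol$clamp_ns,
              start_xyz = start_xyz, t_offset = t_offset, phase = "clamp",
              springs_alive = springs_alive, set_rng = is.null(start_xyz))
}

#' Full ramp-clamp protocol
#'
#' Constant-velocity pulling until the spring force first reaches the clamp
#' setpoint, then constant-force holding for `clamp_ns`, continuing from the
#' ramp end state.  If the ramp never reaches the setpoint the run is
#' reported protocol-incomplete (`complete = FALSE`) rather than erroring.
#'
#' @inheritParams run_ramp
#' @return list: `trace` (combined [force_trace] with ramp/clamp phases),
#'   `trajectory_ramp`, `trajectory_clamp` (NULL when incomplete),
#'   `complete`, `trigger_time`.
#' @export
run_ramp_clamp <- function(system, protocol) {
  ramp <- run_ramp(system, protocol, stop_at_clamp_force = TRUE)
  if (!ramp$triggered) {
    return(list(trace = ramp$trace, trajectory_ramp = ramp$trajectory,
                trajectory_clamp = NULL, complete = FALSE,
                trigger_time = NA_real_))
  }
  clamp <- run_clamp(system, protocol, start_xyz = ramp$final_xyz,
                     t_offset = ramp$trigger_time,
                     springs_alive = ramp$springs_alive)
  tr <- rbind(as.data.frame(ramp$trace),
              as.data.frame(clamp$trace)[-1, , drop = FALSE])
  keep <- !duplicated(tr$time_ns)
  tr <- tr[keep, , drop = FALSE]
  trace <- force_trace(tr$time_ns, tr$force_pN, tr$dummy_A, tr$steered_A, tr$phase)
  list(trace = trace, trajectory_ramp = ramp$trajectory,
       trajectory_clamp = clamp$trajectory, complete = TRUE,
       trigger_time = ramp$trigger_time)
}

#' Rupture force from a force-time trace
#'
#' Running-mean smoothing of the ramp-phase force followed by the global
#' maximum; the peak of the force-time curve is the rupture force.
#'
#' @param trace [force_trace].
#' @param smooth_window_ns running-mean window (ns); 0 disables smoothing.
#' @return list of class `rupture_result`: `rupture_force` (pN),
#'   `rupture_time` (ns), `smoothed` (data frame time_ns/force_pN).
#' @export
rupture_force <- function(trace, smooth_window_ns = 0.05) {
  stopifnot(inherits(trace, "force_trace"))
  d <- as.data.frame(trace)
  d <- d[d$phase == "ramp", , drop = FALSE]
  if (nrow(d) == 0L) stop("rupture_force: trace has no ramp phase")
  f <- d$force_pN
  if (length(unique(f)) == 1L) {
    warning("rupture_force: constant force trace")
    return(structure(list(rupture_force = f[1], rupture_time = d$time_ns[1],
                          smoothed = data.frame(time_ns = d$time_ns, force_pN = f)),
                     class = "rupture_result"))
  }
  if (smooth_window_ns > 0 && nrow(d) > 2L) {
    dt <- stats::median(diff(d$time_ns))
    w <- max(1L, round(smooth_window_ns / dt))
    if (w > 1L) {
      w <- min(w, length(f))
      kern <- rep(1 / w, w)
      sm <- stats::filter(f, kern, sides = 2)
      # shrink the window at the edges instead of dropping them
      half <- (w - 1L) %/% 2L
      for (i in which(is.na(sm))) {
        lo <- max(1L, i - half); hi <- min(length(f), i + half)
        sm[i] <- mean(f[lo:hi])
      }
      f <- as.numeric(sm)
    }
  }
  k <- which.max(f)
  structure(list(rupture_force = f[k], rupture_time = d$time_ns[k],
                 smoothed = data.frame(time_ns = d$time_ns, force_pN = f)),
            class = "rupture_result")
}
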