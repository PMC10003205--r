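#' Engine configuration
#'
#' Collects the integration and interaction settings of the CG engine. The
#' defaults are the production settings of the study protocol: 20 fs time
#' step, 310 K Nose-Hoover thermostat (1 ps coupling), 1 bar Andersen-type
#' semi-isotropic barostat (lateral box lengths coupled together, normal
#' independent, so the area per lipid can equilibrate), 12.5 A cutoff for
#' both van der Waals and real-space electrostatics, Ewald summation for
#' charged beads, and the effective-time factor of 4.
#'
#' @param dt_fs time step, fs
#' @param temperature_K target temperature
#' @param pressure_bar target pressure
#' @param thermostat "nose-hoover" or "none"
#' @param tau_t_ps thermostat coupling time
#' @param barostat "none", "semi-isotropic" or "isotropic"
#' @param tau_p_ps barostat coupling time
#' @param rcut_A nonbonded cutoff (A); must not exceed half the smallest box
#'   length at run time
#' @param coulomb "ewald" or "none"
#' @param ewald_accuracy relative accuracy target; sets the splitting
#'   parameter and reciprocal-space extent
#' @param eff_factor effective-time factor applied to reported times
#' @param stride emit a frame every `stride` steps
#' @param seed integer seed for velocity initialisation
#' @return object of class `cg_engine_config`
#' @export
engine_config <- function(dt_fs = 20, temperature_K = 310, pressure_bar = 1,
                          thermostat = c("nose-hoover", "none"),
                          tau_t_ps = 1.0,
                          barostat = c("none", "semi-isotropic", "isotropic"),
                          tau_p_ps = 5.0, rcut_A = 12.5,
                          coulomb = c("ewald", "none"),
                          ewald_accuracy = 1e-4, eff_factor = 4,
                          stride = 10L, seed = 1L) {
  stopifnot(dt_fs > 0, temperature_K > 0, rcut_A > 0, eff_factor > 0,
            tau_t_ps > 0, tau_p_ps > 0, stride >= 1)
  structure(list(dt_fs = dt_fs, temperature_K = temperature_K,
                 pressure_bar = pressure_bar,
                 thermostat = match.arg(thermostat), tau_t_ps = tau_t_ps,
                 barostat = match.arg(barostat), tau_p_ps = tau_p_ps,
                 rcut_A = rcut_A, coulomb = match.arg(coulomb),
                 ewald_accuracy = ewald_accuracy, eff_factor = eff_factor,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "cg_engine_config")
}

# Map a system + force field onto the flat arrays the C++ kernel takes.
# Lengths here are nm (internal units); the system stores angstroms.
engine_arrays <- function(system, ff) {
  tmap <- match(system$type, ff$types)
  if (anyNA(tmap)) stop("system contains bead types unknown to the force field: ",
                        paste(unique(system$type[is.na(tmap)]), collapse = ", "))
  first_bead <- match(system$molecules$id, system$molecule)
  lip_rows <- which(system$molecules$kind == "lipid")
  bl <- vector("list", length(lip_rows)); al <- bl
  br0l <- bl; bkl <- bl; at0l <- bl; afcl <- bl
  for (q in seq_along(lip_rows)) {
    row <- system$molecules[lip_rows[q], ]
    topo <- system$topologies[[topo_key(row$species, row$protonated)]]
    off <- first_bead[lip_rows[q]] - 1L
    bl[[q]] <- cbind(topo$bonds$i + off, topo$bonds$j + off)
    br0l[[q]] <- topo$bonds$r0                   # already nm in config
    bkl[[q]] <- topo$bonds$k
    al[[q]] <- cbind(topo$angles$i + off, topo$angles$j + off,
                     topo$angles$k_idx + off)
    at0l[[q]] <- topo$angles$theta0 * pi / 180
    afcl[[q]] <- topo$angles$fc
  }
  bonds <- if (length(bl)) do.call(rbind, bl) else matrix(integer(0), 0, 2)
  angles <- if (length(al)) do.call(rbind, al) else matrix(integer(0), 0, 3)
  br0 <- as.numeric(unlist(br0l)); bk <- as.numeric(unlist(bkl))
  at0 <- as.numeric(unlist(at0l)); afc <- as.numeric(unlist(afcl))
  list(tidx = tmap - 1L, charge = system$charge,
       eps = ff$epsilon, sig = ff$sigma,
       bonds = bonds - 1L, bond_r0 = br0, bond_k = bk,
       angles = angles - 1L, angle_theta0 = at0, angle_fc = afc,
       ke = ff$coulomb_constant / ff$relative_dielectric)
}

ewald_params <- function(box_nm, rcut_nm, accuracy) {
  x <- sqrt(max(1, -log(accuracy)))        # erfc(x) ~ exp(-x^2)
  alpha <- x / rcut_nm
  kmax <- pmax(4L, as.integer(ceiling(2 * alpha * x * box_nm / (2 * pi))))
  list(alpha = alpha, kmax = kmax)
}

#' Potential energy, forces and virial of a system
#'
#' Evaluates the full CG interaction model: shifted Lennard-Jones (zero at
#' the cutoff), harmonic bonds, cosine-harmonic angles and, for charged
#' beads, Ewald electrostatics. First bonded neighbours are excluded from
#' the nonbonded terms.
#'
#' @param system a `cg_system`
#' @param ff a `cg_forcefield`
#' @param config an [engine_config()]
#' @param arrays flattened interaction arrays from an earlier call (internal
#'   cache; leave `NULL`)
#' @return list: `energy` (named components, kJ/mol), `forces`
#'   (`[n, 3]`, kJ/mol/A), `virial` (diagonal, kJ/mol), `min_dist` (A),
#'   `overlap` flag (beads closer than the 1 A hard core)
#' @export
energy_forces <- function(system, ff, config = engine_config(),
                          arrays = NULL) {
  box_nm <- system$box * .A2NM
  rcut_nm <- config$rcut_A * .A2NM
  if (rcut_nm > min(box_nm) / 2)
    stop("cutoff exceeds half the smallest box length")
  arr <- if (is.null(arrays)) engine_arrays(system, ff) else arrays
  do_coul <- config$coulomb == "ewald" && any(system$charge != 0)
  ew <- if (do_coul) ewald_params(box_nm, rcut_nm, config$ewald_accuracy)
        else list(alpha = 0, kmax = c(0L, 0L, 0L))
  res <- cg_energy_forces(system$xyz * .A2NM, box_nm, arr$tidx, arr$charge,
                          arr$eps, arr$sig, rcut_nm,
                          arr$bonds, arr$bond_r0, arr$bond_k,
                          arr$angles, arr$angle_theta0, arr$angle_fc,
                          do_coul, arr$ke, ew$alpha, ew$kmax)
  en <- c(potential = res$potential, lj = res$lj, bond = res$bond,
          angle = res$angle, coulomb = res$coulomb)
  list(energy = en, forces = res$forces * .A2NM,  # kJ/mol/nm -> kJ/mol/A
       virial = res$virial, min_dist = res$min_dist * .NM2A,
       overlap = is.finite(res$min_dist) && res$min_dist * .NM2A < 1.0)
}

#' Steepest-descent energy minimisation
#'
#' Removes bad contacts from freshly built systems before dynamics: adaptive
#' steepest descent with energy backtracking. Never increases the potential
#' energy; stops when the largest force component drops below `ftol` or at
#' the iteration cap.
#'
#' @param system a `cg_system`
#' @param ff force field
#' @param config engine configuration (cutoff/electrostatics settings)
#' @param max_iter iteration cap
#' @param ftol force tolerance, kJ/mol/A
#' @param step0_A initial displacement of the largest-force bead, A
#' @return the relaxed system, with attributes `energy_trace` (kJ/mol) and
#'   `converged`
#' @export
minimize <- function(system, ff, config = engine_config(), max_iter = 200L,
                     ftol = 10, step0_A = 0.2) {
  arrays <- engine_arrays(system, ff)
  ef <- energy_forces(system, ff, config, arrays)
  e <- ef$energy[["potential"]]
  trace <- e
  lambda <- step0_A
  for (it in seq_len(max_iter)) {
    fmax <- max(abs(ef$forces))
    if (fmax < ftol) break
    trial <- system
    trial$xyz <- wrap_coords(system$xyz + lambda * ef$forces / fmax, system$box)
    ef_t <- energy_forces(trial, ff, config, arrays)
    if (ef_t$energy[["potential"]] < e) {
      system <- trial
      ef <- ef_t
      e <- ef$energy[["potential"]]
      lambda <- min(lambda * 1.2, 1.0)
    } else {
      lambda <- lambda * 0.5
      if (lambda < 1e-8) break
    }
    trace <- c(trace, e)
  }
  attr(system, "energy_trace") <- trace
  attr(system, "converged") <- max(abs(ef$forces)) < ftol
  system
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities at the target temperature and removes centre-of-mass
#' motion. Velocities are in A/ps.
#' @param system a `cg_system`
#' @param temperature_K target temperature
#' @param seed integer
#' @return the system with `vel` filled in
#' @export
init_velocities <- function(system, temperature_K = 310, seed = 1L) {
  set.seed(seed)
  n <- nrow(system$xyz)
  sd_nm <- sqrt(.kB * temperature_K / system$mass)  # nm/ps per axis
  v <- matrix(rnorm(3 * n), n, 3) * sd_nm * .NM2A   # A/ps
  mv <- colSums(v * system$mass) / sum(system$mass)
  v <- sweep(v, 2, mv)
  # rescale to hit the target exactly (n - 1 COM constraint)
  ke <- 0.5 * sum(system$mass * rowSums((v * .A2NM)^2))
  Tinst <- 2 * ke / ((3 * n - 3) * .kB)
  system$vel <- v * sqrt(temperature_K / Tinst)
  system
}

kinetic_energy <- function(mass, vel_A_ps) {
  0.5 * sum(mass * rowSums((vel_A_ps * .A2NM)^2))  # kJ/mol
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration with an optional Nose-Hoover thermostat and
#' an Andersen-type extended-variable (piston) barostat. With both disabled
#' the run is NVE. Pressure coupling is semi-isotropic by default
#' configuration choice (x and y scale together, z independently), the
#' standard choice for planar bilayers. Frames are emitted every
#' `config$stride` steps; trajectory times carry the effective-time factor.
#'
#' Identical seeds and inputs give bit-identical trajectories. A diverging
#' potential energy aborts with the offending frame attached to the error.
#'
#' @param system a `cg_system`; velocities are initialised from
#'   `config$seed` if unset
#' @param ff force field
#' @param config an [engine_config()]
#' @param n_steps number of integration steps
#' @param verbose print a log line every `log_every` steps (0 = quiet)
#' @param log_every interval for log records
#' @return list: `trajectory` (a `cg_trajectory`), `system` (final state),
#'   `log` (data.frame: step, time_ps, potential, kinetic, temperature_K,
#'   pressure_bar, P_lateral, P_normal, Lx, Ly, Lz)
#' @export
run_md <- function(system, ff, config = engine_config(), n_steps = 1000L,
                   verbose = FALSE, log_every = 50L) {
  dt <- config$dt_fs * 1e-3                   # ps
  n <- nrow(system$xyz)
  if (is.null(system$vel) || all(system$vel == 0))
    system <- init_velocities(system, config$temperature_K, config$seed)
  x <- system$xyz; v <- system$vel; m <- system$mass
  box <- system$box
  Nf <- 3 * n - 3
  kT0 <- .kB * config$temperature_K
  use_th <- config$thermostat == "nose-hoover"
  use_bar <- config$barostat != "none"
  Q <- Nf * kT0 * config$tau_t_ps^2           # NH mass
  xi <- 0
  Wp <- (Nf + 3) * kT0 * config$tau_p_ps^2    # piston mass
  eps_lat <- 0; eps_nrm <- 0                  # piston strain rates, 1/ps

  arrays <- engine_arrays(system, ff)
  ef <- energy_forces(system, ff, config, arrays)
  f <- ef$forces                              # kJ/mol/A
  acc <- function(f) f / m * 100              # (kJ/mol/A)/amu -> A/ps^2
  frames <- list(); boxes <- list(); times <- numeric(0)
  log <- list(); li <- 0L

  pressures <- function(v, W, box) {
    vol <- prod(box * .A2NM)
    kin_d <- colSums(m * (v * .A2NM)^2)       # kJ/mol per axis (sum m v_d^2)
    (kin_d + W) / vol * .BAR_PER_KJ_NM3       # bar
  }

  for (step in seq_len(n_steps)) {
    if (use_th) {
      ke <- kinetic_energy(m, v)
      xi <- xi + 0.5 * dt * (2 * ke - Nf * kT0) / Q
      v <- v * exp(-0.5 * dt * xi)
    }
    v <- v + 0.5 * dt * acc(f)
    x <- x + dt * v
    if (use_bar) {
      Pd <- pressures(v, ef$virial, box)
      vol_nm3 <- prod(box * .A2NM)
      if (config$barostat == "semi-isotropic") {
        Plat <- (Pd[1] + Pd[2]) / 2
        eps_lat <- (eps_lat + dt * (Plat - config$pressure_bar) /
                      .BAR_PER_KJ_NM3 * vol_nm3 / Wp) * exp(-dt / (4 * config$tau_p_ps))
        eps_nrm <- (eps_nrm + dt * (Pd[3] - config$pressure_bar) /
                      .BAR_PER_KJ_NM3 * vol_nm3 / Wp) * exp(-dt / (4 * config$tau_p_ps))
        sl <- exp(eps_lat * dt); sn <- exp(eps_nrm * dt)
      } else {
        Pm <- mean(Pd)
        eps_lat <- (eps_lat + dt * (Pm - config$pressure_bar) /
                      .BAR_PER_KJ_NM3 * vol_nm3 / Wp) * exp(-dt / (4 * config$tau_p_ps))
        sl <- sn <- exp(eps_lat * dt)
      }
      box <- box * c(sl, sl, sn)
      x[, 1:2] <- x[, 1:2] * sl
      x[, 3] <- x[, 3] * sn
    }
    sys_step <- system
    sys_step$xyz <- wrap_coords(x, box)
    sys_step$box <- box
    ef <- energy_forces(sys_step, ff, config, arrays)
    if (!is.finite(ef$energy[["potential"]]) ||
        abs(ef$energy[["potential"]]) > 1e10) {
      err <- simpleError(sprintf("divergent energy at step %d", step))
      err$frame <- sys_step
      stop(err)
    }
    f <- ef$forces
    v <- v + 0.5 * dt * acc(f)
    if (use_th) {
      v <- v * exp(-0.5 * dt * xi)
      ke <- kinetic_energy(m, v)
      xi <- xi + 0.5 * dt * (2 * ke - Nf * kT0) / Q
    }
    x <- sys_step$xyz

    if (step %% config$stride == 0L) {
      frames[[length(frames) + 1L]] <- x
      boxes[[length(boxes) + 1L]] <- box
      times <- c(times, step * dt * 1e-3)     # actual ns
    }
    if (step %% log_every == 0L || step == n_steps) {
      ke <- kinetic_energy(m, v)
      Pd <- pressures(v, ef$virial, box)
      li <- li + 1L
      log[[li]] <- data.frame(
        step = step, time_ps = step * dt,
        potential = ef$energy[["potential"]], kinetic = ke,
        temperature_K = 2 * ke / (Nf * .kB), pressure_bar = mean(Pd),
        P_lateral = (Pd[1] + Pd[2]) / 2, P_normal = Pd[3],
        Lx = box[1], Ly = box[2], Lz = box[3])
      if (verbose)
        message(sprintf("step %6d  Epot %12.2f  T %7.2f K  P %9.2f bar  box %.2f %.2f %.2f",
                        step, ef$energy[["potential"]], 2 * ke / (Nf * .kB),
                        mean(Pd), box[1], box[2], box[3]))
    }
  }
  system$xyz <- x; system$vel <- v; system$box <- box
  traj <- if (length(frames)) {
    trajectory_from_frames(system, frames,
                           box = do.call(rbind, boxes), time_ns = times,
                           eff_factor = config$eff_factor)
  } else NULL
  list(trajectory = traj, system = system, log = do.call(rbind, log))
}
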