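# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

FF <- load_forcefield()

# simple LJ fluid of CG water beads on a jittered grid
make_fluid <- function(n, box_A, seed = 1, type = "P4") {
  sys <- cgbilayer:::empty_system(rep(box_A, 3))
  set.seed(seed)
  g <- ceiling(n^(1 / 3))
  pts <- as.matrix(expand.grid(1:g, 1:g, 1:g))[1:n, , drop = FALSE]
  xyz <- pts * box_A / g - box_A / (2 * g) +
    matrix(runif(3 * n, -0.3, 0.3), n, 3)
  for (i in 1:n)
    sys <- cgbilayer:::append_molecule(
      sys, xyz[i, , drop = FALSE],
      cgbilayer:::solvent_bead_row(type, FF), "water", "water")
  sys
}

# a two-bead system of given types at a given separation along x
make_pair <- function(sep_A, types = c("C1", "C1"), charges = NULL,
                      box_A = 60) {
  sys <- cgbilayer:::empty_system(rep(box_A, 3))
  bd <- data.frame(name = c("A", "B"), type = types,
                   charge = if (is.null(charges))
                     FF$type_info[types, "charge"] else charges,
                   mass = FF$type_info[types, "mass"],
                   stringsAsFactors = FALSE)
  cgbilayer:::append_molecule(
    sys, rbind(c(10, 10, 10), c(10 + sep_A, 10, 10)), bd, "pair", "ion")
}

# direct periodic lattice sum over expanding cubic shells (vacuum boundary);
# the Ewald (tin-foil) energy differs by the standard dipole term
# 2 pi ke |M|^2 / (3V), which the caller adds before comparing.
direct_coulomb_sum <- function(r_nm, q, L_nm, ke, nmax) {
  E <- 0
  np <- nrow(r_nm)
  for (nx in -nmax:nmax) for (ny in -nmax:nmax) for (nz in -nmax:nmax) {
    sh <- c(nx, ny, nz) * L_nm
    home <- nx == 0 && ny == 0 && nz == 0
    for (i in 1:np) for (j in 1:np) {
      if (home && i >= j) next
      fac <- if (i == j) 0.5 else if (home) 1 else 0.5
      E <- E + fac * ke * q[i] * q[j] / sqrt(sum((r_nm[i, ] - r_nm[j, ] + sh)^2))
    }
  }
  E
}

# naive per-frame double-loop P2 average over the requested bond vectors
oracle_p2_bond <- function(traj, from_col, to_col, rows) {
  lip <- lipid_index(traj)[rows, , drop = FALSE]
  total <- 0; count <- 0
  for (f in seq_len(n_frames(traj))) {
    L <- traj$box[f, ]
    for (q in seq_len(nrow(lip))) {
      d <- traj$coords[lip[[to_col]][q], , f] -
        traj$coords[lip[[from_col]][q], , f]
      d <- d - round(d / L) * L
      ct2 <- d[3]^2 / sum(d^2)
      total <- total + 0.5 * (3 * ct2 - 1)
      count <- count + 1
    }
  }
  total / count
}

# total-energy drift per bead of an NVE run
nve_drift <- function(sys, dt_fs, n_steps, seed = 4) {
  cfg <- engine_config(dt_fs = dt_fs, thermostat = "none", barostat = "none",
                       coulomb = "none", stride = n_steps + 1, seed = seed)
  res <- run_md(init_velocities(sys, 310, seed), FF, cfg, n_steps,
                log_every = max(1, n_steps %/% 50))
  etot <- res$log$potential + res$log$kinetic
  (max(etot) - min(etot)) / nrow(sys$xyz)
}
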