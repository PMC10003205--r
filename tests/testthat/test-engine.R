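test_that("Lennard-Jones pair is analytic at the minimum and the cutoff", {
  s <- ff_lookup(FF, "C1", "C1")[["sigma"]] * 10   # A
  cfg <- engine_config(coulomb = "none")
  # force exactly zero at r = 2^(1/6) sigma
  ef <- energy_forces(make_pair(2^(1 / 6) * s), FF, cfg)
  expect_lt(max(abs(ef$forces)), 1e-10)
  # shifted potential continuous: energy exactly 0 at the cutoff
  eps_at <- function(r) energy_forces(make_pair(r), FF, cfg)$energy[["lj"]]
  expect_equal(eps_at(12.5), 0)
  expect_equal(eps_at(12.6), 0)          # beyond cutoff
  expect_lt(eps_at(12.4), 0)             # attractive just inside
  # well depth at the minimum equals epsilon minus the shift
  e <- ff_lookup(FF, "C1", "C1")[["epsilon"]]
  src6 <- (s / 12.5)^6
  expect_equal(eps_at(2^(1 / 6) * s), -e - 4 * e * (src6^2 - src6),
               tolerance = 1e-10)
})

test_that("forces obey Newton's third law and match the numerical gradient", {
  comp <- composition(c("ISUCA-Pal-Ol" = 2),
                      protonated = TRUE, n_water = 0)
  sys <- build_bilayer(comp, c(26, 26, 70), seed = 3, ff = FF)
  cfg <- engine_config(coulomb = "ewald")
  ef <- energy_forces(sys, FF, cfg)
  expect_lt(max(abs(colSums(ef$forces))), 1e-8)
  arr <- cgbilayer:::engine_arrays(sys, FF)
  h <- 1e-5
  fscale <- max(abs(ef$forces))
  for (i in c(1, 5, 14)) for (d in 1:3) {
    sp <- sys; sp$xyz[i, d] <- sp$xyz[i, d] + h
    sm <- sys; sm$xyz[i, d] <- sm$xyz[i, d] - h
    num <- -(energy_forces(sp, FF, cfg, arr)$energy[["potential"]] -
               energy_forces(sm, FF, cfg, arr)$energy[["potential"]]) / (2 * h)
    expect_lt(abs(ef$forces[i, d] - num), 1e-5 * fscale)
  }
})

test_that("Ewald energy of a neutral two-charge pair matches the image sum", {
  sys <- make_pair(3.0, types = c("Q0", "Qa"), box_A = 20)
  cfg <- engine_config(coulomb = "ewald", rcut_A = 8, ewald_accuracy = 1e-6)
  ew <- energy_forces(sys, FF, cfg)$energy[["coulomb"]]
  ke <- FF$coulomb_constant / FF$relative_dielectric
  r <- rbind(c(1, 1, 1), c(1.3, 1, 1))              # nm
  direct <- direct_coulomb_sum(r, c(1, -1), 2, ke, 12)
  # tin-foil Ewald vs vacuum-boundary direct sum: add the dipole term
  M2 <- sum((r[1, ] - r[2, ])^2)
  expect_equal(ew + 2 * pi * ke * M2 / (3 * 2^3), direct, tolerance = 1e-4)
})

test_that("a free particle translates by v dt per step exactly", {
  sys <- make_fluid(1, 100)
  sys$vel <- matrix(c(3, -2, 1), 1, 3)              # A/ps
  cfg <- engine_config(dt_fs = 20, thermostat = "none", barostat = "none",
                       coulomb = "none", stride = 1)
  res <- run_md(sys, FF, cfg, n_steps = 25)
  expect_equal(res$system$xyz, sys$xyz + 25 * 0.02 * sys$vel,
               tolerance = 1e-12)
})

test_that("NVE conserves energy (step-halving convergence) and momentum", {
  sys <- minimize(make_fluid(64, 26, seed = 1), FF,
                  engine_config(coulomb = "none"), max_iter = 80)
  d20 <- nve_drift(sys, 20, 4000)
  d10 <- nve_drift(sys, 10, 8000)
  # halving the step must reduce the drift (2nd-order integrator), and the
  # production step's drift stays small against kT = 2.58 kJ/mol
  expect_lt(d10, d20)
  expect_lt(d20, 0.1)
  cfg <- engine_config(thermostat = "none", barostat = "none",
                       coulomb = "none", stride = 5000)
  res <- run_md(init_velocities(sys, 310, 4), FF, cfg, 2000)
  p <- colSums(res$system$vel * res$system$mass)
  expect_lt(max(abs(p)), 1e-8)
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- make_fluid(27, 26, seed = 2)
  cfg <- engine_config(coulomb = "none", stride = 10, seed = 11)
  r1 <- run_md(sys, FF, cfg, 100)
  r2 <- run_md(sys, FF, cfg, 100)
  expect_identical(r1$system$xyz, r2$system$xyz)
  expect_identical(r1$trajectory$coords, r2$trajectory$coords)
})

test_that("minimisation descends and matches a brute-force grid on a 3-bead toy", {
  # overlapping pair: energy must strictly decrease
  sys <- make_pair(2.0)
  cfg <- engine_config(coulomb = "none")
  e0 <- energy_forces(sys, FF, cfg)$energy[["potential"]]
  sysm <- minimize(sys, FF, cfg, max_iter = 300, ftol = 1e-3)
  e1 <- energy_forces(sysm, FF, cfg)$energy[["potential"]]
  expect_lt(e1, e0)
  trace <- attr(sysm, "energy_trace")
  expect_true(all(diff(trace) <= 0))
  # already-minimal pair stays put
  s <- ff_lookup(FF, "C1", "C1")[["sigma"]] * 10
  sys_min <- make_pair(2^(1 / 6) * s)
  out <- minimize(sys_min, FF, cfg, max_iter = 50)
  expect_equal(out$xyz, sys_min$xyz, tolerance = 1e-6)
  # 3 collinear beads: compare with an exhaustive (r12, r23) energy grid
  mk3 <- function(r12, r23) {
    sys3 <- cgbilayer:::empty_system(rep(60, 3))
    bd <- data.frame(name = c("A", "B", "C"), type = "C1", charge = 0,
                     mass = 72, stringsAsFactors = FALSE)
    cgbilayer:::append_molecule(
      sys3, rbind(c(10, 10, 10), c(10 + r12, 10, 10),
                  c(10 + r12 + r23, 10, 10)), bd, "toy", "ion")
  }
  grid <- seq(4.2, 6.6, by = 0.05)
  egrid <- outer(grid, grid, Vectorize(function(a, b)
    energy_forces(mk3(a, b), FF, cfg)$energy[["potential"]]))
  e_grid_min <- min(egrid)
  start <- mk3(5.1, 6.3)
  relax <- minimize(start, FF, cfg, max_iter = 500, ftol = 1e-4)
  e_relax <- energy_forces(relax, FF, cfg)$energy[["potential"]]
  # grid resolution limits the oracle; the relaxed energy must match the
  # grid minimum to within one grid cell's curvature and never undercut a
  # finer search
  expect_lt(abs(e_relax - e_grid_min), 0.05)
  expect_lte(e_relax, e_grid_min + 1e-9)
})

test_that("noninteracting beads reproduce the ideal-gas pressure NkT/V", {
  sys <- make_fluid(125, 40, seed = 3)
  ff0 <- FF
  ff0$epsilon[] <- 0                      # switch off all interactions
  cfg <- engine_config(thermostat = "nose-hoover", barostat = "none",
                       coulomb = "none", seed = 2, stride = 5000)
  res <- run_md(sys, ff0, cfg, 2000, log_every = 20)
  sel <- res$log$step > 500
  P_ref <- 125 * 0.0083144621 * 310 / prod(sys$box * 0.1) * 16.6054
  expect_equal(mean(res$log$pressure_bar[sel]), P_ref, tolerance = 0.05)
})

test_that("the semi-isotropic barostat scales x and y together, keeps beads", {
  sys <- minimize(make_fluid(216, 31, seed = 5), FF,
                  engine_config(coulomb = "none"), max_iter = 60)
  cfg <- engine_config(thermostat = "nose-hoover",
                       barostat = "semi-isotropic", coulomb = "none",
                       seed = 3, stride = 100)
  res <- run_md(sys, FF, cfg, 600, log_every = 50)
  expect_equal(res$log$Lx / res$log$Ly, rep(1, nrow(res$log)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res$log$Lz[1], tail(res$log$Lz, 1))))
  expect_equal(dim(res$system$xyz), dim(sys$xyz))
  expect_equal(nrow(res$trajectory$coords), 216)
})

test_that("configuration guards: cutoff versus box, divergent energy", {
  sys <- make_fluid(8, 20)
  expect_error(energy_forces(sys, FF, engine_config(rcut_A = 12.5)),
               "half the smallest box length")
  # hard overlap diagnosed
  sys2 <- make_pair(0.4)
  ef <- energy_forces(sys2, FF, engine_config(coulomb = "none"))
  expect_true(ef$overlap)
})

test_that("the thermostat holds the target temperature on a small fluid", {
  sys <- minimize(make_fluid(125, 29, seed = 7), FF,
                  engine_config(coulomb = "none"), max_iter = 60)
  cfg <- engine_config(thermostat = "nose-hoover", barostat = "none",
                       coulomb = "none", seed = 8, stride = 5000)
  res <- run_md(sys, FF, cfg, 2500, log_every = 10)
  Tbar <- mean(res$log$temperature_K[res$log$step > 500])
  expect_equal(Tbar, 310, tolerance = 0.02)
})
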