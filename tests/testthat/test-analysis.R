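test_that("area per lipid follows the box geometry exactly", {
  spec <- synthetic_spec(lipids_per_leaflet = 58, n_frames = 3,
                         apl_A2 = 62.4^2 / 58, D_cm2_s = 0, seed = 1)
  traj <- gen_bilayer_trajectory(spec, FF)
  apl <- area_per_lipid(traj)
  expect_equal(apl$mean, 62.4 * 62.4 / 58, tolerance = 1e-9)
  expect_equal(apl$sd, 0)                  # constant box
  expect_equal(round(apl$mean), 67)
  # unit lateral box, one lipid per leaflet
  tiny <- gen_bilayer_trajectory(
    synthetic_spec(lipids_per_leaflet = 1, n_frames = 2, apl_A2 = 1,
                   thickness_A = 5, box_height_A = 60, D_cm2_s = 0), FF)
  expect_equal(area_per_lipid(tiny)$mean, 1)
  expect_error(area_per_lipid(traj, lipids_per_leaflet = 0), "zero lipids")
})

test_that("hydrophobic thickness recovers the C1-plane distance", {
  spec <- synthetic_spec(n_frames = 4, thickness_A = 14.8, D_cm2_s = 0,
                         seed = 2)
  traj <- gen_bilayer_trajectory(spec, FF)
  th <- hydrophobic_thickness(traj)
  expect_equal(th$mean, 14.8, tolerance = 1e-9)
  # rigid translation along z leaves it unchanged
  shifted <- traj
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 4.2
  expect_equal(hydrophobic_thickness(shifted)$mean, th$mean,
               tolerance = 1e-9)
  # the density-profile oracle agrees within a bin
  expect_lt(abs(thickness_histogram(traj) - th$mean), 1.0)
})

test_that("p2 reproduces its closed-form limits", {
  n <- 5000
  up <- cbind(0, 0, rep(1, n))
  expect_equal(p2(up), 1)
  flat <- cbind(rnorm(n), rnorm(n), 0)
  expect_equal(p2(flat), -0.5)
  # magic angle
  th <- 54.7356 * pi / 180
  v <- cbind(sin(th), 0, cos(th))
  expect_equal(p2(v), 0, tolerance = 1e-4)
  # isotropic vectors: 0 within Monte-Carlo error
  set.seed(1)
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi); r <- sqrt(1 - z^2)
  iso <- cbind(r * cos(phi), r * sin(phi), z)
  se <- sd(0.5 * (3 * z^2 - 1)) / sqrt(n)
  expect_lt(abs(p2(iso)), 3 * se)
  expect_error(p2(rbind(c(0, 0, 0))), "zero-length")
  # arbitrary normal direction honoured
  expect_equal(p2(cbind(1, 0, 0), normal = c(1, 0, 0)), 1)
})

test_that("p2_bond matches the closed form and the brute-force oracle", {
  tilts <- c(20, 35, 50)
  spec <- synthetic_spec(lipids_per_leaflet = 12, n_frames = 6,
                         bond_tilts_deg = tilts, seed = 4)
  traj <- gen_bilayer_trajectory(spec, FF)
  p2b <- p2_bond(traj)
  truth <- attr(traj, "truth")$p2b
  for (b in 1:3) {
    got <- p2b$p2[p2b$bond == names(truth)[b]]
    expect_equal(got, rep(truth[[b]], length(got)), tolerance = 1e-6)
  }
  # decreasing alignment down the chain
  pooled <- p2_bond(traj, by = character(0))
  expect_true(all(diff(pooled$p2) < 0))
  # naive double-loop oracle, exact agreement
  rows_pal <- which(lipid_index(traj)$kind == "pal")
  oracle <- oracle_p2_bond(traj, "c1", "c2", rows_pal)
  expect_equal(p2b$p2[p2b$bond == "c1-c2" & p2b$kind == "pal"], oracle,
               tolerance = 1e-12)
})

test_that("p2_tail is the fixed-tilt closed form and averages chains", {
  # straight vertical tails
  spec0 <- synthetic_spec(lipids_per_leaflet = 6, n_frames = 2,
                          bond_tilts_deg = c(0, 0, 0), D_cm2_s = 0)
  expect_equal(p2_tail(gen_bilayer_trajectory(spec0, FF))$p2, c(1, 1),
               tolerance = 1e-9)
  # uniform tilt theta*: P2t = (3 cos^2 - 1)/2 exactly
  th_star <- 27
  spec1 <- synthetic_spec(lipids_per_leaflet = 6, n_frames = 2,
                          bond_tilts_deg = rep(th_star, 3), D_cm2_s = 0)
  traj1 <- gen_bilayer_trajectory(spec1, FF)
  expect_equal(unique(round(p2_tail(traj1)$p2, 9)),
               round(0.5 * (3 * cos(th_star * pi / 180)^2 - 1), 9))
  # species average equals the mean of per-chain values
  p2t <- p2_tail(traj1)
  pooled <- p2_tail(traj1, by = "species")
  expect_equal(pooled$p2, mean(p2t$p2), tolerance = 1e-9)
})

test_that("order parameters are invariant under lateral moves and rotation", {
  spec <- synthetic_spec(lipids_per_leaflet = 8, n_frames = 4, seed = 6)
  traj <- gen_bilayer_trajectory(spec, FF)
  ref_b <- p2_bond(traj)$p2
  ref_t <- p2_tail(traj)$p2
  # rigid lateral translation (with rewrap)
  tr <- traj
  for (f in seq_len(n_frames(tr))) {
    tr$coords[, 1, f] <- (tr$coords[, 1, f] + 13.7) %% tr$box[f, 1]
    tr$coords[, 2, f] <- (tr$coords[, 2, f] + 5.1) %% tr$box[f, 2]
  }
  expect_equal(p2_bond(tr)$p2, ref_b, tolerance = 1e-9)
  expect_equal(area_per_lipid(tr)$mean, area_per_lipid(traj)$mean)
  expect_equal(hydrophobic_thickness(tr)$mean,
               hydrophobic_thickness(traj)$mean, tolerance = 1e-9)
  # rotation about the normal: P2 depends only on the polar angle.
  # rotate raw bond vectors rather than wrapped coordinates
  rot <- function(v, a) cbind(v[, 1] * cos(a) - v[, 2] * sin(a),
                              v[, 1] * sin(a) + v[, 2] * cos(a), v[, 3])
  lip <- lipid_index(traj)
  v <- cgbilayer:::bond_vectors(traj, lip$c1, lip$c4, seq_len(n_frames(traj)))
  expect_equal(p2(rot(v, 0.83)), p2(v), tolerance = 1e-12)
})

test_that("MSD is zero for static frames and after drift removal", {
  traj <- gen_brownian(10, 0, 1, 50, seed = 3)
  m <- msd_lateral(traj, group = "beads")
  expect_true(all(m$msd == 0))
  # uniform drift: all walkers move identically; COM removal cancels it
  drift <- traj
  for (f in 2:n_frames(drift))
    drift$coords[, 1, f] <- drift$coords[, 1, f] + 2.5 * (f - 1)
  md <- msd_lateral(drift, group = "beads", remove_drift = TRUE)
  expect_lt(max(md$msd), 1e-18)
  expect_error(msd_lateral(gen_brownian(5, 0, 1, 1)), "at least 2 frames")
})

test_that("MSD of a 2-D random walk has slope 4D and unwrapping works", {
  D <- 2.2e-7                       # cm^2/s = 2.2 A^2/ns
  traj <- gen_brownian(80, D, 1, 600, seed = 9, box_A = 40)  # forces wrapping
  m <- msd_lateral(traj, group = "beads", remove_drift = FALSE)
  fit <- fit_diffusion(m, eff_factor = 1)
  expect_equal(fit$D_cm2_s, D, tolerance = 0.05)
})

test_that("fit_diffusion is exact on a line and scales with effective time", {
  t <- 0:100
  D0 <- 3.1                         # A^2/ns slope units
  curve <- list(lag_ns = t, msd = 4 * D0 * t, eff_factor = 1)
  fit <- fit_diffusion(curve)
  expect_equal(fit$D_cm2_s, D0 * 1e-7, tolerance = 1e-12)
  # doubling the effective-time factor halves D
  fit2 <- fit_diffusion(curve, eff_factor = 2)
  expect_equal(fit2$D_cm2_s, fit$D_cm2_s / 2, tolerance = 1e-12)
  # negative slope: warning and D = 0
  bad <- list(lag_ns = t, msd = -0.1 * t, eff_factor = 1)
  expect_warning(f0 <- fit_diffusion(bad), "negative")
  expect_equal(f0$D_cm2_s, 0)
  expect_error(fit_diffusion(list(lag_ns = 0:3, msd = 0:3, eff_factor = 1)),
               "fewer than 10")
})

test_that("leaflet assignment from head-bead z is stable across frames", {
  spec <- synthetic_spec(lipids_per_leaflet = 10, n_frames = 8, seed = 12)
  traj <- gen_bilayer_trajectory(spec, FF)
  lip <- lipid_index(traj)
  lip$leaflet <- NA_character_        # force recomputation
  lf1 <- cgbilayer:::leaflet_of(traj, lip)
  expect_identical(unname(lf1), unname(lipid_index(traj)$leaflet))
  expect_equal(sum(lf1 == "upper"), sum(lf1 == "lower"))
})
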