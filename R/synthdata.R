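#' Specification for a synthetic bilayer trajectory
#'
#' Defines the ground truth a generated trajectory must carry: geometry
#' (area per lipid, C1-plane separation), per-bond tail tilt angles (which
#' fix the order parameters in closed form) and the lateral diffusion
#' coefficient of the rigid 2-D Brownian lipid motion. The defaults mirror
#' the fluid POPC reference state: 58 lipids per monolayer, APL 67 A^2,
#' hydrophobic thickness 14.8 A, D = 2.2e-7 cm^2/s, frames 1 effective ns
#' apart.
#'
#' @param lipids_per_leaflet lipids per monolayer
#' @param n_frames frames in the trajectory
#' @param dt_eff_ns frame interval in effective ns
#' @param apl_A2 target area per lipid
#' @param thickness_A distance between the upper and lower C1 planes
#' @param bond_tilts_deg length-3 polar tilt of the c1-c2, c2-c3, c3-c4
#'   bond vectors from the bilayer normal; each bond's P2 is then exactly
#'   `(3 cos^2 theta - 1)/2`
#' @param D_cm2_s lateral diffusion coefficient of each lipid (effective
#'   time scale)
#' @param species pseudo-lipid species label; 13-bead topologies for the
#'   ISUCA-derived species, 12 for POPC
#' @param box_height_A box length along the normal
#' @param eff_factor effective-time factor recorded on the trajectory
#' @param seed integer; fixes the output exactly
#' @return object of class `cg_synth_spec`
#' @export
synthetic_spec <- function(lipids_per_leaflet = 58, n_frames = 200,
                           dt_eff_ns = 1, apl_A2 = 67,
                           thickness_A = 14.8,
                           bond_tilts_deg = c(20, 35, 50),
                           D_cm2_s = 2.2e-7, species = "POPC",
                           box_height_A = 90, eff_factor = 4, seed = 1L) {
  stopifnot(lipids_per_leaflet >= 1, n_frames >= 1, dt_eff_ns > 0,
            apl_A2 > 0, thickness_A > 0, length(bond_tilts_deg) == 3,
            all(bond_tilts_deg >= 0), all(bond_tilts_deg < 90),
            D_cm2_s >= 0, eff_factor > 0)
  if (thickness_A >= box_height_A)
    stop("thickness target exceeds the box height")
  structure(list(lipids_per_leaflet = lipids_per_leaflet,
                 n_frames = n_frames, dt_eff_ns = dt_eff_ns,
                 apl_A2 = apl_A2, thickness_A = thickness_A,
                 bond_tilts_deg = bond_tilts_deg, D_cm2_s = D_cm2_s,
                 species = species, box_height_A = box_height_A,
                 eff_factor = eff_factor, seed = as.integer(seed)),
            class = "cg_synth_spec")
}

# closed-form truth for the spec's tilt geometry
synth_truth <- function(spec) {
  th <- spec$bond_tilts_deg * pi / 180
  p2_of <- function(ct2) 0.5 * (3 * ct2 - 1)
  p2b <- p2_of(cos(th)^2)
  names(p2b) <- c("c1-c2", "c2-c3", "c3-c4")
  # chain bonds are coplanar (shared azimuth), so the C1->C4 vector has
  # z = sum cos(theta_b), lateral = sum sin(theta_b)
  vz <- sum(cos(th)); vl <- sum(sin(th))
  p2t <- p2_of(vz^2 / (vz^2 + vl^2))
  list(p2b = p2b, p2t = p2t, apl_A2 = spec$apl_A2,
       thickness_A = spec$thickness_A, D_cm2_s = spec$D_cm2_s)
}

#' Generate a synthetic bilayer trajectory with known metrics
#'
#' Builds two leaflets of rigid pseudo-lipids whose tail bonds make fixed
#' polar angles with the bilayer normal (azimuth drawn uniformly per chain,
#' so tilted tails have no preferred lateral direction), C1 beads pinned to
#' planes at +/- thickness/2 about the box midplane, and lateral positions
#' performing independent 2-D Brownian motion with the requested D. The box
#' area equals APL x lipids-per-leaflet, so every analysis metric has a
#' known target; the closed-form values ride along as the `truth` attribute.
#' Coordinates are wrapped into the box exactly as engine output would be.
#'
#' @param spec a [synthetic_spec()]
#' @param ff force field supplying the pseudo-lipid topology
#' @return a `cg_trajectory` with attribute `truth` (list: `p2b`, `p2t`,
#'   `apl_A2`, `thickness_A`, `D_cm2_s`)
#' @export
gen_bilayer_trajectory <- function(spec, ff = load_forcefield()) {
  stopifnot(inherits(spec, "cg_synth_spec"))
  set.seed(spec$seed)
  npl <- spec$lipids_per_leaflet
  L <- sqrt(spec$apl_A2 * npl)
  box <- c(L, L, spec$box_height_A)
  topo <- lipid_topology(spec$species, FALSE, ff)
  nb <- nrow(topo$beads)
  zc <- box[3] / 2
  th <- spec$bond_tilts_deg * pi / 180
  blen <- 4.7                                # A, CG bond length

  sys <- empty_system(box)
  nx <- ceiling(sqrt(npl))
  spacing <- L / nx
  for (leaflet in c("upper", "lower")) {
    sgn <- if (leaflet == "upper") 1 else -1
    for (q in seq_len(npl)) {
      cx <- ((q - 1) %% nx + 0.5) * spacing
      cy <- ((q - 1) %/% nx + 0.5) * spacing
      xyz <- matrix(0, nb, 3)
      for (chain in c("A", "B")) {
        tb <- topo$tails[[chain]]$beads
        phi <- runif(1, 0, 2 * pi)           # shared azimuth: coplanar chain
        p <- c(0, 0, sgn * spec$thickness_A / 2)   # C1 on its plane
        xyz[tb[1], ] <- p
        for (b in 1:3) {
          step <- blen * c(sin(th[b]) * cos(phi), sin(th[b]) * sin(phi),
                           -sgn * cos(th[b]))
          p <- p + step
          xyz[tb[b + 1], ] <- p
        }
        xyz[tb, 1] <- xyz[tb, 1] + if (chain == "A") -1.5 else 1.5
      }
      others <- setdiff(seq_len(nb), c(topo$tails$A$beads, topo$tails$B$beads))
      zbase <- sgn * (spec$thickness_A / 2 + blen)
      xyz[others, 3] <- zbase + sgn * seq_along(others)
      xyz[, 1] <- xyz[, 1] + cx
      xyz[, 2] <- xyz[, 2] + cy
      xyz[, 3] <- xyz[, 3] + zc
      sys <- append_molecule(sys, xyz, topo, spec$species, "lipid", leaflet)
    }
  }

  nf <- spec$n_frames
  nmol <- 2 * npl
  # per-axis Brownian steps on the effective time scale
  sig_step <- sqrt(2 * (spec$D_cm2_s / .A2_PER_NS_TO_CM2_PER_S) * spec$dt_eff_ns)
  disp <- array(rnorm(nmol * 2 * (nf - 1), sd = sig_step),
                c(nmol, 2, max(nf - 1, 0)))
  arr <- array(NA_real_, c(nrow(sys$xyz), 3, nf))
  frame <- sys$xyz
  arr[, , 1] <- wrap_coords(frame, box)
  if (nf > 1) for (f in 2:nf) {
    frame[, 1] <- frame[, 1] + disp[sys$molecule, 1, f - 1]
    frame[, 2] <- frame[, 2] + disp[sys$molecule, 2, f - 1]
    arr[, , f] <- wrap_coords(frame, box)
  }

  t_actual <- (seq_len(nf) - 1) * spec$dt_eff_ns / spec$eff_factor
  traj <- new_trajectory(arr, matrix(box, nf, 3, byrow = TRUE),
                         time_ns = t_actual, eff_factor = spec$eff_factor,
                         meta = list(type = sys$type,
                                     bead_label = sys$bead_label,
                                     molecule = sys$molecule,
                                     molecules = sys$molecules,
                                     topologies = sys$topologies),
                         source = "synthetic")
  attr(traj, "truth") <- synth_truth(spec)
  traj
}

#' Generate independent 2-D Brownian walkers
#'
#' Single-bead walkers with Gaussian steps of per-axis variance `2 D dt`,
#' the direct test bed for the Einstein relation MSD = 4 D t. `D = 0`
#' yields static walkers. Times are on the same scale as `dt_ns`
#' (`eff_factor = 1`), so the fitted D comes back on that scale.
#'
#' @param n_walkers number of walkers
#' @param D_cm2_s diffusion coefficient (negative is an error)
#' @param dt_ns frame interval, ns
#' @param n_frames number of frames
#' @param seed integer; same seed, same paths
#' @param box_A periodic box edge used for wrapping (large by default)
#' @return a `cg_trajectory` of one-bead molecules (kind "walker")
#' @export
gen_brownian <- function(n_walkers, D_cm2_s, dt_ns, n_frames, seed = 1L,
                         box_A = 1e4) {
  if (D_cm2_s < 0) stop("negative diffusion coefficient")
  set.seed(seed)
  sig <- sqrt(2 * (D_cm2_s / .A2_PER_NS_TO_CM2_PER_S) * dt_ns)
  x0 <- matrix(runif(n_walkers * 2, 0, box_A), n_walkers, 2)
  arr <- array(0, c(n_walkers, 3, n_frames))
  arr[, 1:2, 1] <- x0
  if (n_frames > 1) for (f in 2:n_frames) {
    arr[, 1:2, f] <- arr[, 1:2, f - 1] +
      matrix(rnorm(n_walkers * 2, sd = sig), n_walkers, 2)
    arr[, 3, f] <- 0
  }
  arr[, 1, ] <- arr[, 1, ] %% box_A
  arr[, 2, ] <- arr[, 2, ] %% box_A
  box <- c(box_A, box_A, box_A)
  meta <- list(type = rep("P4", n_walkers),
               bead_label = rep("W", n_walkers),
               molecule = seq_len(n_walkers),
               molecules = data.frame(id = seq_len(n_walkers),
                                      species = "walker",
                                      leaflet = NA_character_,
                                      kind = "walker", protonated = FALSE,
                                      stringsAsFactors = FALSE),
               topologies = list())
  new_trajectory(arr, matrix(box, n_frames, 3, byrow = TRUE),
                 time_ns = (seq_len(n_frames) - 1) * dt_ns,
                 eff_factor = 1, meta = meta, source = "synthetic")
}
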