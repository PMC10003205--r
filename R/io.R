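#' Write coordinates in GRO format
#'
#' One frame, fixed-format GRO (positions in nm in the file; the system
#' stores angstroms). Molecule index and bead label map to the residue and
#' atom fields.
#' @param system a `cg_system`
#' @param file output path
#' @param title header line
#' @export
write_gro <- function(system, file, title = "cgbilayer system") {
  n <- nrow(system$xyz)
  res <- system$molecule %% 100000L
  resnm <- substr(system$molecules$species[system$molecule], 1, 5)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res, resnm, substr(system$bead_label, 1, 5),
                     seq_len(n) %% 100000L,
                     system$xyz[, 1] * .A2NM, system$xyz[, 2] * .A2NM,
                     system$xyz[, 3] * .A2NM),
             sprintf("%10.5f%10.5f%10.5f", system$box[1] * .A2NM,
                     system$box[2] * .A2NM, system$box[3] * .A2NM))
  writeLines(lines, file)
  invisible(file)
}

#' Read a GRO coordinate file
#' @param file path
#' @return list: `xyz` (A), `box` (A), `bead_label`, `molecule`, `resname`
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  xyz <- cbind(as.numeric(substr(body, 21, 28)),
               as.numeric(substr(body, 29, 36)),
               as.numeric(substr(body, 37, 44))) * .NM2A
  boxl <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]][1:3]) * .NM2A
  list(xyz = xyz, box = boxl,
       bead_label = trimws(substr(body, 11, 15)),
       molecule = as.integer(substr(body, 1, 5)),
       resname = trimws(substr(body, 6, 10)))
}

#' Write coordinates in PDB format
#'
#' Thin wrapper over [bio3d::write.pdb()].
#' @param system a `cg_system`
#' @param file output path
#' @export
write_pdb <- function(system, file) {
  n <- nrow(system$xyz)
  bio3d::write.pdb(file = file, xyz = as.vector(t(system$xyz)),
                   type = rep("ATOM", n),
                   resno = system$molecule %% 10000L,
                   resid = substr(system$molecules$species[system$molecule], 1, 3),
                   eleno = seq_len(n) %% 100000L,
                   elety = substr(system$bead_label, 1, 4),
                   chain = rep("A", n))
  invisible(file)
}

#' Write a system (coordinates + metadata) to a directory
#'
#' Text formats only: `system.gro` carries the frame, `system.yaml` the
#' bookkeeping (types, charges, masses, molecule table, topologies), so
#' a system round-trips exactly through [read_system()].
#' @param system a `cg_system`
#' @param dir output directory (created)
#' @export
write_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gro(system, file.path(dir, "system.gro"))
  meta <- list(type = system$type, charge = system$charge,
               mass = system$mass, molecule = system$molecule,
               bead_label = system$bead_label,
               molecules = lapply(seq_len(nrow(system$molecules)), function(i)
                 as.list(system$molecules[i, ])),
               box = system$box,
               vel = if (!is.null(system$vel) && any(system$vel != 0))
                 as.vector(system$vel) else NULL,
               topologies = lapply(system$topologies, topology_to_yaml))
  writeLines(yaml::as.yaml(meta, precision = 15),
             file.path(dir, "system.yaml"))
  invisible(dir)
}

#' @rdname write_system
#' @param dir directory written by [write_system()]
#' @export
read_system <- function(dir) {
  g <- read_gro(file.path(dir, "system.gro"))
  meta <- yaml::read_yaml(file.path(dir, "system.yaml"))
  mols <- do.call(rbind, lapply(meta$molecules, function(m)
    data.frame(m, stringsAsFactors = FALSE)))
  n <- length(meta$type)
  sys <- structure(list(
    xyz = g$xyz,
    vel = if (!is.null(meta$vel)) matrix(meta$vel, n, 3) else matrix(0, n, 3),
    type = meta$type, charge = as.numeric(meta$charge),
    mass = as.numeric(meta$mass), molecule = as.integer(meta$molecule),
    bead_label = meta$bead_label, molecules = mols,
    box = as.numeric(meta$box),
    topologies = lapply(meta$topologies, topology_from_yaml)
  ), class = "cg_system")
  sys
}

#' Write a trajectory as plain text
#'
#' Multi-frame coordinate file (`.trj`) plus a CSV sidecar of per-frame
#' time and box. Use [write_system()] alongside so [read_trajectory()] can
#' restore the metadata analyses need.
#' @param traj a `cg_trajectory`
#' @param file output path for the frame data
#' @param sidecar output path for the time/box CSV (default: `file` with
#'   `.times.csv` appended)
#' @param digits coordinate precision
#' @export
write_trj <- function(traj, file, sidecar = paste0(file, ".times.csv"),
                      digits = 4) {
  nf <- n_frames(traj)
  n <- dim(traj$coords)[1]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# cgbilayer text trajectory",
               sprintf("# beads %d frames %d eff_factor %.8g",
                       n, nf, traj$eff_factor)), con)
  fmt <- paste0("%.", digits, "f")
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %.9g %.6f %.6f %.6f", traj$time_ns[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    m <- traj$coords[, , f]
    writeLines(paste(sprintf(fmt, m[, 1]), sprintf(fmt, m[, 2]),
                     sprintf(fmt, m[, 3])), con)
  }
  side <- data.frame(frame = seq_len(nf), time_ns = traj$time_ns,
                     time_eff_ns = time_effective(traj),
                     Lx = traj$box[, 1], Ly = traj$box[, 2],
                     Lz = traj$box[, 3])
  write.csv(side, sidecar, row.names = FALSE)
  invisible(file)
}

#' Read a text trajectory plus its system metadata
#' @param dir directory holding `traj.trj` and the [write_system()] files
#' @return a `cg_trajectory`
#' @export
read_trajectory <- function(dir) {
  tf <- file.path(dir, "traj.trj")
  if (!file.exists(tf)) stop("no trajectory found in ", dir)
  sys <- read_system(dir)
  lines <- readLines(tf)
  hdr <- strsplit(lines[2], "\\s+")[[1]]
  n <- as.integer(hdr[3]); nf <- as.integer(hdr[5])
  eff <- as.numeric(hdr[7])
  arr <- array(NA_real_, c(n, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  times <- numeric(nf)
  pos <- 3L
  for (f in seq_len(nf)) {
    h <- strsplit(lines[pos], "\\s+")[[1]]
    times[f] <- as.numeric(h[2])
    box[f, ] <- as.numeric(h[3:5])
    block <- lines[(pos + 1):(pos + n)]
    arr[, , f] <- matrix(scan(text = block, quiet = TRUE), n, 3, byrow = TRUE)
    pos <- pos + n + 1L
  }
  new_trajectory(arr, box, times, eff,
                 meta = list(type = sys$type, bead_label = sys$bead_label,
                             molecule = sys$molecule,
                             molecules = sys$molecules,
                             topologies = sys$topologies),
                 source = "file")
}

#' Full metrics report for a trajectory
#'
#' Runs the four characterisation metrics: area per lipid, hydrophobic
#' thickness, order parameters P2b/P2t per species and chain kind, and the
#' lateral diffusion coefficient from the MSD fit.
#' @param traj a `cg_trajectory`
#' @param msd_window diffusion fit window (fractions of the maximal lag)
#' @return object of class `cg_metrics`
#' @export
metrics_report <- function(traj, msd_window = c(0.1, 0.5)) {
  apl <- area_per_lipid(traj)
  th <- hydrophobic_thickness(traj)
  p2b <- p2_bond(traj)
  p2t <- p2_tail(traj)
  msd <- msd_lateral(traj)
  dfit <- tryCatch(fit_diffusion(msd, window = msd_window),
                   error = function(e) NULL)
  structure(list(apl = apl, thickness = th, p2b = p2b, p2t = p2t,
                 msd = msd, diffusion = dfit),
            class = "cg_metrics")
}

#' @export
print.cg_metrics <- function(x, ...) {
  cat("== bilayer metrics ==\n")
  print(x$apl)
  print(x$thickness)
  cat("P2b per bond and chain kind:\n")
  print(x$p2b, row.names = FALSE, digits = 3)
  cat("P2t per chain kind:\n")
  print(x$p2t, row.names = FALSE, digits = 3)
  if (!is.null(x$diffusion)) print(x$diffusion)
  invisible(x)
}

#' @export
summary.cg_metrics <- function(object, ...) {
  data.frame(
    metric = c("APL_A2", "thickness_A", "P2t_mean",
               "D_cm2_s"),
    value = c(object$apl$mean, object$thickness$mean,
              mean(object$p2t$p2),
              if (!is.null(object$diffusion)) object$diffusion$D_cm2_s else NA),
    sd = c(object$apl$sd, object$thickness$sd, NA,
           if (!is.null(object$diffusion)) object$diffusion$se_cm2_s else NA))
}

#' Write a metrics report as CSV and JSON
#' @param metrics a `cg_metrics`
#' @param dir output directory
#' @export
write_metrics <- function(metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(summary(metrics), file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(metrics$p2b, file.path(dir, "p2_bond.csv"), row.names = FALSE)
  write.csv(metrics$p2t, file.path(dir, "p2_tail.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    apl_A2 = list(mean = metrics$apl$mean, sd = metrics$apl$sd),
    thickness_A = list(mean = metrics$thickness$mean, sd = metrics$thickness$sd),
    p2b = metrics$p2b, p2t = metrics$p2t,
    D_cm2_s = if (!is.null(metrics$diffusion)) metrics$diffusion$D_cm2_s else NULL,
    msd_fit_window_eff_ns = if (!is.null(metrics$diffusion))
      metrics$diffusion$window_ns else NULL),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Bar chart of order parameters
#'
#' P2b per bond (grouped by chain kind) with P2t alongside, the standard
#' way these order parameters are compared across systems.
#' @param metrics a `cg_metrics`
#' @param main plot title
#' @export
plot_p2 <- function(metrics, main = "order parameters") {
  p2b <- metrics$p2b
  kinds <- unique(p2b$kind)
  bonds <- unique(p2b$bond)
  m <- sapply(kinds, function(k) p2b$p2[match(paste(bonds, k),
                                              paste(p2b$bond, p2b$kind))])
  m <- matrix(m, nrow = length(bonds),
              dimnames = list(bonds, kinds))
  graphics::barplot(t(m), beside = TRUE, ylim = c(-0.5, 1),
                    legend.text = kinds, main = main, ylab = "P2")
  graphics::abline(h = 0, lty = 3)
  invisible(metrics)
}
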