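#' Construct a trajectory object
#'
#' Frame sequence with per-frame periodic boxes and actual times, plus the
#' effective-time convention of coarse-grained dynamics: effective time =
#' actual time x `eff_factor` (4 by default), compensating for the smoothed
#' CG energy landscape. All analysis operations accept this class whether
#' the frames came from the engine or from the synthetic generator.
#'
#' @param coords numeric array `[n_beads, 3, n_frames]`, angstroms
#' @param box numeric matrix `[n_frames, 3]`, angstroms
#' @param time_ns numeric, strictly increasing actual times (ns)
#' @param eff_factor effective-time factor (> 0)
#' @param meta list with per-bead `type`, `bead_label`, `molecule`, the
#'   molecule table `molecules` (id, species, leaflet, kind, protonated) and
#'   `topologies` (named by species key); the synthetic generator fills the
#'   same fields
#' @param source "engine" or "synthetic"
#' @return object of class `cg_trajectory`
#' @export
new_trajectory <- function(coords, box, time_ns, eff_factor = 4,
                           meta = list(), source = "engine") {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  stopifnot(nrow(box) == nf, length(time_ns) == nf)
  if (nf > 1 && any(diff(time_ns) <= 0))
    stop("frame times must be strictly increasing")
  if (eff_factor <= 0) stop("eff_factor must be positive")
  structure(list(coords = coords, box = box, time_ns = time_ns,
                 eff_factor = eff_factor, meta = meta, source = source),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat("<cg_trajectory>", dim(x$coords)[1], "beads,", nf, "frames,",
      sprintf("t = %.4g..%.4g ns (x%g effective => %.4g ns), source: %s\n",
              x$time_ns[1], x$time_ns[nf], x$eff_factor,
              x$time_ns[nf] * x$eff_factor, x$source))
  invisible(x)
}

#' @rdname new_trajectory
#' @param traj a `cg_trajectory`
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Effective frame times (actual time x effective-time factor), ns
#' @param traj a `cg_trajectory`
#' @export
time_effective <- function(traj) traj$time_ns * traj$eff_factor

#' Build a trajectory from a system plus a list of coordinate frames
#'
#' Convenience for tests and for wrapping engine output: metadata is taken
#' from the system.
#' @param system a `cg_system`
#' @param frames list of `[n, 3]` coordinate matrices (A)
#' @param box per-frame box matrix or single box vector
#' @param time_ns frame times (actual ns)
#' @param eff_factor effective-time factor
#' @export
trajectory_from_frames <- function(system, frames, box = system$box,
                                   time_ns = seq_along(frames) - 1,
                                   eff_factor = 4) {
  n <- nrow(system$xyz)
  arr <- array(NA_real_, c(n, 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  new_trajectory(arr, box, time_ns, eff_factor,
                 meta = list(type = system$type, bead_label = system$bead_label,
                             molecule = system$molecule,
                             molecules = system$molecules,
                             topologies = system$topologies),
                 source = "engine")
}

#' Per-lipid tail/head bead index table
#'
#' Flattens trajectory (or system) metadata into one row per lipid chain:
#' molecule id, species, leaflet, chain (A/B), chain kind (pal/ol) and the
#' absolute bead indices of C1..C4. Used by the thickness and order-parameter
#' analyses.
#' @param x a `cg_trajectory` or `cg_system`
#' @return data.frame with columns molecule, species, protonated, leaflet,
#'   chain, kind, c1..c4, head (list-free: head bead indices collapse to the
#'   first head bead)
#' @export
lipid_index <- function(x) {
  meta <- if (inherits(x, "cg_trajectory")) x$meta else
    list(type = x$type, bead_label = x$bead_label, molecule = x$molecule,
         molecules = x$molecules, topologies = x$topologies)
  mols <- meta$molecules
  lip <- mols[mols$kind == "lipid", , drop = FALSE]
  if (!nrow(lip)) stop("no lipids in trajectory metadata")
  rows <- vector("list", 2L * nrow(lip))
  r <- 0L
  for (q in seq_len(nrow(lip))) {
    id <- lip$id[q]
    beads <- which(meta$molecule == id)
    topo <- meta$topologies[[topo_key(lip$species[q], lip$protonated[q])]]
    if (is.null(topo)) stop("missing topology for ", lip$species[q])
    for (chain in c("A", "B")) {
      tl <- topo$tails[[chain]]
      r <- r + 1L
      rows[[r]] <- data.frame(
        molecule = id, species = lip$species[q], protonated = lip$protonated[q],
        leaflet = lip$leaflet[q], chain = chain, kind = tl$kind,
        c1 = beads[tl$beads[1]], c2 = beads[tl$beads[2]],
        c3 = beads[tl$beads[3]], c4 = beads[tl$beads[4]],
        head = beads[topo$head_beads[1]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Resolve periodic jumps frame-to-frame (nearest-image continuity)
#'
#' Returns coordinates unwrapped along each axis by adding the box-length
#' multiple that makes every bead's displacement between consecutive frames
#' smaller than half a box length. Requires a frame interval short enough
#' that no bead moves further than that between frames.
#' @param traj a `cg_trajectory`
#' @return array like `traj$coords`, unwrapped
#' @export
unwrap_coords <- function(traj) {
  arr <- traj$coords
  nf <- dim(arr)[3]
  if (nf < 2) return(arr)
  for (f in 2:nf) {
    L <- traj$box[f, ]
    for (d in 1:3) {
      dx <- arr[, d, f] - arr[, d, f - 1]
      arr[, d, f] <- arr[, d, f] - round(dx / L[d]) * L[d]
    }
  }
  arr
}
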