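#' Bilayer composition
#'
#' Per-leaflet lipid counts plus solvent/counterion bookkeeping. The studied
#' systems all contain 116 lipids (58 per monolayer) and 1840 water beads
#' of which 30% are antifreeze particles; mixtures are mirror-symmetric
#' across leaflets.
#'
#' @param counts named integer vector, species -> lipids per leaflet
#' @param protonated named logical (or single flag) marking which species are
#'   protonated
#' @param n_water total solvent bead count (water + antifreeze)
#' @param antifreeze_fraction fraction of solvent beads typed antifreeze,
#'   in `[0, 1]`
#' @return object of class `cg_composition`
#' @export
composition <- function(counts, protonated = FALSE, n_water = 1840,
                        antifreeze_fraction = 0.30) {
  counts <- setNames(as.integer(counts), names(counts))
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by species")
  if (any(counts < 0) || sum(counts) == 0) stop("invalid lipid counts")
  if (antifreeze_fraction < 0 || antifreeze_fraction > 1)
    stop("antifreeze_fraction must be in [0, 1]")
  if (length(protonated) == 1L) protonated <- setNames(rep(protonated, length(counts)),
                                                       names(counts))
  structure(list(counts = counts, protonated = protonated[names(counts)],
                 n_water = as.integer(n_water),
                 antifreeze_fraction = antifreeze_fraction),
            class = "cg_composition")
}

#' @export
print.cg_composition <- function(x, ...) {
  cat("<cg_composition>", sum(x$counts) * 2L, "lipids (",
      paste(sprintf("%s:%d/leaflet%s", names(x$counts), x$counts,
                    ifelse(x$protonated, "+", "")), collapse = ", "),
      "),", x$n_water, "solvent beads,",
      sprintf("%.0f%% antifreeze", 100 * x$antifreeze_fraction), "\n")
  invisible(x)
}

empty_system <- function(box) {
  structure(list(
    xyz = matrix(numeric(0), 0, 3),
    vel = matrix(numeric(0), 0, 3),
    type = character(0), charge = numeric(0), mass = numeric(0),
    molecule = integer(0), bead_label = character(0),
    molecules = data.frame(id = integer(0), species = character(0),
                           leaflet = character(0), kind = character(0),
                           protonated = logical(0), stringsAsFactors = FALSE),
    box = as.numeric(box),
    topologies = list()
  ), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  nl <- sum(x$molecules$kind == "lipid")
  cat("<cg_system>", nrow(x$xyz), "beads,", nl, "lipids,",
      sum(x$molecules$kind %in% c("water", "antifreeze")), "solvent,",
      sum(x$molecules$kind == "ion"), "ions; box",
      paste(sprintf("%.1f", x$box), collapse = " x "), "A; net charge",
      net_charge(x), "\n")
  invisible(x)
}

n_beads <- function(system) nrow(system$xyz)

topo_key <- function(species, protonated) {
  paste0(species, if (protonated) "+" else "")
}

append_molecule <- function(system, xyz, topo_or_beads, species, kind,
                            leaflet = NA_character_, protonated = FALSE) {
  id <- nrow(system$molecules) + 1L
  if (inherits(topo_or_beads, "cg_topology")) {
    bd <- topo_or_beads$beads
    key <- topo_key(species, protonated)
    if (is.null(system$topologies[[key]])) system$topologies[[key]] <- topo_or_beads
  } else bd <- topo_or_beads
  system$xyz <- rbind(system$xyz, xyz)
  system$vel <- rbind(system$vel, matrix(0, nrow(bd), 3))
  system$type <- c(system$type, bd$type)
  system$charge <- c(system$charge, bd$charge)
  system$mass <- c(system$mass, bd$mass)
  system$molecule <- c(system$molecule, rep(id, nrow(bd)))
  system$bead_label <- c(system$bead_label, bd$name)
  system$molecules <- rbind(system$molecules,
    data.frame(id = id, species = species, leaflet = leaflet, kind = kind,
               protonated = protonated, stringsAsFactors = FALSE))
  system
}

# straight-chain starting conformation for one lipid, bilayer midplane at z = 0;
# leaflet +1 places tails pointing down toward the midplane.
lipid_start_coords <- function(topo, leaflet_sign, spacing_A = 4.7) {
  nb <- nrow(topo$beads)
  z <- numeric(nb)
  for (chain in c("A", "B")) {
    tb <- topo$tails[[chain]]$beads
    # C4 closest to midplane, C1 outermost tail bead
    z[tb] <- (4:1) * spacing_A - spacing_A / 2
  }
  gl <- setdiff(seq_len(nb), c(topo$tails$A$beads, topo$tails$B$beads,
                               topo$head_beads))
  z[gl] <- 4 * spacing_A + spacing_A / 2 + seq_along(gl) * 0.5
  hb <- topo$head_beads
  z[hb] <- max(z[gl]) + seq_along(hb) * 3.0
  x <- rep(0, nb); y <- rep(0, nb)
  # splay the two chains slightly so bonded beads do not overlap laterally
  x[topo$tails$A$beads] <- -1.6
  x[topo$tails$B$beads] <- 1.6
  if (length(hb) == 3) {  # imidazole ring: small triangle
    x[hb] <- c(-1.2, 1.2, 0)
    z[hb[3]] <- z[hb[3]] + 2.0
  }
  cbind(x, y, leaflet_sign * z)
}

#' Assemble an initial bilayer
#'
#' Places lipids on a jittered square lattice, one lattice per leaflet, with
#' tails pointing inward and headgroups outward, species shuffled within each
#' leaflet by `seed`. Leaflet compositions are mirror-symmetric. The bilayer
#' midplane sits at half the box height; coordinates are wrapped into the box.
#'
#' @param comp a [composition()]
#' @param box numeric length-3, box lengths in angstroms
#' @param seed integer; fixes species placement and jitter exactly
#' @param ff force field (topologies are drawn from its species registry)
#' @param min_spacing_A smallest acceptable lattice spacing (A); a lateral
#'   box too small to host the leaflet at this spacing is an error
#' @return a `cg_system` (lipids only; see [solvate()], [add_counterions()])
#' @export
build_bilayer <- function(comp, box, seed = 1L, ff = load_forcefield(),
                          min_spacing_A = 6.0) {
  stopifnot(inherits(comp, "cg_composition"), length(box) == 3, all(box > 0))
  npl <- sum(comp$counts)
  nx <- ceiling(sqrt(npl))
  spacing <- box[1] / nx
  if (spacing < min_spacing_A)
    stop(sprintf(
      "lateral box too small: %d lipids/leaflet need spacing >= %.1f A, got %.2f A",
      npl, min_spacing_A, spacing))

  set.seed(seed)
  sys <- empty_system(box)
  zc <- box[3] / 2
  species_vec <- rep(names(comp$counts), comp$counts)
  prot_vec <- rep(comp$protonated, comp$counts)
  topos <- lapply(seq_along(species_vec), function(i)
    lipid_topology(species_vec[i], prot_vec[i], ff))
  names(topos) <- NULL

  for (leaflet in c("upper", "lower")) {
    sgn <- if (leaflet == "upper") 1 else -1
    ord <- sample.int(npl)            # species shuffle within the leaflet
    sites <- sample.int(nx * nx, npl) # which lattice sites are occupied
    for (q in seq_len(npl)) {
      m <- ord[q]
      s <- sites[q] - 1L
      cx <- (s %% nx + 0.5) * spacing + runif(1, -0.08, 0.08) * spacing
      cy <- (s %/% nx + 0.5) * spacing + runif(1, -0.08, 0.08) * spacing
      xyz <- lipid_start_coords(topos[[m]], sgn)
      xyz[, 1] <- xyz[, 1] + cx
      xyz[, 2] <- xyz[, 2] + cy
      xyz[, 3] <- xyz[, 3] + zc
      sys <- append_molecule(sys, xyz, topos[[m]], species_vec[m], "lipid",
                             leaflet, prot_vec[m])
    }
  }
  up <- table(sys$molecules$species[sys$molecules$leaflet == "upper"])
  lo <- table(sys$molecules$species[sys$molecules$leaflet == "lower"])
  if (!identical(up, lo)) stop("leaflet compositions differ")  # cannot happen
  sys$xyz <- wrap_coords(sys$xyz, sys$box)
  sys$comp <- comp
  sys
}

wrap_coords <- function(xyz, box) {
  for (d in 1:3) xyz[, d] <- xyz[, d] %% box[d]
  xyz
}

solvent_bead_row <- function(type, ff, name = type) {
  data.frame(name = name, type = type,
             charge = ff$type_info[type, "charge"],
             mass = ff$type_info[type, "mass"], stringsAsFactors = FALSE)
}

#' Add CG solvent
#'
#' Fills the slabs above and below the bilayer with solvent beads on a cubic
#' grid (grid pitch close to the liquid CG water spacing, ~5 A), then types
#' `round(antifreeze_fraction * n)` of them, chosen uniformly at random, as
#' antifreeze particles. Each CG water bead stands for four real water
#' molecules; the antifreeze beads counteract the CG water model's elevated
#' freezing point.
#'
#' @param system a `cg_system` containing the bilayer
#' @param n_water total solvent beads to place
#' @param antifreeze_fraction fraction typed antifreeze (of the total)
#' @param seed integer
#' @param ff force field
#' @param clearance_A gap kept between solvent and the outermost lipid bead
#' @return the system with solvent appended
#' @export
solvate <- function(system, n_water = 1840, antifreeze_fraction = 0.30,
                    seed = 1L, ff = load_forcefield(), clearance_A = 2.0) {
  stopifnot(inherits(system, "cg_system"))
  set.seed(seed + 1L)
  box <- system$box
  lip <- system$molecule %in% system$molecules$id[system$molecules$kind == "lipid"]
  zc <- box[3] / 2
  zrel <- (system$xyz[lip, 3] - zc + box[3] / 2) %% box[3] - box[3] / 2  # centred
  zhi <- max(zrel) + clearance_A
  zlo <- min(zrel) - clearance_A
  h_top <- box[3] / 2 - zhi
  h_bot <- zlo + box[3] / 2
  vol <- box[1] * box[2] * (h_top + h_bot)
  if (vol < n_water * 40)   # ~(3.4 A)^3 per CG bead: hard packing floor
    stop("insufficient solvent volume for ", n_water, " beads")
  # grid pitch adapted to the requested count, capped at liquid spacing
  pitch <- min(5.0, (vol / n_water)^(1 / 3))
  gx <- ceiling(box[1] / pitch); gy <- ceiling(box[2] / pitch)
  nz <- ceiling(n_water / (gx * gy))
  if (nz * 3.2 > h_top + h_bot)
    stop("insufficient solvent volume for ", n_water, " beads")
  nz_top <- max(1L, round(nz * h_top / (h_top + h_bot)))
  nz_bot <- nz - nz_top
  zs <- c(zhi + (seq_len(nz_top) - 0.5) * h_top / nz_top,
          if (nz_bot > 0) -box[3] / 2 + (seq_len(nz_bot) - 0.5) * h_bot / nz_bot)
  grid <- expand.grid(ix = seq_len(gx) - 0.5, iy = seq_len(gy) - 0.5, z = zs)
  pos <- cbind(grid$ix * box[1] / gx, grid$iy * box[2] / gy, grid$z + zc)
  pick <- sample.int(nrow(pos), n_water)
  pos <- pos[pick, , drop = FALSE]

  n_af <- round(antifreeze_fraction * n_water)
  af_idx <- if (n_af > 0) sample.int(n_water, n_af) else integer(0)
  is_af <- seq_len(n_water) %in% af_idx
  for (q in seq_len(n_water)) {
    ty <- if (is_af[q]) "BP4" else "P4"
    kind <- if (is_af[q]) "antifreeze" else "water"
    system <- append_molecule(system, pos[q, , drop = FALSE],
                              solvent_bead_row(ty, ff, if (is_af[q]) "WF" else "W"),
                              species = kind, kind = kind)
  }
  system$xyz <- wrap_coords(system$xyz, system$box)
  system
}

#' Neutralise a charged system with counterions
#'
#' Replaces one randomly chosen plain water bead per unit of positive net
#' charge with a Cl- counterion bead (a charged Qa-class particle), so the
#' protonated (acidic-condition) systems are overall neutral. A neutral
#' input is returned unchanged with a warning.
#'
#' @param system a solvated `cg_system`
#' @param seed integer
#' @param ff force field (supplies the ion bead definition)
#' @return the system with `net_charge(system) == 0`
#' @export
add_counterions <- function(system, seed = 1L, ff = load_forcefield()) {
  q <- net_charge(system)
  if (q == 0) {
    warning("system already neutral; no counterions added")
    return(system)
  }
  if (q < 0) stop("negative net charge: only Cl- counterions are available")
  set.seed(seed + 2L)
  waters <- system$molecules$id[system$molecules$kind == "water"]
  if (length(waters) < q) stop("not enough water beads to replace with ions")
  repl <- sample(waters, q)
  ion <- ff$ions$CL
  for (id in repl) {
    bead <- which(system$molecule == id)
    system$type[bead] <- ion$type
    system$charge[bead] <- ion$charge
    system$mass[bead] <- ff$type_info[ion$type, "mass"]
    system$bead_label[bead] <- ion$name
    system$molecules$kind[system$molecules$id == id] <- "ion"
    system$molecules$species[system$molecules$id == id] <- "CL"
  }
  stopifnot(net_charge(system) == 0)
  system
}

#' Minimum inter-bead distance of a system (minimum-image)
#'
#' Diagnostic used to enforce the no-overlap invariant of freshly built
#' systems. Excludes pairs within the same molecule.
#' @param system a `cg_system`
#' @return smallest inter-molecular bead-bead distance (A)
#' @export
min_pair_distance <- function(system) {
  x <- system$xyz; box <- system$box; mol <- system$molecule
  n <- nrow(x)
  if (n < 2) return(Inf)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    dx <- abs(sweep(x[-seq_len(i), , drop = FALSE], 2, x[i, ]))
    if (!nrow(dx)) break
    for (d in 1:3) dx[, d] <- pmin(dx[, d], box[d] - dx[, d])
    same <- mol[-seq_len(i)] == mol[i]
    dd <- sqrt(rowSums(dx^2))
    dd[same] <- Inf
    dmin <- min(dmin, dd)
  }
  dmin
}
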