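# Coarse-grained force field for POPC / ISUCA-derived lipid bilayers.
#
# Nonbonded interactions follow the MARTINI v2 scheme: every bead-type pair
# is assigned an interaction level; each level maps to a Lennard-Jones well
# depth (kJ/mol). Sigma is 0.47 nm except for the special cases handled by
# `rules` below (super-repulsive level IX pairs, small ring beads,
# antifreeze-water cross term).
#
# Bonded terms for the ISUCA imidazole headgroup were parameterized against
# all-atom simulations in the original study's supplementary material, which
# is not redistributed here; the `isuca_head` block therefore carries
# placeholder values and is flagged supplementary_required. Drop in the
# published values to reproduce the original headgroup mechanics; nothing in
# the code hard-codes them.
meta:
  name: martini-v2-cg-bilayer
  units:
    length: nm
    energy: kJ/mol
    mass: amu
    charge: e
    angle: degree
  relative_dielectric: 15.0
  coulomb_constant: 138.935458   # kJ mol^-1 nm e^-2 (vacuum)

bead_types:
  P4:  {mass: 72.0, charge: 0}    # CG water bead, four real water molecules
  BP4: {mass: 72.0, charge: 0}    # antifreeze water bead
  Q0:  {mass: 72.0, charge: 1}    # choline (NC3)
  Qa:  {mass: 72.0, charge: -1}   # phosphate (PO4); also the Cl- counterion
  Na:  {mass: 72.0, charge: 0}    # glycerol ester bead
  C1:  {mass: 72.0, charge: 0}    # saturated acyl bead
  C3:  {mass: 72.0, charge: 0}    # cis-unsaturated acyl bead
  SC4: {mass: 45.0, charge: 0}    # imidazole ring carbon (small bead)
  SP1: {mass: 45.0, charge: 0}    # imidazole ring N-H (small bead)
  SQd: {mass: 45.0, charge: 1}    # protonated imidazole ring bead (small)

# Interaction levels, MARTINI v2 epsilon ladder (kJ/mol).
levels:
  O: 5.6
  I: 5.0
  II: 4.5
  III: 4.0
  IV: 3.5
  V: 3.1
  VI: 2.7
  VII: 2.3
  VIII: 2.0
  IX: 2.0       # with sigma 0.62 nm (super repulsive), see rules

# Level matrix over the base alphabet. Small (S-prefixed) and antifreeze
# beads are mapped onto base types via `aliases` before lookup.
level_matrix:
  base_types: [Q0, Qa, Qd, P4, P1, Na, C1, C3, C4]
  pairs:
    Q0: {Q0: IV, Qa: II, Qd: II, P4: I,  P1: III, Na: III, C1: IX,  C3: VII, C4: VI}
    Qa: {Qa: I,  Qd: O,  P4: O,  P1: I,  Na: II,  C1: IX,  C3: VII, C4: VI}
    Qd: {Qd: I,  P4: O,  P1: I,  Na: II, C1: IX,  C3: VII, C4: VI}
    P4: {P4: I,  P1: II, Na: III, C1: VIII, C3: VI, C4: VI}
    P1: {P1: II, Na: III, C1: VI, C3: V,  C4: V}
    Na: {Na: IV, C1: V,  C3: V,  C4: V}
    C1: {C1: IV, C3: IV, C4: IV}
    C3: {C3: IV, C4: IV}
    C4: {C4: IV}

aliases:
  BP4: P4
  SC4: C4
  SP1: P1
  SQd: Qd

rules:
  sigma_default: 0.47          # nm
  sigma_level_IX: 0.62         # nm, Q-C super-repulsive pairs
  ring_sigma: 0.43             # nm, applied when BOTH beads are S-type
  ring_epsilon_scale: 0.75
  ring_types: [SC4, SP1, SQd]
  special_pairs:               # explicit overrides, applied last
    - {a: BP4, b: P4, epsilon: 5.6, sigma: 0.57}   # antifreeze cross term

bonded_defaults:
  bond_k: 1250.0               # kJ mol^-1 nm^-2
  bond_r0: 0.47                # nm
  angle_k: 25.0                # kJ/mol, cosine-harmonic
  angle_theta0: 180.0          # degrees

# Bonded templates assembled into per-species topologies by lipid_topology().
# Bead names inside a template are local; tails attach at `anchor`.
templates:
  popc_head:
    beads:
      - {name: NC3, type: Q0}
      - {name: PO4, type: Qa}
      - {name: GL1, type: Na}
      - {name: GL2, type: Na}
    bonds:
      - {i: NC3, j: PO4, r0: 0.47, k: 1250.0}
      - {i: PO4, j: GL1, r0: 0.47, k: 1250.0}
      - {i: GL1, j: GL2, r0: 0.37, k: 1250.0}
    angles:
      - {i: PO4, j: GL1, k: GL2, theta0: 120.0, fc: 25.0}
      - {i: PO4, j: GL1, k: C1A, theta0: 180.0, fc: 25.0}
    tail_anchors: {A: GL1, B: GL2}
    head_beads: [NC3, PO4]
  isuca_head:
    supplementary_required: true   # ring bonded terms are placeholders
    beads:
      - {name: IM1, type: SC4}
      - {name: IM2, type: SC4}
      - {name: IM3, type: SP1, protonated_type: SQd}
      - {name: GL1, type: Na}
      - {name: GL2, type: Na}
    bonds:
      - {i: IM1, j: IM2, r0: 0.30, k: 5000.0}
      - {i: IM2, j: IM3, r0: 0.30, k: 5000.0}
      - {i: IM3, j: IM1, r0: 0.30, k: 5000.0}
      - {i: IM1, j: GL1, r0: 0.37, k: 1250.0}
      - {i: GL1, j: GL2, r0: 0.37, k: 1250.0}
    angles:
      - {i: IM1, j: GL1, k: GL2, theta0: 120.0, fc: 25.0}
      - {i: IM1, j: GL1, k: C1A, theta0: 180.0, fc: 25.0}
    tail_anchors: {A: GL1, B: GL2}
    head_beads: [IM1, IM2, IM3]
  tail_pal:                      # palmitoyl: four saturated beads
    bead_types: [C1, C1, C1, C1]
    bond: {r0: 0.47, k: 1250.0}
    angles:
      - {at: 1, theta0: 180.0, fc: 25.0}   # anchor-C1-C2
      - {at: 2, theta0: 180.0, fc: 25.0}   # C1-C2-C3
      - {at: 3, theta0: 180.0, fc: 25.0}   # C2-C3-C4
  tail_ol:                       # oleoyl: cis double bond at bead 2
    bead_types: [C1, C3, C1, C1]
    bond: {r0: 0.47, k: 1250.0}
    angles:
      - {at: 1, theta0: 180.0, fc: 25.0}
      - {at: 2, theta0: 120.0, fc: 45.0}   # kink at the unsaturated bead
      - {at: 3, theta0: 180.0, fc: 25.0}

species:
  POPC:
    head: popc_head
    tails: {A: tail_pal, B: tail_ol}
    protonatable: false
  "ISUCA-2 Pal":
    head: isuca_head
    tails: {A: tail_pal, B: tail_pal}
    protonatable: true
  "ISUCA-2 Ol":
    head: isuca_head
    tails: {A: tail_ol, B: tail_ol}
    protonatable: true
  "ISUCA-Pal-Ol":
    head: isuca_head
    tails: {A: tail_pal, B: tail_ol}
    protonatable: true

ions:
  CL: {type: Qa, charge: -1, name: CL}
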