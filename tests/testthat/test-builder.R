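test_that("compositions validate their inputs", {
  expect_error(composition(c(5, 5)), "named")
  expect_error(composition(c(POPC = 29), antifreeze_fraction = 1.2), "antifreeze")
  comp <- composition(c(POPC = 52, "ISUCA-Pal-Ol" = 6),
                      protonated = c(POPC = FALSE, "ISUCA-Pal-Ol" = TRUE))
  expect_equal(sum(comp$counts) * 2, 116)
})

test_that("build_bilayer places mirror-symmetric leaflets deterministically", {
  comp <- composition(c(POPC = 10, "ISUCA-Pal-Ol" = 2), n_water = 0)
  sys <- build_bilayer(comp, c(30, 30, 80), seed = 9, ff = FF)
  mols <- sys$molecules
  expect_equal(sum(mols$kind == "lipid"), 24)
  up <- table(mols$species[mols$leaflet == "upper"])
  lo <- table(mols$species[mols$leaflet == "lower"])
  expect_equal(as.vector(up), as.vector(lo))
  # determinism
  sys2 <- build_bilayer(comp, c(30, 30, 80), seed = 9, ff = FF)
  expect_identical(sys$xyz, sys2$xyz)
  expect_identical(sys$molecules, sys2$molecules)
  sys3 <- build_bilayer(comp, c(30, 30, 80), seed = 10, ff = FF)
  expect_false(identical(sys$xyz, sys3$xyz))
  # too-small box
  expect_error(build_bilayer(comp, c(15, 15, 80), seed = 1, ff = FF),
               "too small")
})

test_that("initial lateral geometry gives the target area per lipid", {
  # 58 lipids on a 62.4 x 62.4 A leaflet: APL fixed by construction
  comp <- composition(c(POPC = 58), n_water = 0)
  sys <- build_bilayer(comp, c(62.4, 62.4, 90), seed = 1, ff = FF)
  expect_equal(sys$box[1] * sys$box[2] / 58, 67.14, tolerance = 1e-3)
  expect_equal(net_charge(sys), 0)
})

test_that("solvate places the exact requested counts and antifreeze split", {
  comp <- composition(c(POPC = 12), n_water = 0)
  sys <- build_bilayer(comp, c(35, 35, 90), seed = 2, ff = FF)
  solv <- solvate(sys, 400, 0.30, seed = 2, ff = FF)
  expect_equal(sum(solv$molecules$kind == "antifreeze"), 120)  # 0.3 x 400
  expect_equal(sum(solv$molecules$kind == "water"), 280)
  solv0 <- solvate(sys, 200, 0, seed = 2, ff = FF)
  expect_equal(sum(solv0$molecules$kind == "antifreeze"), 0)
  expect_error(solvate(sys, 50000, 0.3, seed = 2, ff = FF), "insufficient")
})

test_that("bead bookkeeping matches the published system sizes", {
  sys <- build_named_system("POPC", seed = 1, ff = FF)
  expect_equal(nrow(sys$xyz), 116 * 12 + 1840)  # 3232 beads
  expect_equal(sum(sys$molecules$kind == "antifreeze"), round(0.3 * 1840))
  expect_equal(net_charge(sys), 0)
  # no bad contacts between molecules in the fresh build
  expect_gt(min_pair_distance(sys), 2.0)
})

test_that("counterions neutralise the protonated system by replacing water", {
  sys <- build_named_system("90:10 POPC/ISUCA+-Pal-Ol", seed = 1, ff = FF)
  mols <- sys$molecules
  expect_equal(sum(mols$kind == "ion"), 12)       # +12 from 12 ISUCA+
  expect_equal(sum(mols$kind %in% c("water", "antifreeze")), 1840 - 12)
  expect_equal(net_charge(sys), 0)
  expect_equal(nrow(sys$xyz), 104 * 12 + 12 * 13 + 1840)
  expect_equal(sum(mols$species == "POPC"), 104)
  expect_equal(sum(mols$species == "ISUCA-Pal-Ol"), 12)
  # neutral system: no-op with warning
  neutral <- build_named_system("POPC", seed = 1, ff = FF)
  expect_warning(out <- add_counterions(neutral, ff = FF), "already neutral")
  expect_identical(out$type, neutral$type)
})

test_that("the registry expands every published composition correctly", {
  reg <- system_registry()
  expect_equal(length(reg), 9)
  for (nm in names(reg)) {
    ent <- reg[[nm]]
    expect_equal(sum(ent$counts) * 2, 116, info = nm)
    expect_equal(ent$n_water, 1840L, info = nm)
    expect_equal(ent$antifreeze_fraction, 0.30, info = nm)
  }
  expect_equal(unname(reg[["90:10 POPC/ISUCA-Pal-Ol"]]$counts),
               c(52L, 6L))  # 104 + 12 total
  expect_true(any(unlist(reg[["90:10 POPC/ISUCA+-Pal-Ol"]]$protonated)))
  expect_error(build_named_system("nope", ff = FF), "unknown system")
})
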