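test_that("binding energy is the exact ladder difference", {
  expect_equal(binding_energy(-100, -80, -5), -15)
  expect_equal(binding_energy(-85, -80, -5), 0)   # null binding
  # shifting all three inputs by +c changes the result by -c
  c0 <- binding_energy(-30, -20, -4)
  expect_equal(binding_energy(-30 + 7, -20 + 7, -4 + 7), c0 - 7)
  expect_error(binding_energy(Inf, 0, 0), "non-finite")
  # the record identity holds by construction
  rec <- binding_record("X", "productive", -100, -80, -5)
  expect_equal(rec$e_bind, rec$e_complex - (rec$e_ref + rec$e_lig),
               tolerance = 1e-12)
})

test_that("energy ladder covers the requested component states", {
  p <- default_energy_params()
  sys <- test_system()
  cfg <- fast_cfg(seed = 31, n_decoys = 2, max_K = 2)
  # three states on a ligand-free complex: no ligand entries
  no_lig <- subset_components(sys$structure,
                              c("catalytic_water", "cofactor"))
  lad <- energy_ladder(no_lig, cfg, p,
                       states = c("apo", "water", "water_nadp"))
  expect_setequal(names(lad$energies), c("apo", "water", "water_nadp"))
  expect_error(energy_ladder(no_lig, cfg, p, states = "complex"),
               "missing component")
  # ligand-alone state: energy evaluation only, coordinates untouched
  lad2 <- energy_ladder(sys$structure, cfg, p, states = "complex")
  expect_true("ligand_alone" %in% names(lad2$energies))
  lig_in <- ligand_from_structure(sys$structure)
  expect_equal(as.matrix(lad2$structures$ligand_alone$atoms[, c("x", "y", "z")]),
               as.matrix(lig_in$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_equal(lad2$energies[["ligand_alone"]],
               ligand_energy(lig_in, p)$total)
})

test_that("pose classification against the cofactor plane", {
  sys <- test_system()
  s <- sys$structure
  cls <- classify_pose(s)
  # the planted pose is coplanar with the cofactor ring
  expect_equal(cls$position, "unproductive")
  expect_lt(cls$angle, 30)
  # rotate the ligand 90 degrees about an in-plane axis -> productive
  rows <- which(s$atoms$comp_kind == "ligand")
  m <- coords(s)
  cen <- colMeans(m[rows, , drop = FALSE])
  m90 <- m; m90[rows, ] <- rotate_about_axis(m[rows, , drop = FALSE],
                                             cen, c(1, 0, 0), 90)
  cls90 <- classify_pose(set_coords(s, m90))
  expect_equal(cls90$position, "productive")
  expect_gt(cls90$angle, 60)
  # 45 degrees is ambiguous
  m45 <- m; m45[rows, ] <- rotate_about_axis(m[rows, , drop = FALSE],
                                             cen, c(1, 0, 0), 45)
  expect_equal(classify_pose(set_coords(s, m45))$position, "ambiguous")
  # invariant under rigid motion of the whole complex
  mall <- rotate_about_axis(m90, c(0, 0, 0), c(1, 2, 3), 61)
  mall <- sweep(mall, 2, c(4, 4, -7), `+`)
  expect_equal(classify_pose(set_coords(s, mall))$angle, cls90$angle,
               tolerance = 1e-6)
})

test_that("pose RMSD is the in-frame heavy-atom deviation", {
  l <- synthetic_active_ligand()
  expect_equal(pose_rmsd(l, l), 0)
  # uniform 1 A translation of every atom -> exactly 1
  l2 <- l
  l2$atoms$x <- l2$atoms$x + 1
  expect_equal(pose_rmsd(l, l2), 1)
  # random displacement matches the direct formula
  set.seed(5)
  l3 <- l
  d <- matrix(rnorm(3 * nrow(l$atoms), sd = 0.5), ncol = 3)
  l3$atoms$x <- l3$atoms$x + d[, 1]
  l3$atoms$y <- l3$atoms$y + d[, 2]
  l3$atoms$z <- l3$atoms$z + d[, 3]
  heavy <- !l$atoms$is_h
  expect_equal(pose_rmsd(l, l3),
               sqrt(mean(rowSums(d[heavy, , drop = FALSE]^2))))
  # atom mismatch errors
  l4 <- l; l4$atoms <- l4$atoms[-1, ]
  expect_error(pose_rmsd(l, l4), "heavy-atom counts")
})

test_that("ligand ranking reproduces the reference productive-column order", {
  # productive-position binding energies of the reference study's
  # screen: testosterone -11, finasteride -27, beta-sitosterol -28,
  # stigmasterol -29, campesterol -8, daucosterol -30, oleic -34,
  # myristic -20, palmitic -13, linoleic -28; lauric acid not binding
  recs <- rbind(
    binding_record("testosterone", "productive", -11, 0, 0),
    binding_record("finasteride", "productive", -27, 0, 0),
    binding_record("beta-sitosterol", "productive", -28, 0, 0),
    binding_record("stigmasterol", "productive", -29, 0, 0),
    binding_record("campesterol", "productive", -8, 0, 0),
    binding_record("daucosterol", "productive", -30, 0, 0),
    binding_record("oleic acid", "productive", -34, 0, 0),
    binding_record("lauric acid", "productive", 0, 0, 0, binding = FALSE),
    binding_record("myristic acid", "productive", -20, 0, 0),
    binding_record("palmitic acid", "productive", -13, 0, 0),
    binding_record("linoleic acid", "productive", -28, 0, 0))
  rk <- rank_ligands(recs)
  expect_equal(rk$ligand_name[1], "oleic acid")          # -34 first
  expect_equal(rk$ligand_name[2], "daucosterol")         # -30 second
  binders <- rk$ligand_name[rk$binding]
  expect_equal(binders[length(binders)], "campesterol")  # -8 last binder
  expect_equal(rk$ligand_name[nrow(rk)], "lauric acid")  # not binding last
  # equal energies break alphabetically
  expect_equal(rk$ligand_name[rk$e_bind == -28],
               c("beta-sitosterol", "linoleic acid"))
  # rank order invariant under a constant shift of all e_bind
  recs2 <- recs; recs2$e_bind <- recs2$e_bind + 100
  expect_equal(rank_ligands(recs2)$ligand_name, rk$ligand_name)
})
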