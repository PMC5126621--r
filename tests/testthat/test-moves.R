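test_that("flexible-residue selection follows the 4 A first/later rule", {
  sys <- test_system()
  s <- sys$structure
  first <- select_flexible_residues(s, first_cycle = TRUE, radius = 4)
  later <- select_flexible_residues(s, first_cycle = FALSE, radius = 4)
  # first cycle adds cofactor-proximal and declared active residues
  expect_true(all(later %in% first))
  expect_true(all(s$active_residues %in% first))
  # threshold is sharp: distances straddling the radius decide membership
  ids <- atom_res_ids(s)
  m <- coords(s)
  lig <- m[s$atoms$comp_kind == "ligand", , drop = FALSE]
  for (id in res_ids(s, "protein")) {
    rows <- which(ids == id)
    dmin <- sqrt(min(outer(rowSums(m[rows, , drop = FALSE]^2),
                           rowSums(lig^2), `+`) -
                       2 * m[rows, , drop = FALSE] %*% t(lig)))
    expect_equal(id %in% later, dmin <= 4, label = id)
  }
  # result independent of atom ordering
  perm <- s
  o <- rev(seq_len(nrow(s$atoms)))
  perm$atoms <- s$atoms[o, ]
  perm$topology <- NULL
  perm$ligand_info <- NULL  # not needed for selection geometry
  perm$atoms$comp_kind[perm$atoms$comp_kind == "ligand"] <- "ligand"
  expect_equal(select_flexible_residues(perm, FALSE, 4), later)
  # no ligand is an error
  expect_error(select_flexible_residues(
    subset_components(s, "cofactor"), FALSE, 4), "no ligand")
})

test_that("small moves perturb phi/psi within bounds, deterministically", {
  s <- make_test_chain(6)
  spec <- move_spec(small_max_angle = 5)
  # zero magnitude is the identity
  set.seed(1)
  s0 <- apply_small_move(s, "A:3", move_spec(small_max_angle = 0))
  expect_equal(coords(s0), coords(s))
  # |delta phi|, |delta psi| <= max over repeated draws
  for (i in 1:10) {
    set.seed(i)
    s1 <- apply_small_move(s, "A:3", spec)
    d <- pocketmc:::wrap_angle(residue_phi_psi(s1, "A:3") - residue_phi_psi(s, "A:3"))
    expect_true(all(abs(d) <= 5 + 1e-9))
  }
  # same seed -> identical output
  set.seed(7); a <- apply_small_move(s, "A:3", spec)
  set.seed(7); b <- apply_small_move(s, "A:3", spec)
  expect_identical(coords(a), coords(b))
  # upstream residues never move
  set.seed(7); s1 <- apply_small_move(s, "A:3", spec)
  up <- which(s$atoms$resno < 3)
  expect_equal(coords(s1)[up, ], coords(s)[up, ])
})

test_that("shear moves compensate: less end displacement than small moves", {
  s <- make_test_chain(10)
  # equal delta applied by hand through the internal rotation helper
  delta <- 5
  sh <- pocketmc:::.rotate_backbone(s, "A:6", "phi", delta)
  sh <- pocketmc:::.rotate_backbone(sh, "A:5", "psi", -delta)
  sm <- pocketmc:::.rotate_backbone(s, "A:6", "phi", delta)
  sm <- pocketmc:::.rotate_backbone(sm, "A:6", "psi", delta)
  term <- which(s$atoms$resno == 10)
  disp <- function(x) max(sqrt(rowSums((coords(x)[term, ] -
                                          coords(s)[term, ])^2)))
  expect_lt(disp(sh), disp(sm))
  # identity at delta = 0, determinism under a seed
  set.seed(3)
  s0 <- apply_shear_move(s, "A:5", "A:6", move_spec(shear_max_angle = 0))
  expect_equal(coords(s0), coords(s))
  set.seed(4); a <- apply_shear_move(s, "A:5", "A:6", move_spec())
  set.seed(4); b <- apply_shear_move(s, "A:5", "A:6", move_spec())
  expect_identical(coords(a), coords(b))
  expect_error(apply_shear_move(s, "A:2", "A:6", move_spec()),
               "adjacent")
})

test_that("moves preserve bond lengths (only dihedrals change)", {
  s <- pocketmc::ensure_topology(make_test_chain(8))
  set.seed(11)
  s1 <- apply_small_move(s, "A:4", move_spec(small_max_angle = 30))
  b <- s$topology$bonds
  len <- function(st) sqrt(rowSums((coords(st)[b[, 1], ] -
                                      coords(st)[b[, 2], ])^2))
  expect_equal(len(s1), len(s), tolerance = 1e-6)
})

test_that("repacking picks non-clashing rotamers and matches enumeration", {
  p <- default_energy_params()
  sys <- test_system()
  s <- sys$structure
  sers <- res_ids(s, "protein")[vapply(res_ids(s, "protein"), function(id)
    s$atoms$resname[residue_rows(s, id)[1]] == "SER", TRUE)]
  lib <- default_rotamer_library()
  # brute-force oracle over all rotamer combinations of the two serines
  res2 <- sers[1:2]
  combos <- expand.grid(r1 = 1:3, r2 = 1:3)
  tpS <- pocketmc:::residue_template("SER")
  set_rot <- function(st, id, chi1) {
    rows <- residue_rows(st, id)
    pocketmc:::.set_chi(st, rows, tpS, 1, chi1)
  }
  score_total <- function(st) complex_energy(st, p)$total
  best <- Inf; best_combo <- NULL
  for (i in seq_len(nrow(combos))) {
    st <- set_rot(s, res2[1], lib$SER$chis[combos$r1[i], 1])
    st <- set_rot(st, res2[2], lib$SER$chis[combos$r2[i], 1])
    e <- score_total(st)
    if (e < best) { best <- e; best_combo <- combos[i, ] }
  }
  got <- repack_side_chains(s, res2, lib, p)
  expect_equal(score_total(got), best, tolerance = 1e-6)
  # backbone atoms never move during repacking
  bb <- which(s$atoms$comp_kind == "protein" &
                s$atoms$name %in% c("N", "CA", "C", "O", "H"))
  expect_equal(coords(got)[bb, ], coords(s)[bb, ])
  # empty residue set is the identity
  expect_equal(coords(repack_side_chains(s, character(), lib, p)),
               coords(s))
  # missing rotamer entry errors
  lib2 <- lib; lib2$SER <- NULL
  expect_error(repack_side_chains(s, res2, lib2, p), "rotamer")
})

test_that("component perturbation is rigid, seeded, and protein-free", {
  sys <- test_system()
  s <- sys$structure
  spec0 <- move_spec(ligand_translation_max = 0, ligand_rotation_max = 0)
  set.seed(1)
  s0 <- perturb_component(s, "catalytic_water", spec0)
  expect_equal(coords(s0), coords(s), tolerance = 1e-12)
  # rigidity: intra-component distances preserved for water and cofactor
  for (kind in c("catalytic_water", "cofactor")) {
    set.seed(5)
    s1 <- perturb_component(s, kind, move_spec())
    rows <- which(s$atoms$comp_kind == kind)
    expect_equal(as.vector(dist(coords(s1)[rows, ])),
                 as.vector(dist(coords(s)[rows, ])), tolerance = 1e-9)
  }
  set.seed(9); a <- perturb_component(s, "ligand", move_spec())
  set.seed(9); b <- perturb_component(s, "ligand", move_spec())
  expect_identical(coords(a), coords(b))
  expect_error(perturb_component(s, "protein", move_spec()), "hetero")
})
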