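test_that("system generation is deterministic and structurally valid", {
  sys <- test_system()
  sys2 <- make_mini_pocket(seed = 42, n_residues = 15)
  expect_identical(coords(sys$structure), coords(sys2$structure))
  expect_identical(sys$planted_pose, sys2$planted_pose)
  expect_true(validate_structure(sys$structure))
  kinds <- unique(sys$structure$atoms$comp_kind)
  expect_setequal(kinds, c("protein", "cofactor", "catalytic_water",
                           "ligand"))
  n_res <- length(res_ids(sys$structure, "protein"))
  expect_true(n_res >= 10 && n_res <= 40)
  expect_error(make_mini_pocket(seed = 1, n_residues = 5))
})

test_that("the planted pose is a strict local minimum of the energy model", {
  p <- default_energy_params()
  sys <- test_system()
  e0 <- complex_energy(sys$structure, p)$total
  rows <- which(sys$structure$atoms$comp_kind == "ligand")
  m0 <- coords(sys$structure)
  set.seed(99)
  raised <- 0
  for (j in 1:100) {
    m <- m0
    cen <- colMeans(m[rows, , drop = FALSE])
    R <- pocketmc:::random_rotation(1.5)
    pt <- sweep(m[rows, , drop = FALSE], 2, cen) %*% t(R)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    m[rows, ] <- sweep(pt, 2, cen + 0.3 * dir, `+`)
    if (complex_energy(set_coords(sys$structure, m), p)$total > e0)
      raised <- raised + 1
  }
  expect_gte(raised, 95)
})

test_that("decoy ligands are property-matched but topology-distinct", {
  active <- synthetic_active_ligand()
  decs <- make_decoy_ligands(active, n = 6, seed = 1)
  expect_length(decs, 6)
  n_heavy <- sum(!active$atoms$is_h)
  for (d in decs) {
    expect_lte(abs(sum(!d$atoms$is_h) - n_heavy), 2)
    expect_equal(ligand_net_charge(d), ligand_net_charge(active))
    # independent graph-isomorphism oracle
    ga <- igraph::graph_from_edgelist(active$bonds, directed = FALSE)
    gd <- igraph::graph_from_edgelist(d$bonds, directed = FALSE)
    expect_false(igraph::isomorphic(ga, gd))
    expect_true(pocketmc:::.graph_connected(nrow(d$atoms), d$bonds))
  }
  # deterministic in the seed
  decs2 <- make_decoy_ligands(active, n = 6, seed = 1)
  expect_identical(lapply(decs, `[[`, "atoms"),
                   lapply(decs2, `[[`, "atoms"))
})

test_that("pose perturbation hits the requested displacement scale", {
  sys <- test_system()
  # magnitude 0 is the identity
  expect_identical(coords(perturb_pose(sys, 0, seed = 1)),
                   coords(sys$structure))
  # same seed -> identical output
  expect_identical(coords(perturb_pose(sys, 1.5, seed = 3)),
                   coords(perturb_pose(sys, 1.5, seed = 3)))
  # only the ligand moves
  s1 <- perturb_pose(sys, 1.5, seed = 3)
  fixed <- sys$structure$atoms$comp_kind != "ligand"
  expect_identical(coords(s1)[fixed, ], coords(sys$structure)[fixed, ])
  # mean heavy-atom RMSD over 50 seeds within 20% of the target
  lig0 <- ligand_from_structure(sys$structure)
  rmsds <- vapply(1:50, function(sd)
    pose_rmsd(ligand_from_structure(perturb_pose(sys, 1.5, seed = sd)),
              lig0), numeric(1))
  expect_lt(abs(mean(rmsds) - 1.5) / 1.5, 0.2)
})
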