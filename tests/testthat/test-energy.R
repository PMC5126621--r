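mk_atom <- function(x, q = 0, eps = 0.2, sigma = 3.0, element = "C",
                    role = "none") {
  atom_table(name = "X", element = element, x = x[1], y = x[2], z = x[3],
             chain = "A", resno = 1L, resname = "UNK",
             comp_kind = "protein", charge = q, eps = eps, sigma = sigma,
             hb_role = role)
}

test_that("pair energy matches the analytic Lennard-Jones landmarks", {
  p <- default_energy_params()
  a <- mk_atom(c(0, 0, 0))
  # minimum at r = 2^(1/6) sigma with depth -eps
  b <- mk_atom(c(2^(1 / 6) * 3.0, 0, 0))
  expect_equal(pair_energy(a, b, p)$lj, -0.2, tolerance = 1e-12)
  # root at r = sigma
  b <- mk_atom(c(3.0, 0, 0))
  expect_equal(pair_energy(a, b, p)$lj, 0, tolerance = 1e-12)
  # Coulomb closed form with eps(r) = 4r at r = 3: k q1 q2 / (4 r^2)
  a$charge <- 1; bq <- mk_atom(c(3, 0, 0), q = 1)
  expect_equal(pair_energy(a, bq, p)$coulomb, 332.0637 / (4 * 9),
               tolerance = 1e-12)
  # zero beyond cutoff; singular at r = 0
  far <- mk_atom(c(2 * p$nonbonded_cutoff, 0, 0))
  expect_equal(pair_energy(a, far, p)$total, 0)
  expect_error(pair_energy(a, mk_atom(c(0, 0, 0))), "r = 0")
  # symmetry
  b2 <- mk_atom(c(1.7, 2.2, -0.4), q = -0.3)
  a2 <- mk_atom(c(-0.5, 0.1, 0.8), q = 0.4)
  expect_equal(pair_energy(a2, b2, p)$total, pair_energy(b2, a2, p)$total)
})

test_that("complex energy equals an independent all-pairs summation", {
  p <- default_energy_params()
  sys <- test_system()
  # a small sub-complex: ligand + water + cofactor (31 atoms)
  sub <- subset_components(sys$structure, c("ligand", "cofactor",
                                            "catalytic_water"))
  sub$atoms <- sub$atoms[sub$atoms$comp_kind != "protein", , drop = FALSE]
  sub$tethers <- NULL
  sub$topology <- NULL
  e <- complex_energy(sub, p)
  ora <- oracle_nonbonded(sub, p)
  expect_equal(e$lj, ora$lj, tolerance = 1e-9)
  expect_equal(e$coulomb, ora$coulomb, tolerance = 1e-9)
  expect_equal(e$hbond, ora$hbond, tolerance = 1e-9)
})

test_that("complex energy: degenerate inputs and cutoff behaviour", {
  p <- default_energy_params()
  empty <- new_structure(synthetic_active_ligand()$atoms[0, ],
                         prepared = TRUE)
  expect_equal(complex_energy(empty, p)$total, 0)
  # two neutral atoms beyond cutoff interact not at all
  a2 <- rbind(mk_atom(c(0, 0, 0)), mk_atom(c(2 * p$nonbonded_cutoff, 0, 0)))
  a2$resno <- c(1L, 2L)
  s2 <- new_structure(a2, prepared = TRUE)
  expect_equal(complex_energy(s2, p)$total, 0)
})

test_that("complex energy is invariant under rigid motion", {
  p <- default_energy_params()
  sys <- test_system()
  s <- sys$structure
  s$tethers <- NULL  # tethers are lab-frame anchored by design
  e0 <- complex_energy(s, p)$total
  m <- rotate_about_axis(coords(s), c(1, 2, 3), c(1, 1, 0), 37.5)
  m <- sweep(m, 2, c(5, -3, 2), `+`)
  e1 <- complex_energy(set_coords(s, m), p)$total
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("energy goes smoothly to zero at the cutoff", {
  p <- default_energy_params()
  a <- mk_atom(c(0, 0, 0), q = 0.5)
  rs <- seq(p$nonbonded_cutoff - 0.1, p$nonbonded_cutoff, by = 0.01)
  es <- vapply(rs, function(r)
    pair_energy(a, mk_atom(c(r, 0, 0), q = 0.5), p)$total, numeric(1))
  expect_equal(es[length(es)], 0)
  expect_lt(max(abs(diff(es))), 1e-2)  # no jump at the boundary
})

test_that("ligand internal energy: torsion prior and brute-force oracle", {
  p <- default_energy_params()
  # single atom -> 0
  one <- synthetic_active_ligand()
  single <- new_ligand(one$atoms[1, , drop = FALSE],
                       matrix(integer(), 0, 2))
  expect_equal(ligand_energy(single, p)$total, 0)
  # 4-atom chain: anti torsion strictly below eclipsed
  chain4 <- function(phi) {
    xyz <- rbind(c(0, 1.0, 0), c(0, 0, 0), c(1.5, 0, 0),
                 c(1.5 + cos(phi * pi / 180), 0, 0))
    xyz[4, ] <- c(1.5, 0, 0) +
      as.vector(rotate_about_axis(matrix(c(0, 1.0, 0), 1),
                                  c(0, 0, 0), c(1, 0, 0), phi))
    at <- atom_table(paste0("C", 1:4), "C", xyz[, 1], xyz[, 2], xyz[, 3],
                     "X", 201L, "LIG", "ligand", charge = 0, eps = 0.1,
                     sigma = 3.5)
    new_ligand(at, rbind(c(1, 2), c(2, 3), c(3, 4)))
  }
  expect_lt(ligand_energy(chain4(180), p)$torsion,
            ligand_energy(chain4(0), p)$torsion)
  # the active ligand matches a direct term-by-term oracle
  l <- synthetic_active_ligand()
  e <- ligand_energy(l, p)
  sl <- new_structure(l$atoms,
                      ligand_info = list(name = l$name, bonds = l$bonds,
                                         order = l$order,
                                         torsions = l$torsions),
                      prepared = TRUE)
  ora <- oracle_nonbonded(sl, p)
  expect_equal(e$lj, ora$lj, tolerance = 1e-9)
  expect_equal(e$coulomb, ora$coulomb, tolerance = 1e-9)
  # disconnected graph errors (drop the hydroxyl-H bond, a bridge)
  bad <- l; bad$bonds <- l$bonds[-nrow(l$bonds), ]
  expect_error(ligand_energy(bad, p), "connected")
})
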