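# a hand-built two-atom-site complex: one serine-like donor aimed at a
# ligand oxygen at a controllable distance/angle
hb_fixture <- function(dOA = 2.8, angle = 170) {
  # ligand: C-O (acceptor); protein: OG-HG donor aimed at the O
  lig <- atom_table(c("C1", "O1"), c("C", "O"),
                    x = c(-1.4, 0), y = 0, z = 0, chain = "X",
                    resno = 201L, resname = "LIG", comp_kind = "ligand",
                    charge = c(0.45, -0.45), eps = 0.17, sigma = 3.0,
                    hb_role = c("none", "acceptor"))
  # donor O at distance dOA along +x; H placed by solving the D-H-A
  # triangle so the O-H...A angle is exactly `angle` with |D-H| = 0.96
  og <- c(dOA, 0, 0)
  gam <- angle * pi / 180
  ang_A <- asin(min(1, 0.96 * sin(gam) / dOA))
  ang_D <- pi - gam - ang_A
  ah <- dOA * sin(ang_D) / sin(gam)
  hg <- ah * c(cos(ang_A), sin(ang_A), 0)
  prot <- atom_table(c("CB", "OG", "HG"), c("C", "O", "H"),
                     x = c(dOA + 1.4, og[1], hg[1]),
                     y = c(0, og[2], hg[2]), z = c(0, og[3], hg[3]),
                     chain = "A", resno = 1L, resname = "SER",
                     comp_kind = "protein",
                     charge = c(0.265, -0.683, 0.418),
                     eps = c(0.1, 0.17, 0.015), sigma = c(3.55, 3.0, 0.8),
                     hb_role = c("none", "both", "none"))
  new_structure(rbind(prot, lig),
                ligand_info = list(name = "LIG",
                                   bonds = matrix(c(1L, 2L), 1),
                                   order = 1L, torsions = list()),
                prepared = TRUE)
}

test_that("hydrogen bonds are detected inside the geometric cutoffs", {
  s <- hb_fixture(dOA = 2.8, angle = 170)
  hb <- find_hbonds(s, 3.5, 120)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "OG")
  expect_equal(hb$acceptor_atom, "O1")
  expect_equal(hb$distance, 2.8, tolerance = 1e-6)
  expect_equal(hb$angle, 170, tolerance = 1e-6)
  # beyond the distance cutoff: absent
  expect_equal(nrow(find_hbonds(hb_fixture(dOA = 5.0), 3.5, 120)), 0)
  # below the angle cutoff: absent
  expect_equal(nrow(find_hbonds(hb_fixture(angle = 100), 3.5, 120)), 0)
})

test_that("hbond detection matches an exhaustive pair scan on a complex", {
  sys <- test_system()
  s <- ensure_topology(sys$structure)
  hb <- find_hbonds(s, 3.5, 120)
  # oracle: scan every polar H x acceptor pair directly
  a <- s$atoms; m <- coords(s); tp <- s$topology
  n_expect <- 0
  for (h in which(tp$don > 0)) {
    D <- tp$don[h]
    for (acc in which(tp$acc == 1)) {
      kinds <- c(a$comp_kind[D], a$comp_kind[acc])
      if (!("ligand" %in% kinds && "protein" %in% kinds)) next
      dDA <- sqrt(sum((m[D, ] - m[acc, ])^2))
      if (dDA > 3.5) next
      u <- m[D, ] - m[h, ]; v <- m[acc, ] - m[h, ]
      ang <- acos(min(1, max(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang >= 120) n_expect <- n_expect + 1
    }
  }
  expect_equal(nrow(hb), n_expect)
  expect_gte(nrow(hb), 1)  # the designed serine contact is present
  # raising a cutoff never removes an interaction
  expect_gte(nrow(find_hbonds(s, 3.8, 120)), nrow(hb))
  expect_gte(nrow(find_hbonds(s, 3.5, 110)), nrow(hb))
})

test_that("hydrophobic contacts are carbon-carbon only, residue-aggregated", {
  sys <- test_system()
  s <- sys$structure
  hc <- find_hydrophobic_contacts(s, 3.9)
  expect_gte(nrow(hc), 1)
  expect_true(all(hc$min_distance <= 3.9))
  expect_false(anyDuplicated(hc$res_id) > 0)
  # oracle: exhaustive C-C scan aggregated by residue
  a <- s$atoms; m <- coords(s); ids <- atom_res_ids(s)
  ligC <- which(a$comp_kind == "ligand" & a$element == "C")
  protC <- which(a$comp_kind == "protein" & a$element == "C")
  mind <- tapply(seq_along(protC), ids[protC], function(ii) {
    min(sqrt(outer(rowSums(m[protC[ii], , drop = FALSE]^2),
                   rowSums(m[ligC, , drop = FALSE]^2), `+`) -
               2 * m[protC[ii], , drop = FALSE] %*% t(m[ligC, , drop = FALSE])))
  })
  expect_setequal(hc$res_id, names(mind)[mind <= 3.9])
  # an O-C pair inside the cutoff is not a hydrophobic contact
  s2 <- hb_fixture(dOA = 3.5)  # donor O 3.5 A from ligand O, C further
  hc2 <- find_hydrophobic_contacts(s2, 3.9)
  expect_false("O1" %in% hc2$ligand_atom)
  expect_false("OG" %in% hc2$protein_atom)
  # monotone in the cutoff
  expect_gte(nrow(find_hydrophobic_contacts(s, 4.4)), nrow(hc))
})

test_that("shared residues respect the threshold fraction", {
  mk_report <- function(res) {
    r <- list(ligand_name = "L",
              hbonds = data.frame(protein_res = character()),
              hydrophobic_contacts = data.frame(res_id = res,
                                                stringsAsFactors = FALSE))
    class(r) <- "InteractionReport"
    r
  }
  reports <- list(mk_report(c("A:1", "A:2")), mk_report(c("A:1", "A:2")),
                  mk_report(c("A:1", "A:3")), mk_report(c("A:1", "A:2")),
                  mk_report(c("A:1", "A:2")))
  expect_equal(shared_residues(reports, 1.0), "A:1")
  # 4/5 sits exactly on the 0.8 boundary
  expect_setequal(shared_residues(reports, 0.8), c("A:1", "A:2"))
  # subset property: threshold 1 result contained in any lower threshold
  expect_true(all(shared_residues(reports, 1.0) %in%
                    shared_residues(reports, 0.4)))
  expect_error(shared_residues(list(), 0.8), "no interaction")
  expect_error(shared_residues(reports, 0), "threshold")
  expect_error(shared_residues(reports, 1.2), "threshold")
})
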