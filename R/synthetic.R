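# Synthetic mini-complexes: a rigid pocket of 10-40 residues arranged
# around a planted ligand whose pose is (verified at generation) a
# strict local minimum of the package's energy model; a planar
# cofactor stand-in placed so that both the parallel (unproductive)
# and perpendicular (productive) ligand orientations are geometrically
# realizable; a catalytic water; and property-matched decoy ligands.
# Systems are generated already "prepared" (charges, radii, polar H).

#' Build the planted active ligand
#'
#' A six-membered carbon ring (the planar core used for pose
#' classification) carrying a two-point pharmacophore at fixed
#' geometry: a hydroxyl at C1 (donor/acceptor) and a carbonyl-like
#' oxygen at C4 (acceptor) on the opposite rim, ~5.5 A apart, plus a
#' methyl at C2; one rotatable hydroxyl torsion.
#'
#' @param name ligand label.
#' @return a `Ligand` centred near the origin, ring in the xy plane.
#' @export
synthetic_active_ligand <- function(name = "LG1") {
  ring <- t(vapply(0:5, function(i) {
    th <- i * pi / 3
    c(1.4 * cos(th), 1.4 * sin(th), 0)
  }, numeric(3)))
  o1 <- c(2.76, 0, 0)                       # hydroxyl on C1 (+x rim)
  o2 <- c(-2.63, 0, 0)                      # carbonyl on C4 (-x rim)
  c7 <- 2.9 / 1.4 * ring[2, ]               # methyl on C2
  h1 <- o1 + 0.96 * c(cos(71 * pi / 180), sin(71 * pi / 180), 0)
  xyz <- rbind(ring, c7, o1, o2, h1)
  element <- c(rep("C", 7), "O", "O", "H")
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
                 c(2, 7), c(1, 8), c(4, 9), c(8, 10))
  order <- c(rep(1L, 8), 2L, 1L)
  lj <- .lj_lookup(element)
  pars <- ligand_atom_parameters(element, bonds, order)
  atoms <- atom_table(
    name = c(paste0("C", 1:7), "O1", "O2", "HO1"), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = "X", resno = 201L,
    resname = "LIG", comp_kind = "ligand", charge = pars$charge,
    eps = lj$eps, sigma = lj$sigma, hb_role = pars$hb_role)
  new_ligand(atoms, bonds, order, name = name)
}

# polar sites of the active used to aim the pocket's serines:
# (oxygen row, parent-carbon row)
.active_polar_sites <- list(c(o = 8L, c = 1L), c(o = 9L, c = 4L))

# rotate direction d by `ang` degrees within the plane spanned by d and
# the horizontal tangent
.tilt <- function(d, t, ang) {
  as.vector(rotate_about_axis(matrix(d, 1), c(0, 0, 0),
                              pracma_cross(d, t), ang))
}

#' Generate a synthetic mini-pocket system
#'
#' Pocket residues (one hydrogen-bonding serine aimed at the ligand
#' hydroxyl, the rest a hydrophobic lining of ALA/VAL/LEU) are placed
#' on a spherical band of directions around the planted ligand, side
#' chains pointing inward; a `complementarity` fraction of the lining
#' sits at Lennard-Jones contact distance, the rest one shell further
#' out. A planar cofactor ring lies parallel to the planted ligand
#' plane (so the planted pose is the unproductive orientation and the
#' 90-degree rotation the productive one), with the catalytic water
#' adjacent. After assembly the hetero components are relaxed and the
#' planted pose is verified to be a strict local minimum of the energy
#' model; generation is retried (new direction jitter) up to
#' `max_attempts` times.
#'
#' @param seed integer seed; generation is deterministic in
#'   `(seed, parameters)`.
#' @param n_residues pocket size, 10-40.
#' @param complementarity fraction in 0-1 controlling how much of the
#'   lining is at contact distance (default 0.8).
#' @param p `EnergyParams` used for the settle/verification.
#' @param max_attempts generation retries before giving up.
#' @return object of class `SyntheticSystem`: `structure` (prepared
#'   complex), `planted_pose` (ligand coordinate matrix), `seed`,
#'   `descriptor`.
#' @export
make_mini_pocket <- function(seed, n_residues = 15, complementarity = 0.8,
                             p = default_energy_params(),
                             max_attempts = 100) {
  stopifnot(n_residues >= 10, n_residues <= 40,
            complementarity >= 0, complementarity <= 1)
  lig <- synthetic_active_ligand()
  for (attempt in seq_len(max_attempts)) {
    set.seed((seed + 7919L * (attempt - 1L)) %% 2147483647L)
    sys <- .build_pocket_attempt(lig, n_residues, complementarity, p)
    if (is.null(sys)) next
    ver <- .verify_planted_minimum(sys$structure, p, n_trials = 20,
                                   magnitude = 0.3)
    if (ver$frac_raised >= 0.9) {
      sys$seed <- seed
      sys$descriptor$attempt <- attempt
      sys$descriptor$minimum_check <- ver
      return(sys)
    }
  }
  stop("infeasible pocket geometry after ", max_attempts, " attempts")
}

.build_pocket_attempt <- function(lig, n_residues, complementarity, p) {
  lig_xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  heavy <- !lig$atoms$is_h
  # directions spread evenly (Fibonacci lattice) over a spherical band,
  # leaving a gap toward the cofactor (-y)
  ks <- seq_len(n_residues)
  z <- cos(125 * pi / 180) +
    (ks - 0.5) / n_residues * (cos(55 * pi / 180) - cos(125 * pi / 180))
  theta <- acos(z)
  golden <- 137.50776 * pi / 180
  phi <- (ks * golden + stats::runif(n_residues, -0.06, 0.06)) %% (2 * pi)
  # compress azimuths into (-50, 230) degrees so the -y sector stays open
  phi <- (-50 + phi / (2 * pi) * 280) * pi / 180
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  # one serine per ligand polar site, at the best-aligned direction
  types <- rep(c("VAL", "ALA", "LEU"), length.out = n_residues)
  ser_ks <- integer(); ser_site <- list()
  for (site in .active_polar_sites) {
    sd <- unit(lig_xyz[site[["o"]], ] - lig_xyz[site[["c"]], ])
    cand <- order(-(dirs %*% sd))
    k <- cand[!cand %in% ser_ks][1]
    ser_ks <- c(ser_ks, k)
    ser_site[[as.character(k)]] <- site
  }
  types[ser_ks] <- "SER"
  n_tight <- round(complementarity * (n_residues - length(ser_ks)))
  lining <- setdiff(ks, ser_ks)
  # spread the contact-distance subset evenly over the shell
  tight <- if (n_tight > 0)
    lining[unique(round(seq(1, length(lining), length.out = n_tight)))]
  else integer()
  rows <- list()
  for (k in ks) {
    d <- dirs[k, ]
    t_k <- unit(pracma_cross(c(0, 0, 1), d))
    b_k <- unit(pracma_cross(d, t_k))
    # side-chain zigzag directions in the (d, t) plane; the backbone N/C
    # split along +/- b so 1-4 side-chain/backbone pairs stay apart
    u1 <- unit(cos(22 * pi / 180) * d + sin(22 * pi / 180) * t_k)
    u2 <- unit(cos(22 * pi / 180) * d - sin(22 * pi / 180) * t_k)
    ub <- unit(-0.3 * d + 0.9 * t_k - 0.5 * b_k)  # methyl branch direction
    gap <- if (k %in% tight || k %in% ser_ks) 4.1 else 6.0
    supp <- max(lig_xyz[heavy, ] %*% d)
    tip <- as.numeric((supp + gap) * d)
    ty <- types[k]
    at <- switch(ty,
      SER = {
        site <- ser_site[[as.character(k)]]
        o_lig <- lig_xyz[site[["o"]], ]
        og <- o_lig + 2.85 * unit(o_lig - lig_xyz[site[["c"]], ])
        hg <- og + 0.96 * unit(o_lig - og)  # donor H aimed at the ligand O
        cb <- og + 1.42 * u1
        ca <- cb + 1.53 * u2
        list(names = c("CB", "OG", "HG"), xyz = rbind(cb, og, hg), ca = ca)
      },
      ALA = {
        cb <- tip
        ca <- cb + 1.53 * u2
        list(names = "CB", xyz = rbind(cb), ca = ca)
      },
      VAL = {
        cg1 <- tip
        cb <- cg1 + 1.53 * u1
        cg2 <- cb + 1.53 * ub
        ca <- cb + 1.53 * u2
        list(names = c("CB", "CG1", "CG2"), xyz = rbind(cb, cg1, cg2),
             ca = ca)
      },
      LEU = {
        cd1 <- tip
        cg <- cd1 + 1.53 * u1
        cd2 <- cg + 1.53 * ub
        cb <- cg + 1.53 * u2
        ca <- cb + 1.53 * u1
        list(names = c("CB", "CG", "CD1", "CD2"),
             xyz = rbind(cb, cg, cd1, cd2), ca = ca)
      })
    ca <- at$ca
    nv <- ca + 1.45 * unit(0.55 * d + b_k)
    cv <- ca + 1.45 * unit(0.55 * d - b_k)
    ov <- cv + 1.23 * unit(d)
    hv <- nv + 0.98 * unit(d)
    nm <- c("N", "H", "CA", "C", "O", at$names)
    xyz <- rbind(nv, hv, ca, cv, ov, at$xyz)
    tp <- residue_template(ty)
    mi <- match(nm, tp$atoms$name)
    rows[[k]] <- atom_table(
      name = nm, element = tp$atoms$element[mi],
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = "A",
      resno = k, resname = ty, comp_kind = "protein",
      charge = tp$atoms$charge[mi],
      eps = .lj_lookup(tp$atoms$element[mi])$eps,
      sigma = .lj_lookup(tp$atoms$element[mi])$sigma,
      hb_role = tp$atoms$hb_role[mi])
  }
  # cofactor: planar six-ring parallel to the ligand plane, offset in -y
  cof_cen <- c(0, -6.2, 0)
  cof_xyz <- t(vapply(0:5, function(i) {
    th <- (90 + i * 60) * pi / 180
    cof_cen + c(1.4 * cos(th), 1.4 * sin(th), 0)
  }, numeric(3)))
  cof_names <- c("C2", "C3", "C4", "N1", "C5", "C6")  # N1 on the -y rim
  cof_el <- ifelse(cof_names == "N1", "N", "C")
  cof_q <- ifelse(cof_names == "N1", -0.3,
                  ifelse(cof_names %in% c("C4", "C5"), 0.15, 0))
  cof <- atom_table(
    name = cof_names, element = cof_el, x = cof_xyz[, 1], y = cof_xyz[, 2],
    z = cof_xyz[, 3], chain = "X", resno = 202L, resname = "NAP",
    comp_kind = "cofactor", charge = cof_q,
    eps = .lj_lookup(cof_el)$eps, sigma = .lj_lookup(cof_el)$sigma,
    hb_role = ifelse(cof_el == "N", "acceptor", "none"))
  # catalytic water between ligand edge and cofactor, above the plane
  w0 <- c(0, -4.4, 3.3)
  wdir1 <- unit(cof_cen - w0)
  wdir2 <- unit(c(0.5, 0.2, 1))
  wat <- atom_table(
    name = c("O", "H1", "H2"), element = c("O", "H", "H"),
    x = c(w0[1], w0[1] + 0.96 * wdir1[1], w0[1] + 0.96 * wdir2[1]),
    y = c(w0[2], w0[2] + 0.96 * wdir1[2], w0[2] + 0.96 * wdir2[2]),
    z = c(w0[3], w0[3] + 0.96 * wdir1[3], w0[3] + 0.96 * wdir2[3]),
    chain = "X", resno = 203L, resname = "HOH",
    comp_kind = "catalytic_water",
    charge = c(-0.834, 0.417, 0.417),
    eps = .lj_lookup(c("O", "H", "H"))$eps,
    sigma = .lj_lookup(c("O", "H", "H"))$sigma,
    hb_role = c("both", "none", "none"))
  atoms <- rbind(do.call(rbind, rows), cof, wat, lig$atoms)
  ser_id <- paste0("A:", sort(which(types == "SER")))
  s <- new_structure(atoms, active_residues = ser_id,
                     catalytic_water = "X:203",
                     ligand_info = list(name = lig$name, bonds = lig$bonds,
                                        order = lig$order,
                                        torsions = lig$torsions),
                     provenance = "make_mini_pocket", prepared = TRUE)
  validate_structure(s)
  # settle: snap side chains to their best library rotamers (so the
  # planted state is a repacker fixed point), then relax all residue
  # dihedrals and the hetero components; one more repack/minimise pass
  # resolves cross-talk
  lib <- default_rotamer_library()
  all_res <- res_ids(s, "protein")
  s <- repack_side_chains(s, all_res, lib, p)
  mn <- minimize_energy(s, p, flexible_ids = all_res, max_iter = 60)
  s <- repack_side_chains(mn$structure, all_res, lib, p)
  mn <- minimize_energy(s, p, flexible_ids = all_res, max_iter = 60)
  # final high-precision polish of the hetero components sharpens the
  # planted minimum
  mn <- minimize_energy(mn$structure, p, flexible_ids = character(),
                        max_iter = 120, gtol = 1e-5)
  # short basin search: the planted state must be the deepest
  # component placement reachable from its neighbourhood, so restarts
  # from perturbed ligand/cofactor/water placements that find a lower
  # minimum are adopted (repeated while improvements appear)
  bspec <- move_spec(ligand_translation_max = 0.8,
                     ligand_rotation_max = 15)
  for (round in 1:3) {
    improved <- FALSE
    for (j in 1:6) {
      sp <- mn$structure
      for (kind in c("ligand", "cofactor", "catalytic_water"))
        sp <- perturb_component(sp, kind, bspec)
      mj <- minimize_energy(sp, p, flexible_ids = character(),
                            max_iter = 100, gtol = 1e-5)
      if (is.finite(mj$energy) && mj$energy < mn$energy - 1e-6) {
        mn <- mj
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  s <- mn$structure
  if (!is.finite(mn$energy)) return(NULL)
  # anchor harmonic backbone tethers on the fully relaxed scaffold:
  # they stand in for the rigidity of the protein core this pocket
  # fragment was cut from, while side chains stay free; the planted
  # state carries zero restraint energy by construction
  # the cofactor is also tethered (weakly): in the template enzyme the
  # nicotinamide ring sits in its own groove, which this fragment lacks
  bb <- which((s$atoms$comp_kind == "protein" &
                 s$atoms$name %in% c("N", "CA", "C", "O")) |
                s$atoms$comp_kind == "cofactor")
  s$tethers <- list(keys = paste(s$atoms$chain[bb], s$atoms$resno[bb],
                                 s$atoms$name[bb], sep = ":"),
                    ref = coords(s)[bb, , drop = FALSE], k = 3.0)
  # feasibility: the planted ligand must sit attractively in the pocket
  ei <- .energy_inputs(s)
  lig_rows <- which(s$atoms$comp_kind == "ligand")
  e_int <- .group_energy(ei, lig_rows, p)
  if (e_int > -3) return(NULL)
  planted <- coords(s)[s$atoms$comp_kind == "ligand", , drop = FALSE]
  out <- list(structure = s, planted_pose = planted, seed = NA_integer_,
              descriptor = list(n_residues = n_residues,
                                complementarity = complementarity,
                                serine = ser_id,
                                energy = mn$energy))
  class(out) <- "SyntheticSystem"
  out
}

.verify_planted_minimum <- function(s, p, n_trials = 20, magnitude = 0.3) {
  e0 <- complex_energy(s, p)$total
  rows <- which(s$atoms$comp_kind == "ligand")
  m0 <- coords(s)
  raised <- 0L
  for (j in seq_len(n_trials)) {
    m <- m0
    cen <- colMeans(m[rows, , drop = FALSE])
    R <- random_rotation(5 * magnitude)
    pturb <- sweep(m[rows, , drop = FALSE], 2, cen) %*% t(R)
    dir <- stats::rnorm(3); dir <- unit(dir)
    m[rows, ] <- sweep(pturb, 2, cen + magnitude * dir, `+`)
    e <- complex_energy(set_coords(s, m), p)$total
    if (e > e0) raised <- raised + 1L
  }
  list(e0 = e0, frac_raised = raised / n_trials)
}

#' @export
print.SyntheticSystem <- function(x, ...) {
  cat("SyntheticSystem: seed", x$seed, "-",
      x$descriptor$n_residues, "pocket residues, complementarity",
      x$descriptor$complementarity, "\n")
  print(x$structure)
  invisible(x)
}

# clearly-nonisomorphic check on small molecular graphs: differing
# cycle rank or differing degree sequence suffices
.graphs_distinct <- function(n1, bonds1, n2, bonds2) {
  rank1 <- nrow(bonds1) - n1 + 1L
  rank2 <- nrow(bonds2) - n2 + 1L
  if (rank1 != rank2) return(TRUE)
  deg <- function(n, b) sort(tabulate(c(b[, 1], b[, 2]), nbins = n))
  !identical(deg(n1, bonds1), deg(n2, bonds2))
}

#' Generate property-matched decoy ligands
#'
#' Each decoy matches the active ligand's heavy-atom count to within 2
#' and its net formal charge, but has a different bond topology
#' (acyclic, possibly branched, versus the active's ring; enforced by
#' a cycle-rank / degree-sequence check) with the polar oxygen placed
#' at a scrambled position along the chain.
#'
#' @param active the active `Ligand`.
#' @param n number of decoys (the validation set size is 6 by
#'   convention).
#' @param seed integer seed.
#' @return list of `Ligand`s named DEC1..DECn.
#' @export
make_decoy_ligands <- function(active, n = 6, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  n_heavy <- sum(!active$atoms$is_h)
  q_active <- ligand_net_charge(active)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      nh <- n_heavy + sample(0:2, 1)
      o_pos <- sample(2:(nh - 3), 1)
      branch <- sample(3:(nh - 3), 1)
      dec <- .build_chain_ligand(nh, o_pos, branch, paste0("DEC", i))
      if (.graphs_distinct(nrow(dec$atoms), dec$bonds,
                           nrow(active$atoms), active$bonds) &&
          ligand_net_charge(dec) == q_active &&
          .polar_geometry_scrambled(dec, active))
        break
      dec <- NULL
    }
    if (is.null(dec)) stop("failed to generate a topology-distinct decoy")
    out[[i]] <- dec
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# a decoy's polar-atom placement must be genuinely scrambled: its
# oxygen-oxygen through-space spacing has to differ from the active's
# by at least 1.2 A, so it cannot silently reproduce the active's
# pharmacophore geometry
.polar_geometry_scrambled <- function(dec, active) {
  oo <- function(l) {
    o <- which(l$atoms$element == "O")
    if (length(o) < 2) return(NA_real_)
    stats::dist(as.matrix(l$atoms[o, c("x", "y", "z")]))[1]
  }
  d1 <- oo(dec); d2 <- oo(active)
  if (is.na(d1) || is.na(d2)) return(TRUE)
  abs(d1 - d2) >= 1.2
}

# zigzag heavy-atom chain with an optional one-atom branch; atom o_pos
# is a hydroxyl oxygen (with hydrogen) and the chain terminus is a
# carbonyl-like oxygen, matching the active's polar-atom count with a
# scrambled relative geometry
.build_chain_ligand <- function(n_heavy, o_pos, branch, name) {
  main <- if (is.na(branch)) n_heavy else n_heavy - 1L
  # rigid helical backbone: genuinely three-dimensional bulk, unlike
  # the flat ring of the active
  xyz <- t(vapply(seq_len(main), function(i)
    c((i - 1) * 1.15, 0.95 * cos(i * 2.0), 0.95 * sin(i * 2.0)),
    numeric(3)))
  bonds <- if (main > 1) cbind(seq_len(main - 1), 2:main)
           else matrix(integer(), 0, 2)
  element <- rep("C", main)
  if (!is.na(branch)) {
    bpar <- min(branch, main - 1L)
    off <- unit(xyz[bpar, ] - c(xyz[bpar, 1], 0, 0))
    xyz <- rbind(xyz, xyz[bpar, ] + 1.5 * off)
    bonds <- rbind(bonds, c(bpar, main + 1L))
    element <- c(element, "C")
  }
  o_pos <- min(max(2L, o_pos), main - 2L)
  element[o_pos] <- "O"
  element[main] <- "O"  # terminal acceptor oxygen
  # hydroxyl hydrogen on the interior oxygen
  h_xyz <- xyz[o_pos, ] + c(0, 0.35, 0.9)
  xyz <- rbind(xyz, h_xyz)
  element <- c(element, "H")
  bonds <- rbind(bonds, c(o_pos, nrow(xyz)))
  lj <- .lj_lookup(element)
  pars <- ligand_atom_parameters(element, bonds)
  atoms <- atom_table(
    name = paste0(element, seq_along(element)), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = "X", resno = 201L,
    resname = "LIG", comp_kind = "ligand", charge = pars$charge,
    eps = lj$eps, sigma = lj$sigma, hb_role = pars$hb_role)
  # property matching includes flexibility: like the active, the decoy
  # exposes a single rotatable torsion (the hydroxyl), the scaffold
  # being treated as rigid
  all_tors <- detect_rotatable_torsions(bonds, element)
  oh_tors <- Filter(function(tq) any(element[tq[2:3]] == "O"), all_tors)
  tors <- if (length(oh_tors)) oh_tors[1] else all_tors[seq_len(min(1,
    length(all_tors)))]
  new_ligand(atoms, bonds, name = name, torsions = tors)
}

#' Perturb the planted ligand pose
#'
#' Displaces the ligand by a random rigid motion whose expected
#' heavy-atom RMSD is approximately `magnitude` (translation of norm
#' ~U(0.9, 1.05) x magnitude plus a small rotation scaling with
#' magnitude); the rest of the system is untouched. `magnitude = 0` is
#' the identity.
#'
#' @param sys `SyntheticSystem`.
#' @param magnitude target displacement, Angstrom.
#' @param seed integer seed.
#' @return perturbed `Structure`.
#' @export
perturb_pose <- function(sys, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  s <- sys$structure
  if (magnitude == 0) return(s)
  set.seed(seed)
  rows <- which(s$atoms$comp_kind == "ligand")
  m <- coords(s)
  cen <- colMeans(m[rows, , drop = FALSE])
  R <- random_rotation(5 * magnitude)
  pt <- sweep(m[rows, , drop = FALSE], 2, cen) %*% t(R)
  dir <- stats::rnorm(3); while (vnorm(dir) < 1e-8) dir <- stats::rnorm(3)
  shift <- unit(dir) * magnitude * stats::runif(1, 0.9, 1.05)
  m[rows, ] <- sweep(pt, 2, cen + shift, `+`)
  set_coords(s, m)
}
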