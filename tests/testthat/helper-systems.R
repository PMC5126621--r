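# Shared fixtures. Synthetic systems are expensive to generate, so they
# are built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

test_system <- function(seed = 42, n_residues = 15) {
  cached(paste0("sys_", seed, "_", n_residues),
         make_mini_pocket(seed = seed, n_residues = n_residues))
}

# reduced-scale refinement configuration used by the slower end-to-end
# tests: 20 decoys of 1 x 1 x 2 steps, shallow per-step minimisation,
# convergence at the 0.05-0.1 kcal/mol granularity of the fixture's
# micro-minima
fast_cfg <- function(seed = 1, n_decoys = 20, max_K = 5,
                     convergence_tol = 0.1)
  refinement_config(outer_cycles = 1, mid_blocks = 1, inner_steps = 2,
                    n_decoys = n_decoys, inner_min_iter = 6, seed = seed,
                    max_K = max_K, convergence_tol = convergence_tol)

# an extended all-trans peptide chain (bond directions alternate +/-25
# degrees about +x, as in a beta strand), so psi(i-1) and phi(i) axes
# are near-parallel as in real backbones
make_test_chain <- function(n = 10, resname = "GLY") {
  tilt <- function(k) (if (k %% 2 == 0) 1 else -1) * 25 * pi / 180
  bdir <- function(k) c(cos(tilt(k)), sin(tilt(k)), 0)
  pos <- c(0, 0, 0)
  k <- 0
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    N <- pos
    k <- k + 1; CA <- N + 1.46 * bdir(k)
    k <- k + 1; C <- CA + 1.52 * bdir(k)
    O <- C + 1.23 * c(0, 0, 1)
    H <- N + 0.98 * c(0, 0, -1)
    rows[[i]] <- atom_table(name = c("N", "H", "CA", "C", "O"),
                            element = c("N", "H", "C", "C", "O"),
                            x = c(N[1], H[1], CA[1], C[1], O[1]),
                            y = c(N[2], H[2], CA[2], C[2], O[2]),
                            z = c(N[3], H[3], CA[3], C[3], O[3]),
                            chain = "A", resno = i, resname = resname,
                            comp_kind = "protein")
    k <- k + 1; pos <- C + 1.33 * bdir(k)
  }
  s <- new_structure(do.call(rbind, rows))
  s <- pocketmc:::.assign_parameters(s)
  s$prepared <- TRUE
  s
}

# small PDB text fixture: two protein residues, one NAP group, three
# waters, one GOL, and a 3-atom ligand
fixture_pdb_text <- function() {
  fmt <- function(serial, name, resn, chain, resno, x, y, z, el,
                  rec = "ATOM") {
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, resn, chain, resno, x, y, z, el)
  }
  lines <- c(
    fmt(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    fmt(2, "CA", "ALA", "A", 1, 1.45, 0.3, 0.0, "C"),
    fmt(3, "C", "ALA", "A", 1, 2.3, 0.0, 1.1, "C"),
    fmt(4, "O", "ALA", "A", 1, 2.0, 0.4, 2.2, "O"),
    fmt(5, "CB", "ALA", "A", 1, 1.8, 1.6, -0.8, "C"),
    fmt(6, "N", "SER", "A", 2, 3.4, -0.7, 0.9, "N"),
    fmt(7, "CA", "SER", "A", 2, 4.4, -1.0, 1.9, "C"),
    fmt(8, "C", "SER", "A", 2, 5.7, -1.4, 1.3, "C"),
    fmt(9, "O", "SER", "A", 2, 5.8, -2.0, 0.2, "O"),
    fmt(10, "CB", "SER", "A", 2, 4.6, 0.2, 2.9, "C"),
    fmt(11, "OG", "SER", "A", 2, 5.3, 1.3, 2.3, "O"),
    fmt(12, "C1", "NAP", "A", 101, 8.0, 0.0, 0.0, "C", "HETATM"),
    fmt(13, "C2", "NAP", "A", 101, 9.4, 0.0, 0.0, "C", "HETATM"),
    fmt(14, "O", "HOH", "A", 201, 10.0, 3.0, 1.0, "O", "HETATM"),
    fmt(15, "O", "HOH", "A", 202, 12.0, 3.0, 1.0, "O", "HETATM"),
    fmt(16, "O", "HOH", "A", 203, 14.0, 3.0, 1.0, "O", "HETATM"),
    fmt(17, "C1", "GOL", "A", 301, 0.0, 5.0, 0.0, "C", "HETATM"),
    fmt(18, "O1", "GOL", "A", 301, 1.2, 5.4, 0.6, "O", "HETATM"),
    fmt(19, "C1", "UNL", "A", 401, 6.0, 4.0, 4.0, "C", "HETATM"),
    fmt(20, "C2", "UNL", "A", 401, 7.5, 4.0, 4.0, "C", "HETATM"),
    fmt(21, "O1", "UNL", "A", 401, 8.1, 5.1, 4.4, "O", "HETATM"),
    "END")
  paste(lines, collapse = "\n")
}

# independent R-level brute-force nonbonded oracle (no switching test
# shortcuts: re-derives LJ, Coulomb and the H-bond rule from scratch)
oracle_nonbonded <- function(s, p) {
  s <- ensure_topology(s)
  a <- s$atoms
  m <- coords(s)
  tp <- s$topology
  excl <- matrix(FALSE, nrow(a), nrow(a))
  if (nrow(tp$excl) > 0) {
    excl[tp$excl] <- TRUE
    excl[tp$excl[, c(2, 1), drop = FALSE]] <- TRUE
  }
  sw <- function(r, cutoff, wdt) {
    if (r >= cutoff) 0
    else if (r <= cutoff - wdt) 1
    else { t <- (cutoff - r) / wdt; t * t * (3 - 2 * t) }
  }
  lj <- 0; coul <- 0; hb <- 0
  for (i in seq_len(nrow(a) - 1)) for (j in seq(i + 1, nrow(a))) {
    if (excl[i, j]) next
    r <- sqrt(sum((m[i, ] - m[j, ])^2))
    if (r >= p$nonbonded_cutoff) next
    sg <- (a$sigma[i] + a$sigma[j]) / 2
    ep <- sqrt(a$eps[i] * a$eps[j])
    s_r <- sw(r, p$nonbonded_cutoff, p$switch_width)
    lj <- lj + s_r * 4 * ep * ((sg / r)^12 - (sg / r)^6)
    coul <- coul + s_r * p$coulomb_constant * a$charge[i] * a$charge[j] /
      (4 * r^2)
  }
  for (h in which(tp$don > 0)) {
    D <- tp$don[h]
    for (acc in which(tp$acc == 1)) {
      if (acc == D || acc == h || excl[D, acc]) next
      dDA <- sqrt(sum((m[D, ] - m[acc, ])^2))
      if (dDA >= p$hbond_distance_cutoff) next
      u <- m[D, ] - m[h, ]; v <- m[acc, ] - m[h, ]
      ang <- acos(min(1, max(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang < p$hbond_angle_cutoff) next
      fang <- (ang - p$hbond_angle_cutoff) / (180 - p$hbond_angle_cutoff)
      hb <- hb - p$hbond_well_depth * sw(dDA, p$hbond_distance_cutoff, 0.4) *
        fang
    }
  }
  list(lj = lj, coulomb = coul, hbond = hb)
}

# one small screen (active + 2 decoy ligands, both position classes) is
# built once and shared between the screen and acceptance checks
small_screen <- function() {
  cached("screen_small", {
    sys <- test_system()
    active <- ligand_from_structure(sys$structure)
    decs <- make_decoy_ligands(active, n = 2, seed = 42)
    ligs <- c(stats::setNames(list(active), active$name), decs)
    cfg <- screen_config(
      refinement = fast_cfg(n_decoys = 5, max_K = 3),
      positions = c("unproductive", "productive"), seed = 8)
    run_screen(sys, ligs, cfg)
  })
}
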