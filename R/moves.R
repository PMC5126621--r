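# Perturbation operators: flexible-residue selection, backbone
# small/shear moves (with standard downstream propagation along the
# chain), discrete side-chain repacking over a rotamer library, and
# rigid-body / torsion perturbation of hetero components.

#' Move magnitudes
#'
#' @param small_max_angle maximum |delta| for small-move phi/psi draws,
#'   degrees.
#' @param shear_max_angle maximum shear delta, degrees.
#' @param ligand_translation_max maximum rigid-body translation norm,
#'   Angstrom.
#' @param ligand_rotation_max maximum rigid-body rotation (and ligand
#'   torsion twist), degrees.
#' @param rng_seed optional integer seed recorded alongside the move magnitudes.
#' @return object of class `MoveSpec`.
#' @export
move_spec <- function(small_max_angle = 5, shear_max_angle = 5,
                      ligand_translation_max = 0.5,
                      ligand_rotation_max = 10, rng_seed = NULL) {
  stopifnot(small_max_angle >= 0, shear_max_angle >= 0,
            ligand_translation_max >= 0, ligand_rotation_max >= 0)
  sp <- list(small_max_angle = small_max_angle,
             shear_max_angle = shear_max_angle,
             ligand_translation_max = ligand_translation_max,
             ligand_rotation_max = ligand_rotation_max,
             rng_seed = rng_seed)
  class(sp) <- "MoveSpec"
  sp
}

#' Select flexible residues around the binding site
#'
#' First-cycle rule: every protein residue with any atom within
#' `radius` of any cofactor or ligand atom, united with the declared
#' active residues. Later cycles: residues within `radius` of ligand
#' atoms only. The result is sorted (chain, resno), so it does not
#' depend on input atom ordering.
#'
#' @param s Structure containing a ligand.
#' @param first_cycle logical; use the first-cycle rule?
#' @param radius selection distance in Angstrom (default 4).
#' @return character vector of residue ids.
#' @export
select_flexible_residues <- function(s, first_cycle = FALSE, radius = 4) {
  stopifnot(radius > 0)
  a <- s$atoms
  lig <- a$comp_kind == "ligand"
  if (!any(lig)) stop("structure has no ligand component")
  target <- lig
  if (first_cycle) target <- target | a$comp_kind == "cofactor"
  tc <- coords(s)[target, , drop = FALSE]
  ids <- atom_res_ids(s)
  sel <- character()
  for (id in res_ids(s, "protein")) {
    rows <- which(ids == id)
    pc <- coords(s)[rows, , drop = FALSE]
    d2 <- outer(rowSums(pc^2), rowSums(tc^2), `+`) - 2 * pc %*% t(tc)
    if (min(d2) <= radius^2) sel <- c(sel, id)
  }
  if (first_cycle) sel <- union(sel, s$active_residues)
  key <- do.call(rbind, strsplit(sel, ":", fixed = TRUE))
  if (length(sel)) sel <- sel[order(key[, 1], as.numeric(key[, 2]))]
  sel
}

# residues strictly after `id` in the same protein chain
.downstream_rows <- function(s, id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  a <- s$atoms
  which(a$comp_kind == "protein" & a$chain == parts[1] &
          a$resno > as.numeric(parts[2]))
}

.named_row <- function(s, rows, name) {
  r <- rows[s$atoms$name[rows] == name]
  if (length(r) != 1) return(NA_integer_)
  r
}

# rotate phi (about N-CA) or psi (about CA-C) by delta degrees, moving
# the standard downstream subtree
.rotate_backbone <- function(s, id, which_angle, delta) {
  if (abs(delta) < 1e-15) return(s)
  rows <- residue_rows(s, id)
  m <- coords(s)
  N <- .named_row(s, rows, "N"); CA <- .named_row(s, rows, "CA")
  C <- .named_row(s, rows, "C")
  if (any(is.na(c(N, CA, C)))) stop("residue ", id, " lacks backbone atoms")
  down <- .downstream_rows(s, id)
  if (which_angle == "phi") {
    moving <- c(setdiff(rows, c(N, rows[s$atoms$name[rows] == "H"])), down)
    moving <- setdiff(moving, CA)  # on the axis
    m[moving, ] <- rotate_about_axis(m[moving, , drop = FALSE],
                                     m[N, ], m[CA, ] - m[N, ], delta)
  } else {
    O <- rows[s$atoms$name[rows] == "O"]
    moving <- c(O, down)
    m[moving, ] <- rotate_about_axis(m[moving, , drop = FALSE],
                                     m[CA, ], m[C, ] - m[CA, ], delta)
  }
  set_coords(s, m)
}

#' Backbone phi/psi dihedrals of a residue
#' @param s Structure.
#' @param id residue id.
#' @return named numeric vector `c(phi=, psi=)`; `NA` at chain termini.
#' @export
residue_phi_psi <- function(s, id) {
  rows <- residue_rows(s, id)
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  m <- coords(s)
  N <- .named_row(s, rows, "N"); CA <- .named_row(s, rows, "CA")
  C <- .named_row(s, rows, "C")
  prev <- residue_rows(s, paste0(parts[1], ":", as.numeric(parts[2]) - 1))
  nxt <- residue_rows(s, paste0(parts[1], ":", as.numeric(parts[2]) + 1))
  Cp <- if (length(prev)) .named_row(s, prev, "C") else NA_integer_
  Nn <- if (length(nxt)) .named_row(s, nxt, "N") else NA_integer_
  phi <- if (!is.na(Cp)) dihedral_angle(m[Cp, ], m[N, ], m[CA, ], m[C, ])
         else NA_real_
  psi <- if (!is.na(Nn)) dihedral_angle(m[N, ], m[CA, ], m[C, ], m[Nn, ])
         else NA_real_
  c(phi = phi, psi = psi)
}

#' Apply a small move to one residue
#'
#' Perturbs phi and psi by independent uniform draws in
#' `[-small_max_angle, +small_max_angle]`; the side chain is carried
#' rigidly and the change propagates downstream along the chain.
#' Consumes two draws from the current RNG stream.
#'
#' @param s Structure.
#' @param id residue id.
#' @param spec `MoveSpec`.
#' @return updated Structure.
#' @export
apply_small_move <- function(s, id, spec = move_spec()) {
  mx <- spec$small_max_angle
  dphi <- stats::runif(1, -mx, mx)
  dpsi <- stats::runif(1, -mx, mx)
  s <- .rotate_backbone(s, id, "phi", dphi)
  .rotate_backbone(s, id, "psi", dpsi)
}

#' Apply a shear move to two adjacent residues
#'
#' Draws delta uniform in `[0, shear_max_angle]` and applies +delta to
#' the phi of the later residue and -delta to the psi of the earlier
#' one, so downstream displacement largely cancels.
#'
#' @param s Structure.
#' @param id1,id2 adjacent residue ids (same chain, consecutive resno).
#' @param spec `MoveSpec`.
#' @return updated Structure.
#' @export
apply_shear_move <- function(s, id1, id2, spec = move_spec()) {
  p1 <- strsplit(id1, ":", fixed = TRUE)[[1]]
  p2 <- strsplit(id2, ":", fixed = TRUE)[[1]]
  if (p1[1] != p2[1] || abs(as.numeric(p1[2]) - as.numeric(p2[2])) != 1)
    stop("shear move requires adjacent residues in one chain")
  if (as.numeric(p1[2]) > as.numeric(p2[2])) { tmp <- id1; id1 <- id2; id2 <- tmp }
  delta <- stats::runif(1, 0, spec$shear_max_angle)
  s <- .rotate_backbone(s, id2, "phi", delta)
  .rotate_backbone(s, id1, "psi", -delta)
}

# ---- Rotamers --------------------------------------------------------

#' Built-in minimal rotamer library
#'
#' Chi angles at all combinations of -60/+60/180 degrees with uniform
#' prior probabilities, for every residue type with a chi definition in
#' the template table; chi-less residues get a single empty rotamer.
#'
#' @return object of class `RotamerLibrary`: per res_name a list with
#'   `chis` (matrix, one row per rotamer) and `prob`.
#' @export
default_rotamer_library <- function() {
  lib <- list()
  for (rn in names(.residue_templates)) {
    if (rn == "HOH") next
    tp <- .residue_templates[[rn]]
    k <- length(tp$chi)
    if (k == 0) {
      lib[[rn]] <- list(chis = matrix(numeric(), 1, 0), prob = 1)
    } else {
      grid <- as.matrix(expand.grid(rep(list(c(-60, 60, 180)), k)))
      colnames(grid) <- NULL
      lib[[rn]] <- list(chis = grid, prob = rep(1 / nrow(grid), nrow(grid)))
    }
  }
  class(lib) <- "RotamerLibrary"
  lib
}

#' Current side-chain chi angles of a residue
#' @param s Structure.
#' @param id residue id.
#' @return numeric vector (may be length 0).
#' @export
residue_chis <- function(s, id) {
  rows <- residue_rows(s, id)
  tp <- residue_template(s$atoms$resname[rows[1]])
  if (is.null(tp) || length(tp$chi) == 0) return(numeric())
  m <- coords(s)
  vapply(tp$chi, function(ch) {
    idx <- vapply(ch$dihedral, function(nm) .named_row(s, rows, nm), 1L)
    dihedral_angle(m[idx[1], ], m[idx[2], ], m[idx[3], ], m[idx[4], ])
  }, numeric(1))
}

# set one chi angle to a target value (degrees)
.set_chi <- function(s, rows, tp, k, target) {
  ch <- tp$chi[[k]]
  m <- coords(s)
  idx <- vapply(ch$dihedral, function(nm) .named_row(s, rows, nm), 1L)
  cur <- dihedral_angle(m[idx[1], ], m[idx[2], ], m[idx[3], ], m[idx[4], ])
  ax <- vapply(ch$axis, function(nm) .named_row(s, rows, nm), 1L)
  moving <- rows[s$atoms$name[rows] %in% ch$moving]
  m[moving, ] <- rotate_about_axis(m[moving, , drop = FALSE], m[ax[1], ],
                                   m[ax[2], ] - m[ax[1], ],
                                   wrap_angle(target - cur))
  set_coords(s, m)
}

#' Discrete side-chain repacking
#'
#' Assigns each flexible residue the library rotamer minimising its
#' interaction energy with the fixed environment (plus its own chi
#' torsion prior), sweeping residue-by-residue to a fixed point (at
#' most `max_sweeps` sweeps). Backbone atoms never move.
#'
#' @param s prepared Structure.
#' @param residues character vector of residue ids to repack.
#' @param lib `RotamerLibrary`.
#' @param p `EnergyParams`.
#' @param max_sweeps maximum sweeps over the residue set.
#' @return updated Structure.
#' @export
repack_side_chains <- function(s, residues,
                               lib = default_rotamer_library(),
                               p = default_energy_params(),
                               max_sweeps = 5) {
  if (length(residues) == 0) return(s)
  residues <- sort(residues)
  ids <- atom_res_ids(s)
  for (id in residues) {
    rn <- s$atoms$resname[ids == id][1]
    if (is.na(rn)) stop("unknown residue id ", id)
    if (is.null(lib[[rn]]))
      stop("no rotamer entry for residue type ", rn)
  }
  # precompute topology-level information once; the sweep loop then
  # works on a bare coordinate matrix with direct C++ energy calls
  ei <- .energy_inputs(s)
  s <- ei$s
  m <- ei$coords
  pars <- .pars_list(p)
  w <- p$term_weights
  n <- nrow(m)
  info <- list()
  for (id in residues) {
    rows <- residue_rows(s, id)
    rn <- s$atoms$resname[rows[1]]
    tp <- residue_template(rn)
    entry <- lib[[rn]]
    if (ncol(entry$chis) == 0 || is.null(tp) || length(tp$chi) == 0) next
    group <- rows[s$atoms$name[rows] %in%
                    unique(unlist(lapply(tp$chi, `[[`, "moving")))]
    active <- integer(n); active[group] <- 1L
    quads <- ei$quads
    own <- quads[rowSums(matrix(quads %in% rows, nrow = nrow(quads))) == 4,
                 , drop = FALSE]
    chi_def <- lapply(tp$chi, function(ch) list(
      idx = vapply(ch$dihedral, function(nm) .named_row(s, rows, nm), 1L),
      ax = vapply(ch$axis, function(nm) .named_row(s, rows, nm), 1L),
      moving = rows[s$atoms$name[rows] %in% ch$moving]))
    info[[id]] <- list(entry = entry, active = active, own = own,
                       chi = chi_def)
  }
  score <- function(mm, inf) {
    nb <- nb_terms_cpp(mm, ei$q, ei$eps, ei$sig, ei$don, ei$acc,
                       ei$excl_i, ei$excl_j, pars, inf$active, 2L)
    w[["lj"]] * nb[["lj"]] + w[["coulomb"]] * nb[["coulomb"]] +
      w[["hbond"]] * nb[["hbond"]] +
      w[["torsion"]] * torsion_energy_cpp(mm, inf$own, p$torsion_k)
  }
  set_chis <- function(mm, inf, targets) {
    for (k in seq_along(inf$chi)) {
      cd <- inf$chi[[k]]
      cur <- dihedral_angle(mm[cd$idx[1], ], mm[cd$idx[2], ],
                            mm[cd$idx[3], ], mm[cd$idx[4], ])
      mm[cd$moving, ] <- rotate_about_axis(
        mm[cd$moving, , drop = FALSE], mm[cd$ax[1], ],
        mm[cd$ax[2], ] - mm[cd$ax[1], ], wrap_angle(targets[k] - cur))
    }
    mm
  }
  picked <- stats::setNames(rep(NA_integer_, length(info)), names(info))
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (id in names(info)) {
      inf <- info[[id]]
      best_e <- Inf; best_m <- m; best_r <- NA_integer_
      for (r in seq_len(nrow(inf$entry$chis))) {
        mm <- set_chis(m, inf, inf$entry$chis[r, ])
        e <- score(mm, inf)
        if (e < best_e - 1e-9) { best_e <- e; best_m <- mm; best_r <- r }
      }
      if (!identical(best_r, picked[[id]])) changed <- TRUE
      picked[[id]] <- best_r
      m <- best_m
    }
    if (!changed) break
  }
  set_coords(s, m)
}

# ---- Component perturbation -----------------------------------------

#' Rigid-body (and torsion) perturbation of a hetero component
#'
#' Applies a random rigid-body translation (norm <= max) and rotation
#' about the component centroid (angle <= max); a ligand additionally
#' receives one random rotatable-torsion twist. Refuses protein chains.
#'
#' @param s Structure.
#' @param kind one of "ligand", "cofactor", "catalytic_water".
#' @param spec `MoveSpec`.
#' @return updated Structure.
#' @export
perturb_component <- function(s, kind, spec = move_spec()) {
  if (!kind %in% c("ligand", "cofactor", "catalytic_water"))
    stop("moves apply to hetero components only, not ", kind)
  rows <- which(s$atoms$comp_kind == kind)
  if (length(rows) == 0) stop("no ", kind, " component present")
  m <- coords(s)
  cen <- colMeans(m[rows, , drop = FALSE])
  R <- random_rotation(spec$ligand_rotation_max)
  p <- sweep(m[rows, , drop = FALSE], 2, cen)
  p <- p %*% t(R)
  dir <- stats::rnorm(3); while (vnorm(dir) < 1e-8) dir <- stats::rnorm(3)
  shift <- unit(dir) * stats::runif(1, 0, spec$ligand_translation_max)
  m[rows, ] <- sweep(p, 2, cen + shift, `+`)
  s <- set_coords(s, m)
  if (kind == "ligand" && length(s$ligand_info$torsions) > 0) {
    ti <- if (length(s$ligand_info$torsions) == 1) 1L else
      sample.int(length(s$ligand_info$torsions), 1)
    tw <- stats::runif(1, -spec$ligand_rotation_max,
                       spec$ligand_rotation_max)
    s <- .twist_ligand_torsion(s, ti, tw)
  }
  s
}

# rotate the ligand subtree on the far side of torsion bond (b, c)
.twist_ligand_torsion <- function(s, torsion_index, delta) {
  rows <- which(s$atoms$comp_kind == "ligand")
  tq <- s$ligand_info$torsions[[torsion_index]]
  b <- tq[2]; cc <- tq[3]
  n <- length(rows)
  adj <- .adjacency(n, s$ligand_info$bonds)
  seen <- logical(n); seen[b] <- TRUE; seen[cc] <- TRUE; queue <- cc
  sub <- cc
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; sub <- c(sub, w); queue <- c(queue, w)
    }
  }
  moving <- rows[setdiff(sub, cc)]
  if (length(moving) == 0) return(s)
  m <- coords(s)
  m[moving, ] <- rotate_about_axis(m[moving, , drop = FALSE],
                                   m[rows[b], ], m[rows[cc], ] - m[rows[b], ],
                                   delta)
  set_coords(s, m)
}
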