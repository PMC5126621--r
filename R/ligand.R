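# Ligand container: explicit atoms + bond graph + rotatable torsions.
# Small molecules are kept separate from Structure so that the same
# ligand can be placed, perturbed and swapped between complexes.

#' Construct a Ligand
#'
#' @param atoms atom table (see [atom_table()]); `comp_kind` should be
#'   "ligand".
#' @param bonds m x 2 matrix of atom indices (rows of `atoms`).
#' @param order integer bond orders (length m).
#' @param name ligand label.
#' @param torsions optional list of length-4 atom-index vectors defining
#'   rotatable torsions; autodetected from the bond graph when `NULL`.
#' @return object of class `Ligand`.
#' @export
new_ligand <- function(atoms, bonds, order = rep(1L, nrow(bonds)),
                       name = "LIG", torsions = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && max(bonds) > nrow(atoms))
    stop("bond indices reference missing atoms")
  if (!.graph_connected(nrow(atoms), bonds))
    stop("ligand bond graph is not connected")
  if (is.null(torsions))
    torsions <- detect_rotatable_torsions(bonds, toupper(atoms$element))
  for (tq in torsions) {
    ok <- any((bonds[, 1] == tq[2] & bonds[, 2] == tq[3]) |
              (bonds[, 1] == tq[3] & bonds[, 2] == tq[2]))
    if (!ok) stop("rotatable torsion does not lie on an existing bond")
  }
  l <- list(atoms = atoms, bonds = bonds, order = as.integer(order),
            torsions = torsions, name = name)
  class(l) <- "Ligand"
  l
}

#' @export
print.Ligand <- function(x, ...) {
  cat("Ligand", x$name, ":", nrow(x$atoms), "atoms (",
      sum(!x$atoms$is_h), "heavy ),", nrow(x$bonds), "bonds,",
      length(x$torsions), "rotatable torsions\n")
  invisible(x)
}

.graph_connected <- function(n, bonds) {
  if (n == 1) return(TRUE)
  if (nrow(bonds) == 0) return(FALSE)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  adj <- .adjacency(n, bonds)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds[b, 1]]] <- c(adj[[bonds[b, 1]]], bonds[b, 2])
    adj[[bonds[b, 2]]] <- c(adj[[bonds[b, 2]]], bonds[b, 1])
  }
  adj
}

# is bond b part of a cycle? (removing it leaves endpoints connected)
.in_ring <- function(n, bonds, b) {
  rest <- bonds[-b, , drop = FALSE]
  i <- bonds[b, 1]; j <- bonds[b, 2]
  seen <- logical(n); seen[i] <- TRUE; queue <- i
  adj <- .adjacency(n, rest)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[j]
}

#' Detect rotatable torsions from a bond graph
#'
#' A bond is rotatable when it is a single bond, not in a ring, and both
#' endpoints have at least one further heavy or hydrogen neighbour (so a
#' dihedral can be defined). One torsion quadruple is returned per
#' rotatable bond, using the lowest-index flanking neighbours.
#'
#' @param bonds m x 2 index matrix.
#' @param element element symbols per atom.
#' @param order bond orders (default all single).
#' @return list of length-4 integer vectors.
#' @export
detect_rotatable_torsions <- function(bonds, element,
                                      order = rep(1L, nrow(bonds))) {
  n <- length(element)
  adj <- .adjacency(n, bonds)
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    if (order[b] != 1L) next
    i <- bonds[b, 1]; j <- bonds[b, 2]
    ni <- sort(setdiff(adj[[i]], j)); nj <- sort(setdiff(adj[[j]], i))
    if (length(ni) == 0 || length(nj) == 0) next
    if (.in_ring(n, bonds, b)) next
    out[[length(out) + 1]] <- c(ni[1], i, j, nj[1])
  }
  out
}

#' Rule-based ligand atom parameters
#'
#' Assigns partial charges and hydrogen-bond roles from local topology:
#' hydroxyl O -0.5 / H +0.4 (role both), carbonyl C +0.45 / O -0.45
#' (acceptor), amine N -0.40 / H +0.35 (donor), carbon attached to a
#' hydroxyl O +0.10; everything else neutral.
#'
#' @param element element symbols.
#' @param bonds m x 2 bond index matrix.
#' @param order bond orders.
#' @return list with `charge` and `hb_role` vectors.
#' @export
ligand_atom_parameters <- function(element, bonds,
                                   order = rep(1L, nrow(bonds))) {
  n <- length(element)
  element <- toupper(element)
  adj <- .adjacency(n, bonds)
  charge <- numeric(n)
  role <- rep("none", n)
  for (i in seq_len(n)) {
    if (element[i] == "O") {
      nb <- adj[[i]]
      has_h <- any(element[nb] == "H")
      dbl <- any(vapply(seq_len(nrow(bonds)), function(b)
        (bonds[b, 1] == i || bonds[b, 2] == i) && order[b] == 2L, TRUE))
      if (has_h) {
        charge[i] <- -0.5
        role[i] <- "both"
        for (h in nb[element[nb] == "H"]) charge[h] <- 0.4
        for (cpar in nb[element[nb] == "C"]) charge[cpar] <- charge[cpar] + 0.1
      } else {
        charge[i] <- -0.45
        role[i] <- "acceptor"
        if (dbl || length(nb) == 1)
          for (cpar in nb[element[nb] == "C"])
            charge[cpar] <- charge[cpar] + 0.45
      }
    } else if (element[i] == "N") {
      nb <- adj[[i]]
      if (any(element[nb] == "H")) {
        nh <- sum(element[nb] == "H")
        charge[i] <- -0.35 * nh
        role[i] <- "donor"
        for (h in nb[element[nb] == "H"]) charge[h] <- 0.35
      } else {
        charge[i] <- -0.2
        role[i] <- "acceptor"
        for (cpar in nb[element[nb] == "C"])
          charge[cpar] <- charge[cpar] + 0.2 / max(1, sum(element[nb] == "C"))
      }
    }
  }
  # enforce integral net charge by spreading any rounding residue
  resid <- sum(charge) - round(sum(charge))
  if (abs(resid) > 1e-9) {
    cidx <- which(element == "C")
    if (length(cidx)) charge[cidx] <- charge[cidx] - resid / length(cidx)
    else charge <- charge - resid / n
  }
  list(charge = charge, hb_role = role)
}

#' Net formal charge of a ligand (rounded sum of partial charges)
#' @param l Ligand.
#' @return integer charge in e.
#' @export
ligand_net_charge <- function(l) as.integer(round(sum(l$atoms$charge)))

#' Read a ligand from an SDF/MOL file
#'
#' Uses ChemmineR to parse the V2000 atom and bond blocks; rotatable
#' torsions are derived from the bond graph, and charges/LJ parameters
#' from the built-in rule table.
#'
#' @param file path to an SDF or MOL file.
#' @param name optional ligand label (defaults to the SDF header).
#' @return a `Ligand`.
#' @export
read_ligand_sdf <- function(file, name = NULL) {
  sdfs <- ChemmineR::read.SDFset(file)
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- toupper(gsub("_.*", "", rownames(ab)))
  xyz <- ab[, 1:3, drop = FALSE]
  bonds <- matrix(as.integer(bb[, 1:2]), ncol = 2)
  order <- as.integer(bb[, 3])
  lj <- .lj_lookup(element)
  pars <- ligand_atom_parameters(element, bonds, order)
  nm <- name %||% ChemmineR::sdfid(sdf)
  atoms <- atom_table(
    name = paste0(element, seq_along(element)), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = "X", resno = 201L, resname = "LIG", comp_kind = "ligand",
    charge = pars$charge, eps = lj$eps, sigma = lj$sigma,
    hb_role = pars$hb_role)
  new_ligand(atoms, bonds, order, name = nm)
}

#' Write a ligand as a V2000 MOL/SDF block
#' @param l Ligand.
#' @param file optional path; if NULL the text is returned.
#' @return SDF text (invisibly when `file` is given).
#' @export
write_ligand_sdf <- function(l, file = NULL) {
  a <- l$atoms
  hdr <- c(l$name, "  pocketmc", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(l$bonds))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   a$x, a$y, a$z, a$element)
  bonds <- if (nrow(l$bonds)) sprintf("%3d%3d%3d  0", l$bonds[, 1],
                                      l$bonds[, 2], l$order) else character()
  txt <- paste(c(hdr, counts, atoms, bonds, "M  END", "$$$$"),
               collapse = "\n")
  if (is.null(file)) txt else { writeLines(txt, file); invisible(txt) }
}

#' Extract the ligand component of a complex as a Ligand
#' @param s Structure with a ligand component.
#' @return a `Ligand` carrying the in-complex coordinates.
#' @export
ligand_from_structure <- function(s) {
  rows <- which(s$atoms$comp_kind == "ligand")
  if (length(rows) == 0) stop("structure has no ligand component")
  li <- s$ligand_info
  new_ligand(s$atoms[rows, , drop = FALSE], li$bonds, li$order,
             name = li$name, torsions = li$torsions)
}

#' Replace the ligand component of a complex
#'
#' Swaps in another ligand (atoms, bonds and torsions); the new ligand
#' keeps its own coordinates. Residue numbering of the ligand block is
#' preserved.
#'
#' @param s Structure with a ligand component.
#' @param l replacement `Ligand`.
#' @return updated Structure.
#' @export
set_structure_ligand <- function(s, l) {
  rows <- which(s$atoms$comp_kind == "ligand")
  if (length(rows) == 0) stop("structure has no ligand component")
  la <- l$atoms
  la$chain <- s$atoms$chain[rows[1]]
  la$resno <- s$atoms$resno[rows[1]]
  la$resname <- s$atoms$resname[rows[1]]
  la$comp_kind <- "ligand"
  la$comp_name <- l$name
  atoms <- rbind(s$atoms[seq_len(rows[1] - 1), , drop = FALSE],
                 la[, .atom_cols],
                 s$atoms[setdiff(seq_len(nrow(s$atoms)),
                                 c(seq_len(rows[1] - 1), rows)), ,
                         drop = FALSE])
  new_structure(atoms, active_residues = s$active_residues,
                catalytic_water = s$catalytic_water,
                ligand_info = list(name = l$name, bonds = l$bonds,
                                   order = l$order, torsions = l$torsions),
                provenance = s$provenance, prepared = s$prepared,
                tethers = s$tethers)
}

#' Replace ligand coordinates inside a complex
#' @param s Structure with a ligand component.
#' @param m k x 3 matrix matching the ligand atom count and order.
#' @return updated Structure.
#' @export
set_ligand_coords <- function(s, m) {
  rows <- which(s$atoms$comp_kind == "ligand")
  stopifnot(length(rows) == nrow(m))
  s$atoms$x[rows] <- m[, 1]; s$atoms$y[rows] <- m[, 2]
  s$atoms$z[rows] <- m[, 3]
  s
}
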