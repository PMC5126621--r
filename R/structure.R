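# Structure container and PDB plumbing.
#
# A Structure holds one flat atom table plus component bookkeeping.
# Atom identity is the row index; residue identity is "chain:resno"
# taken verbatim from the source (no renumbering). Component kinds:
# protein, cofactor, catalytic_water, water, ligand, other_het.

.atom_cols <- c("name", "element", "x", "y", "z", "charge", "eps",
                "sigma", "hb_role", "is_h", "chain", "resno", "resname",
                "comp_kind", "comp_name")

#' Construct an atom table
#' @param name,element,x,y,z,chain,resno,resname,comp_kind atom fields.
#' @param charge,eps,sigma,hb_role,comp_name optional fields with defaults.
#' @return data.frame with the canonical atom columns.
#' @export
atom_table <- function(name, element, x, y, z, chain, resno, resname,
                       comp_kind, charge = NA_real_, eps = NA_real_,
                       sigma = NA_real_, hb_role = "none",
                       comp_name = resname) {
  data.frame(name = name, element = toupper(element), x = x, y = y, z = z,
             charge = charge, eps = eps, sigma = sigma, hb_role = hb_role,
             is_h = toupper(element) == "H", chain = chain, resno = resno,
             resname = resname, comp_kind = comp_kind,
             comp_name = comp_name, stringsAsFactors = FALSE)
}

#' Construct a Structure
#'
#' @param atoms atom table (see [atom_table()]).
#' @param active_residues character vector of residue ids ("chain:resno")
#'   designated catalytically active.
#' @param catalytic_water residue id of the conserved active-site water,
#'   or `NA` if none is declared.
#' @param ligand_info list describing the ligand component: `name`,
#'   `bonds` (m x 2 indices into the ligand's atom rows, in order),
#'   `order` (bond orders), `torsions` (list of length-4 index vectors).
#' @param provenance free-text source description.
#' @param prepared logical; TRUE once charges/radii/polar H are in place.
#' @param tethers optional harmonic positional restraints: a list with
#'   `keys` (character "chain:resno:name" atom keys), `ref` (matching
#'   coordinate matrix) and `k` (kcal/mol/A^2). Used by synthetic
#'   fixtures to emulate the rigidity the surrounding protein core
#'   would provide; anchored in the lab frame by design.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, active_residues = character(),
                          catalytic_water = NA_character_,
                          ligand_info = NULL, provenance = "",
                          prepared = FALSE, tethers = NULL) {
  stopifnot(is.data.frame(atoms), all(.atom_cols %in% names(atoms)))
  rownames(atoms) <- NULL
  s <- list(atoms = atoms[, .atom_cols], active_residues = active_residues,
            catalytic_water = catalytic_water, ligand_info = ligand_info,
            provenance = provenance, prepared = prepared, tethers = tethers,
            topology = NULL)
  class(s) <- "Structure"
  s
}

# resolve tether atom keys to current row indices (atoms may have been
# subset or reordered since the tethers were declared)
.tether_rows <- function(s) {
  if (is.null(s$tethers)) return(list(rows = integer(),
                                      ref = matrix(0, 0, 3), k = 0))
  key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$name, sep = ":")
  m <- match(s$tethers$keys, key)
  keep <- !is.na(m)
  list(rows = as.integer(m[keep]),
       ref = s$tethers$ref[keep, , drop = FALSE], k = s$tethers$k)
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(res_ids(x, "protein")), "protein residues\n")
  tab <- table(x$atoms$comp_kind)
  cat("  components:", paste(names(tab), tab, sep = ":", collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-atom residue ids ("chain:resno")
#' @param s Structure.
#' @return character vector, one entry per atom.
#' @export
atom_res_ids <- function(s) paste0(s$atoms$chain, ":", s$atoms$resno)

#' Residue ids present in a structure
#' @param s Structure.
#' @param kind optional component kind filter.
#' @return character vector of unique residue ids, in atom order.
#' @export
res_ids <- function(s, kind = NULL) {
  keep <- if (is.null(kind)) rep(TRUE, nrow(s$atoms)) else
    s$atoms$comp_kind %in% kind
  unique(atom_res_ids(s)[keep])
}

#' Atom row indices of one residue
#' @param s Structure.
#' @param id residue id "chain:resno".
#' @return integer vector of row indices.
#' @export
residue_rows <- function(s, id) which(atom_res_ids(s) == id)

#' Coordinates as an n x 3 matrix
#' @param s Structure.
#' @return numeric matrix.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Replace all coordinates
#' @param s Structure.
#' @param m n x 3 coordinate matrix.
#' @return updated Structure.
#' @export
set_coords <- function(s, m) {
  stopifnot(nrow(m) == nrow(s$atoms), ncol(m) == 3)
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

#' Validate Structure invariants
#'
#' Checks finite coordinates, non-empty elements, no duplicate atom
#' identity within a residue, at most one ligand component, at most one
#' catalytic water, and (for prepared structures) finite charges and
#' positive radii on every atom.
#'
#' @param s Structure.
#' @return invisibly TRUE; stops on violation.
#' @export
validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) stop("empty structure")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(!nzchar(a$element))) stop("atoms with empty element")
  key <- paste(a$chain, a$resno, a$name)
  if (anyDuplicated(key)) stop("duplicate atom identity: ",
                               key[duplicated(key)][1])
  if (length(unique(atom_res_ids(s)[a$comp_kind == "ligand"])) > 1)
    stop("more than one ligand component")
  if (length(unique(atom_res_ids(s)[a$comp_kind == "catalytic_water"])) > 1)
    stop("more than one catalytic water")
  if (isTRUE(s$prepared)) {
    if (!all(is.finite(a$charge))) stop("unparameterized charges")
    if (!all(is.finite(a$sigma) & a$sigma > 0)) stop("non-positive radii")
  }
  invisible(TRUE)
}

#' Component summary table
#' @param s Structure.
#' @return data.frame with kind, name, residue id and atom count per
#'   component residue (protein collapsed to one row).
#' @export
components <- function(s) {
  a <- s$atoms
  ids <- atom_res_ids(s)
  het <- a$comp_kind != "protein"
  out <- data.frame(kind = "protein", name = "protein",
                    res_id = NA_character_,
                    n_atoms = sum(!het), stringsAsFactors = FALSE)
  if (any(het)) {
    sp <- split(seq_len(nrow(a))[het], ids[het])
    out <- rbind(out, data.frame(
      kind = vapply(sp, function(i) a$comp_kind[i[1]], ""),
      name = vapply(sp, function(i) a$comp_name[i[1]], ""),
      res_id = names(sp),
      n_atoms = lengths(sp), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# ---- PDB reading -----------------------------------------------------

.cofactor_names <- c("NAP", "NDP", "NAI", "NDC")
.water_names <- c("HOH", "WAT", "DOD")
.buffer_names <- c("GOL", "EDO", "SO4", "PO4", "ACT", "PEG", "DMS")

#' Read a structure from PDB text or file
#'
#' ATOM records become protein residues; HETATM groups are classified by
#' residue name (NAP/NDP -> cofactor, HOH -> water, common
#' buffers/cryoprotectants -> other_het); of the remaining HETATM
#' groups the largest is taken as the ligand. Only altloc ' ' or 'A'
#' atoms are kept. Parsing itself is done by bio3d.
#'
#' @param x PDB-format text (single string or character vector of
#'   lines) or a path to a PDB file.
#' @param chain_filter optional chain id; other chains are dropped.
#' @return a `Structure` (not yet prepared).
#' @export
read_pdb <- function(x, chain_filter = NULL) {
  if (length(x) > 1 || grepl("\n", x[1], fixed = TRUE) ||
      !file.exists(x[1])) {
    lines <- if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x
    .check_pdb_lines(lines)
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(lines, path)
  } else {
    path <- x
    .check_pdb_lines(readLines(path, warn = FALSE))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  n_alt <- sum(!keep)
  if (n_alt > 0)
    message("dropped ", n_alt, " alternate-location atoms (kept 'A'/blank)")
  a <- a[keep, ]
  if (!is.null(chain_filter)) a <- a[a$chain %in% chain_filter, ]
  if (nrow(a) == 0) stop("empty structure after chain filter")
  element <- toupper(ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                            substr(trimws(a$elety), 1, 1), a$elesy))
  resname <- toupper(a$resid)
  is_prot <- a$type == "ATOM"
  kind <- ifelse(is_prot, "protein",
          ifelse(resname %in% .cofactor_names, "cofactor",
          ifelse(resname %in% .water_names, "water",
          ifelse(resname %in% .buffer_names, "other_het", "lig_candidate"))))
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  ids <- paste0(chain, ":", a$resno)
  # largest remaining het group is the ligand; the rest are other_het
  if (any(kind == "lig_candidate")) {
    cand <- table(ids[kind == "lig_candidate"])
    lig_id <- names(cand)[which.max(cand)]
    kind[kind == "lig_candidate"] <-
      ifelse(ids[kind == "lig_candidate"] == lig_id, "ligand", "other_het")
  }
  atoms <- atom_table(name = trimws(a$elety), element = element,
                      x = a$x, y = a$y, z = a$z, chain = chain,
                      resno = a$resno, resname = resname, comp_kind = kind)
  lig_info <- NULL
  if (any(kind == "ligand")) {
    li <- which(kind == "ligand")
    bonds <- .distance_bonds(as.matrix(cbind(a$x, a$y, a$z))[li, , drop = FALSE],
                             element[li])
    lig_info <- list(name = resname[li[1]], bonds = bonds$pairs,
                     order = bonds$order,
                     torsions = detect_rotatable_torsions(
                       bonds$pairs, element[li]))
  }
  new_structure(atoms, ligand_info = lig_info,
                provenance = paste0("read_pdb(",
                                    if (file.exists(path)) basename(path)
                                    else "text", ")"))
}

.check_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop("no ATOM or HETATM records found")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(
      c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": bad coordinates")
  }
  invisible(TRUE)
}

# Distance-based intra-group bond perception for HET groups read from
# PDB (no CONECT handling): cutoff 1.25 A when a hydrogen is involved,
# 2.1 A when S or P is involved, 1.9 A otherwise.
.distance_bonds <- function(xyz, element) {
  n <- nrow(xyz)
  pairs <- matrix(integer(), 0, 2)
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      cut <- if (element[i] == "H" || element[j] == "H") 1.25
             else if (element[i] %in% c("S", "P") ||
                      element[j] %in% c("S", "P")) 2.1 else 1.9
      if (d[i, j] <= cut) pairs <- rbind(pairs, c(i, j))
    }
  }
  list(pairs = pairs, order = rep(1L, nrow(pairs)))
}

# ---- PDB writing -----------------------------------------------------

#' Write a structure as PDB text
#'
#' Protein atoms are emitted as ATOM records, every hetero component as
#' a HETATM block; coordinates keep the PDB's 3-decimal precision so
#' that `read_pdb(write_pdb(s))` reproduces the atom table.
#'
#' @param s Structure.
#' @param file optional path; if `NULL` the PDB text is returned.
#' @return the PDB text (invisibly when `file` is given).
#' @export
write_pdb <- function(s, file = NULL) {
  if (nrow(s$atoms) == 0) stop("empty structure")
  a <- s$atoms
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(s))),
                   type = ifelse(a$comp_kind == "protein", "ATOM", "HETATM"),
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (is.null(file)) { unlink(path); txt } else invisible(txt)
}

# ---- Preparation -----------------------------------------------------

#' Prepare a structure for scoring
#'
#' Mirrors the usual apo-protein preparation: all waters except the
#' declared catalytic one are removed, glycerol (GOL) components are
#' removed, polar hydrogens (N-H, O-H) are placed geometrically where
#' missing, and every atom receives a partial charge and Lennard-Jones
#' parameters from the built-in table. Protein heavy-atom coordinates
#' are never altered, and the operation is idempotent.
#'
#' @param s Structure.
#' @param catalytic_water_id residue id ("chain:resno") of the water to
#'   retain. The catalytic water is always declared by the user, never
#'   inferred. `NULL` removes all waters.
#' @return prepared Structure.
#' @export
prepare_apo <- function(s, catalytic_water_id = NULL) {
  a <- s$atoms
  ids <- atom_res_ids(s)
  is_water <- a$comp_kind %in% c("water", "catalytic_water")
  if (!is.null(catalytic_water_id)) {
    if (!catalytic_water_id %in% ids[is_water]) {
      warning("declared catalytic water ", catalytic_water_id,
              " not found among water records")
      catalytic_water_id <- NULL
    }
  }
  drop <- (is_water & (is.null(catalytic_water_id) |
                         ids != (catalytic_water_id %||% ""))) |
    (a$resname == "GOL")
  a <- a[!drop, , drop = FALSE]
  ids <- paste0(a$chain, ":", a$resno)
  if (!is.null(catalytic_water_id))
    a$comp_kind[ids == catalytic_water_id] <- "catalytic_water"
  s2 <- new_structure(a, active_residues = s$active_residues,
                      catalytic_water = catalytic_water_id %||% NA_character_,
                      ligand_info = s$ligand_info,
                      provenance = s$provenance, prepared = FALSE,
                      tethers = s$tethers)
  s2 <- .add_polar_hydrogens(s2)
  s2 <- .assign_parameters(s2)
  s2$prepared <- TRUE
  validate_structure(s2)
  s2
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Geometric placement of missing polar hydrogens. Bond lengths: N-H
# 0.98 A, O-H 0.96 A; water H-O-H 104.5 degrees in a fixed global frame.
.add_polar_hydrogens <- function(s) {
  a <- s$atoms
  ids <- atom_res_ids(s)
  new_rows <- list()
  lig_extra <- list()  # new ligand H: list(parent_local_idx, row)
  for (id in unique(ids)) {
    rows <- which(ids == id)
    kind <- a$comp_kind[rows[1]]
    nm <- a$name[rows]
    if (kind == "protein") {
      tp <- residue_template(a$resname[rows[1]])
      # backbone amide H
      if ("N" %in% nm && !"H" %in% nm && (is.null(tp) || "H" %in% tp$atoms$name)) {
        N <- unlist(a[rows[nm == "N"], c("x", "y", "z")])
        CA <- unlist(a[rows[nm == "CA"][1], c("x", "y", "z")])
        prev <- which(ids == paste0(a$chain[rows[1]], ":",
                                    a$resno[rows[1]] - 1L))
        Cp <- if (length(prev) && any(a$name[prev] == "C"))
          unlist(a[prev[a$name[prev] == "C"][1], c("x", "y", "z")])
        else unlist(a[rows[nm == "C"][1], c("x", "y", "z")])
        dir <- unit(unit(N - CA) + unit(N - Cp))
        new_rows[[length(new_rows) + 1]] <- atom_table(
          "H", "H", N[1] + 0.98 * dir[1], N[2] + 0.98 * dir[2],
          N[3] + 0.98 * dir[3], a$chain[rows[1]], a$resno[rows[1]],
          a$resname[rows[1]], kind)
      }
      # side-chain hydroxyl H by template (OG/OG1/OH)
      for (oh in intersect(c("OG", "OG1", "OH"), nm)) {
        hname <- c(OG = "HG", OG1 = "HG1", OH = "HH")[[oh]]
        if (hname %in% nm) next
        parent <- c(OG = "CB", OG1 = "CB", OH = "CZ")[[oh]]
        if (!parent %in% nm) next
        O <- unlist(a[rows[nm == oh][1], c("x", "y", "z")])
        P <- unlist(a[rows[nm == parent][1], c("x", "y", "z")])
        H <- O + 0.96 * unit(O - P)
        new_rows[[length(new_rows) + 1]] <- atom_table(
          hname, "H", H[1], H[2], H[3], a$chain[rows[1]],
          a$resno[rows[1]], a$resname[rows[1]], kind)
      }
    } else if (kind %in% c("water", "catalytic_water")) {
      if (!any(a$element[rows] == "H")) {
        O <- unlist(a[rows[1], c("x", "y", "z")])
        th <- 104.5 / 2 * pi / 180
        for (k in 1:2) {
          u <- c(ifelse(k == 1, sin(th), -sin(th)), 0, cos(th))
          new_rows[[length(new_rows) + 1]] <- atom_table(
            paste0("H", k), "H", O[1] + 0.96 * u[1], O[2] + 0.96 * u[2],
            O[3] + 0.96 * u[3], a$chain[rows[1]], a$resno[rows[1]],
            a$resname[rows[1]], kind)
        }
      }
    } else if (kind == "ligand" && !is.null(s$ligand_info)) {
      # hydroxyl O: single-bonded O with no H neighbour
      li <- s$ligand_info
      for (k in seq_along(rows)) {
        if (a$element[rows[k]] != "O") next
        nb <- c(li$bonds[li$bonds[, 1] == k, 2], li$bonds[li$bonds[, 2] == k, 1])
        if (length(nb) != 1) next
        if (a$element[rows[nb]] == "H") next
        O <- unlist(a[rows[k], c("x", "y", "z")])
        P <- unlist(a[rows[nb], c("x", "y", "z")])
        H <- O + 0.96 * unit(O - P)
        lig_extra[[length(lig_extra) + 1]] <- list(
          parent = k,
          row = atom_table(paste0("H", a$name[rows[k]]), "H", H[1], H[2],
                           H[3], a$chain[rows[1]], a$resno[rows[1]],
                           a$resname[rows[1]], kind))
      }
    }
  }
  if (length(new_rows) == 0 && length(lig_extra) == 0) return(s)
  add <- do.call(rbind, c(new_rows, lapply(lig_extra, `[[`, "row")))
  atoms <- rbind(a, add)
  # keep residue blocks contiguous: re-sort by first appearance of id
  ids2 <- paste0(atoms$chain, ":", atoms$resno)
  atoms <- atoms[order(match(ids2, unique(ids))), , drop = FALSE]
  li <- s$ligand_info
  if (length(lig_extra) > 0) {
    # new ligand H atoms land at the end of the ligand block (stable sort)
    n_old <- sum(a$comp_kind == "ligand")
    for (k in seq_along(lig_extra)) {
      li$bonds <- rbind(li$bonds, c(lig_extra[[k]]$parent, n_old + k))
      li$order <- c(li$order, 1L)
    }
    lig_el <- toupper(atoms$element[atoms$comp_kind == "ligand"])
    li$torsions <- detect_rotatable_torsions(li$bonds, lig_el)
  }
  new_structure(atoms, active_residues = s$active_residues,
                catalytic_water = s$catalytic_water, ligand_info = li,
                provenance = s$provenance, prepared = s$prepared,
                tethers = s$tethers)
}

.assign_parameters <- function(s) {
  a <- s$atoms
  lj <- .lj_lookup(a$element)
  a$eps <- lj$eps
  a$sigma <- lj$sigma
  a$charge <- 0
  a$hb_role <- "none"
  ids <- atom_res_ids(s)
  warned <- character()
  for (id in unique(ids)) {
    rows <- which(ids == id)
    kind <- a$comp_kind[rows[1]]
    rn <- a$resname[rows[1]]
    if (kind == "protein" || kind %in% c("water", "catalytic_water")) {
      tp <- residue_template(if (kind == "protein") rn else "HOH")
      if (is.null(tp)) {
        # generic amino acid: backbone charges by name, side chain neutral
        m <- match(a$name[rows], names(.backbone_q))
        a$charge[rows] <- ifelse(is.na(m), 0, .backbone_q[m])
        a$hb_role[rows][a$name[rows] == "O"] <- "acceptor"
        a$hb_role[rows][a$name[rows] == "N"] <- "donor"
        a$hb_role[rows][a$element[rows] == "O" & a$name[rows] != "O"] <-
          "acceptor"
        warned <- c(warned, rn)
      } else {
        m <- match(a$name[rows], tp$atoms$name)
        if (kind != "protein" && all(is.na(m)))
          m <- seq_along(rows)  # water with nonstandard names, in O,H,H order
        bad <- is.na(m) | m > nrow(tp$atoms)
        a$charge[rows][!bad] <- tp$atoms$charge[m[!bad]]
        a$hb_role[rows][!bad] <- tp$atoms$hb_role[m[!bad]]
        if (any(bad)) warned <- c(warned, paste0(rn, "/",
                                                 a$name[rows][bad]))
      }
    } else if (kind == "ligand" && !is.null(s$ligand_info)) {
      pars <- ligand_atom_parameters(a$element[rows], s$ligand_info$bonds,
                                     s$ligand_info$order)
      a$charge[rows] <- pars$charge
      a$hb_role[rows] <- pars$hb_role
    } else {
      # unknown HET: neutral, element radii, oxygens as acceptors
      a$hb_role[rows][a$element[rows] == "O"] <- "acceptor"
      warned <- c(warned, rn)
    }
  }
  if (length(warned) > 0)
    warning("element-fallback parameters used for: ",
            paste(unique(warned), collapse = ", "))
  s$atoms <- a
  s$topology <- NULL
  s
}

# ---- Topology (bonds, exclusions, donors, torsions) ------------------

#' Ensure derived topology is cached on a structure
#'
#' Builds the global bond list (residue templates + peptide bonds +
#' distance-perceived HET bonds + declared ligand bonds), the 1-2/1-3
#' exclusion pairs used by the nonbonded sum, polar-hydrogen donor
#' mapping, acceptor flags, and the torsion quadruples (residue chi
#' angles plus ligand rotatable torsions) scored by the torsion prior.
#' Pure topology: unaffected by coordinate changes.
#'
#' @param s Structure.
#' @return Structure with `$topology` filled.
#' @export
ensure_topology <- function(s) {
  if (!is.null(s$topology)) return(s)
  a <- s$atoms
  ids <- atom_res_ids(s)
  bonds <- matrix(integer(), 0, 2)
  uids <- unique(ids)
  rows_of <- split(seq_len(nrow(a)), factor(ids, levels = uids))
  for (id in uids) {
    rows <- rows_of[[id]]
    kind <- a$comp_kind[rows[1]]
    if (kind == "protein" || kind %in% c("water", "catalytic_water")) {
      tp <- residue_template(if (kind == "protein") a$resname[rows[1]]
                             else "HOH")
      done <- FALSE
      if (!is.null(tp)) {
        m <- match(a$name[rows], tp$atoms$name)
        if (!all(is.na(m))) {
          for (b in seq_len(nrow(tp$bonds))) {
            i <- rows[which(a$name[rows] == tp$bonds[b, 1])]
            j <- rows[which(a$name[rows] == tp$bonds[b, 2])]
            if (length(i) == 1 && length(j) == 1)
              bonds <- rbind(bonds, c(i, j))
          }
          done <- TRUE
        }
      }
      if (!done) {
        db <- .distance_bonds(coords(s)[rows, , drop = FALSE],
                              a$element[rows])
        if (nrow(db$pairs)) bonds <- rbind(bonds,
                                           matrix(rows[db$pairs], ncol = 2))
      }
    } else if (kind == "ligand" && !is.null(s$ligand_info)) {
      lb <- s$ligand_info$bonds
      if (length(lb)) bonds <- rbind(bonds, matrix(rows[lb], ncol = 2))
    } else {
      db <- .distance_bonds(coords(s)[rows, , drop = FALSE], a$element[rows])
      if (nrow(db$pairs)) bonds <- rbind(bonds,
                                         matrix(rows[db$pairs], ncol = 2))
    }
  }
  # peptide bonds between consecutive residues of a chain
  prot_ids <- uids[vapply(rows_of[uids], function(r)
    a$comp_kind[r[1]] == "protein", TRUE)]
  for (id in prot_ids) {
    rows <- rows_of[[id]]
    nxt <- paste0(a$chain[rows[1]], ":", a$resno[rows[1]] + 1L)
    if (!nxt %in% prot_ids) next
    i <- rows[a$name[rows] == "C"]
    j <- rows_of[[nxt]][a$name[rows_of[[nxt]]] == "N"]
    if (length(i) == 1 && length(j) == 1) bonds <- rbind(bonds, c(i, j))
  }
  # adjacency and 1-2/1-3 exclusions
  n <- nrow(a)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds[b, 1]]] <- c(adj[[bonds[b, 1]]], bonds[b, 2])
    adj[[bonds[b, 2]]] <- c(adj[[bonds[b, 2]]], bonds[b, 1])
  }
  ex <- matrix(integer(), 0, 2)
  exl <- list()
  for (i in seq_len(n)) {
    nb1 <- adj[[i]]
    nb2 <- unique(unlist(adj[nb1]))
    ex_i <- setdiff(unique(c(nb1, nb2)), i)
    ex_i <- ex_i[ex_i > i]
    if (length(ex_i)) exl[[length(exl) + 1]] <- cbind(i, ex_i)
  }
  if (length(exl)) ex <- do.call(rbind, exl)
  # polar-hydrogen donor mapping
  don <- integer(n)
  for (i in which(a$is_h)) {
    hv <- adj[[i]]
    hv <- hv[a$element[hv] %in% c("N", "O")]
    if (length(hv)) don[i] <- hv[1]
  }
  acc <- as.integer(a$hb_role %in% c("acceptor", "both"))
  # torsion quadruples
  quads <- list()
  for (id in prot_ids) {
    rows <- rows_of[[id]]
    tp <- residue_template(a$resname[rows[1]])
    if (is.null(tp)) next
    for (ch in tp$chi) {
      m <- match(ch$dihedral, a$name[rows])
      if (any(is.na(m))) next
      quads[[length(quads) + 1]] <- rows[m]
    }
  }
  if (!is.null(s$ligand_info) && length(s$ligand_info$torsions)) {
    lrows <- which(a$comp_kind == "ligand")
    for (tq in s$ligand_info$torsions)
      quads[[length(quads) + 1]] <- lrows[tq]
  }
  s$topology <- list(
    bonds = bonds, excl = ex, don = don, acc = acc,
    torsions = if (length(quads)) do.call(rbind, quads)
               else matrix(integer(), 0, 4),
    adj = adj, rows_of = rows_of, res_order = uids)
  s
}
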