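# LigPlot-style interaction fingerprints: ligand-protein hydrogen
# bonds and residue-level hydrophobic (carbon-carbon) contacts, plus
# the cross-ligand shared-residue consensus.

#' Detect ligand-protein hydrogen bonds
#'
#' All donor-acceptor pairs with donor...acceptor distance at most
#' `dist_cutoff` and donor-H...acceptor angle at least `angle_cutoff`,
#' restricted to pairs with one side on the ligand and the other on the
#' protein. Requires polar hydrogens to be present.
#'
#' @param s prepared Structure with a ligand.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff minimum D-H...A angle, degrees (default 120).
#' @return data.frame: donor/acceptor atom names, residue ids, residue
#'   names, distance (A) and angle (degrees); zero rows if none.
#' @export
find_hbonds <- function(s, dist_cutoff = 3.5, angle_cutoff = 120) {
  s <- ensure_topology(s)
  a <- s$atoms
  tp <- s$topology
  m <- coords(s)
  ids <- atom_res_ids(s)
  out <- list()
  for (h in which(tp$don > 0)) {
    D <- tp$don[h]
    for (acc in which(tp$acc == 1)) {
      # ligand <-> protein pairs only
      kinds <- c(a$comp_kind[D], a$comp_kind[acc])
      if (!("ligand" %in% kinds && "protein" %in% kinds)) next
      dDA <- vnorm(m[D, ] - m[acc, ])
      if (dDA > dist_cutoff) next
      u <- m[D, ] - m[h, ]; v <- m[acc, ] - m[h, ]
      ang <- acos(min(1, max(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) *
        180 / pi
      if (ang < angle_cutoff) next
      out[[length(out) + 1]] <- data.frame(
        donor_atom = a$name[D], donor_res = ids[D],
        donor_resname = a$resname[D],
        acceptor_atom = a$name[acc], acceptor_res = ids[acc],
        acceptor_resname = a$resname[acc],
        protein_res = if (a$comp_kind[D] == "protein") ids[D] else ids[acc],
        distance = dDA, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(donor_atom = character(), donor_res = character(),
                      donor_resname = character(),
                      acceptor_atom = character(),
                      acceptor_res = character(),
                      acceptor_resname = character(),
                      protein_res = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Detect ligand-protein hydrophobic contacts
#'
#' Carbon-carbon pairs across the ligand-protein interface within
#' `cutoff`, aggregated to one row per protein residue with the
#' minimum contact distance and the closest ligand atom.
#'
#' @param s prepared Structure with a ligand.
#' @param cutoff C-C distance cutoff, Angstrom (default 3.9).
#' @return data.frame: residue id/name, ligand atom, protein atom,
#'   min_distance (A).
#' @export
find_hydrophobic_contacts <- function(s, cutoff = 3.9) {
  a <- s$atoms
  m <- coords(s)
  ids <- atom_res_ids(s)
  ligC <- which(a$comp_kind == "ligand" & a$element == "C")
  protC <- which(a$comp_kind == "protein" & a$element == "C")
  out <- list()
  if (length(ligC) && length(protC)) {
    for (rid in unique(ids[protC])) {
      rows <- protC[ids[protC] == rid]
      pc <- m[rows, , drop = FALSE]
      lc <- m[ligC, , drop = FALSE]
      d2 <- outer(rowSums(pc^2), rowSums(lc^2), `+`) - 2 * pc %*% t(lc)
      d2[d2 < 0] <- 0
      if (min(d2) <= cutoff^2) {
        best <- arrayInd(which.min(d2), dim(d2))
        out[[length(out) + 1]] <- data.frame(
          res_id = rid, resname = a$resname[rows[best[1]]],
          protein_atom = a$name[rows[best[1]]],
          ligand_atom = a$name[ligC[best[2]]],
          min_distance = sqrt(min(d2)), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(res_id = character(), resname = character(),
                      protein_atom = character(),
                      ligand_atom = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Full interaction report for one complex
#' @param s prepared Structure with a ligand.
#' @param dist_cutoff,angle_cutoff hydrogen-bond cutoffs.
#' @param hydrophobic_cutoff C-C contact cutoff.
#' @return object of class `InteractionReport`: `ligand_name`,
#'   `hbonds`, `hydrophobic_contacts`.
#' @export
interaction_report <- function(s, dist_cutoff = 3.5, angle_cutoff = 120,
                               hydrophobic_cutoff = 3.9) {
  rep <- list(
    ligand_name = s$ligand_info$name %||% "LIG",
    hbonds = find_hbonds(s, dist_cutoff, angle_cutoff),
    hydrophobic_contacts = find_hydrophobic_contacts(s, hydrophobic_cutoff))
  class(rep) <- "InteractionReport"
  rep
}

#' Protein residues touched (either interaction kind) by a report
#' @param report `InteractionReport`.
#' @return character vector of protein residue ids.
#' @export
report_residues <- function(report) {
  unique(c(report$hbonds$protein_res,
           report$hydrophobic_contacts$res_id))
}

#' Residues shared across interaction reports
#'
#' Protein residues appearing (in either interaction kind) in at least
#' `threshold` fraction of the reports.
#'
#' @param reports list of `InteractionReport`s (at least one).
#' @param threshold fraction in (0, 1].
#' @return character vector of residue ids.
#' @export
shared_residues <- function(reports, threshold = 0.8) {
  if (length(reports) == 0) stop("no interaction reports given")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  per <- lapply(reports, report_residues)
  counts <- table(unlist(per))
  sort(names(counts)[counts >= threshold * length(reports) - 1e-9])
}
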