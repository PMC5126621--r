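# Binding-energy ladder, the binding-energy equation, pose
# classification against the cofactor plane, in-frame ligand RMSD and
# ligand ranking.

#' Binding energy from the three ladder energies
#'
#' `E_bind = E_complex - (E_ref + E_lig)`, where `E_ref` is the energy
#' of the enzyme in complex with the cofactor and catalytic water but
#' no ligand, and `E_lig` the internal energy of the ligand alone.
#' Entropic contributions are ignored by explicit assumption (taken as
#' near-identical across the compared ligands).
#'
#' @param e_complex,e_ref,e_lig energies in kcal/mol.
#' @return binding energy, kcal/mol.
#' @export
binding_energy <- function(e_complex, e_ref, e_lig) {
  if (!all(is.finite(c(e_complex, e_ref, e_lig))))
    stop("non-finite input to binding_energy")
  e_complex - (e_ref + e_lig)
}

#' One ligand x position binding record
#'
#' @param ligand_name label.
#' @param position pose class: "productive", "unproductive" or
#'   "ambiguous" (the attempted/assigned placement).
#' @param e_complex,e_ref,e_lig ladder energies, kcal/mol.
#' @param binding FALSE marks a not-binding outcome (positive binding
#'   energy or a ligand that drifted out of the pocket).
#' @return one-row data.frame of class `BindingRecord`; `e_bind` is
#'   computed from the identity, which therefore holds exactly.
#' @export
binding_record <- function(ligand_name, position, e_complex, e_ref,
                           e_lig, binding = TRUE) {
  stopifnot(position %in% c("productive", "unproductive", "ambiguous",
                            "not_binding"))
  if (identical(position, "not_binding")) binding <- FALSE
  rec <- data.frame(ligand_name = ligand_name, position = position,
                    binding = binding, e_complex = e_complex,
                    e_ref = e_ref, e_lig = e_lig,
                    e_bind = binding_energy(e_complex, e_ref, e_lig),
                    stringsAsFactors = FALSE)
  class(rec) <- c("BindingRecord", class(rec))
  rec
}

#' Strip a complex to a subset of component kinds
#' @param s Structure.
#' @param kinds component kinds to keep (protein always kept).
#' @return Structure with the other hetero components removed.
#' @export
subset_components <- function(s, kinds) {
  keep <- s$atoms$comp_kind %in% unique(c("protein", kinds))
  a <- s$atoms[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure after subsetting")
  new_structure(a, active_residues = s$active_residues,
                catalytic_water = if ("catalytic_water" %in% kinds)
                  s$catalytic_water else NA_character_,
                ligand_info = if ("ligand" %in% kinds) s$ligand_info,
                provenance = s$provenance, prepared = s$prepared,
                tethers = s$tethers)
}

.ladder_states <- list(
  apo = character(),
  water = "catalytic_water",
  water_nadp = c("catalytic_water", "cofactor"),
  complex = c("catalytic_water", "cofactor", "ligand"))

#' Energy ladder over component states
#'
#' Optimises (via [refine_to_convergence()]) the apo protein, the
#' protein + catalytic water, + cofactor, and the full complex; the
#' ligand alone receives only an energy evaluation ([ligand_energy()]),
#' with its coordinates untouched.
#'
#' @param s prepared Structure containing all requested components.
#' @param cfg `RefinementConfig`.
#' @param p `EnergyParams`.
#' @param states character subset of
#'   `c("apo", "water", "water_nadp", "complex")`.
#' @param lib `RotamerLibrary`.
#' @return object of class `LadderResult`: `energies` (named, incl.
#'   `ligand_alone` when a ligand is present), `structures`, `traces`.
#' @export
energy_ladder <- function(s, cfg = refinement_config(),
                          p = default_energy_params(),
                          states = names(.ladder_states),
                          lib = default_rotamer_library()) {
  states <- match.arg(states, names(.ladder_states), several.ok = TRUE)
  have <- unique(s$atoms$comp_kind)
  energies <- list(); structures <- list(); traces <- list()
  for (st in states) {
    need <- .ladder_states[[st]]
    if (!all(need %in% have))
      stop("state '", st, "' requires missing component(s): ",
           paste(setdiff(need, have), collapse = ", "))
    sub <- subset_components(s, need)
    if ("ligand" %in% need) {
      res <- refine_to_convergence(sub, cfg, p, lib = lib)
      energies[[st]] <- utils::tail(res$trace$cycle_energies, 1)
    } else {
      # no ligand: the 4 A ligand rule is inapplicable; the declared
      # active residues are the flexible set
      res <- .refine_ref_state(sub, cfg, p, lib)
      energies[[st]] <- res$energy
    }
    structures[[st]] <- res$structure
    traces[[st]] <- res$trace
  }
  if ("ligand" %in% have) {
    lig <- ligand_from_structure(s)
    energies[["ligand_alone"]] <- ligand_energy(lig, p)$total
    structures[["ligand_alone"]] <- lig  # unchanged by construction
  }
  out <- list(energies = unlist(energies), structures = structures,
              traces = traces)
  class(out) <- "LadderResult"
  out
}

# Reference states carry no ligand, so the 4 A ligand-distance rule is
# inapplicable; refine with the active residues (if any) flexible and
# the retained hetero components mobile, under the same round/decoy
# bookkeeping.
.refine_ref_state <- function(sub, cfg, p, lib) {
  flex <- intersect(sub$active_residues, res_ids(sub, "protein"))
  flex <- flex[vapply(flex, function(id) {
    rn <- sub$atoms$resname[residue_rows(sub, id)[1]]
    !is.null(lib[[rn]])
  }, TRUE)]
  comps <- intersect(c("cofactor", "catalytic_water"),
                     unique(sub$atoms$comp_kind))
  e_inc <- complex_energy(sub, p)$total
  incumbent <- sub
  energies <- numeric(); converged <- FALSE
  for (k in seq_len(cfg$max_K)) {
    set.seed((cfg$seed + 131L * k) %% 2147483647L)
    s_try <- incumbent
    if (length(comps) || length(flex)) {
      for (kind in comps) s_try <- perturb_component(s_try, kind, cfg$move)
      if (length(flex)) s_try <- repack_side_chains(s_try, flex, lib, p)
      ops_possible <- length(flex) > 0 || length(comps) > 0
      if (ops_possible) {
        mn <- minimize_energy(s_try, p, flexible_ids = flex,
                              max_iter = cfg$inner_min_iter)
        if (mn$energy < e_inc) { incumbent <- mn$structure; e_inc <- mn$energy }
      }
    }
    energies <- c(energies, e_inc)
    if (k >= 2 && abs(energies[k] - energies[k - 1]) <= cfg$convergence_tol) {
      converged <- TRUE; break
    }
  }
  trace <- list(cycle_energies = energies, K = length(energies),
                converged = converged)
  class(trace) <- "RefinementTrace"
  list(structure = incumbent, trace = trace, energy = e_inc)
}

#' Classify a ligand pose against the cofactor plane
#'
#' Computes the angle between the best-fit-plane normals of the ligand
#' core (heavy atoms) and of the cofactor's nicotinamide-like ring.
#' Planes parallel (angle <= `parallel_max`) is the unproductive
#' orientation; perpendicular (angle >= `perpendicular_min`) the
#' productive one; in between is ambiguous. Invariant under rigid
#' motion of the whole complex.
#'
#' @param s Structure containing ligand and cofactor.
#' @param ring_names cofactor atom names defining the ring plane;
#'   `NULL` uses all cofactor heavy atoms.
#' @param parallel_max,perpendicular_min classification thresholds,
#'   degrees.
#' @return list with `position` ("productive"/"unproductive"/
#'   "ambiguous") and `angle` (degrees).
#' @export
classify_pose <- function(s, ring_names = NULL, parallel_max = 30,
                          perpendicular_min = 60) {
  a <- s$atoms
  lig <- which(a$comp_kind == "ligand" & !a$is_h)
  cof <- which(a$comp_kind == "cofactor" & !a$is_h)
  if (length(lig) < 3) stop("ligand needs >= 3 heavy atoms")
  if (length(cof) < 3) stop("cofactor ring needs >= 3 atoms")
  if (!is.null(ring_names)) {
    cof <- cof[a$name[cof] %in% ring_names]
    if (length(cof) < 3) stop("fewer than 3 cofactor ring atoms match")
  }
  m <- coords(s)
  ang <- plane_angle(best_fit_plane_normal(m[lig, , drop = FALSE]),
                     best_fit_plane_normal(m[cof, , drop = FALSE]))
  position <- if (ang <= parallel_max) "unproductive"
              else if (ang >= perpendicular_min) "productive"
              else "ambiguous"
  list(position = position, angle = ang)
}

#' Heavy-atom RMSD between two ligand poses
#'
#' In the fixed receptor frame (no re-superposition), heavy atoms only,
#' matched by atom name.
#'
#' @param a,b `Ligand` objects (or atom tables) with identical heavy
#'   atom names.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  ta <- if (inherits(a, "Ligand")) a$atoms else a
  tb <- if (inherits(b, "Ligand")) b$atoms else b
  ta <- ta[!ta$is_h, , drop = FALSE]
  tb <- tb[!tb$is_h, , drop = FALSE]
  if (nrow(ta) != nrow(tb)) stop("heavy-atom counts differ")
  m <- match(ta$name, tb$name)
  if (any(is.na(m)) || anyDuplicated(m))
    stop("atom names do not correspond one-to-one")
  d <- as.matrix(ta[, c("x", "y", "z")]) -
    as.matrix(tb[m, c("x", "y", "z")])
  sqrt(mean(rowSums(d * d)))
}

#' Rank binding records within each position class
#'
#' Binders are sorted ascending by `e_bind` within each position class;
#' not-binding entries go last within their class; ties break
#' alphabetically by ligand name.
#'
#' @param records data.frame of binding records (rbind of
#'   [binding_record()] rows).
#' @return the same rows, ordered, with a `rank` column per class.
#' @export
rank_ligands <- function(records) {
  if (nrow(records) == 0) return(records)
  recs <- as.data.frame(records)
  if (!"binding" %in% names(recs))
    recs$binding <- recs$position != "not_binding"
  ord <- order(recs$position,
               !recs$binding * 1L,
               ifelse(recs$binding, recs$e_bind, Inf),
               recs$ligand_name)
  out <- recs[ord, , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$position,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}
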