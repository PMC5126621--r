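# Scoring-function interface. The package's score is a declared
# four-term model (LJ + screened Coulomb + directional H-bond + torsion
# prior) in kcal/mol; it targets relative ranking and protocol
# mechanics, not the magnitudes of any particular forcefield.

new_energy_breakdown <- function(lj = 0, coulomb = 0, hbond = 0,
                                 torsion = 0, weights, restraint = 0) {
  total <- sum(weights * c(lj, coulomb, hbond, torsion)) + restraint
  out <- list(lj = lj, coulomb = coulomb, hbond = hbond,
              torsion = torsion, restraint = restraint, total = total)
  class(out) <- "EnergyBreakdown"
  out
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf(
    "Energy (kcal/mol): total %.4f [lj %.4f, coulomb %.4f, hbond %.4f, torsion %.4f, restraint %.4f]\n",
    x$total, x$lj, x$coulomb, x$hbond, x$torsion, x$restraint))
  invisible(x)
}

#' Nonbonded energy of a single atom pair
#'
#' Lennard-Jones 12-6 with Lorentz-Berthelot combination and Coulomb
#' with the distance-dependent dielectric eps(r) = 4r, both switched to
#' zero at the cutoff. If `h` (the donor's polar hydrogen) is supplied
#' and one atom is a donor and the other an acceptor, the directional
#' hydrogen-bond bonus is evaluated as well.
#'
#' @param a,b single-row atom tables (see [atom_table()]); must be
#'   parameterized (finite charge, positive sigma).
#' @param p `EnergyParams`.
#' @param h optional single-row atom table: the hydrogen bonded to the
#'   donor among `a`, `b`.
#' @return an `EnergyBreakdown`.
#' @export
pair_energy <- function(a, b, p = default_energy_params(), h = NULL) {
  pa <- unlist(a[1, c("x", "y", "z")]); pb <- unlist(b[1, c("x", "y", "z")])
  r <- vnorm(pa - pb)
  if (r < 1e-9) stop("coincident atoms: pair energy singular at r = 0")
  w <- p$term_weights
  if (r >= p$nonbonded_cutoff)
    return(new_energy_breakdown(weights = w))
  s <- .switch_fun(r, p$nonbonded_cutoff, p$switch_width)
  sg <- (a$sigma + b$sigma) / 2
  ep <- sqrt(a$eps * b$eps)
  sr6 <- (sg / r)^6
  lj <- s * 4 * ep * (sr6^2 - sr6)
  coul <- s * p$coulomb_constant * a$charge * b$charge / (4 * r^2)
  hb <- 0
  if (!is.null(h)) {
    don <- if (a$hb_role %in% c("donor", "both") &&
               b$hb_role %in% c("acceptor", "both")) list(d = a, ac = b)
           else if (b$hb_role %in% c("donor", "both") &&
                    a$hb_role %in% c("acceptor", "both")) list(d = b, ac = a)
           else NULL
    if (!is.null(don)) {
      pd <- unlist(don$d[1, c("x", "y", "z")])
      pac <- unlist(don$ac[1, c("x", "y", "z")])
      ph <- unlist(h[1, c("x", "y", "z")])
      dDA <- vnorm(pd - pac)
      if (dDA < p$hbond_distance_cutoff) {
        u <- pd - ph; v <- pac - ph
        ang <- acos(min(1, max(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) *
          180 / pi
        if (ang >= p$hbond_angle_cutoff) {
          fang <- (ang - p$hbond_angle_cutoff) / (180 - p$hbond_angle_cutoff)
          hb <- -p$hbond_well_depth *
            .switch_fun(dDA, p$hbond_distance_cutoff, 0.4) * fang
        }
      }
    }
  }
  new_energy_breakdown(lj, coul, hb, 0, w)
}

.switch_fun <- function(r, cutoff, width) {
  if (r >= cutoff) return(0)
  if (r <= cutoff - width) return(1)
  t <- (cutoff - r) / width
  t * t * (3 - 2 * t)
}

.energy_inputs <- function(s) {
  if (!isTRUE(s$prepared))
    stop("structure must be prepared (see prepare_apo) before scoring")
  s <- ensure_topology(s)
  tp <- s$topology
  a <- s$atoms
  if (!all(is.finite(a$charge)) || !all(is.finite(a$sigma)))
    stop("unparameterized atoms present")
  list(s = s, coords = coords(s), q = a$charge, eps = a$eps, sig = a$sigma,
       don = as.integer(tp$don), acc = as.integer(tp$acc),
       excl_i = as.integer(tp$excl[, 1]), excl_j = as.integer(tp$excl[, 2]),
       quads = matrix(as.integer(tp$torsions), ncol = 4))
}

.pars_list <- function(p) p[c("nonbonded_cutoff", "switch_width",
                              "coulomb_constant", "hbond_distance_cutoff",
                              "hbond_angle_cutoff", "hbond_well_depth",
                              "torsion_k")]

#' Total energy of a complex
#'
#' Sum of pairwise nonbonded energies over all atom pairs (excluding
#' 1-2/1-3 bonded pairs) plus the torsion prior over residue chi angles
#' and ligand rotatable torsions. Deterministic for fixed input;
#' invariant under rigid motion of the whole system.
#'
#' @param s prepared Structure.
#' @param p `EnergyParams`.
#' @return an `EnergyBreakdown`.
#' @export
complex_energy <- function(s, p = default_energy_params()) {
  if (nrow(s$atoms) == 0)
    return(new_energy_breakdown(weights = p$term_weights))
  ei <- .energy_inputs(s)
  nb <- nb_terms_cpp(ei$coords, ei$q, ei$eps, ei$sig, ei$don, ei$acc,
                     ei$excl_i, ei$excl_j, .pars_list(p), integer(0), 0L)
  tors <- torsion_energy_cpp(ei$coords, ei$quads, p$torsion_k)
  th <- .tether_rows(ei$s)
  rest <- if (length(th$rows))
    tether_energy_cpp(ei$coords, th$rows, th$ref, th$k) else 0
  new_energy_breakdown(nb[["lj"]], nb[["coulomb"]], nb[["hbond"]], tors,
                       p$term_weights, restraint = rest)
}

#' Internal energy of a ligand alone
#'
#' Intra-ligand nonbonded interactions between atom pairs separated by
#' at least 3 bonds, plus the torsion prior over rotatable torsions.
#'
#' @param l Ligand (bond graph must be connected).
#' @param p `EnergyParams`.
#' @return an `EnergyBreakdown`.
#' @export
ligand_energy <- function(l, p = default_energy_params()) {
  stopifnot(inherits(l, "Ligand"))
  n <- nrow(l$atoms)
  if (n == 1) return(new_energy_breakdown(weights = p$term_weights))
  if (!.graph_connected(n, l$bonds)) stop("disconnected ligand bond graph")
  adj <- .adjacency(n, l$bonds)
  ex <- list()
  for (i in seq_len(n)) {
    nb1 <- adj[[i]]
    nb2 <- unique(unlist(adj[nb1]))
    ex_i <- setdiff(unique(c(nb1, nb2)), i)
    ex_i <- ex_i[ex_i > i]
    if (length(ex_i)) ex[[length(ex) + 1]] <- cbind(i, ex_i)
  }
  ex <- if (length(ex)) do.call(rbind, ex) else matrix(integer(), 0, 2)
  don <- integer(n)
  for (i in which(l$atoms$is_h)) {
    hv <- adj[[i]]
    hv <- hv[toupper(l$atoms$element[hv]) %in% c("N", "O")]
    if (length(hv)) don[i] <- hv[1]
  }
  acc <- as.integer(l$atoms$hb_role %in% c("acceptor", "both"))
  quads <- if (length(l$torsions))
    matrix(as.integer(do.call(rbind, l$torsions)), ncol = 4)
  else matrix(integer(), 0, 4)
  xyz <- as.matrix(l$atoms[, c("x", "y", "z")])
  nb <- nb_terms_cpp(xyz, l$atoms$charge, l$atoms$eps, l$atoms$sigma,
                     don, acc, as.integer(ex[, 1]), as.integer(ex[, 2]),
                     .pars_list(p), integer(0), 0L)
  tors <- torsion_energy_cpp(xyz, quads, p$torsion_k)
  new_energy_breakdown(nb[["lj"]], nb[["coulomb"]], nb[["hbond"]], tors,
                       p$term_weights)
}

# Energy of cross interactions between a subset of atoms and the rest
# of the system (used by the repacker to score one side chain against
# its fixed environment, and for pocket feasibility checks).
.group_energy <- function(ei, rows, p) {
  active <- integer(nrow(ei$coords))
  active[rows] <- 1L
  nb <- nb_terms_cpp(ei$coords, ei$q, ei$eps, ei$sig, ei$don, ei$acc,
                     ei$excl_i, ei$excl_j, .pars_list(p), active, 2L)
  w <- p$term_weights
  w[["lj"]] * nb[["lj"]] + w[["coulomb"]] * nb[["coulomb"]] +
    w[["hbond"]] * nb[["hbond"]]
}
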