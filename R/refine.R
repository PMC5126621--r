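# The iterative Monte Carlo refinement protocol: nested perturbation
# cycles (outer annealing cycles x blocks x steps, 8 x 4 x 6 = 192 by
# default) with side-chain repacking, DFP minimisation and Metropolis
# acceptance; 200 decoys per optimization round; rounds repeated K
# times until the round-best energies converge.

#' Refinement protocol configuration
#'
#' Defaults follow the reference protocol: 8 x 4 x 6 = 192 perturbation
#' steps per decoy trajectory, 200 decoys per round, annealing from
#' kT = 3.0 down to 1.0, a 4 Angstrom flexible-residue selection
#' radius, and convergence when two subsequent round energies agree to
#' `convergence_tol`.
#'
#' @param outer_cycles annealing cycles per decoy (default 8).
#' @param mid_blocks blocks per outer cycle (default 4).
#' @param inner_steps perturbation steps per block (default 6).
#' @param n_decoys decoys per optimization round (default 200).
#' @param kt_start,kt_end annealing endpoints in energy units
#'   (defaults 3.0 and 1.0).
#' @param selection_radius flexible-residue radius, Angstrom (default 4).
#' @param convergence_tol |E_k - E_(k-1)| tolerance, kcal/mol.
#' @param max_K cap on optimization rounds (default 50).
#' @param seed integer RNG seed for the whole refinement.
#' @param move `MoveSpec` with the per-step move magnitudes.
#' @param inner_min_iter DFP iteration cap for the per-step
#'   minimisation inside a trajectory (default 30).
#' @return object of class `RefinementConfig`.
#' @export
refinement_config <- function(outer_cycles = 8, mid_blocks = 4,
                              inner_steps = 6, n_decoys = 200,
                              kt_start = 3.0, kt_end = 1.0,
                              selection_radius = 4.0,
                              convergence_tol = 1e-3, max_K = 50,
                              seed = 1, move = move_spec(),
                              inner_min_iter = 30) {
  stopifnot(outer_cycles >= 1, mid_blocks >= 1, inner_steps >= 1,
            n_decoys >= 1, kt_start >= kt_end, kt_end > 0,
            selection_radius > 0, max_K >= 1)
  cfg <- list(outer_cycles = outer_cycles, mid_blocks = mid_blocks,
              inner_steps = inner_steps, n_decoys = n_decoys,
              kt_start = kt_start, kt_end = kt_end,
              selection_radius = selection_radius,
              convergence_tol = convergence_tol, max_K = max_K,
              seed = seed, move = move, inner_min_iter = inner_min_iter)
  class(cfg) <- "RefinementConfig"
  cfg
}

#' Total perturbation steps per decoy trajectory
#' @param cfg `RefinementConfig`.
#' @return integer outer_cycles * mid_blocks * inner_steps.
#' @export
total_cycles <- function(cfg)
  cfg$outer_cycles * cfg$mid_blocks * cfg$inner_steps

#' Metropolis acceptance criterion
#'
#' Downhill moves (`e_new <= e_old`) are always accepted; uphill moves
#' with probability `exp(-(e_new - e_old)/kt)`. Consumes one uniform
#' draw from the current RNG stream only for uphill proposals.
#'
#' @param e_new,e_old energies, kcal/mol.
#' @param kt temperature in energy units (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(e_new, e_old, kt) {
  if (!is.finite(e_new) || !is.finite(e_old))
    stop("non-finite energies in Metropolis criterion")
  stopifnot(kt > 0)
  de <- e_new - e_old
  if (de <= 0) return(TRUE)
  stats::runif(1) < exp(-de / kt)
}

#' Annealing temperature for an outer cycle
#'
#' Linear interpolation from `kt_start` (first outer cycle) to `kt_end`
#' (last outer cycle).
#'
#' @param cfg `RefinementConfig`.
#' @param outer_index 0-based outer cycle index.
#' @return kT in energy units.
#' @export
anneal_kt <- function(cfg, outer_index) {
  if (outer_index < 0 || outer_index >= cfg$outer_cycles)
    stop("outer_index out of range [0, ", cfg$outer_cycles - 1, "]")
  if (cfg$outer_cycles == 1) return(cfg$kt_start)
  cfg$kt_start + (cfg$kt_end - cfg$kt_start) *
    outer_index / (cfg$outer_cycles - 1)
}

#' Generate one decoy structure
#'
#' Runs `outer_cycles` annealing cycles of `mid_blocks` x `inner_steps`
#' perturbation steps. Each step perturbs the hetero components
#' (ligand, cofactor, catalytic water), applies a small move and a
#' shear move to randomly chosen flexible residues, repacks the
#' flexible side chains, minimises, and applies the Metropolis
#' criterion against the last accepted state at the current kT. The
#' flexible set follows the first-cycle/later rule of the protocol.
#'
#' @param start prepared Structure with a ligand.
#' @param cfg `RefinementConfig`.
#' @param p `EnergyParams`.
#' @param first_cycle logical; use the first-cycle flexible rule?
#' @param seed optional integer seed for this trajectory.
#' @param index decoy index recorded on the result.
#' @param lib `RotamerLibrary`.
#' @return object of class `Decoy`: `structure`, `energy`, `index`,
#'   `n_steps` (instrumented perturbation-step counter).
#' @export
generate_decoy <- function(start, cfg = refinement_config(),
                           p = default_energy_params(),
                           first_cycle = FALSE, seed = NULL, index = 1L,
                           lib = default_rotamer_library()) {
  if (!is.null(seed)) set.seed(seed)
  flex <- select_flexible_residues(start, first_cycle = first_cycle,
                                   radius = cfg$selection_radius)
  flex <- flex[!vapply(flex, function(id) {
    rn <- start$atoms$resname[residue_rows(start, id)[1]]
    is.null(lib[[rn]])
  }, TRUE)]
  comps <- intersect(c("ligand", "cofactor", "catalytic_water"),
                     unique(start$atoms$comp_kind))
  s <- start
  e <- complex_energy(s, p)$total
  best_s <- s; best_e <- e
  n_steps <- 0L
  prot <- res_ids(s, "protein")
  for (oc in seq_len(cfg$outer_cycles)) {
    kt <- anneal_kt(cfg, oc - 1)
    for (blk in seq_len(cfg$mid_blocks)) {
      for (st in seq_len(cfg$inner_steps)) {
        n_steps <- n_steps + 1L
        s_try <- s
        for (kind in comps) s_try <- perturb_component(s_try, kind, cfg$move)
        if (length(flex) > 0) {
          rid <- flex[sample.int(length(flex), 1)]
          s_try <- apply_small_move(s_try, rid, cfg$move)
          parts <- strsplit(rid, ":", fixed = TRUE)[[1]]
          nxt <- paste0(parts[1], ":", as.numeric(parts[2]) + 1)
          prv <- paste0(parts[1], ":", as.numeric(parts[2]) - 1)
          pair <- if (nxt %in% prot) c(rid, nxt) else
            if (prv %in% prot) c(prv, rid) else NULL
          if (!is.null(pair))
            s_try <- apply_shear_move(s_try, pair[1], pair[2], cfg$move)
          s_try <- repack_side_chains(s_try, flex, lib, p)
        }
        mn <- minimize_energy(s_try, p, flexible_ids = flex,
                              max_iter = cfg$inner_min_iter)
        if (metropolis_accept(mn$energy, e, kt)) {
          s <- mn$structure
          e <- mn$energy
          if (e < best_e) { best_s <- s; best_e <- e }
        }
      }
    }
  }
  # recover-low: the decoy is the lowest-energy accepted state of the
  # trajectory, not whatever state the walk ended in
  out <- list(structure = best_s, energy = best_e, index = as.integer(index),
              n_steps = n_steps)
  class(out) <- "Decoy"
  out
}

#' @export
print.Decoy <- function(x, ...) {
  cat(sprintf("Decoy %d: energy %.4f kcal/mol (%d perturbation steps)\n",
              x$index, x$energy, x$n_steps))
  invisible(x)
}

#' One optimization round: n_decoys decoys, lowest-energy one selected
#'
#' Decoy trajectories are seeded with independent child seeds derived
#' from `cfg$seed`, so the round is reproducible; ties on energy break
#' to the lowest decoy index.
#'
#' @param start prepared Structure.
#' @param cfg `RefinementConfig`.
#' @param p `EnergyParams`.
#' @param first_cycle logical, passed to each decoy trajectory.
#' @param lib `RotamerLibrary`.
#' @return the lowest-energy `Decoy`, with the energies of all decoys
#'   in the round attached as field `round_energies`.
#' @export
optimization_round <- function(start, cfg = refinement_config(),
                               p = default_energy_params(),
                               first_cycle = FALSE,
                               lib = default_rotamer_library()) {
  set.seed(cfg$seed)
  child <- sample.int(2147483646L, cfg$n_decoys)
  decoys <- vector("list", cfg$n_decoys)
  for (i in seq_len(cfg$n_decoys))
    decoys[[i]] <- generate_decoy(start, cfg, p, first_cycle = first_cycle,
                                  seed = child[i], index = i, lib = lib)
  energies <- vapply(decoys, `[[`, numeric(1), "energy")
  best <- decoys[[which.min(energies)]]  # which.min: lowest index on ties
  best$round_energies <- energies
  best
}

#' Refine a complex to convergence over K optimization rounds
#'
#' Iterates [optimization_round()], carrying forward the better of the
#' incumbent and the new round best (so the energy trace is
#' non-increasing), until two subsequent cycle energies agree within
#' `convergence_tol` or `max_K` rounds have run. The first round uses
#' the first-cycle flexible-residue rule; later rounds the ligand-only
#' rule.
#'
#' @param start prepared Structure.
#' @param cfg `RefinementConfig`.
#' @param p `EnergyParams`.
#' @param lib `RotamerLibrary`.
#' @return list with `structure` (final refined complex) and `trace`
#'   (class `RefinementTrace`: `cycle_energies`, `K`, `converged`).
#' @export
refine_to_convergence <- function(start, cfg = refinement_config(),
                                  p = default_energy_params(),
                                  lib = default_rotamer_library()) {
  incumbent <- start
  e_inc <- complex_energy(start, p)$total
  energies <- numeric()
  converged <- FALSE
  for (k in seq_len(cfg$max_K)) {
    cfg_k <- cfg
    cfg_k$seed <- (cfg$seed + 97L * k) %% 2147483647L
    rd <- optimization_round(incumbent, cfg_k, p,
                             first_cycle = (k == 1), lib = lib)
    # polish the selected decoy: the per-step minimisations inside a
    # trajectory are iteration-capped, the round winner is converged
    # properly before entering the trace
    flex <- select_flexible_residues(rd$structure, first_cycle = (k == 1),
                                     radius = cfg$selection_radius)
    flex <- flex[vapply(flex, function(id) {
      rn <- rd$structure$atoms$resname[residue_rows(rd$structure, id)[1]]
      !is.null(lib[[rn]])
    }, TRUE)]
    pol <- minimize_energy(rd$structure, p, flexible_ids = flex,
                           max_iter = 150)
    rd$structure <- pol$structure
    rd$energy <- pol$energy
    if (rd$energy < e_inc) {
      incumbent <- rd$structure
      e_inc <- rd$energy
    }
    energies <- c(energies, e_inc)
    if (k >= 2 &&
        abs(energies[k] - energies[k - 1]) <= cfg$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  trace <- list(cycle_energies = energies, K = length(energies),
                converged = converged)
  class(trace) <- "RefinementTrace"
  list(structure = incumbent, trace = trace)
}

#' @export
print.RefinementTrace <- function(x, ...) {
  cat("RefinementTrace: K =", x$K,
      if (x$converged) "(converged)" else "(max_K reached)", "\n")
  cat("  energies:", paste(sprintf("%.4f", x$cycle_energies),
                           collapse = ", "), "\n")
  invisible(x)
}
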