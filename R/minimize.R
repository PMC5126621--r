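# Quasi-Newton minimisation with the Davidon-Fletcher-Powell inverse
# Hessian update, over internal coordinates (flexible backbone/side
# chain dihedrals, ligand rotatable torsions) plus per-component
# rigid-body degrees of freedom.

#' DFP quasi-Newton minimiser
#'
#' Minimises `fn` from `x0` using numerical central-difference gradients
#' and the DFP inverse-Hessian update with a backtracking Armijo line
#' search. Stops when the gradient norm falls below `gtol` or after
#' `max_iter` iterations.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point.
#' @param gtol gradient-norm tolerance (default 1e-4).
#' @param max_iter iteration cap (default 200).
#' @param h finite-difference step.
#' @param max_step cap on the infinity norm of a single line-search
#'   step (degrees / Angstrom); keeps early steps, taken with a unit
#'   inverse-Hessian guess, inside the local basin.
#' @param gr optional gradient function (central differences on `fn`
#'   when omitted).
#' @return list with `x`, `value`, `iterations`, `converged`.
#' @export
dfp_minimize <- function(fn, x0, gtol = 1e-4, max_iter = 200, h = 1e-3,
                         max_step = 1.0, gr = NULL) {
  n <- length(x0)
  stopifnot(n >= 1)
  num_grad <- if (!is.null(gr)) function(x, f0) gr(x) else function(x, f0) {
    g <- numeric(n)
    for (i in seq_len(n)) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      g[i] <- (fn(xp) - fn(xm)) / (2 * h)
    }
    g
  }
  x <- x0
  f <- fn(x)
  if (!is.finite(f)) stop("objective not finite at the start point")
  H <- diag(n)
  g <- num_grad(x, f)
  iter <- 0
  converged <- sqrt(sum(g^2)) < gtol
  while (!converged && iter < max_iter) {
    iter <- iter + 1
    d <- -as.vector(H %*% g)
    if (sum(d * g) > 0) { d <- -g; H <- diag(n) }  # reset on ascent dir
    alpha <- min(1, max_step / max(abs(d)))
    f_new <- Inf
    repeat {
      f_new <- fn(x + alpha * d)
      if (is.finite(f_new) && f_new <= f + 1e-4 * alpha * sum(g * d)) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (!is.finite(f_new) || f_new >= f) break  # no further progress
    x_new <- x + alpha * d
    g_new <- num_grad(x_new, f_new)
    sv <- x_new - x
    yv <- g_new - g
    sy <- sum(sv * yv)
    Hy <- as.vector(H %*% yv)
    yHy <- sum(yv * Hy)
    if (sy > 1e-12 && yHy > 1e-12)
      H <- H + outer(sv, sv) / sy - outer(Hy, Hy) / yHy
    x <- x_new; f <- f_new; g <- g_new
    converged <- sqrt(sum(g^2)) < gtol
  }
  list(x = x, value = f, iterations = iter, converged = converged)
}

# Build the DOF operation list for a structure: backbone phi/psi and chi
# dihedrals of the flexible residues, ligand rotatable torsions, and one
# rigid-body block per hetero component.
.build_dof_ops <- function(s, flexible_ids) {
  a <- s$atoms
  ops <- list()
  for (id in flexible_ids) {
    rows <- residue_rows(s, id)
    N <- .named_row(s, rows, "N"); CA <- .named_row(s, rows, "CA")
    C <- .named_row(s, rows, "C")
    if (any(is.na(c(N, CA, C)))) next
    down <- .downstream_rows(s, id)
    Hrow <- rows[a$name[rows] == "H"]
    phi_moving <- setdiff(c(setdiff(rows, c(N, Hrow)), down), CA)
    ops[[length(ops) + 1]] <- list(type = 0L, a1 = N, a2 = CA,
                                   moving = as.integer(phi_moving))
    Or <- rows[a$name[rows] == "O"]
    ops[[length(ops) + 1]] <- list(type = 0L, a1 = CA, a2 = C,
                                   moving = as.integer(c(Or, down)))
    tp <- residue_template(a$resname[rows[1]])
    if (!is.null(tp)) for (ch in tp$chi) {
      ax <- vapply(ch$axis, function(nm) .named_row(s, rows, nm), 1L)
      mv <- rows[a$name[rows] %in% ch$moving]
      if (any(is.na(ax)) || length(mv) == 0) next
      ops[[length(ops) + 1]] <- list(type = 0L, a1 = ax[1], a2 = ax[2],
                                     moving = as.integer(mv))
    }
  }
  lig_rows <- which(a$comp_kind == "ligand")
  if (length(lig_rows) && length(s$ligand_info$torsions)) {
    n <- length(lig_rows)
    adj <- .adjacency(n, s$ligand_info$bonds)
    for (tq in s$ligand_info$torsions) {
      b <- tq[2]; cc <- tq[3]
      seen <- logical(n); seen[b] <- TRUE; seen[cc] <- TRUE
      queue <- cc; sub <- integer()
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (!seen[w]) {
          seen[w] <- TRUE; sub <- c(sub, w); queue <- c(queue, w)
        }
      }
      if (length(sub) == 0) next
      ops[[length(ops) + 1]] <- list(type = 0L, a1 = lig_rows[b],
                                     a2 = lig_rows[cc],
                                     moving = as.integer(lig_rows[sub]))
    }
  }
  for (kind in c("ligand", "cofactor", "catalytic_water")) {
    rows <- which(a$comp_kind == kind)
    if (length(rows))
      ops[[length(ops) + 1]] <- list(type = 1L,
                                     moving = as.integer(rows))
  }
  ops
}

.dof_length <- function(ops)
  sum(vapply(ops, function(op) if (op$type == 0L) 1L else 6L, 1L))

#' Minimise the energy of a complex over its declared DOF
#'
#' Degrees of freedom: phi/psi and chi dihedrals of `flexible_ids`,
#' ligand rotatable torsions, and rigid-body motion of each hetero
#' component. Quasi-Newton (DFP) with numerical gradients; the result
#' never has higher energy than the input.
#'
#' @param s prepared Structure.
#' @param p `EnergyParams`.
#' @param flexible_ids residue ids treated as flexible (may be empty).
#' @param max_iter,gtol minimiser controls.
#' @return list with `structure` (minimised), `energy` (total,
#'   kcal/mol), `iterations`, `converged`.
#' @export
minimize_energy <- function(s, p = default_energy_params(),
                            flexible_ids = character(),
                            max_iter = 200, gtol = 1e-4) {
  ei <- .energy_inputs(s)
  ops <- .build_dof_ops(s, flexible_ids)
  if (length(ops) == 0) stop("no degrees of freedom to minimise")
  nd <- .dof_length(ops)
  pars <- .pars_list(p)
  w <- as.numeric(p$term_weights)
  th <- .tether_rows(ei$s)
  obj <- function(x)
    dof_energy_cpp(ei$coords, ops, x, ei$q, ei$eps, ei$sig, ei$don,
                   ei$acc, ei$excl_i, ei$excl_j, ei$quads, pars, w,
                   th$rows, th$ref, th$k, FALSE)$total
  grf <- function(x)
    dof_energy_grad_cpp(ei$coords, ops, x, ei$q, ei$eps, ei$sig, ei$don,
                        ei$acc, ei$excl_i, ei$excl_j, ei$quads, pars, w,
                        th$rows, th$ref, th$k, 1e-3)$grad
  e_in <- obj(numeric(nd))
  if (!is.finite(e_in)) stop("energy not finite at minimisation start")
  res <- dfp_minimize(obj, numeric(nd), gtol = gtol, max_iter = max_iter,
                      gr = grf)
  if (res$value <= e_in) {
    fin <- dof_energy_cpp(ei$coords, ops, res$x, ei$q, ei$eps, ei$sig,
                          ei$don, ei$acc, ei$excl_i, ei$excl_j, ei$quads,
                          pars, w, th$rows, th$ref, th$k, TRUE)
    s_out <- set_coords(ei$s, fin$coords)
    energy <- fin$total
  } else {
    s_out <- ei$s
    energy <- e_in
  }
  list(structure = s_out, energy = energy, iterations = res$iterations,
       converged = res$converged)
}
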