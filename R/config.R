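# Structured-text (YAML) interfaces: the editable energy-parameter
# table, the site declaration (chain, catalytic water, active
# residues), and the rotamer library.

#' Write energy parameters as YAML
#' @param p `EnergyParams`.
#' @param file path.
#' @return invisibly, the path.
#' @export
write_energy_params <- function(p, file) {
  stopifnot(inherits(p, "EnergyParams"))
  x <- unclass(p)
  x$term_weights <- as.list(x$term_weights)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read energy parameters from YAML
#'
#' Fields missing from the file keep their defaults, so a config may
#' override single values (for example just the hydrogen-bond cutoffs).
#'
#' @param file path to a YAML file.
#' @return `EnergyParams`.
#' @export
read_energy_params <- function(file) {
  x <- yaml::read_yaml(file)
  d <- default_energy_params()
  for (nm in intersect(names(x), names(d))) {
    if (nm == "term_weights") {
      w <- unlist(x$term_weights)
      d$term_weights[names(w)] <- w
    } else d[[nm]] <- x[[nm]]
  }
  do.call(default_energy_params, d[names(formals(default_energy_params))])
}

#' Read a site declaration
#'
#' YAML with fields `chain` (chain id to keep), `catalytic_water`
#' (residue id, e.g. "A:602"; the catalytic water is always declared,
#' never inferred) and `active_residues` (list of residue ids).
#'
#' @param file path to a YAML file.
#' @return list with `chain`, `catalytic_water`, `active_residues`.
#' @export
read_site_config <- function(file) {
  x <- yaml::read_yaml(file)
  list(chain = x$chain %||% NULL,
       catalytic_water = x$catalytic_water %||% NULL,
       active_residues = as.character(unlist(x$active_residues %||%
                                               character())))
}

#' Write a rotamer library as YAML
#' @param lib `RotamerLibrary`.
#' @param file path.
#' @return invisibly, the path.
#' @export
write_rotamer_library <- function(lib, file) {
  x <- lapply(unclass(lib), function(e)
    list(chis = apply(e$chis, 1, as.numeric, simplify = FALSE),
         prob = as.numeric(e$prob)))
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a rotamer library from YAML
#' @param file path to a YAML file written by [write_rotamer_library()]
#'   (or hand-edited in the same shape).
#' @return `RotamerLibrary`.
#' @export
read_rotamer_library <- function(file) {
  x <- yaml::read_yaml(file)
  lib <- lapply(x, function(e) {
    chis <- if (length(e$chis) == 0) matrix(numeric(), 1, 0) else
      do.call(rbind, lapply(e$chis, as.numeric))
    prob <- as.numeric(e$prob)
    stopifnot(abs(sum(prob) - 1) < 1e-6,
              all(chis > -180 - 1e-9 & chis <= 180 + 1e-9))
    list(chis = chis, prob = prob)
  })
  class(lib) <- "RotamerLibrary"
  lib
}
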