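# Built-in parameter tables: per-element Lennard-Jones parameters and
# per-residue partial charges / hydrogen-bond roles. The tables are
# deliberately small: the scoring function only needs polar hydrogens,
# approximate point charges and contact radii, not a full forcefield
# typer. Nonpolar hydrogens are implicit (united-atom carbons with
# enlarged radii).

# eps in kcal/mol, sigma in Angstrom
.element_lj <- data.frame(
  element = c("C", "N", "O", "H", "S", "P", "F", "CL", "BR"),
  eps     = c(0.10, 0.17, 0.17, 0.015, 0.25, 0.20, 0.06, 0.27, 0.32),
  sigma   = c(3.55, 3.25, 3.00, 0.80, 3.55, 3.74, 2.90, 3.40, 3.60),
  stringsAsFactors = FALSE
)

.lj_lookup <- function(element) {
  el <- toupper(element)
  i <- match(el, .element_lj$element)
  eps <- ifelse(is.na(i), 0.10, .element_lj$eps[i])
  sig <- ifelse(is.na(i), 3.50, .element_lj$sigma[i])
  list(eps = eps, sigma = sig)
}

# Backbone charges sum to zero per residue; side-chain polar groups are
# neutral as a group (OPLS-like magnitudes, rounded).
.backbone_q <- c(N = -0.35, H = 0.25, CA = 0.10, C = 0.51, O = -0.51)

.residue_templates <- local({
  bb_atoms <- data.frame(
    name = c("N", "H", "CA", "C", "O"),
    element = c("N", "H", "C", "C", "O"),
    charge = unname(.backbone_q[c("N", "H", "CA", "C", "O")]),
    hb_role = c("donor", "none", "none", "none", "acceptor"),
    stringsAsFactors = FALSE)
  bb_bonds <- rbind(c("N", "H"), c("N", "CA"), c("CA", "C"), c("C", "O"))
  sc <- function(name, element, charge, hb_role = "none")
    data.frame(name = name, element = element, charge = charge,
               hb_role = hb_role, stringsAsFactors = FALSE)
  tmpl <- function(side = NULL, side_bonds = NULL, chi = list()) {
    atoms <- rbind(bb_atoms, side)
    bonds <- rbind(bb_bonds, side_bonds)
    list(atoms = atoms, bonds = bonds, chi = chi)
  }
  list(
    GLY = tmpl(),
    ALA = tmpl(sc("CB", "C", 0), rbind(c("CA", "CB"))),
    SER = tmpl(
      rbind(sc("CB", "C", 0.265), sc("OG", "O", -0.683, "both"),
            sc("HG", "H", 0.418)),
      rbind(c("CA", "CB"), c("CB", "OG"), c("OG", "HG")),
      chi = list(list(dihedral = c("N", "CA", "CB", "OG"),
                      axis = c("CA", "CB"), moving = c("OG", "HG")))),
    THR = tmpl(
      rbind(sc("CB", "C", 0.265), sc("OG1", "O", -0.683, "both"),
            sc("HG1", "H", 0.418), sc("CG2", "C", 0)),
      rbind(c("CA", "CB"), c("CB", "OG1"), c("OG1", "HG1"), c("CB", "CG2")),
      chi = list(list(dihedral = c("N", "CA", "CB", "OG1"),
                      axis = c("CA", "CB"),
                      moving = c("OG1", "HG1", "CG2")))),
    CYS = tmpl(
      rbind(sc("CB", "C", 0), sc("SG", "S", 0)),
      rbind(c("CA", "CB"), c("CB", "SG")),
      chi = list(list(dihedral = c("N", "CA", "CB", "SG"),
                      axis = c("CA", "CB"), moving = "SG"))),
    VAL = tmpl(
      rbind(sc("CB", "C", 0), sc("CG1", "C", 0), sc("CG2", "C", 0)),
      rbind(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")),
      chi = list(list(dihedral = c("N", "CA", "CB", "CG1"),
                      axis = c("CA", "CB"), moving = c("CG1", "CG2")))),
    LEU = tmpl(
      rbind(sc("CB", "C", 0), sc("CG", "C", 0), sc("CD1", "C", 0),
            sc("CD2", "C", 0)),
      rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
      chi = list(
        list(dihedral = c("N", "CA", "CB", "CG"), axis = c("CA", "CB"),
             moving = c("CG", "CD1", "CD2")),
        list(dihedral = c("CA", "CB", "CG", "CD1"), axis = c("CB", "CG"),
             moving = c("CD1", "CD2")))),
    PHE = tmpl(
      rbind(sc("CB", "C", 0), sc("CG", "C", 0), sc("CD1", "C", 0),
            sc("CD2", "C", 0), sc("CE1", "C", 0), sc("CE2", "C", 0),
            sc("CZ", "C", 0)),
      rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
            c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
      chi = list(
        list(dihedral = c("N", "CA", "CB", "CG"), axis = c("CA", "CB"),
             moving = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
        list(dihedral = c("CA", "CB", "CG", "CD1"), axis = c("CB", "CG"),
             moving = c("CD1", "CD2", "CE1", "CE2", "CZ")))),
    TYR = tmpl(
      rbind(sc("CB", "C", 0), sc("CG", "C", 0), sc("CD1", "C", 0),
            sc("CD2", "C", 0), sc("CE1", "C", 0), sc("CE2", "C", 0),
            sc("CZ", "C", 0.15), sc("OH", "O", -0.585, "both"),
            sc("HH", "H", 0.435)),
      rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
            c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
            c("CZ", "OH"), c("OH", "HH")),
      chi = list(
        list(dihedral = c("N", "CA", "CB", "CG"), axis = c("CA", "CB"),
             moving = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH", "HH")),
        list(dihedral = c("CA", "CB", "CG", "CD1"), axis = c("CB", "CG"),
             moving = c("CD1", "CD2", "CE1", "CE2", "CZ", "OH", "HH")))),
    ASN = tmpl(
      rbind(sc("CB", "C", 0), sc("CG", "C", 0.50),
            sc("OD1", "O", -0.50, "acceptor"),
            sc("ND2", "N", -0.76, "donor"),
            sc("HD21", "H", 0.38), sc("HD22", "H", 0.38)),
      rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2"),
            c("ND2", "HD21"), c("ND2", "HD22")),
      chi = list(
        list(dihedral = c("N", "CA", "CB", "CG"), axis = c("CA", "CB"),
             moving = c("CG", "OD1", "ND2", "HD21", "HD22")),
        list(dihedral = c("CA", "CB", "CG", "OD1"), axis = c("CB", "CG"),
             moving = c("OD1", "ND2", "HD21", "HD22")))),
    ASP = tmpl(  # neutral (protonation-free) approximation
      rbind(sc("CB", "C", 0), sc("CG", "C", 0.70),
            sc("OD1", "O", -0.35, "acceptor"),
            sc("OD2", "O", -0.35, "acceptor")),
      rbind(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
      chi = list(
        list(dihedral = c("N", "CA", "CB", "CG"), axis = c("CA", "CB"),
             moving = c("CG", "OD1", "OD2")))),
    HOH = list(
      atoms = data.frame(
        name = c("O", "H1", "H2"), element = c("O", "H", "H"),
        charge = c(-0.834, 0.417, 0.417),
        hb_role = c("both", "none", "none"), stringsAsFactors = FALSE),
      bonds = rbind(c("O", "H1"), c("O", "H2")), chi = list())
  )
})

#' Residue template lookup
#' @param res_name 3-letter residue code.
#' @return template list (atoms, bonds, chi) or NULL if unknown.
#' @keywords internal
residue_template <- function(res_name) {
  .residue_templates[[toupper(res_name)]]
}

#' Default energy-model parameters
#'
#' The package's scoring function is a four-term docking-style model:
#' Lennard-Jones 12-6 (Lorentz-Berthelot combination), Coulomb with a
#' distance-dependent dielectric eps(r) = 4r, a directional hydrogen-bond
#' bonus, and a threefold cosine torsion prior with minima at staggered
#' conformations. Nonbonded terms are tapered smoothly to zero over the
#' last `switch_width` Angstrom before `nonbonded_cutoff`.
#'
#' @param nonbonded_cutoff nonbonded cutoff, Angstrom (default 9).
#' @param switch_width switching-region width, Angstrom (default 1).
#' @param coulomb_constant electrostatic constant, kcal A / (mol e^2).
#' @param hbond_well_depth hydrogen-bond well depth, kcal/mol.
#' @param hbond_distance_cutoff maximum donor-acceptor distance, Angstrom.
#' @param hbond_angle_cutoff minimum donor-H-acceptor angle, degrees.
#' @param torsion_k torsion prior amplitude, kcal/mol.
#' @param term_weights named multipliers for lj, coulomb, hbond, torsion.
#' @return an object of class `EnergyParams`.
#' @export
default_energy_params <- function(nonbonded_cutoff = 9.0,
                                  switch_width = 1.0,
                                  coulomb_constant = 332.0637,
                                  hbond_well_depth = 2.0,
                                  hbond_distance_cutoff = 3.5,
                                  hbond_angle_cutoff = 120,
                                  torsion_k = 0.6,
                                  term_weights = c(lj = 1, coulomb = 1,
                                                   hbond = 1, torsion = 1)) {
  stopifnot(nonbonded_cutoff > 0, switch_width > 0,
            hbond_well_depth > 0, hbond_distance_cutoff > 0,
            hbond_angle_cutoff > 0, all(is.finite(term_weights)))
  p <- list(nonbonded_cutoff = nonbonded_cutoff,
            switch_width = switch_width,
            coulomb_constant = coulomb_constant,
            hbond_well_depth = hbond_well_depth,
            hbond_distance_cutoff = hbond_distance_cutoff,
            hbond_angle_cutoff = hbond_angle_cutoff,
            torsion_k = torsion_k,
            term_weights = term_weights[c("lj", "coulomb", "hbond", "torsion")])
  class(p) <- "EnergyParams"
  p
}
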