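test_that("PDB parsing classifies components and preserves coordinates", {
  s <- read_pdb(fixture_pdb_text())
  expect_setequal(unique(s$atoms$comp_kind),
                  c("protein", "cofactor", "water", "other_het", "ligand"))
  expect_equal(length(res_ids(s, "protein")), 2)
  # NAP -> cofactor; largest leftover het group (UNL) -> ligand
  expect_equal(sum(s$atoms$comp_kind == "cofactor"), 2)
  expect_equal(unique(s$atoms$resname[s$atoms$comp_kind == "ligand"]), "UNL")
  expect_equal(s$atoms$x[s$atoms$name == "CA" & s$atoms$resno == 1], 1.45)
  # chain filter that matches nothing is an error
  expect_error(read_pdb(fixture_pdb_text(), chain_filter = "Z"),
               "empty structure")
  # malformed coordinates are reported with a line number
  bad <- sub("1.45", "xx.x", fixture_pdb_text(), fixed = TRUE)
  expect_error(read_pdb(bad), "line 2")
  expect_error(read_pdb("JUNK\nEND"), "no ATOM or HETATM")
})

test_that("preparation keeps one flagged water, drops glycerol, adds polar H", {
  s <- read_pdb(fixture_pdb_text())
  prep <- suppressWarnings(prepare_apo(s, catalytic_water_id = "A:202"))
  wat <- prep$atoms[prep$atoms$comp_kind %in% c("water", "catalytic_water"), ]
  expect_equal(unique(paste0(wat$chain, ":", wat$resno)), "A:202")
  expect_false(any(prep$atoms$resname == "GOL"))
  # polar hydrogens: backbone amide H and SER hydroxyl H were placed
  expect_true("HG" %in% prep$atoms$name[prep$atoms$resname == "SER"])
  expect_true(any(prep$atoms$name == "H" & prep$atoms$resno == 2))
  # all atoms parameterized after preparation
  expect_true(all(is.finite(prep$atoms$charge)))
  expect_true(all(prep$atoms$sigma > 0))
  # protein heavy atoms never move
  h0 <- s$atoms[s$atoms$comp_kind == "protein" & !s$atoms$is_h, ]
  h1 <- prep$atoms[prep$atoms$comp_kind == "protein" & !prep$atoms$is_h, ]
  key <- function(d) paste(d$chain, d$resno, d$name)
  expect_equal(h1[match(key(h0), key(h1)), c("x", "y", "z")],
               h0[, c("x", "y", "z")], ignore_attr = TRUE)
  # idempotence
  prep2 <- suppressWarnings(prepare_apo(prep, catalytic_water_id = "A:202"))
  expect_equal(prep2$atoms, prep$atoms)
  # a missing declared water warns (alongside the HET fallback warning)
  w <- testthat::capture_warnings(prepare_apo(s, catalytic_water_id = "A:999"))
  expect_true(any(grepl("not found", w)))
})

test_that("PDB write/read round-trip preserves the atom table", {
  s <- suppressWarnings(prepare_apo(read_pdb(fixture_pdb_text()),
                                    catalytic_water_id = "A:202"))
  rt <- read_pdb(write_pdb(s))
  expect_equal(nrow(rt$atoms), nrow(s$atoms))
  expect_equal(rt$atoms$name, s$atoms$name)
  expect_equal(paste(rt$atoms$chain, rt$atoms$resno),
               paste(s$atoms$chain, s$atoms$resno))
  expect_equal(coords(rt), coords(s), tolerance = 1e-3, ignore_attr = TRUE)
  # hetero components come back as HETATM groups of the same kind
  expect_equal(sum(rt$atoms$comp_kind == "cofactor"),
               sum(s$atoms$comp_kind == "cofactor"))
  expect_equal(sum(rt$atoms$comp_kind == "ligand"),
               sum(s$atoms$comp_kind == "ligand"))
  expect_error(write_pdb(new_structure(s$atoms[0, ])), "empty")
})

test_that("structure invariants are enforced", {
  sys <- test_system()
  expect_true(validate_structure(sys$structure))
  bad <- sys$structure
  bad$atoms$x[1] <- NA
  expect_error(validate_structure(bad), "non-finite")
  two_lig <- sys$structure
  two_lig$atoms$comp_kind[two_lig$atoms$comp_kind == "cofactor"] <- "ligand"
  expect_error(validate_structure(two_lig), "ligand")
})

test_that("SDF ligand round-trip through ChemmineR parsing", {
  l <- synthetic_active_ligand()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(l, path)
  l2 <- read_ligand_sdf(path, name = l$name)
  expect_equal(nrow(l2$atoms), nrow(l$atoms))
  expect_equal(l2$atoms$element, l$atoms$element)
  expect_equal(as.matrix(l2$atoms[, c("x", "y", "z")]),
               as.matrix(l$atoms[, c("x", "y", "z")]),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(nrow(l2$bonds), nrow(l$bonds))
})

test_that("ligand construction validates its bond graph", {
  a <- synthetic_active_ligand()$atoms
  expect_error(new_ligand(a, matrix(c(1, 2), 1, 2)), "not connected")
  expect_error(new_ligand(a[1:2, ], matrix(c(1, 5), 1, 2)),
               "missing atoms")
})

test_that("structured-text configs round-trip", {
  dir <- withr::local_tempdir()
  # energy parameters: single-field override keeps other defaults
  p <- default_energy_params(hbond_distance_cutoff = 3.2)
  f <- file.path(dir, "params.yaml")
  write_energy_params(p, f)
  p2 <- read_energy_params(f)
  expect_equal(p2$hbond_distance_cutoff, 3.2)
  expect_equal(p2$nonbonded_cutoff, p$nonbonded_cutoff)
  expect_equal(p2$term_weights, p$term_weights)
  # site declaration
  writeLines(c("chain: A", "catalytic_water: 'A:202'",
               "active_residues:", "  - 'A:2'"),
             file.path(dir, "site.yaml"))
  site <- read_site_config(file.path(dir, "site.yaml"))
  expect_equal(site$chain, "A")
  expect_equal(site$catalytic_water, "A:202")
  expect_equal(site$active_residues, "A:2")
  # rotamer library
  lib <- default_rotamer_library()
  g <- file.path(dir, "rotamers.yaml")
  write_rotamer_library(lib, g)
  lib2 <- read_rotamer_library(g)
  expect_equal(lib2$SER$chis, lib$SER$chis, ignore_attr = TRUE)
  expect_equal(lib2$LEU$prob, lib$LEU$prob, tolerance = 1e-6)
})
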