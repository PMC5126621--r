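test_that("a screen yields one ranked record per ligand and position", {
  rep <- small_screen()
  recs <- rep$records
  expect_equal(nrow(recs), 3 * 2)
  expect_setequal(unique(recs$position), c("unproductive", "productive"))
  for (pos in unique(recs$position)) {
    sub <- recs[recs$position == pos, ]
    expect_equal(nrow(sub), 3)
    b <- sub[sub$binding, ]
    expect_true(all(diff(b$e_bind) >= 0))  # ascending within class
  }
  expect_length(rep$traces, 6)
  expect_length(rep$interactions, 6)
})

test_that("every screen record satisfies the binding-energy identity", {
  recs <- small_screen()$records
  ok <- is.finite(recs$e_bind)
  expect_true(any(ok))
  expect_lt(max(abs(recs$e_bind[ok] -
                      (recs$e_complex[ok] -
                         (recs$e_ref[ok] + recs$e_lig[ok])))), 1e-9)
})

test_that("the report table has the ligand x position-class layout", {
  tab <- screen_table(small_screen())
  expect_equal(names(tab),
               c("substrate", "unproductive_position", "productive_position"))
  expect_equal(nrow(tab), 3)
  expect_true(all(c("LG1", "DEC1", "DEC2") %in% tab$substrate))
  # writable as TSV
  dir <- withr::local_tempdir()
  paths <- write_screen_report(small_screen(), dir)
  expect_true(all(file.exists(paths)))
  re <- utils::read.delim(paths[["table"]])
  expect_equal(nrow(re), 3)
})

test_that("screens are reproducible under a fixed seed", {
  sys <- test_system()
  active <- ligand_from_structure(sys$structure)
  cfg <- screen_config(refinement = fast_cfg(n_decoys = 3, max_K = 2),
                       positions = "unproductive", seed = 12)
  r1 <- run_screen(sys, stats::setNames(list(active), "LG1"), cfg)
  r2 <- run_screen(sys, stats::setNames(list(active), "LG1"), cfg)
  expect_identical(r1$records, r2$records)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen_report(r1, d1); write_screen_report(r2, d2)
  expect_identical(readLines(file.path(d1, "binding_table.tsv")),
                   readLines(file.path(d2, "binding_table.tsv")))
})
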