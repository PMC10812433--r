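test_that("read_pdb parses a minimal residue and honours chain selection", {
  m <- read_pdb(write_pdb_text(pdb_ala_lines()))
  expect_s3_class(m, "structure_model")
  expect_equal(length(unique(m$atoms$chain)), 1)
  expect_equal(nrow(m$residues), 1)
  expect_equal(nrow(m$atoms), 5)
  expect_equal(m$residues$resn, "ALA")

  # chains A,B plus 50 waters; keep_chains = A drops chain B and all waters
  wat <- sprintf(paste0("HETATM%5d  O   HOH B%4d    %8.3f%8.3f%8.3f",
                        "  1.00  0.00           O"),
                 100 + 1:50, 500 + 1:50, 30 + 3 * (1:50), 0, 0)
  chB <- sub(" A ", " B ", pdb_ala_lines()[1:5])
  path <- write_pdb_text(c(pdb_ala_lines()[1:5], chB, wat, "END"))
  m2 <- read_pdb(path, keep_chains = "A")
  expect_equal(unique(m2$atoms$chain), "A")
  expect_false(any(m2$atoms$resn %in% c("HOH", "WAT")))
  expect_equal(nrow(m2$atoms), 5)

  expect_error(read_pdb(path, keep_chains = "Z"), "absent")
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("alternate locations resolve to highest occupancy, tie to altloc A", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END")
  m <- read_pdb(write_pdb_text(lines))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$atom == "N"], 9.0)   # higher occupancy
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 1.0)  # tie -> altloc A
})

test_that("write/read round trip preserves identity, order and coordinates", {
  toy <- make_toy_complex(toy_complex_spec(seed = 3))
  path <- tempfile(fileext = ".pdb")
  write_pdb(toy$model, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(toy$model$atoms))
  expect_equal(back$residues$resn, toy$model$residues$resn)
  expect_equal(back$residues$res_seq, toy$model$residues$res_seq)
  expect_equal(back$atoms$x, toy$model$atoms$x, tolerance = 5e-4)
  expect_equal(back$atoms$y, toy$model$atoms$y, tolerance = 5e-4)
  expect_equal(back$atoms$z, toy$model$atoms$z, tolerance = 5e-4)
  # residue order strictly increasing within chains
  for (ch in unique(back$residues$chain))
    expect_true(all(diff(back$residues$res_seq[back$residues$chain == ch]) > 0))
})

test_that("residue class assignment follows the configured tables", {
  m <- model_from_residues(cluster_res("A", 1, "GLU", c(0, 0, 0)),
                           cluster_res("A", 2, "GLY", c(10, 0, 0)),
                           cluster_res("A", 3, "TRP", c(20, 0, 0)),
                           cluster_res("A", 4, "SER", c(30, 0, 0)))
  m <- assign_residue_classes(m)
  r <- m$residues
  expect_equal(r$charge_class[r$resn == "GLU"], "charged")
  expect_equal(r$hydropathy_class[r$resn == "GLU"], "charged")
  expect_equal(r$hydropathy_class[r$resn == "GLY"], "none")
  expect_equal(r$charge_class[r$resn == "GLY"], "apolar")
  expect_equal(r$hydropathy_class[r$resn == "TRP"], "hydrophobic")
  expect_equal(r$charge_class[r$resn == "SER"], "polar")

  bad <- c(default_charge_classes(), GLU = "polar")
  expect_error(assign_residue_classes(m, charge_table = bad), "two classes")

  m2 <- model_from_residues(cluster_res("A", 1, "MSE", c(0, 0, 0)))
  expect_warning(assign_residue_classes(m2), "non-standard")
})

test_that("SASA matches the closed form for isolated spheres", {
  lone <- function(el, r) {
    m <- make_model(atom_row("A", 1, "ALA", "X1", el, 0, 0, 0))
    s <- compute_sasa(m, n_points = 960)
    expect_equal(s$abs_sasa, 4 * pi * (r + 1.4)^2, tolerance = 0.01)
  }
  lone("C", 1.70); lone("N", 1.55); lone("O", 1.52); lone("S", 1.80)

  # two identical atoms beyond 2(r + probe): each keeps the lone-sphere value
  m2 <- make_model(atom_row("A", 1, "ALA", "X1", "C", 0, 0, 0),
                   atom_row("A", 2, "ALA", "X1", "C", 6.5, 0, 0))
  s2 <- compute_sasa(m2, n_points = 960)
  expect_equal(s2$abs_sasa, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
})

test_that("SASA is invariant under rigid motion within sampling tolerance", {
  toy <- make_toy_fold(toy_fold_spec(cbind(1:5, 2:6), seed = 8))
  s1 <- compute_sasa(toy$model, n_points = 2400)
  s2 <- compute_sasa(rigid_move(toy$model), n_points = 2400)
  expect_equal(s2$abs_sasa, s1$abs_sasa, tolerance = 0.01)
})

test_that("truncate_to_ala keeps backbone + CB, never moves atoms", {
  m <- model_from_residues(cluster_res("A", 1, "LYS", c(0, 0, 0)),
                           cluster_res("A", 2, "GLY", c(10, 0, 0)),
                           cluster_res("A", 3, "ALA", c(20, 0, 0)))
  t1 <- truncate_to_ala(m, "A", 1)
  expect_equal(t1$residues$resn[1], "ALA")
  expect_equal(sum(t1$atoms$res_seq == 1), 5)
  untouched <- t1$atoms[t1$atoms$res_seq != 1, ]
  expect_equal(untouched, m$atoms[m$atoms$res_seq != 1, ],
               ignore_attr = TRUE)
  # original untouched
  expect_equal(m$residues$resn[1], "LYS")

  t2 <- truncate_to_ala(m, "A", 2)  # GLY -> ALA without CB construction
  expect_equal(t2$residues$resn[2], "ALA")
  expect_false("CB" %in% t2$atoms$atom[t2$atoms$res_seq == 2])

  t3 <- truncate_to_ala(m, "A", 3)  # ALA no-op
  expect_equal(t3$atoms, m$atoms, ignore_attr = TRUE)

  expect_error(truncate_to_ala(m, "A", 99), "not found")
})

test_that("truncation sweep leaves every residue with at most 5 heavy atoms", {
  f <- make_toy_fold(toy_fold_spec(cbind(1:29, 2:30),
                                   resn = rep(c("LYS", "TRP", "SER"), 10),
                                   seed = 9))
  m <- f$model
  for (i in seq_len(30)) m <- truncate_to_ala(m, "A", i)
  heavy <- m$atoms[m$atoms$element != "H", ]
  expect_true(all(table(heavy$res_seq) <= 5))
  expect_true(all(m$residues$resn == "ALA"))
})
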