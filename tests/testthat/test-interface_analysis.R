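two_res_complex <- function(sep) {
  m <- model_from_residues(cluster_res("A", 1, "LEU", c(0, 0, 0)),
                           cluster_res("B", 1, "VAL", c(0, 0, sep)))
  assign_residue_classes(m)
}

test_that("contact detection applies the heavy-atom cutoff exactly", {
  # clusters are planar, so the centre separation is the min atom distance
  expect_equal(nrow(find_interface_contacts(two_res_complex(5.4), "A", "B")), 1)
  expect_equal(nrow(find_interface_contacts(two_res_complex(5.6), "A", "B")), 0)
  expect_error(find_interface_contacts(two_res_complex(5), "A", "A"), "overlap")
})

test_that("pegboard complexes yield exactly the planted contacts, symmetrically", {
  spec <- toy_complex_spec(ic_counts = c(cc = 3, ca = 4, pp = 2, aa = 3),
                           seed = 21)
  toy <- make_toy_complex(spec)
  fwd <- find_interface_contacts(toy$model, "A", "B")
  expect_equal(nrow(fwd), 12)
  rev <- find_interface_contacts(toy$model, "B", "A")
  expect_setequal(paste(fwd$rec_seq, fwd$lig_seq),
                  paste(rev$lig_seq, rev$rec_seq))
  # monotone in the cutoff
  wider <- find_interface_contacts(toy$model, "A", "B", contact_cutoff = 7)
  expect_true(all(paste(fwd$rec_seq, fwd$lig_seq) %in%
                  paste(wider$rec_seq, wider$lig_seq)))
  # invariant under rigid motion
  moved <- find_interface_contacts(rigid_move(toy$model), "A", "B")
  expect_equal(moved[, 1:8], fwd[, 1:8])
})

test_that("interaction typing follows the geometric rules", {
  m <- make_model(
    atom_row("A", 1, "LYS", "CA", "C", 0, 0, 0),
    atom_row("A", 1, "LYS", "NZ", "N", 0, 0, 3.0),
    atom_row("B", 1, "GLU", "CA", "C", 0, 0, 9.4),
    atom_row("B", 1, "GLU", "OE1", "O", 0, 0, 6.2))
  m <- assign_residue_classes(m)
  ct <- classify_interaction_types(find_interface_contacts(m, "A", "B"), m)
  expect_setequal(ct$types[[1]], c("hydrogen_bond", "salt_bridge"))

  m2 <- assign_residue_classes(make_model(
    atom_row("A", 1, "LEU", "CD1", "C", 0, 0, 0),
    atom_row("B", 1, "VAL", "CG1", "C", 0, 0, 4.2)))
  ct2 <- classify_interaction_types(find_interface_contacts(m2, "A", "B"), m2)
  expect_equal(ct2$types[[1]], "hydrophobic")

  # backbone-only pair at 5.2 A with no N/O pair within 3.5 -> other
  m3 <- assign_residue_classes(make_model(
    atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
    atom_row("A", 1, "GLY", "N", "N", -1.4, 0, 0),
    atom_row("B", 1, "GLY", "CA", "C", 0, 0, 5.2),
    atom_row("B", 1, "GLY", "N", "N", -1.4, 0, 5.2)))
  ct3 <- classify_interaction_types(find_interface_contacts(m3, "A", "B"), m3)
  expect_equal(ct3$types[[1]], "other")
})

test_that("contact profiles reproduce generator bookkeeping exactly", {
  spec <- toy_complex_spec(ic_counts = c(cc = 2, ca = 3, pp = 1, pa = 4),
                           nis_counts = c(charged = 6, polar = 3, apolar = 3),
                           seed = 5)
  toy <- make_toy_complex(spec)
  prof <- contact_profile(toy$model, "A", "B", sasa_cfg = list(n_points = 240))
  expect_equal(prof$ic_counts, toy$profile$ic_counts)
  expect_equal(sum(prof$ic_counts), prof$n_contacts)
  expect_equal(unname(prof$nis_percent), c(50, 25, 25))
  expect_equal(prof$contact_residues_receptor$res_seq,
               toy$profile$contact_residues_receptor$res_seq)
})

test_that("an empty interface gives zero counts and normal NIS", {
  toy <- make_toy_complex(toy_complex_spec(
    ic_counts = c(cc = 0), nis_counts = c(charged = 2, polar = 1, apolar = 1),
    seed = 6))
  prof <- contact_profile(toy$model, "A", "B", sasa_cfg = list(n_points = 240))
  expect_true(all(prof$ic_counts == 0))
  expect_equal(nrow(prof$contact_residues_receptor), 0)
  expect_equal(nrow(prof$contact_residues_ligand), 0)
  expect_equal(sum(prof$nis_percent), 100)
})

test_that("contact_residues deduplicates and handles empties", {
  # three ligand residues all touching receptor residue 1
  m <- assign_residue_classes(model_from_residues(
    cluster_res("A", 1, "LYS", c(0, 0, 0)),
    cluster_res("B", 1, "SER", c(0, 0, 5)),
    cluster_res("B", 2, "ALA", c(3.5, 0, 3.5)),
    cluster_res("B", 3, "GLU", c(-3.5, 0, 3.5))))
  rec <- contact_residues(m, "A", "B", "receptor")
  expect_equal(rec$res_seq, 1)
  lig <- contact_residues(m, "A", "B", "ligand")
  expect_equal(lig$res_seq, 1:3)
  empty <- contact_residues(two_res_complex(20), "A", "B", "receptor")
  expect_equal(nrow(empty), 0)
  expect_error(contact_residues(m, "A", "B", "bogus"))
})
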