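test_that("contacts respect the distance cutoff exactly", {
  at <- rbind(test_atom("A", 1, "ALA", "CB", "C", 0, 0, 0),
              test_atom("B", 1, "ALA", "CB", "C", 4.4, 0, 0))
  path <- write_test_pdb(at, tempfile(fileext = ".pdb"))
  atoms <- read_structure(path)
  expect_equal(nrow(compute_contacts(atoms, "A", "B")), 1L)

  at2 <- at; at2$x[2L] <- 4.6
  atoms2 <- read_structure(write_test_pdb(at2, tempfile(fileext = ".pdb")))
  expect_equal(nrow(compute_contacts(atoms2, "A", "B")), 0L)
})

test_that("salt bridges are detected at 4.0 A between basic N and acidic O", {
  at <- rbind(test_atom("A", 1, "ASP", "OD1", "O", 0, 0, 0),
              test_atom("B", 1, "LYS", "NZ", "N", 3.5, 0, 0),
              test_atom("B", 2, "LYS", "CB", "C", 3.6, 0, 0))
  atoms <- read_structure(write_test_pdb(at, tempfile(fileext = ".pdb")))
  co <- compute_contacts(atoms, "A", "B")
  sb <- detect_salt_bridges(co)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$basic_resid, "LYS")
  expect_equal(sb$min_distance, 3.5, tolerance = 1e-6)

  at$x[2L] <- 4.5  # beyond the salt-bridge cutoff (still a contact)
  atoms <- read_structure(write_test_pdb(at, tempfile(fileext = ".pdb")))
  expect_equal(nrow(detect_salt_bridges(compute_contacts(atoms, "A", "B"))),
               0L)
})

test_that("contact lists equal a brute-force all-pairs distance scan", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  co <- compute_contacts(atoms, "A", "B", cutoff = 4.5)
  a <- atoms[atoms$chain == "A", ]
  b <- atoms[atoms$chain == "B", ]
  brute <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
              (a$z[i] - b$z[j])^2)
    if (d <= 4.5) {
      brute <- brute + 1L
      expect_true(any(co$resno_a == a$resno[i] & co$elety_a == a$elety[i] &
                      co$resno_b == b$resno[j] & co$elety_b == b$elety[j] &
                      abs(co$distance - d) < 1e-9))
    }
  }
  expect_equal(nrow(co), brute)
  # symmetry: swapping the chain roles yields the same pair set
  rev <- compute_contacts(atoms, "B", "A", cutoff = 4.5)
  expect_equal(nrow(rev), nrow(co))
  expect_setequal(paste(co$resno_a, co$elety_a, co$resno_b, co$elety_b),
                  paste(rev$resno_b, rev$elety_b, rev$resno_a, rev$elety_a))
})

test_that("dihedrals round-trip the generating conformation within 1 degree", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  dih <- compute_dihedrals(atoms, "B")
  interior <- 2:(nrow(dih) - 1L)
  expect_true(all(abs(dih$phi[interior] - (-75)) < 1))
  expect_true(all(abs(dih$psi[interior] - 145) < 1))
  expect_true(all(is_ppii(dih)[interior]))
  expect_true(is.na(dih$phi[1L]))  # chain start has no phi

  fa <- gen_ppii_fixture("GALPAKPARSG", conformation = "ALPHA",
                         path = tempfile(fileext = ".pdb"))
  da <- compute_dihedrals(read_structure(fa$path), "B")
  expect_false(any(is_ppii(da), na.rm = TRUE))
})

test_that("package dihedrals agree with an independent torsion implementation", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  dih <- compute_dihedrals(read_structure(fx$path), "B")
  pdb <- bio3d::read.pdb(fx$path)
  tor <- bio3d::torsion.pdb(pdb)$tbl
  pep <- grep("\\.B\\.", rownames(tor))
  expect_equal(dih$phi, unname(tor[pep, "phi"]), tolerance = 1e-4)
  expect_equal(dih$psi, unname(tor[pep, "psi"]), tolerance = 1e-4)
})

test_that("rigid-body transforms change no contact, bridge or dihedral output", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  co <- compute_contacts(atoms, "A", "B")
  sb <- detect_salt_bridges(co)
  dih <- compute_dihedrals(atoms, "B")

  th <- 0.7; ph <- 1.3
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3,
               byrow = TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  moved <- atoms
  moved$x <- xyz[, 1L] + 11.1
  moved$y <- xyz[, 2L] - 5.2
  moved$z <- xyz[, 3L] + 0.37

  co2 <- compute_contacts(moved, "A", "B")
  expect_equal(nrow(co2), nrow(co))
  expect_equal(co2$distance, co$distance, tolerance = 1e-6)
  sb2 <- detect_salt_bridges(co2)
  expect_equal(sb2$min_distance, sb$min_distance, tolerance = 1e-6)
  dih2 <- compute_dihedrals(moved, "B")
  expect_equal(dih2$phi, dih$phi, tolerance = 1e-4)
  expect_equal(dih2$psi, dih$psi, tolerance = 1e-4)
})

test_that("planted salt bridges are recovered exactly", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  sb <- detect_salt_bridges(compute_contacts(atoms, "A", "B"))
  planted <- fx$truth$salt_bridges
  expect_equal(nrow(sb), nrow(planted))
  expect_setequal(paste(sb$basic_resno, sb$acidic_resno),
                  paste(planted$basic_resno, planted$acidic_resno))
  # salt bridges are a subset of contacts at the wider cutoff
  co <- compute_contacts(atoms, "A", "B", cutoff = 4.5)
  for (i in seq_len(nrow(sb)))
    expect_true(any(co$resno_a == sb$acidic_resno[i] &
                    co$resno_b == sb$basic_resno[i]))
})

test_that("register recovery from seeded PPII fixtures is exact", {
  set.seed(11)
  for (rep in 1:20) {
    pep <- random_motif_peptide()
    fx <- gen_ppii_fixture(pep$seq, path = tempfile(fileext = ".pdb"))
    atoms <- read_structure(fx$path)
    reg <- assign_register_from_structure(
      atoms, "A", "B", list(aromatic_resno = fx$truth$aromatic_resno))
    expect_false(reg$mismatch)
    expect_identical(as.integer(reg$register),
                     as.integer(fx$truth$register))
    expect_equal(reg$register[["0"]], pep$p0)
  }
})

test_that("a register planted on the wrong proline pair raises a mismatch warning", {
  # two proline pairs; markers planted on the second, sequence motif on the first
  fx <- gen_ppii_fixture("GAPAKPARPAKPARG", register_p0 = 9L,
                         path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  expect_warning(
    reg <- assign_register_from_structure(
      atoms, "A", "B", list(aromatic_resno = fx$truth$aromatic_resno)),
    "disagree")
  expect_true(reg$mismatch)
  expect_equal(reg$register[["0"]], 3L)  # sequence register wins
  expect_equal(reg$structural_anchors, c(9L, 12L))
})

test_that("a peptide with no groove contacts is unassignable", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  # strip the groove marker residues from the pseudo-SH3 chain
  pruned <- atoms[!(atoms$chain == "A" &
                    atoms$resno %in% fx$truth$aromatic_resno), ]
  expect_error(assign_register_from_structure(
    pruned, "A", "B", list(aromatic_resno = fx$truth$aromatic_resno)),
    "unassignable")
})

test_that("structure reading validates input and resolves altloc/hydrogens", {
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "no ATOM")

  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1      garbage"), bad)
  expect_error(read_structure(bad), "line 2")

  # altloc resolved to highest occupancy; hydrogens dropped
  at <- rbind(test_atom("A", 1, "SER", "CA", "C", 0, 0, 0, alt = "A", o = 0.4),
              test_atom("A", 1, "SER", "CA", "C", 9, 9, 9, alt = "B", o = 0.6),
              test_atom("A", 1, "SER", "HB1", "H", 1, 1, 1))
  atoms <- read_structure(write_test_pdb(at, tempfile(fileext = ".pdb")))
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$x, 9)

  # single-chain structures read fine but contact analyses refuse
  single <- read_structure(write_test_pdb(
    test_atom("A", 1, "ALA", "CA", "C", 0, 0, 0),
    tempfile(fileext = ".pdb")))
  expect_error(compute_contacts(single, "A", "B"), "chain 'B'")
})

test_that("the interface report bundles all analyses and serializes to JSON", {
  fx <- gen_ppii_fixture("GALPAKPARSG", path = tempfile(fileext = ".pdb"))
  atoms <- read_structure(fx$path)
  rep <- interface_report(atoms, "A", "B",
                          list(aromatic_resno = fx$truth$aromatic_resno))
  expect_s3_class(rep, "interface_report")
  expect_gt(nrow(rep$contacts), 0L)
  expect_equal(nrow(rep$salt_bridges), 2L)
  # anchor prolines contact the groove markers, position 2/5 the acidic atoms
  ps <- rep$pocket_summary
  expect_gt(ps$aromatic_contacts[ps$position == "0"], 0L)
  expect_gt(ps$aromatic_contacts[ps$position == "3"], 0L)
  expect_gt(ps$acidic_contacts[ps$position == "2"], 0L)
  expect_gt(ps$acidic_contacts[ps$position == "5"], 0L)
  path <- tempfile(fileext = ".json")
  write_interface_report(rep, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$register$`0`, 4L)
})
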