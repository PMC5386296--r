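test_that("toy complexes round-trip through the PDB parser", {
  path <- tempfile(fileext = ".pdb")
  make_toy_complex(3, list(c(2, 2)), path = path)
  s <- read_structure(path)
  expect_s3_class(s, "switch_structure")
  expect_equal(nrow(s$residues), 6)
  expect_setequal(unique(s$residues$chain_id), c("A", "B"))
  expect_equal(s$residues$seq_pos[s$residues$chain_id == "A"], 1:3)
  expect_true(all(s$residues$aa == "A"))
})

test_that("phosphoresidues SEP/TPO/PTR are detected with their parent amino acid", {
  path <- tempfile(fileext = ".pdb")
  make_toy_complex(4, sequence_a = "ASTY", sequence_b = "AAAA",
                   phospho = data.frame(chain = c("A", "A"), pos = c(2, 3)),
                   path = path)
  s <- read_structure(path)
  ph <- detect_phospho_residues(s)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$aa, c("S", "T"))
  expect_true(all(ph$phospho))
  # and a structure without any phosphoresidue gives an empty subset
  make_toy_complex(3, path = path)
  expect_equal(nrow(detect_phospho_residues(read_structure(path))), 0)
})

test_that("a TPO planted on chain B is reported at its position", {
  path <- tempfile(fileext = ".pdb")
  make_toy_complex(4, sequence_b = "ATAA",
                   phospho = data.frame(chain = "B", pos = 2), path = path)
  ph <- detect_phospho_residues(read_structure(path))
  expect_equal(ph$chain_id, "B")
  expect_equal(ph$seq_pos, 2)
  expect_equal(ph$aa, "T")
})

test_that("degenerate structure files are rejected", {
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "cannot read")
})

test_that("non-standard residues are skipped with a warning", {
  path <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "MSE", "A", 2, 5, 0, 0)
  ))
  expect_warning(s <- read_structure(path), "MSE")
  expect_equal(nrow(s$residues), 1)
})

test_that("contact cutoff is inclusive and monotone", {
  # exact CB-CB separation of 4.9 Angstrom across chains
  s <- read_structure(two_residue_pdb(4.9))
  m5 <- find_interface_contacts(s, "A", "B", cutoff = 5.0)
  expect_equal(nrow(m5$contacts), 1)
  expect_equal(m5$contacts$min_dist, 4.9, tolerance = 1e-6)
  m4 <- find_interface_contacts(s, "A", "B", cutoff = 4.0)
  expect_equal(nrow(m4$contacts), 0)
  # monotone non-decreasing contact count in the cutoff
  path <- tempfile(fileext = ".pdb")
  make_toy_complex(6, list(c(2, 2), c(5, 4)), path = path)
  st <- read_structure(path)
  counts <- sapply(c(2, 4, 5, 8, 40), function(ct)
    nrow(find_interface_contacts(st, "A", "B", cutoff = ct)$contacts))
  expect_true(all(diff(counts) >= 0))
})

test_that("missing chains raise a lookup error", {
  s <- read_structure(two_residue_pdb(4))
  expect_error(find_interface_contacts(s, "A", "C"), "chain")
})

test_that("mirrored homodimeric interfaces are flagged and contain the self contact", {
  path <- tempfile(fileext = ".pdb")
  seq <- "AAAASAAA"
  make_toy_complex(8, list(c(5, 5)), sequence_a = seq, sequence_b = seq,
                   path = path)
  m <- find_interface_contacts(read_structure(path), "A", "B")
  expect_true(m$homodimer)
  expect_true(any(m$contacts$pos_a == 5 & m$contacts$pos_b == 5))
  # the flag does not depend on which chain is named first
  m2 <- find_interface_contacts(read_structure(path), "B", "A")
  expect_true(m2$homodimer)
  expect_equal(nrow(m2$contacts), nrow(m$contacts))
})

test_that("side-chain ASA matches analytic sphere areas", {
  # isolated side-chain atom 100 A from its backbone: full sphere
  path <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 100, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 0, 0, 0)
  ))
  asa <- sidechain_asa(read_structure(path))
  expect_equal(asa$sidechain_asa[1], sphere_area(1.70), tolerance = 0.005)
  # two equal spheres at distance d: closed-form spherical-cap area
  d <- 3.0
  path2 <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 100, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 2, -100, 0, 0),
    pdb_atom_line(4, "CB", "ALA", "A", 2, d, 0, 0)
  ))
  asa2 <- sidechain_asa(read_structure(path2))
  expect_equal(asa2$sidechain_asa[1], two_sphere_exposed(1.70 + 1.4, d),
               tolerance = 0.01)
})

test_that("a densely caged side chain is buried and glycine scores zero", {
  # surround one CB with a shell of occluding atoms at 2.8 A
  pts <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3) * 2.8
  shell <- rbind(pts, 2.8 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  dimnames(shell) <- NULL
  lines <- c(pdb_atom_line(1, "CA", "SER", "A", 1, 50, 50, 50),
             pdb_atom_line(2, "CB", "SER", "A", 1, 0, 0, 0))
  for (i in seq_len(nrow(shell))) {
    lines <- c(lines, pdb_atom_line(2 + i, "CB", "ALA", "B", i,
                                    shell[i, 1], shell[i, 2], shell[i, 3]))
  }
  lines <- c(lines, pdb_atom_line(99, "CA", "GLY", "A", 2, -50, -50, -50))
  asa <- sidechain_asa(read_structure(write_mini_pdb(lines)))
  caged <- asa[asa$chain_id == "A" & asa$seq_pos == 1, ]
  expect_lt(caged$sidechain_asa, 5)
  gly <- asa[asa$aa == "G", ]
  expect_identical(gly$sidechain_asa, 0)
})

test_that("removing the partner chain never decreases a residue's ASA", {
  path <- tempfile(fileext = ".pdb")
  make_toy_complex(5, list(c(2, 2), c(4, 4)), path = path)
  s <- read_structure(path)
  both <- sidechain_asa(s)
  alone <- sidechain_asa(subset_chains(s, "A"))
  a_both <- both[both$chain_id == "A", "sidechain_asa"]
  expect_true(all(alone$sidechain_asa >= a_both - 1e-6))
})

test_that("a residue with missing side-chain atoms gets an unset ASA, not zero", {
  path <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0),  # no CB/OG present
    pdb_atom_line(2, "CA", "ALA", "A", 2, 50, 0, 0),
    pdb_atom_line(3, "CB", "ALA", "A", 2, 50, 1.5, 0)
  ))
  asa <- sidechain_asa(read_structure(path))
  expect_true(is.na(asa$sidechain_asa[1]))
  expect_false(is.na(asa$sidechain_asa[2]))
})

test_that("homologous-interface matching applies all three 50% criteria", {
  path <- tempfile(fileext = ".pdb")
  seq_a <- "ASTYKLMN"
  seq_b <- "DEFGHIKL"
  make_toy_complex(8, list(c(3, 4)), sequence_a = seq_a, sequence_b = seq_b,
                   path = path)
  q <- find_interface_contacts(read_structure(path), "A", "B")
  ident <- list(a = list(query = seq_a, template = seq_a),
                b = list(query = seq_b, template = seq_b))
  # identical duplicate: 100/100/100
  res <- find_homologous_interfaces(q, list(dup = q), list(dup = ident))
  expect_true(res$match)
  expect_equal(res$identity, 1.0)
  expect_equal(res$shared_interface, 1.0)
  # 37.5% identity fails the first criterion despite full coverage
  low_id <- list(a = list(query = seq_a, template = "ASTAAAAA"),
                 b = list(query = seq_b, template = seq_b))
  res2 <- find_homologous_interfaces(q, list(c2 = q), list(c2 = low_id))
  expect_false(res2$match)
  # good identity/coverage but disjoint interface residues fails the third
  path3 <- tempfile(fileext = ".pdb")
  make_toy_complex(8, list(c(7, 8)), sequence_a = seq_a, sequence_b = seq_b,
                   path = path3)
  cand3 <- find_interface_contacts(read_structure(path3), "A", "B")
  res3 <- find_homologous_interfaces(q, list(c3 = cand3), list(c3 = ident))
  expect_equal(res3$identity, 1.0)
  expect_false(res3$match)
  expect_equal(res3$shared_interface, 0)
  # candidates without alignments are skipped with a warning
  expect_warning(
    res4 <- find_homologous_interfaces(q, list(c4 = q), list()),
    "no alignment")
  expect_equal(nrow(res4), 0)
})

test_that("contacts TSV export carries the interface columns", {
  path <- tempfile(fileext = ".pdb")
  make_toy_complex(4, list(c(2, 3)), path = path)
  m <- find_interface_contacts(read_structure(path), "A", "B")
  out <- tempfile(fileext = ".tsv")
  write_contacts_tsv(m, out)
  got <- read.delim(out)
  expect_equal(nrow(got), 1)
  expect_true(all(c("struct_id", "chain_a", "pos_a", "aa_a", "phospho_a",
                    "chain_b", "pos_b", "aa_b", "phospho_b", "min_dist")
                  %in% names(got)))
})
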