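# Readers/writers and the domain-type invariants.

pdb_line <- function(serial, name, resname, resno, x, y, z, b,
                     record = "ATOM", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, resno, x, y, z, 1, b, element)
}

test_that("PDB fields map onto the model: residues, confidences, order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", 1, 0, 0, 0, 81.2),
    pdb_line(2, "CA", "ALA", 2, 3.8, 0, 0, 54.0),
    pdb_line(3, "CA", "ALA", 3, 7.6, 0, 0, 92.1),
    "END"), f)
  m <- read_structure(f)
  expect_s3_class(m, "protein_model")
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$confidence, c(81.2, 54.0, 92.1))
  expect_equal(m$residues$aa, rep("A", 3))
  expect_true(all(diff(m$residues$number) > 0))
})

test_that("HETATM-only files and duplicated residue numbers are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "C1", "LIG", 1, 0, 0, 0, 50, record = "HETATM"),
               "END"), f)
  expect_error(read_structure(f), "empty model")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", 1, 0, 0, 0, 80),
    pdb_line(2, "CA", "GLY", 1, 3.8, 0, 0, 80),   # same number, other residue
    "END"), f2)
  expect_error(read_structure(f2), "duplicate residue numbers")
})

test_that("hydrogens are dropped at parse time; heavy-atom counts match a text scan", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", 1, 0, 0, 0, 80),
    pdb_line(2, "H", "ALA", 1, 0.5, 0.5, 0, 80),
    pdb_line(3, "CA", "ALA", 1, 1.5, 0, 0, 80),
    pdb_line(4, "HA", "ALA", 1, 1.5, 1, 0, 80, element = "H"),
    pdb_line(5, "CA", "GLY", 2, 5.0, 0, 0, 70),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(m$atoms), text_scan_heavy_atoms(f))
})

test_that("parsed heavy-atom counts match the text-scan oracle on random synthetic models", {
  for (s in 1:20) {
    fold <- c("helix", "sheet-pair", "coil")[1 + s %% 3]
    m <- make_structure(10 + (s * 3) %% 40, fold, seed = s)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(m, f)
    expect_equal(nrow(m$atoms), text_scan_heavy_atoms(f), info = paste("seed", s))
  }
})

test_that("rosettafold-like confidences in [0,1] are normalized to 0-100", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "ALA", 1, 0, 0, 0, 0.90),
    pdb_line(2, "CA", "ALA", 2, 3.8, 0, 0, 0.50),
    "END"), f)
  m <- read_structure(f, source = "rosettafold-like")
  expect_equal(m$residues$confidence, c(90, 50))
  # normalization is idempotent: an already-0-100 model is unchanged
  m2 <- read_structure(f, source = "alphafold-like")
  expect_equal(m2$residues$confidence, c(0.90, 0.50))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f2)
  expect_equal(read_structure(f2)$residues$confidence, c(90, 50))
})

test_that("structure write/read is the identity on synthetic models", {
  m <- make_structure(40, "coil", seed = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f, model_id = m$model_id)
  expect_equal(m2$atoms[, c("resno", "elety", "x", "y", "z", "b")],
               m$atoms[, c("resno", "elety", "x", "y", "z", "b")])
  expect_equal(m2$residues, m$residues)
  # 0-1 scale round trip through the rosettafold convention
  m2r <- perturb_model(m, 1.5, seed = 2)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2r, f2, scale_out = "0-1")
  back <- read_structure(f2, source = "rosettafold-like", model_id = m2r$model_id)
  expect_equal(back$residues$confidence, m2r$residues$confidence)
  expect_equal(back$atoms$x, m2r$atoms$x)
})

test_that("aligned FASTA: shape, ragged error, taxon metadata, round trip", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a TaxID=9606", "ACDEF", ">b", "ACDEF"), f)
  x <- read_msa(f)
  expect_equal(x$depth, 2L)
  expect_equal(x$length, 5L)
  expect_equal(x$taxon, c(9606L, NA_integer_))

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACDEFG"), f2)
  expect_error(read_msa(f2), "format error")

  aln <- make_msa(12, 5, conserved_columns = 1:3, seed = 4)
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(aln, f3)
  back <- read_msa(f3)
  expect_equal(back$ali, aln$ali)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$taxon, aln$taxon)
})

test_that("mutation tables: parsing, category aliases, wild==mutant filter", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tposition\twild\tmutant\tcategory\tdisease",
               "P1\t7\tR\tC\tdisease\tX",
               "P1\t9\tA\tV\tLB/B\t",
               "P1\t11\tG\tG\tLP/P\tY"), f)
  expect_warning(mt <- read_mutations(f), "rejected")
  expect_equal(nrow(mt), 2L)
  expect_equal(mt$category, c("disease", "polymorphism"))
  expect_equal(mt$position, c(7L, 9L))
  # unknown categories are fatal after alias mapping
  expect_error(mutation_table(data.frame(
    accession = "P1", position = 1L, wild_aa = "A", mutant_aa = "V",
    category = "benign?", disease_name = "")), "unknown mutation categories")
  # round trip
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_mutations(mt, f2)
  expect_equal(as.data.frame(read_mutations(f2)), as.data.frame(mt))
})

test_that("predictor tables validate ranges and positions and round-trip", {
  m <- make_structure(20, "helix", seed = 1)
  tb <- make_predictors(m, planted_ligand = c(5L, 6L), spec = cohort_spec(),
                        seed = 3)
  d <- withr::local_tempdir()
  write_predictors(tb, d)
  back <- read_predictors(d, model = m)
  expect_equal(back$ligand_prob, tb$ligand_prob)
  expect_equal(back$foldx_ddg, tb$foldx_ddg)
  expect_equal(back$pathogenicity, tb$pathogenicity)
  # invariant violations
  expect_error(predictor_tables(
    setNames(1.2, 1), setNames(0.1, 1),
    data.frame(position = 1, mutant = "V", value = 0),
    data.frame(position = 1, mutant = "V", value = 0),
    data.frame(position = 1, mutant = "V", value = 0.5),
    setNames(0.1, 1)), "outside")
  expect_error(predictor_tables(
    setNames(0.5, 99), setNames(0.1, 1),
    data.frame(position = 1, mutant = "V", value = 0),
    data.frame(position = 1, mutant = "V", value = 0),
    data.frame(position = 1, mutant = "V", value = 0.5),
    setNames(0.1, 1), model = m), "absent from the model")
})

test_that("domain segments enforce ordering, disjointness and the 50-residue rule", {
  s <- domain_segment("P1", rbind(c(10, 20), c(30, 40)), "CATH")
  expect_equal(segment_positions(s), c(10:20, 30:40))
  expect_error(domain_segment("P1", rbind(c(10, 25), c(20, 40)), "CATH"),
               "overlap")
  expect_error(domain_segment("P1", cbind(10, 40), "unassigned"),
               "at least 50")
  expect_silent(domain_segment("P1", cbind(10, 60), "unassigned"))
})
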