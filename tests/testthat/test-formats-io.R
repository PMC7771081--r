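test_that("FASTA reading validates sequences and preserves order", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACDE"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$sequence, "ACDE")
  expect_equal(length(recs[[1]]), 4L)

  writeLines(c(">a desc", "acd*", ">b", "GHIK"), f)
  recs2 <- read_fasta(f)
  expect_equal(vapply(recs2, `[[`, character(1), "id"), c("a", "b"))
  expect_equal(recs2[[1]]$sequence, "ACD")  # upper-cased, '*' stripped

  writeLines(c(">bad", "ABDE"), f)
  expect_error(read_fasta(f), "B")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|malformed")
})

test_that("MSA dialects normalize to the query's columns", {
  f <- tempfile(fileext = ".a3m")
  writeLines(c(">q", "ACD", ">hit", "A-dC"), f)
  msa <- read_msa(f, "a3m")
  expect_equal(msa$rows, c("ACD", "A-C"))  # lowercase insertion removed

  g <- tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACDE", ">dup", "ACDE"), g)
  msa2 <- read_msa(g, "aligned_fasta")
  expect_length(msa2$rows, 2L)
  expect_equal(msa2$rows[1], msa2$rows[2])

  writeLines(c(">q", "ACD", ">short", "AC"), g)
  expect_error(read_msa(g, "aligned_fasta"), "row 2")
})

test_that("PDB reading takes model 1, picks altlocs, applies the Gly rule", {
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(f, c(
    "MODEL     1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0, 0),
    pdb_atom_line(5, "CB", "SER", "A", 3, 8.2, 1, 0),
    "ENDMDL",
    "MODEL     2",
    pdb_atom_line(6, "CA", "ALA", "A", 1, 99, 0, 0),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 99, 3, 0),
    pdb_atom_line(8, "CA", "SER", "A", 3, 99, 6, 0),
    "ENDMDL"))
  rec <- read_structure(f, "A")
  expect_equal(rec$sequence, "AGS")
  expect_equal(rec$ca_coords[, 1], c(0, 3.8, 7.6))  # model 1 only
  expect_equal(rec$cb_coords[2, ], rec$ca_coords[2, ])  # Gly: CB = CA
  expect_equal(rec$cb_coords[1, ], c(1.5, 0, 0))
  expect_equal(nchar(rec$sequence), nrow(rec$ca_coords))
  expect_error(read_structure(f, "B"), "available: A")

  write_toy_pdb(f, c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 3, 7.6, 0, 0)))
  all_gly <- read_structure(f, "A")
  expect_equal(all_gly$cb_coords, all_gly$ca_coords)
})

test_that("matrix files must be square and become symmetric", {
  f <- tempfile()
  writeLines(c("0 1", "1 0"), f)
  expect_equal(read_matrix(f), matrix(c(0, 1, 1, 0), 2, 2))

  writeLines(c("0,0.5", "0.5,0"), f)
  expect_equal(read_matrix(f)[1, 2], 0.5)  # comma dialect

  writeLines(c("0 1", "0 0"), f)
  expect_warning(m <- read_matrix(f), "symmetriz")
  expect_equal(m, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  writeLines(c("0 1 0", "1 0 0"), f)
  expect_error(suppressWarnings(read_matrix(f)), "square")
})

test_that("alignment TSV round-trips exactly and PIR lays out gaps", {
  tpl <- protein_record("tpl", "ACD")
  qry <- protein_record("qry", "AC")
  res <- structure(list(pairs = cbind(t = c(1L, 3L), q = c(1L, 2L)),
                        score = 1.1, alpha = 0.3),
                   class = "alignment_result")
  f <- tempfile(fileext = ".tsv")
  write_alignment(res, tpl, qry, f, "tsv", probs = c(0.9, 0.8))
  back <- read_alignment_tsv(f)
  expect_equal(unname(back$pairs), unname(res$pairs))
  expect_equal(back$probs, c(0.9, 0.8))
  # the on-disk interchange convention is 0-based
  raw <- utils::read.delim(f)
  expect_equal(raw$template_index, c(0L, 2L))

  g <- tempfile(fileext = ".pir")
  write_alignment(res, tpl, qry, g, "pir")
  lines <- readLines(g)
  expect_equal(lines[3], "ACD*")  # one template deletion
  expect_equal(lines[6], "A-C*")

  single <- structure(list(pairs = cbind(t = 1L, q = 1L), score = 0.5,
                           alpha = 0.3), class = "alignment_result")
  write_alignment(single, protein_record("t1", "A"),
                  protein_record("q1", "A"), g, "pir")
  expect_equal(readLines(g)[c(3, 6)], c("A*", "A*"))

  empty <- structure(list(pairs = cbind(t = integer(0), q = integer(0)),
                          score = 0, alpha = 0.3),
                     class = "alignment_result")
  write_alignment(empty, tpl, qry, f, "tsv")
  expect_equal(nrow(utils::read.delim(f)), 0L)
  expect_warning(out <- write_alignment(empty, tpl, qry, g, "pir"),
                 "empty")
  expect_null(out)
})

test_that("reference alignments round-trip through TSV", {
  ref <- reference_alignment(cbind(c(2L, 5L, 9L), c(1L, 4L, 6L)),
                             weights = c(1, 0.5, 0.25))
  f <- tempfile(fileext = ".tsv")
  write_reference_tsv(ref, f)
  back <- read_reference_tsv(f)
  expect_equal(back$pairs, ref$pairs)
  expect_equal(back$weights, ref$weights)
})

test_that("record constructors enforce their invariants", {
  expect_error(protein_record("x", "AB"), "B")
  expect_error(protein_record("x", "AC", ca_coords = matrix(0, 3, 3)),
               "3 x 3|2 x 3")
  expect_error(protein_record("x", "AC",
                              ca_coords = matrix(c(0, Inf), 2, 3)),
               "finite")
  expect_error(protein_msa("q", c("AC-", "ACD")), "ungapped")
  expect_error(reference_alignment(cbind(c(1L, 1L), c(1L, 2L))),
               "increasing")
  expect_error(reference_alignment(cbind(1L, 1L), weights = 2), "\\[0, 1\\]")
})
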