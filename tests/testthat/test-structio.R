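test_that("a minimal one-atom PDB reads into a 1-chain/1-residue/1-atom structure", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   7      1.000   2.000   3.000  1.00 12.00           C",
    "END"), tf)
  s <- read_structure(tf)
  expect_s3_class(s, "lobe_structure")
  expect_equal(nrow(s), 1)
  expect_equal(s$chain, "A")
  expect_equal(s$resno, 7L)
  expect_equal(c(s$x, s$y, s$z), c(1, 2, 3))
  expect_equal(s$bfactor, 12)
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties -> first altloc", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1      0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1      9.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA AALA A   2      0.000   5.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   2      9.000   5.000   0.000  0.50 10.00           C",
    "END"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s), 2)
  expect_equal(s$altloc, c("B", "A"))
  expect_equal(s$x, c(9, 0))
})

test_that("unreadable and empty files raise informative errors", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", tf)
  expect_error(read_structure(tf), "empty|parse")
})

test_that("structure write -> read round-trips coordinates to PDB precision", {
  h <- make_ideal_helix(helix_spec(12), full_backbone = TRUE)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, tf)
  h2 <- read_structure(tf)
  expect_equal(nrow(h2), nrow(h))
  expect_lt(max(abs(coords_matrix(h) - coords_matrix(h2))), 1e-3)
})

test_that("assembly expansion applies operators exactly and renames chains", {
  h <- make_ideal_helix(helix_spec(8))
  # identity only: congruent output
  asm0 <- build_assembly(h, "all")
  expect_equal(structure_chains(asm0), "A1")
  expect_equal(coords_matrix(asm0), coords_matrix(h))

  R2 <- rotation_about_axis(c(0, 0, 1), 180)
  ops <- list(list(R = diag(3), t = c(0, 0, 0)),
              list(R = R2, t = c(12, 0, 0)))
  s <- new_structure(tibble::as_tibble(h), assembly_ops = ops)
  asm <- build_assembly(s, "all")
  expect_equal(structure_chains(asm), c("A1", "A2"))
  # image centroid = R %*% centroid + t
  cen <- colMeans(coords_matrix(h))
  img <- colMeans(coords_matrix(asm)[tibble::as_tibble(asm)$chain == "A2", ])
  expect_equal(unname(img), as.numeric(R2 %*% cen + c(12, 0, 0)),
               tolerance = 1e-12)
  # exact C2 symmetry: applying the operator again maps A2 back onto A1
  a2 <- coords_matrix(asm)[tibble::as_tibble(asm)$chain == "A2", ]
  back <- sweep(a2, 2, c(12, 0, 0)) %*% R2  # R2 is its own inverse transpose
  expect_lt(max(abs(back - coords_matrix(h))), 1e-9)
  # rigid transform preserves intra-chain distances
  expect_lt(max(abs(dist(a2) - dist(coords_matrix(h)))), 1e-6)
  # missing operators are refused with the available indices listed
  expect_error(build_assembly(s, 5), "available|stored")
})

test_that("per-residue scores land in the B-factor column and round-trip", {
  h <- make_ideal_helix(helix_spec(10), full_backbone = TRUE)
  tf <- withr::local_tempfile(fileext = ".pdb")
  # all zero
  sc0 <- tibble::tibble(chain = "A", resno = 1:10, score = 0)
  write_structure_with_scores(h, sc0, tf)
  expect_true(all(read_structure(tf)$bfactor == 0))
  # single scored residue, others sentinel
  sc1 <- tibble::tibble(chain = "A", resno = 3, score = 0.5)
  write_structure_with_scores(h, sc1, tf)
  rt <- read_structure(tf)
  expect_true(all(rt$bfactor[rt$resno == 3] == 0.5))
  expect_true(all(rt$bfactor[rt$resno != 3] == 0))
  # an entropy-like profile round-trips to 0.01
  sc <- tibble::tibble(chain = "A", resno = 1:10,
                       score = seq(0.05, 0.95, length.out = 10))
  write_structure_with_scores(h, sc, tf)
  rt <- read_structure(tf)
  got <- dplyr::distinct(tibble::as_tibble(rt), resno, bfactor)
  expect_equal(got$bfactor[order(got$resno)], sc$score, tolerance = 0.011)
  # scores for residues absent from the structure are an error
  expect_error(write_structure_with_scores(
    h, tibble::tibble(chain = "A", resno = 99, score = 1), tf), "absent")
})

test_that("MSA FASTA I/O normalizes symbols and rejects ragged alignments", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDEF", ">s2", "ac.ef"), tf)
  m <- read_msa(tf)
  expect_equal(msa_width(m), 5L)
  expect_equal(m$seq[2], "AC-EF")
  writeLines(c(">s1", "ACDEF", ">bad", "ACD"), tf)
  expect_error(read_msa(tf), "bad")
  # round-trip of a larger synthetic alignment is exact
  big <- make_synthetic_msa(50, 100, 0.3, gap_profile = 0.05, seed = 31)
  write_msa(big, tf)
  expect_identical(read_msa(tf)$seq, big$seq)
  expect_identical(read_msa(tf)$id, big$id)
})
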