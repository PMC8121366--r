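test_that("p-distances match direct column counting", {
  m <- msa(c("a", "b"), c("AAAA", "AACC"))
  d <- distance_matrix(m)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(diag(d), c(a = 0, b = 0))
  ident <- msa(c("x", "y"), c("ACDE", "ACDE"))
  expect_equal(distance_matrix(ident)["x", "y"], 0)
  # gap columns are excluded from the comparison
  g <- msa(c("x", "y"), c("A-CD", "AAC-"))
  expect_equal(distance_matrix(g)["x", "y"], 0)  # comparable: pos 1, 3
  # no comparable columns -> distance 1 with a warning
  expect_warning(dd <- distance_matrix(msa(c("x", "y"), c("A--", "-AA"))),
                 "comparable")
  expect_equal(dd["x", "y"], 1)
  expect_error(distance_matrix(msa("x", "AA")), "two sequences")
})

test_that("a seeded random alignment matches a brute-force recount", {
  m <- make_synthetic_msa(10, 30, 0.4, gap_profile = 0.1, seed = 41)
  d <- distance_matrix(m)
  chars <- strsplit(m$seq, "")
  for (i in 1:9) for (j in (i + 1):10) {
    ci <- chars[[i]]; cj <- chars[[j]]
    comp <- ci != "-" & cj != "-"
    want <- if (sum(comp) == 0) 1 else 1 - sum(ci[comp] == cj[comp]) / sum(comp)
    expect_equal(d[i, j], want)
  }
})

test_that("pruning removes the duplicate and is the identity at target n", {
  m <- msa(c("s1", "s2", "s3"), c("ACDE", "ACDE", "WWWW"))
  p <- prune_redundancy(m, 2)
  expect_equal(p$id, c("s1", "s3"))  # later duplicate removed on the tie
  expect_identical(prune_redundancy(m, 3)$seq, m$seq)
  expect_error(prune_redundancy(m, 1), "target_n")
  expect_error(prune_redundancy(m, 4), "target_n")
})

test_that("the five-sequence hand-traced case prunes exactly as the rule dictates", {
  # d(s1,s2)=0 -> tie on means -> drop s2 (higher index);
  # next pair (s1,s3) at 0.25 (lexicographic tie-break over (s4,s5)):
  # mean dists are tied at 2/3 -> drop s3 (higher index); 3 survive.
  m <- msa(c("s1", "s2", "s3", "s4", "s5"),
           c("AAAA", "AAAA", "AAAC", "CCCC", "CCCA"))
  p <- prune_redundancy(m, 3)
  expect_equal(p$id, c("s1", "s4", "s5"))
})

test_that("pruning matches the independent naive oracle on seeded alignments", {
  for (seed in c(5, 6, 7)) {
    m <- make_synthetic_msa(18, 25, 0.35,
                            redundancy = list(n_clusters = 6,
                                              mutations_per_copy = 2),
                            seed = seed)
    for (target in c(6, 10)) {
      got <- prune_redundancy(m, target)
      expect_equal(got$id, prune_oracle_ids(m, target))
      expect_equal(nrow(got), target)
    }
  }
})

test_that("pruning is deterministic and spreads the surviving set out", {
  m <- make_synthetic_msa(40, 30, 0.3,
                          redundancy = list(n_clusters = 8,
                                            mutations_per_copy = 1),
                          seed = 51)
  p1 <- prune_redundancy(m, 8)
  p2 <- prune_redundancy(m, 8)
  expect_identical(p1$id, p2$id)
  mean_od <- mean(distance_matrix(m)[upper.tri(diag(nrow(m)))])
  mean_pd <- mean(distance_matrix(p1)[upper.tri(diag(8))])
  expect_gte(mean_pd, mean_od)
  # every redundancy cluster keeps at least one member
  cl <- attr(m, "clusters")
  expect_setequal(unique(cl[match(p1$id, m$id)]), unique(cl))
})

test_that("greedy pruning removes from the closest pair first", {
  # removing a single sequence must take it from the globally closest pair,
  # and no more-distant pair may lose a member while a closer pair still has
  # both members present (checked by replaying the removal order)
  for (seed in c(61, 62, 63)) {
    m <- make_synthetic_msa(15, 20, 0.3,
                            redundancy = list(n_clusters = 5,
                                              mutations_per_copy = 1),
                            seed = seed)
    d <- distance_matrix(m)
    pr <- which(upper.tri(d), arr.ind = TRUE)
    closest <- pr[which.min(d[pr]), ]
    removed_one <- setdiff(m$id, prune_redundancy(m, nrow(m) - 1)$id)
    expect_true(removed_one %in% m$id[closest])
    # successive targets nest: the n-1 survivor set contains the n-2 set, etc.
    prev <- m$id
    for (target in seq(nrow(m) - 1, 5)) {
      cur <- prune_redundancy(m, target)$id
      expect_true(all(cur %in% prev))
      expect_length(cur, target)
      prev <- cur
    }
  }
})

test_that("column entropy hits its closed forms", {
  all_a <- msa(c("a", "b"), c("A", "A"))
  expect_equal(column_entropy(all_a)$entropy, 0)
  twenty <- msa(sprintf("s%02d", 1:20), lobescope:::.aa_standard)
  expect_equal(column_entropy(twenty)$entropy, 1)
  half <- msa(c("a", "b"), c("A", "V"))
  expect_equal(column_entropy(half)$entropy, log(2, base = 20))
  expect_equal(column_entropy(half)$entropy, 0.2313782, tolerance = 1e-6)
})

test_that("entropy handles gaps, ambiguity codes and empty columns as specified", {
  m <- msa(c("a", "b", "c", "d"), c("A-XA", "A-XC", "ACX-", "-CXG"))
  prof <- column_entropy(m, gap_max = 0.4)
  # column 1: three A's (gap excluded) -> S = 0
  expect_equal(prof$entropy[1], 0)
  expect_equal(prof$gap_fraction[1], 0.25)
  # column 2: gap fraction 0.5 > 0.4 -> flagged but computed
  expect_true(prof$gap_flagged[2])
  expect_equal(prof$entropy[2], 0)
  # column 3: only X -> undefined, not an exception
  expect_true(prof$undefined[3])
  expect_true(is.na(prof$entropy[3]))
  # column 4: A, C, G equally -> S = log20(3)
  expect_equal(prof$entropy[4], log(3, base = 20))
})

test_that("entropy is invariant to row order and to duplicating every row", {
  m <- make_synthetic_msa(12, 15, 0.4, seed = 71)
  base <- column_entropy(m)$entropy
  perm <- msa(paste0("p", seq_len(nrow(m))), sample(m$seq))
  expect_equal(column_entropy(perm)$entropy, base)
  doubled <- msa(c(m$id, paste0(m$id, "_dup")), c(m$seq, m$seq))
  expect_equal(column_entropy(doubled)$entropy, base)
})

test_that("residue frequencies are unit vectors for a single sequence and sum to 1", {
  one <- msa("only", "AV")
  fr <- residue_frequencies(one)
  expect_equal(fr$A[1], 1)
  expect_equal(fr$V[2], 1)
  m <- make_synthetic_msa(30, 20, 0.5, gap_profile = 0.1, seed = 81)
  fr2 <- residue_frequencies(m)
  sums <- rowSums(fr2[, lobescope:::.aa_standard])
  expect_true(all(abs(sums[fr2$n_effective > 0] - 1) < 1e-9))
})

test_that("entropy maps onto a structure through the reference sequence", {
  m <- make_synthetic_msa(20, 15, 0.3, seed = 91)
  prof <- column_entropy(m)
  ref_seq <- m$seq[1]
  s <- make_ideal_helix(helix_spec(15, sequence = ref_seq))
  mapped <- map_entropy_to_structure(s, prof, m, reference_id = m$id[1])
  expect_equal(mapped$scores$score, round(prof$entropy, 10), tolerance = 1e-9)
  expect_equal(unique(mapped$structure$bfactor),
               unique(round(prof$entropy, 2)))
  # fully conserved alignment maps all zeros
  cons <- msa(c("r1", "r2"), c(ref_seq, ref_seq))
  pc <- column_entropy(cons)
  m0 <- map_entropy_to_structure(s, pc, cons, "r1")
  expect_true(all(m0$structure$bfactor == 0))
})

test_that("an N-terminally truncated structure maps with the correct offset", {
  m <- make_synthetic_msa(20, 15, 0.3, seed = 95)
  prof <- column_entropy(m)
  full <- m$seq[1]
  trunc <- substr(full, 4, 15)                 # drop 3 N-terminal residues
  s <- make_ideal_helix(helix_spec(12, sequence = trunc))
  mapped <- map_entropy_to_structure(s, prof, m, reference_id = m$id[1])
  expect_equal(mapped$scores$score, prof$entropy[4:15], tolerance = 1e-9)
})

test_that("mapping errors are informative", {
  m <- make_synthetic_msa(10, 12, 0.3, seed = 97)
  prof <- column_entropy(m)
  s <- make_ideal_helix(helix_spec(12, sequence = m$seq[1]))
  expect_error(map_entropy_to_structure(s, prof, m, "nope"), "not in alignment")
  unrelated <- make_ideal_helix(helix_spec(12, sequence = "WWWWWWWWWWWW"))
  expect_error(map_entropy_to_structure(unrelated, prof, m, m$id[1]),
               "identity")
})

test_that("entropy TSV and position-frequency tables are written", {
  m <- make_synthetic_msa(10, 8, 0.4, seed = 99)
  prof <- column_entropy(m)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_tsv(prof, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(nrow(back), 8)
  expect_true(all(c("column", "entropy", "top_residues") %in% names(back)))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_pfm(m, tf2)
  pfm <- readr::read_tsv(tf2, show_col_types = FALSE)
  expect_equal(dim(pfm), c(8, 21))
})
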