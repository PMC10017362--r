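# Alignment parsing, occupancy/conservation profiling, consensus trimming,
# reference mapping and construct assembly.

test_that("aligned_family validates lengths and alphabet", {
  fam <- aligned_family(c("a", "b"), c("AC-", "A-C"))
  expect_equal(fam$alignment_length, 3L)
  expect_error(aligned_family(c("a", "b"), c("ACD", "ACDE")),
               "record 2 \\('b'\\) has length 4")
  expect_error(aligned_family("a", "AC*D"), "illegal symbol '\\*'")
  # '.' gaps normalized, lowercase uppercased
  fam2 <- aligned_family("a", "ac.d")
  expect_equal(fam2$seqs, "AC-D")
})

test_that("alignment FASTA round-trips through write/parse", {
  fam <- random_family(8, 30)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(fam, path)
  back <- parse_alignment(path)
  expect_equal(back$ids, fam$ids)
  expect_equal(back$seqs, fam$seqs)
  expect_error(parse_alignment(file.path(tempdir(), "nope.fa")),
               "no such file")
})

test_that("column profiles match hand counts", {
  # column: 5xA, 3xG, 2 gaps over 10 rows
  fam <- aligned_family(sprintf("s%d", 1:10),
                        c(rep("A", 5), rep("G", 3), rep("-", 2)))
  prof <- compute_column_profiles(fam)
  expect_equal(prof$occupancy, 0.8)
  expect_equal(prof$consensus, "A")
  expect_equal(prof$conservation, 0.625)
  expect_equal(prof$counts[[1]][["A"]], 5L)

  # identical sequences: occupancy and conservation 1 everywhere
  fam2 <- aligned_family(sprintf("s%d", 1:10), rep("MKWVT", 10))
  prof2 <- compute_column_profiles(fam2)
  expect_true(all(prof2$occupancy == 1))
  expect_true(all(prof2$conservation == 1))
  expect_equal(paste(prof2$consensus, collapse = ""), "MKWVT")

  # all-gap column: occupancy 0, consensus NA
  fam3 <- aligned_family(c("a", "b"), c("A-C", "G-C"))
  prof3 <- compute_column_profiles(fam3)
  expect_equal(prof3$occupancy[2], 0)
  expect_true(is.na(prof3$consensus[2]))
})

test_that("ties break by the fixed residue order and X never wins", {
  # A vs G tie: A precedes G in ARNDCQEGHILKMFPSTWYV
  fam <- aligned_family(c("a", "b"), c("A", "G"))
  expect_equal(compute_column_profiles(fam)$consensus, "A")
  # X outnumbers A but cannot win; counts toward occupancy
  fam2 <- aligned_family(c("a", "b", "c"), c("X", "X", "A"))
  prof2 <- compute_column_profiles(fam2)
  expect_equal(prof2$consensus, "A")
  expect_equal(prof2$occupancy, 1)
  # column of only extended codes: the modal extended code wins
  fam3 <- aligned_family(c("a", "b"), c("X", "X"))
  expect_equal(compute_column_profiles(fam3)$consensus, "X")
})

test_that("profiles equal the brute-force oracle on random families", {
  withr::with_seed(31, {
    for (dims in list(c(5, 20), c(20, 80), c(50, 200))) {
      fam <- random_family(dims[1], dims[2])
      prof <- compute_column_profiles(fam)
      orc <- oracle_profiles(fam)
      expect_equal(prof$occupancy,
                   vapply(orc, `[[`, numeric(1), "occupancy"))
      expect_equal(prof$conservation,
                   vapply(orc, `[[`, numeric(1), "conservation"))
      expect_equal(prof$consensus,
                   vapply(orc, `[[`, character(1), "consensus"))
    }
  })
})

test_that("column permutation permutes profiles identically", {
  withr::with_seed(32, {
    fam <- random_family(12, 40)
    perm <- sample(40)
    mat <- do.call(rbind, strsplit(fam$seqs, ""))
    fam2 <- aligned_family(fam$ids,
                           apply(mat[, perm], 1, paste, collapse = ""))
    p1 <- compute_column_profiles(fam)
    p2 <- compute_column_profiles(fam2)
    expect_equal(p2$occupancy, p1$occupancy[perm])
    expect_equal(p2$consensus, p1$consensus[perm])
  })
})

test_that("build_consensus keeps exactly the at-threshold columns", {
  fam <- aligned_family(sprintf("s%02d", 1:10), c(
    rep("AC-", 1), rep("ACD", 9)))  # col 3 occupancy 0.9, col 2 1.0
  prof <- compute_column_profiles(fam)
  expect_error(build_consensus(prof, 0), "\\(0, 1\\]")
  expect_error(build_consensus(prof, 1.2), "\\(0, 1\\]")

  # occupancy exactly at the threshold is kept (strictly-below removed)
  fam2 <- aligned_family(sprintf("s%02d", 1:10),
                         c(rep("A-", 9), "AG"))  # col 2 occupancy 0.10
  cons <- build_consensus(compute_column_profiles(fam2), 0.10)
  expect_equal(cons$kept_columns, c(1L, 2L))
  cons2 <- build_consensus(compute_column_profiles(fam2), 0.11)
  expect_equal(cons2$kept_columns, 1L)

  # all-identical family: consensus equals the member
  fam3 <- aligned_family(c("a", "b"), rep("MKWVT", 2))
  expect_equal(build_consensus(
    compute_column_profiles(fam3))$consensus_sequence, "MKWVT")
})

test_that("raising the threshold never lengthens the consensus", {
  withr::with_seed(33, {
    fam <- random_family(20, 60, gap_prob = 0.4)
    prof <- compute_column_profiles(fam)
    lens <- vapply(seq(0.05, 1, by = 0.05), function(th)
      nchar(build_consensus(prof, th)$consensus_sequence), numeric(1))
    expect_true(all(diff(lens) <= 0))
  })
})

test_that("sub-threshold insert columns are trimmed and truth recovered", {
  fs <- family_spec(strrep("ACDEFGHIKLMNPQRSTVWY", 3), 500,
                    per_column_conservation = 0.7,
                    insert_blocks = list(
                      list(anchor = 20, length = 5, carrier_fraction = 0.05),
                      list(anchor = 45, length = 3, carrier_fraction = 0.05)),
                    seed = 97)
  g <- generate_family(fs)
  prof <- compute_column_profiles(g$family)
  cons <- build_consensus(prof, 0.10)
  # every insert column is below threshold and removed
  expect_true(all(g$truth$occupancy[g$truth$is_insert] < 0.10))
  expect_true(!any(which(g$truth$is_insert) %in% cons$kept_columns))
  # all core columns kept, truth consensus recovered at >= 99% of them
  expect_equal(cons$kept_columns, g$truth$core_columns)
  agree <- mean(strsplit(cons$consensus_sequence, "")[[1]] ==
                  strsplit(g$truth$consensus, "")[[1]])
  expect_gte(agree, 0.99)
})

test_that("map_to_reference numbers ungapped reference residues", {
  fam <- aligned_family(c("ref", "x"), c("A-CD", "AGCD"))
  m <- map_to_reference(fam, "ref")
  expect_equal(m$pairs$column, c(1L, 3L, 4L))
  expect_equal(m$pairs$ref_number, 1:3)
  expect_equal(m$pairs$ref_residue, c("A", "C", "D"))
  expect_error(map_to_reference(fam, "nope"), "not found")

  # lookup at a gapped reference column is NA, not an error
  cons <- build_consensus(compute_column_profiles(fam), 0.10)
  m2 <- map_to_reference(fam, "ref", cons)
  expect_true(is.na(m2$consensus_to_reference$ref_number[2]))
})

test_that("a reference-only N-terminal extension offsets numbering", {
  # mimic of the 12-residue offset between consensus and reference
  # numbering: reference has 12 extra N-terminal residues, consensus side
  # is gapped there
  ext <- strrep("M", 12)
  core <- "ACDEFGHIKLMNPQRSTVWY"
  fam <- aligned_family(
    c("ref", sprintf("s%02d", 1:9)),
    c(paste0(ext, core), rep(paste0(strrep("-", 12), core), 9)))
  prof <- compute_column_profiles(fam)
  cons <- build_consensus(prof, 0.15)  # drops the 12 ref-only columns
  expect_equal(nchar(cons$consensus_sequence), nchar(core))
  m <- map_to_reference(fam, "ref", cons)
  ctr <- m$consensus_to_reference
  expect_equal(ctr$ref_number, ctr$consensus_position + 12L)
  expect_equal(reference_to_consensus(m, 13L), 1L)
})

test_that("construct assembly follows the tag-replacement rule", {
  cons <- "MSPPNNNCOREPXXX"
  regions <- region_annotation(
    c("signal_peptide", "prodomain_nonconserved", "prodomain_conserved",
      "c_terminal_tail"),
    start = c(1, 3, 5, 13), end = c(2, 4, 12, 15))
  d <- assemble_construct(cons, regions)
  expect_equal(d$sequence, paste0("HHHHHH", "NNNCOREP", "HHHHHH"))
  # edit log replays byte-for-byte
  expect_equal(replay_edits(d), d$sequence)

  # empty tags and no regions: identity
  d2 <- assemble_construct(cons, NULL, n_tag = "", c_tag = "")
  expect_equal(d2$sequence, cons)
  expect_equal(replay_edits(d2), cons)

  expect_error(region_annotation(c("core", "cap"), c(1, 3), c(5, 8)),
               "overlap")
  expect_error(region_annotation("inner_membrane", 1, 2), "unknown region")
  bad <- region_annotation("c_terminal_tail", 40, 50)
  expect_error(assemble_construct(cons, bad), "out of bounds")
})
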