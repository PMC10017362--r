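# Synthetic-data generators: determinism, truth metadata, degenerate
# specs and statistical sanity.

test_that("family generation is deterministic and validates its spec", {
  fs <- family_spec("ACDEFGHIKL", 20, 0.8, seed = 5)
  g1 <- generate_family(fs)
  g2 <- generate_family(fs)
  expect_identical(g1$family$seqs, g2$family$seqs)
  expect_identical(g1$truth, g2$truth)

  expect_error(family_spec("ACDB", 5), "nonstandard residue")
  expect_error(
    family_spec("ACDE", 5, insert_blocks = list(
      list(anchor = 9, length = 2, carrier_fraction = 0.05))),
    "anchored at column 9")
})

test_that("full conservation without inserts reproduces the truth", {
  fs <- family_spec("MKWVTFISLLFLFSSAYS", 10, 1.0, seed = 3)
  g <- generate_family(fs)
  expect_true(all(g$family$seqs == fs$truth_consensus))
  expect_true(all(g$truth$occupancy == 1))
})

test_that("insert blocks produce sparse columns with correct bookkeeping", {
  fs <- family_spec(strrep("ACDEFGHIKL", 2), 200, 1.0,
                    insert_blocks = list(
                      list(anchor = 10, length = 5,
                           carrier_fraction = 0.05)),
                    seed = 8)
  g <- generate_family(fs)
  expect_equal(g$family$alignment_length, 25L)
  expect_equal(which(g$truth$is_insert), 11:15)
  # realized occupancy near the carrier fraction, identical across the
  # block (one carrier draw per row), and matching an independent count
  ins_occ <- g$truth$occupancy[11:15]
  expect_true(all(ins_occ == ins_occ[1]))
  expect_lt(abs(ins_occ[1] - 0.05), 0.04)
  mat <- do.call(rbind, strsplit(g$family$seqs, ""))
  expect_equal(unname(colMeans(mat != "-")), unname(g$truth$occupancy))
  # core columns fully occupied
  expect_true(all(g$truth$occupancy[-(11:15)] == 1))
})

test_that("truth occupancy equals the profile module's computation", {
  fs <- family_spec(strrep("WYKL", 5), 50, 0.6,
                    insert_blocks = list(
                      list(anchor = 4, length = 3, carrier_fraction = 0.08)),
                    seed = 13)
  g <- generate_family(fs)
  prof <- compute_column_profiles(g$family)
  expect_equal(prof$occupancy, unname(g$truth$occupancy))
})

test_that("LAD variant generation honours labels and degenerate cases", {
  base <- "ACDEGHIKLMNGQRSTV"  # Gly at 5 and 12
  expect_equal(nrow(generate_lad_variants(base, c(12, 5), 0)), 0L)
  expect_error(generate_lad_variants(base, c(12, 6), 1),
               "lacks Gly at LAD position 6")

  # n_per_class = 1, zero background: the AEP parent and the double mutant
  v <- generate_lad_variants(base, c(12, 5), 1, seed = 2,
                             background_rate = 0)
  expect_equal(v$sequence[v$label == "AEP-like"], base)
  pal <- v$sequence[v$label == "PAL-like"]
  expect_equal(substring(pal, 12, 12), "V")
  expect_equal(substring(pal, 5, 5), "A")
  expect_equal(sum(strsplit(pal, "")[[1]] != strsplit(base, "")[[1]]), 2L)

  # background mutations never touch LAD or protected positions
  v2 <- generate_lad_variants(base, c(12, 5), 30, seed = 9,
                              background_rate = 0.2, protected = 1L)
  expect_true(all(v2$lad1[v2$label == "AEP-like"] == "G"))
  expect_true(all(substring(v2$sequence, 1, 1) == "A"))
  expect_identical(v2, generate_lad_variants(base, c(12, 5), 30, seed = 9,
                                             background_rate = 0.2,
                                             protected = 1L))
})

test_that("rate generation obeys the Michaelis-Menten identities", {
  # half-saturation: S = KM gives v = kcat*E0/2 exactly
  rs <- rate_spec(10, 25, enzyme_conc = 1e-8,
                  substrate_concs = c(25, 1e7), noise_cv = 0)
  rd <- generate_rate_data(rs)
  e0_uM <- 1e-8 * 1e6
  expect_equal(rd$rate_uM_per_s[1], 10 * e0_uM / 2, tolerance = 1e-12)
  # saturation limit
  expect_equal(rd$rate_uM_per_s[2], 10 * e0_uM, tolerance = 1e-4)
  expect_error(rate_spec(10, -1), "km_true > 0")
})

test_that("mean of noisy rates converges to the noiseless curve", {
  rs0 <- rate_spec(16.52, 31.89, noise_cv = 0)
  truth <- generate_rate_data(rs0)$rate_uM_per_s
  reps <- vapply(1:1000, function(s)
    generate_rate_data(rate_spec(16.52, 31.89, noise_cv = 0.05,
                                 seed = s))$rate_uM_per_s,
    numeric(length(truth)))
  m <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(m - truth) < 3 * se))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(generate_family(family_spec("ACDEFGHIKL", 5, seed = 1)))
  invisible(generate_rate_data(rate_spec(1, 1, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("product profiles follow the logistic C/H law", {
  grid <- seq(4.5, 8, by = 0.5)
  # slope 0: identical C/H everywhere
  p0 <- generate_product_profiles(grid, ch_slope = 0)
  expect_true(all(p0$ch_ratio == p0$ch_ratio[1]))
  # positive slope: strictly increasing C/H
  p1 <- generate_product_profiles(grid, ch_slope = 2)
  expect_true(all(diff(p1$ch_ratio) > 0))
  # percentages sum to 100
  expect_equal(p1$percent_hydrolyzed + p1$percent_cyclized +
                 p1$percent_remaining, rep(100, length(grid)))
})

test_that("profiles round-trip through quantify_products", {
  p <- generate_product_profiles(c(5, 6.5, 7.5))
  for (i in seq_len(nrow(p))) {
    q <- quantify_products(
      c("substrate", "hydrolyzed", "cyclized"),
      c(p$percent_remaining[i], p$percent_hydrolyzed[i],
        p$percent_cyclized[i]),
      c("substrate", "hydrolysis", "cyclic"))
    expect_equal(q$percent_hydrolyzed, p$percent_hydrolyzed[i],
                 tolerance = 1e-9)
    expect_equal(q$percent_cyclized, p$percent_cyclized[i],
                 tolerance = 1e-9)
    expect_equal(q$ch_ratio, p$ch_ratio[i], tolerance = 1e-9)
  }
})

test_that("rate tables and truth sidecars write as declared", {
  rd <- generate_rate_data(rate_spec(5, 20, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(rd, path)
  expect_equal(readLines(path, n = 1), "substrate_uM,rate_uM_per_s")
  back <- utils::read.csv(path)
  expect_equal(back$rate_uM_per_s, rd$rate_uM_per_s, tolerance = 1e-6)

  g <- generate_family(family_spec("ACDEFGHIKL", 10, seed = 2))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_family_truth(g$truth, tpath)
  tb <- utils::read.delim(tpath)
  expect_equal(tb$occupancy, unname(g$truth$occupancy))
})
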