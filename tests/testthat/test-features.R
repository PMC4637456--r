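test_that("split amino acid composition matches direct segment counting", {
  # homopolymer: frequency 1 for A in all three parts
  s <- compute_saac(strrep("A", 100), lnc = 22)
  expect_length(s, 60)
  expect_equal(unname(s[c(1, 21, 41)]), c(1, 1, 1)) # A is first per part
  expect_equal(sum(s), 3)

  # direct-count oracle on a 48-residue repeat, lnc = 22
  seq <- strrep("ACDE", 12)
  s <- compute_saac(seq, lnc = 22)
  chars <- strsplit(seq, "")[[1]]
  parts <- list(chars[1:22], chars[23:26], chars[27:48])
  expected <- unlist(lapply(parts, function(p) {
    vapply(AA_ALPHA, function(a) sum(p == a) / length(p), numeric(1))
  }))
  expect_equal(unname(s), unname(expected))
  # each part sums to 1
  expect_equal(unname(vapply(0:2, function(k) sum(s[k * 20 + 1:20]),
                             numeric(1))),
               c(1, 1, 1))
})

test_that("short sequences follow the configured policy", {
  expect_error(compute_saac("ACDEFGHIKL", lnc = 22), "2\\*lnc")
  s <- compute_saac("AAACCCGGG", lnc = 22, policy = "thirds")
  expect_equal(unname(s[s > 0]), c(1, 1, 1))
  expect_equal(unname(s[1]), 1)                 # N third = AAA
  expect_equal(unname(s[20 + 2]), 1)            # middle third = CCC
  expect_equal(unname(s[40 + 6]), 1)            # C third = GGG
})

test_that("swapping the terminal segments swaps the SAAC parts exactly", {
  set.seed(7)
  seq <- random_sequence(80)
  chars <- strsplit(seq, "")[[1]]
  swapped <- paste(c(chars[59:80], chars[23:58], chars[1:22]),
                   collapse = "")
  a <- compute_saac(seq, lnc = 22)
  b <- compute_saac(swapped, lnc = 22)
  expect_equal(unname(b[1:20]), unname(a[41:60]))
  expect_equal(unname(b[41:60]), unname(a[1:20]))
  expect_equal(unname(b[21:40]), unname(a[21:40]))
})

test_that("pseudo amino acid composition equals the double-loop oracle", {
  props <- aa_properties()
  # constant profile: every autocovariance vanishes
  expect_equal(unname(compute_pseaac(strrep("G", 50), props, 8)),
               rep(0, 96))

  # 4-residue toy sequence, toy single-property table, lag 1 by hand:
  # values 1, 2, 4, 8 -> mean 3.75; cov = ((1-3.75)(2-3.75) + (2-3.75)
  # (4-3.75) + (4-3.75)(8-3.75)) / 3
  toy <- matrix(0, 20, 1, dimnames = list(AA_ALPHA, "toy"))
  toy[c("A", "C", "D", "E"), 1] <- c(1, 2, 4, 8)
  hand <- ((1 - 3.75) * (2 - 3.75) + (2 - 3.75) * (4 - 3.75) +
             (4 - 3.75) * (8 - 3.75)) / 3
  expect_equal(unname(compute_pseaac("ACDE", toy, 1)), hand)
  expect_equal(unname(compute_pseaac("ACDE", toy, 1)),
               oracle_pseaac("ACDE", toy, 1))

  # oracle equivalence on 50 random fixtures
  set.seed(11)
  for (i in 1:50) {
    s <- random_sequence(sample(15:40, 1))
    g <- sample(3:6, 1)
    expect_equal(unname(compute_pseaac(s, props, g)),
                 oracle_pseaac(s, props, g), tolerance = 1e-12)
  }
  expect_length(compute_pseaac(random_sequence(60), props, 8), 96)
  expect_error(compute_pseaac("ACDE", props, 8), "exceed")
})

test_that("PseAAC is invariant to affine rescaling of raw property scales", {
  raw <- aa_properties(standardize = FALSE)
  shifted <- raw
  shifted[, 3] <- shifted[, 3] * 10 + 3
  z <- function(m) {
    m <- scale(m)
    attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
    m
  }
  set.seed(3)
  s <- random_sequence(60)
  expect_equal(compute_pseaac(s, z(raw), 5), compute_pseaac(s, z(shifted), 5),
               tolerance = 1e-9)
})

test_that("sigmoid normalisation matches elementwise evaluation", {
  expect_equal(sigmoid_normalize(matrix(0, 1, 1))[1, 1], 0.5)
  x <- matrix(seq(-5, 5, length.out = 40), 2, 20)
  expect_equal(sigmoid_normalize(x) + sigmoid_normalize(-x),
               matrix(1, 2, 20)) # f(x) + f(-x) = 1
  set.seed(5)
  fix <- matrix(sample(-5:5, 40, replace = TRUE), 2, 20)
  expect_equal(sigmoid_normalize(fix), 1 / (1 + exp(-fix)))
})

test_that("PSSM autocovariance equals the double-loop oracle", {
  expect_equal(unname(compute_pssm_ac(zero_pssm(30), 5)), rep(0, 100))

  set.seed(13)
  fix <- matrix(sample(-6:8, 120, replace = TRUE), 6, 20)
  expect_equal(unname(compute_pssm_ac(pssm_profile(fix), 2)),
               oracle_pssm_ac(fix, 2), tolerance = 1e-12)

  for (i in 1:50) {
    L <- sample(8:20, 1)
    lam <- sample(2:4, 1)
    m <- matrix(sample(-6:8, L * 20, replace = TRUE), L, 20)
    expect_equal(unname(compute_pssm_ac(pssm_profile(m), lam)),
                 oracle_pssm_ac(m, lam), tolerance = 1e-12)
  }
  expect_length(compute_pssm_ac(pssm_profile(matrix(1, 10, 20)), 5), 100)
  expect_error(compute_pssm_ac(zero_pssm(4), 5), "lambda_max")
})

test_that("the hybrid feature vector obeys the dimension law", {
  set.seed(17)
  rec <- protein_record("r1", random_sequence(120),
                        pssm = pssm_profile(
                          matrix(sample(-6:8, 120 * 20, TRUE), 120, 20)))
  v <- extract_features(rec)
  expect_length(v, 256)
  expect_equal(names(v), feature_names(feature_config()))

  for (i in 1:5) {
    cfg <- feature_config(lnc = sample(5:20, 1), gamma_max = sample(2:9, 1),
                          lambda_max = sample(2:6, 1))
    v <- extract_features(rec, cfg)
    expect_length(v, 60 + 12 * cfg$gamma_max + 20 * cfg$lambda_max)
  }

  blocks <- feature_blocks(feature_config())
  expect_equal(sort(unname(unlist(blocks))), 1:256)
  expect_length(blocks$saac, 60)
  expect_length(blocks$pseaac, 96)
  expect_length(blocks$pssm_ac, 100)
})

test_that("a fallback PSSM zeroes only the PSSM block", {
  set.seed(19)
  s <- random_sequence(120)
  with_p <- protein_record("a", s, pssm = pssm_profile(
    matrix(sample(-6:8, 120 * 20, TRUE), 120, 20)))
  without <- protein_record("a", s)
  va <- extract_features(with_p)
  vb <- extract_features(without)
  blocks <- feature_blocks(feature_config())
  expect_equal(unname(vb[blocks$pssm_ac]), rep(0, 100))
  expect_equal(vb[c(blocks$saac, blocks$pseaac)],
               va[c(blocks$saac, blocks$pseaac)])
})

test_that("feature tables round-trip through disk", {
  sim <- simulate_dataset(sim_config(
    class_counts = c(I = 3, II = 3, III = 5, IV = 2),
    length_range = c(60, 70), seed = 2))
  fm <- feature_matrix(sim, bench_feature_config())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(fm, f)
  back <- read_feature_table(f)
  expect_equal(dim(back), dim(fm))
  expect_equal(as.vector(back), as.vector(fm), tolerance = 1e-12)
  expect_equal(attr(back, "labels"), attr(fm, "labels"))
  expect_equal(colnames(back), feature_names(bench_feature_config()))
})
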