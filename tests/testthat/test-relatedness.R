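test_that("sharing counts credit every carrier breed and pair", {
  breeds <- c("A", "B", "C", "D")
  N <- count_shared_signatures(list(c("A", "B", "C")), breeds)
  expect_equal(diag(N), c(A = 1L, B = 1L, C = 1L, D = 0L))
  expect_equal(N["A", "B"], 1L)
  expect_equal(N["B", "C"], 1L)
  expect_equal(N["A", "D"], 0L)
  # disjoint carrier sets leave all off-diagonals zero
  N2 <- count_shared_signatures(list("A", "B", "C"), breeds)
  expect_equal(sum(N2) - sum(diag(N2)), 0L)
  # random catalogs against a per-pair brute-force intersection oracle
  set.seed(71)
  for (rep in 1:20) {
    sets <- replicate(sample(5:30, 1),
                      sample(breeds, sample(1:4, 1)), simplify = FALSE)
    N3 <- count_shared_signatures(sets, breeds)
    expect_true(isSymmetric(N3))
    for (i in 1:4) {
      expect_equal(N3[i, i],
                   sum(vapply(sets, function(s) breeds[i] %in% s,
                              logical(1))))
      for (j in seq_len(4)[-i]) {
        both <- sum(vapply(sets, function(s)
          all(breeds[c(i, j)] %in% s), logical(1)))
        expect_equal(N3[i, j], both)
        expect_lte(N3[i, j], min(N3[i, i], N3[j, j]))
      }
    }
  }
})

test_that("similarity uses the geometric mean and standardises to [0, 1]", {
  breeds <- c("A", "B", "C")
  N <- matrix(c(100L, 50L, 10L,
                50L, 200L, 5L,
                10L, 5L, 50L), 3, 3, dimnames = list(breeds, breeds))
  sim <- similarity_matrix(N)
  expect_equal(sim$s["A", "B"], 50 / sqrt(100 * 200))
  expect_equal(sim$s["A", "B"], 0.3536, tolerance = 1e-3)
  expect_equal(sim$pct["A", "B"], 35.36, tolerance = 1e-2)
  off <- sim$z[row(sim$z) != col(sim$z)]
  expect_equal(max(off, na.rm = TRUE), 1)
  expect_equal(min(off, na.rm = TRUE), 0)
  # identical catalogs give s = 1 (a single pair cannot be
  # standardised, which similarity_matrix warns about)
  N_eq <- matrix(c(7L, 7L, 7L, 7L), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(s_eq <- similarity_matrix(N_eq), "equal")
  expect_equal(s_eq$s["A", "B"], 1)
  # duplicating every record leaves s unchanged
  expect_equal(similarity_matrix(2L * N)$s, sim$s)
  # zero-signature breed reported NA with a warning
  N0 <- N
  N0[3, ] <- 0L
  N0[, 3] <- 0L
  ws <- capture_warnings(s0 <- similarity_matrix(N0))
  expect_match(ws, "zero", all = FALSE)
  expect_true(all(is.na(s0$s[3, ])))
})

test_that("score correlations match the textbook definitions", {
  a <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(correlate_score_vectors(a, a, "spearman"), 1)
  expect_equal(correlate_score_vectors(a, a, "pearson"), 1)
  expect_equal(correlate_score_vectors(a, -a, "spearman"), -1)
  set.seed(81)
  for (rep in 1:20) {
    x <- sample(100, 8)  # distinct: no ties for the textbook formula
    y <- sample(100, 8)
    expect_equal(correlate_score_vectors(x, y, "spearman"),
                 oracle_spearman(x, y))
  }
  expect_warning(r <- correlate_score_vectors(c(1, 1, 1), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(r))
  expect_error(correlate_score_vectors(1:2, 1:2), "at least 3")
})

test_that("similarity scores correlate across variant types on simulated data", {
  scan <- small_scan()
  breeds <- names(small_sim()$panel$breeds)
  score_by_type <- function(t) {
    g <- scan$gs[scan$gs$type == t, ]
    similarity_matrix(count_shared_signatures(g, breeds))$s
  }
  s_snp <- score_by_type("SNP")
  s_indel <- score_by_type("INDEL")
  ut <- upper.tri(s_snp)
  keep <- !is.na(s_snp[ut]) & !is.na(s_indel[ut])
  r <- correlate_score_vectors(s_snp[ut][keep], s_indel[ut][keep],
                               "spearman")
  expect_true(is.finite(r))
  expect_true(abs(r) <= 1)
})

test_that("breed composition scores 0 / 0.5 / 1 per carried genotype", {
  cfg <- signature_config(min_reference_n = 5L)
  panel <- tiny_panel(c(A = 5L, B = 5L))
  # two A-specific GS loci; sample A1 hom-alt at both, B1 het at both
  gts1 <- c("1/1", "1/1", "1/1", "1/1", "1/1",
            "0/1", "0/1", "0/0", "0/0", "0/0")
  loci <- list(mk_locus(gts1, pos = 1000L),
               mk_locus(gts1, pos = 2000L),
               # a B-specific reference-orientation GS
               mk_locus(c("1/1", "1/1", "1/1", "0/1", "0/1",
                          "0/0", "0/0", "0/0", "0/0", "0/0"),
                        pos = 3000L))
  cohort <- variant_cohort(loci, names(panel$assignments), panel)
  scan <- discover_signatures(cohort, cfg)
  expect_equal(nrow(scan$gs), 3)
  comp <- infer_breed_composition(cohort, scan$gs, cfg)
  expect_equal(comp["A1", "A"], 1.0)     # purebred carries everything
  expect_equal(comp["B1", "A"], 0.5)     # heterozygous at both A loci
  expect_equal(comp["B5", "A"], 0)
  expect_equal(comp["B1", "B"], 1.0)     # hom-ref at the B REFERENCE GS
  expect_equal(comp["A4", "B"], 0.5)     # het scores half on REFERENCE
  expect_equal(rank_breed_composition(comp, "A1")$breed[1], "A")
})

test_that("purebred simulated dogs rank their own breed first", {
  sim <- small_sim()
  scan <- small_scan()
  cfg <- signature_config(min_reference_n = 20L)
  comp <- infer_breed_composition(sim$cohort, scan$gs, cfg)
  for (b in names(sim$panel$breeds)) {
    dog <- sim$panel$breeds[[b]][1]
    expect_equal(rank_breed_composition(comp, dog)$breed[1], b)
    expect_equal(comp[dog, b], 1.0)
  }
})
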