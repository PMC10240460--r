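mk_catalog <- function(pos, breed = "Akita", chrom = "chr17",
                       type = "SNP", region = NA_character_,
                       gene = NA_character_, effect = NA_character_,
                       functional = FALSE) {
  data.frame(chrom = chrom, pos = as.integer(pos), breed = breed,
             type = type, region = region, gene = gene, effect = effect,
             is_functional = functional, stringsAsFactors = FALSE)
}

test_that("k-way BSGS merge equals the concatenate-and-sort oracle", {
  snp <- mk_catalog(c(100L, 300L, 900L))
  indel <- mk_catalog(c(200L, 800L), type = "INDEL")
  str1 <- mk_catalog(500L, type = "STR")
  m <- merge_bsgs_catalogs(snp, indel, str1)
  expect_equal(m$pos, c(100L, 200L, 300L, 500L, 800L, 900L))
  expect_equal(sum(m$n_total), 6L)
  # same-coordinate multi-type entries fuse into one record
  m2 <- merge_bsgs_catalogs(mk_catalog(100L), NULL,
                            mk_catalog(100L, type = "STR"))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$type, "SNP+STR")
  expect_equal(m2$n_total, 2L)
  expect_error(merge_bsgs_catalogs(mk_catalog(c(300L, 100L)), NULL, NULL),
               "not sorted")
  set.seed(31)
  for (rep in 1:20) {
    mk_rand <- function(type) {
      k <- sample(0:6, 1)
      if (!k) return(NULL)
      mk_catalog(sort(sample(1:5000, k)),
                 chrom = sample(c("chr1", "chr2"), 1), type = type)
    }
    a <- mk_rand("SNP"); b <- mk_rand("INDEL"); c3 <- mk_rand("STR")
    lst <- Filter(Negate(is.null), list(a, b, c3))
    if (!length(lst)) next
    m <- merge_bsgs_catalogs(a, b, c3)
    pooled <- do.call(rbind, lapply(lst, function(d) d[1:3]))
    pooled <- pooled[order(pooled$chrom, pooled$pos), ]
    expect_equal(sum(m$n_total), nrow(pooled))
    expect_equal(rep(m$pos, times = m$n_total), pooled$pos)
  }
})

test_that("published stretch arithmetic is reproduced from endpoints", {
  # 13 breed-specific SNPs spanning 50532539-50533705: 1.17 kb at
  # 11.15 signatures/kb
  pos <- 50532539 + round(seq(0, 1166, length.out = 13))
  res <- find_density_stretches(pos)
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 50532539L)
  expect_equal(res$end, 50533705L)
  expect_equal(res$n, 13L)
  expect_equal(breedsig:::round_half_up(res$length_kb, 2), 1.17)
  expect_equal(breedsig:::round_half_up(res$density, 2), 11.15)
  # 10 positions over 2000 bp: density 5/kb, below threshold
  expect_equal(nrow(find_density_stretches(seq(0, 2000, length.out = 10))), 0)
  # exactly 10/kb qualifies (inclusive)
  expect_equal(nrow(find_density_stretches(seq(0, 1000, length.out = 10))), 1)
})

test_that("stretch finder matches the exhaustive-window oracle", {
  cfg <- signature_config(stretch_min = 5L, stretch_density = 10)
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    pos <- sort(sample(1:5000, n))
    got <- find_density_stretches(pos, cfg)
    want <- oracle_stretches(pos, 5L, 10)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n, want$n)
    # every reported stretch satisfies its defining predicate
    for (r in seq_len(nrow(got))) {
      expect_gte(got$n[r], cfg$stretch_min)
      expect_gte(got$n[r] / got$length_kb[r], cfg$stretch_density)
    }
  }
})

test_that("published structure arithmetic is reproduced from endpoints", {
  # 204 members (180 SNP, 23 INDEL, 1 STR) spanning chr17:1900616-2086392:
  # 185.78 kb at 1.10 signatures/kb
  pos <- 1900616 + round(seq(0, 185776, length.out = 204))
  types <- c(rep("SNP", 180), rep("INDEL", 23), "STR")[sample.int(204)]
  cat1 <- merge_bsgs_catalogs(
    mk_catalog(pos[types == "SNP"]),
    mk_catalog(pos[types == "INDEL"], type = "INDEL"),
    mk_catalog(pos[types == "STR"], type = "STR"))
  res <- find_breed_structures(cat1)
  expect_equal(nrow(res), 1)
  expect_equal(c(res$n_snp, res$n_indel, res$n_str, res$n_total),
               c(180L, 23L, 1L, 204L))
  expect_equal(breedsig:::round_half_up(res$length_kb, 2), 185.78)
  expect_equal(breedsig:::round_half_up(res$density, 2), 1.10)
})

test_that("structures split at gaps and the gap rule is inclusive", {
  # two clusters of 6 members 150 kb apart: both below structure_min
  pos <- c(seq(1e6, 1e6 + 5e4, length.out = 6),
           seq(1.2e6, 1.2e6 + 5e4, length.out = 6))
  cat1 <- merge_bsgs_catalogs(mk_catalog(sort(round(pos))), NULL, NULL)
  expect_equal(nrow(find_breed_structures(cat1)), 0)
  # 10 members exactly 100,000 bp apart stay one structure
  pos2 <- seq(1e6, by = 1e5, length.out = 10)
  cat2 <- merge_bsgs_catalogs(mk_catalog(as.integer(pos2)), NULL, NULL)
  res <- find_breed_structures(cat2)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_total, 10L)
  # one bp more and the run splits
  pos3 <- pos2
  pos3[10] <- pos3[10] + 1
  cat3 <- merge_bsgs_catalogs(mk_catalog(as.integer(pos3)), NULL, NULL)
  expect_equal(nrow(find_breed_structures(cat3)), 0)
})

test_that("structures carry functional flags and re-verify their predicate", {
  set.seed(51)
  for (rep in 1:15) {
    n <- sample(8:40, 1)
    pos <- sort(sample(seq(1e6, 3e6, by = 997), n))
    fun <- seq_len(n) == 1
    cat1 <- merge_bsgs_catalogs(
      mk_catalog(pos, gene = "PUS7", effect = "missense_variant",
                 functional = fun), NULL, NULL)
    res <- find_breed_structures(cat1)
    for (r in seq_len(nrow(res))) {
      members <- cat1[cat1$pos >= res$start[r] & cat1$pos <= res$end[r], ]
      expect_gte(nrow(members), 10)
      expect_true(all(diff(members$pos) <= 1e5))
      expect_equal(res$has_functional[r], any(members$is_functional))
      if (res$has_functional[r]) {
        expect_equal(res$functional_genes[r], "PUS7")
      }
    }
  }
})

test_that("gene hotspots require hotspot_min members in one region", {
  five <- mk_catalog(seq(100L, 500L, by = 100L), region = "NKAIN3_like")
  cat5 <- merge_bsgs_catalogs(five, NULL, NULL)
  hs <- find_gene_hotspots(cat5)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_total, 5L)
  expect_equal(hs$region, "NKAIN3_like")
  four <- merge_bsgs_catalogs(five[1:4, ], NULL, NULL)
  expect_equal(nrow(find_gene_hotspots(four)), 0)
  # missing region labels pool under "unannotated" with a warning
  expect_warning(hs2 <- find_gene_hotspots(cat5 |>
    transform(region = NA_character_)), "unannotated")
  expect_equal(hs2$region, "unannotated")
})

test_that("a large planted single-gene hotspot is recovered intact", {
  scan <- small_scan()
  snp <- scan$bsgs[scan$bsgs$type == "SNP", ]
  snp <- snp[order(snp$chrom, snp$pos), ]
  indel <- scan$bsgs[scan$bsgs$type == "INDEL", ]
  indel <- indel[order(indel$chrom, indel$pos), ]
  str1 <- scan$bsgs[scan$bsgs$type == "STR", ]
  str1 <- str1[order(str1$chrom, str1$pos), ]
  merged <- merge_bsgs_catalogs(snp, indel, str1)
  hs <- find_gene_hotspots(merged)
  big <- hs[hs$region == "LOC555100", ]
  expect_equal(big$n_total, 15L)     # the planted multi-type cluster
  expect_equal(c(big$n_snp, big$n_indel, big$n_str), c(11L, 3L, 1L))
  expect_true("LOC555001" %in% hs$region)  # the 13-SNP stretch gene
  # the planted stretch is found at its planted density
  st <- find_all_stretches(merged)
  planted <- st[st$chrom == "chr1" & st$start == 30e6, ]
  expect_equal(planted$n, 13L)
  expect_equal(breedsig:::round_half_up(planted$density, 2), 11.15)
  # and the multi-type structure is one segment
  stru <- find_breed_structures(merged)
  big_s <- stru[stru$chrom == "chr1" & stru$start == 35e6, ]
  expect_equal(big_s$n_total, 15L)
  expect_true(big_s$has_functional)
})

test_that("block tiling follows the 1-based closed convention", {
  gs <- data.frame(chrom = "chr1", pos = c(10000L, 10001L, 25000L),
                   n_carrier_breeds = c(3L, 13L, 4L))
  blocks <- summarize_blocks(gs)
  expect_equal(blocks$block, c(0L, 1L, 2L))
  expect_equal(blocks$start, c(1, 10001, 20001))
  expect_equal(blocks$n_gs, c(1L, 1L, 1L))
  # mean carrier breeds within a block
  gs2 <- data.frame(chrom = "chr1", pos = c(5L, 6L),
                    n_carrier_breeds = c(3L, 13L))
  expect_equal(summarize_blocks(gs2)$mean_breeds_per_gs, 8)
  # conservation: block counts sum to the GS count
  set.seed(61)
  gs3 <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                    pos = sample.int(1e6, 500),
                    n_carrier_breeds = sample(1:10, 500, TRUE))
  expect_equal(sum(summarize_blocks(gs3)$n_gs), 500L)
})

test_that("PAR summary restricts to X blocks inside the interval", {
  cfg <- signature_config(block_high = 40L)
  gs <- data.frame(
    chrom = c(rep("chrX", 45), "chrX", "chr1"),
    pos = c(seq(6501000L, by = 100L, length.out = 45), 6600001L, 500L),
    n_carrier_breeds = c(rep(4L, 45), 2L, 2L),
    carriers = c(rep("Akita,Collie", 45), "Akita", "Akita"))
  blocks <- summarize_blocks(gs, cfg)
  ps <- par_summary(blocks, cfg, gs = gs)
  expect_equal(ps$n_gs, 45L)            # the 6,600,001 block is outside
  expect_equal(ps$n_high_blocks, 1L)
  expect_equal(ps$frac_gs_high_blocks, 1)
  expect_equal(ps$mean_breeds_per_gs, 4)
  expect_equal(ps$breeds_represented, "Akita,Collie")
  expect_warning(z <- par_summary(summarize_blocks(gs[47, ], cfg), cfg),
                 "no X")
  expect_equal(z$n_gs, 0L)
})
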