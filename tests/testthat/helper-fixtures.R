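# Shared fixture builders: tiny hand-built loci and a memoised small
# simulated cohort.

tiny_cfg <- function(...) {
  signature_config(min_reference_n = 6L, ...)
}

# panel of four 5-dog breeds
tiny_panel <- function(breeds = c(A = 5L, B = 5L, C = 5L, D = 5L)) {
  bn <- rep(names(breeds), times = breeds)
  breed_panel(sprintf("%s%d", bn, unlist(lapply(breeds, seq_len))), bn)
}

gt_from_strings <- function(s) {
  vapply(strsplit(s, "[/|]"), function(p) {
    if (any(p == ".")) c(NA_integer_, NA_integer_) else as.integer(p)
  }, integer(2))
}

# bi- or multi-allelic locus from genotype strings; depth is either a
# scalar or per-sample vector, split evenly across het alleles
mk_locus <- function(gts, chrom = "chr1", pos = 1000L, ref = "A",
                     alts = "T", depth = 20L, ann = NULL) {
  gt <- gt_from_strings(gts)
  n <- ncol(gt)
  depth <- rep_len(depth, n)
  n_allele <- 1L + length(alts)
  ad <- matrix(0L, n_allele, n)
  for (j in seq_len(n)) {
    if (anyNA(gt[, j]) || is.na(depth[j])) {
      ad[, j] <- NA_integer_
      next
    }
    a <- gt[1, j] + 1L
    b <- gt[2, j] + 1L
    if (a == b) {
      ad[a, j] <- depth[j]
    } else {
      ad[a, j] <- depth[j] %/% 2L
      ad[b, j] <- depth[j] - depth[j] %/% 2L
    }
  }
  variant_locus(chrom, pos, ref, alts, gt, ad,
                ann = if (is.character(ann)) parse_ann(ann) else ann)
}

# genotype strings per breed pattern: names are breeds, each entry a
# character vector recycled to the breed size
gts_by_breed <- function(panel, patterns) {
  unlist(lapply(names(panel$breeds), function(b) {
    m <- length(panel$breeds[[b]])
    rep_len(patterns[[b]], m)
  }))
}

# memoised small simulated cohort shared across test files
.sim_env <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_env$sim)) {
    .sim_env$dir <- file.path(tempdir(), "breedsig-small-sim")
    .sim_env$sim <- simulate_cohort(cohort_design(n_background = 250L),
                                    seed = 42L, out_dir = .sim_env$dir)
  }
  .sim_env$sim
}
small_scan <- function() {
  if (is.null(.sim_env$scan)) {
    .sim_env$scan <- discover_signatures(small_sim()$cohort,
                                         signature_config(min_reference_n = 20L))
  }
  .sim_env$scan
}
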