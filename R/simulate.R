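# Deterministic multi-breed cohort simulator with planted signatures
# and a truth table, so discovery is testable end to end at desk scale.

#' Desk-scale cohort design with planted signatures
#'
#' Builds the default validation design: 8 breeds x 5 dogs over two
#' autosomes and an X chromosome (with the pseudoautosomal interval at
#' its head), roughly 5,000 loci in total. Planted features cover every
#' signature kind the scanner can discover — breed-specific SNPs,
#' INDELs and STR expansions/contractions, multi-carrier genetic
#' signatures, breed-pair-exclusive signatures, a high-density SNP
#' stretch, a multi-type breed structure, gene hotspots, a PAR
#' signature cluster — plus universal variants and near-miss decoys
#' that each violate exactly one rule (carrier frequency, call depth,
#' breed validity, reference support, or STR group fixation).
#' Background loci are constructed so that no breed can reach the
#' carrier threshold in any orientation in any solid subset, so the
#' truth table is exact for every seed.
#'
#' @param n_background Number of background (non-signature) loci.
#' @param breeds Named integer vector breed -> dog count.
#' @param chrom_lengths Named chromosome lengths in bp (must include an
#'   X-named chromosome).
#' @param depth_mean,depth_size Negative-binomial read-depth law.
#' @param dropout Fraction of background calls pushed below the depth
#'   threshold (exercises the quality filter).
#' @return A list of class `"cohort_design"` with the feature table.
#' @export
cohort_design <- function(n_background = 4500L,
                          breeds = c(Akita = 5L, AlaskanMalamute = 5L,
                                     BullTerrier = 5L, ChowChow = 5L,
                                     Collie = 5L, Keeshond = 5L,
                                     Samoyed = 5L, SussexSpaniel = 5L),
                          chrom_lengths = c(chr1 = 60e6, chr2 = 40e6,
                                            chrX = 10e6),
                          depth_mean = 30, depth_size = 8,
                          dropout = 0.05) {
  bn <- names(breeds)
  nb <- length(bn)
  stopifnot(nb >= 4L, all(breeds >= 3L))
  feat <- list()
  add <- function(chrom, pos, kind, type, orientation, carriers,
                  gene = NA, effect = NA, aa = NA,
                  unit = NA, low = NA, high = NA, note = "") {
    feat[[length(feat) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos), kind = kind, type = type,
      orientation = orientation,
      carriers = paste(carriers, collapse = ","),
      gene = as.character(gene), effect = as.character(effect),
      aa = as.character(aa), unit = as.character(unit),
      low = as.character(low), high = as.character(high),
      note = note, stringsAsFactors = FALSE)
  }
  # scattered breed-specific SNPs: 4 per breed, one missense, one
  # reference-orientation
  for (i in seq_len(nb)) {
    base <- 2e6 * i
    add("chr1", base, "BSGS_SNP", "SNP", "VARIANT", bn[i],
        gene = sprintf("GENE%dA", i), effect = "missense_variant",
        aa = "120/480")
    add("chr1", base + 3e5, "BSGS_SNP", "SNP", "VARIANT", bn[i],
        gene = sprintf("GENE%dB", i), effect = "intron_variant")
    add("chr1", base + 6e5, "BSGS_SNP", "SNP", "VARIANT", bn[i],
        gene = sprintf("LOCBG%d-LOCBH%d", i, i),
        effect = "intergenic_region")
    add("chr1", base + 9e5, "BSGS_SNP", "SNP", "REFERENCE", bn[i],
        gene = sprintf("GENE%dC", i), effect = "intron_variant")
  }
  # high-density SNP stretch for the first breed: 13 members / 1166 bp
  stretch_pos <- 30e6 + round(seq(0, 1166, length.out = 13))
  for (p in stretch_pos) {
    add("chr1", p, "BSGS_SNP", "SNP", "VARIANT", bn[1],
        gene = "LOC555001", effect = "intron_variant")
  }
  # multi-type structure for the second breed: 15 members over ~180 kb
  struct_pos <- 35e6 + round(seq(0, 18e4, length.out = 15))
  struct_types <- c(rep("SNP", 6), "INDEL", rep("SNP", 3), "INDEL",
                    "SNP", "INDEL", "SNP", "STR")
  for (k in seq_along(struct_pos)) {
    ty <- struct_types[k]
    if (ty == "SNP") {
      add("chr1", struct_pos[k], "BSGS_SNP", "SNP", "VARIANT", bn[2],
          gene = "LOC555100",
          effect = if (k == 1L) "missense_variant" else "intron_variant",
          aa = if (k == 1L) "44/317" else NA)
    } else if (ty == "INDEL") {
      add("chr1", struct_pos[k], "BSGS_INDEL", "INDEL", "VARIANT", bn[2],
          gene = "LOC555100", effect = "intron_variant")
    } else {
      add("chr1", struct_pos[k], "BSGS_STR_EXPANSION", "STR", "STR_HIGH",
          bn[2], gene = "LOC555100", effect = "intron_variant",
          unit = "TG", low = "0,1,2", high = "6,7")
    }
  }
  # hotspot-only cluster for the third breed: 6 SNPs over 400 kb
  for (k in 0:5) {
    add("chr1", 40e6 + k * 8e4, "BSGS_SNP", "SNP", "VARIANT", bn[3],
        gene = "LOC555200", effect = "intron_variant")
  }
  # scattered breed-specific short INDELs: 2 per breed
  for (i in seq_len(nb)) {
    base <- 45e6 + 2e5 * i
    add("chr1", base, "BSGS_INDEL", "INDEL", "VARIANT", bn[i],
        gene = sprintf("GENE%dD", i), effect = "intron_variant")
    add("chr1", base + 1e5, "BSGS_INDEL", "INDEL", "REFERENCE", bn[i],
        gene = sprintf("GENE%dE", i), effect = "intron_variant")
  }
  # one long INDEL (length difference >= 10): GS but never a short
  # INDEL BSGS
  add("chr1", 48e6, "BSGS_INDEL_LONG", "INDEL", "VARIANT", bn[4],
      gene = "GENELONG", effect = "intron_variant")
  # STR expansion + contraction per breed
  units <- c("TTCT", "AC", "T", "AGAT", "CT", "G", "TG", "A")
  for (i in seq_len(nb)) {
    u <- units[(i - 1L) %% length(units) + 1L]
    base <- 5e6 + 4e5 * i
    add("chr2", base, "BSGS_STR_EXPANSION", "STR", "STR_HIGH", bn[i],
        gene = sprintf("GENE%dS", i), effect = "intron_variant",
        unit = u, low = "0,1,2,3", high = "8,9,10")
    add("chr2", base + 2e5, "BSGS_STR_CONTRACTION", "STR", "STR_LOW",
        bn[i], gene = sprintf("LOCS%d-LOCT%d", i, i),
        effect = "intergenic_region", unit = u, low = "0",
        high = "3,4")
  }
  # multi-carrier genetic signatures (SNP): 30 loci, carrier sets of
  # size 3..4 cycling over the breed list (larger sets would leave too
  # few reference samples at desk scale)
  for (k in seq_len(30L)) {
    sz <- 3L + (k %% 2L)
    carr <- bn[((k + seq_len(sz) - 2L) %% nb) + 1L]
    add("chr2", 12e6 + k * 5e4, "GS", "SNP", "VARIANT", sort(carr),
        gene = sprintf("LOCG%d-LOCH%d", k, k),
        effect = "intergenic_region")
  }
  # multi-carrier INDEL and STR genetic signatures
  for (k in seq_len(4L)) {
    carr <- sort(bn[((k + 0:2) %% nb) + 1L])
    add("chr2", 15e6 + k * 6e4, "GS", "INDEL", "VARIANT", carr,
        gene = sprintf("GENEI%d", k), effect = "intron_variant")
    add("chr2", 16e6 + k * 6e4, "GS", "STR", "STR_HIGH", carr,
        gene = sprintf("GENEJ%d", k), effect = "intron_variant",
        unit = "CT", low = "0,1", high = "5,6")
  }
  # breed-pair-exclusive SNP signatures: 4 designated pairs x 3 loci
  pair_idx <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))
  for (pi in seq_along(pair_idx)) {
    pr <- sort(bn[pair_idx[[pi]]])
    for (k in seq_len(3L)) {
      add("chr2", 20e6 + pi * 4e5 + k * 3e4, "PAIR_SIGNATURE", "SNP",
          "VARIANT", pr, gene = sprintf("LOCP%d-LOCQ%d", pi, pi),
          effect = "intergenic_region")
    }
  }
  # universal variants (all dogs homozygous alternative): excluded
  for (k in seq_len(3L)) {
    add("chr2", 24e6 + k * 1e5, "UNIVERSAL", "SNP", "VARIANT", bn,
        note = "universal")
  }
  # near-miss decoys, each failing exactly one rule
  add("chr2", 26e6, "NEAR_MISS_DECOY", "SNP", "VARIANT", bn[1],
      note = "carrier_het")          # one het dog: bvf 0.8 < 0.9
  add("chr2", 26.1e6, "NEAR_MISS_DECOY", "SNP", "VARIANT", bn[5],
      note = "carrier_het")
  add("chr2", 26.2e6, "NEAR_MISS_DECOY", "SNP", "VARIANT", bn[2],
      note = "carrier_depth")        # 2 solid carriers: breed invalid
  add("chr2", 26.3e6, "NEAR_MISS_DECOY", "SNP", "VARIANT", bn[3],
      note = "reference_support")    # < min_reference_n solid others
  add("chr2", 26.4e6, "NEAR_MISS_DECOY", "STR", "STR_HIGH", bn[6],
      unit = "TG", low = "0,1", high = "4,5",
      note = "str_mixed")            # one MIXED carrier dog: 0.8
  add("chr2", 26.5e6, "NEAR_MISS_DECOY", "SNP", "VARIANT",
      sort(bn[c(1L, 2L, 3L)]), note = "three_carriers")  # GS, no pair
  # PAR cluster on X: 45 signatures inside one 10-kb block, plus 8
  # X signatures outside the PAR
  for (k in seq_len(45L)) {
    sz <- 3L + (k %% 2L)
    carr <- sort(bn[((k + seq_len(sz) - 2L) %% nb) + 1L])
    add("chrX", 6.5e6 + 1000 + (k - 1L) * 195, "GS", "SNP", "VARIANT",
        carr, note = "par_cluster")
  }
  for (k in seq_len(8L)) {
    carr <- sort(bn[((k + 0:2) %% nb) + 1L])
    add("chrX", 7e6 + k * 1e5, "GS", "SNP", "VARIANT", carr)
  }
  # X-specific BSGS whose carriers sit at depth 5..9: solid only under
  # the X depth threshold
  add("chrX", 2e6, "BSGS_SNP", "SNP", "VARIANT", bn[5],
      gene = "GENEX1", effect = "intron_variant", note = "x_depth")
  add("chrX", 2.5e6, "BSGS_SNP", "SNP", "VARIANT", bn[5],
      gene = "GENEX2", effect = "intron_variant", note = "x_depth")
  # non-STR multi-allelic INDELs (rejected by unit decomposition) and
  # multi-allelic SNPs (class OTHER)
  for (k in seq_len(3L)) {
    add("chr2", 28e6 + k * 1e5, "NON_STR_MULTIALLELIC", "OTHER",
        "VARIANT", bn[1], note = "no_single_unit")
  }
  for (k in seq_len(2L)) {
    add("chr2", 28.5e6 + k * 1e5, "MULTIALLELIC_SNP", "OTHER",
        "VARIANT", bn[1], note = "multiallelic_snp")
  }
  # sites without an AD FORMAT field: depth-unknown everywhere
  add("chr2", 29e6, "NO_AD", "SNP", "VARIANT", bn[1], note = "no_ad")
  add("chr2", 29.1e6, "NO_AD", "SNP", "VARIANT", bn[2], note = "no_ad")
  features <- do.call(rbind, feat)
  if (anyDuplicated(features[c("chrom", "pos")])) {
    stop("design error: duplicate feature position")
  }
  structure(list(breeds = breeds, chrom_lengths = chrom_lengths,
                 features = features, n_background = as.integer(n_background),
                 depth_mean = depth_mean, depth_size = depth_size,
                 dropout = dropout),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("Cohort design: %d breeds x %s dogs, %d planted features, %d background loci\n",
              length(x$breeds), paste(unique(x$breeds), collapse = "/"),
              nrow(x$features), x$n_background))
  print(table(x$features$kind))
  invisible(x)
}

#' Construct the multi-allelic VCF record of a planted STR locus
#'
#' Alleles are written as `anchor + unit^k` for each planted repeat
#' count; the reference allele carries the smallest count. The unit
#' must be primitive, 1-6 bp, and the low/high groups must be separated
#' by at least one repeat.
#'
#' @param unit Repeat unit sequence.
#' @param low_counts,high_counts Planted repeat-count groups.
#' @param anchor Shared flanking base(s) before the repeat tract.
#' @return List with `ref`, `alts`, `counts` (per allele, ref first).
#' @export
plant_str_locus <- function(unit, low_counts, high_counts, anchor = "A") {
  if (nchar(unit) < 1L || nchar(unit) > 6L) stop("unit must be 1-6 bp")
  if (!is_primitive_unit(unit)) stop("unit must be primitive")
  low_counts <- sort(as.integer(low_counts))
  high_counts <- sort(as.integer(high_counts))
  if (min(high_counts) - max(low_counts) < 1L) {
    stop("repeat groups must be separated by at least one unit")
  }
  counts <- c(low_counts, high_counts)
  alleles <- paste0(anchor, strrep(unit, counts))
  if (anyDuplicated(alleles)) stop("design error: duplicate STR alleles")
  list(ref = alleles[1], alts = alleles[-1], counts = counts)
}

# safe background genotype multisets for a 5-dog breed:
# (n_hom_ref, n_het, n_hom_alt) with at most 2 homozygotes per class,
# so no solid subset of >= 3 dogs can reach bvf >= 0.9
bg_patterns <- rbind(c(2, 2, 1), c(1, 2, 2), c(2, 1, 2), c(1, 3, 1),
                     c(0, 3, 2), c(2, 3, 0), c(1, 4, 0), c(0, 4, 1),
                     c(0, 5, 0))

# gt matrix for one bi-allelic locus: carriers homozygous for the
# oriented state, every other breed in a threshold-safe mixed pattern
sim_biallelic_gt <- function(breed_f, carriers, orientation,
                             carrier_het = 0L) {
  n <- length(breed_f)
  gt <- matrix(0L, 2L, n)
  for (b in levels(breed_f)) {
    idx <- which(breed_f == b)
    m <- length(idx)
    if (b %in% carriers) {
      hom <- if (orientation == "VARIANT") 1L else 0L
      gt[, idx] <- hom
      if (carrier_het > 0L) {
        het_idx <- idx[sample.int(m, carrier_het)]
        gt[1L, het_idx] <- 0L
        gt[2L, het_idx] <- 1L
      }
    } else {
      # VARIANT-safe: 2 het + rest hom-ref; REFERENCE-safe: 2 het +
      # rest hom-alt (keeps both orientations below threshold)
      base <- if (orientation == "VARIANT") 0L else 1L
      gt[, idx] <- base
      het_idx <- idx[sample.int(m, min(2L, m))]
      gt[1L, het_idx] <- 0L
      gt[2L, het_idx] <- 1L
    }
  }
  gt
}

sim_background_gt <- function(breed_f) {
  n <- length(breed_f)
  gt <- matrix(0L, 2L, n)
  for (b in levels(breed_f)) {
    idx <- which(breed_f == b)
    m <- length(idx)
    pat <- bg_patterns[sample.int(nrow(bg_patterns), 1L), ]
    cls <- rep(c(0L, 1L, 2L), times = pat)  # 0 hom-ref, 1 het, 2 hom-alt
    if (length(cls) > m) cls <- cls[seq_len(m)]
    if (length(cls) < m) cls <- c(cls, rep(1L, m - length(cls)))
    cls <- cls[sample.int(m)]
    gt[1L, idx] <- ifelse(cls == 2L, 1L, 0L)
    gt[2L, idx] <- ifelse(cls >= 1L, 1L, 0L)
  }
  gt
}

# STR gt: carrier breeds homozygous within the signature group; other
# breeds one straddling (MIXED) dog plus hom dogs of the opposite group
sim_str_gt <- function(breed_f, carriers, counts, low_counts, high_counts,
                       orientation, carrier_mixed = FALSE) {
  n <- length(breed_f)
  low_idx <- which(counts %in% low_counts) - 1L   # 0-based allele index
  high_idx <- which(counts %in% high_counts) - 1L
  carr_pool <- if (orientation == "STR_HIGH") high_idx else low_idx
  other_pool <- if (orientation == "STR_HIGH") low_idx else high_idx
  gt <- matrix(0L, 2L, n)
  for (b in levels(breed_f)) {
    idx <- which(breed_f == b)
    m <- length(idx)
    if (b %in% carriers) {
      a <- carr_pool[(seq_len(m) - 1L) %% length(carr_pool) + 1L]
      gt[1L, idx] <- a
      gt[2L, idx] <- carr_pool[seq_len(m) %% length(carr_pool) + 1L]
      if (carrier_mixed) {
        j <- idx[sample.int(m, 1L)]
        gt[1L, j] <- other_pool[1L]
        gt[2L, j] <- carr_pool[1L]
      }
    } else {
      a <- other_pool[(seq_len(m) - 1L) %% length(other_pool) + 1L]
      gt[1L, idx] <- a
      gt[2L, idx] <- other_pool[seq_len(m) %% length(other_pool) + 1L]
      j <- idx[sample.int(m, 1L)]   # one MIXED dog keeps the breed
      gt[1L, j] <- other_pool[1L]   # below fixation in its own group
      gt[2L, j] <- carr_pool[1L]
    }
  }
  gt
}

sim_depths <- function(n, thr, design, force_solid = TRUE,
                       low_idx = integer(), x_window = FALSE) {
  d <- stats::rnbinom(n, mu = design$depth_mean, size = design$depth_size)
  if (force_solid) d <- pmax(d, thr)
  if (x_window) d <- 5L + (d %% 5L)  # depths 5..9: solid only on X
  if (length(low_idx)) {
    d[low_idx] <- sample.int(thr, length(low_idx), replace = TRUE) - 1L
  }
  as.integer(d)
}

sim_ad <- function(gt, depth, n_allele) {
  n <- ncol(gt)
  ad <- matrix(0L, n_allele, n)
  for (j in seq_len(n)) {
    a <- gt[1L, j] + 1L
    b <- gt[2L, j] + 1L
    if (a == b) {
      ad[a, j] <- depth[j]
    } else {
      k <- stats::rbinom(1L, depth[j], 0.5)
      ad[a, j] <- k
      ad[b, j] <- depth[j] - k
    }
  }
  ad
}

ann_string <- function(alt, effect, gene, aa = NA) {
  if (is.na(effect) || !nzchar(effect)) return(NA_character_)
  aa_field <- if (is.na(aa)) "" else aa
  paste0("ANN=", alt, "|", effect, "|MODIFIER|", gene, "|", gene,
         "|transcript|tx1|protein_coding|1/1|c.1A>T|p.(=)|1/1|1/1|",
         aa_field, "|0|")
}

snp_alleles <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  c(ref, alt)
}

indel_alleles <- function(size = NULL) {
  base <- sample(c("A", "C", "G", "T"), 1L)
  if (is.null(size)) size <- sample.int(8L, 1L)
  ins <- paste0(base, paste(sample(c("A", "C", "G", "T"), size,
                                   replace = TRUE), collapse = ""))
  if (stats::runif(1) < 0.5) c(base, ins) else c(ins, base)
}

#' Simulate a multi-breed cohort with planted signatures
#'
#' Generates the VCF (GT/AD/ANN), the breed panel, and a truth table
#' enumerating the records the scanner is expected to discover (and the
#' planted decoys it must reject). Byte-identical outputs for identical
#' seeds.
#'
#' @param design A [cohort_design()].
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created if needed); when `NULL`
#'   nothing is written and only the in-memory cohort is returned.
#' @return List of class `"sim_cohort"`: `cohort` (the in-memory
#'   [variant_cohort()]), `truth` (data frame), `panel`, and the file
#'   paths (`vcf`, `panel_path`, `truth_path`) when `out_dir` is set.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  bn <- names(design$breeds)
  samples <- unlist(lapply(seq_along(bn), function(i)
    sprintf("%s_%02d", toupper(substr(gsub("[^A-Za-z]", "", bn[i]), 1, 3)),
            seq_len(design$breeds[i]))))
  breed_vec <- rep(bn, times = design$breeds)
  # disambiguate colliding sample prefixes, if any
  if (anyDuplicated(samples)) {
    samples <- paste0(sprintf("S%02d", seq_along(samples)), "_", samples)
  }
  panel <- breed_panel(samples, breed_vec)
  breed_f <- factor(breed_vec, levels = bn)
  n <- length(samples)

  feats <- design$features
  # background positions, avoiding feature coordinates
  bg <- list()
  per_chrom <- table(factor(
    sample(names(design$chrom_lengths), design$n_background, replace = TRUE,
           prob = design$chrom_lengths / sum(design$chrom_lengths)),
    levels = names(design$chrom_lengths)))
  for (ch in names(design$chrom_lengths)) {
    taken <- feats$pos[feats$chrom == ch]
    p <- sample.int(design$chrom_lengths[[ch]], per_chrom[[ch]])
    p <- sort(setdiff(p, taken))
    if (length(p)) {
      bg[[ch]] <- data.frame(chrom = ch, pos = as.integer(p),
                             stringsAsFactors = FALSE)
    }
  }
  bg <- do.call(rbind, bg)

  all_sites <- rbind(
    data.frame(chrom = feats$chrom, pos = feats$pos,
               fi = seq_len(nrow(feats)), stringsAsFactors = FALSE),
    data.frame(chrom = bg$chrom, pos = bg$pos, fi = NA_integer_,
               stringsAsFactors = FALSE))
  all_sites <- all_sites[order(match(all_sites$chrom,
                                     names(design$chrom_lengths)),
                               all_sites$pos), , drop = FALSE]

  loci <- vector("list", nrow(all_sites))
  truth <- list()
  add_truth <- function(chrom, pos, kind, type, orientation, carriers,
                        expect_gs, expect_bsgs, expect_pair,
                        signature_type = NA, unit_diff = NA, note = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos), kind = kind, type = type,
      orientation = orientation, carriers = carriers,
      breed = if (expect_bsgs) carriers else NA_character_,
      expect_gs = expect_gs, expect_bsgs = expect_bsgs,
      expect_pair = expect_pair,
      signature_type = as.character(signature_type),
      unit_diff = as.integer(unit_diff), note = note,
      stringsAsFactors = FALSE)
  }

  for (si in seq_len(nrow(all_sites))) {
    ch <- all_sites$chrom[si]
    pos <- all_sites$pos[si]
    on_x <- ch %in% c("chrX", "X")
    thr <- if (on_x) 5L else 10L
    fi <- all_sites$fi[si]
    if (is.na(fi)) {
      # background locus
      al <- if (stats::runif(1) < 0.97) snp_alleles() else indel_alleles()
      gt <- sim_background_gt(breed_f)
      low_idx <- which(stats::runif(n) < design$dropout)
      depth <- sim_depths(n, thr, design, low_idx = low_idx)
      ad <- sim_ad(gt, depth, 2L)
      ann <- if (stats::runif(1) < 0.5)
        ann_string(al[2], "intergenic_region",
                   sprintf("LOCB%d-LOCC%d", si, si)) else NA_character_
      loci[[si]] <- variant_locus(ch, pos, al[1], al[2], gt, ad,
                                  ann = parse_ann(ann))
      attr(loci[[si]], "ann_str") <- ann
      next
    }
    f <- feats[fi, ]
    carriers <- strsplit(f$carriers, ",", fixed = TRUE)[[1]]
    kind <- f$kind
    if (f$type == "STR") {
      low <- as.integer(strsplit(f$low, ",")[[1]])
      high <- as.integer(strsplit(f$high, ",")[[1]])
      pl <- plant_str_locus(f$unit, low, high)
      gt <- sim_str_gt(breed_f, carriers, pl$counts, low, high,
                       f$orientation,
                       carrier_mixed = identical(f$note, "str_mixed"))
      depth <- sim_depths(n, thr, design)
      ad <- sim_ad(gt, depth, length(pl$counts))
      ann <- ann_string(pl$alts[1], f$effect, f$gene)
      loci[[si]] <- variant_locus(ch, pos, pl$ref, pl$alts, gt, ad,
                                  ann = parse_ann(ann))
      attr(loci[[si]], "ann_str") <- ann
      ud <- min(high) - max(low)
      if (kind %in% c("BSGS_STR_EXPANSION", "BSGS_STR_CONTRACTION")) {
        add_truth(ch, pos, kind, "STR", f$orientation, f$carriers,
                  TRUE, TRUE, FALSE,
                  signature_type = if (f$orientation == "STR_HIGH")
                    "EXPANSION" else "CONTRACTION",
                  unit_diff = ud)
      } else if (kind == "GS") {
        add_truth(ch, pos, kind, "STR", f$orientation, f$carriers,
                  TRUE, FALSE, FALSE, unit_diff = ud)
      } else {
        add_truth(ch, pos, kind, "STR", f$orientation, f$carriers,
                  FALSE, FALSE, FALSE, note = f$note)
      }
      next
    }
    if (kind == "NON_STR_MULTIALLELIC") {
      # three alleles with no shared single repeat unit
      gt <- sim_background_gt(breed_f)  # indices 0/1 only: safe
      depth <- sim_depths(n, thr, design)
      ad <- sim_ad(gt, depth, 3L)
      loci[[si]] <- variant_locus(ch, pos, "A", c("AT", "ACG"), gt, ad)
      add_truth(ch, pos, kind, "OTHER", f$orientation, f$carriers,
                FALSE, FALSE, FALSE, note = f$note)
      next
    }
    if (kind == "MULTIALLELIC_SNP") {
      gt <- sim_background_gt(breed_f)
      depth <- sim_depths(n, thr, design)
      ad <- sim_ad(gt, depth, 3L)
      loci[[si]] <- variant_locus(ch, pos, "A", c("C", "G"), gt, ad)
      add_truth(ch, pos, kind, "OTHER", f$orientation, f$carriers,
                FALSE, FALSE, FALSE, note = f$note)
      next
    }
    # bi-allelic kinds
    al <- if (f$type == "SNP") snp_alleles()
          else if (kind == "BSGS_INDEL_LONG") indel_alleles(size = 12L)
          else indel_alleles()
    carrier_het <- if (identical(f$note, "carrier_het")) 1L else 0L
    orient <- if (kind == "UNIVERSAL") "VARIANT" else f$orientation
    if (kind == "UNIVERSAL") {
      gt <- matrix(1L, 2L, n)
    } else {
      gt <- sim_biallelic_gt(breed_f, carriers, orient, carrier_het)
    }
    low_idx <- integer()
    if (identical(f$note, "carrier_depth")) {
      low_idx <- which(breed_f == carriers)[3:5]
    } else if (identical(f$note, "reference_support")) {
      # leave two non-carrier breeds fully solid, knock the rest to
      # at most two solid dogs each
      others <- setdiff(bn, carriers)
      for (b in others[-(1:2)]) {
        low_idx <- c(low_idx, which(breed_f == b)[3:5])
      }
    }
    depth <- sim_depths(n, thr, design, low_idx = low_idx,
                        x_window = identical(f$note, "x_depth"))
    ad <- sim_ad(gt, depth, 2L)
    if (identical(f$note, "no_ad")) ad[] <- NA_integer_
    ann <- ann_string(al[2], f$effect, f$gene, f$aa)
    loci[[si]] <- variant_locus(ch, pos, al[1], al[2], gt, ad,
                                ann = parse_ann(ann))
    attr(loci[[si]], "ann_str") <- ann
    if (kind %in% c("BSGS_SNP", "BSGS_INDEL")) {
      add_truth(ch, pos, kind, f$type, orient, f$carriers, TRUE, TRUE,
                FALSE, note = f$note)
    } else if (kind == "BSGS_INDEL_LONG") {
      add_truth(ch, pos, kind, "INDEL", orient, f$carriers, TRUE, FALSE,
                FALSE, note = "long_indel")
    } else if (kind == "GS") {
      add_truth(ch, pos, kind, f$type, orient, f$carriers, TRUE, FALSE,
                FALSE, note = f$note)
    } else if (kind == "PAIR_SIGNATURE") {
      add_truth(ch, pos, kind, "SNP", orient, f$carriers, TRUE, FALSE,
                TRUE)
    } else if (kind == "NEAR_MISS_DECOY" &&
               identical(f$note, "three_carriers")) {
      add_truth(ch, pos, "GS", "SNP", orient, f$carriers, TRUE, FALSE,
                FALSE, note = f$note)
    } else {
      add_truth(ch, pos, kind, f$type, orient, f$carriers, FALSE, FALSE,
                FALSE, note = f$note)
    }
  }

  truth <- do.call(rbind, truth)
  cohort <- variant_cohort(loci, samples, panel)
  out <- list(cohort = cohort, truth = truth, panel = panel,
              design = design, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(out_dir, "cohort.vcf")
    panel_path <- file.path(out_dir, "panel.tsv")
    truth_path <- file.path(out_dir, "truth.tsv")
    write_cohort_vcf(cohort, vcf)
    write_breed_panel(panel, panel_path)
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$vcf <- vcf
    out$panel_path <- panel_path
    out$truth_path <- truth_path
  }
  class(out) <- "sim_cohort"
  out
}

#' Write a variant cohort as a VCF 4.2 text file
#'
#' Emits GT/AD FORMAT fields (AD omitted at loci whose depths are all
#' unknown) and the ANN INFO string when annotations are present.
#'
#' @param cohort A [variant_cohort()].
#' @param path Output path.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "variant_cohort"))
  chroms <- unique(vapply(cohort$loci, `[[`, character(1), "chrom"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chroms, ">"),
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$samples), collapse = "\t"))
  rows <- vapply(cohort$loci, function(lc) {
    ann <- attr(lc, "ann_str")
    info <- if (is.null(ann) || is.na(ann)) "." else ann
    has_ad <- !all(is.na(lc$ad))
    fmt <- if (has_ad) "GT:AD" else "GT"
    cells <- vapply(seq_len(ncol(lc$gt)), function(j) {
      g <- lc$gt[, j]
      gs <- if (anyNA(g)) "./." else paste(g, collapse = "/")
      if (!has_ad) return(gs)
      ds <- if (all(is.na(lc$ad[, j]))) "." else
        paste(lc$ad[, j], collapse = ",")
      paste0(gs, ":", ds)
    }, character(1))
    paste(c(lc$chrom, lc$pos, lc$id, lc$ref,
            paste(lc$alts, collapse = ","), ".", "PASS", info, fmt,
            cells), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Compare a signature scan against a simulation truth table
#'
#' Matches GS records on (chrom, pos, orientation, carrier set), BSGS
#' on (chrom, pos, orientation, breed) and pair records on (chrom, pos,
#' orientation, pair), and returns precision and recall per catalog
#' plus the decoy rejection rate.
#'
#' @param scan A `"signature_scan"` from [discover_signatures()].
#' @param truth Truth table from [simulate_cohort()].
#' @return Data frame with one row per catalog.
#' @export
compare_to_truth <- function(scan, truth) {
  key_gs_obs <- paste(scan$gs$chrom, scan$gs$pos, scan$gs$orientation,
                      scan$gs$carriers)
  key_gs_exp <- paste(truth$chrom, truth$pos, truth$orientation,
                      truth$carriers)[truth$expect_gs]
  key_bs_obs <- paste(scan$bsgs$chrom, scan$bsgs$pos,
                      scan$bsgs$orientation, scan$bsgs$breed)
  key_bs_exp <- paste(truth$chrom, truth$pos, truth$orientation,
                      truth$breed)[truth$expect_bsgs]
  pair_obs_key <- paste(scan$pair$chrom, scan$pair$pos,
                        scan$pair$orientation,
                        paste(scan$pair$breed_a, scan$pair$breed_b,
                              sep = ","))
  pair_exp_key <- paste(truth$chrom, truth$pos, truth$orientation,
                        truth$carriers)[truth$expect_pair]
  pr <- function(obs, exp) {
    tp <- sum(obs %in% exp)
    data.frame(n_expected = length(exp), n_observed = length(obs),
               precision = if (length(obs)) tp / length(obs) else NA_real_,
               recall = if (length(exp)) tp / length(exp) else NA_real_)
  }
  res <- rbind(cbind(catalog = "gs", pr(key_gs_obs, key_gs_exp)),
               cbind(catalog = "bsgs", pr(key_bs_obs, key_bs_exp)),
               cbind(catalog = "pair", pr(pair_obs_key, pair_exp_key)))
  decoys <- truth[truth$kind == "NEAR_MISS_DECOY" & !truth$expect_gs, ]
  decoy_keys <- paste(decoys$chrom, decoys$pos)
  hit <- c(paste(scan$gs$chrom, scan$gs$pos),
           paste(scan$bsgs$chrom, scan$bsgs$pos),
           paste(scan$pair$chrom, scan$pair$pos))
  res$decoy_rejection <- NA_real_
  res$decoy_rejection[1] <- if (nrow(decoys))
    mean(!(decoy_keys %in% hit)) else NA_real_
  res
}
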