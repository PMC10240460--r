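#' Solid-call test for one sample at one locus
#'
#' A call is solid when the genotype is non-missing and the summed read
#' depth of the called allele types reaches the chromosome-class
#' threshold (`depth_autosome`, or `depth_x` on X chromosomes). Unknown
#' depth is never solid.
#'
#' @param gt Integer pair of allele indices (0 = ref), `NA` for missing.
#' @param depths Per-allele read depths aligned to the locus alleles, or
#'   `NULL`/`NA` when unknown.
#' @param chrom Chromosome name.
#' @param cfg A [signature_config()].
#' @return `TRUE` or `FALSE`.
#' @export
is_solid_call <- function(gt, depths, chrom, cfg) {
  if (length(gt) != 2L || anyNA(gt)) return(FALSE)
  if (is.null(depths)) return(FALSE)
  called <- unique(as.integer(gt)) + 1L
  if (any(called > length(depths))) return(FALSE)
  d <- depths[called]
  if (anyNA(d)) return(FALSE)
  thr <- if (chrom %in% cfg$x_chrom_names) cfg$depth_x else cfg$depth_autosome
  sum(d) >= thr
}

# Per-locus solid vector for every sample (vectorised over samples).
locus_solid <- function(locus, cfg) {
  gt <- locus$gt
  ad <- locus$ad
  thr <- if (locus$chrom %in% cfg$x_chrom_names) cfg$depth_x else cfg$depth_autosome
  n <- ncol(gt)
  miss <- is.na(gt[1L, ]) | is.na(gt[2L, ])
  eff <- rep(NA_real_, n)
  for (j in which(!miss)) {
    called <- unique(gt[, j]) + 1L
    d <- ad[called, j]
    if (!anyNA(d)) eff[j] <- sum(d)
  }
  !miss & !is.na(eff) & eff >= thr
}

#' Solid-call mask for a whole cohort
#'
#' @param cohort A [variant_cohort()].
#' @param cfg A [signature_config()].
#' @return Logical matrix, loci x samples, with per-sample solid flags.
#' @export
solid_call_mask <- function(cohort, cfg) {
  stopifnot(inherits(cohort, "variant_cohort"))
  m <- t(vapply(cohort$loci, locus_solid, logical(length(cohort$samples)),
                cfg = cfg))
  dimnames(m) <- list(NULL, cohort$samples)
  m
}

#' Valid breeds at a locus
#'
#' A breed is valid at a locus when at least `min_breed_n` of its dogs
#' have solid calls there. Validity is recomputed independently per
#' locus.
#'
#' @param solid Logical vector of per-sample solid flags at the locus,
#'   in panel sample order.
#' @param panel A [breed_panel()].
#' @param cfg A [signature_config()].
#' @return Character vector of valid breed names.
#' @export
locus_valid_breeds <- function(solid, panel, cfg) {
  breeds <- panel_breeds_of(panel, names(panel$assignments))
  counts <- tapply(solid, factor(breeds, levels = names(panel$breeds)), sum)
  counts[is.na(counts)] <- 0L
  names(counts)[counts >= cfg$min_breed_n]
}

#' Effective-reference-size filter for a candidate signature
#'
#' Candidates are dropped when fewer than `min_reference_n` solid-call
#' samples belong to valid breeds that do not carry the signature. The
#' count is evaluated per candidate (per allele orientation).
#'
#' @param carrier_breeds Breeds carrying the candidate.
#' @param breed_solid Named integer vector of solid-call counts for the
#'   valid breeds at the locus.
#' @param cfg A [signature_config()].
#' @return `TRUE` when the candidate has enough reference support.
#' @export
passes_reference_support <- function(carrier_breeds, breed_solid, cfg) {
  ref <- breed_solid[setdiff(names(breed_solid), carrier_breeds)]
  sum(ref) >= cfg$min_reference_n
}
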