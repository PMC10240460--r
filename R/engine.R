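# Population-frequency analyzer: per-breed BVF records and the GS /
# BSGS / breed-pair / STR signature scans.

#' Compute a breed variant frequency record at one locus
#'
#' BVF for a breed is the number of solid-call dogs homozygous for the
#' oriented allele state divided by the breed's solid-call count.
#' Heterozygous dogs count in the denominator but never in the
#' numerator. Only valid breeds (>= `min_breed_n` solid dogs) appear in
#' the record; the totals used for universal-variant exclusion cover all
#' solid samples, including those in invalid breeds.
#'
#' @param locus A [variant_locus()].
#' @param orientation One of `"VARIANT"`, `"REFERENCE"`, `"STR_HIGH"`,
#'   `"STR_LOW"`.
#' @param panel A [breed_panel()].
#' @param solid Logical per-sample solid vector at this locus.
#' @param cfg A [signature_config()].
#' @param calls Per-sample repeat-group calls (required for STR
#'   orientations); for STR loci the solid set is the set of samples
#'   with a `LOW`/`HIGH`/`MIXED` call.
#' @return A list of class `"bvf_record"`: `chrom`, `pos`, `orientation`,
#'   `breeds` (data frame breed / n_carriers / n_solid / bvf),
#'   `n_solid_total`, `n_carrier_total`.
#' @export
compute_bvf <- function(locus, orientation, panel, solid, cfg,
                        calls = NULL) {
  orientation <- match.arg(orientation,
                           c("VARIANT", "REFERENCE", "STR_HIGH", "STR_LOW"))
  if (orientation %in% c("VARIANT", "REFERENCE")) {
    if (length(locus$alts) != 1L) {
      stop("orientation ", orientation, " requires a bi-allelic locus")
    }
    target <- if (orientation == "VARIANT") 1L else 0L
    carrier <- !is.na(locus$gt[1L, ]) & locus$gt[1L, ] == target &
      locus$gt[2L, ] == target
  } else {
    if (is.null(calls)) stop("STR orientations require group calls")
    solid <- calls != "NO_CALL"
    carrier <- calls == (if (orientation == "STR_HIGH") "HIGH" else "LOW")
  }
  breeds_all <- panel_breeds_of(panel, names(panel$assignments))
  f <- factor(breeds_all, levels = names(panel$breeds))
  n_solid <- tapply(solid, f, sum)
  n_solid[is.na(n_solid)] <- 0L
  n_carr <- tapply(carrier & solid, f, sum)
  n_carr[is.na(n_carr)] <- 0L
  valid <- n_solid >= cfg$min_breed_n
  breeds <- data.frame(breed = names(n_solid)[valid],
                       n_carriers = as.integer(n_carr[valid]),
                       n_solid = as.integer(n_solid[valid]),
                       stringsAsFactors = FALSE)
  breeds$bvf <- ifelse(breeds$n_solid > 0, breeds$n_carriers / breeds$n_solid, NA)
  structure(list(chrom = locus$chrom, pos = locus$pos,
                 orientation = orientation, breeds = breeds,
                 n_solid_total = sum(solid),
                 n_carrier_total = sum(carrier & solid)),
            class = "bvf_record")
}

#' Universal-variant test
#'
#' A variant state is universal when every solid-call sample across all
#' breeds carries it homozygously; such states are attributable to the
#' reference individual and are excluded from the candidate pool.
#'
#' @param bvf A `"bvf_record"`.
#' @return `TRUE`/`FALSE` (with a warning when no sample is solid).
#' @export
is_universal_variant <- function(bvf) {
  if (bvf$n_solid_total == 0L) {
    warning("no solid samples at ", bvf$chrom, ":", bvf$pos)
    return(FALSE)
  }
  bvf$n_carrier_total == bvf$n_solid_total
}

# shared scaffolding: carriers at >= bvf_high among valid breeds
bvf_carriers <- function(bvf, cfg) {
  bvf$breeds$breed[bvf$breeds$bvf >= cfg$bvf_high]
}

bvf_reference_solid <- function(bvf, carriers) {
  sum(bvf$breeds$n_solid[!(bvf$breeds$breed %in% carriers)])
}

signature_record <- function(bvf, carriers, cfg) {
  breed_solid <- stats::setNames(bvf$breeds$n_solid, bvf$breeds$breed)
  if (!passes_reference_support(carriers, breed_solid, cfg)) return(NULL)
  list(chrom = bvf$chrom, pos = bvf$pos, orientation = bvf$orientation,
       carrier_breeds = sort(carriers),
       n_reference_solid = bvf_reference_solid(bvf, carriers))
}

#' Scan a BVF record for a genetic signature (GS)
#'
#' A GS is a locus+orientation with BVF at or above `bvf_high` in at
#' least one valid breed, excluding universal states and candidates
#' without enough reference support.
#'
#' @param bvf A `"bvf_record"` (not universal).
#' @param cfg A [signature_config()].
#' @return A signature record (list) or `NULL`.
#' @export
scan_gs <- function(bvf, cfg) {
  carriers <- bvf_carriers(bvf, cfg)
  if (!length(carriers)) return(NULL)
  signature_record(bvf, carriers, cfg)
}

#' Scan a BVF record for a breed-specific genetic signature (BSGS)
#'
#' A BSGS requires BVF >= `bvf_high` in exactly one valid breed and
#' BVF <= `bvf_low` in every other valid breed (inclusive comparisons at
#' both thresholds), plus reference support.
#'
#' @inheritParams scan_gs
#' @return A record with a single `breed` and its `bvf`, or `NULL`.
#' @export
scan_bsgs <- function(bvf, cfg) {
  carriers <- bvf_carriers(bvf, cfg)
  if (length(carriers) != 1L) return(NULL)
  others <- bvf$breeds[bvf$breeds$breed != carriers, , drop = FALSE]
  if (any(others$bvf > cfg$bvf_low)) return(NULL)
  rec <- signature_record(bvf, carriers, cfg)
  if (is.null(rec)) return(NULL)
  rec$breed <- carriers
  rec$bvf <- bvf$breeds$bvf[bvf$breeds$breed == carriers]
  rec
}

#' Scan a BVF record for a breed-pair-exclusive signature
#'
#' Exactly two valid breeds at or above `bvf_high`, all other valid
#' breeds at or below `bvf_low`, with reference support.
#'
#' @inheritParams scan_gs
#' @return A record with `breed_pair` (sorted pair), or `NULL`.
#' @export
scan_pair_signatures <- function(bvf, cfg) {
  carriers <- bvf_carriers(bvf, cfg)
  if (length(carriers) != 2L) return(NULL)
  others <- bvf$breeds[!(bvf$breeds$breed %in% carriers), , drop = FALSE]
  if (any(others$bvf > cfg$bvf_low)) return(NULL)
  rec <- signature_record(bvf, carriers, cfg)
  if (is.null(rec)) return(NULL)
  rec$breed_pair <- sort(carriers)
  rec
}

#' Scan an STR locus for an expansion/contraction signature
#'
#' Runs the BSGS condition on the `STR_HIGH` and `STR_LOW` group
#' orientations. A carrier breed fixed in the high-repeat group is an
#' `EXPANSION`; fixed in the low-repeat group, a `CONTRACTION`. The
#' repeat difference `unit_diff = min(high) - max(low)` is attached and
#' flagged when it reaches `repeat_diff_report`.
#'
#' @param locus The multi-allelic [variant_locus()].
#' @param model Its accepted `"str_locus_model"`.
#' @param calls Per-sample group calls from [locus_group_calls()].
#' @param panel A [breed_panel()].
#' @param cfg A [signature_config()].
#' @return List of BSGS records (possibly empty).
#' @export
scan_str_signatures <- function(locus, model, calls, panel, cfg) {
  out <- list()
  for (orient in c("STR_HIGH", "STR_LOW")) {
    bvf <- compute_bvf(locus, orient, panel, solid = NULL, cfg, calls = calls)
    if (bvf$n_solid_total == 0L || is_universal_variant(bvf)) next
    rec <- scan_bsgs(bvf, cfg)
    if (is.null(rec)) next
    rec$signature_type <- if (orient == "STR_HIGH") "EXPANSION" else "CONTRACTION"
    rec$unit <- model$unit
    rec$unit_diff <- model$unit_diff
    rec$flagged_large <- model$unit_diff >= cfg$repeat_diff_report
    carr_counts <- if (orient == "STR_HIGH") model$high_counts else model$low_counts
    ref_counts <- if (orient == "STR_HIGH") model$low_counts else model$high_counts
    rec$carrier_range <- str_range_label(model$anchor, model$unit, carr_counts)
    rec$reference_range <- str_range_label(model$anchor, model$unit, ref_counts)
    out[[length(out) + 1L]] <- rec
  }
  out
}

# first annotation row matching the alt allele (fall back to first row)
locus_annotation <- function(locus) {
  ann <- locus$ann
  if (is.null(ann) || !nrow(ann)) {
    return(list(effect = NA_character_, gene = NA_character_,
                region = NA_character_, aa_pos = NA_integer_,
                aa_len = NA_integer_, all_effects = character()))
  }
  hit <- which(ann$allele %in% locus$alts)
  i <- if (length(hit)) hit[1] else 1L
  list(effect = ann$effect[i], gene = ann$gene[i], region = ann$region[i],
       aa_pos = ann$aa_pos[i], aa_len = ann$aa_len[i],
       all_effects = unlist(strsplit(ann$effect, "&", fixed = TRUE)))
}

is_functional_annotation <- function(ann_info, cfg) {
  any(ann_info$all_effects %in% cfg$functional_terms)
}

#' Scan one locus in both allele orientations
#'
#' Runs the class-appropriate scans: bi-allelic SNPs and INDELs are
#' scanned in `VARIANT` and `REFERENCE` orientation for GS, BSGS and
#' (SNPs only, following the published pair analysis) breed-pair
#' signatures; multi-allelic INDEL candidates go through STR typing and
#' the `STR_HIGH`/`STR_LOW` orientations; class `OTHER` is skipped.
#' INDEL BSGS are reported only when the length difference is below
#' `max_short_indel` (the GS record is kept regardless).
#'
#' @param locus A [variant_locus()].
#' @param panel A [breed_panel()].
#' @param solid Logical per-sample solid vector at this locus.
#' @param cfg A [signature_config()].
#' @return List with `gs`, `bsgs`, `pair` record lists and `str_model`
#'   (the accepted model or `NULL`).
#' @export
scan_locus <- function(locus, panel, solid, cfg) {
  cls <- classify_variant(locus)
  gs <- list()
  bsgs <- list()
  pair <- list()
  model <- NULL
  ann_info <- locus_annotation(locus)
  decorate <- function(rec, type) {
    rec$variant_type <- type
    rec$ref <- locus$ref
    rec$alt <- paste(locus$alts, collapse = ",")
    rec$effect <- ann_info$effect
    rec$gene <- ann_info$gene
    rec$region <- ann_info$region
    rec$aa_pos <- ann_info$aa_pos
    rec$aa_len <- ann_info$aa_len
    rec$is_functional <- is_functional_annotation(ann_info, cfg)
    rec
  }
  if (cls %in% c("SNP", "BIALLELIC_INDEL")) {
    type <- if (cls == "SNP") "SNP" else "INDEL"
    indel_diff <- abs(nchar(locus$ref) - nchar(locus$alts[1]))
    seen <- character()
    for (orient in c("VARIANT", "REFERENCE")) {
      bvf <- compute_bvf(locus, orient, panel, solid, cfg)
      if (bvf$n_solid_total == 0L || is_universal_variant(bvf)) next
      g <- scan_gs(bvf, cfg)
      if (!is.null(g)) {
        key <- paste(sort(g$carrier_breeds), collapse = ",")
        # duality guard: a non-universal locus cannot yield the same
        # carrier set in both orientations
        stopifnot(!(key %in% seen))
        seen <- c(seen, key)
        gs[[length(gs) + 1L]] <- decorate(g, type)
      }
      b <- scan_bsgs(bvf, cfg)
      if (!is.null(b) && (type == "SNP" || indel_diff < cfg$max_short_indel)) {
        bsgs[[length(bsgs) + 1L]] <- decorate(b, type)
      }
      if (type == "SNP") {
        p <- scan_pair_signatures(bvf, cfg)
        if (!is.null(p)) pair[[length(pair) + 1L]] <- decorate(p, type)
      }
    }
  } else if (cls == "MULTIALLELIC_INDEL_CANDIDATE") {
    model <- decompose_str_locus(c(locus$ref, locus$alts), cfg)
    if (!is.null(model)) {
      calls <- locus_group_calls(locus, model, cfg)
      for (orient in c("STR_HIGH", "STR_LOW")) {
        bvf <- compute_bvf(locus, orient, panel, solid = NULL, cfg,
                           calls = calls)
        if (bvf$n_solid_total == 0L || is_universal_variant(bvf)) next
        g <- scan_gs(bvf, cfg)
        if (!is.null(g)) gs[[length(gs) + 1L]] <- decorate(g, "STR")
      }
      for (rec in scan_str_signatures(locus, model, calls, panel, cfg)) {
        bsgs[[length(bsgs) + 1L]] <- decorate(rec, "STR")
      }
    }
  }
  list(gs = gs, bsgs = bsgs, pair = pair, str_model = model)
}

rec_field <- function(recs, field, mode = "character") {
  vals <- lapply(recs, function(r) {
    v <- r[[field]]
    if (is.null(v) || !length(v)) NA else v[1]
  })
  as.vector(unlist(lapply(vals, as.vector, mode = mode)), mode = mode)
}

#' Discover all signatures in a cohort
#'
#' Streams every locus through [scan_locus()] and assembles the GS,
#' BSGS and breed-pair catalogs plus the accepted STR locus catalog.
#' Output is deterministic (file order; no randomness).
#'
#' @param cohort A [variant_cohort()].
#' @param cfg A [signature_config()].
#' @return A list of class `"signature_scan"` with data frames `gs`,
#'   `bsgs`, `pair`, `str_catalog`.
#' @export
discover_signatures <- function(cohort, cfg = signature_config()) {
  stopifnot(inherits(cohort, "variant_cohort"))
  mask <- solid_call_mask(cohort, cfg)
  gs <- list()
  bsgs <- list()
  pair <- list()
  strc <- list()
  for (i in seq_along(cohort$loci)) {
    locus <- cohort$loci[[i]]
    res <- scan_locus(locus, cohort$panel, mask[i, ], cfg)
    gs <- c(gs, res$gs)
    bsgs <- c(bsgs, res$bsgs)
    pair <- c(pair, res$pair)
    if (!is.null(res$str_model)) {
      m <- res$str_model
      strc[[length(strc) + 1L]] <- data.frame(
        chrom = locus$chrom, pos = locus$pos, anchor = m$anchor,
        unit = m$unit,
        allele_counts = paste(m$repeat_counts, collapse = ","),
        low_range = str_range_label(m$anchor, m$unit, m$low_counts),
        high_range = str_range_label(m$anchor, m$unit, m$high_counts),
        unit_diff = m$unit_diff, stringsAsFactors = FALSE)
    }
  }
  gs_df <- if (length(gs)) data.frame(
    chrom = rec_field(gs, "chrom"),
    pos = rec_field(gs, "pos", "integer"),
    ref = rec_field(gs, "ref"), alt = rec_field(gs, "alt"),
    type = rec_field(gs, "variant_type"),
    orientation = rec_field(gs, "orientation"),
    carriers = vapply(gs, function(r)
      paste(r$carrier_breeds, collapse = ","), character(1)),
    n_carrier_breeds = vapply(gs, function(r)
      length(r$carrier_breeds), integer(1)),
    n_reference_solid = rec_field(gs, "n_reference_solid", "integer"),
    effect = rec_field(gs, "effect"), gene = rec_field(gs, "gene"),
    region = rec_field(gs, "region"),
    is_functional = rec_field(gs, "is_functional", "logical"),
    stringsAsFactors = FALSE) else empty_gs_df()
  bsgs_df <- if (length(bsgs)) data.frame(
    chrom = rec_field(bsgs, "chrom"),
    pos = rec_field(bsgs, "pos", "integer"),
    ref = rec_field(bsgs, "ref"), alt = rec_field(bsgs, "alt"),
    type = rec_field(bsgs, "variant_type"),
    orientation = rec_field(bsgs, "orientation"),
    breed = rec_field(bsgs, "breed"),
    bvf = rec_field(bsgs, "bvf", "double"),
    n_reference_solid = rec_field(bsgs, "n_reference_solid", "integer"),
    effect = rec_field(bsgs, "effect"), gene = rec_field(bsgs, "gene"),
    region = rec_field(bsgs, "region"),
    aa_pos = rec_field(bsgs, "aa_pos", "integer"),
    aa_len = rec_field(bsgs, "aa_len", "integer"),
    is_functional = rec_field(bsgs, "is_functional", "logical"),
    signature_type = rec_field(bsgs, "signature_type"),
    unit = rec_field(bsgs, "unit"),
    unit_diff = rec_field(bsgs, "unit_diff", "integer"),
    flagged_large = rec_field(bsgs, "flagged_large", "logical"),
    carrier_range = rec_field(bsgs, "carrier_range"),
    reference_range = rec_field(bsgs, "reference_range"),
    stringsAsFactors = FALSE) else empty_bsgs_df()
  pair_df <- if (length(pair)) data.frame(
    chrom = rec_field(pair, "chrom"),
    pos = rec_field(pair, "pos", "integer"),
    ref = rec_field(pair, "ref"), alt = rec_field(pair, "alt"),
    type = rec_field(pair, "variant_type"),
    orientation = rec_field(pair, "orientation"),
    breed_a = vapply(pair, function(r) r$breed_pair[1], character(1)),
    breed_b = vapply(pair, function(r) r$breed_pair[2], character(1)),
    n_reference_solid = rec_field(pair, "n_reference_solid", "integer"),
    stringsAsFactors = FALSE) else empty_pair_df()
  str_df <- if (length(strc)) do.call(rbind, strc) else data.frame(
    chrom = character(), pos = integer(), anchor = character(),
    unit = character(), allele_counts = character(),
    low_range = character(), high_range = character(),
    unit_diff = integer(), stringsAsFactors = FALSE)
  structure(list(gs = gs_df, bsgs = bsgs_df, pair = pair_df,
                 str_catalog = str_df, config = cfg),
            class = "signature_scan")
}

empty_gs_df <- function() data.frame(
  chrom = character(), pos = integer(), ref = character(),
  alt = character(), type = character(), orientation = character(),
  carriers = character(), n_carrier_breeds = integer(),
  n_reference_solid = integer(), effect = character(),
  gene = character(), region = character(), is_functional = logical(),
  stringsAsFactors = FALSE)

empty_bsgs_df <- function() data.frame(
  chrom = character(), pos = integer(), ref = character(),
  alt = character(), type = character(), orientation = character(),
  breed = character(), bvf = numeric(), n_reference_solid = integer(),
  effect = character(), gene = character(), region = character(),
  aa_pos = integer(), aa_len = integer(), is_functional = logical(),
  signature_type = character(), unit = character(),
  unit_diff = integer(), flagged_large = logical(),
  carrier_range = character(), reference_range = character(),
  stringsAsFactors = FALSE)

empty_pair_df <- function() data.frame(
  chrom = character(), pos = integer(), ref = character(),
  alt = character(), type = character(), orientation = character(),
  breed_a = character(), breed_b = character(),
  n_reference_solid = integer(), stringsAsFactors = FALSE)

#' @export
print.signature_scan <- function(x, ...) {
  cat("Signature scan\n")
  cat(sprintf("  GS records:    %d\n", nrow(x$gs)))
  cat(sprintf("  BSGS records:  %d (SNP %d, INDEL %d, STR %d)\n",
              nrow(x$bsgs), sum(x$bsgs$type == "SNP"),
              sum(x$bsgs$type == "INDEL"), sum(x$bsgs$type == "STR")))
  cat(sprintf("  pair records:  %d\n", nrow(x$pair)))
  cat(sprintf("  STR loci typed: %d\n", nrow(x$str_catalog)))
  invisible(x)
}
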