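#' Threshold configuration for signature discovery
#'
#' Bundles every tunable cutoff used by the quality filter, the STR typer
#' and the population-frequency scans. Defaults mirror the full-cohort
#' study design (412 dogs, 76 breeds); for small synthetic cohorts
#' `min_reference_n` must be scaled down to the cohort (see
#' [cohort_design()]).
#'
#' @param bvf_high Breed variant frequency at or above which a breed
#'   counts as a signature carrier (inclusive). Default 0.9.
#' @param bvf_low BVF at or below which a non-target breed is considered
#'   free of the signature (inclusive). Default 0.1.
#' @param min_breed_n Minimum number of solid-call dogs for a breed to be
#'   valid at a locus. Default 3.
#' @param min_reference_n Minimum number of solid-call samples in valid
#'   non-carrier breeds required to keep a candidate signature.
#'   Default 300.
#' @param depth_autosome,depth_x Minimum summed called-allele read depth
#'   for a solid call on autosomes (10) and on the X chromosome (5).
#' @param max_short_indel Exclusive upper bound (bp) on the length
#'   difference of a breed-specific short INDEL. Default 10.
#' @param hotspot_min Minimum breed-specific signatures in one gene
#'   region to call a hotspot. Default 5.
#' @param stretch_min,stretch_density Minimum member count and minimum
#'   density (signatures/kb) of a high-density stretch. Defaults 10 and 10.
#' @param structure_gap Maximum gap (bp, inclusive) between consecutive
#'   members of a breed-specific structure. Default 100000.
#' @param structure_min Minimum member count of a structure. Default 10.
#' @param block_size Genomic block length (bp) for spatial summaries.
#'   Default 10000.
#' @param block_high Signature count at or above which a block counts as
#'   high-density. Default 40.
#' @param unit_len_range Allowed STR repeat-unit lengths (bp), inclusive
#'   two-vector within 1..6.
#' @param repeat_diff_report Minimum repeat-unit difference between the
#'   carrier and reference groups for an STR signature to be flagged as a
#'   large expansion/contraction. Default 3.
#' @param x_chrom_names Chromosome names treated as X.
#' @param par_region Two-vector `c(start, end)` of the X pseudoautosomal
#'   region in bp. Default `c(0, 6600000)`.
#' @param functional_terms Effect terms that mark a signature as
#'   protein-altering.
#' @param coding_terms Effect terms counted as coding in effect
#'   tabulations.
#'
#' @return A list of class `"signature_config"`.
#' @export
signature_config <- function(bvf_high = 0.9,
                             bvf_low = 0.1,
                             min_breed_n = 3L,
                             min_reference_n = 300L,
                             depth_autosome = 10L,
                             depth_x = 5L,
                             max_short_indel = 10L,
                             hotspot_min = 5L,
                             stretch_min = 10L,
                             stretch_density = 10,
                             structure_gap = 100000L,
                             structure_min = 10L,
                             block_size = 10000L,
                             block_high = 40L,
                             unit_len_range = c(1L, 6L),
                             repeat_diff_report = 3L,
                             x_chrom_names = c("chrX", "X"),
                             par_region = c(0, 6600000),
                             functional_terms = c("missense_variant",
                                                  "stop_gained",
                                                  "frameshift_variant",
                                                  "disruptive_inframe_deletion",
                                                  "disruptive_inframe_insertion",
                                                  "conservative_inframe_deletion",
                                                  "conservative_inframe_insertion"),
                             coding_terms = c("missense_variant",
                                              "stop_gained",
                                              "stop_lost",
                                              "start_lost",
                                              "synonymous_variant",
                                              "frameshift_variant",
                                              "disruptive_inframe_deletion",
                                              "disruptive_inframe_insertion",
                                              "conservative_inframe_deletion",
                                              "conservative_inframe_insertion",
                                              "coding_sequence_variant")) {
  if (!(bvf_low >= 0 && bvf_low < bvf_high && bvf_high <= 1)) {
    stop("thresholds must satisfy 0 <= bvf_low < bvf_high <= 1")
  }
  counts <- c(min_breed_n, min_reference_n, depth_autosome, depth_x,
              max_short_indel, hotspot_min, stretch_min, structure_gap,
              structure_min, block_size, block_high, repeat_diff_report)
  if (any(counts < 0)) stop("count thresholds must be non-negative")
  if (length(unit_len_range) != 2L ||
      unit_len_range[1] < 1L || unit_len_range[2] > 6L ||
      unit_len_range[1] > unit_len_range[2]) {
    stop("unit_len_range must lie within [1, 6]")
  }
  if (length(par_region) != 2L || par_region[1] > par_region[2]) {
    stop("par_region must be c(start, end) with start <= end")
  }
  cfg <- list(bvf_high = bvf_high, bvf_low = bvf_low,
              min_breed_n = as.integer(min_breed_n),
              min_reference_n = as.integer(min_reference_n),
              depth_autosome = as.integer(depth_autosome),
              depth_x = as.integer(depth_x),
              max_short_indel = as.integer(max_short_indel),
              hotspot_min = as.integer(hotspot_min),
              stretch_min = as.integer(stretch_min),
              stretch_density = stretch_density,
              structure_gap = as.integer(structure_gap),
              structure_min = as.integer(structure_min),
              block_size = as.integer(block_size),
              block_high = as.integer(block_high),
              unit_len_range = as.integer(unit_len_range),
              repeat_diff_report = as.integer(repeat_diff_report),
              x_chrom_names = x_chrom_names,
              par_region = as.numeric(par_region),
              functional_terms = functional_terms,
              coding_terms = coding_terms)
  class(cfg) <- "signature_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value` (or `key<TAB>value`); `#` starts a comment.
#' Keys must match [signature_config()] argument names; vector-valued
#' keys take comma-separated values.
#'
#' @param path Path to the configuration file.
#' @return A `"signature_config"` list.
#' @export
read_signature_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", fixed = FALSE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (anyNA(num)) parts else num
  }
  known <- names(formals(signature_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(signature_config, args)
}

#' @export
print.signature_config <- function(x, ...) {
  cat("Signature discovery configuration\n")
  cat(sprintf("  BVF carrier >= %.2f, non-carrier <= %.2f\n",
              x$bvf_high, x$bvf_low))
  cat(sprintf("  solid call depth: autosome >= %d, X >= %d\n",
              x$depth_autosome, x$depth_x))
  cat(sprintf("  valid breed >= %d dogs; reference support >= %d samples\n",
              x$min_breed_n, x$min_reference_n))
  cat(sprintf("  STR units %d-%d bp; flag repeat diff >= %d\n",
              x$unit_len_range[1], x$unit_len_range[2],
              x$repeat_diff_report))
  invisible(x)
}

# round-half-up at `digits` decimals; R's round() is banker's rounding,
# but printed report values (99.91, 1.07, 11.15, 1.10) are half-up.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
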