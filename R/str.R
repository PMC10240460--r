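# STR locus typing: repeat-unit decomposition of multi-allelic INDEL
# alleles and two-group k-means classification of repeat counts.

# TRUE when u is not itself a repetition of a shorter unit
is_primitive_unit <- function(u) {
  L <- nchar(u)
  if (L <= 1L) return(TRUE)
  for (d in seq_len(L - 1L)) {
    if (L %% d == 0L && strrep(substr(u, 1L, d), L / d) == u) return(FALSE)
  }
  TRUE
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# greedy front-strip of unit u; returns list(k, tail)
strip_unit <- function(s, u) {
  L <- nchar(u)
  k <- 0L
  while (nchar(s) >= L && substr(s, 1L, L) == u) {
    s <- substring(s, L + 1L)
    k <- k + 1L
  }
  list(k = k, tail = s)
}

#' Decompose a multi-allelic locus into an STR model
#'
#' Searches for the shortest primitive repeat unit `u` (length within
#' `cfg$unit_len_range`) and the maximal common anchor such that every
#' allele equals `anchor + u^k (+ common suffix)` with the repeat count
#' `k` varying across alleles. Loci whose alleles cannot be explained by
#' a single repeat unit are rejected (returned as `NULL`), mirroring the
#' restriction to single-unit repeat loci.
#'
#' @param alleles Character vector of allele sequences (reference
#'   first by convention); at least 3 distinct alleles.
#' @param cfg A [signature_config()].
#' @return A list of class `"str_locus_model"` with `anchor`, `unit`,
#'   `suffix`, `repeat_counts` (named by allele, in input order),
#'   `low_counts`, `high_counts`, `boundary` and `unit_diff`, or `NULL`
#'   when the locus is not a single-unit STR.
#' @export
decompose_str_locus <- function(alleles, cfg = signature_config()) {
  alleles <- as.character(alleles)
  uniq <- unique(alleles)
  if (length(uniq) < 3L) return(NULL)
  if (any(!nzchar(uniq))) return(NULL)
  lens <- nchar(uniq)
  # distinct alleles of equal length cannot share a single-unit model
  if (anyDuplicated(lens)) return(NULL)
  shortest <- uniq[which.min(lens)]
  longest <- uniq[which.max(lens)]
  g <- 0L
  for (l in lens) g <- gcd2(g, l - min(lens))
  if (g == 0L) return(NULL)
  for (L in seq(cfg$unit_len_range[1], cfg$unit_len_range[2])) {
    if (g %% L != 0L) next
    for (a in rev(seq.int(0L, min(lens)))) {
      anchor <- substr(shortest, 1L, a)
      if (a > 0L && !all(startsWith(uniq, anchor))) next
      rem_long <- substring(longest, a + 1L)
      if (nchar(rem_long) < L) next
      u <- substr(rem_long, 1L, L)
      if (!is_primitive_unit(u)) next
      dec <- lapply(substring(uniq, a + 1L), strip_unit, u = u)
      tails <- vapply(dec, `[[`, character(1), "tail")
      if (length(unique(tails)) != 1L) next
      ks <- vapply(dec, `[[`, integer(1), "k")
      if (length(unique(ks)) < 2L) next
      counts <- stats::setNames(ks[match(alleles, uniq)], alleles)
      grp <- split_repeat_groups(ks)
      return(structure(list(anchor = anchor, unit = u, suffix = tails[1],
                            repeat_counts = counts,
                            low_counts = grp$low, high_counts = grp$high,
                            boundary = grp$boundary,
                            unit_diff = min(grp$high) - max(grp$low)),
                       class = "str_locus_model"))
    }
  }
  NULL
}

#' @export
print.str_locus_model <- function(x, ...) {
  cat(sprintf("STR model: %s(%s)k + %s\n",
              if (nzchar(x$anchor)) x$anchor else "-", x$unit,
              if (nzchar(x$suffix)) x$suffix else "-"))
  cat(sprintf("  low group counts %s | high group counts %s (diff %d)\n",
              paste(x$low_counts, collapse = ","),
              paste(x$high_counts, collapse = ","), x$unit_diff))
  invisible(x)
}

#' Repeat count of one allele under an STR model
#'
#' @param allele Allele sequence.
#' @param model An `"str_locus_model"`.
#' @return Integer exponent of the unit in
#'   `anchor + unit^k + suffix`; errors when the allele does not
#'   decompose under the model.
#' @export
allele_repeat_count <- function(allele, model) {
  a <- nchar(model$anchor)
  if (a > 0L && substr(allele, 1L, a) != model$anchor) {
    stop("allele does not start with model anchor: ", allele)
  }
  mid <- substring(allele, a + 1L)
  s <- nchar(model$suffix)
  if (s > 0L) {
    if (nchar(mid) < s ||
        substring(mid, nchar(mid) - s + 1L) != model$suffix) {
      stop("allele does not end with model suffix: ", allele)
    }
    mid <- substr(mid, 1L, nchar(mid) - s)
  }
  L <- nchar(model$unit)
  if (nchar(mid) %% L != 0L) {
    stop("allele is not a whole number of repeat units: ", allele)
  }
  k <- nchar(mid) %/% L
  if (strrep(model$unit, k) != mid) {
    stop("allele does not decompose under model unit: ", allele)
  }
  k
}

#' Split repeat counts into low and high groups by two-group k-means
#'
#' Computes the two-cluster k-means solution on the distinct repeat
#' counts. In one dimension the optimal clusters are contiguous, so the
#' k-means objective (within-group sum of squares) is minimised exactly
#' over all contiguous cuts of the sorted counts — the fixed point that
#' Lloyd iterations from the minimum/maximum seeds aim for, without
#' their risk of stalling in a local optimum on scattered counts. When
#' two cuts tie, the one with the larger low group wins (a count
#' equidistant between the group centres goes to the low group:
#' deterministic, conservative toward contraction).
#'
#' @param counts Integer repeat counts (multiset; duplicates ignored).
#' @return List with sorted `low` and `high` count vectors and the
#'   `boundary` midpoint between the final group means. Errors when
#'   fewer than two distinct counts exist.
#' @export
split_repeat_groups <- function(counts) {
  x <- sort(unique(as.integer(counts)))
  if (length(x) < 2L) stop("need at least two distinct repeat counts")
  best <- Inf
  best_cut <- 0L
  for (cut in seq_len(length(x) - 1L)) {
    lo <- x[seq_len(cut)]
    hi <- x[-seq_len(cut)]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    # strictly better, or tied with a larger low group (ties go low)
    if (wss < best - 1e-12 ||
        (abs(wss - best) <= 1e-12 && cut > best_cut)) {
      best <- wss
      best_cut <- cut
    }
  }
  low <- x[seq_len(best_cut)]
  high <- x[-seq_len(best_cut)]
  list(low = low, high = high, boundary = (mean(low) + mean(high)) / 2)
}

#' Repeat-group call for one sample at an STR locus
#'
#' `NO_CALL` when the genotype is missing or the total effective allele
#' depth (sum of depths of the called allele types) is below the
#' chromosome-class threshold; `LOW`/`HIGH` when both called alleles
#' fall in that repeat group; `MIXED` when they straddle the boundary.
#'
#' @param gt Integer pair of allele indices (0 = ref), `NA` missing.
#' @param depths Per-allele depths at the locus.
#' @param model An `"str_locus_model"` whose `repeat_counts` are ordered
#'   as the locus alleles (ref first, then alts).
#' @param chrom Chromosome name.
#' @param cfg A [signature_config()].
#' @return One of `"LOW"`, `"HIGH"`, `"MIXED"`, `"NO_CALL"`.
#' @export
sample_group_call <- function(gt, depths, model, chrom, cfg) {
  if (!is_solid_call(gt, depths, chrom, cfg)) return("NO_CALL")
  k <- model$repeat_counts[as.integer(gt) + 1L]
  in_high <- k %in% model$high_counts
  if (all(in_high)) return("HIGH")
  if (all(!in_high)) return("LOW")
  "MIXED"
}

# group calls for all samples at a locus
locus_group_calls <- function(locus, model, cfg) {
  vapply(seq_len(ncol(locus$gt)), function(j) {
    sample_group_call(locus$gt[, j], locus$ad[, j], model, locus$chrom, cfg)
  }, character(1))
}

# Table-4-style "X(unit)a-b" notation for a count range
str_range_label <- function(anchor, unit, counts) {
  r <- range(counts)
  span <- if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2])
  paste0(anchor, "(", unit, ")", span)
}
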