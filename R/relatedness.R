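# Breed-pair sharing counts, geometric-mean similarity, score
# correlations, and per-dog breed composition from GS catalogs.

#' Breed-by-breed signature sharing counts
#'
#' Every GS with carrier set C increments the diagonal cell of each
#' carrier breed and the off-diagonal cell of every unordered carrier
#' pair: a signature homozygous in three breeds counts towards all
#' three breeds and all three breed-pairs.
#'
#' @param gs GS data frame with a `carriers` column (comma-joined breed
#'   names), or a list of carrier-breed character vectors.
#' @param breeds Breed list fixing the matrix order.
#' @return Symmetric integer count matrix (breeds x breeds).
#' @export
count_shared_signatures <- function(gs, breeds) {
  carrier_sets <- if (is.data.frame(gs)) {
    strsplit(gs$carriers, ",", fixed = TRUE)
  } else {
    gs
  }
  n <- length(breeds)
  N <- matrix(0L, n, n, dimnames = list(breeds, breeds))
  for (cs in carrier_sets) {
    idx <- match(cs, breeds)
    if (anyNA(idx)) stop("carrier breed not in breed list: ",
                         paste(cs[is.na(idx)], collapse = ", "))
    N[idx, idx] <- N[idx, idx] + 1L
  }
  N
}

#' Geometric-mean similarity matrix with min-max standardisation
#'
#' `s[i,j] = N[i,j] / sqrt(N[i,i] * N[j,j])`; `z` rescales the
#' off-diagonal entries of `s` to `[0, 1]` (the most similar pair maps
#' to 1, the least similar to 0). Breeds with zero signatures get `NA`
#' rows/columns.
#'
#' @param N Sharing count matrix from [count_shared_signatures()].
#' @return List of class `"breed_similarity"` with matrices `s`, `z`
#'   and `pct` (`s` as a percentage).
#' @export
similarity_matrix <- function(N) {
  d <- diag(N)
  if (any(d == 0)) {
    warning("breed(s) with zero signatures reported as NA: ",
            paste(rownames(N)[d == 0], collapse = ", "))
  }
  denom <- sqrt(outer(d, d))
  s <- ifelse(denom > 0, N / denom, NA_real_)
  off <- s[row(s) != col(s)]
  off <- off[!is.na(off)]
  z <- matrix(NA_real_, nrow(N), ncol(N), dimnames = dimnames(N))
  if (length(off)) {
    lo <- min(off)
    hi <- max(off)
    if (hi > lo) {
      z[] <- (s - lo) / (hi - lo)
    } else {
      warning("all off-diagonal similarities equal; standardised scores NA")
    }
    diag(z) <- NA_real_
  }
  structure(list(s = s, z = z, pct = 100 * s), class = "breed_similarity")
}

#' @export
print.breed_similarity <- function(x, ...) {
  cat(sprintf("Breed similarity over %d breeds\n", nrow(x$s)))
  off <- x$s[row(x$s) != col(x$s)]
  off <- off[!is.na(off)]
  if (length(off)) {
    top <- which(x$s == max(off) & row(x$s) < col(x$s), arr.ind = TRUE)[1, ]
    cat(sprintf("  most similar pair: %s - %s (s = %.4f, %.2f%%)\n",
                rownames(x$s)[top[1]], colnames(x$s)[top[2]],
                max(off), 100 * max(off)))
  }
  invisible(x)
}

#' Correlate two per-pair score vectors
#'
#' Rank (Spearman) or linear (Pearson) correlation of similarity scores
#' aligned on the same breed-pair set; used to compare SNP-based scores
#' with INDEL- and STR-based scores, and signature counts with sample
#' sizes.
#'
#' @param a,b Aligned numeric vectors (length >= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation coefficient, or `NA` for constant input (with a
#'   warning).
#' @export
correlate_score_vectors <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("score vectors must be aligned")
  if (length(a) < 3L) stop("need at least 3 paired scores")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant score vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Per-dog breed composition from GS carrying scores
#'
#' For each sample and each breed, scores every GS locus of the breed
#' 0, 0.5 or 1 according to whether the sample is homozygous for the
#' opposite state, heterozygous, or homozygous for the signature state
#' (for STR signatures: LOW/MIXED/HIGH group calls, or the reverse for
#' low-repeat signatures). Non-solid loci score 0 but stay in the
#' denominator, which is the breed's total GS count.
#'
#' @param cohort A [variant_cohort()] holding the samples to profile.
#' @param gs GS data frame from [discover_signatures()] (its loci must
#'   exist in `cohort` by chrom+pos).
#' @param cfg A [signature_config()].
#' @return Matrix samples x breeds of carrying fractions in `[0, 1]`
#'   (class `"breed_composition"`); breeds with no GS get `NA`.
#' @export
infer_breed_composition <- function(cohort, gs, cfg = signature_config()) {
  stopifnot(inherits(cohort, "variant_cohort"))
  samples <- cohort$samples
  breeds <- names(cohort$panel$breeds)
  if (is.data.frame(gs) && nrow(gs)) {
    loc_key <- vapply(cohort$loci, function(l)
      paste(l$chrom, l$pos, sep = ":"), character(1))
    gs_idx <- match(paste(gs$chrom, gs$pos, sep = ":"), loc_key)
    if (anyNA(gs_idx)) stop("GS locus missing from cohort")
  } else {
    gs_idx <- integer()
  }
  score <- matrix(0, length(samples), length(breeds),
                  dimnames = list(samples, breeds))
  totals <- stats::setNames(rep(0L, length(breeds)), breeds)
  if (length(gs_idx)) {
    carrier_sets <- strsplit(gs$carriers, ",", fixed = TRUE)
    for (r in seq_along(gs_idx)) {
      locus <- cohort$loci[[gs_idx[r]]]
      orient <- gs$orientation[r]
      sc <- locus_carry_scores(locus, orient, cfg)
      for (b in carrier_sets[[r]]) {
        score[, b] <- score[, b] + sc
        totals[b] <- totals[b] + 1L
      }
    }
  }
  frac <- score
  for (j in seq_along(breeds)) {
    frac[, j] <- if (totals[j] > 0) score[, j] / totals[j] else NA_real_
  }
  structure(frac, class = c("breed_composition", class(frac)))
}

# per-sample carry score (0 / 0.5 / 1) for one GS locus+orientation
locus_carry_scores <- function(locus, orientation, cfg) {
  solid <- locus_solid(locus, cfg)
  if (orientation %in% c("VARIANT", "REFERENCE")) {
    target <- if (orientation == "VARIANT") 1L else 0L
    hits <- colSums(locus$gt == target)
    sc <- ifelse(is.na(hits), 0, hits / 2)
    ifelse(solid, sc, 0)
  } else {
    model <- decompose_str_locus(c(locus$ref, locus$alts), cfg)
    if (is.null(model)) stop("GS locus is not an STR locus: ",
                             locus$chrom, ":", locus$pos)
    calls <- locus_group_calls(locus, model, cfg)
    full <- if (orientation == "STR_HIGH") "HIGH" else "LOW"
    ifelse(calls == full, 1, ifelse(calls == "MIXED", 0.5, 0))
  }
}

#' Ranked view of a composition matrix
#'
#' @param composition Output of [infer_breed_composition()].
#' @param sample Sample id to rank.
#' @param top Number of best/worst breeds to show.
#' @return Data frame of breeds ranked by carrying fraction.
#' @export
rank_breed_composition <- function(composition, sample, top = 5L) {
  fr <- composition[sample, ]
  fr <- fr[!is.na(fr)]
  ord <- order(-fr)
  data.frame(breed = names(fr)[ord], fraction = unname(fr[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
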