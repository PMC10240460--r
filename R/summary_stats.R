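# Effect-category tabulation and the exact 2x2 enrichment test.

#' Tabulate signature records by effect category
#'
#' A record is coding when any of its effect terms (`&`-separated
#' SnpEff terms are split) is in the configured coding-term set.
#' Percentages are printed-half-up at two decimals. Functional classes
#' follow the protein-impact vocabulary (missense, nonsense, frameshift,
#' inframe indel).
#'
#' @param records Signature data frame with an `effect` column and
#'   optionally `breed` and `type`.
#' @param cfg A [signature_config()].
#' @return List of class `"effect_tabulation"`: `overall` (one-row data
#'   frame), `classes` (counts by functional class) and `by_breed`
#'   (when a breed column exists).
#' @export
tabulate_effect_categories <- function(records, cfg = signature_config()) {
  if (!nrow(records)) {
    return(structure(list(overall = data.frame(n = 0L, n_coding = 0L,
                                               n_noncoding = 0L,
                                               pct_coding = NA_real_,
                                               pct_noncoding = NA_real_),
                          classes = data.frame(class = character(),
                                               n = integer()),
                          by_breed = NULL),
                     class = "effect_tabulation"))
  }
  terms <- strsplit(ifelse(is.na(records$effect), "", records$effect),
                    "&", fixed = TRUE)
  coding <- vapply(terms, function(t) any(t %in% cfg$coding_terms),
                   logical(1))
  n <- nrow(records)
  overall <- data.frame(n = n, n_coding = sum(coding),
                        n_noncoding = sum(!coding),
                        pct_coding = round_half_up(100 * sum(coding) / n, 2),
                        pct_noncoding = round_half_up(100 * sum(!coding) / n, 2))
  cls <- vapply(terms, function(t) {
    if (any(t == "stop_gained")) "nonsense"
    else if (any(t == "missense_variant")) "missense"
    else if (any(t == "frameshift_variant")) "frameshift"
    else if (any(grepl("inframe", t, fixed = TRUE))) "inframe_indel"
    else "other"
  }, character(1))
  classes <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  names(classes) <- c("class", "n")
  by_breed <- NULL
  if ("breed" %in% names(records)) {
    agg <- tapply(coding, records$breed, function(v)
      c(n = length(v), n_coding = sum(v)))
    by_breed <- data.frame(breed = names(agg),
                           n = vapply(agg, `[[`, numeric(1), "n"),
                           n_coding = vapply(agg, `[[`, numeric(1), "n_coding"),
                           stringsAsFactors = FALSE)
    by_breed$pct_coding <- round_half_up(100 * by_breed$n_coding / by_breed$n, 2)
    rownames(by_breed) <- NULL
  }
  structure(list(overall = overall, classes = classes, by_breed = by_breed),
            class = "effect_tabulation")
}

#' @export
print.effect_tabulation <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Effect tabulation: %d records, %d coding (%.2f%%), %d non-coding (%.2f%%)\n",
              o$n, o$n_coding, o$pct_coding, o$n_noncoding, o$pct_noncoding))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric point
#' probabilities, over all tables with the observed margins, that do
#' not exceed the observed table's point probability (standard exact
#' convention, with the customary `1 + 1e-7` relative tolerance on the
#' comparison). Degenerate margins give p = 1.
#'
#' @param tab 2x2 integer matrix, or the four cells `a, b, c, d`
#'   (row-wise) as a vector.
#' @return The exact p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("table cells must be non-negative integers")
  }
  r1 <- sum(tab[1L, ])
  r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- logp[match(tab[1L, 1L], support)]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}
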