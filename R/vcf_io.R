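#' Construct a single variant locus
#'
#' Low-level constructor used by the VCF reader and the cohort
#' simulator; also convenient for building small fixtures in tests.
#' Coordinates are 1-based inclusive (VCF convention) throughout.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref Reference allele sequence.
#' @param alts Character vector of alternative alleles (>= 1).
#' @param gt 2 x n_samples integer matrix of allele indices (0 = ref),
#'   `NA` for missing genotypes.
#' @param ad (1 + length(alts)) x n_samples integer matrix of per-allele
#'   read depths; an all-`NA` column marks a depth-unknown sample.
#' @param ann Data frame of effect annotations (columns `allele`,
#'   `effect`, `gene`, `region`, `aa_pos`, `aa_len`) or `NULL`.
#' @param id Optional variant id.
#' @return A list of class `"variant_locus"`.
#' @export
variant_locus <- function(chrom, pos, ref, alts, gt, ad, ann = NULL,
                          id = ".") {
  alts <- as.character(alts)
  if (length(alts) < 1L) stop("at least one alternative allele required")
  if (pos < 1) stop("pos must be >= 1")
  gt <- matrix(as.integer(gt), nrow = 2L)
  n_allele <- 1L + length(alts)
  if (any(gt >= n_allele, na.rm = TRUE) || any(gt < 0L, na.rm = TRUE)) {
    stop("genotype allele index out of range at ", chrom, ":", pos)
  }
  ad <- matrix(as.integer(ad), nrow = n_allele)
  if (ncol(ad) != ncol(gt)) stop("gt and ad disagree on sample count")
  if (any(ad < 0L, na.rm = TRUE)) stop("allele depths must be non-negative")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 id = as.character(id), ref = as.character(ref),
                 alts = alts, gt = gt, ad = ad, ann = ann),
            class = "variant_locus")
}

#' Assemble a variant cohort from loci
#'
#' @param loci List of [variant_locus()] objects, in genomic file order.
#' @param samples Character vector of sample ids (column order of every
#'   locus matrix).
#' @param panel A [breed_panel()] covering exactly these samples.
#' @return A list of class `"variant_cohort"`.
#' @export
variant_cohort <- function(loci, samples, panel) {
  stopifnot(inherits(panel, "breed_panel"))
  missing <- setdiff(samples, names(panel$assignments))
  if (length(missing)) {
    stop("samples absent from panel: ", paste(missing, collapse = ", "))
  }
  for (lc in loci) {
    if (ncol(lc$gt) != length(samples)) {
      stop("locus at ", lc$chrom, ":", lc$pos, " has wrong sample count")
    }
  }
  structure(list(loci = loci, samples = samples, panel = panel),
            class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cls <- table(vapply(x$loci, classify_variant, character(1)))
  cat(sprintf("Variant cohort: %d loci, %d samples, %d breeds\n",
              length(x$loci), length(x$samples), length(x$panel$breeds)))
  for (nm in names(cls)) cat(sprintf("  %s: %d\n", nm, cls[[nm]]))
  invisible(x)
}

#' Read a multi-sample VCF into a variant cohort
#'
#' Reads a plain or bgzipped VCF 4.x with per-sample `GT` and `AD`
#' FORMAT fields and optional SnpEff-style `ANN` INFO annotations.
#' Samples are restricted and reordered to the panel order; extra VCF
#' samples are dropped. Sites lacking `AD` are kept with all samples
#' marked depth-unknown (they later fail the solid-call filter).
#'
#' @param path Path to the VCF file.
#' @param panel A [breed_panel()]; every panel sample must appear in the
#'   VCF header.
#' @return A `"variant_cohort"`.
#' @export
read_cohort <- function(path, panel) {
  stopifnot(inherits(panel, "breed_panel"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  want <- names(panel$assignments)
  missing <- setdiff(want, vcf_samples)
  if (length(missing)) {
    stop("panel sample(s) absent from VCF header: ",
         paste(missing, collapse = ", "))
  }
  fix <- v@fix
  gt_raw <- v@gt[, want, drop = FALSE]
  fmt <- v@gt[, 1]
  n <- nrow(fix)
  loci <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_allele <- 1L + length(alts)
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    gt_k <- match("GT", keys)
    ad_k <- match("AD", keys)
    cells <- strsplit(gt_raw[i, ], ":", fixed = TRUE)
    gt <- matrix(NA_integer_, 2L, length(want))
    ad <- matrix(NA_integer_, n_allele, length(want))
    for (j in seq_along(cells)) {
      f <- cells[[j]]
      if (!is.na(gt_k) && length(f) >= gt_k) {
        al <- strsplit(f[gt_k], "[/|]")[[1]]
        if (length(al) == 2L && !any(al == ".")) {
          gt[, j] <- as.integer(al)
        }
      }
      if (!is.na(ad_k) && length(f) >= ad_k && f[ad_k] != ".") {
        d <- suppressWarnings(as.integer(
          strsplit(f[ad_k], ",", fixed = TRUE)[[1]]))
        if (length(d) == n_allele && !anyNA(d)) ad[, j] <- d
      }
    }
    loci[[i]] <- variant_locus(
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"], alts = alts, gt = gt, ad = ad,
      ann = parse_ann(fix[i, "INFO"]),
      id = if (is.na(fix[i, "ID"])) "." else fix[i, "ID"])
  }
  variant_cohort(loci, want, panel)
}

#' Parse a SnpEff-style ANN INFO field
#'
#' Retains only the subfields that drive downstream logic: the described
#' allele, the effect term(s), the gene/region label, and the protein
#' position (`AA.pos/AA.len`). Unknown subfields are ignored.
#'
#' @param info Raw INFO string of one VCF record (or a bare
#'   `ANN=...` value).
#' @return A data frame with columns `allele`, `effect`, `gene`,
#'   `region`, `aa_pos`, `aa_len`, or `NULL` when no ANN entry exists.
#' @export
parse_ann <- function(info) {
  if (is.na(info) || !nzchar(info)) return(NULL)
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  ann <- fields[startsWith(fields, "ANN=")]
  if (!length(ann)) return(NULL)
  entries <- strsplit(sub("^ANN=", "", ann[1]), ",", fixed = TRUE)[[1]]
  parts <- strsplit(entries, "|", fixed = TRUE)
  get <- function(p, k) if (length(p) >= k && nzchar(p[k])) p[k] else NA_character_
  allele <- vapply(parts, get, character(1), 1L)
  effect <- vapply(parts, get, character(1), 2L)
  gene <- vapply(parts, get, character(1), 4L)
  aa <- vapply(parts, get, character(1), 14L)
  aa_pos <- rep(NA_integer_, length(aa))
  aa_len <- rep(NA_integer_, length(aa))
  has <- !is.na(aa) & grepl("/", aa, fixed = TRUE)
  if (any(has)) {
    sp <- strsplit(aa[has], "/", fixed = TRUE)
    aa_pos[has] <- suppressWarnings(as.integer(vapply(sp, `[`, character(1), 1L)))
    aa_len[has] <- suppressWarnings(as.integer(vapply(sp, `[`, character(1), 2L)))
  }
  bad <- !is.na(aa_pos) & !is.na(aa_len) & aa_pos > aa_len
  if (any(bad)) stop("ANN protein position exceeds protein length")
  data.frame(allele = allele, effect = effect, gene = gene, region = gene,
             aa_pos = aa_pos, aa_len = aa_len, stringsAsFactors = FALSE)
}

#' Classify a variant locus into an analysis class
#'
#' `SNP`: one alt, ref and alt both single bases. `BIALLELIC_INDEL`: one
#' alt of different length. `MULTIALLELIC_INDEL_CANDIDATE`: two or more
#' alts with at least two alleles differing in length (the pool STR
#' typing draws from). `OTHER`: everything else (e.g. multi-allelic
#' SNPs), excluded from all scans.
#'
#' @param locus A `"variant_locus"`.
#' @return One of `"SNP"`, `"BIALLELIC_INDEL"`,
#'   `"MULTIALLELIC_INDEL_CANDIDATE"`, `"OTHER"`.
#' @export
classify_variant <- function(locus) {
  lens <- nchar(c(locus$ref, locus$alts))
  n_alt <- length(locus$alts)
  if (n_alt == 1L) {
    if (lens[1] == 1L && lens[2] == 1L) return("SNP")
    if (lens[1] != lens[2]) return("BIALLELIC_INDEL")
    return("OTHER")
  }
  if (length(unique(lens)) >= 2L) return("MULTIALLELIC_INDEL_CANDIDATE")
  "OTHER"
}

#' Write a record table as a deterministic TSV report
#'
#' Writes a header row plus one tab-separated row per record. Numeric
#' double columns are printed with two decimals (half-up, matching the
#' density/length precision of the published tables); integer columns
#' are printed as-is. Rows are ordered by `chrom`, `pos`, `breed`
#' (whichever of those columns exist), so identical inputs give
#' byte-identical files.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  ord_cols <- intersect(c("chrom", "pos", "breed"), names(df))
  if (length(ord_cols) && nrow(df)) {
    df <- df[do.call(order, df[ord_cols]), , drop = FALSE]
  }
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col) && !is.integer(col)) {
      out[[nm]] <- ifelse(is.na(col), "NA",
                          sprintf("%.2f", round_half_up(col, 2)))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Restrict a cohort to a genomic region and/or variant classes
#'
#' The variant-selector step: narrows the loci the frequency analyzer
#' sees. Selecting then scanning equals scanning then filtering the
#' report.
#'
#' @param cohort A [variant_cohort()].
#' @param region `"chrom:start-end"` string (1-based inclusive), or
#'   `NULL`.
#' @param classes Character vector of [classify_variant()] classes to
#'   keep, or `NULL`.
#' @return A filtered `"variant_cohort"`.
#' @export
filter_cohort <- function(cohort, region = NULL, classes = NULL) {
  stopifnot(inherits(cohort, "variant_cohort"))
  keep <- rep(TRUE, length(cohort$loci))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must be chrom:start-end, got ", region)
    chrom <- m[2]
    start <- as.numeric(m[3])
    end <- as.numeric(m[4])
    keep <- keep & vapply(cohort$loci, function(l)
      l$chrom == chrom && l$pos >= start && l$pos <= end, logical(1))
  }
  if (!is.null(classes)) {
    keep <- keep & vapply(cohort$loci, classify_variant,
                          character(1)) %in% classes
  }
  variant_cohort(cohort$loci[keep], cohort$samples, cohort$panel)
}
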