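# Positional aggregation: merged BSGS catalog, gene hotspots,
# high-density stretches, breed-specific structures, 10-kb blocks.

chrom_pos_sorted <- function(df) {
  all(order(df$chrom, df$pos) == seq_len(nrow(df)))
}

#' Merge per-type BSGS catalogs into one sorted queue
#'
#' K-way merge of coordinate-sorted SNP, INDEL and STR BSGS lists: at
#' each step the record with the smallest (chrom, pos) among the queue
#' heads moves to the merged list. Records of different types at the
#' same coordinate for the same breed are fused into one entry listing
#' both types; member counts are conserved.
#'
#' @param snp,indel,str Data frames with at least `chrom`, `pos`,
#'   `breed` (and optionally `region`, `effect`, `gene`,
#'   `is_functional`), each sorted by (chrom, pos).
#' @return A data frame of class `"merged_bsgs"` sorted by (chrom, pos)
#'   with per-type member counts `n_snp`, `n_indel`, `n_str`, `n_total`
#'   and a `types` label.
#' @export
merge_bsgs_catalogs <- function(snp, indel, str) {
  norm <- function(df, type) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(chrom = character(), pos = integer(),
                        breed = character(), type = character(),
                        region = character(), gene = character(),
                        effect = character(), is_functional = logical(),
                        stringsAsFactors = FALSE))
    }
    if (!chrom_pos_sorted(df)) {
      stop(type, " catalog is not sorted by (chrom, pos)")
    }
    data.frame(chrom = df$chrom, pos = as.integer(df$pos),
               breed = df$breed, type = type,
               region = if ("region" %in% names(df)) df$region else NA_character_,
               gene = if ("gene" %in% names(df)) df$gene else NA_character_,
               effect = if ("effect" %in% names(df)) df$effect else NA_character_,
               is_functional = if ("is_functional" %in% names(df))
                 df$is_functional else FALSE,
               stringsAsFactors = FALSE)
  }
  queues <- list(norm(snp, "SNP"), norm(indel, "INDEL"), norm(str, "STR"))
  heads <- rep(1L, 3L)
  sizes <- vapply(queues, nrow, integer(1))
  out <- vector("list", sum(sizes))
  k <- 0L
  while (any(heads <= sizes)) {
    best <- 0L
    for (q in 1:3) {
      if (heads[q] > sizes[q]) next
      if (best == 0L) { best <- q; next }
      a <- queues[[q]][heads[q], ]
      b <- queues[[best]][heads[best], ]
      if (a$chrom < b$chrom || (a$chrom == b$chrom && a$pos < b$pos)) best <- q
    }
    k <- k + 1L
    out[[k]] <- queues[[best]][heads[best], ]
    heads[best] <- heads[best] + 1L
  }
  merged <- do.call(rbind, out[seq_len(k)])
  if (is.null(merged)) merged <- norm(NULL, "SNP")
  merged$n_snp <- as.integer(merged$type == "SNP")
  merged$n_indel <- as.integer(merged$type == "INDEL")
  merged$n_str <- as.integer(merged$type == "STR")
  # fuse same-coordinate multi-type entries per breed
  key <- paste(merged$chrom, merged$pos, merged$breed, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    idx <- match(key, key[first])
    fused <- merged[first, , drop = FALSE]
    fused$n_snp <- as.integer(tapply(merged$n_snp, idx, sum))
    fused$n_indel <- as.integer(tapply(merged$n_indel, idx, sum))
    fused$n_str <- as.integer(tapply(merged$n_str, idx, sum))
    fused$type <- vapply(split(merged$type, idx), function(t)
      paste(sort(unique(t)), collapse = "+"), character(1))
    fused$is_functional <- as.logical(tapply(merged$is_functional, idx, any))
    merged <- fused
  }
  merged$n_total <- merged$n_snp + merged$n_indel + merged$n_str
  rownames(merged) <- NULL
  class(merged) <- c("merged_bsgs", "data.frame")
  merged
}

segment_row <- function(breed, chrom, members) {
  start <- min(members$pos)
  end <- max(members$pos)
  length_kb <- (end - start) / 1000  # span without +1 (published arithmetic)
  n_total <- sum(members$n_total)
  fn <- members$is_functional %in% TRUE
  data.frame(breed = breed, chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             n_snp = sum(members$n_snp), n_indel = sum(members$n_indel),
             n_str = sum(members$n_str), n_total = n_total,
             length_kb = length_kb,
             density = if (length_kb > 0) n_total / length_kb else Inf,
             has_functional = any(fn),
             functional_genes = paste(sort(unique(members$gene[fn & !is.na(members$gene)])),
                                      collapse = ","),
             functional_effects = paste(sort(unique(members$effect[fn & !is.na(members$effect)])),
                                        collapse = ","),
             stringsAsFactors = FALSE)
}

#' Gene-region signature hotspots
#'
#' Groups one breed's BSGS by annotated gene region and reports regions
#' holding at least `hotspot_min` members. Records lacking a region
#' label are pooled under `"unannotated"` with a warning.
#'
#' @param catalog A `"merged_bsgs"` catalog (or any data frame with
#'   `breed`, `chrom`, `pos`, `region` and per-type counts).
#' @param cfg A [signature_config()].
#' @return Data frame of hotspot segments with per-type counts, span and
#'   density.
#' @export
find_gene_hotspots <- function(catalog, cfg = signature_config()) {
  df <- as.data.frame(catalog)
  if (!nrow(df)) return(df_segments_empty(region = TRUE))
  region <- df$region
  if (any(is.na(region) | !nzchar(region))) {
    warning("BSGS without region label counted under 'unannotated'")
    region[is.na(region) | !nzchar(region)] <- "unannotated"
  }
  if (!"n_total" %in% names(df)) {
    df$n_snp <- as.integer(df$type == "SNP")
    df$n_indel <- as.integer(df$type == "INDEL")
    df$n_str <- as.integer(df$type == "STR")
    df$n_total <- 1L
  }
  out <- list()
  for (grp in split(seq_len(nrow(df)),
                    paste(df$breed, region, sep = "\r"))) {
    members <- df[grp, , drop = FALSE]
    if (sum(members$n_total) < cfg$hotspot_min) next
    seg <- segment_row(members$breed[1], members$chrom[1], members)
    seg$region <- region[grp[1]]
    out[[length(out) + 1L]] <- seg
  }
  if (!length(out)) return(df_segments_empty(region = TRUE))
  res <- do.call(rbind, out)
  res[order(res$breed, res$chrom, res$start), , drop = FALSE]
}

df_segments_empty <- function(region = FALSE) {
  df <- data.frame(breed = character(), chrom = character(),
                   start = integer(), end = integer(), n_snp = integer(),
                   n_indel = integer(), n_str = integer(),
                   n_total = integer(), length_kb = numeric(),
                   density = numeric(), has_functional = logical(),
                   functional_genes = character(),
                   functional_effects = character(),
                   stringsAsFactors = FALSE)
  if (region) df$region <- character()
  df
}

# qualifying predicate for an index window [i, j] over sorted positions
stretch_qualifies <- function(positions, i, j, cfg) {
  n <- j - i + 1L
  if (n < cfg$stretch_min) return(FALSE)
  span <- positions[j] - positions[i]
  if (span <= 0) return(TRUE)  # zero span: infinite density
  n / (span / 1000) >= cfg$stretch_density
}

#' High-density signature stretches on one chromosome
#'
#' Finds maximal runs of one breed's sorted BSGS positions with at least
#' `stretch_min` members and density (members per kb of span) at least
#' `stretch_density`. A qualifying window is maximal when no one-member
#' extension on either side still qualifies; overlapping maximal windows
#' are reduced to the longest one (ties: more members, then leftmost).
#'
#' @param positions Sorted positions of one breed's BSGS on one
#'   chromosome.
#' @param cfg A [signature_config()].
#' @return Data frame with `start`, `end`, `n`, `length_kb`, `density`.
#' @export
find_density_stretches <- function(positions, cfg = signature_config()) {
  positions <- as.numeric(positions)
  if (is.unsorted(positions)) stop("positions must be sorted")
  n <- length(positions)
  empty <- data.frame(start = integer(), end = integer(), n = integer(),
                      length_kb = numeric(), density = numeric())
  m <- cfg$stretch_min
  if (n < m) return(empty)
  # all qualifying windows, vectorised per start index
  qual <- matrix(FALSE, n, n)
  for (i in seq_len(n - m + 1L)) {
    js <- (i + m - 1L):n
    cnt <- js - i + 1L
    span <- positions[js] - positions[i]
    ok <- cnt * 1000 >= cfg$stretch_density * span
    qual[i, js] <- ok
  }
  wins <- which(qual, arr.ind = TRUE)
  if (!nrow(wins)) return(empty)
  maximal <- wins[apply(wins, 1L, function(w) {
    i <- w[1]; j <- w[2]
    left_ok <- i > 1L && qual[i - 1L, j]
    right_ok <- j < n && qual[i, j + 1L]
    !left_ok && !right_ok
  }), , drop = FALSE]
  maximal <- maximal[order(maximal[, 1L], maximal[, 2L]), , drop = FALSE]
  # coalesce overlapping maximal windows: keep the longest per group
  groups <- list()
  cur <- maximal[1L, , drop = FALSE]
  cur_end <- cur[1L, 2L]
  for (r in seq_len(nrow(maximal))[-1L]) {
    if (maximal[r, 1L] <= cur_end) {
      cur <- rbind(cur, maximal[r, ])
      cur_end <- max(cur_end, maximal[r, 2L])
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- maximal[r, , drop = FALSE]
      cur_end <- maximal[r, 2L]
    }
  }
  groups[[length(groups) + 1L]] <- cur
  rows <- lapply(groups, function(g) {
    span <- positions[g[, 2L]] - positions[g[, 1L]]
    cnt <- g[, 2L] - g[, 1L] + 1L
    best <- order(-span, -cnt, g[, 1L])[1L]
    i <- g[best, 1L]; j <- g[best, 2L]
    length_kb <- (positions[j] - positions[i]) / 1000
    data.frame(start = as.integer(positions[i]),
               end = as.integer(positions[j]),
               n = j - i + 1L, length_kb = length_kb,
               density = if (length_kb > 0) (j - i + 1L) / length_kb else Inf)
  })
  do.call(rbind, rows)
}

#' High-density stretches for every breed and chromosome in a catalog
#'
#' @param catalog A `"merged_bsgs"` catalog or BSGS data frame with
#'   `breed`, `chrom`, `pos`.
#' @param cfg A [signature_config()].
#' @return Data frame with `breed`, `chrom`, `start`, `end`, `n`,
#'   `length_kb`, `density`.
#' @export
find_all_stretches <- function(catalog, cfg = signature_config()) {
  df <- as.data.frame(catalog)
  out <- list()
  for (grp in split(seq_len(nrow(df)), paste(df$breed, df$chrom, sep = "\r"))) {
    members <- df[grp, , drop = FALSE]
    res <- find_density_stretches(sort(members$pos), cfg)
    if (!nrow(res)) next
    res <- cbind(breed = members$breed[1], chrom = members$chrom[1], res,
                 stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- res
  }
  if (!length(out)) {
    return(data.frame(breed = character(), chrom = character(),
                      start = integer(), end = integer(), n = integer(),
                      length_kb = numeric(), density = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$breed, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Breed-specific genomic structures
#'
#' Per breed and chromosome, splits the merged BSGS catalog at gaps
#' larger than `structure_gap` (the gap rule is inclusive: members
#' exactly `structure_gap` apart stay joined) and keeps runs with at
#' least `structure_min` members. Per-type counts, span, density and the
#' functional-effect flags of contained members are reported.
#'
#' @param catalog A `"merged_bsgs"` catalog.
#' @param cfg A [signature_config()].
#' @return Data frame of structure segments.
#' @export
find_breed_structures <- function(catalog, cfg = signature_config()) {
  df <- as.data.frame(catalog)
  if (!nrow(df)) return(df_segments_empty())
  out <- list()
  for (grp in split(seq_len(nrow(df)), paste(df$breed, df$chrom, sep = "\r"))) {
    members <- df[grp, , drop = FALSE]
    members <- members[order(members$pos), , drop = FALSE]
    gaps <- diff(members$pos)
    run_id <- cumsum(c(0L, as.integer(gaps > cfg$structure_gap)))
    for (run in split(seq_len(nrow(members)), run_id)) {
      seg_members <- members[run, , drop = FALSE]
      if (sum(seg_members$n_total) < cfg$structure_min) next
      out[[length(out) + 1L]] <- segment_row(seg_members$breed[1],
                                             seg_members$chrom[1],
                                             seg_members)
    }
  }
  if (!length(out)) return(df_segments_empty())
  res <- do.call(rbind, out)
  res <- res[order(res$breed, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tile genetic signatures into fixed-size genomic blocks
#'
#' Blocks are 1-based closed intervals `[k*block_size + 1,
#' (k+1)*block_size]` (block index `k` starting at 0), so position
#' 10000 falls in block 0 and 10001 in block 1 for 10-kb blocks. Only
#' non-empty blocks are returned; block counts sum to the number of GS
#' records.
#'
#' @param gs GS data frame with `chrom`, `pos`, `n_carrier_breeds`.
#' @param cfg A [signature_config()].
#' @return Data frame with `chrom`, `block`, `start`, `end`, `n_gs`,
#'   `mean_breeds_per_gs`.
#' @export
summarize_blocks <- function(gs, cfg = signature_config()) {
  if (!nrow(gs)) {
    return(data.frame(chrom = character(), block = integer(),
                      start = numeric(), end = numeric(), n_gs = integer(),
                      mean_breeds_per_gs = numeric()))
  }
  block <- (gs$pos - 1L) %/% cfg$block_size
  key <- paste(gs$chrom, block, sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  res <- data.frame(chrom = gs$chrom[first], block = block[first],
                    stringsAsFactors = FALSE)
  res$start <- res$block * as.numeric(cfg$block_size) + 1
  res$end <- (res$block + 1) * as.numeric(cfg$block_size)
  res$n_gs <- as.integer(tabulate(idx, nbins = sum(first)))
  res$mean_breeds_per_gs <- as.numeric(
    tapply(gs$n_carrier_breeds, idx, mean))
  res <- res[order(res$chrom, res$block), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summary of signatures in the X pseudoautosomal region
#'
#' Restricts block summaries to X-chromosome blocks fully inside the
#' configured PAR interval and reports the signature count, the share
#' contained in high-density blocks (>= `block_high` signatures), the
#' mean number of carrier breeds per signature, and (when the GS
#' catalog is supplied) the breeds represented.
#'
#' @param blocks Output of [summarize_blocks()].
#' @param cfg A [signature_config()].
#' @param gs Optional GS data frame for breed representation.
#' @return A one-row data frame summary (zero counts when X is absent,
#'   with a warning).
#' @export
par_summary <- function(blocks, cfg = signature_config(), gs = NULL) {
  on_x <- blocks$chrom %in% cfg$x_chrom_names
  if (!any(on_x)) warning("no X-chromosome blocks found")
  par <- blocks[on_x & blocks$end <= cfg$par_region[2] &
                  blocks$start >= cfg$par_region[1] + 1, , drop = FALSE]
  n_gs <- sum(par$n_gs)
  high <- par$n_gs >= cfg$block_high
  breeds <- NA_character_
  n_breeds <- NA_integer_
  if (!is.null(gs) && nrow(gs)) {
    in_par <- gs$chrom %in% cfg$x_chrom_names &
      gs$pos >= cfg$par_region[1] + 1 & gs$pos <= cfg$par_region[2]
    carr <- unique(unlist(strsplit(gs$carriers[in_par], ",", fixed = TRUE)))
    breeds <- paste(sort(carr), collapse = ",")
    n_breeds <- length(carr)
  }
  data.frame(n_blocks = nrow(par), n_gs = n_gs,
             n_high_blocks = sum(high),
             n_gs_high_blocks = sum(par$n_gs[high]),
             frac_gs_high_blocks = if (n_gs > 0)
               sum(par$n_gs[high]) / n_gs else NA_real_,
             mean_breeds_per_gs = if (n_gs > 0)
               sum(par$mean_breeds_per_gs * par$n_gs) / n_gs else NA_real_,
             n_breeds_represented = n_breeds,
             breeds_represented = breeds,
             stringsAsFactors = FALSE)
}
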