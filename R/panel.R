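#' Construct a breed panel
#'
#' @param samples Character vector of sample identifiers.
#' @param breeds Character vector of breed names, parallel to `samples`.
#' @return A list of class `"breed_panel"` with `assignments` (named
#'   character vector sample -> breed) and `breeds` (list breed ->
#'   sample ids, in first-appearance order).
#' @export
breed_panel <- function(samples, breeds) {
  samples <- as.character(samples)
  breeds <- as.character(breeds)
  if (length(samples) != length(breeds)) {
    stop("samples and breeds must have equal length")
  }
  dup <- samples[duplicated(samples)]
  if (length(dup)) {
    stop("duplicate sample id(s) in panel: ", paste(unique(dup), collapse = ", "))
  }
  if (length(breeds) && any(!nzchar(breeds))) stop("breed names must be non-empty")
  assignments <- stats::setNames(breeds, samples)
  by_breed <- split(samples, factor(breeds, levels = unique(breeds)))
  structure(list(assignments = assignments, breeds = by_breed),
            class = "breed_panel")
}

#' Read a two-column sample-to-breed panel file
#'
#' Each non-comment line holds a sample id and a breed name separated by
#' a tab. Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to the panel file.
#' @return A `"breed_panel"` object.
#' @export
read_breed_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    warning("panel file is empty: ", path)
    return(breed_panel(character(), character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad)) {
    stop(sprintf("malformed panel line %d: expected <sample>\\t<breed>, got %s",
                 idx[bad[1]], sQuote(lines[idx[bad[1]]])))
  }
  m <- do.call(rbind, fields)
  breed_panel(trimws(m[, 1]), trimws(m[, 2]))
}

#' Write a breed panel to a tab-separated file
#' @param panel A `"breed_panel"`.
#' @param path Output path.
#' @export
write_breed_panel <- function(panel, path) {
  stopifnot(inherits(panel, "breed_panel"))
  writeLines(paste(names(panel$assignments), panel$assignments, sep = "\t"),
             path)
  invisible(path)
}

#' @export
print.breed_panel <- function(x, ...) {
  cat(sprintf("Breed panel: %d samples, %d breeds\n",
              length(x$assignments), length(x$breeds)))
  for (b in names(x$breeds)) {
    cat(sprintf("  %s: %d\n", b, length(x$breeds[[b]])))
  }
  invisible(x)
}

# breed of each sample, in cohort sample order
panel_breeds_of <- function(panel, samples) {
  unname(panel$assignments[samples])
}
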