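#' Largest-remainder proportional allocation
#'
#' Apportions `total` synthetic images across lesion classes proportionally
#' to source class counts, using largest-remainder (Hamilton) rounding: each
#' class first receives the floor of its exact quota `total * n_k / sum(n)`,
#' then the leftover units go one-by-one to the classes with the largest
#' fractional parts. Ties on the fractional part are broken toward the larger
#' raw count, then lexicographically by class name, so the result is
#' deterministic and independent of input order.
#'
#' @param classCounts named non-negative numeric vector of source class
#'   counts, at least one positive.
#' @param total non-negative integer number of images to allocate.
#' @return Named integer vector summing exactly to `total`; every entry is
#'   the floor or ceiling of its exact quota.
#' @export
#' @examples
#' allocateProportional(hamClassCounts(), total = 5000)
allocateProportional <- function(classCounts, total) {
  if (is.null(names(classCounts)) || anyNA(classCounts))
    stop("classCounts must be a named vector without NA")
  if (any(classCounts < 0) || sum(classCounts) <= 0)
    stop("classCounts must be non-negative with a positive sum")
  total <- as.integer(total)
  if (is.na(total) || total < 0) stop("total must be a non-negative integer")
  q <- total * classCounts / sum(classCounts)
  base <- floor(q + 1e-9)                      # guard exact-integer quotas
  frac <- q - base
  left <- total - sum(base)
  out <- base
  if (left > 0) {
    ord <- order(-frac, -classCounts, names(classCounts))
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(out), names(classCounts))
}

#' Build the per-tone allocation table
#'
#' Applies \code{\link{allocateProportional}} once and assigns the same
#' per-class counts to the medium and the dark tone, so the grand total is
#' `2 * totalPerTone`.
#'
#' @param classCounts named source class counts.
#' @param totalPerTone images to generate per tone (the published dataset
#'   uses 5000 per tone for a 10,000-image total).
#' @return An \linkS4class{AllocationTable}.
#' @export
#' @examples
#' buildAllocation(hamClassCounts(), 5000)
buildAllocation <- function(classCounts, totalPerTone) {
  per <- allocateProportional(classCounts, totalPerTone)
  ord <- order(names(per))
  new("AllocationTable", classNames = names(per)[ord],
      medium = unname(per[ord]), dark = unname(per[ord]))
}

#' HAM10000 metadata class counts
#'
#' Per-class image counts of the HAM10000 dermoscopy benchmark (10,015
#' images over seven diagnostic classes), carried as a repository fixture
#' (`extdata/ham10000_class_counts.csv`). These are the source counts from
#' which the published per-tone allocation is derived.
#'
#' @return Named integer vector over \code{\link{lesionClasses}()}.
#' @export
hamClassCounts <- function() {
  f <- system.file("extdata", "ham10000_class_counts.csv", package = "ToneGAN",
                   mustWork = TRUE)
  readClassCounts(f)
}

#' Read / write class-count and allocation CSVs
#'
#' `readClassCounts` reads a two-column CSV (`class,count`);
#' `writeAllocationCsv` writes an \linkS4class{AllocationTable} with the
#' published table's layout (`Class,Medium,Dark`).
#'
#' @param path CSV file path.
#' @return `readClassCounts`: named integer vector.
#' @export
readClassCounts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "count") %in% names(df)))
    stop("expected columns 'class' and 'count' in ", path)
  stats::setNames(as.integer(df$count), df$class)
}

#' @rdname readClassCounts
#' @param x an \linkS4class{AllocationTable}.
#' @export
writeAllocationCsv <- function(x, path) {
  stopifnot(is(x, "AllocationTable"))
  utils::write.csv(allocationDF(x), path, row.names = FALSE)
  invisible(path)
}

#' Class counts of a loaded dataset
#'
#' @param dataset a \linkS4class{LabeledImageSet}.
#' @return Named integer vector of per-class image counts.
#' @export
datasetClassCounts <- function(dataset) {
  stopifnot(is(dataset, "LabeledImageSet"))
  tab <- table(lesionLabels(dataset))
  stats::setNames(as.integer(tab), names(tab))
}
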