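## Occupancy classification across the four samples.
## Sample order is fixed everywhere: working cardiomyocyte first, then the
## three conduction-system components.

#' Fixed sample order for occupancy analysis
#' @export
CCS_SAMPLES <- c("CM", "SAN", "AVN", "VCS")

#' Occupancy category names
#'
#' The eight named component/CCS categories plus `Shared` and `Mixed`.
#' @export
CCS_CATEGORIES <- c("Shared", "CCS Open", "CCS Closed",
                    "SAN Open", "SAN Closed", "AVN Open", "AVN Closed",
                    "VCS Open", "VCS Closed", "Mixed")

## bit pattern (CM,SAN,AVN,VCS) -> category, the named part of the table
.CATEGORY_TABLE <- c(
  "1111" = "Shared",
  "0111" = "CCS Open",   # open across the CCS, closed in CM
  "1000" = "CCS Closed", # open in CM only, closed across the CCS
  "0100" = "SAN Open",
  "1011" = "SAN Closed",
  "0010" = "AVN Open",
  "1101" = "AVN Closed",
  "0001" = "VCS Open",
  "1110" = "VCS Closed")

.bits_key <- function(bits) {
  if (is.matrix(bits)) apply(bits, 1, function(b) paste(as.integer(b), collapse = ""))
  else paste(as.integer(bits), collapse = "")
}

#' Categorize a presence pattern as open/closed
#'
#' Applies the occupancy truth table over the fixed sample order
#' (CM, SAN, AVN, VCS). A region open in all four samples is `Shared`; a
#' region open in SAN, AVN and CM but closed in VCS is `VCS Closed`; a region
#' open in CM but closed in SAN, AVN and VCS is `CCS Closed`; and so on for
#' the eight named component/CCS categories. The six remaining attainable
#' patterns are `Mixed`. All-zero patterns are a contract violation (union
#' regions are by construction open somewhere).
#'
#' @param bits logical/0-1 vector of length 4, or a matrix with 4 columns
#'   (one row per region), ordered (CM, SAN, AVN, VCS).
#' @param lenient alternative, less strict reading of component uniqueness:
#'   patterns with CM closed and two (but not all three) CCS components open
#'   are assigned `CCS Open`, and the mirrored CM-open patterns `CCS Closed`,
#'   instead of `Mixed`.
#' @return character vector of category names.
#' @export
categorize <- function(bits, lenient = FALSE) {
  if (!is.matrix(bits)) bits <- matrix(as.logical(bits), nrow = 1)
  if (ncol(bits) != 4) stop("bits must have 4 entries (CM, SAN, AVN, VCS)")
  mode(bits) <- "logical"
  if (any(rowSums(bits) == 0))
    stop("all-zero presence pattern: union regions must be open in >= 1 sample")
  key <- .bits_key(bits)
  cat <- unname(.CATEGORY_TABLE[key])
  mixed <- is.na(cat)
  cat[mixed] <- "Mixed"
  if (lenient && any(mixed)) {
    ccs_open_n <- rowSums(bits[, 2:4, drop = FALSE])
    cat[mixed & !bits[, 1] & ccs_open_n == 2] <- "CCS Open"
    cat[mixed & bits[, 1] & ccs_open_n == 1] <- "CCS Closed"
  }
  cat
}

#' Build the master region-by-sample occupancy table
#'
#' One record per master (nonredundant union) region, with a presence bit per
#' sample (set iff the sample's peak set overlaps the region by at least
#' `min_overlap_bp`) and the derived open/closed category.
#'
#' @param master the merged union of the four sample peak sets
#'   (an `interval_set`).
#' @param samples named or ordered list of 4 `interval_set`s in the order
#'   (CM, SAN, AVN, VCS).
#' @param min_overlap_bp minimum shared basepairs for presence.
#' @param lenient passed to [categorize()].
#' @return data.frame (class `occupancy`) with columns `chrom`, `start`,
#'   `end`, one logical column per sample, and `category`.
#' @export
build_occupancy <- function(master, samples, min_overlap_bp = 1, lenient = FALSE) {
  if (length(samples) != 4)
    stop("samples must be the 4 peak sets in order (CM, SAN, AVN, VCS)")
  if (!is.null(names(samples)) && !identical(names(samples), CCS_SAMPLES))
    samples <- samples[CCS_SAMPLES]
  mgr <- .as_gr(master)
  bits <- vapply(samples, function(s) {
    if (nrow(s) == 0) rep(FALSE, length(mgr))
    else .count_ov(mgr, .as_gr(s), minoverlap = min_overlap_bp) > 0
  }, logical(length(mgr)))
  bits <- matrix(bits, nrow = length(mgr), dimnames = list(NULL, CCS_SAMPLES))
  if (any(rowSums(bits) == 0))
    stop("master region with no overlapping sample: master must be the union of the samples")
  out <- data.frame(chrom = master$chrom, start = master$start, end = master$end,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(bits))
  out$category <- categorize(bits, lenient = lenient)
  class(out) <- c("occupancy", "data.frame")
  out
}

#' Reconcile two replicate peak sets
#'
#' Optional pre-step for replicate peak BEDs: the merged union of the two
#' replicates, restricted to regions present (>= `min_overlap_bp`) in both.
#' @param a,b replicate `interval_set`s.
#' @param min_overlap_bp minimum shared basepairs.
#' @return an `interval_set`.
#' @export
reconcile_replicates <- function(a, b, min_overlap_bp = 1) {
  un <- merge_intervals(interval_set(rbind(as.data.frame(a)[1:6], as.data.frame(b)[1:6]),
                                     label = set_label(a), normalize = FALSE))
  intersect_intervals(intersect_intervals(un, a, min_overlap_bp), b, min_overlap_bp)
}

#' Summarize occupancy categories
#'
#' Exact per-category counts and fractions, plus the aggregate Open vs Closed
#' totals over the eight named component/CCS categories.
#'
#' @param records an `occupancy` data.frame from [build_occupancy()].
#' @return list with `counts`, `fractions` (named over [CCS_CATEGORIES]) and
#'   `open_closed` (named totals `Open`, `Closed`).
#' @export
summarize_categories <- function(records) {
  if (nrow(records) == 0) stop("no occupancy records to summarize")
  counts <- table(factor(records$category, levels = CCS_CATEGORIES))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  fractions <- counts / sum(counts)
  open_cats <- grep(" Open$", CCS_CATEGORIES, value = TRUE)
  closed_cats <- grep(" Closed$", CCS_CATEGORIES, value = TRUE)
  list(counts = counts, fractions = fractions,
       open_closed = c(Open = sum(counts[open_cats]),
                       Closed = sum(counts[closed_cats])))
}

#' Export the regions of one occupancy category as BED
#'
#' Produces the region set fed to downstream Gene Ontology tools and to the
#' motif/network stage.
#' @param records an `occupancy` data.frame.
#' @param category one of [CCS_CATEGORIES].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
export_category_regions <- function(records, category, path) {
  if (!category %in% CCS_CATEGORIES)
    stop("unknown category: ", category)
  sel <- records[records$category == category, , drop = FALSE]
  x <- if (nrow(sel) == 0) .empty_set(category)
  else interval_set(sel$chrom, sel$start, sel$end, label = category,
                    normalize = FALSE)
  write_bed(x, path)
}

#' Regions of one occupancy category as an interval set
#' @param records an `occupancy` data.frame.
#' @param category one of [CCS_CATEGORIES].
#' @return an `interval_set`.
#' @export
category_regions <- function(records, category) {
  if (!category %in% CCS_CATEGORIES) stop("unknown category: ", category)
  sel <- records[records$category == category, , drop = FALSE]
  if (nrow(sel) == 0) return(.empty_set(category))
  interval_set(sel$chrom, sel$start, sel$end, label = category, normalize = FALSE)
}

#' Write the full occupancy matrix as TSV
#' @param records an `occupancy` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(records, path) {
  df <- as.data.frame(records)
  for (s in CCS_SAMPLES) df[[s]] <- as.integer(df[[s]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
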