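#' @title Genomic interval sets
#' @description
#' The currency of the package: a set of 0-based half-open genomic intervals
#' carried as a data frame with class `interval_set`. Columns are `chrom`,
#' `start`, `end`, `name`, `score`, `strand`; the sample/catalog label is an
#' attribute. After normalization intervals on one chromosome are sorted and
#' non-overlapping. Strand is carried but ignored in all overlap computations
#' (chromatin accessibility is unstranded).
#' @name interval_set
NULL

#' Construct an interval set
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end` (and optionally `name`, `score`,
#'   `strand`).
#' @param start,end integer vectors; 0-based half-open coordinates,
#'   `0 <= start < end`.
#' @param name,score,strand optional per-interval annotation; `strand` is one
#'   of `"+"`, `"-"`, `"."`.
#' @param label sample or catalog name attached to the set.
#' @param normalize if `TRUE` (default), sort and fuse overlapping/bookended
#'   intervals so the set satisfies the normalization invariant.
#' @return an `interval_set`.
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, name = NA_character_,
                         score = NA_real_, strand = ".", label = "",
                         normalize = TRUE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop("data.frame input needs columns chrom, start, end")
    chrom <- as.character(df$chrom)
    start <- df$start
    end <- df$end
    if ("name" %in% names(df)) name <- as.character(df$name)
    if ("score" %in% names(df)) score <- df$score
    if ("strand" %in% names(df)) strand <- as.character(df$strand)
  }
  n <- length(start)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("invalid interval(s) at index ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  x <- structure(df, class = c("interval_set", "data.frame"), label = label)
  if (normalize) x <- merge_intervals(x, max_gap = 0) else x <- .sort_set(x)
  x
}

.empty_set <- function(label = "") {
  structure(data.frame(chrom = character(), start = numeric(), end = numeric(),
                       name = character(), score = numeric(), strand = character(),
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"), label = label)
}

.sort_set <- function(x) {
  o <- order(x$chrom, x$start, x$end)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$label <- attr(x, "label")
  class(out) <- c("interval_set", "data.frame")
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set '%s': %d interval(s), %d chromosome(s), %s bp\n",
              set_label(x), nrow(x), length(unique(x$chrom)),
              format(total_bp(x), big.mark = ",")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Label of an interval set
#' @param x an `interval_set`.
#' @return character scalar.
#' @export
set_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "" else lab
}

#' Total basepairs covered by an interval set
#'
#' For a normalized set this equals the basepairs of the merged set.
#' @param x an `interval_set`.
#' @return numeric scalar (bp).
#' @export
total_bp <- function(x) sum(x$end - x$start)

## GRanges bridge: 0-based half-open -> 1-based closed. Strand deliberately
## dropped to "*" so overlaps are unstranded.
.as_gr <- function(x) {
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

.from_gr <- function(gr, label = "") {
  if (length(gr) == 0) return(.empty_set(label))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   name = NA_character_, score = NA_real_, strand = ".",
                   stringsAsFactors = FALSE)
  .sort_set(structure(df, class = c("interval_set", "data.frame"), label = label))
}


## countOverlaps with GenomeInfoDb's disjoint-seqlevels warning silenced
## (comparing sets on entirely different chromosomes is legitimate here)
.count_ov <- function(a, b, minoverlap = 1) {
  suppressWarnings(GenomicRanges::countOverlaps(a, b, minoverlap = minoverlap))
}

#' Read a BED file
#'
#' Accepts the BED3-BED6 dialect: tab-separated, optional `track`/`browser`/`#`
#' header lines, extra columns beyond the sixth ignored. Coordinates are
#' 0-based half-open and preserved exactly; the returned set is normalized
#' (sorted, overlapping and bookended records fused).
#'
#' @param path BED file path.
#' @param label label for the resulting set (defaults to the file name).
#' @param normalize fuse overlapping records (default `TRUE`).
#' @return an `interval_set`.
#' @export
read_bed <- function(path, label = basename(path), normalize = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(.empty_set(label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", idx[which(nf < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": start >= end (zero-length interval)")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  NA_real_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  interval_set(chrom, start, end, name = name, score = score, strand = strand,
               label = label, normalize = normalize)
}

#' Write a BED file
#'
#' Emits BED3 when no annotation columns are populated, BED6 otherwise;
#' coordinates round-trip losslessly through [read_bed()].
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  has_meta <- any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != ".")
  if (has_meta) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end),
                     ifelse(is.na(x$name), ".", x$name),
                     ifelse(is.na(x$score), "0", format(x$score, trim = TRUE, scientific = FALSE)),
                     x$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Fuses intervals whose gap is `<= max_gap`; bookended intervals (gap 0)
#' fuse for any `max_gap >= 0`. The result is normalized.
#'
#' @param x an `interval_set`.
#' @param max_gap maximum gap (bp) fused across; `>= 0`.
#' @return a normalized `interval_set`.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0) return(.empty_set(set_label(x)))
  gr <- GenomicRanges::reduce(.as_gr(x), min.gapwidth = max_gap + 1)
  .from_gr(gr, set_label(x))
}

#' Element-level intersection
#'
#' Returns the regions of `a` that overlap `b` by at least `min_overlap_bp`
#' basepairs, preserving `a`'s coordinates (element-level semantics, not
#' clipped bp). Asymmetric by design; `intersect_intervals(a, b)` is always a
#' subset of `a`.
#'
#' @param a,b `interval_set`s.
#' @param min_overlap_bp minimum shared basepairs (`>= 1`).
#' @return subset of `a` as an `interval_set`.
#' @export
intersect_intervals <- function(a, b, min_overlap_bp = 1) {
  stopifnot(min_overlap_bp >= 1)
  if (nrow(a) == 0 || nrow(b) == 0) return(.empty_set(set_label(a)))
  hits <- .count_ov(.as_gr(a), .as_gr(b), minoverlap = min_overlap_bp) > 0
  out <- a[hits, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$label <- set_label(a)
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Fraction of regions of one set overlapping another
#'
#' @param a,b `interval_set`s; `a` must be nonempty.
#' @param min_overlap_bp minimum shared basepairs.
#' @return proportion in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, min_overlap_bp = 1) {
  if (nrow(a) == 0) stop("overlap_fraction undefined for an empty query set")
  nrow(intersect_intervals(a, b, min_overlap_bp)) / nrow(a)
}

#' n-way membership partition of a region union
#'
#' Builds the nonredundant union (merge of all sets) and assigns each union
#' region the membership signature of the input sets overlapping it by at
#' least 1 bp. Partition classes are disjoint, their region counts sum to the
#' union's region count, and the all-zero class is empty. This is the region
#' partition behind a proportional multi-set (Chow-Ruskey style) overlap
#' diagram.
#'
#' @param sets list of 2-6 `interval_set`s; names (or set labels) name the
#'   signature positions.
#' @return list with elements `labels` (set names, in order), `union`
#'   (the merged `interval_set`), `signature` (character vector of 0/1
#'   signatures per union region), `classes` (named list signature ->
#'   `interval_set`), `counts` and `bp` (named numeric vectors per signature).
#' @export
multiway_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 6)
    stop("multiway_partition requires between 2 and 6 interval sets")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(seq_along(sets), function(i) {
      lab <- set_label(sets[[i]])
      if (nzchar(lab)) lab else paste0("set", i)
    }, "")
  all_df <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)[c("chrom", "start", "end")]))
  if (nrow(all_df) == 0) {
    return(list(labels = labels, union = .empty_set("union"), signature = character(),
                classes = list(), counts = numeric(), bp = numeric()))
  }
  un <- merge_intervals(interval_set(all_df, label = "union", normalize = FALSE))
  ugr <- .as_gr(un)
  bits <- vapply(sets, function(s) {
    if (nrow(s) == 0) rep(FALSE, length(ugr))
    else .count_ov(ugr, .as_gr(s)) > 0
  }, logical(length(ugr)))
  bits <- matrix(bits, nrow = length(ugr))
  sig <- apply(bits, 1, function(b) paste(as.integer(b), collapse = ""))
  stopifnot(!any(sig == strrep("0", length(sets))))
  classes <- lapply(split(seq_along(sig), sig), function(i) {
    out <- un[i, , drop = FALSE]
    rownames(out) <- NULL
    attributes(out)$label <- "union"
    class(out) <- c("interval_set", "data.frame")
    out
  })
  counts <- vapply(classes, nrow, 0L)
  bp <- vapply(classes, total_bp, 0)
  list(labels = labels, union = un, signature = sig, classes = classes,
       counts = counts, bp = bp)
}

#' Regions of a query absent from a universe
#'
#' Returns the regions of `query` with zero basepairs of overlap with
#' `universe` (e.g. peaks never encountered in a DHS universe catalog).
#'
#' @param query,universe `interval_set`s.
#' @return subset of `query`.
#' @export
subtract_universe <- function(query, universe) {
  if (nrow(universe) == 0 || nrow(query) == 0) return(query)
  hits <- .count_ov(.as_gr(query), .as_gr(universe)) > 0
  out <- query[!hits, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$label <- set_label(query)
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene`, `chrom`, `tss`, `strand`; `tss`
#' is a 0-based basepair. One TSS record per gene symbol.
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene))
    stop("duplicate gene symbol(s) in annotation: ",
         paste(unique(df$gene[duplicated(df$gene)])[1:3], collapse = ", "))
  df[need]
}

#' Write a gene annotation table
#' @param genes data.frame with `gene`, `chrom`, `tss`, `strand`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split regions into TSS-proximal and distal
#'
#' A region is proximal iff its span overlaps `[tss - cutoff, tss + cutoff)`
#' of any gene; the split is exhaustive and disjoint. The default cutoff of
#' 2 kb either side of the TSS follows common promoter-window practice.
#'
#' @param x an `interval_set`.
#' @param genes gene annotation data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @param cutoff window half-width in bp (`> 0`).
#' @return list with `proximal` and `distal` `interval_set`s.
#' @export
split_proximal_distal <- function(x, genes, cutoff = 2000) {
  stopifnot(cutoff > 0)
  if (nrow(x) == 0) return(list(proximal = x, distal = x))
  if (is.null(genes) || nrow(genes) == 0) {
    warning("empty gene list: all regions classified distal")
    return(list(proximal = .empty_set(set_label(x)), distal = x))
  }
  win_start <- pmax(0, genes$tss - cutoff)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(start = win_start + 1,
                                                 end = genes$tss + cutoff))
  prox <- .count_ov(.as_gr(x), win) > 0
  mk <- function(df) {
    rownames(df) <- NULL
    attributes(df)$label <- set_label(x)
    class(df) <- c("interval_set", "data.frame")
    df
  }
  list(proximal = mk(x[prox, , drop = FALSE]),
       distal = mk(x[!prox, , drop = FALSE]))
}

#' Normalize chromosome-name dialect
#'
#' Converts between `"chr1"` and `"1"` style names, or applies an explicit
#' alias map; names with no alias are left unchanged with a warning listing
#' them.
#' @param x an `interval_set`.
#' @param style target style, `"chr"` or `"plain"`; ignored when `alias`
#'   is given.
#' @param alias optional named character vector `old -> new`.
#' @return an `interval_set` with renamed chromosomes.
#' @export
normalize_chroms <- function(x, style = c("chr", "plain"), alias = NULL) {
  if (!is.null(alias)) {
    unmatched <- setdiff(unique(x$chrom), names(alias))
    if (length(unmatched))
      warning("chromosomes without alias left unchanged: ",
              paste(unmatched, collapse = ", "))
    hit <- x$chrom %in% names(alias)
    x$chrom[hit] <- unname(alias[x$chrom[hit]])
    return(.sort_set(x))
  }
  style <- match.arg(style)
  if (style == "chr") {
    plain <- !grepl("^chr", x$chrom)
    x$chrom[plain] <- paste0("chr", x$chrom[plain])
  } else {
    x$chrom <- sub("^chr", "", x$chrom)
  }
  .sort_set(x)
}
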