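## Position weight matrices and motif scanning.
##
## A PWM is a 4 x W column-stochastic matrix of base probabilities over
## (A, C, G, T) with a background distribution; hits are scored as summed
## per-column log2 odds (bits). Scanning covers both strands: a minus-strand
## hit at a position is the score of the window's reverse complement.

#' Construct a position weight matrix
#'
#' Accepts counts or probabilities. When any column contains a zero, a
#' pseudocount of 0.25 is added to every cell before renormalization so every
#' log-odds entry is finite.
#'
#' @param mat 4 x W numeric matrix, rows (A, C, G, T).
#' @param tf_name transcription-factor name.
#' @param background base background distribution (default uniform 0.25).
#' @return object of class `pwm` with elements `tf_name`, `mat`
#'   (probabilities), `background`, `log_odds` (4 x W, bits), `width`.
#' @export
pwm <- function(mat, tf_name, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) stop("PWM entries must be nonnegative")
  if (any(background <= 0)) stop("background probabilities must be positive")
  background <- background / sum(background)
  if (any(mat == 0)) mat <- mat + 0.25
  mat <- sweep(mat, 2, colSums(mat), "/")
  if (any(abs(colSums(mat) - 1) > 1e-6)) stop("PWM columns failed to normalize")
  rownames(mat) <- .DNA_BASES
  lo <- log2(mat / background)
  structure(list(tf_name = tf_name, mat = mat,
                 background = stats::setNames(as.numeric(background), .DNA_BASES),
                 log_odds = lo, width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, consensus %s, max score %.2f bits\n",
              x$tf_name, x$width, pwm_consensus(x), pwm_max_score(x)))
  invisible(x)
}

#' Maximum achievable log-odds score of a PWM (bits)
#' @param x a `pwm`.
#' @return numeric scalar.
#' @export
pwm_max_score <- function(x) sum(apply(x$log_odds, 2, max))

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) paste(.DNA_BASES[apply(x$mat, 2, which.max)], collapse = "")

## PWM for scoring the reverse strand on the forward sequence:
## reverse columns, complement rows.
.pwm_rc_log_odds <- function(x) x$log_odds[4:1, rev(seq_len(x$width)), drop = FALSE]

#' Read a JASPAR-style PWM panel
#'
#' Text format: a `>NAME` header per motif followed by four rows
#' `A [ 1 2 3 ]` (brackets optional), in A, C, G, T order; counts or
#' probabilities.
#' @param path file path.
#' @param background background distribution passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers ('>NAME') found in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) < 4)
      stop("motif block under header line ", heads[i], " has fewer than 4 rows")
    nm <- sub("^>\\s*", "", lines[heads[i]])
    nm <- strsplit(nm, "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1) stop("ragged PWM rows for motif ", nm)
    out[[nm]] <- pwm(do.call(rbind, rows), tf_name = nm, background = background)
  }
  out
}

#' Write a PWM panel in JASPAR-style text
#' @param pwms named list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_name), con)
    for (i in 1:4)
      writeLines(sprintf("%s [ %s ]", .DNA_BASES[i],
                         paste(format(p$mat[i, ], digits = 6), collapse = " ")), con)
  }
  invisible(path)
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of width W on both strands as summed per-column log2
#' odds; windows containing N (or any non-ACGT base) are skipped. Reported
#' coordinates are genomic: the window's position within the sequence plus
#' `offset`.
#'
#' @param sequence DNA string.
#' @param x a `pwm`.
#' @param min_score_bits score threshold; default 0.8 times the PWM's maximum
#'   achievable score.
#' @param chrom chromosome name attached to hits.
#' @param offset 0-based genomic position of the first base of `sequence`.
#' @return data.frame with columns `chrom`, `start`, `end`, `tf_name`,
#'   `strand`, `score` (one row per hit, both strands).
#' @export
scan_pwm <- function(sequence, x, min_score_bits = NULL, chrom = "seq", offset = 0) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(min_score_bits)) min_score_bits <- 0.8 * pwm_max_score(x)
  W <- x$width
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      tf_name = character(), strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  s <- .encode_dna(sequence)
  L <- length(s)
  if (L < W) return(empty)
  n_win <- L - W + 1
  fwd <- numeric(n_win)
  rev <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  lo <- x$log_odds
  lo_rc <- .pwm_rc_log_odds(x)
  for (i in seq_len(W)) {
    b <- s[i:(i + n_win - 1)]
    bad <- is.na(b)
    bi <- ifelse(bad, 1L, b)
    fwd <- fwd + lo[cbind(bi, i)]
    rev <- rev + lo_rc[cbind(bi, i)]
    valid <- valid & !bad
  }
  pos_f <- which(valid & fwd >= min_score_bits)
  pos_r <- which(valid & rev >= min_score_bits)
  if (!length(pos_f) && !length(pos_r)) return(empty)
  out <- data.frame(
    chrom = chrom,
    start = offset + c(pos_f, pos_r) - 1,
    end = offset + c(pos_f, pos_r) - 1 + W,
    tf_name = x$tf_name,
    strand = c(rep("+", length(pos_f)), rep("-", length(pos_r))),
    score = c(fwd[pos_f], rev[pos_r]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

## scan every region of a set, concatenating hits (genomic coordinates)
.scan_regions <- function(regions, x, genome, min_score_bits = NULL) {
  hits <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    L <- nchar(genome[[r$chrom]])
    if (is.null(L) || r$start >= L) return(NULL)
    seq <- get_sequence(genome, r$chrom, r$start, min(r$end, L))
    scan_pwm(seq, x, min_score_bits, chrom = r$chrom, offset = r$start)
  })
  do.call(rbind, hits)
}

#' Motif fold-enrichment of a target region set over a background
#'
#' For every PWM, computes the fraction of target and background regions
#' containing at least one hit at the given threshold; fold-enrichment is the
#' ratio target fraction / background fraction, and the p-value is a
#' one-sided hypergeometric test on the region counts. Results are sorted by
#' fold descending (the ranking displayed in motif-enrichment panels).
#'
#' @param target,background `interval_set`s (target nonempty).
#' @param pwms named list of `pwm` objects.
#' @param genome named character vector of chromosome sequences.
#' @param min_score_bits threshold passed to [scan_pwm()] (per-PWM default
#'   0.8 of maximum score).
#' @return data.frame with columns `tf_name`, `target_hits`, `target_n`,
#'   `background_hits`, `background_n`, `target_frac`, `background_frac`,
#'   `fold`, `p_value`, `infinite_fold` (flag set when the background
#'   fraction is zero while the target fraction is positive).
#' @export
motif_enrichment <- function(target, background, pwms, genome, min_score_bits = NULL) {
  if (nrow(target) == 0) stop("target region set is empty")
  if (nrow(background) == 0) stop("background region set is empty")
  frac_with_hit <- function(regions, p) {
    has <- vapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      L <- nchar(genome[[r$chrom]])
      if (is.null(L) || r$start >= L) return(FALSE)
      seq <- get_sequence(genome, r$chrom, r$start, min(r$end, L))
      nrow(scan_pwm(seq, p, min_score_bits, chrom = r$chrom, offset = r$start)) > 0
    }, TRUE)
    sum(has)
  }
  rows <- lapply(pwms, function(p) {
    th <- frac_with_hit(target, p)
    bh <- frac_with_hit(background, p)
    tf_frac <- th / nrow(target)
    bg_frac <- bh / nrow(background)
    inf_fold <- bg_frac == 0 && tf_frac > 0
    fold <- if (inf_fold) Inf else if (bg_frac == 0) 0 else tf_frac / bg_frac
    ## one-sided hypergeometric: target draws from the pooled regions
    pv <- if (th == 0) 1 else stats::phyper(th - 1, th + bh,
                                            (nrow(target) - th) + (nrow(background) - bh),
                                            nrow(target), lower.tail = FALSE)
    data.frame(tf_name = p$tf_name, target_hits = th, target_n = nrow(target),
               background_hits = bh, background_n = nrow(background),
               target_frac = tf_frac, background_frac = bg_frac,
               fold = fold, p_value = pv, infinite_fold = inf_fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fold, out$p_value, out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find tandem GGAA microsatellite runs
#'
#' Reports maximal non-overlapping runs of tandem GGAA units and, separately,
#' of the reverse-complement TTCC units, with at least `min_units` units.
#' Interrupted runs do not count.
#'
#' @param sequence DNA string.
#' @param min_units minimum tandem unit count (`>= 2`).
#' @param chrom chromosome name attached to runs.
#' @param offset 0-based genomic position of the first base of `sequence`.
#' @return data.frame with columns `chrom`, `start`, `end`, `motif`
#'   (`GGAA` or `TTCC`), `n_units`.
#' @export
find_ggaa_repeats <- function(sequence, min_units = 2, chrom = "seq", offset = 0) {
  stopifnot(min_units >= 2)
  sequence <- toupper(sequence)
  one_motif <- function(unit) {
    m <- gregexpr(paste0("(?:", unit, ")+"), sequence)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    units <- len %/% 4
    keep <- units >= min_units
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom,
               start = offset + as.integer(m[keep]) - 1,
               end = offset + as.integer(m[keep]) - 1 + units[keep] * 4L,
               motif = unit, n_units = units[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(one_motif("GGAA"), one_motif("TTCC"))
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      motif = character(), n_units = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
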