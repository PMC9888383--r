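# Independent brute-force oracles. Everything here works on per-bp boolean
# arrays, exhaustive window scoring, or direct enumeration, and never calls
# the interval/scanning code paths it checks.

# per-bp occupancy vector for one chromosome (length L, 0-based positions)
bp_mask <- function(df, chrom, L) {
  m <- logical(L)
  sub <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) m[(sub$start[i] + 1):sub$end[i]] <- TRUE
  m
}

# merged intervals of a boolean mask as a data.frame (0-based half-open)
mask_to_intervals <- function(m, chrom) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
}

# brute-force merge with max_gap over a single chromosome: fill gaps
# <= max_gap on the bp mask until a fixed point is reached
oracle_merge <- function(df, chrom, L, max_gap = 0) {
  m <- bp_mask(df, chrom, L)
  repeat {
    iv <- mask_to_intervals(m, chrom)
    if (nrow(iv) <= 1) break
    gaps <- iv$start[-1] - iv$end[-nrow(iv)]
    fill <- which(gaps > 0 & gaps <= max_gap)
    if (!length(fill)) break
    for (i in fill) m[(iv$end[i] + 1):iv$start[i + 1]] <- TRUE
  }
  mask_to_intervals(m, chrom)
}

# all-pairs element-level intersection count: rows of a overlapping b
oracle_intersect_idx <- function(a, b, min_overlap = 1) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) { keep[i] <- TRUE; break }
    }
  }
  which(keep)
}

# exhaustive per-window PWM scoring on both strands (returns all windows
# with score >= threshold); completely independent of scan_pwm internals
oracle_scan <- function(seq, mat, background, min_score) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  W <- ncol(mat)
  L <- nchar(seq)
  res <- list()
  if (L < W) return(data.frame(start = integer(), strand = character(), score = numeric()))
  for (j in 1:(L - W + 1)) {
    win <- strsplit(substr(seq, j, j + W - 1), "")[[1]]
    if (any(!win %in% bases)) next
    sc_f <- sum(vapply(seq_len(W), function(i)
      log2(mat[match(win[i], bases), i] / background[match(win[i], bases)]), 0))
    rcwin <- rev(unname(comp[win]))
    sc_r <- sum(vapply(seq_len(W), function(i)
      log2(mat[match(rcwin[i], bases), i] / background[match(rcwin[i], bases)]), 0))
    if (sc_f >= min_score)
      res[[length(res) + 1]] <- data.frame(start = j - 1, strand = "+", score = sc_f)
    if (sc_r >= min_score)
      res[[length(res) + 1]] <- data.frame(start = j - 1, strand = "-", score = sc_r)
  }
  if (!length(res)) return(data.frame(start = integer(), strand = character(), score = numeric()))
  do.call(rbind, res)
}

# two-sided Fisher exact p by direct enumeration with log-choose arithmetic
# (no dhyper), same tie rule as the classical test
oracle_fisher <- function(h1, n1, h2, n2) {
  k <- h1 + h2
  N <- n1 + n2
  xs <- max(0, k - n2):min(k, n1)
  logp <- lchoose(n1, xs) + lchoose(n2, k - xs) - lchoose(N, k)
  p <- exp(logp)
  p_obs <- p[xs == h1]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# brute-force tandem-unit run enumeration
oracle_runs <- function(seq, unit, min_units) {
  L <- nchar(seq)
  W <- nchar(unit)
  res <- list()
  j <- 1
  while (j <= L - W + 1) {
    n_units <- 0
    while (substr(seq, j + n_units * W, j + (n_units + 1) * W - 1) == unit) n_units <- n_units + 1
    if (n_units >= min_units)
      res[[length(res) + 1]] <- data.frame(start = j - 1, end = j - 1 + n_units * W,
                                           n_units = n_units)
    j <- j + max(1, n_units * W)
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer(), n_units = integer()))
  do.call(rbind, res)
}

# random interval data.frame on one chromosome
random_intervals <- function(n, L, max_w = 500) {
  start <- sample.int(L - max_w, n, replace = TRUE) - 1
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start, end = pmin(start + w, L))
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
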