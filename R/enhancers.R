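## Enhancer prioritization cascade: distal accessible regions intersected
## with active-mark (H3K27ac) catalogs, assignment against a validated
## (VISTA-like) enhancer database, hit-rate statistics, and target-gene
## nomination with window, contact and expression filters.

#' Round a percentage half away from zero
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percentage of hits among tested, rounded to the nearest integer
#' @param hits,tested nonnegative counts, `hits <= tested`, `tested >= 1`.
#' @return numeric percentage (0-100), rounded half away from zero.
#' @export
percent_of <- function(hits, tested) {
  stopifnot(tested >= 1, hits <= tested, hits >= 0)
  round_half_up(100 * hits / tested)
}

#' Select candidate enhancers for a component
#'
#' Distal accessible regions (per [split_proximal_distal()]) that overlap the
#' union of the supplied active-mark catalogs by at least 1 bp. "Across
#' development" is modeled as the union of the catalogs.
#'
#' @param component_peaks `interval_set` of the component's accessible
#'   regions.
#' @param genes gene annotation data.frame.
#' @param cutoff_bp proximal/distal TSS cutoff (bp).
#' @param h3k27ac_catalogs list of `interval_set`s (active-mark peak
#'   catalogs), pooled by union.
#' @return list with `candidates` (`interval_set` of retained distal
#'   regions), `n_distal`, `n_candidates`, and `percent_overlap` (percentage
#'   of distal regions retained, nearest integer).
#' @export
select_candidate_enhancers <- function(component_peaks, genes, cutoff_bp = 2000,
                                       h3k27ac_catalogs = list()) {
  if (!length(h3k27ac_catalogs)) stop("at least one active-mark catalog required")
  pd <- split_proximal_distal(component_peaks, genes, cutoff = cutoff_bp)
  distal <- pd$distal
  cat_df <- do.call(rbind, lapply(h3k27ac_catalogs,
                                  function(s) as.data.frame(s)[c("chrom", "start", "end")]))
  catalog <- merge_intervals(interval_set(cat_df, label = "H3K27ac", normalize = FALSE))
  cands <- if (nrow(distal) == 0) distal else intersect_intervals(distal, catalog)
  list(candidates = cands,
       n_distal = nrow(distal),
       n_candidates = nrow(cands),
       percent_overlap = if (nrow(distal) == 0) NA_real_
                         else percent_of(nrow(cands), nrow(distal)))
}

#' Assign validated enhancers to components
#'
#' Four-way analysis of a validated-enhancer catalog against per-component
#' candidate enhancer sets (including CM): each catalog element overlapping
#' at least one candidate set is assigned the subset of overlapping
#' components. An element is CCS-enriched when it overlaps at least one CCS
#' component and not CM.
#'
#' @param candidate_sets named list of `interval_set`s; must include `"CM"`.
#' @param vista `interval_set` whose `name` column carries element
#'   identifiers.
#' @return data.frame with columns `vista_id`, `chrom`, `start`, `end`,
#'   `components` (comma-separated), one logical column per candidate set,
#'   and `ccs_enriched`.
#' @export
assign_vista <- function(candidate_sets, vista) {
  if (!"CM" %in% names(candidate_sets))
    stop("candidate_sets must include a 'CM' entry")
  if (nrow(vista) == 0 || any(is.na(vista$name)))
    stop("validated-enhancer catalog must carry element identifiers in the name column")
  vgr <- .as_gr(vista)
  bits <- vapply(candidate_sets, function(s) {
    if (nrow(s) == 0) rep(FALSE, length(vgr))
    else .count_ov(vgr, .as_gr(s)) > 0
  }, logical(length(vgr)))
  bits <- matrix(bits, nrow = length(vgr), dimnames = list(NULL, names(candidate_sets)))
  any_hit <- rowSums(bits) > 0
  comp_names <- apply(bits, 1, function(b) paste(colnames(bits)[b], collapse = ","))
  ccs_cols <- setdiff(colnames(bits), "CM")
  out <- data.frame(vista_id = vista$name, chrom = vista$chrom,
                    start = vista$start, end = vista$end,
                    components = comp_names, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(bits))
  out$ccs_enriched <- rowSums(bits[, ccs_cols, drop = FALSE]) > 0 & !bits[, "CM"]
  out[any_hit, , drop = FALSE]
}

## two-sided Fisher exact p for a 2x2 table by hypergeometric point-mass
## summation: sum of all tables (fixed margins) whose probability does not
## exceed the observed table's, with the standard relative tie tolerance.
.fisher2x2 <- function(h1, n1, h2, n2) {
  k <- h1 + h2
  lo <- max(0, k - n2)
  hi <- min(k, n1)
  x <- lo:hi
  d <- stats::dhyper(x, n1, n2, k)
  d_obs <- stats::dhyper(h1, n1, n2, k)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Compare an observed enhancer hit rate with a control
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[hits, tested - hits], [control_hits, control_tested - control_hits]]`,
#' with the p-value computed by hypergeometric point-mass summation.
#' Percentages are rounded to the nearest integer (half away from zero).
#'
#' @param observed_hits,observed_tested observed counts (`hits <= tested`).
#' @param control_hits,control_tested control counts.
#' @return object of class `hit_rate`: list with `observed`, `control`
#'   (each `c(hits, tested)`), `observed_pct`, `control_pct`, `fisher_p`.
#' @export
hit_rate_comparison <- function(observed_hits, observed_tested,
                                control_hits, control_tested) {
  stopifnot(observed_hits <= observed_tested, control_hits <= control_tested,
            observed_tested >= 1, control_tested >= 1,
            observed_hits >= 0, control_hits >= 0)
  structure(list(
    observed = c(hits = observed_hits, tested = observed_tested),
    control = c(hits = control_hits, tested = control_tested),
    observed_pct = percent_of(observed_hits, observed_tested),
    control_pct = percent_of(control_hits, control_tested),
    fisher_p = .fisher2x2(observed_hits, observed_tested, control_hits, control_tested)),
    class = "hit_rate")
}

#' @export
print.hit_rate <- function(x, ...) {
  cat(sprintf("hit rate: %d of %d (%d%%) vs control %d of %d (%d%%); Fisher exact p = %.3g\n",
              x$observed["hits"], x$observed["tested"], x$observed_pct,
              x$control["hits"], x$control["tested"], x$control_pct, x$fisher_p))
  invisible(x)
}

#' Read a per-component expression-enrichment table
#'
#' TSV with a `gene` column and one numeric column per component holding the
#' component-vs-CM expression ratio.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("expression table must have a 'gene' column")
  df
}

#' Read a promoter-anchored contact table
#'
#' TSV with columns `bait_chrom`, `bait_start`, `bait_end`, `gene`,
#' `other_chrom`, `other_start`, `other_end` (coordinates 0-based half-open).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("bait_chrom", "bait_start", "bait_end", "gene",
            "other_chrom", "other_start", "other_end")
  if (!all(need %in% names(df)))
    stop("contact table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Nominate target genes for an enhancer
#'
#' Genes whose TSS lies within `window_bp` either side of the enhancer and
#' whose expression enrichment (component vs CM) meets the threshold; a
#' nomination is contact-supported when a contact pair links the gene's
#' promoter to an interval overlapping the enhancer. Sorted by
#' (`contact_supported`, `expression_enrichment`) descending.
#'
#' @param enhancer one-row `interval_set` or list/row with `chrom`, `start`,
#'   `end`.
#' @param genes gene annotation data.frame.
#' @param window_bp window half-width (default 500 kb; a 1 Mb window is the
#'   documented alternative).
#' @param expression expression-enrichment data.frame from
#'   [read_expression_table()].
#' @param contacts contact data.frame from [read_contacts()] (or `NULL`).
#' @param component name of the expression column to use.
#' @param enrichment_threshold minimum enrichment ratio (default 1.5).
#' @return data.frame with columns `gene`, `distance_bp`,
#'   `expression_enrichment`, `contact_supported`, `rank`.
#' @export
nominate_targets <- function(enhancer, genes, window_bp = 500000, expression,
                             contacts = NULL, component,
                             enrichment_threshold = 1.5) {
  stopifnot(window_bp > 0)
  ch <- enhancer$chrom[1]
  es <- enhancer$start[1]
  ee <- enhancer$end[1]
  ## distance from TSS to the enhancer span (0 when the TSS falls inside it)
  dist_bp <- ifelse(genes$tss < es, es - genes$tss,
                    ifelse(genes$tss >= ee, genes$tss - ee + 1, 0))
  cand <- genes[genes$chrom == ch & dist_bp <= window_bp, , drop = FALSE]
  cand_dist <- dist_bp[genes$chrom == ch & dist_bp <= window_bp]
  empty <- data.frame(gene = character(), distance_bp = numeric(),
                      expression_enrichment = numeric(),
                      contact_supported = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  if (!component %in% names(expression))
    stop("expression table has no column for component: ", component)
  enr <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    j <- match(cand$gene[i], expression$gene)
    if (is.na(j)) {
      warning("gene absent from expression table, enrichment set to 0: ", cand$gene[i])
      enr[i] <- 0
    } else enr[i] <- expression[[component]][j]
  }
  supported <- rep(FALSE, nrow(cand))
  if (!is.null(contacts) && nrow(contacts)) {
    ov_enh <- contacts$other_chrom == ch & contacts$other_start < ee &
      contacts$other_end > es
    for (i in seq_len(nrow(cand)))
      supported[i] <- any(ov_enh & contacts$gene == cand$gene[i])
  }
  keep <- enr >= enrichment_threshold
  out <- data.frame(gene = cand$gene[keep],
                    distance_bp = cand_dist[keep],
                    expression_enrichment = enr[keep],
                    contact_supported = supported[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(empty)
  o <- order(-out$contact_supported, -out$expression_enrichment, out$gene)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
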