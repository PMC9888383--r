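## Motif-based TF -> gene network construction and connectivity ranking.
##
## Edges come from PWM hits inside component-accessible regions proximal to a
## gene's TSS; the interaction score aggregates hit bit-scores per
## (TF, gene). Connectivity is the number of distinct target genes per TF,
## and components are ranked against the working-cardiomyocyte network by the
## connectivity difference.

#' Build a motif-based TF-gene regulatory network
#'
#' For each gene, collects the component-accessible regions whose span
#' overlaps `[tss - cutoff_bp, tss + cutoff_bp)`, scans them with each PWM on
#' both strands, and aggregates hit scores into one edge per (TF, gene). An
#' edge is emitted when its aggregate exceeds zero.
#'
#' @param component_peaks `interval_set` of accessible regions for the
#'   component.
#' @param genes gene annotation data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @param pwms named list of `pwm` objects.
#' @param genome named character vector of chromosome sequences.
#' @param cutoff_bp TSS window half-width (bp, `> 0`).
#' @param min_score_bits hit threshold passed to [scan_pwm()].
#' @param component component label stored on the edges.
#' @param metric `"score"` (default; sum of hit bit-scores) or `"count"`
#'   (number of hits) as the interaction score.
#' @return data.frame of edges with columns `tf_name`, `target_gene`,
#'   `component`, `interaction_score`, `n_hits`.
#' @export
build_grn <- function(component_peaks, genes, pwms, genome, cutoff_bp = 2000,
                      min_score_bits = NULL, component = "",
                      metric = c("score", "count")) {
  stopifnot(cutoff_bp > 0)
  metric <- match.arg(metric)
  empty <- data.frame(tf_name = character(), target_gene = character(),
                      component = character(), interaction_score = numeric(),
                      n_hits = integer(), stringsAsFactors = FALSE)
  if (nrow(component_peaks) == 0 || nrow(genes) == 0 || length(pwms) == 0) {
    warning("no accessible proximal regions, genes or PWMs: empty network")
    return(empty)
  }
  pk <- .as_gr(component_peaks)
  win_start <- pmax(0, genes$tss - cutoff_bp)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(win_start + 1, genes$tss + cutoff_bp))
  ov <- GenomicRanges::findOverlaps(win, pk)
  if (length(ov) == 0) {
    warning("no accessible region proximal to any gene: empty network")
    return(empty)
  }
  rows <- list()
  by_gene <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  for (gi_chr in names(by_gene)) {
    gi <- as.integer(gi_chr)
    regions <- component_peaks[unique(by_gene[[gi_chr]]), , drop = FALSE]
    for (p in pwms) {
      hits <- .scan_regions(regions, p, genome, min_score_bits)
      if (is.null(hits) || nrow(hits) == 0) next
      score <- if (metric == "score") sum(hits$score) else nrow(hits)
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = p$tf_name, target_gene = genes$gene[gi], component = component,
        interaction_score = score, n_hits = nrow(hits), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no motif hits in any proximal accessible region: empty network")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tf_name, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank TFs by connectivity gain over the CM network
#'
#' Connectivity is the number of distinct target genes per TF. TFs are sorted
#' by `delta = connectivity_component - connectivity_cm` descending, ties
#' broken by component connectivity descending then TF name.
#'
#' @param component_edges,cm_edges edge data.frames from [build_grn()] built
#'   with the same PWM panel and parameters.
#' @return data.frame with columns `tf_name`, `connectivity_component`,
#'   `connectivity_cm`, `delta`, `rank`.
#' @export
rank_tfs <- function(component_edges, cm_edges) {
  conn <- function(edges) {
    if (nrow(edges) == 0) return(stats::setNames(integer(), character()))
    tapply(edges$target_gene, edges$tf_name, function(g) length(unique(g)))
  }
  cc <- conn(component_edges)
  cm <- conn(cm_edges)
  tfs <- sort(union(names(cc), names(cm)))
  cc_n <- ifelse(tfs %in% names(cc), cc[tfs], 0L)
  cm_n <- ifelse(tfs %in% names(cm), cm[tfs], 0L)
  out <- data.frame(tf_name = tfs,
                    connectivity_component = as.integer(cc_n),
                    connectivity_cm = as.integer(cm_n),
                    stringsAsFactors = FALSE)
  out$delta <- out$connectivity_component - out$connectivity_cm
  o <- order(-out$delta, -out$connectivity_component, out$tf_name)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Extract the strongest edges of one TF
#'
#' @param edges edge data.frame from [build_grn()].
#' @param tf_name TF present in the edge list.
#' @param top_k number of edges retained (by `interaction_score` descending).
#' @return data.frame of at most `top_k` edges.
#' @export
extract_subnetwork <- function(edges, tf_name, top_k = Inf) {
  sel <- edges[edges$tf_name == tf_name, , drop = FALSE]
  if (nrow(sel) == 0) stop("TF not present in edge list: ", tf_name)
  sel <- sel[order(-sel$interaction_score, sel$target_gene), , drop = FALSE]
  out <- utils::head(sel, top_k)
  rownames(out) <- NULL
  out
}

#' Write a network as node/edge TSVs for graph viewers
#'
#' @param edges edge data.frame from [build_grn()].
#' @param edge_path edge TSV path (`source`, `target`, `score`, `component`).
#' @param node_path optional node TSV path (`node`, `type`).
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(edges, edge_path, node_path = NULL) {
  ed <- data.frame(source = edges$tf_name, target = edges$target_gene,
                   score = edges$interaction_score, component = edges$component,
                   stringsAsFactors = FALSE)
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path)) {
    nodes <- data.frame(node = c(unique(edges$tf_name), unique(edges$target_gene)),
                        type = rep(c("TF", "gene"),
                                   c(length(unique(edges$tf_name)),
                                     length(unique(edges$target_gene)))),
                        stringsAsFactors = FALSE)
    utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edge_path)
}
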