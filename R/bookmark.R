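# Occupancy classification across A / M / G1, replicate-reproducibility
# filtering, clustering of union-peak enrichment profiles, the
# differential-expression significance filter, and hypergeometric overlap
# statistics.

overlaps_any <- function(contig, start, end, other) {
  vapply(seq_along(contig), function(i) {
    any(other$contig == contig[i] & other$start < end[i] &
          other$end > start[i])
  }, logical(1))
}

#' Keep pooled peaks supported by every replicate
#'
#' A permissive reproducibility rule: a pooled peak is kept iff it
#' overlaps (by at least 1 bp) a peak called in each individual replicate.
#'
#' @param pooled_peaks Peak data.frame from the pooled tags.
#' @param replicate_peaksets List (length >= 1) of peak data.frames, one
#'   per replicate.
#' @return The supported subset of `pooled_peaks`.
#' @export
reproducible_peaks <- function(pooled_peaks, replicate_peaksets) {
  if (length(replicate_peaksets) == 0) stop("no replicate peak sets given")
  keep <- rep(TRUE, nrow(pooled_peaks))
  for (rp in replicate_peaksets) {
    keep <- keep & overlaps_any(pooled_peaks$contig, pooled_peaks$start,
                                pooled_peaks$end, rp)
  }
  pooled_peaks[keep, , drop = FALSE]
}

#' Union-peak fold-enrichment matrix across conditions
#'
#' For every union peak, the fold enrichment at its summit is read from
#' each condition's FE track; rows are then scaled to unit maximum
#' (all-zero rows are dropped with a warning).
#'
#' @param union_peaks Peak data.frame (merged kept peaks across
#'   conditions; summit defaults to the midpoint when absent).
#' @param fe_tracks Named list (one entry per condition) of per-contig FE
#'   vectors as returned by [call_peaks()].
#' @param normalize Scale each row to unit maximum.
#' @return Numeric matrix, one row per retained union peak (rownames =
#'   peak names), one column per condition.
#' @export
occupancy_matrix <- function(union_peaks, fe_tracks, normalize = TRUE) {
  conds <- names(fe_tracks)
  if (is.null(conds) || any(!nzchar(conds))) {
    stop("fe_tracks must be a named list of condition tracks")
  }
  ref <- peak_refpoint(union_peaks)
  m <- vapply(conds, function(cd) {
    tr <- fe_tracks[[cd]]
    vapply(seq_len(nrow(union_peaks)), function(i) {
      v <- tr[[union_peaks$contig[i]]]
      if (is.null(v)) stop("FE track for condition ", cd,
                           " lacks contig ", union_peaks$contig[i])
      v[ref[i] + 1L]
    }, numeric(1))
  }, numeric(nrow(union_peaks)))
  m <- matrix(m, nrow = nrow(union_peaks), dimnames = list(
    if ("name" %in% names(union_peaks)) union_peaks$name else NULL, conds))
  if (normalize) {
    mx <- apply(m, 1, max)
    drop <- mx == 0
    if (any(drop)) {
      warning(sum(drop), " all-zero enrichment row(s) dropped")
      m <- m[!drop, , drop = FALSE]
      mx <- mx[!drop]
    }
    m <- m / mx
  }
  m
}

# k-means++ seeding: first center uniform, then each next center drawn
# with probability proportional to squared distance to the nearest chosen
# center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  d2 <- rowSums((x - centers[rep(1, n), , drop = FALSE])^2)
  while (nrow(centers) < k) {
    p <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
    i <- sample.int(n, 1, prob = p)
    centers <- rbind(centers, x[i, , drop = FALSE])
    nd <- rowSums((x - x[rep(i, n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' Cluster enrichment profiles with k-means
#'
#' Lloyd k-means with k-means++ seeding, best of `n_init` restarts by
#' total within-cluster sum of squares, deterministic under `seed`.
#' Cluster labels are relabelled 1..k by descending cluster size.
#'
#' @param m Numeric matrix (rows = profiles).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_init Number of independent restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Upper bound on accepted center movement at convergence; the
#'   Lloyd iterations run to an exact assignment fixpoint (or `max_iter`),
#'   which always satisfies it.
#' @return Integer vector of cluster labels (named by rownames of `m`),
#'   with the within-cluster sum of squares as attribute `tot_withinss`.
#' @export
cluster_profiles <- function(m, k = 4, seed = 1, n_init = 10,
                             max_iter = 300, tol = 1e-6) {
  if (nrow(m) < k) stop("need at least k = ", k, " rows, got ", nrow(m))
  set.seed(derive_seed(seed, "kmeans"))
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(m, k)
    fit <- suppressWarnings(
      kmeans(m, centers = centers, iter.max = max_iter,
             algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- order(order(-sizes))     # old label -> new label by size
  labels <- relabel[best$cluster]
  names(labels) <- rownames(m)
  attr(labels, "tot_withinss") <- best$tot.withinss
  labels
}

#' Classify genes by occupancy across A, M and G1
#'
#' Pure set algebra on the per-condition bound-gene sets:
#' shared (bookmarked through G1) = M intersect G1; M-only = M minus G1;
#' G1-only = G1 minus M; A-not-MG1 = A minus (M union G1). The categories
#' partition the union of all bound genes.
#'
#' @param a_genes,m_genes,g1_genes Character vectors of bound gene ids in
#'   the asynchronous, mitotic and early-G1 populations.
#' @return A list with `report` (data.frame: `gene_id`, `category`) and
#'   `counts` (named list: `A`, `M`, `G1`, `shared_M_G1`, `M_only`,
#'   `G1_only`, `A_not_MG1`, `union_M_G1`).
#' @export
classify_genes <- function(a_genes, m_genes, g1_genes) {
  a <- unique(a_genes); m <- unique(m_genes); g1 <- unique(g1_genes)
  shared <- intersect(m, g1)
  m_only <- setdiff(m, g1)
  g1_only <- setdiff(g1, m)
  a_not <- setdiff(a, union(m, g1))
  all_bound <- sort(unique(c(a, m, g1)))
  category <- rep("other-combination", length(all_bound))
  category[all_bound %in% shared] <- "shared_M_G1"
  category[all_bound %in% m_only] <- "M_only"
  category[all_bound %in% g1_only] <- "G1_only"
  category[all_bound %in% a_not] <- "A_not_MG1"
  counts <- list(A = length(a), M = length(m), G1 = length(g1),
                 shared_M_G1 = length(shared), M_only = length(m_only),
                 G1_only = length(g1_only), A_not_MG1 = length(a_not),
                 union_M_G1 = length(m) + length(g1) - length(shared))
  list(report = data.frame(gene_id = all_bound, category = category),
       counts = counts)
}

#' Differential-expression significance filter parameters
#'
#' All three thresholds are strict inequalities.
#'
#' @param min_base_mean Keep rows with `base_mean` strictly greater.
#' @param min_abs_lfc Keep rows with `|log2fc|` strictly greater.
#' @param max_pvalue Keep rows with `pvalue` strictly smaller.
#' @return A list of class `de_filter_params`.
#' @export
de_filter_params <- function(min_base_mean = 5, min_abs_lfc = 1,
                             max_pvalue = 0.05) {
  stopifnot(is.finite(min_base_mean), is.finite(min_abs_lfc),
            is.finite(max_pvalue))
  structure(list(min_base_mean = min_base_mean, min_abs_lfc = min_abs_lfc,
                 max_pvalue = max_pvalue), class = "de_filter_params")
}

#' Apply the differential-expression significance filter
#'
#' Keeps records with `base_mean > 5`, `|log2fc| > 1` and `pvalue < 0.05`
#' (defaults; all strict).
#'
#' @param records data.frame with `gene_id`, `base_mean`, `log2fc`,
#'   `pvalue`.
#' @param params A [de_filter_params()] object.
#' @return Character vector of significant gene ids.
#' @export
filter_de <- function(records, params = de_filter_params()) {
  need <- c("gene_id", "base_mean", "log2fc", "pvalue")
  if (!all(need %in% names(records))) {
    stop("DE table lacks column(s): ",
         paste(setdiff(need, names(records)), collapse = ", "))
  }
  keep <- records$base_mean > params$min_base_mean &
    abs(records$log2fc) > params$min_abs_lfc &
    records$pvalue < params$max_pvalue
  records$gene_id[keep]
}

#' Hypergeometric overlap of gene-set categories with a DE set
#'
#' For each category set the upper-tail hypergeometric probability of the
#' observed overlap with `de_set` is computed (drawing `|category|` genes
#' from a universe with `|de_set|` successes), with Benjamini-Hochberg
#' adjustment across the categories tested.
#'
#' @param category_sets Named list of character vectors (subsets of
#'   `universe`).
#' @param de_set Character vector of significant genes (subset of
#'   `universe`).
#' @param universe Character vector of all genes considered.
#' @return data.frame with `category`, `size`, `overlap`, `pvalue`,
#'   `padj`.
#' @export
overlap_enrichment <- function(category_sets, de_set, universe) {
  universe <- unique(universe)
  de_set <- unique(de_set)
  if (length(setdiff(de_set, universe)) > 0) {
    stop("de_set is not a subset of the universe")
  }
  rows <- lapply(names(category_sets), function(nm) {
    s <- unique(category_sets[[nm]])
    if (length(setdiff(s, universe)) > 0) {
      stop("category '", nm, "' is not a subset of the universe")
    }
    ov <- length(intersect(s, de_set))
    # P(X >= ov), X ~ Hypergeom(N = |U|, K = |de|, n = |s|)
    p <- phyper(ov - 1, length(de_set), length(universe) - length(de_set),
                length(s), lower.tail = FALSE)
    data.frame(category = nm, size = length(s), overlap = ov, pvalue = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
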