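# TSS annotation of filtered peaks and regional distribution. Peaks are
# assigned, separately for protein-coding (mRNA) and lncRNA genes, to the
# nearest TSS within a distance cutoff (default 5 kb, inclusive); a gene
# is "bound" if it receives at least one peak.

#' Annotation parameters
#'
#' @param max_tss_distance Maximum summit-to-TSS distance in bases
#'   (inclusive) for an assignment.
#' @param promoter_up,promoter_down Promoter span upstream/downstream of
#'   the TSS in bases (strand-oriented).
#' @param all_within Assign a peak to every TSS within the cutoff instead
#'   of only the nearest one per biotype class.
#' @return A list of class `annotate_params`.
#' @export
annotate_params <- function(max_tss_distance = 5000, promoter_up = 2000,
                            promoter_down = 2000, all_within = FALSE) {
  stopifnot(max_tss_distance >= 0, promoter_up >= 0, promoter_down >= 0)
  structure(list(max_tss_distance = max_tss_distance,
                 promoter_up = promoter_up, promoter_down = promoter_down,
                 all_within = all_within),
            class = "annotate_params")
}

peak_refpoint <- function(peaks) {
  if ("summit" %in% names(peaks) && !all(is.na(peaks$summit))) {
    ifelse(is.na(peaks$summit),
           floor((peaks$start + peaks$end) / 2), peaks$summit)
  } else {
    floor((peaks$start + peaks$end) / 2)
  }
}

#' Annotate peaks to mRNA and lncRNA TSSs
#'
#' The reference point is the peak summit (midpoint when absent). For each
#' biotype class (`protein_coding`, `lncRNA`) a peak is assigned to the
#' nearest TSS iff `|summit - TSS| <= max_tss_distance`; equidistant ties
#' go to the lexicographically smaller `gene_id`. With
#' `all_within = TRUE`, every TSS within the cutoff is assigned.
#'
#' @param peaks Peak data.frame (`contig`, `start`, `end`, `name`,
#'   optional `summit`).
#' @param genes Gene-model list (`genes`, `exons`) from [read_gtf()] or
#'   [make_genes()].
#' @param params An [annotate_params()] object.
#' @return data.frame with `peak`, `gene_id`, `biotype`, `distance`, one
#'   row per assignment.
#' @export
annotate_tss <- function(peaks, genes, params = annotate_params()) {
  g <- genes$genes
  if (nrow(peaks) > 0 && length(intersect(peaks$contig, g$contig)) == 0) {
    stop("peaks and gene annotation share no contig")
  }
  ref <- peak_refpoint(peaks)
  rows <- list()
  for (bt in c("protein_coding", "lncRNA")) {
    gb <- g[g$biotype == bt, , drop = FALSE]
    if (nrow(gb) == 0) next
    gb <- gb[order(gb$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(peaks))) {
      cand <- gb[gb$contig == peaks$contig[i], , drop = FALSE]
      if (nrow(cand) == 0) next
      d <- abs(ref[i] - cand$tss)
      within <- which(d <= params$max_tss_distance)
      if (length(within) == 0) next
      take <- if (params$all_within) within else
        within[order(d[within], cand$gene_id[within])][1]
      rows[[length(rows) + 1]] <- data.frame(
        peak = peaks$name[i], gene_id = cand$gene_id[take],
        biotype = bt, distance = d[take])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(peak = character(), gene_id = character(),
                      biotype = character(), distance = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regional distribution of peak summits
#'
#' Each peak is counted once by its summit with precedence
#' promoter > exonic > intronic > intergenic. The promoter is the
#' strand-oriented window `[TSS - promoter_up, TSS + promoter_down]`
#' (both inclusive); exons are the basic-tag exons; intronic means inside
#' a gene body but in no exon.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene-model list.
#' @param params An [annotate_params()] object.
#' @return Named integer vector with counts for `promoter`, `exonic`,
#'   `intronic`, `intergenic`; sums to `nrow(peaks)`.
#' @export
regional_distribution <- function(peaks, genes, params = annotate_params()) {
  g <- genes$genes
  ex <- genes$exons
  body <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    data.frame(contig = e$contig[1], start = min(e$start), end = max(e$end))
  }))
  ref <- peak_refpoint(peaks)
  counts <- c(promoter = 0L, exonic = 0L, intronic = 0L, intergenic = 0L)
  for (i in seq_len(nrow(peaks))) {
    p <- ref[i]; cm <- peaks$contig[i]
    gc <- g[g$contig == cm, , drop = FALSE]
    prom_lo <- ifelse(gc$strand == "+", gc$tss - params$promoter_up,
                      gc$tss - params$promoter_down)
    prom_hi <- ifelse(gc$strand == "+", gc$tss + params$promoter_down,
                      gc$tss + params$promoter_up)
    cat_i <- if (nrow(gc) > 0 && any(p >= prom_lo & p <= prom_hi)) {
      "promoter"
    } else if (any(ex$contig == cm & p >= ex$start & p < ex$end)) {
      "exonic"
    } else if (any(body$contig == cm & p >= body$start & p < body$end)) {
      "intronic"
    } else {
      "intergenic"
    }
    counts[cat_i] <- counts[cat_i] + 1L
  }
  counts
}

#' Bound gene sets per condition, split by biotype
#'
#' @param annotations Named list (`A`, `M`, `G1`) of annotation
#'   data.frames from [annotate_tss()].
#' @return Named list: for each condition a list with `protein_coding` and
#'   `lncRNA` sorted gene-id vectors and `all` (their union).
#' @export
bound_gene_sets <- function(annotations) {
  bad <- setdiff(names(annotations), c("A", "M", "G1"))
  if (length(bad) > 0) stop("unknown condition label: ", bad[1])
  lapply(annotations, function(a) {
    pc <- sort(unique(a$gene_id[a$biotype == "protein_coding"]))
    lnc <- sort(unique(a$gene_id[a$biotype == "lncRNA"]))
    list(protein_coding = pc, lncRNA = lnc, all = sort(union(pc, lnc)))
  })
}
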