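# End-to-end orchestration: per-condition peak calling on pooled tags,
# replicate-reproducibility filtering, per-peak strand cross-correlation
# filtering, TSS annotation, occupancy classification, union-profile
# clustering and DE-overlap statistics, with every stage's artifacts
# written to disk and an aggregate summary.json.

#' Pipeline configuration
#'
#' @param genome_sizes Path to a `contig<TAB>length` file.
#' @param gtf Path to the gene annotation GTF.
#' @param tags Named list (`A`, `M`, `G1`) of character vectors of
#'   replicate tag-TSV paths.
#' @param de Optional path to a DE results TSV (`gene_id`, `base_mean`,
#'   `log2fc`, `pvalue`).
#' @param outdir Output directory.
#' @param peak_params,xcor_params,annotate_params,de_params Stage
#'   parameter objects (defaults used when NULL).
#' @param k Number of k-means clusters for the union enrichment profiles.
#' @param seed Global seed; per-stage streams are derived from it.
#' @param repro_mode `"overlap"` (keep pooled peaks supported by every
#'   replicate) or `"none"`.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_sizes, gtf, tags, de = NULL, outdir,
                            peak_params = NULL, xcor_params = NULL,
                            annotate_params = NULL, de_params = NULL,
                            k = 4, seed = 1, repro_mode = "overlap") {
  cfg <- list(genome_sizes = genome_sizes, gtf = gtf, tags = tags, de = de,
              outdir = outdir,
              peak_params = peak_params %||% peak_call_params(),
              xcor_params = xcor_params %||% .default_xcor_params(),
              annotate_params = annotate_params %||%
                .default_annotate_params(),
              de_params = de_params %||% de_filter_params(),
              k = k, seed = as.integer(seed), repro_mode = repro_mode)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolved at call time so argument names may shadow the constructors
.default_xcor_params <- function() xcor_params()
.default_annotate_params <- function() annotate_params()

validate_pipeline_config <- function(cfg) {
  if (!setequal(names(cfg$tags), c("A", "M", "G1"))) {
    stop("config error: tags must be a named list with conditions A, M, G1")
  }
  if (!cfg$repro_mode %in% c("overlap", "none")) {
    stop("config error: repro_mode must be 'overlap' or 'none'")
  }
  for (p in c(cfg$genome_sizes, cfg$gtf, unlist(cfg$tags), cfg$de)) {
    if (!file.exists(p)) stop("config error: input file not found: ", p)
  }
  stopifnot(cfg$k >= 1, is.integer(cfg$seed))
  invisible(cfg)
}

log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the full bookmarking pipeline
#'
#' Stage order: peak calling (pooled per condition) with FE tracks ->
#' replicate reproducibility -> strand cross-correlation filter -> TSS
#' annotation -> occupancy classification, union-profile k-means and DE
#' overlap. All per-stage artifacts are written under `cfg$outdir`;
#' `summary.json` aggregates the counts and is byte-identical across
#' reruns with the same config and seed.
#'
#' @param cfg A [pipeline_config()] object.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(cfg$outdir, "run.log"), "w")
  on.exit(close(logcon))
  log_line(logcon, "pipeline seed: ", cfg$seed)
  for (blk in c("peak_params", "xcor_params", "annotate_params",
                "de_params")) {
    log_line(logcon, blk, ": ",
             paste(names(cfg[[blk]]), vapply(cfg[[blk]], function(v)
               paste(format(v), collapse = ","), character(1)),
               sep = "=", collapse = "; "))
  }
  log_line(logcon, "k = ", cfg$k, "; repro_mode = ", cfg$repro_mode)
  lengths <- read_genome_sizes(cfg$genome_sizes)
  genes <- run_stage("read_gtf", cfg$gtf, read_gtf(cfg$gtf))
  conds <- c("A", "M", "G1")
  kept <- list(); fe <- list(); ann <- list(); xrep <- list()
  for (cd in conds) {
    paths <- cfg$tags[[cd]]
    reps <- lapply(paths, function(p)
      run_stage("read_tags", p, read_tags(p)))
    pooled <- do.call(rbind, reps)
    called <- run_stage("call_peaks", paths[1],
                        call_peaks(pooled, lengths, cfg$peak_params))
    log_line(logcon, cd, ": ", nrow(called$peaks), " pooled peaks")
    peaks <- called$peaks
    if (cfg$repro_mode == "overlap" && length(reps) >= 2) {
      rep_sets <- lapply(reps, function(t)
        call_peaks(t, lengths, cfg$peak_params)$peaks)
      peaks <- reproducible_peaks(peaks, rep_sets)
      log_line(logcon, cd, ": ", nrow(peaks), " reproducible peaks")
    }
    flt <- run_stage("filter_peaks", paths[1],
                     filter_peaks(peaks, pooled, lengths, cfg$xcor_params))
    log_line(logcon, cd, ": ", nrow(flt$kept), " peaks pass xcor filter")
    kept[[cd]] <- flt$kept
    fe[[cd]] <- called$fe_track
    xrep[[cd]] <- flt$report
    ann[[cd]] <- run_stage("annotate_tss", cfg$gtf,
                           annotate_tss(flt$kept, genes,
                                        cfg$annotate_params))
    write_narrowpeak(called$peaks,
                     file.path(cfg$outdir, sprintf("peaks_%s_pooled.narrowPeak", cd)))
    write_narrowpeak(flt$kept,
                     file.path(cfg$outdir, sprintf("peaks_%s_kept.narrowPeak", cd)))
    write_bedgraph(called$fe_track,
                   file.path(cfg$outdir, sprintf("fe_%s.bedGraph", cd)))
    write.table(flt$report,
                file.path(cfg$outdir, sprintf("xcor_%s.tsv", cd)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ann[[cd]],
                file.path(cfg$outdir, sprintf("annotations_%s.tsv", cd)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sets <- bound_gene_sets(ann)
  cls <- classify_genes(sets$A$all, sets$M$all, sets$G1$all)
  regions <- regional_distribution(
    do.call(rbind, lapply(kept, function(p)
      p[, c("contig", "start", "end", "name", "summit")])),
    genes, cfg$annotate_params)

  union_peaks <- merge_intervals(do.call(rbind, lapply(
    kept, function(p) p[, c("contig", "start", "end")])))
  summary <- list(
    seed = cfg$seed,
    peaks_kept = lapply(kept, nrow),
    bound_genes = lapply(sets, function(s)
      list(protein_coding = length(s$protein_coding),
           lncRNA = length(s$lncRNA), all = length(s$all))),
    category_counts = cls$counts,
    regional_distribution = as.list(regions),
    union_peaks = nrow(union_peaks))
  if (nrow(union_peaks) > 0) {
    union_peaks$name <- sprintf("union_%d", seq_len(nrow(union_peaks)))
    # union peaks have no single summit; profile is read at the midpoint
    mat <- occupancy_matrix(union_peaks, fe)
    if (nrow(mat) >= cfg$k) {
      labels <- cluster_profiles(mat, k = cfg$k,
                                 seed = derive_seed(cfg$seed, "cluster"))
      cl_tab <- data.frame(peak = names(labels), cluster = as.integer(labels))
      write.table(cl_tab, file.path(cfg$outdir, "clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$cluster_sizes <- as.list(tabulate(labels, nbins = cfg$k))
    }
  }
  report <- cls$report
  biotype_of <- setNames(genes$genes$biotype, genes$genes$gene_id)
  report$biotype <- unname(biotype_of[report$gene_id])
  if (!is.null(cfg$de)) {
    de_tab <- read.table(cfg$de, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
    de_genes <- filter_de(de_tab, cfg$de_params)
    report$de_status <- report$gene_id %in% de_genes
    cat_sets <- lapply(split(report$gene_id, report$category),
                       function(s) intersect(s, de_tab$gene_id))
    enr <- overlap_enrichment(cat_sets, intersect(de_genes, de_tab$gene_id),
                              de_tab$gene_id)
    write.table(enr, file.path(cfg$outdir, "de_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$de_significant <- length(de_genes)
    summary$de_overlap <- setNames(as.list(enr$overlap), enr$category)
  }
  write.table(report, file.path(cfg$outdir, "bookmark_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(logcon, "summary written")
  invisible(summary)
}

# Wrap a stage so failures report the stage name and offending input.
run_stage <- function(stage, input, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed on input '", input, "': ",
         conditionMessage(e), call. = FALSE)
  })
}
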