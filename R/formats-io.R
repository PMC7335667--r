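#' @importFrom stats rnorm runif rpois rbinom rexp rlnorm setNames ppois
#'   phyper p.adjust kmeans dist
#' @importFrom utils read.table write.table
NULL

# All internal coordinates are 0-based half-open; conversion to/from 1-based
# (FASTA positions in messages, GTF) happens only at file boundaries.

#' Read a FASTA file into a genome
#'
#' Reads a (possibly soft-masked) FASTA file and returns a named character
#' vector of upper-case sequences, one element per contig, in file order.
#' Only the bases A, C, G, T and N are accepted; soft-masked lower-case
#' bases are upper-cased, hard-masked bases stay `N`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences (a genome).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("FASTA record with empty name in ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1])
  }
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' in record '%s' at base %d",
                 substr(seqs[i], bad[i], bad[i]), nm[i], bad[i]))
  }
  if (any(nchar(seqs) < 1)) {
    stop("zero-length sequence for record '", nm[which(nchar(seqs) < 1)[1]], "'")
  }
  setNames(seqs, nm)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param line_width Bases per sequence line.
#' @return `path`, invisibly. `read_fasta(write_fasta(g, p))` returns `g`.
#' @export
write_fasta <- function(genome, path, line_width = 60) {
  validate_genome(genome)
  stopifnot(line_width >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1, nchar(s))), con)
  }
  invisible(path)
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome contigs must be named")
  }
  if (anyDuplicated(names(genome))) stop("duplicate contig names")
  if (any(nchar(genome) < 1)) stop("zero-length contig")
  invisible(genome)
}

#' Contig lengths of a genome
#'
#' @param genome Named character vector of sequences.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

#' Read stranded tag positions
#'
#' Tags are aligned-read 5'-start positions: tab-separated columns
#' `contig`, `pos` (0-based 5'-most base of the read; for a minus-strand
#' read this is the highest-coordinate base), `strand` (`+` or `-`).
#' Lines starting with `#` are skipped. Output is sorted by (contig, pos).
#'
#' @param path Path to a tag TSV file.
#' @return data.frame with columns `contig`, `pos`, `strand`.
#' @export
read_tags <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("contig", "pos", "strand"),
                   colClasses = c("character", "integer", "character"))
  validate_tags(df)
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_tags <- function(tags) {
  stopifnot(all(c("contig", "pos", "strand") %in% names(tags)))
  if (nrow(tags) == 0) return(invisible(tags))
  if (any(!tags$strand %in% c("+", "-"))) {
    stop("tag strand must be '+' or '-' (got '",
         tags$strand[!tags$strand %in% c("+", "-")][1], "')")
  }
  if (any(tags$pos < 0)) stop("negative tag position: ", min(tags$pos))
  invisible(tags)
}

#' Write stranded tag positions
#'
#' @param tags data.frame with columns `contig`, `pos`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  validate_tags(tags)
  write.table(tags[, c("contig", "pos", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Gencode-dialect GTF into gene models
#'
#' Parses `gene` and `exon` features (1-based inclusive coordinates,
#' converted to the internal 0-based half-open convention), keeping only
#' exons carrying the `basic` tag. The TSS is the 5'-most base of the gene
#' model respecting strand: the start of the first exon on `+`, the last
#' (highest-coordinate, 0-based) base of the last exon on `-`.
#'
#' @param path Path to a GTF file with attributes `gene_id`, `gene_name`,
#'   `gene_type` and (on exons) `tag "basic"`.
#' @return A list with `genes` (data.frame: `gene_id`, `gene_name`,
#'   `biotype`, `contig`, `strand`, `tss`) and `exons` (data.frame:
#'   `gene_id`, `contig`, `start`, `end`), both 0-based half-open.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("gene_id", "gene_type") %in% names(meta))) {
    stop("GTF lacks gene_id/gene_type attributes: ", path)
  }
  is_exon <- meta$type == "exon"
  if ("tag" %in% names(meta)) {
    has_basic <- vapply(meta$tag, function(t) "basic" %in% t, logical(1))
    is_exon <- is_exon & has_basic
  }
  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)
  exons <- data.frame(
    gene_id = as.character(exm$gene_id),
    contig = as.character(GenomicRanges::seqnames(ex)),
    # GTF is 1-based inclusive; internal is 0-based half-open
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  strand_of <- tapply(as.character(GenomicRanges::strand(ex)), exons$gene_id,
                      function(s) s[1])
  info <- unique(data.frame(
    gene_id = as.character(exm$gene_id),
    gene_name = as.character(if ("gene_name" %in% names(exm)) exm$gene_name
                             else exm$gene_id),
    biotype = as.character(exm$gene_type),
    contig = exons$contig,
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(info$gene_id)) stop("gene spans multiple contigs/biotypes")
  info <- info[order(info$gene_id), , drop = FALSE]
  info$strand <- as.character(strand_of[info$gene_id])
  tss_plus <- tapply(exons$start, exons$gene_id, min)
  tss_minus <- tapply(exons$end, exons$gene_id, max) - 1L
  info$tss <- ifelse(info$strand == "+",
                     unname(tss_plus[info$gene_id]),
                     unname(tss_minus[info$gene_id]))
  info$tss <- as.integer(info$tss)
  rownames(info) <- NULL
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  list(genes = info, exons = exons)
}

#' Write gene models as a Gencode-dialect GTF
#'
#' Emits one `gene` and one `exon` row per feature, with attributes
#' `gene_id`, `gene_name`, `gene_type`, and `tag "basic"` on exons.
#' Internal 0-based half-open coordinates become 1-based inclusive.
#'
#' @param models A list with `genes` and `exons` as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  genes <- models$genes
  exons <- models$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##description: synthetic gene annotation", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    attr_base <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                         g$gene_id, g$gene_name, g$biotype)
    span <- c(min(gex$start), max(gex$end))
    writeLines(sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$contig, span[1] + 1L, span[2], g$strand, attr_base),
               con)
    writeLines(sprintf('%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s tag "basic";',
                       gex$contig, gex$start + 1L, gex$end, g$strand, attr_base),
               con)
  }
  invisible(path)
}

validate_intervals <- function(x) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (any(x$end < x$start)) stop("interval with end < start")
  if (any(x$start < 0)) stop("negative interval start")
  invisible(x)
}

#' Write intervals as BED6
#'
#' Internal 0-based half-open intervals map directly onto BED.
#'
#' @param x data.frame with `contig`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  out <- data.frame(
    contig = x$contig, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file.
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("contig", "start", "end", "name", "score",
                                 "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character"))
  validate_intervals(df)
  df
}

#' Write peaks in narrowPeak (BED6+4) format
#'
#' Column 10 is the summit offset from the peak start, or -1 when the
#' summit is absent.
#'
#' @param peaks data.frame with `contig`, `start`, `end`, `name` and
#'   optional `summit` (absolute 0-based position), `min_pvalue`,
#'   `fold_enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks)
  n <- nrow(peaks)
  getcol <- function(col, default) {
    if (col %in% names(peaks)) peaks[[col]] else rep(default, n)
  }
  pv <- getcol("min_pvalue", NA_real_)
  out <- data.frame(
    contig = peaks$contig, start = peaks$start, end = peaks$end,
    name = getcol("name", sprintf("peak_%d", seq_len(max(n, 1))[seq_len(n)])),
    score = round(pmin(1000, -10 * log10(pmax(pv, 1e-300)))),
    strand = ".",
    signalValue = getcol("fold_enrichment", 0),
    pValue = ifelse(is.na(pv), -1, -log10(pmax(pv, 1e-300))),
    qValue = -1,
    peak = ifelse(is.na(getcol("summit", NA_integer_)), -1L,
                  getcol("summit", NA_integer_) - peaks$start)
  )
  out$score[is.na(out$score)] <- 0
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' @param path Path to a narrowPeak (BED6+4) file.
#' @return data.frame with `contig`, `start`, `end`, `name`,
#'   `fold_enrichment`, `min_pvalue` and absolute `summit` (NA when the
#'   summit column is -1).
#' @export
read_narrowpeak <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("contig", "start", "end", "name", "score",
                                 "strand", "signalValue", "pValue", "qValue",
                                 "peak"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character",
                                  "numeric", "numeric", "numeric", "integer"))
  validate_intervals(df)
  data.frame(
    contig = df$contig, start = df$start, end = df$end, name = df$name,
    fold_enrichment = df$signalValue,
    min_pvalue = ifelse(df$pValue < 0, NA_real_, 10^(-df$pValue)),
    summit = ifelse(df$peak < 0, NA_integer_, df$start + df$peak)
  )
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal value are collapsed into 0-based half-open intervals;
#' values are written with 4 decimal places.
#'
#' @param track Named list of per-contig numeric vectors (value at 0-based
#'   position `i` is element `i + 1`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track)) {
    v <- round(track[[nm]], 4)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%.4f", nm, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Read a bedGraph file into per-contig per-base vectors
#'
#' @param path Path to a bedGraph file.
#' @param lengths Named integer vector of contig lengths (positions beyond
#'   the last record are filled with 0).
#' @return Named list of per-contig numeric vectors.
#' @export
read_bedgraph <- function(path, lengths) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("contig", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer",
                                  "numeric"))
  out <- lapply(names(lengths), function(nm) {
    v <- numeric(lengths[[nm]])
    sub <- df[df$contig == nm, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
    }
    v
  })
  setNames(out, names(lengths))
}

#' Write contig sizes as a two-column TSV
#'
#' @param lengths Named integer vector of contig lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_sizes <- function(lengths, path) {
  write.table(data.frame(contig = names(lengths), length = unname(lengths)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read contig sizes from a two-column TSV
#'
#' @param path Path to a `contig<TAB>length` file.
#' @return Named integer vector of contig lengths.
#' @export
read_genome_sizes <- function(path) {
  df <- read.table(path, sep = "\t", col.names = c("contig", "length"),
                   colClasses = c("character", "integer"))
  setNames(df$length, df$contig)
}
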