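#' Gene model table
#'
#' Gene models are plain data frames with one row per gene and columns
#' `gene_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`, `end` (0-based
#' half-open ORF coordinates, the end being the end of the codon prior to
#' the STOP codon), `biotype` and `is_mito`. The constructor validates the
#' invariants.
#'
#' @param df A data frame with the columns above (`biotype` and `is_mito`
#'   optional; they default to `"protein_coding"` and `FALSE`).
#' @return A validated data frame of gene models.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene models need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  if (is.null(df$is_mito)) df$is_mito <- FALSE
  if (!all(df$strand %in% c("+", "-"))) {
    stop("unknown strand character (must be '+' or '-')", call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop("gene with end <= start after coordinate conversion", call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  df[c("gene_id", "chrom", "strand", "start", "end", "biotype", "is_mito")]
}

# chromosome names conventionally used for the mitochondrial genome
.MITO_CHROMS <- c("chrM", "chrMT", "Mito", "MT", "chrmt", "mito")

#' Load gene models from GFF3 or BED
#'
#' GFF3 is 1-based closed and converted to the internal 0-based half-open
#' convention (`start - 1`, `end` unchanged); BED is already 0-based
#' half-open. When several ORF records share a `gene_id`, only the single
#' largest is kept (ties broken by leftmost coordinate), mirroring the
#' one-largest-ORF-per-gene convention used for yeast annotation.
#'
#' @param annotation_path Path to a GFF3 or BED file.
#' @param format `"gff3"` or `"bed"`.
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @param default_biotype Biotype assigned when the annotation carries none
#'   (always the case for BED).
#' @return A gene-model data frame (see [gene_models()]).
#' @export
load_gene_models <- function(annotation_path, format = c("gff3", "bed"),
                             mito_chroms = .MITO_CHROMS,
                             default_biotype = "protein_coding") {
  format <- match.arg(format)
  gr <- rtracklayer::import(annotation_path, format = format)
  md <- as.data.frame(gr)
  strand <- as.character(md$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand character in annotation", call. = FALSE)
  }
  if (format == "gff3") {
    if (!is.null(md$type)) {
      keep <- md$type %in% c("gene", "ORF", "CDS", "mRNA")
      if (any(keep)) md <- md[keep, , drop = FALSE]
    }
    id <- md$ID
    if (is.null(id)) id <- md$Name
    if (is.null(id)) stop("GFF3 records lack ID/Name attributes", call. = FALSE)
    biotype <- md$biotype
    if (is.null(biotype)) biotype <- md$gene_biotype
    if (is.null(biotype)) biotype <- default_biotype
    start0 <- md$start - 1L # GFF 1-based closed -> 0-based half-open
    end0 <- md$end
  } else {
    id <- md$name
    if (is.null(id)) id <- paste0("gene_", seq_len(nrow(md)))
    biotype <- default_biotype
    start0 <- md$start - 1L # rtracklayer reports 1-based starts internally
    end0 <- md$end
  }
  df <- data.frame(
    gene_id = as.character(id), chrom = as.character(md$seqnames),
    strand = as.character(md$strand), start = start0, end = end0,
    biotype = as.character(biotype), stringsAsFactors = FALSE
  )
  # largest ORF per gene; ties resolved to the leftmost record
  df <- df[order(df$gene_id, -(df$end - df$start), df$start), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$is_mito <- df$chrom %in% mito_chroms
  gene_models(df)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  genes <- gene_models(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\ttterm\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id, genes$biotype), con)
  invisible(path)
}

#' Write gene models as BED6
#'
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  genes <- gene_models(genes)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                     genes$end, genes$gene_id, genes$strand), path)
  invisible(path)
}
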