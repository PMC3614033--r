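#' Build a table of single-exon gene models
#'
#' Gene models are intronless (budding-yeast style): one CDS per gene given
#' by 1-based inclusive genomic coordinates, plus a promoter window extending
#' upstream of the coding start. CDS length must be divisible by 3.
#'
#' @param gene Character vector of gene names.
#' @param chrom Chromosome name per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param cds_start,cds_end 1-based inclusive genomic CDS coordinates
#'   (`cds_start <= cds_end` regardless of strand).
#' @param promoter_window Length in bp of the promoter window upstream of the
#'   coding start (default 500).
#' @return A tibble with one row per gene.
#' @export
#' @examples
#' gene_models("ACE2", "chrI", "+", 101, 160)
gene_models <- function(gene, chrom, strand, cds_start, cds_end,
                        promoter_window = 500L) {
  out <- tibble::tibble(
    gene = as.character(gene),
    chrom = as.character(chrom),
    strand = as.character(strand),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    promoter_window = as.integer(promoter_window)
  )
  validate_gene_models(out)
}

validate_gene_models <- function(genes) {
  stopifnot(is.data.frame(genes))
  req <- c("gene", "chrom", "strand", "cds_start", "cds_end",
           "promoter_window")
  missing <- setdiff(req, names(genes))
  if (length(missing)) {
    stop("gene model table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(genes$cds_start > genes$cds_end)) {
    stop("cds_start must not exceed cds_end", call. = FALSE)
  }
  if (any((genes$cds_end - genes$cds_start + 1L) %% 3L != 0L)) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  if (any(genes$promoter_window < 0L)) {
    stop("promoter_window must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(genes$gene)) {
    stop("duplicate gene names", call. = FALSE)
  }
  tibble::as_tibble(genes)
}

#' Read or write gene models as a 6-column TSV
#'
#' Columns: gene, chrom, strand, cds_start, cds_end, promoter_window.
#' Lines starting with `#` are metadata and ignored on read.
#'
#' @param path File path.
#' @return A validated gene-model tibble (reader) or `path` (writer).
#' @export
read_gene_models_tsv <- function(path) {
  genes <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      gene = "c", chrom = "c", strand = "c",
      cds_start = "i", cds_end = "i", promoter_window = "i"
    )
  )
  validate_gene_models(genes)
}

#' @rdname read_gene_models_tsv
#' @param genes A gene-model tibble.
#' @export
write_gene_models_tsv <- function(genes, path) {
  readr::write_tsv(validate_gene_models(genes), path)
  invisible(path)
}

#' Import gene models from GFF3
#'
#' Accepts only `gene` and `CDS` features; each gene must have exactly one
#' CDS (single-exon models). The gene name is taken from the `Name`
#' attribute, falling back to `ID`.
#'
#' @param path GFF3 file path.
#' @param promoter_window Promoter window applied to every imported gene.
#' @return A gene-model tibble.
#' @export
read_gene_models_gff3 <- function(path, promoter_window = 500L) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 import", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("gene", "CDS"), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in GFF3", call. = FALSE)
  name <- if ("Name" %in% names(cds)) as.character(cds$Name) else NA_character_
  id <- if ("ID" %in% names(cds)) as.character(cds$ID) else NA_character_
  gene_name <- ifelse(is.na(name) | name == "", id, name)
  if (anyNA(gene_name)) stop("CDS features need a Name or ID", call. = FALSE)
  if (anyDuplicated(gene_name)) {
    stop("multi-exon CDS models are not supported", call. = FALSE)
  }
  gene_models(
    gene = gene_name,
    chrom = as.character(cds$seqnames),
    strand = as.character(cds$strand),
    cds_start = cds$start,
    cds_end = cds$end,
    promoter_window = promoter_window
  )
}
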