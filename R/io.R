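#' Read and write variant tables (VCF-lite TSV)
#'
#' Strict four-column contract: chrom, pos, ref, alt (empty alt = deletion,
#' empty ref = insertion). Tab-separated with a single header line;
#' `#`-prefixed lines are metadata.
#'
#' @param path File path.
#' @return A variant tibble (see [variants()]).
#' @export
read_variants_tsv <- function(path) {
  v <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", pos = "i",
                                               ref = "c", alt = "c"),
                       na = character())
  if (!identical(names(v), c("chrom", "pos", "ref", "alt"))) {
    stop("variant table must have exactly columns chrom, pos, ref, alt",
         call. = FALSE)
  }
  variants(v$chrom, v$pos, v$ref, v$alt)
}

#' @rdname read_variants_tsv
#' @param v A variant tibble.
#' @export
write_variants_tsv <- function(v, path) {
  readr::write_tsv(v[, c("chrom", "pos", "ref", "alt")], path)
  invisible(path)
}

#' Read and write pooled read counts
#'
#' Columns: chrom, pos, ref, alt, mutant_reads, total_reads.
#'
#' @param path File path.
#' @return A tibble with the six columns.
#' @export
read_pool_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = "c", pos = "i", ref = "c", alt = "c",
                         mutant_reads = "i", total_reads = "i"),
                       na = character())
  if (any(x$mutant_reads > x$total_reads)) {
    stop("mutant_reads exceeds total_reads", call. = FALSE)
  }
  x
}

#' @rdname read_pool_counts_tsv
#' @param counts A pool-counts tibble.
#' @export
write_pool_counts_tsv <- function(counts, path) {
  readr::write_tsv(
    counts[, c("chrom", "pos", "ref", "alt", "mutant_reads",
               "total_reads")], path)
  invisible(path)
}

#' Read and write windowed depth tracks (BED-like TSV)
#'
#' Columns: chrom, start, end, depth; coordinates 0-based half-open (BED
#' convention), single header line.
#'
#' @param path File path.
#' @return A depth tibble.
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", start = "i",
                                          end = "i", depth = "d"))
}

#' @rdname read_depth_tsv
#' @param depth A depth tibble.
#' @export
write_depth_tsv <- function(depth, path) {
  readr::write_tsv(depth[, c("chrom", "start", "end", "depth")], path)
  invisible(path)
}

#' Read and write Sanger trace peak-height tables
#'
#' Columns: allele, time_point, h_mut, h_anc.
#'
#' @param path File path.
#' @return A trace tibble.
#' @export
read_trace_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(allele = "c", time_point = "d",
                                          h_mut = "d", h_anc = "d"))
}

#' @rdname read_trace_tsv
#' @param series A trace tibble.
#' @export
write_trace_tsv <- function(series, path) {
  readr::write_tsv(series[, c("allele", "time_point", "h_mut", "h_anc")],
                   path)
  invisible(path)
}

#' Load the packaged summary table of putative causal mutations
#'
#' Ships the published study's causal-mutation table as plain TSV fixtures:
#' 81 nucleotide-level rows across 12 evolved clones (one gene, MED1 in
#' EvoClone9, carries two changes), plus the footnote lists of flagged
#' hitchhikers, time-zero alleles, and alleles below 5% final frequency.
#' The fixture is validated structurally on load (column contract, row
#' count, read-count sanity); failures raise a corrupted-fixture error.
#'
#' @return A list with tibbles `mutations` (clone, nominal_generations,
#'   clone_mutations, gene, nt_name, aa_name, mutant_reads, total_reads,
#'   pool_fraction), `hitchhikers`, `timezero`, `low_final_frequency`.
#' @export
load_table5 <- function() {
  f <- function(name) system.file("extdata", name, package = "poolseg",
                                  mustWork = TRUE)
  mut <- readr::read_tsv(f("table5_mutations.tsv"), comment = "#",
                         show_col_types = FALSE)
  hh <- readr::read_tsv(f("table5_hitchhikers.tsv"), comment = "#",
                        show_col_types = FALSE)
  tz <- readr::read_tsv(f("table5_timezero.tsv"), comment = "#",
                        show_col_types = FALSE)
  low <- readr::read_tsv(f("table5_low_final_frequency.tsv"), comment = "#",
                         show_col_types = FALSE)
  ok <- identical(names(mut), c("clone", "nominal_generations",
                                "clone_mutations", "gene", "nt_name",
                                "aa_name", "mutant_reads", "total_reads")) &&
    nrow(mut) == 81L && dplyr::n_distinct(mut$clone) == 12L &&
    all(mut$mutant_reads <= mut$total_reads) && all(mut$mutant_reads > 0) &&
    identical(names(hh), c("clone", "hitchhiker", "linked_to"))
  if (!ok) stop("packaged causal-mutation fixture is corrupted",
                call. = FALSE)
  mut$pool_fraction <- compute_pool_fraction(mut$mutant_reads,
                                             mut$total_reads)
  list(mutations = mut, hitchhikers = hh, timezero = tz,
       low_final_frequency = low)
}

#' Re-run the causal classifier over the packaged mutation table
#'
#' Reconstructs each fixture row's effect class from its protein-level
#' name, re-applies [classify_causal()] to the read counts, summarizes
#' each clone at gene level, and builds the cross-clone summary (with the
#' glucose-sensing SNF3/MTH1/RGT1 pathway group attached).
#'
#' @return A list with `candidates` (classified rows), `reports` (one
#'   `clone_report` per clone), and `summary` (a `bsa_summary`).
#' @export
table5_summary <- function() {
  mut <- load_table5()$mutations
  mut$effect_class <- dplyr::case_when(
    mut$aa_name == "Promoter" ~ "promoter",
    grepl("fs", mut$aa_name) ~ "frameshift",
    grepl("\\*$", mut$aa_name) ~ "nonsense",
    TRUE ~ "missense"
  )
  cls <- classify_causal(mut)
  reports <- lapply(split(cls, cls$clone), function(d) {
    summarize_clone(d$clone[1], d)
  })
  list(
    candidates = cls,
    reports = reports,
    summary = cross_clone_summary(
      reports,
      pathways = list(rgt1_group = c("SNF3", "MTH1", "RGT1")))
  )
}

#' Putative causal calls near the classification threshold
#'
#' Lists causal calls whose pool fraction is within `margin` of the
#' threshold -- borderline calls that deserve a manual look (the analog of
#' an allele segregating at 91% against a 90% cutoff).
#'
#' @param candidates Classified candidates from [classify_causal()].
#' @param threshold Causal threshold used in classification.
#' @param margin Report window above the threshold (default 0.02).
#' @return The borderline subset of `candidates`.
#' @export
causal_margin <- function(candidates, threshold = 0.9, margin = 0.02) {
  candidates[candidates$classification == "putative_causal" &
               candidates$pool_fraction <= threshold + margin, ,
             drop = FALSE]
}

#' Run the pooled-segregant pipeline end to end
#'
#' Orchestrates call -> annotate -> classify -> hitchhiker-flag ->
#' summarize for one clone: compares variant sets, annotates effects
#' against the genome and gene models, joins pooled read counts, applies
#' the causal criteria, flags linked hitchhikers, and emits a
#' report-shaped table. When `out_dir` is given, writes the candidate
#' table, a one-row summary, and a run log as TSV/text.
#'
#' @param clone_variants,ancestor_variants,timezero_variants Variant
#'   tibbles (or paths to VCF-lite TSVs).
#' @param pool_counts Pool-counts tibble or path.
#' @param genome A [genome()] or FASTA path.
#' @param genes Gene-model tibble or TSV path.
#' @param clone_name Clone label used in outputs.
#' @param threshold,min_depth,linkage_cM,cM_per_bp Classification and
#'   linkage parameters; `cM_per_bp` converts positions to map distance
#'   for hitchhiker flagging.
#' @param out_dir Optional output directory.
#' @return A `clone_report` (see [summarize_clone()]); its `candidates`
#'   tibble carries the full per-variant annotation and classification.
#' @export
run_bsa_pipeline <- function(clone_variants, pool_counts, genome, genes,
                             ancestor_variants = NULL,
                             timezero_variants = NULL,
                             clone_name = "clone",
                             threshold = 0.9, min_depth = 10L,
                             linkage_cM = 25, cM_per_bp = 4e-4,
                             out_dir = NULL) {
  if (is.character(clone_variants)) {
    clone_variants <- read_variants_tsv(clone_variants)
  }
  if (is.character(ancestor_variants)) {
    ancestor_variants <- read_variants_tsv(ancestor_variants)
  }
  if (is.character(timezero_variants)) {
    timezero_variants <- read_variants_tsv(timezero_variants)
  }
  if (is.character(pool_counts)) pool_counts <- read_pool_counts_tsv(pool_counts)
  if (is.character(genome) && !inherits(genome, "poolseg_genome")) {
    genome <- read_genome_fasta(genome)
  }
  if (is.character(genes)) genes <- read_gene_models_tsv(genes)

  called <- call_clone_mutations(clone_variants, ancestor_variants,
                                 timezero_variants)
  if (nrow(called) == 0L) {
    warning("no clone-specific variants; empty report", call. = FALSE)
    report <- summarize_clone(clone_name, tibble::tibble(
      chrom = character(), pos = integer(), gene = character(),
      effect_class = character(), classification = character(),
      hitchhiker_flag = logical()))
    return(report)
  }
  ann <- annotate_variants(called, genome, genes)
  ann <- dplyr::left_join(
    ann, pool_counts[, c("chrom", "pos", "ref", "alt", "mutant_reads",
                         "total_reads")],
    by = c("chrom", "pos", "ref", "alt")
  )
  if (anyNA(ann$total_reads)) {
    ann$mutant_reads[is.na(ann$total_reads)] <- 0L
    ann$total_reads[is.na(ann$total_reads)] <- 0L
  }
  cls <- classify_causal(ann, threshold = threshold, min_depth = min_depth)
  cls$map_cM <- cls$pos * cM_per_bp
  cls <- flag_hitchhikers(cls, linkage_cM = linkage_cM)
  report <- summarize_clone(clone_name, cls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tidy(report),
                     file.path(out_dir, paste0(clone_name, "_candidates.tsv")))
    readr::write_tsv(glance(report),
                     file.path(out_dir, paste0(clone_name, "_summary.tsv")))
    writeLines(c(
      paste0("clone: ", clone_name),
      paste0("threshold: ", threshold),
      paste0("min_depth: ", min_depth),
      paste0("linkage_cM: ", linkage_cM),
      paste0("n_input_variants: ", nrow(clone_variants)),
      paste0("n_called: ", nrow(called)),
      paste0("n_putative_causal_rows: ",
             sum(cls$classification == "putative_causal")),
      paste0("gene_level_causal: ", report$gene_level_causal_count)
    ), file.path(out_dir, paste0(clone_name, "_log.txt")))
  }
  report
}
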