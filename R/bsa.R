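#' Compare variant sets: clone vs ancestor, with time-zero exclusion
#'
#' Returns the clone's variants that are absent from the ancestor reference
#' set. Variants also present in the time-zero strain are retained but
#' marked `excluded_timezero = TRUE`; they can never be classified causal
#' (they predate the evolution being analysed).
#'
#' @param clone_variants,ancestor_variants,timezero_variants Variant
#'   tibbles (chrom, pos, ref, alt) on the same genome.
#' @return The clone-specific variants with an `excluded_timezero` column.
#' @export
call_clone_mutations <- function(clone_variants, ancestor_variants = NULL,
                                 timezero_variants = NULL) {
  vkey <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  check_conflicts <- function(v, label) {
    if (is.null(v) || nrow(v) == 0L) return(invisible(NULL))
    pk <- paste(v$chrom, v$pos)
    if (anyDuplicated(pk)) {
      conf <- pk[duplicated(pk)]
      stop("conflicting alleles at duplicate positions in ", label, ": ",
           paste(unique(conf), collapse = ", "), call. = FALSE)
    }
  }
  check_conflicts(clone_variants, "clone set")
  check_conflicts(ancestor_variants, "ancestor set")
  check_conflicts(timezero_variants, "time-zero set")
  out <- tibble::as_tibble(clone_variants)
  if (nrow(out) == 0L) {
    out$excluded_timezero <- logical(0)
    return(out)
  }
  if (!is.null(ancestor_variants) && nrow(ancestor_variants) > 0L) {
    out <- out[!vkey(out) %in% vkey(ancestor_variants), , drop = FALSE]
  }
  out$excluded_timezero <-
    if (!is.null(timezero_variants) && nrow(timezero_variants) > 0L) {
      vkey(out) %in% vkey(timezero_variants)
    } else rep(FALSE, nrow(out))
  out
}

#' Pool allele fraction from read counts
#'
#' Exact rational division mutant_reads / total_reads. Variants with zero
#' total reads are uncallable and return `NA` (never causal).
#'
#' @param mutant_reads,total_reads Non-negative integer vectors.
#' @return Numeric fractions in [0, 1] (NA where total_reads is 0).
#' @export
#' @examples
#' compute_pool_fraction(77, 79)
compute_pool_fraction <- function(mutant_reads, total_reads) {
  stopifnot(all(mutant_reads <= total_reads, na.rm = TRUE),
            all(mutant_reads >= 0, na.rm = TRUE))
  ifelse(total_reads > 0, mutant_reads / total_reads, NA_real_)
}

#' Classify candidate mutations as putative causal
#'
#' Implements the three selection criteria: (1) the variant is a new
#' mutation in the evolved clone (time-zero alleles are excluded upstream);
#' (2) it is protein-altering or a promoter change (missense, nonsense,
#' frameshift, or promoter -- synonymous and intergenic variants are
#' excluded regardless of frequency); (3) its selected-pool read fraction
#' is strictly above the threshold (default 0.9, i.e. "more than 90% of
#' reads"). Variants with fewer than `min_depth` total reads are reported
#' `uncallable`.
#'
#' @param candidates Tibble with columns `effect_class`, `mutant_reads`,
#'   `total_reads`, and optionally `excluded_timezero`.
#' @param threshold Causal pool-fraction threshold (strict inequality).
#' @param min_depth Minimum total reads for a callable variant.
#' @return The input with `pool_fraction` and `classification` appended;
#'   classification is one of `putative_causal`, `non_causal`,
#'   `excluded_timezero`, `excluded_synonymous_or_intergenic`, `uncallable`.
#' @export
classify_causal <- function(candidates, threshold = 0.9, min_depth = 10L) {
  stopifnot(threshold > 0, threshold < 1)
  out <- tibble::as_tibble(candidates)
  if (!"excluded_timezero" %in% names(out)) out$excluded_timezero <- FALSE
  out$pool_fraction <- compute_pool_fraction(out$mutant_reads,
                                             out$total_reads)
  causal_effects <- c("missense", "nonsense", "frameshift", "promoter")
  out$classification <- dplyr::case_when(
    out$excluded_timezero ~ "excluded_timezero",
    !out$effect_class %in% causal_effects ~
      "excluded_synonymous_or_intergenic",
    is.na(out$pool_fraction) | out$total_reads < min_depth ~ "uncallable",
    out$pool_fraction > threshold ~ "putative_causal",
    TRUE ~ "non_causal"
  )
  out
}

#' Flag linked hitchhikers among putative causal mutations
#'
#' For every pair of putative causal candidates on the same chromosome
#' within `linkage_cM` of each other, the one with the lower pool fraction
#' is flagged as a likely hitchhiker riding on the higher-fraction allele
#' (`linked_to` records that gene). Flagged candidates keep their causal
#' classification but are separated in reports. Exact ties flag neither
#' and emit a warning.
#'
#' @param candidates Classified candidates with columns `gene`, `chrom`,
#'   `map_cM`, `pool_fraction`, `classification`.
#' @param linkage_cM Linkage radius in centimorgans (default 25).
#' @return The input with `hitchhiker_flag` and `linked_to` appended.
#' @export
flag_hitchhikers <- function(candidates, linkage_cM = 25) {
  out <- tibble::as_tibble(candidates)
  out$hitchhiker_flag <- FALSE
  out$linked_to <- NA_character_
  idx <- which(out$classification == "putative_causal")
  if (length(idx) < 2L) return(out)
  if (!all(c("chrom", "map_cM") %in% names(out)) ||
      anyNA(out$map_cM[idx])) {
    stop("map positions (chrom, map_cM) required for all putative causal ",
         "candidates", call. = FALSE)
  }
  for (a in idx) {
    for (b in idx) {
      if (a >= b) next
      if (out$chrom[a] != out$chrom[b]) next
      if (abs(out$map_cM[a] - out$map_cM[b]) > linkage_cM) next
      fa <- out$pool_fraction[a]; fb <- out$pool_fraction[b]
      if (fa == fb) {
        warning("linked putative causal pair with equal pool fractions (",
                out$gene[a], ", ", out$gene[b], "); neither flagged",
                call. = FALSE)
        next
      }
      lo <- if (fa < fb) a else b
      hi <- if (fa < fb) b else a
      out$hitchhiker_flag[lo] <- TRUE
      # record the strongest linked partner
      if (is.na(out$linked_to[lo]) ||
          out$pool_fraction[hi] > out$pool_fraction[
            match(out$linked_to[lo], out$gene)]) {
        out$linked_to[lo] <- out$gene[hi]
      }
    }
  }
  out
}

#' Summarize one clone's classified mutations
#'
#' Gene-level counting: multiple causal nucleotide changes in the same gene
#' of one clone collapse to a single gene-level causal mutation. Flagged
#' hitchhikers are excluded from the causal count.
#'
#' @param clone Clone name.
#' @param candidates Classified (and optionally hitchhiker-flagged)
#'   candidate tibble.
#' @return A list of class `clone_report`: `clone`, `candidates`,
#'   `gene_level_causal_count`, `causal_genes`.
#' @export
summarize_clone <- function(clone, candidates) {
  cand <- tibble::as_tibble(candidates)
  if (!"hitchhiker_flag" %in% names(cand)) cand$hitchhiker_flag <- FALSE
  if (!"classification" %in% names(cand)) {
    if (nrow(cand) > 0L) {
      stop("candidates must be classified first (see classify_causal())",
           call. = FALSE)
    }
    cand$classification <- character(0)
  }
  causal <- cand[cand$classification == "putative_causal" &
                   !cand$hitchhiker_flag, , drop = FALSE]
  genes <- unique(causal$gene)
  structure(
    list(clone = clone, candidates = cand,
         gene_level_causal_count = length(genes),
         causal_genes = sort(genes)),
    class = "clone_report"
  )
}

#' @export
print.clone_report <- function(x, ...) {
  cat("<clone_report> ", x$clone, ": ", x$gene_level_causal_count,
      " gene-level putative causal mutation(s)\n", sep = "")
  if (length(x$causal_genes)) {
    cat("  genes: ", paste(x$causal_genes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' @rdname summarize_clone
#' @param x A `clone_report`.
#' @param ... Unused.
#' @method tidy clone_report
#' @export
tidy.clone_report <- function(x, ...) {
  out <- x$candidates
  out$clone <- x$clone
  dplyr::relocate(out, "clone")
}

#' @rdname summarize_clone
#' @method glance clone_report
#' @export
glance.clone_report <- function(x, ...) {
  tibble::tibble(
    clone = x$clone,
    n_candidates = nrow(x$candidates),
    n_putative_causal_rows = sum(
      x$candidates$classification == "putative_causal"),
    n_hitchhiker_flagged = sum(x$candidates$hitchhiker_flag),
    gene_level_causal_count = x$gene_level_causal_count
  )
}

#' Cross-clone summary of gene-level causal mutations
#'
#' @param reports A list of `clone_report` objects, or a tibble with
#'   columns `clone`, `gene`, `classification` (and optionally
#'   `hitchhiker_flag`).
#' @param pathways Optional named list mapping pathway name to a character
#'   vector of member genes.
#' @return A list of class `bsa_summary`: `total_causal` (gene-level, each
#'   gene counted once per clone), `distinct_genes`, `per_gene` (tibble of
#'   clone counts per gene), `per_pathway` (clones carrying at least one
#'   member mutation), `genes_mutated_once`.
#' @export
cross_clone_summary <- function(reports, pathways = NULL) {
  rows <- if (is.data.frame(reports)) {
    r <- tibble::as_tibble(reports)
    if (!"hitchhiker_flag" %in% names(r)) r$hitchhiker_flag <- FALSE
    r[r$classification == "putative_causal" & !r$hitchhiker_flag,
      c("clone", "gene")]
  } else {
    purrr::map_dfr(reports, function(rep) {
      tibble::tibble(clone = rep$clone, gene = rep$causal_genes)
    })
  }
  rows <- dplyr::distinct(rows, .data$clone, .data$gene)
  per_gene <- rows |>
    dplyr::count(.data$gene, name = "n_clones") |>
    dplyr::arrange(dplyr::desc(.data$n_clones), .data$gene)
  per_pathway <- if (!is.null(pathways)) {
    purrr::imap_dfr(pathways, function(members, name) {
      tibble::tibble(
        pathway = name,
        n_clones = dplyr::n_distinct(rows$clone[rows$gene %in% members])
      )
    })
  } else NULL
  structure(
    list(
      total_causal = nrow(rows),
      distinct_genes = dplyr::n_distinct(rows$gene),
      per_gene = per_gene,
      per_pathway = per_pathway,
      genes_mutated_once = sum(per_gene$n_clones == 1L)
    ),
    class = "bsa_summary"
  )
}

#' @export
print.bsa_summary <- function(x, ...) {
  cat("<bsa_summary> ", x$total_causal,
      " gene-level putative causal mutations in ", x$distinct_genes,
      " distinct genes (", x$genes_mutated_once, " mutated once)\n",
      sep = "")
  invisible(x)
}

#' @rdname cross_clone_summary
#' @param x A `bsa_summary`.
#' @param ... Unused.
#' @method tidy bsa_summary
#' @export
tidy.bsa_summary <- function(x, ...) x$per_gene

#' @rdname cross_clone_summary
#' @method glance bsa_summary
#' @export
glance.bsa_summary <- function(x, ...) {
  tibble::tibble(
    total_causal = x$total_causal,
    distinct_genes = x$distinct_genes,
    genes_mutated_once = x$genes_mutated_once
  )
}
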