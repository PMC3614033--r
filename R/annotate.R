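#' Build a variant table
#'
#' Variants are substitutions, insertions, or deletions on a genome,
#' 1-based. A substitution has single-base `ref` and `alt`; a deletion has
#' empty `alt` (with `pos` the first deleted base); an insertion has empty
#' `ref` (with `pos` the base immediately 5', in genome orientation, of the
#' insertion point).
#'
#' @param chrom,pos,ref,alt Vectors describing each variant.
#' @return A tibble with columns chrom, pos, ref, alt, kind.
#' @export
#' @examples
#' variants("chrI", 103, "G", "T")
variants <- function(chrom, pos, ref, alt) {
  out <- tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt))
  )
  out$kind <- variant_kind(out$ref, out$alt)
  out
}

#' Classify the kind of a variant from its alleles
#' @param ref,alt Reference and alternate allele strings ("" allowed).
#' @return `"substitution"`, `"insertion"`, or `"deletion"`.
#' @export
variant_kind <- function(ref, alt) {
  kind <- dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "substitution",
    nchar(alt) == 0L & nchar(ref) >= 1L ~ "deletion",
    nchar(ref) == 0L & nchar(alt) >= 1L ~ "insertion",
    TRUE ~ NA_character_
  )
  if (anyNA(kind)) {
    stop("unsupported allele combination (multi-base substitutions are not ",
         "modelled)", call. = FALSE)
  }
  kind
}

#' Translate a codon with the standard genetic code
#'
#' @param codon Character vector of 3-letter A/C/G/T codons.
#' @return Single-letter amino acids; stop codons return `"*"`.
#' @export
#' @examples
#' translate_codon(c("GAA", "TAA"))
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon))) {
    stop("codons must be 3-letter A/C/G/T strings", call. = FALSE)
  }
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa
}

#' Signed CDS coordinate of genomic positions relative to a gene
#'
#' Positions inside the CDS map to positive 1-based offsets in coding
#' orientation; positions up to `promoter_window` bp upstream of the coding
#' start map to negative offsets (-1 is the base immediately upstream; there
#' is no position 0). Anything else is `NA`.
#'
#' @param pos Integer vector of 1-based genomic positions.
#' @param gene A single gene-model row (see [gene_models()]).
#' @return Integer vector of signed CDS coordinates (NA outside both).
#' @export
cds_coordinate <- function(pos, gene) {
  stopifnot(nrow(gene) == 1L)
  pos <- as.integer(pos)
  if (gene$strand == "+") {
    inside <- pos >= gene$cds_start & pos <= gene$cds_end
    up <- gene$cds_start - pos
  } else {
    inside <- pos >= gene$cds_start & pos <= gene$cds_end
    up <- pos - gene$cds_end
  }
  coord <- ifelse(
    inside,
    if (gene$strand == "+") pos - gene$cds_start + 1L
    else gene$cds_end - pos + 1L,
    ifelse(up >= 1L & up <= gene$promoter_window, -up, NA_integer_)
  )
  as.integer(coord)
}

cds_sequence <- function(genome, gene) {
  s <- subseq_chr(genome, gene$chrom, gene$cds_start, gene$cds_end)
  if (gene$strand == "-") revcomp(s) else s
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Pick the gene a variant belongs to: CDS hits beat promoter hits; among
# CDS hits the gene whose coding start is nearest wins; among promoter hits
# the smallest upstream distance wins.
assign_gene <- function(chrom, pos, genes) {
  cand <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  coords <- vapply(seq_len(nrow(cand)),
                   function(i) cds_coordinate(pos, cand[i, ]), integer(1))
  in_cds <- which(!is.na(coords) & coords > 0L)
  if (length(in_cds) > 0L) {
    starts <- ifelse(cand$strand[in_cds] == "+",
                     cand$cds_start[in_cds], cand$cds_end[in_cds])
    i <- in_cds[which.min(abs(pos - starts))]
    return(list(gene = cand[i, ], cds_pos = coords[i], region = "coding"))
  }
  in_prom <- which(!is.na(coords) & coords < 0L)
  if (length(in_prom) > 0L) {
    i <- in_prom[which.min(-coords[in_prom])]
    return(list(gene = cand[i, ], cds_pos = coords[i], region = "promoter"))
  }
  NULL
}

# Mutant CDS (coding orientation) plus up to `tail` nt of downstream genomic
# sequence, after applying a genomic indel. Used for the frameshift stop scan.
mutant_cds_with_tail <- function(genome, gene, pos, ref, alt, tail = 300L) {
  chr_len <- nchar(unclass(genome)[[gene$chrom]])
  if (gene$strand == "+") {
    lo <- gene$cds_start
    hi <- min(chr_len, gene$cds_end + tail)
  } else {
    lo <- max(1L, gene$cds_start - tail)
    hi <- gene$cds_end
  }
  region <- subseq_chr(genome, gene$chrom, lo, hi)
  off <- pos - lo + 1L
  if (nchar(alt) == 0L) {                       # deletion of ref at pos..
    region <- paste0(substr(region, 1L, off - 1L),
                     substr(region, off + nchar(ref), nchar(region)))
  } else {                                      # insertion after pos
    region <- paste0(substr(region, 1L, off), alt,
                     substr(region, off + 1L, nchar(region)))
  }
  if (gene$strand == "-") revcomp(region) else region
}

annotate_one <- function(genome, genes, chrom, pos, ref, alt) {
  kind <- variant_kind(ref, alt)
  # reference allele must match the genome
  if (kind != "insertion") {
    obs <- subseq_chr(genome, chrom, pos, pos + nchar(ref) - 1L)
    if (!identical(obs, ref)) {
      stop(sprintf("ref allele mismatch at %s:%d (genome has '%s', variant '%s')",
                   chrom, pos, obs, ref), call. = FALSE)
    }
  }
  blank <- list(
    gene = NA_character_, region = "intergenic", cds_pos = NA_integer_,
    codon_index = NA_integer_, aa_ref = NA_character_, aa_alt = NA_character_,
    effect_class = "intergenic", nt_name = NA_character_,
    aa_name = NA_character_
  )
  hit <- assign_gene(chrom, pos, genes)
  if (is.null(hit)) return(blank)
  g <- hit$gene
  minus <- g$strand == "-"
  orient <- function(x) if (minus) revcomp(x) else x

  if (hit$region == "promoter") {
    nt <- format_nt_name(kind, genome, g, pos, ref, alt)
    return(utils::modifyList(blank, list(
      gene = g$gene, region = "promoter", cds_pos = hit$cds_pos,
      effect_class = "promoter", nt_name = nt, aa_name = "Promoter"
    )))
  }

  cds <- cds_sequence(genome, g)
  ref_prot <- translate_codon(split_codons(cds))

  if (kind == "substitution") {
    p <- hit$cds_pos
    ref_c <- orient(ref); alt_c <- orient(alt)
    ci <- as.integer(ceiling(p / 3))
    off <- p - (ci - 1L) * 3L
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    mut_codon <- codon
    substr(mut_codon, off, off) <- alt_c
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(mut_codon)
    cls <- if (aa_ref == aa_alt) "synonymous"
           else if (aa_alt == "*" && aa_ref != "*") "nonsense"
           else "missense"
    aa_name <- if (cls == "synonymous") paste0(aa_ref, ci, aa_alt)
               else paste0(aa_ref, ci, aa_alt)
    return(utils::modifyList(blank, list(
      gene = g$gene, region = "coding", cds_pos = p, codon_index = ci,
      aa_ref = aa_ref, aa_alt = aa_alt, effect_class = cls,
      nt_name = paste0(p, ref_c, "->", alt_c), aa_name = aa_name
    )))
  }

  # coding indel
  indel_len <- abs(nchar(ref) - nchar(alt))
  frameshift <- indel_len %% 3L != 0L
  mut <- mutant_cds_with_tail(genome, g, pos, ref, alt)
  mut_prot <- translate_codon(split_codons(mut))
  # first codon where the mutant protein departs from the reference
  n <- min(length(ref_prot), length(mut_prot))
  diffs <- which(ref_prot[seq_len(n)] != mut_prot[seq_len(n)])
  i <- if (length(diffs)) diffs[1L] else n + 1L
  if (i > length(ref_prot) || i > length(mut_prot)) {
    # degenerate: no observable protein change within the reference span
    aa_ref <- aa_alt <- NA_character_
    aa_name <- if (frameshift) "fs?" else NA_character_
  } else {
    aa_ref <- ref_prot[i]
    aa_alt <- mut_prot[i]
    if (frameshift) {
      stop_at <- which(mut_prot[seq(i, length(mut_prot))] == "*")
      if (aa_alt == "*") {
        aa_name <- paste0(aa_ref, i, "*")
      } else if (length(stop_at)) {
        aa_name <- paste0(aa_ref, i, aa_alt, "fs", i + stop_at[1L] - 1L)
      } else {
        aa_name <- paste0(aa_ref, i, aa_alt, "fs?")
      }
    } else {
      aa_name <- paste0(aa_ref, i, aa_alt)
    }
  }
  utils::modifyList(blank, list(
    gene = g$gene, region = "coding", cds_pos = hit$cds_pos,
    codon_index = as.integer(ceiling(hit$cds_pos / 3)),
    aa_ref = aa_ref, aa_alt = aa_alt,
    effect_class = if (frameshift) "frameshift" else "missense",
    nt_name = format_nt_name(kind, genome, g, pos, ref, alt),
    aa_name = aa_name
  ))
}

format_nt_name <- function(kind, genome, gene, pos, ref, alt) {
  minus <- gene$strand == "-"
  orient <- function(x) if (minus) revcomp(x) else x
  if (kind == "substitution") {
    p <- cds_coordinate(pos, gene)
    return(paste0(p, orient(ref), "->", orient(alt)))
  }
  if (kind == "deletion") {
    bases <- pos:(pos + nchar(ref) - 1L)
    coords <- cds_coordinate(bases, gene)
    return(paste0(min(coords), "_", max(coords), "del", orient(ref)))
  }
  # insertion between genomic pos and pos + 1
  flank <- if (minus) pos + 1L else pos
  m <- cds_coordinate(flank, gene)
  paste0(m, "_", m + 1L, "ins", orient(alt))
}

#' Annotate variants against a genome and gene models
#'
#' Assigns each variant to a gene region (coding, promoter, or intergenic)
#' and computes its functional consequence: synonymous, missense, nonsense,
#' frameshift (indels whose length is not divisible by 3, with the new stop
#' found by translating the shifted frame through the CDS plus up to 300 nt
#' of downstream sequence), or promoter. Minus-strand genes are handled in
#' coding orientation (alleles complemented). Mutation names follow the
#' conventional compact nomenclature: `703G->T`, `675_675delG`,
#' `2494_2495insT` at the nucleotide level (negative coordinates for
#' promoter positions) and `E235*`, `T2996S`, `G227Vfs249` at the protein
#' level (`Promoter` for promoter variants).
#'
#' @param variants A variant tibble (see [variants()]).
#' @param genome A [genome()].
#' @param genes A gene-model tibble.
#' @return The variant tibble with columns gene, region, cds_pos,
#'   codon_index, aa_ref, aa_alt, effect_class, nt_name, aa_name appended.
#' @export
annotate_variants <- function(variants, genome, genes) {
  genes <- validate_gene_models(genes)
  lens <- genome_lengths(genome)
  bad <- !variants$chrom %in% lens$chrom
  if (any(bad)) {
    stop("variants on unknown chromosomes: ",
         paste(unique(variants$chrom[bad]), collapse = ", "), call. = FALSE)
  }
  ann <- purrr::pmap(
    list(variants$chrom, variants$pos, variants$ref, variants$alt),
    function(chrom, pos, ref, alt) {
      tibble::as_tibble(annotate_one(genome, genes, chrom, pos, ref, alt))
    }
  )
  dplyr::bind_cols(variants, dplyr::bind_rows(ann))
}

#' Parse compact mutation nomenclature back into alleles
#'
#' Inverse of the nucleotide-level naming used by [annotate_variants()]:
#' recovers the CDS-space position(s), reference and alternate alleles, and
#' variant kind from names such as `"703G->T"`, `"-379G->A"`,
#' `"675_675delG"`, or `"2494_2495insT"`.
#'
#' @param nt_name Character vector of nucleotide-level names.
#' @return A tibble with columns kind, start, end, ref, alt (positions in
#'   signed CDS coordinates).
#' @export
parse_nomenclature <- function(nt_name) {
  parse1 <- function(x) {
    m <- regmatches(x, regexec("^(-?[0-9]+)([ACGT])->([ACGT])$", x))[[1]]
    if (length(m)) {
      p <- as.integer(m[2])
      return(tibble::tibble(kind = "substitution", start = p, end = p,
                            ref = m[3], alt = m[4]))
    }
    m <- regmatches(x, regexec("^(-?[0-9]+)_(-?[0-9]+)del([ACGT]+)$", x))[[1]]
    if (length(m)) {
      return(tibble::tibble(kind = "deletion", start = as.integer(m[2]),
                            end = as.integer(m[3]), ref = m[4], alt = ""))
    }
    m <- regmatches(x, regexec("^(-?[0-9]+)_(-?[0-9]+)ins([ACGT]+)$", x))[[1]]
    if (length(m)) {
      return(tibble::tibble(kind = "insertion", start = as.integer(m[2]),
                            end = as.integer(m[3]), ref = "", alt = m[4]))
    }
    stop("unparseable mutation name: ", x, call. = FALSE)
  }
  dplyr::bind_rows(lapply(nt_name, parse1))
}
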