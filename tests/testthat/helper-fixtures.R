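# Shared fixtures and independent oracles used across the suite.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# A single plus-strand gene with chosen codons planted at chosen indices,
# 600 bp of upstream (promoter) sequence and 400 bp downstream.
make_gene_fixture <- function(n_codons = 300, plant = list(), seed = 42,
                              gene = "ACE2") {
  set.seed(seed)
  codons <- vapply(seq_len(n_codons - 1L), function(i) {
    repeat {
      cd <- random_seq(3)
      if (poolseg::translate_codon(cd) != "*") return(cd)
    }
  }, character(1))
  codons <- c(codons, "TAA")
  for (idx in names(plant)) codons[as.integer(idx)] <- plant[[idx]]
  cds <- paste(codons, collapse = "")
  chr <- paste0(random_seq(600), cds, random_seq(400))
  list(
    genome = poolseg::genome(c(chrI = chr)),
    genes = poolseg::gene_models(gene, "chrI", "+", 601L,
                                 600L + nchar(cds)),
    cds_offset = 600L,
    cds = cds
  )
}

# genomic position of a 1-based CDS coordinate in the fixture
fx_pos <- function(fx, cds_pos) fx$cds_offset + cds_pos

# Independent Haldane map oracle
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# Brute-force per-base codon index: walk the CDS base by base
oracle_codon_index <- function(p, n_codons = 1000) {
  rep(seq_len(n_codons), each = 3L)[p]
}

# Literal re-derivation of the three causal-mutation criteria:
# (1) new in the clone (not time-zero), (2) nonsynonymous coding or
# promoter, (3) present in more than 90% of pool reads.
oracle_classify <- function(effect_class, mutant_reads, total_reads,
                            excluded_timezero, threshold = 0.9,
                            min_depth = 10) {
  n <- length(effect_class)
  out <- character(n)
  for (i in seq_len(n)) {
    if (excluded_timezero[i]) {
      out[i] <- "excluded_timezero"
    } else if (!effect_class[i] %in%
                 c("missense", "nonsense", "frameshift", "promoter")) {
      out[i] <- "excluded_synonymous_or_intergenic"
    } else if (total_reads[i] < min_depth) {
      out[i] <- "uncallable"
    } else if (mutant_reads[i] / total_reads[i] > threshold) {
      out[i] <- "putative_causal"
    } else {
      out[i] <- "non_causal"
    }
  }
  out
}

# Minimal hand-built clone object for meiosis/selection tests (bypasses
# the full genome simulation).
manual_clone <- function(chrom, map_cM, role, s,
                         chromosome_length_bp = 250000L,
                         cM_per_bp = 4e-4) {
  cfg <- poolseg::sim_config(
    chromosome_length_bp = chromosome_length_bp, cM_per_bp = cM_per_bp,
    n_causal = sum(role == "causal"), seed = 1L
  )
  n <- length(chrom)
  geno <- tibble::tibble(
    chrom = chrom, pos = as.integer(round(map_cM / cM_per_bp)),
    ref = "A", alt = "T", kind = "substitution",
    role = role, map_cM = map_cM, s = s
  )
  structure(list(genome = NULL, genes = NULL, genotype = geno,
                 config = cfg),
            class = "evolved_clone")
}

# Candidate tables for the packaged causal-mutation fixture: effect class
# reconstructed from the protein-level name, classification re-derived by
# the package classifier.
table5_candidates <- function() {
  t5 <- poolseg::load_table5()
  mut <- t5$mutations
  mut$effect_class <- dplyr::case_when(
    mut$aa_name == "Promoter" ~ "promoter",
    grepl("fs", mut$aa_name) ~ "frameshift",
    grepl("\\*$", mut$aa_name) ~ "nonsense",
    TRUE ~ "missense"
  )
  poolseg::classify_causal(mut)
}
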