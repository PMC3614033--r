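#' Configuration for a synthetic pooled-segregant experiment
#'
#' Bundles the parameters that define a simulated mutator-evolution /
#' backcross / spore-selection experiment. Defaults follow the scale of the
#' real design the simulator emulates: a clone carrying 5 strongly selected
#' causal mutations and ~110 neutral hitchhikers after ~273 generations of
#' mutator evolution, haploid spores from a backcross selected for ~34
#' generations, and pooled sequencing at 90x coverage. Selection
#' coefficients are not observable in such experiments and default to
#' s = 0.1 per causal allele, strong enough that 34 generations of selection
#' drives a heterozygously segregating allele past 95% frequency.
#'
#' @param n_chromosomes Number of chromosomes in the synthetic genome.
#' @param chromosome_length_bp Length of each chromosome (bp).
#' @param cM_per_bp Genetic map density (default 4e-4, i.e. 0.4 cM/kb,
#'   the budding-yeast scale).
#' @param n_causal Number of planted causal mutations (one per causal gene).
#' @param selection_coefficients Dimensionless s per causal allele,
#'   recycled to `n_causal`.
#' @param causal_promoter_frac Fraction of causal mutations planted in the
#'   promoter window rather than the CDS.
#' @param n_hitchhikers Number of neutral mutations in the evolved clone.
#' @param hitchhiker_cds_frac Fraction of hitchhikers planted inside decoy
#'   gene CDSs (the rest fall uniformly on the genome).
#' @param n_timezero Number of variants shared with the time-zero strain.
#' @param n_decoy_genes Non-causal gene models available to receive
#'   hitchhikers.
#' @param evolution_generations Nominal generations of mutator evolution.
#' @param mutation_rate Optional per-generation mutation rate; when set,
#'   the hitchhiker count is drawn as Poisson(generations * rate) instead
#'   of being fixed at `n_hitchhikers`.
#' @param selection_generations Generations of spore selection (default 34,
#'   one 100:1 dilution plus three 500:1 dilutions).
#' @param n_spores Spores in the selected pool.
#' @param pool_coverage Mean sequencing depth of the pool.
#' @param seq_error_rate Per-read per-site error rate.
#' @param seed Integer seed from which all randomness flows.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 8L,
                       chromosome_length_bp = 250000L,
                       cM_per_bp = 4e-4,
                       n_causal = 5L,
                       selection_coefficients = 0.1,
                       causal_promoter_frac = 0.2,
                       n_hitchhikers = 110L,
                       hitchhiker_cds_frac = 0.3,
                       n_timezero = 5L,
                       n_decoy_genes = 20L,
                       evolution_generations = 273L,
                       mutation_rate = NULL,
                       selection_generations = 34L,
                       n_spores = 2000L,
                       pool_coverage = 90,
                       seq_error_rate = 0.001,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    cM_per_bp = cM_per_bp,
    n_causal = as.integer(n_causal),
    selection_coefficients = rep_len(selection_coefficients,
                                     max(1L, as.integer(n_causal))),
    causal_promoter_frac = causal_promoter_frac,
    n_hitchhikers = as.integer(n_hitchhikers),
    hitchhiker_cds_frac = hitchhiker_cds_frac,
    n_timezero = as.integer(n_timezero),
    n_decoy_genes = as.integer(n_decoy_genes),
    evolution_generations = as.integer(evolution_generations),
    mutation_rate = mutation_rate,
    selection_generations = as.integer(selection_generations),
    n_spores = as.integer(n_spores),
    pool_coverage = pool_coverage,
    seq_error_rate = seq_error_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chromosomes > 0L, cfg$chromosome_length_bp > 0L,
    cfg$cM_per_bp >= 0, cfg$n_causal >= 0L, all(cfg$selection_coefficients >= 0),
    cfg$n_hitchhikers >= 0L, cfg$n_timezero >= 0L, cfg$n_spores > 0L,
    cfg$pool_coverage > 0, cfg$seq_error_rate >= 0, cfg$seq_error_rate < 0.5
  )
  structure(cfg, class = "sim_config")
}

random_chromosomes <- function(n, len) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  genome(stats::setNames(seqs, sprintf("chr%02d", seq_len(n))))
}

# Place gene models at non-overlapping positions, each with room for its
# 500 bp promoter window.
place_genes <- function(n, prefix, genome, cds_len = 900L, window = 500L) {
  lens <- genome_lengths(genome)
  placed <- list()
  occupied <- tibble::tibble(chrom = character(), lo = integer(),
                             hi = integer())
  for (i in seq_len(n)) {
    repeat {
      chrom <- sample(lens$chrom, 1L)
      start <- sample.int(lens$length[lens$chrom == chrom] - cds_len -
                            2L * window, 1L) + window
      lo <- start - window; hi <- start + cds_len - 1L + window
      clash <- occupied$chrom == chrom &
        occupied$lo <= hi & occupied$hi >= lo
      if (!any(clash)) break
    }
    occupied <- dplyr::bind_rows(
      occupied, tibble::tibble(chrom = chrom, lo = lo, hi = hi))
    placed[[i]] <- gene_models(
      gene = sprintf("%s%02d", prefix, i), chrom = chrom, strand = "+",
      cds_start = start, cds_end = start + cds_len - 1L,
      promoter_window = window
    )
  }
  dplyr::bind_rows(placed)
}

# A substitution inside a gene's CDS guaranteed to change the protein.
draw_nonsynonymous <- function(genome, gene) {
  repeat {
    p <- sample.int(gene$cds_end - gene$cds_start + 1L, 1L)
    pos <- gene$cds_start + p - 1L
    ref <- subseq_chr(genome, gene$chrom, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    ci <- ceiling(p / 3)
    codon <- substr(cds_sequence(genome, gene), 3 * ci - 2, 3 * ci)
    mut <- codon
    substr(mut, p - (ci - 1L) * 3L, p - (ci - 1L) * 3L) <- alt
    if (translate_codon(codon) != translate_codon(mut) &&
        translate_codon(codon) != "*") {
      return(tibble::tibble(chrom = gene$chrom, pos = pos, ref = ref,
                            alt = alt))
    }
  }
}

draw_substitutions <- function(genome, n, at = NULL) {
  lens <- genome_lengths(genome)
  if (is.null(at)) {
    chrom <- sample(lens$chrom, n, replace = TRUE)
    pos <- vapply(chrom, function(ch) {
      sample.int(lens$length[lens$chrom == ch], 1L)
    }, integer(1))
  } else {
    chrom <- at$chrom; pos <- at$pos
  }
  ref <- vapply(seq_len(n), function(i) {
    subseq_chr(genome, chrom[i], pos[i], pos[i])
  }, character(1))
  alt <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Simulate an evolved mutator clone
#'
#' Builds a synthetic genome and gene models, then plants three classes of
#' mutation: causal mutations (nonsynonymous CDS or promoter substitutions
#' in designated causal genes, each with selection coefficient s > 0),
#' neutral hitchhikers (uniform positions, a configurable fraction inside
#' decoy CDSs), and time-zero background variants shared with the
#' ancestor-of-record. Position collisions are resolved by redrawing.
#'
#' @param config A [sim_config()].
#' @return A list of class `evolved_clone` with elements `genome`, `genes`
#'   (gene-model tibble), `genotype` (tibble with chrom, pos, ref, alt,
#'   kind, role, map_cM, s), and `config`.
#' @export
simulate_evolved_clone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  gen <- random_chromosomes(config$n_chromosomes, config$chromosome_length_bp)
  causal_genes <- place_genes(config$n_causal, "CGENE", gen)
  decoy_genes <- place_genes(config$n_decoy_genes, "GENE", gen)
  genes <- dplyr::bind_rows(causal_genes, decoy_genes)

  n_hh <- if (!is.null(config$mutation_rate)) {
    stats::rpois(1L, config$evolution_generations * config$mutation_rate)
  } else config$n_hitchhikers

  empty_vars <- tibble::tibble(chrom = character(), pos = integer(),
                               ref = character(), alt = character())
  causal <- if (config$n_causal == 0L) empty_vars else
    purrr::map_dfr(seq_len(config$n_causal), function(i) {
    g <- causal_genes[i, ]
    if (stats::runif(1) < config$causal_promoter_frac) {
      up <- sample.int(g$promoter_window, 1L)
      pos <- g$cds_start - up          # plus-strand genes only in simulation
      ref <- subseq_chr(gen, g$chrom, pos, pos)
      tibble::tibble(chrom = g$chrom, pos = pos, ref = ref,
                     alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
    } else {
      draw_nonsynonymous(gen, g)
    }
  })
  if (config$n_causal > 0) {
    causal$role <- "causal"
    causal$s <- config$selection_coefficients
  }

  # hitchhikers (a fraction steered into decoy CDSs for a realistic
  # coding/noncoding mix) and time-zero background variants
  n_other <- n_hh + config$n_timezero
  n_in_cds <- if (nrow(decoy_genes) > 0) {
    as.integer(round(config$hitchhiker_cds_frac * n_hh))
  } else 0L
  draw_other <- function(in_cds, n_uniform) {
    pieces <- list()
    if (in_cds > 0L) {
      gi <- sample.int(nrow(decoy_genes), in_cds, replace = TRUE)
      pos <- decoy_genes$cds_start[gi] +
        vapply(gi, function(j) {
          sample.int(decoy_genes$cds_end[j] - decoy_genes$cds_start[j] + 1L,
                     1L) - 1L
        }, integer(1))
      pieces$cds <- draw_substitutions(
        gen, in_cds,
        at = tibble::tibble(chrom = decoy_genes$chrom[gi], pos = pos))
    }
    if (n_uniform > 0L) pieces$unif <- draw_substitutions(gen, n_uniform)
    dplyr::bind_rows(pieces)
  }
  other <- if (n_other > 0) {
    draw_other(n_in_cds, n_other - n_in_cds)
  } else tibble::tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
  in_cds_flag <- rep(c(TRUE, FALSE), c(n_in_cds, n_other - n_in_cds))
  # redraw any position collisions (against causal sites and each other),
  # preserving each draw's category
  repeat {
    key <- c(paste(causal$chrom, causal$pos),
             paste(other$chrom, other$pos))
    dup <- duplicated(key)[nrow(causal) + seq_len(nrow(other))]
    if (!any(dup)) break
    redo <- draw_other(sum(dup & in_cds_flag), sum(dup & !in_cds_flag))
    other[which(dup)[order(!in_cds_flag[dup])], ] <- redo
  }
  if (n_other > 0) {
    # CDS-steered hitchhikers come first, then uniform hitchhikers, then
    # the time-zero background variants
    other$role <- rep(c("hitchhiker", "timezero"),
                      c(n_hh, config$n_timezero))
    other$s <- 0
  }
  genotype <- dplyr::bind_rows(
    if (nrow(causal)) causal else NULL,
    if (n_other > 0) other else NULL
  )
  genotype$kind <- "substitution"
  genotype$map_cM <- genotype$pos * config$cM_per_bp
  genotype <- dplyr::arrange(genotype, .data$chrom, .data$pos)
  structure(
    list(genome = gen, genes = genes, genotype = genotype, config = config),
    class = "evolved_clone"
  )
}

#' @export
print.evolved_clone <- function(x, ...) {
  cat("<evolved_clone> ", nrow(x$genotype), " planted mutations (",
      sum(x$genotype$role == "causal"), " causal, ",
      sum(x$genotype$role == "hitchhiker"), " hitchhiker, ",
      sum(x$genotype$role == "timezero"), " time-zero)\n", sep = "")
  invisible(x)
}

#' Simulate meiotic spores from the backcross diploid
#'
#' Each spore inherits, per chromosome, a mosaic of evolved and ancestral
#' haplotype. Crossover breakpoints follow a Poisson process at 1 per
#' 100 cM along the genetic map (no interference), so the probability that
#' two loci d cM apart are separated is the Haldane recombination fraction
#' r = (1 - exp(-2d/100)) / 2, and loci on different chromosomes assort
#' independently.
#'
#' @param clone An [simulate_evolved_clone()] result.
#' @param n_spores Number of spores (defaults to the config value).
#' @param seed Optional seed; omit to continue the current RNG stream.
#' @return A list of class `spore_genotypes`: `inherit`, an
#'   n_spores x n_variants logical matrix (TRUE = evolved allele), and
#'   `variants`, the clone genotype tibble.
#' @export
simulate_meiosis <- function(clone, n_spores = clone$config$n_spores,
                             seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  geno <- clone$genotype
  cfg <- clone$config
  n_v <- nrow(geno)
  inherit <- matrix(FALSE, nrow = n_spores, ncol = n_v)
  L_cM <- cfg$chromosome_length_bp * cfg$cM_per_bp
  for (ch in unique(geno$chrom)) {
    j <- which(geno$chrom == ch)
    m <- geno$map_cM[j]
    start <- sample(0:1, n_spores, replace = TRUE)
    k <- stats::rpois(n_spores, L_cM / 100)
    bp <- stats::runif(sum(k), 0, L_cM)
    sid <- rep.int(seq_len(n_spores), k)
    for (jj in seq_along(j)) {
      cnt <- tabulate(sid[bp < m[jj]], nbins = n_spores)
      inherit[, j[jj]] <- (start + cnt) %% 2L == 1L
    }
  }
  structure(list(inherit = inherit, variants = geno, config = cfg),
            class = "spore_genotypes")
}

#' Apply spore selection and compute pool allele frequencies
#'
#' Selection is modelled as deterministic exponential weighting: each
#' spore's final weight is proportional to the product over its carried
#' causal alleles of (1+s)^generations. The pool frequency of a variant is
#' the weight share of its carriers. With s = 0 everywhere, frequencies
#' equal the pre-selection spore frequencies.
#'
#' @param spores A [simulate_meiosis()] result.
#' @param selection_generations Generations of selection (default from the
#'   config).
#' @return A tibble of class `spore_pool`: the variant table plus
#'   `pool_freq` in [0, 1].
#' @export
select_spores <- function(spores,
                          selection_generations =
                            spores$config$selection_generations) {
  geno <- spores$variants
  M <- spores$inherit
  causal <- which(geno$role == "causal" & geno$s > 0)
  logw <- if (length(causal)) {
    as.numeric(M[, causal, drop = FALSE] %*%
                 (selection_generations * log1p(geno$s[causal])))
  } else rep(0, nrow(M))
  w <- exp(logw - max(logw))
  freq <- as.numeric(crossprod(M, w)) / sum(w)
  out <- geno
  out$pool_freq <- freq
  class(out) <- c("spore_pool", class(out))
  out
}

#' Sample pooled sequencing read counts
#'
#' Per variant the total depth is Poisson(coverage) and the mutant count is
#' binomial with success probability f(1-e) + (1-f)e, where f is the pool
#' allele frequency and e the per-read error rate.
#'
#' @param pool A [select_spores()] result (or any tibble with `pool_freq`).
#' @param coverage Mean depth.
#' @param seq_error_rate Per-read per-site error rate.
#' @param seed Optional seed.
#' @return The input tibble with `mutant_reads` and `total_reads` appended.
#' @export
sample_pool_reads <- function(pool, coverage = 90, seq_error_rate = 0.001,
                              seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(pool)
  total <- stats::rpois(n, coverage)
  p <- pool$pool_freq * (1 - seq_error_rate) +
    (1 - pool$pool_freq) * seq_error_rate
  mutant <- stats::rbinom(n, total, p)
  out <- tibble::as_tibble(pool)
  out$mutant_reads <- mutant
  out$total_reads <- total
  out
}

#' Simulate windowed depth profiles with copy-number events
#'
#' Emits ancestor, clone, and selected-pool depth tracks on a shared window
#' grid. The ancestor is single copy everywhere. Clone windows inside a CNV
#' event take its copy number. In the pool, a non-causal event segregates
#' neutrally (half the selected spores carry it), so its expected copy
#' number is (copy + 1)/2 -- a clone duplication at 2x appears as a 50%
#' increase; a causal event is retained by selection and keeps the clone
#' copy number. Window depths are Poisson around coverage x copy ratio.
#'
#' @param genome A [genome()] defining the grid.
#' @param cnv_events Tibble with chrom, start, end (1-based inclusive bp),
#'   copy_number, causal (logical). Events must not overlap.
#' @param window_bp Window size (default 1000).
#' @param coverage Mean single-copy depth.
#' @param seed Optional seed.
#' @return A list of class `depth_profiles` with tibbles `ancestor`,
#'   `clone`, `pool` (chrom, start, end, depth; 0-based half-open windows).
#' @export
simulate_depth_profiles <- function(genome, cnv_events = NULL,
                                    window_bp = 1000L, coverage = 90,
                                    seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(cnv_events)) {
    cnv_events <- tibble::tibble(chrom = character(), start = integer(),
                                 end = integer(), copy_number = numeric(),
                                 causal = logical())
  }
  by_chr <- split(cnv_events, cnv_events$chrom)
  for (ev in by_chr) {
    if (nrow(ev) > 1L) {
      ev <- dplyr::arrange(ev, .data$start)
      if (any(ev$start[-1L] <= ev$end[-nrow(ev)])) {
        stop("overlapping CNV events", call. = FALSE)
      }
    }
  }
  lens <- genome_lengths(genome)
  grid <- purrr::map_dfr(seq_len(nrow(lens)), function(i) {
    starts <- seq(0L, lens$length[i] - 1L, by = window_bp)
    tibble::tibble(chrom = lens$chrom[i], start = starts,
                   end = pmin(starts + window_bp, lens$length[i]))
  })
  copy <- rep(1, nrow(grid))
  pool_copy <- rep(1, nrow(grid))
  for (i in seq_len(nrow(cnv_events))) {
    ev <- cnv_events[i, ]
    hit <- grid$chrom == ev$chrom & grid$start >= ev$start - 1L &
      grid$end <= ev$end
    copy[hit] <- ev$copy_number
    pool_copy[hit] <- if (isTRUE(ev$causal)) ev$copy_number
                      else (ev$copy_number + 1) / 2
  }
  draw <- function(ratio) {
    g <- grid
    g$depth <- stats::rpois(nrow(grid), coverage * ratio)
    g
  }
  structure(
    list(ancestor = draw(rep(1, nrow(grid))), clone = draw(copy),
         pool = draw(pool_copy)),
    class = "depth_profiles"
  )
}

#' Simulate Sanger trace peak heights along a time course
#'
#' For each (allele, time point) emits mutant and ancestral peak heights
#' whose ratio equals the true allele frequency plus truncated Gaussian
#' noise (observed frequency clipped to [0, 1]).
#'
#' @param trajectory Tibble with columns allele, time_point, freq in [0,1].
#' @param noise_sd Standard deviation of the frequency noise.
#' @param total_height Summed peak height (arbitrary fluorescence units).
#' @param seed Optional seed.
#' @return A tibble with allele, time_point, h_mut, h_anc.
#' @export
simulate_sanger_timecourse <- function(trajectory, noise_sd = 0.02,
                                       total_height = 1000, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(all(trajectory$freq >= 0), all(trajectory$freq <= 1))
  f <- pmin(1, pmax(0, trajectory$freq +
                      stats::rnorm(nrow(trajectory), 0, noise_sd)))
  tibble::tibble(
    allele = trajectory$allele,
    time_point = trajectory$time_point,
    h_mut = total_height * f,
    h_anc = total_height * (1 - f)
  )
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: simulate the evolved clone, meiosis, spore
#' selection, and pooled read sampling, all from the single config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `clone`, `spores`, `pool`, and `counts` (the pool
#'   tibble with read counts).
#' @export
simulate_bsa_experiment <- function(config) {
  clone <- simulate_evolved_clone(config)
  withr::local_seed(config$seed + 1000000L)
  spores <- simulate_meiosis(clone, n_spores = config$n_spores)
  pool <- select_spores(spores)
  counts <- sample_pool_reads(pool, coverage = config$pool_coverage,
                              seq_error_rate = config$seq_error_rate)
  list(clone = clone, spores = spores, pool = pool, counts = counts)
}
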