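test_that("the evolved-clone generator is deterministic and plants the configured counts", {
  cfg <- sim_config(n_causal = 5L, n_hitchhikers = 110L,
                    evolution_generations = 273L, seed = 11L)
  cl1 <- simulate_evolved_clone(cfg)
  cl2 <- simulate_evolved_clone(cfg)
  expect_identical(cl1$genotype, cl2$genotype)
  expect_identical(unclass(cl1$genome), unclass(cl2$genome))
  expect_equal(sum(cl1$genotype$role != "timezero"), 115L)
  expect_equal(sum(cl1$genotype$role == "causal"), 5L)
  expect_true(all(cl1$genotype$s[cl1$genotype$role == "causal"] > 0))
  expect_true(all(cl1$genotype$s[cl1$genotype$role != "causal"] == 0))
  expect_false(anyDuplicated(paste(cl1$genotype$chrom,
                                   cl1$genotype$pos)) > 0)
  # no causal mutations -> only hitchhiker/timezero roles
  cl0 <- simulate_evolved_clone(sim_config(n_causal = 0L, seed = 3L))
  expect_true(all(cl0$genotype$role %in% c("hitchhiker", "timezero")))
})

test_that("planted causal mutations are protein-altering or promoter", {
  cl <- simulate_evolved_clone(sim_config(seed = 19L))
  ann <- annotate_variants(cl$genotype, cl$genome, cl$genes)
  causal <- ann[ann$role == "causal", ]
  expect_true(all(causal$effect_class %in%
                    c("missense", "nonsense", "promoter")))
})

test_that("meiosis reproduces the Haldane map", {
  # loci at the same map position are always co-inherited
  cl <- manual_clone("chr01", c(10, 10), c("causal", "hitchhiker"),
                     c(0.1, 0))
  sp <- simulate_meiosis(cl, n_spores = 2000L, seed = 1L)
  expect_true(all(sp$inherit[, 1] == sp$inherit[, 2]))

  # different chromosomes assort independently (r = 1/2)
  cl2 <- manual_clone(c("chr01", "chr02"), c(10, 10),
                      c("causal", "hitchhiker"), c(0.1, 0))
  sp2 <- simulate_meiosis(cl2, n_spores = 10000L, seed = 2L)
  recomb <- mean(sp2$inherit[, 1] != sp2$inherit[, 2])
  expect_lt(abs(recomb - 0.5), 0.02)

  # 10 cM apart: recombinant fraction matches the closed form 0.0906
  cl3 <- manual_clone(c("chr01", "chr01"), c(20, 30),
                      c("causal", "hitchhiker"), c(0.1, 0))
  sp3 <- simulate_meiosis(cl3, n_spores = 10000L, seed = 3L)
  recomb3 <- mean(sp3$inherit[, 1] != sp3$inherit[, 2])
  expect_lt(abs(recomb3 - haldane_r(10)), 0.006)
})

test_that("without selection every allele segregates at 1/2 (binomial 99% band)", {
  cl <- simulate_evolved_clone(sim_config(seed = 23L, n_hitchhikers = 30L))
  sp <- simulate_meiosis(cl, n_spores = 10000L, seed = 5L)
  pool <- select_spores(sp, selection_generations = 0L)
  counts <- colSums(sp$inherit)
  lo <- qbinom(0.005, 10000, 0.5)
  hi <- qbinom(0.995, 10000, 0.5)
  expect_true(all(counts >= lo & counts <= hi))
  expect_equal(pool$pool_freq, counts / 10000)
})

test_that("selection drives causal alleles by the logistic expectation", {
  cl <- manual_clone("chr01", 50, "causal", 0.1)
  sp <- simulate_meiosis(cl, n_spores = 10000L, seed = 7L)
  pool <- select_spores(sp, selection_generations = 34L)
  p0 <- mean(sp$inherit[, 1])
  expected <- p0 * 1.1^34 / (p0 * 1.1^34 + (1 - p0))
  expect_lt(abs(pool$pool_freq - expected), 1e-9)  # deterministic weighting
  expect_gt(pool$pool_freq, 0.95)

  # s = 0 everywhere leaves frequencies untouched
  cl0 <- manual_clone("chr01", 50, "causal", 0)
  sp0 <- simulate_meiosis(cl0, n_spores = 1000L, seed = 8L)
  pool0 <- select_spores(sp0)
  expect_equal(pool0$pool_freq, mean(sp0$inherit[, 1]))
})

test_that("a neutral hitchhiker d cM from a fully selected allele reaches 1 - r(d)", {
  cl <- manual_clone(c("chr01", "chr01"), c(40, 50),
                     c("causal", "hitchhiker"), c(3, 0))
  sp <- simulate_meiosis(cl, n_spores = 10000L, seed = 9L)
  pool <- select_spores(sp, selection_generations = 34L)
  # (1+s)^g is astronomically large, so only causal carriers remain
  expect_lt(abs(pool$pool_freq[2] - (1 - haldane_r(10))), 0.01)

  # and an unlinked neutral variant stays near 1/2
  cl2 <- manual_clone(c("chr01", "chr02"), c(40, 50),
                      c("causal", "hitchhiker"), c(3, 0))
  sp2 <- simulate_meiosis(cl2, n_spores = 10000L, seed = 10L)
  pool2 <- select_spores(sp2, selection_generations = 34L)
  expect_lt(abs(pool2$pool_freq[2] - 0.5), 0.02)
})

test_that("pooled read sampling follows the binomial error model", {
  pool <- tibble::tibble(pool_freq = rep(1, 50))
  cnt <- sample_pool_reads(pool, coverage = 90, seq_error_rate = 0,
                           seed = 1L)
  expect_equal(cnt$mutant_reads, cnt$total_reads)

  pool2 <- tibble::tibble(pool_freq = 0.5)
  cnt2 <- sample_pool_reads(pool2, coverage = 10000, seq_error_rate = 0,
                            seed = 2L)
  frac <- cnt2$mutant_reads / cnt2$total_reads
  expect_gt(frac, 0.49)
  expect_lt(frac, 0.51)

  # error model arithmetic: f = 1, e = 0.01 -> expected fraction 0.99
  pool3 <- tibble::tibble(pool_freq = rep(1, 2000))
  cnt3 <- sample_pool_reads(pool3, coverage = 90, seq_error_rate = 0.01,
                            seed = 3L)
  expect_lt(abs(sum(cnt3$mutant_reads) / sum(cnt3$total_reads) - 0.99),
            0.005)
})

test_that("depth profiles encode the clone/pool copy-number expectations", {
  set.seed(1)
  gen <- genome(c(chrA = random_seq(60000)))
  flat <- simulate_depth_profiles(gen, window_bp = 1000L, coverage = 200,
                                  seed = 4L)
  r <- depth_ratio(flat$clone, flat$ancestor)
  expect_lt(abs(mean(r$ratio) - 1), 0.05)

  ev <- tibble::tibble(chrom = "chrA", start = 20001L, end = 40000L,
                       copy_number = 2, causal = FALSE)
  prof <- simulate_depth_profiles(gen, ev, window_bp = 1000L,
                                  coverage = 200, seed = 5L)
  rc <- depth_ratio(prof$clone, prof$ancestor)
  rp <- depth_ratio(prof$pool, prof$ancestor)
  inside <- rc$start >= 20000 & rc$end <= 40000
  expect_lt(abs(mean(rc$ratio[inside]) /
                  mean(rc$ratio[!inside]) - 2), 0.15)
  expect_lt(abs(mean(rp$ratio[inside]) /
                  mean(rp$ratio[!inside]) - 1.5), 0.15)

  # causal events keep the clone copy number in the pool
  evc <- dplyr::mutate(ev, causal = TRUE)
  profc <- simulate_depth_profiles(gen, evc, window_bp = 1000L,
                                   coverage = 200, seed = 6L)
  rpc <- depth_ratio(profc$pool, profc$ancestor)
  expect_lt(abs(mean(rpc$ratio[inside]) /
                  mean(rpc$ratio[!inside]) - 2), 0.15)

  # a 3 -> 2 collapse: clone at 2/3 of the ancestral copy number
  ev23 <- tibble::tibble(chrom = "chrA", start = 20001L, end = 40000L,
                         copy_number = 2 / 3, causal = FALSE)
  p23 <- simulate_depth_profiles(gen, ev23, window_bp = 1000L,
                                 coverage = 300, seed = 7L)
  r23 <- depth_ratio(p23$clone, p23$ancestor)
  expect_lt(abs(mean(r23$ratio[inside]) /
                  mean(r23$ratio[!inside]) - 2 / 3), 0.1)

  expect_error(
    simulate_depth_profiles(
      gen, tibble::tibble(chrom = "chrA", start = c(1L, 5000L),
                          end = c(10000L, 15000L), copy_number = 2,
                          causal = FALSE)),
    "overlapping")
})

test_that("Sanger trace simulation respects the frequency-to-height map", {
  traj <- tibble::tibble(allele = "m1", time_point = 1:2, freq = c(0, 1))
  tr <- simulate_sanger_timecourse(traj, noise_sd = 0, seed = 1L)
  expect_equal(tr$h_mut[1], 0)
  expect_equal(tr$h_anc[2], 0)

  # logistic sweep recovered within 0.05 outside the clamped tails
  g <- seq(0, 250, by = 25)
  f <- 1 / (1 + exp(-0.05 * (g - 120)))
  traj2 <- tibble::tibble(allele = "m2", time_point = g, freq = f)
  tr2 <- simulate_sanger_timecourse(traj2, noise_sd = 0.02, seed = 2L)
  tc <- build_timecourse(tr2)
  mid <- f > 0.05 & f < 0.95
  expect_true(all(abs(tc$frequency[mid] - f[mid]) < 0.05))
})

test_that("the full synthetic experiment is reproducible from one seed", {
  cfg <- sim_config(seed = 31L, n_spores = 500L, n_hitchhikers = 20L)
  e1 <- simulate_bsa_experiment(cfg)
  e2 <- simulate_bsa_experiment(cfg)
  expect_identical(e1$counts, e2$counts)
})
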