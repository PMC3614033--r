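test_that("translate_codon follows the standard genetic code", {
  expect_equal(translate_codon("GAA"), "E")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("AGT"), "S")
  expect_equal(translate_codon(c("ATG", "TGA", "TAG")), c("M", "*", "*"))
  expect_error(translate_codon("GA"), "3-letter")
  expect_error(translate_codon("GAN"), "A/C/G/T")
})

test_that("signed CDS coordinates: coding positive, promoter negative, no zero", {
  g <- gene_models("G1", "chrI", "+", 1001L, 1060L, promoter_window = 500L)
  expect_equal(cds_coordinate(1001L, g), 1L)
  expect_equal(cds_coordinate(1060L, g), 60L)
  expect_equal(cds_coordinate(1000L, g), -1L)
  expect_equal(cds_coordinate(1001L - 379L, g), -379L)
  expect_equal(cds_coordinate(1001L - 500L, g), -500L)
  expect_true(is.na(cds_coordinate(1001L - 501L, g)))
  expect_true(is.na(cds_coordinate(1061L, g)))

  gm <- gene_models("G2", "chrI", "-", 1001L, 1060L, promoter_window = 500L)
  expect_equal(cds_coordinate(1060L, gm), 1L)
  expect_equal(cds_coordinate(1001L, gm), 60L)
  expect_equal(cds_coordinate(1061L, gm), -1L)
  expect_true(is.na(cds_coordinate(1060L + 501L, gm)))
})

test_that("codon index equals ceil(p/3), checked against a per-base scan", {
  p <- sample.int(3000, 200)
  expect_equal(as.integer(ceiling(p / 3)), oracle_codon_index(p))
})

test_that("coding substitutions get codon-accurate effects and names", {
  fx <- make_gene_fixture(plant = list(`235` = "GAA", `50` = "ACT"))
  # G -> T at codon 235 base 1 creates a stop
  v <- variants("chrI", fx_pos(fx, 703), "G", "T")
  a <- annotate_variants(v, fx$genome, fx$genes)
  expect_equal(a$effect_class, "nonsense")
  expect_equal(a$codon_index, 235L)
  expect_equal(a$nt_name, "703G->T")
  expect_equal(a$aa_name, "E235*")
  # ACT codon: C -> G at base 2 gives T -> S missense
  v2 <- variants("chrI", fx_pos(fx, 148L + 1L), "C", "G")
  a2 <- annotate_variants(v2, fx$genome, fx$genes)
  expect_equal(a2$effect_class, "missense")
  expect_equal(a2$aa_ref, "T")
  expect_equal(a2$aa_alt, "S")
  expect_equal(a2$aa_name, "T50S")
  # synonymous iff amino acid unchanged: GAA -> GAG is still E
  v3 <- variants("chrI", fx_pos(fx, 705), substr(fx$cds, 705, 705), "G")
  a3 <- annotate_variants(v3, fx$genome, fx$genes)
  expect_equal(a3$effect_class, "synonymous")
  expect_equal(a3$aa_ref, a3$aa_alt)
})

test_that("promoter variants use negative coordinates and the window rule", {
  fx <- make_gene_fixture()
  pos <- 601L - 379L  # 379 bp upstream of the coding start
  ref <- substr(unclass(fx$genome)[["chrI"]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  a <- annotate_variants(variants("chrI", pos, ref, alt),
                         fx$genome, fx$genes)
  expect_equal(a$region, "promoter")
  expect_equal(a$cds_pos, -379L)
  expect_equal(a$effect_class, "promoter")
  expect_equal(a$aa_name, "Promoter")
  expect_match(a$nt_name, "^-379")
  # 501 bp upstream is outside the 500 bp window -> intergenic
  pos2 <- 601L - 501L
  ref2 <- substr(unclass(fx$genome)[["chrI"]], pos2, pos2)
  a2 <- annotate_variants(variants("chrI", pos2, ref2,
                                   setdiff(c("A", "C", "G", "T"), ref2)[1]),
                          fx$genome, fx$genes)
  expect_equal(a2$effect_class, "intergenic")
})

test_that("frameshift indels scan the shifted frame for the new stop", {
  fx <- make_gene_fixture(seed = 7)
  pos <- fx_pos(fx, 675)
  ref <- substr(fx$cds, 675, 675)
  a <- annotate_variants(variants("chrI", pos, ref, ""),
                         fx$genome, fx$genes)
  expect_equal(a$effect_class, "frameshift")
  expect_equal(a$nt_name, paste0("675_675del", ref))
  # independent re-derivation: translate the deleted-frame sequence directly
  chr <- unclass(fx$genome)[["chrI"]]
  mutant <- paste0(substr(chr, 601, pos - 1),
                   substr(chr, pos + 1, nchar(chr)))
  n_cod <- nchar(mutant) %/% 3
  mut_aa <- translate_codon(substring(mutant, 3 * seq_len(n_cod) - 2,
                                      3 * seq_len(n_cod)))
  ref_aa <- translate_codon(substring(fx$cds, 3 * seq_len(300) - 2,
                                      3 * seq_len(300)))
  i <- which(ref_aa != mut_aa[seq_len(300)])[1]
  stop_at <- i - 1 + which(mut_aa[seq(i, length(mut_aa))] == "*")[1]
  expect_equal(a$aa_name, paste0(ref_aa[i], i, mut_aa[i], "fs", stop_at))
  # frameshift declared iff indel length not divisible by 3
  a3 <- annotate_variants(
    variants("chrI", pos, substr(chr, pos, pos + 2), ""),
    fx$genome, fx$genes)
  expect_equal(a3$effect_class, "missense")
})

test_that("insertions are named between their flanking CDS bases", {
  fx <- make_gene_fixture(seed = 9)
  a <- annotate_variants(variants("chrI", fx_pos(fx, 10), "", "T"),
                         fx$genome, fx$genes)
  expect_equal(a$nt_name, "10_11insT")
  expect_equal(a$effect_class, "frameshift")
})

test_that("minus-strand annotation equals the reverse-complement construct", {
  for (seed in c(11, 12, 13)) {
    fx <- make_gene_fixture(seed = seed)
    chr <- unclass(fx$genome)[["chrI"]]
    rc_gen <- genome(c(chrI = poolseg:::revcomp(chr)))
    L <- nchar(chr)
    rc_genes <- gene_models("ACE2", "chrI", "-",
                            L - fx$genes$cds_end + 1L,
                            L - fx$genes$cds_start + 1L)
    set.seed(seed)
    for (i in 1:10) {
      p <- sample.int(300 * 3, 1)
      pos <- fx_pos(fx, p)
      ref <- substr(chr, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      plus <- annotate_variants(variants("chrI", pos, ref, alt),
                                fx$genome, fx$genes)
      minus <- annotate_variants(
        variants("chrI", L - pos + 1L, chartr("ACGT", "TGCA", ref),
                 chartr("ACGT", "TGCA", alt)),
        rc_gen, rc_genes)
      expect_equal(minus$cds_pos, plus$cds_pos)
      expect_equal(minus$effect_class, plus$effect_class)
      expect_equal(minus$nt_name, plus$nt_name)
      expect_equal(minus$aa_name, plus$aa_name)
    }
  }
})

test_that("nomenclature formats round-trip through the parser", {
  fx <- make_gene_fixture(seed = 21)
  chr <- unclass(fx$genome)[["chrI"]]
  set.seed(21)
  for (i in 1:100) {
    kind <- sample(c("substitution", "deletion", "insertion"), 1)
    p <- sample.int(880, 1)
    pos <- fx_pos(fx, p)
    if (kind == "substitution") {
      ref <- substr(chr, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (kind == "deletion") {
      len <- sample.int(4, 1)
      ref <- substr(chr, pos, pos + len - 1)
      alt <- ""
    } else {
      ref <- ""
      alt <- random_seq(sample.int(4, 1))
    }
    a <- annotate_variants(variants("chrI", pos, ref, alt),
                           fx$genome, fx$genes)
    parsed <- parse_nomenclature(a$nt_name)
    expect_equal(parsed$kind, kind)
    expect_equal(parsed$start, p)
    expect_equal(parsed$ref, ref)
    expect_equal(parsed$alt, alt)
    if (kind == "deletion") expect_equal(parsed$end, p + nchar(ref) - 1L)
    if (kind == "insertion") expect_equal(parsed$end, p + 1L)
  }
})

test_that("reference mismatches against the genome are a hard error", {
  fx <- make_gene_fixture()
  pos <- fx_pos(fx, 10)
  ref <- substr(fx$cds, 10, 10)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(
    annotate_variants(variants("chrI", pos, wrong, ref),
                      fx$genome, fx$genes),
    "mismatch")
})

test_that("a CDS hit outranks another gene's promoter window", {
  # gene B starts 100 bp downstream of gene A's CDS end, so A's tail lies
  # inside B's promoter window; variants there must annotate to A
  set.seed(5)
  chr <- random_seq(3000)
  gen <- genome(c(chrI = chr))
  genes <- gene_models(c("A", "B"), "chrI", "+", c(501L, 1201L),
                       c(1100L, 1800L))
  pos <- 1050L
  ref <- substr(chr, pos, pos)
  a <- annotate_variants(
    variants("chrI", pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1]),
    gen, genes)
  expect_equal(a$gene, "A")
  expect_equal(a$region, "coding")
})
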