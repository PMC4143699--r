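test_that("rare-variant selection is strict and drops monomorphic variants", {
  ped <- founder_ped(sprintf("I%02d", 1:50))
  counts <- matrix(0L, 50, 4,
                   dimnames = list(ped$individual_id, paste0("v", 1:4)))
  gm <- gm_from_counts(counts, ped = ped)
  gm$variants$founder_maf <- c(0.009, 0.01, 0.05, 0)
  expect_equal(select_rare_variants(gm, 0.01), "v1")
  # threshold 0.5 keeps every polymorphic variant
  expect_setequal(select_rare_variants(gm, 0.5), c("v1", "v2", "v3"))
})

test_that("v0 and v1 weights match their definitions", {
  expect_equal(unname(compute_weights(c(0.1, 0.4), scheme = "v0")), c(1, 1))
  expect_equal(unname(compute_weights(0.5, scheme = "v1", zeta = 1)), 2)
  expect_equal(unname(compute_weights(0.01, scheme = "v1", zeta = 10)),
               1 / sqrt(10 * 0.01 * 0.99), tolerance = 1e-12)
  expect_equal(unname(compute_weights(0.01, scheme = "v1", zeta = 10)),
               3.17821, tolerance = 1e-5)
  # linear (unrooted) sensitivity form
  expect_equal(unname(compute_weights(0.01, scheme = "v1", zeta = 10,
                                      weight_form = "linear")),
               1 / (10 * 0.01 * 0.99), tolerance = 1e-12)
  expect_error(compute_weights(0, scheme = "v1", zeta = 10), "0 < maf < 1")
  expect_error(compute_weights(0.1, scheme = "v1"), "zeta")
  # strictly decreasing in p on (0, 0.5]
  p <- seq(0.001, 0.5, length.out = 40)
  w <- compute_weights(p, scheme = "v1", zeta = 7)
  expect_true(all(diff(w) < 0))
})

test_that("collapsing reproduces per-offspring conditional moments", {
  # two variants, weights (1, 2); parents (1,0) and (0,0); offspring (1, 0)
  ped <- family_ped("C1")
  counts <- matrix(c(1L, 0L, 1L,   # v1: F, M, C1
                     0L, 0L, 0L),  # v2
                   nrow = 3, dimnames = list(c("F", "M", "C1"), c("v1", "v2")))
  gm <- gm_from_counts(counts, ped = ped)
  nucs <- decompose_nuclear_families(ped)
  cm <- collapse_genotypes(gm, nucs, c("v1", "v2"), c(1, 2))
  expect_equal(cm$offspring$x, 1)
  expect_equal(cm$offspring$expected, 0.5)
  expect_equal(cm$offspring$variance, 0.25)
})

test_that("missing genotypes drop offspring or whole families as required", {
  ped <- family_ped(c("C1", "C2"))
  counts <- matrix(c(1L, 0L, 1L, 0L,
                     0L, 0L, NA, 0L),
                   nrow = 4, dimnames = list(c("F", "M", "C1", "C2"),
                                             c("v1", "v2")))
  gm <- gm_from_counts(counts, ped = ped)
  nucs <- decompose_nuclear_families(ped)
  # C1 misses v2: dropped from the 2-variant unit, kept for v1 alone
  cm <- collapse_genotypes(gm, nucs, c("v1", "v2"), c(1, 1))
  expect_equal(cm$offspring$offspring_id, "C2")
  expect_equal(cm$n_offspring_missing, 1L)
  cm1 <- collapse_genotypes(gm, nucs, "v1", 1)
  expect_setequal(cm1$offspring$offspring_id, c("C1", "C2"))

  # a parent missing any collapsed variant removes the whole family
  counts2 <- counts
  counts2["M", "v2"] <- NA
  gm2 <- gm_from_counts(counts2, ped = ped)
  cm2 <- collapse_genotypes(gm2, nucs, c("v1", "v2"), c(1, 1))
  expect_equal(nrow(cm2$offspring), 0L)
  expect_equal(cm2$n_families_parent_missing, 1L)
})

test_that("a single-variant v0 unit reduces to the raw single-marker test", {
  ds <- simulate_dataset(sim_config(seed = 17, n_pedigrees = 6L,
                                    generations = 3L, n_genes = 1L,
                                    variants_per_gene = 12L,
                                    rare_maf_range = c(0.02, 0.08),
                                    rare_fraction = 1, n_replicates = 1L))
  gm <- ds$genotypes
  nucs <- ds$nucs
  tr <- fbatrare:::replicate_traits(ds$pheno, 1)
  vid <- gm$variants$variant_id[which.max(gm$variants$founder_maf)]
  cfg <- fbat_config(scheme = "v0", min_informative = 1L)

  cm <- collapse_genotypes(gm, nucs, vid, 1)
  collapsed <- fbatrare:::fbat_unit_test(cm, tr, cfg, unit_name = "u")

  # raw single-marker route via the elementary building blocks
  off <- cm$offspring
  tt <- tr[off$offspring_id]
  tc <- center_trait(as.numeric(tt))
  contribs <- do.call(rbind, lapply(split(seq_len(nrow(off)), off$nuc_id),
    function(i) {
      as.data.frame(family_score_contribution(off$x[i], off$expected[i],
                                              off$variance[i], tc[i]))
    }))
  raw <- fbat_test(contribs, min_informative = 1L)
  expect_identical(collapsed$score_u, raw$score_u)
  expect_identical(collapsed$variance_v, raw$variance_v)
  expect_identical(collapsed$z, raw$z)
  expect_identical(collapsed$p, raw$p)
})

test_that("Z and p are invariant to rescaling all weights", {
  ds <- simulate_dataset(sim_config(seed = 19, n_pedigrees = 8L,
                                    generations = 3L, n_genes = 1L,
                                    variants_per_gene = 15L,
                                    rare_fraction = 1,
                                    rare_maf_range = c(0.02, 0.08),
                                    n_replicates = 1L))
  rare <- select_rare_variants(ds$genotypes, maf_threshold = 0.2)
  expect_gte(length(rare), 2L)
  maf <- ds$genotypes$variants$founder_maf[
    match(rare, ds$genotypes$variants$variant_id)]
  w <- compute_weights(setNames(maf, rare), scheme = "v1",
                       zeta = n_nuclear_families(ds$nucs))
  tr <- fbatrare:::replicate_traits(ds$pheno, 1)
  cfg <- fbat_config(min_informative = 1L)
  r1 <- fbatrare:::fbat_unit_test(
    collapse_genotypes(ds$genotypes, ds$nucs, rare, w), tr, cfg, "u")
  r2 <- fbatrare:::fbat_unit_test(
    collapse_genotypes(ds$genotypes, ds$nucs, rare, 37.5 * w), tr, cfg, "u")
  expect_equal(r1$z, r2$z, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("window tiling is disjoint, exhaustive and 0-anchored", {
  w <- tile_windows("3", 250000)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0, 1e5, 2e5))
  expect_equal(w$end, c(1e5, 2e5, 3e5))

  # a 0-based region 47,892,000-48,131,000 overlaps exactly 4 windows
  ov <- windows_overlapping(data.frame(chrom = "3", start = 47892000,
                                       end = 48131000))
  expect_equal(nrow(ov), 4L)
  expect_equal(ov$start, c(47.8e6, 47.9e6, 48.0e6, 48.1e6))

  # 1-based VCF position 100,000 is 0-based 99,999 -> window 1,
  # but the tiling still runs through the window containing coordinate 100,000
  w2 <- tile_windows("3", 100000)
  expect_equal(nrow(w2), 2L)
  expect_equal((100000L - 1L) %/% 100000L + 1L, 1L)
})

test_that("Bonferroni adjustment doubles, caps and validates", {
  expect_equal(bonferroni_adjust(1e-7, 2), 2e-7)
  expect_equal(bonferroni_adjust(0.6, 4), 1)
  expect_equal(bonferroni_adjust(0.01, 1), 0.01)
  expect_error(bonferroni_adjust(0.01, 0), "n_tests")
})

test_that("every rare variant lands in exactly one scanned window", {
  ds <- simulate_dataset(sim_config(seed = 23, n_pedigrees = 10L,
                                    generations = 3L, n_genes = 5L,
                                    variants_per_gene = 20L,
                                    gene_span = 150000L,
                                    n_replicates = 1L))
  gm <- ds$genotypes
  rare <- select_rare_variants(gm)
  tr <- fbatrare:::replicate_traits(ds$pheno, 1)
  cfg <- fbat_config(min_informative = 1L)
  scan <- window_scan(gm, ds$nucs, tr, "3", cfg)
  expect_equal(sum(scan$n_variants), length(rare))
  # each window is a distinct, disjoint unit
  expect_false(anyDuplicated(scan$unit_name) > 0)
  expect_true(all(diff(scan$start) >= 100000))
  # scan output is sorted by position, independent of input order
  perm <- sample(seq_len(nrow(gm$variants)))
  gm_perm <- genotype_matrix(gm$variants[perm, ],
                             gm$counts[, perm, drop = FALSE])
  scan2 <- window_scan(gm_perm, ds$nucs, tr, "3", cfg)
  expect_equal(scan2$unit_name, scan$unit_name)
  expect_equal(scan2$z, scan$z)
})

test_that("gene_test handles regions without usable rare variants", {
  ds <- simulate_dataset(sim_config(seed = 29, n_pedigrees = 4L,
                                    generations = 3L, n_genes = 1L,
                                    variants_per_gene = 5L,
                                    n_replicates = 1L))
  tr <- fbatrare:::replicate_traits(ds$pheno, 1)
  empty <- data.frame(chrom = "3", start = 5e6, end = 6e6, name = "desert")
  res <- gene_test(ds$genotypes, ds$nucs, tr, empty)
  expect_equal(res$status, "uninformative")
  expect_equal(res$n_variants, 0L)
  expect_true(is.na(res$p))
})
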