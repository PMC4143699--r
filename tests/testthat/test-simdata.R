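test_that("pedigree construction honours the configured shape", {
  # two generations, fixed two offspring -> one nuclear family of 2 per pedigree
  cfg <- sim_config(seed = 1, n_pedigrees = 5L, generations = 2L,
                    offspring_range = c(2L, 2L), n_genes = 1L,
                    variants_per_gene = 2L, n_replicates = 1L)
  ped <- withr::with_seed(1, simulate_pedigrees(cfg))
  nucs <- decompose_nuclear_families(ped)
  expect_equal(n_nuclear_families(nucs), 5L)
  expect_true(all(table(nucs$nuc_id) == 2L))
  expect_equal(max(ped$generation), 2L)

  # identical seeds give identical pedigrees
  ped2 <- withr::with_seed(1, simulate_pedigrees(cfg))
  expect_identical(ped, ped2)
})

test_that("gene dropping reproduces configured founder frequencies", {
  cfg <- sim_config(seed = 2, n_pedigrees = 40L, generations = 2L,
                    offspring_range = c(1L, 1L), n_genes = 1L,
                    variants_per_gene = 30L,
                    rare_fraction = 0, common_maf_range = c(0.2, 0.2),
                    n_replicates = 1L)
  ds <- simulate_dataset(cfg)
  fnd <- founders(ds$pedigree)
  expect_gte(length(fnd), 80L)
  est <- founder_minor_allele_freq(ds$genotypes, ds$pedigree)
  sd3 <- 3 * sqrt(0.2 * 0.8 / (2 * length(fnd)))
  expect_true(all(abs(est - 0.2) < sd3 + 1e-12) || mean(abs(est - 0.2) < sd3) > 0.9)
  expect_equal(count_mendelian_errors(ds$genotypes, ds$pedigree), 0L)
})

test_that("a wide gene spreads its variants across several windows", {
  genes <- data.frame(name = "BIG", chrom = "3", start = 1e6, end = 1.25e6,
                      n_variants = 40L, causal = FALSE, clustered = FALSE)
  ds <- simulate_dataset(sim_config(seed = 3, n_pedigrees = 3L,
                                    generations = 3L, genes = genes,
                                    n_replicates = 1L))
  pos0 <- ds$genotypes$variants$pos - 1L
  expect_gte(length(unique(pos0 %/% 100000L)), 3L)
})

test_that("phenotype replicates follow the declared trait model", {
  cfg <- sim_config(seed = 4, n_pedigrees = 5L, generations = 3L,
                    n_genes = 2L, variants_per_gene = 10L,
                    n_replicates = 200L)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$pheno), nrow(ds$pedigree) * 200L)
  expect_true(all(table(ds$pheno$individual_id) == 200L))

  # beta_age = 2 and no noise -> adjustment residuals vanish
  cfg0 <- sim_config(seed = 4, n_pedigrees = 5L, generations = 3L,
                     n_genes = 1L, variants_per_gene = 2L,
                     beta_age = 2, family_effect_sd = 0, residual_sd = 0,
                     n_replicates = 2L)
  ds0 <- simulate_dataset(cfg0)
  adj <- adjust_phenotype(ds0$pheno)
  expect_lt(max(abs(adj$trait)), 1e-8)

  # null model: trait uncorrelated with any variant's counts
  cfgn <- sim_config(seed = 6, n_pedigrees = 10L, generations = 3L,
                     n_genes = 1L, variants_per_gene = 10L,
                     family_effect_sd = 0, n_replicates = 1L)
  dsn <- simulate_dataset(cfgn)
  tr <- fbatrare:::replicate_traits(dsn$pheno, 1)
  n <- length(tr)
  for (j in seq_len(ncol(dsn$genotypes$counts))) {
    x <- dsn$genotypes$counts[names(tr), j]
    if (stats::sd(x) > 0) {
      expect_lt(abs(cor(tr, x)), 3 / sqrt(n) + 0.05)
    }
  }
})

test_that("injected genetic effects raise power monotonically", {
  pow <- vapply(c(0, -8, -16), function(eff) {
    cfg <- sim_config(seed = 8, n_pedigrees = 16L, generations = 4L,
                      n_genes = 1L, variants_per_gene = 40L,
                      causal_genes = "GENE001", causal_maf_cutoff = 0.0095,
                      effect_size = eff, n_replicates = 15L)
    ds <- simulate_dataset(cfg)
    ex <- run_experiment(ds, schemes = "v1",
                         power_thresholds = c(1e-4, 1e-2),
                         config = fbat_config(min_informative = 5L))
    unname(ex$power[ex$power$scheme == "v1", "0.01"])
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], pow[1])
})

test_that("scenario presets declare the advertised truth structure", {
  # null: no causal gene anywhere
  dsn <- cached_dataset("null", 11)
  expect_false(any(dsn$truth$genes$causal))
  expect_true(all(dsn$truth$variants$beta == 0))
  expect_equal(length(unique(dsn$pedigree$family_id)), 20L)

  # map4_like: 9 causal variants confined to 2 distinct windows of a
  # 4-window gene
  dsm <- cached_dataset("map4_like", 11)
  tv <- dsm$truth$variants
  cz <- tv$variant_id[tv$beta != 0]
  expect_length(cz, 9L)
  gv <- dsm$genotypes$variants
  wins <- (gv$pos[match(cz, gv$variant_id)] - 1L) %/% 100000L
  expect_equal(length(unique(wins)), 2L)
  reg <- dsm$regions[dsm$regions$name == "MAP4L", ]
  expect_equal(nrow(windows_overlapping(reg)), 4L)
  # causal variants pass the rare filter by construction
  expect_true(all(cz %in% select_rare_variants(dsm$genotypes)))

  # weight_favoring: effects only on variants with realised MAF <= 0.005
  dsw <- cached_dataset("weight_favoring", 11)
  tvw <- dsw$truth$variants
  hit <- tvw$variant_id[tvw$beta != 0]
  expect_gt(length(hit), 0L)
  mafs <- dsw$genotypes$variants$founder_maf[
    match(hit, dsw$genotypes$variants$variant_id)]
  expect_true(all(mafs > 0 & mafs <= 0.005))
  expect_error(make_gaw_like_scenario("bogus", seed = 1))
})
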