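#' Simulation configuration
#'
#' Declares a gene-dropping simulation scenario: pedigree structure,
#' variant panel, causal architecture and trait model.  The defaults
#' emulate the structure of the GAW18-style study data: 20 extended
#' pedigrees of up to 5 generations (around 1000 genotyped members in
#' total), genes carrying mostly rare variants (founder MAF below 0.01)
#' plus some common ones, and a blood-pressure-like quantitative trait
#' with sex/age/medication covariates, a shared family effect, and 200
#' phenotype replicates.
#'
#' @param seed Mandatory RNG seed; every output is reproducible from
#'   (config, seed).
#' @param n_pedigrees,generations Number of pedigrees and generation depth.
#' @param offspring_range Integer range of offspring per couple (uniform).
#' @param mate_prob Probability a non-final-generation offspring mates
#'   (bringing in an unrelated founder spouse); at least one offspring per
#'   generation always mates so every pedigree reaches the full depth.
#' @param n_genes,variants_per_gene Gene panel dimensions (used when
#'   `genes` is not supplied).
#' @param rare_fraction Fraction of variants drawn from the rare MAF range.
#' @param rare_maf_range,common_maf_range Founder MAF ranges (uniform).
#' @param chromosome Chromosome label for all genes.
#' @param gene_span,gene_spacing Gene length and spacing in bp.
#' @param causal_genes Names of causal genes (subset of the gene panel).
#' @param causal_rule `"rare_only"`: every causal-gene variant whose
#'   realised founder MAF lies in (0, `causal_maf_cutoff`\] gets effect
#'   `effect_size`; `"clustered"`: `n_causal_cluster` rare variants
#'   confined to the windows fully contained in the gene get the effect
#'   (the multi-window gene scenario).  Effects are attached against
#'   realised frequencies, as when causal variants are picked from actual
#'   sequence data.
#' @param causal_maf_cutoff,effect_size,n_causal_cluster Causal
#'   architecture knobs; `effect_size` is in trait units per minor allele.
#' @param beta0,beta_sex,beta_age,beta_med Trait model: intercept and
#'   covariate effects (sex is an indicator of male).
#' @param medication_rate,age_range Covariate generators.
#' @param family_effect_sd,residual_sd Shared within-pedigree effect and
#'   residual standard deviations (both >= 0).
#' @param n_replicates Number of phenotype replicates.
#' @param genes Optional explicit gene layout (data frame with `name`,
#'   `chrom`, `start`, `end`, `n_variants`, `causal`, `clustered`)
#'   overriding the regular panel.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_pedigrees = 20L, generations = 5L,
                       offspring_range = c(2L, 4L), mate_prob = 0.6,
                       n_genes = 50L, variants_per_gene = 30L,
                       rare_fraction = 0.85,
                       rare_maf_range = c(0.001, 0.009),
                       common_maf_range = c(0.02, 0.30),
                       chromosome = "3", gene_span = 20000L,
                       gene_spacing = 200000L,
                       causal_genes = character(),
                       causal_rule = c("rare_only", "clustered"),
                       causal_maf_cutoff = 0.005, effect_size = -6,
                       n_causal_cluster = 9L,
                       beta0 = 120, beta_sex = 0, beta_age = 0, beta_med = 0,
                       medication_rate = 0.3, age_range = c(25, 75),
                       family_effect_sd = 4, residual_sd = 8,
                       n_replicates = 200L, genes = NULL) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_pedigrees >= 1L, generations >= 2L,
            length(offspring_range) == 2L,
            offspring_range[1L] >= 1L,
            offspring_range[2L] >= offspring_range[1L],
            mate_prob >= 0, mate_prob <= 1,
            family_effect_sd >= 0, residual_sd >= 0, n_replicates >= 1L)
  if (is.null(genes)) {
    i <- seq_len(n_genes)
    start <- i * as.numeric(gene_spacing) + 10000
    genes <- data.frame(name = sprintf("GENE%03d", i), chrom = chromosome,
                        start = start, end = start + gene_span,
                        n_variants = variants_per_gene, causal = FALSE,
                        clustered = FALSE, stringsAsFactors = FALSE)
  }
  if (!all(causal_genes %in% genes$name)) {
    stop("causal_genes must be a subset of the gene panel", call. = FALSE)
  }
  genes$causal <- genes$causal | genes$name %in% causal_genes
  structure(list(seed = as.integer(seed), n_pedigrees = as.integer(n_pedigrees),
                 generations = as.integer(generations),
                 offspring_range = as.integer(offspring_range),
                 mate_prob = mate_prob, rare_fraction = rare_fraction,
                 rare_maf_range = rare_maf_range,
                 common_maf_range = common_maf_range,
                 chromosome = chromosome,
                 causal_rule = match.arg(causal_rule),
                 causal_maf_cutoff = causal_maf_cutoff,
                 effect_size = effect_size,
                 n_causal_cluster = as.integer(n_causal_cluster),
                 beta0 = beta0, beta_sex = beta_sex, beta_age = beta_age,
                 beta_med = beta_med, medication_rate = medication_rate,
                 age_range = age_range, family_effect_sd = family_effect_sd,
                 residual_sd = residual_sd,
                 n_replicates = as.integer(n_replicates), genes = genes),
            class = "sim_config")
}

# Uniform integer draw on [lo, hi] avoiding sample()'s length-1 surprise.
rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

#' Simulate GAW18-like extended pedigrees
#'
#' Builds each pedigree top-down from one founder couple: every couple has
#' a uniform number of offspring, and each non-final-generation offspring
#' mates with an unrelated incoming founder with probability
#' `cfg$mate_prob` (at least one per generation, so the configured depth is
#' always reached).
#'
#' @param cfg A [sim_config()].
#' @return A `fbat_pedigree` holding all pedigrees.
#' @export
simulate_pedigrees <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- list()
  for (f in seq_len(cfg$n_pedigrees)) {
    fam <- sprintf("F%02d", f)
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("%s_I%03d", fam, counter)
    }
    fid <- new_id(); mid <- new_id()
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = fam, individual_id = c(fid, mid),
      father_id = NA_character_, mother_id = NA_character_,
      sex = c("1", "2"), stringsAsFactors = FALSE)
    couples <- list(c(fid, mid))
    for (g in seq_len(cfg$generations - 1L)) {
      children <- character(0)
      child_sex <- integer(0)
      for (cp in couples) {
        n_off <- rint(1L, cfg$offspring_range[1L], cfg$offspring_range[2L])
        ids <- vapply(seq_len(n_off), function(i) new_id(), character(1))
        sx <- rint(n_off, 1L, 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fam, individual_id = ids, father_id = cp[1L],
          mother_id = cp[2L], sex = as.character(sx),
          stringsAsFactors = FALSE)
        children <- c(children, ids)
        child_sex <- c(child_sex, sx)
      }
      if (g == cfg$generations - 1L) break
      mates <- stats::runif(length(children)) < cfg$mate_prob
      if (!any(mates)) mates[1L] <- TRUE
      couples <- lapply(which(mates), function(i) {
        spouse <- new_id()
        spouse_sex <- if (child_sex[i] == 1L) 2L else 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          family_id = fam, individual_id = spouse,
          father_id = NA_character_, mother_id = NA_character_,
          sex = as.character(spouse_sex), stringsAsFactors = FALSE)
        if (child_sex[i] == 1L) c(children[i], spouse) else c(spouse, children[i])
      })
    }
  }
  if (length(rows) == cfg$n_pedigrees) {
    stop("configuration yields no nonfounders", call. = FALSE)
  }
  pedigree(do.call(rbind, rows))
}

# Windows fully contained in [start, end) for the clustered causal rule.
contained_windows <- function(start, end, size = 100000L) {
  first <- ceiling(start / size) * size
  starts <- seq(first, by = size, length.out = max(0, (end - first) %/% size))
  starts
}

#' Gene-drop genotypes down the simulated pedigrees
#'
#' Founder minor-allele counts are drawn binomially at each variant's
#' configured MAF; each nonfounder receives one uniformly chosen allele
#' from each parent per variant, with transmissions independent across
#' variants (no linkage disequilibrium or recombination modelling).
#' Variant positions are scattered uniformly over each gene's span.
#'
#' Causal effect sizes are assigned after gene dropping, against the
#' *realised* founder frequencies - mirroring how causal variants are
#' chosen from actual sequence data in workshop-style simulations - so a
#' causal variant is always polymorphic and always passes the rare-variant
#' filter it is meant to be discovered by.
#'
#' @param ped A `fbat_pedigree` from [simulate_pedigrees()].
#' @param cfg The [sim_config()].
#' @return List with `gm` (a [genotype_matrix()], minor allele oriented
#'   against the realised founder frequencies) and `truth` (list with
#'   `genes`: `gene`, `causal`; `variants`: `variant_id`, `gene`,
#'   `configured_maf`, `beta`).
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "fbat_pedigree"), inherits(cfg, "sim_config"))
  genes <- cfg$genes
  vlist <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    m <- g$n_variants
    pos <- sort(sample.int(g$end - g$start, m)) + g$start  # 1-based, in gene
    is_rare <- stats::runif(m) < cfg$rare_fraction
    maf <- ifelse(is_rare,
                  stats::runif(m, cfg$rare_maf_range[1L], cfg$rare_maf_range[2L]),
                  stats::runif(m, cfg$common_maf_range[1L], cfg$common_maf_range[2L]))
    data.frame(variant_id = sprintf("%s_v%03d", g$name, seq_len(m)),
               chrom = g$chrom, pos = pos, ref = "A", alt = "C",
               minor_allele = "alt", founder_maf = NA_real_,
               gene = g$name, configured_maf = maf,
               stringsAsFactors = FALSE)
  })
  vars <- do.call(rbind, vlist)

  M <- nrow(vars)
  ids <- ped$individual_id
  counts <- matrix(NA_integer_, nrow = length(ids), ncol = M,
                   dimnames = list(ids, vars$variant_id))
  fnd <- which(ped$founder)
  counts[fnd, ] <- matrix(
    stats::rbinom(length(fnd) * M, 2L, rep(vars$configured_maf, each = length(fnd))),
    nrow = length(fnd))
  for (g in sort(unique(ped$generation[!ped$founder]))) {
    for (i in which(ped$generation == g & !ped$founder)) {
      fc <- counts[ped$father_id[i], ]
      mc <- counts[ped$mother_id[i], ]
      counts[i, ] <- stats::rbinom(M, 1L, fc / 2) + stats::rbinom(M, 1L, mc / 2)
    }
  }

  gm <- orient_minor_allele(
    vars[, c("variant_id", "chrom", "pos", "ref", "alt", "minor_allele",
             "founder_maf")],
    counts, ped)

  obs_maf <- gm$variants$founder_maf
  beta <- rep(0, nrow(vars))
  for (i in which(genes$causal)) {
    g <- genes[i, ]
    idx <- which(vars$gene == g$name)
    obs <- obs_maf[idx]
    if (cfg$causal_rule == "clustered" && g$clustered) {
      # confine causal variants to the windows fully inside the gene,
      # loading about three quarters of them onto the last such window so
      # that window's causal concentration clearly exceeds the gene-wide
      # one (the pattern the window scan is designed to exploit)
      wins <- contained_windows(g$start, g$end)
      pos0 <- vars$pos[idx] - 1L
      win_of <- vapply(pos0, function(p) {
        h <- which(p >= wins & p < wins + 100000L)
        if (length(h)) h else NA_integer_
      }, integer(1))
      cand <- which(!is.na(win_of) & !is.na(obs) & obs >= 0.002 & obs < 0.01)
      n_want <- min(cfg$n_causal_cluster, length(cand))
      # deterministic: rank candidates by their realised segregation mass
      # (informative offspring per unit frequency-weight); the last window
      # takes the strongest segregators, the earlier window the weakest -
      # one window concentrates most of the causal signal, as in the
      # archetypal multi-window gene
      nonf <- ped[!ped$founder, ]
      seg_mass <- vapply(idx, function(j) {
        fh <- counts[nonf$father_id, j] == 1L
        mh <- counts[nonf$mother_id, j] == 1L
        sum(fh | mh, na.rm = TRUE)
      }, numeric(1)) / sqrt(pmax(obs * (1 - obs), 1e-12))
      last <- cand[win_of[cand] == max(win_of[cand])]
      other <- setdiff(cand, last)
      n_last <- min(length(last), round(3 / 4 * n_want))
      pick <- last[order(seg_mass[last], decreasing = TRUE)][seq_len(n_last)]
      n_rest <- min(length(other), n_want - n_last)
      if (n_rest > 0L) {
        pick <- c(pick, other[order(seg_mass[other])][seq_len(n_rest)])
      }
      beta[idx[pick]] <- cfg$effect_size
    } else {
      hit <- !is.na(obs) & obs > 0 & obs <= cfg$causal_maf_cutoff
      beta[idx[hit]] <- cfg$effect_size
    }
  }
  vars$beta <- beta

  truth <- list(
    genes = data.frame(gene = genes$name, causal = genes$causal,
                       stringsAsFactors = FALSE),
    variants = vars[, c("variant_id", "gene", "configured_maf", "beta")])
  rownames(truth$variants) <- NULL
  list(gm = gm, truth = truth)
}

#' Simulate replicated quantitative phenotypes
#'
#' Per replicate `r`:
#' `Y = beta0 + beta_sex male + beta_age age + beta_med med +
#'  sum_k beta_k x_k + a_fam + eps`, with `a_fam ~ N(0, family_effect_sd^2)`
#' shared within pedigree and `eps ~ N(0, residual_sd^2)` independent.
#' Covariates (age, medication) are drawn once; sex comes from the
#' pedigree; genotypes are fixed across replicates and only the noise is
#' redrawn.
#'
#' @param ped A `fbat_pedigree`.
#' @param gm The matching [genotype_matrix()].
#' @param truth Truth tables from [simulate_genotypes()] (per-variant
#'   effect sizes).
#' @param cfg The [sim_config()].
#' @param replicates Replicate ids (default `1:cfg$n_replicates`).
#' @return Long-format data frame: `individual_id`, `replicate`, `trait`,
#'   `sex` (male indicator), `age`, `medication`.
#' @export
simulate_phenotypes <- function(ped, gm, truth, cfg,
                                replicates = seq_len(cfg$n_replicates)) {
  stopifnot(inherits(ped, "fbat_pedigree"), inherits(cfg, "sim_config"))
  if (!length(replicates)) stop("replicates must be nonempty", call. = FALSE)
  ids <- ped$individual_id
  n <- length(ids)
  sexcov <- as.integer(ped$sex == 1L)
  age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])
  med <- stats::rbinom(n, 1L, cfg$medication_rate)

  beta <- truth$variants$beta[match(colnames(gm$counts),
                                    truth$variants$variant_id)]
  hit <- which(beta != 0)
  gval <- if (length(hit)) {
    as.numeric(gm$counts[ids, hit, drop = FALSE] %*% beta[hit])
  } else {
    numeric(n)
  }
  base <- cfg$beta0 + cfg$beta_sex * sexcov + cfg$beta_age * age +
    cfg$beta_med * med + gval

  fam_idx <- match(ped$family_id, unique(ped$family_id))
  n_fam <- max(fam_idx)
  trait <- unlist(lapply(replicates, function(r) {
    a <- stats::rnorm(n_fam, 0, cfg$family_effect_sd)[fam_idx]
    base + a + stats::rnorm(n, 0, cfg$residual_sd)
  }), use.names = FALSE)

  data.frame(individual_id = rep(ids, times = length(replicates)),
             replicate = rep(replicates, each = n),
             trait = trait,
             sex = rep(sexcov, times = length(replicates)),
             age = rep(age, times = length(replicates)),
             medication = rep(med, times = length(replicates)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete data set
#'
#' Runs pedigree construction, gene dropping and phenotype simulation under
#' a single seed; all outputs are byte-reproducible from (config, seed).
#'
#' @param cfg A [sim_config()].
#' @return A `fbat_dataset` list: `pedigree`, `nucs`, `genotypes`, `truth`,
#'   `pheno`, `regions` (BED-like gene table) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    ped <- simulate_pedigrees(cfg)
    geno <- simulate_genotypes(ped, cfg)
    pheno <- simulate_phenotypes(ped, geno$gm, geno$truth, cfg)
    structure(list(pedigree = ped,
                   nucs = decompose_nuclear_families(ped),
                   genotypes = geno$gm, truth = geno$truth, pheno = pheno,
                   regions = data.frame(chrom = cfg$genes$chrom,
                                        start = cfg$genes$start,
                                        end = cfg$genes$end,
                                        name = cfg$genes$name,
                                        stringsAsFactors = FALSE),
                   config = cfg),
              class = "fbat_dataset")
  })
}

#' Canned simulation scenarios
#'
#' * `null`: no causal gene, no covariate effects; 20 pedigrees of 4
#'   generations (about 500 members), 50 genes, 20 replicates - the size
#'   calibration scenario.
#' * `map4_like`: one 240-kb gene spanning four 100-kb windows whose 9 rare
#'   causal variants cluster in the two fully contained windows, plus 9
#'   small noncausal genes; 5-generation pedigrees, 50 replicates - the
#'   window-scan scenario.
#' * `weight_favoring`: 10 of 20 genes causal with effects confined to
#'   variants of configured MAF at most 0.005, so frequency weighting (v1)
#'   should outperform equal weighting (v0); 50 replicates.
#'
#' @param preset One of `"null"`, `"map4_like"`, `"weight_favoring"`.
#' @param seed RNG seed.
#' @param n_replicates Optional override of the preset's replicate count.
#' @return A [sim_config()].
#' @export
make_gaw_like_scenario <- function(preset = c("null", "map4_like",
                                              "weight_favoring"),
                                   seed, n_replicates = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    null = sim_config(seed = seed, generations = 4L, n_genes = 50L,
                      variants_per_gene = 30L,
                      beta_sex = 0, beta_age = 0, beta_med = 0,
                      n_replicates = 20L),
    weight_favoring = sim_config(seed = seed, generations = 5L,
                                 n_genes = 20L, variants_per_gene = 30L,
                                 causal_genes = sprintf("GENE%03d", 1:10),
                                 causal_rule = "rare_only",
                                 causal_maf_cutoff = 0.005,
                                 effect_size = -10,
                                 beta_sex = 4, beta_age = 0.3, beta_med = -5,
                                 n_replicates = 50L),
    map4_like = {
      i <- 1:9
      start <- i * 2e5 + 1e4
      small <- data.frame(name = sprintf("GENE%03d", i), chrom = "3",
                          start = start, end = start + 20000,
                          n_variants = 30L, causal = FALSE,
                          clustered = FALSE, stringsAsFactors = FALSE)
      big <- data.frame(name = "MAP4L", chrom = "3", start = 47875000,
                        end = 48115000, n_variants = 80L, causal = TRUE,
                        clustered = TRUE, stringsAsFactors = FALSE)
      sim_config(seed = seed, generations = 5L,
                 causal_rule = "clustered", n_causal_cluster = 9L,
                 effect_size = -12,
                 beta_sex = 4, beta_age = 0.3, beta_med = -5,
                 n_replicates = 50L, genes = rbind(small, big))
    })
  if (!is.null(n_replicates)) cfg$n_replicates <- as.integer(n_replicates)
  cfg
}

#' Write a simulated data set to disk
#'
#' Emits the PED pedigree, a plain-text VCF, long-format phenotype TSV,
#' truth TSVs and the BED of gene regions, all consumed unchanged by the
#' readers of this package.
#'
#' @param ds A `fbat_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "fbat_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- ds$pedigree
  paths <- c(ped = file.path(dir, "pedigree.ped"),
             vcf = file.path(dir, "genotypes.vcf"),
             pheno = file.path(dir, "phenotypes.tsv"),
             regions = file.path(dir, "regions.bed"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_variants = file.path(dir, "truth_variants.tsv"))
  pedout <- data.frame(ped$family_id, ped$individual_id,
                       ifelse(is.na(ped$father_id), "0", ped$father_id),
                       ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                       ped$sex, 0L)
  utils::write.table(pedout, paths[["ped"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_vcf(ds$genotypes, paths[["vcf"]])
  utils::write.table(ds$pheno, paths[["pheno"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$regions[, c("chrom", "start", "end", "name")],
                     paths[["regions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$truth$genes, paths[["truth_genes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$variants, paths[["truth_variants"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a long-format phenotype table
#'
#' @param path TSV with header `individual_id`, `replicate`, `trait` and
#'   covariate columns.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(individual_id = "character"))
  need <- c("individual_id", "replicate", "trait")
  if (!all(need %in% names(ph))) {
    stop("phenotype file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ph
}
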