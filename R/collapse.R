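#' Analysis configuration
#'
#' Bundles the tunable parameters of the collapsing pipeline.
#'
#' @param maf_threshold Founder MAF cut-off defining "rare"; variants with
#'   `0 < maf < maf_threshold` (strict) are collapsed.  Default 0.01.
#' @param scheme `"v1"` (frequency-weighted) or `"v0"` (unweighted).
#' @param weight_form `"sqrt"` for the Madsen-Browning reciprocal
#'   square-root weight `1/sqrt(zeta p (1-p))`; `"linear"` for the
#'   unrooted form `1/(zeta p (1-p))` kept for sensitivity checks.
#' @param variance_mode `"model"` or `"empirical"` (see [fbat_test()]).
#' @param min_informative Minimum informative families per test.
#' @param window_size Window width in bp for [window_scan()]; default
#'   100000, anchored at absolute coordinate 0.
#' @param offset A [trait_offset()] policy.
#' @return A `fbat_config` list.
#' @export
fbat_config <- function(maf_threshold = 0.01, scheme = c("v1", "v0"),
                        weight_form = c("sqrt", "linear"),
                        variance_mode = c("model", "empirical"),
                        min_informative = 10L, window_size = 100000L,
                        offset = trait_offset("sample_mean")) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5,
            window_size >= 1L, inherits(offset, "trait_offset"))
  structure(list(maf_threshold = maf_threshold,
                 scheme = match.arg(scheme),
                 weight_form = match.arg(weight_form),
                 variance_mode = match.arg(variance_mode),
                 min_informative = as.integer(min_informative),
                 window_size = as.integer(window_size),
                 offset = offset),
            class = "fbat_config")
}

#' Select rare variants by founder minor allele frequency
#'
#' Keeps variants with `0 < founder_maf < maf_threshold` (strict
#' inequality); monomorphic variants and variants with no typed founder are
#' excluded.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_threshold Frequency cut-off (default 0.01).
#' @return Character vector of variant ids.
#' @export
select_rare_variants <- function(gm, maf_threshold = 0.01) {
  maf <- gm$variants$founder_maf
  gm$variants$variant_id[!is.na(maf) & maf > 0 & maf < maf_threshold]
}

#' Collapsing weights for a set of rare variants
#'
#' v0 weights every variant equally (`w_k = 1`).  v1 follows the
#' Madsen-Browning scheme: `w_k = 1/sqrt(zeta p_k (1 - p_k))` where `zeta`
#' is the total number of nuclear families in the data set and `p_k` the
#' founder minor allele frequency, so the rarest variants get the largest
#' weights.  `weight_form = "linear"` drops the square root.
#'
#' @param maf Founder minor allele frequencies, all strictly inside (0, 1).
#' @param scheme `"v0"` or `"v1"`.
#' @param zeta Total nuclear-family count (required for v1, >= 1).
#' @param weight_form `"sqrt"` (default) or `"linear"`.
#' @return Numeric weights, named like `maf` if it has names.
#' @export
compute_weights <- function(maf, scheme = c("v1", "v0"), zeta = NULL,
                            weight_form = c("sqrt", "linear")) {
  scheme <- match.arg(scheme)
  weight_form <- match.arg(weight_form)
  if (scheme == "v0") {
    return(stats::setNames(rep(1, length(maf)), names(maf)))
  }
  if (is.null(zeta) || zeta < 1L) {
    stop("v1 weights require zeta >= 1 (total nuclear families)", call. = FALSE)
  }
  if (anyNA(maf) || any(maf <= 0 | maf >= 1)) {
    stop("v1 weights require 0 < maf < 1; filter monomorphic variants first",
         call. = FALSE)
  }
  w <- 1 / (zeta * maf * (1 - maf))
  if (weight_form == "sqrt") w <- sqrt(w)
  stats::setNames(w, names(maf))
}

#' Collapse rare variants into a weighted pseudo-marker
#'
#' Forms, for each offspring, the pseudo-count `X = sum_k w_k x_k` together
#' with its conditional mean and variance given the parental genotypes
#' (variance summed across variants under the independent-transmission
#' assumption; the empirical variance mode of [fbat_test()] bypasses that
#' assumption downstream).  A nuclear family whose father or mother is
#' missing at any collapsed variant is dropped entirely; an offspring
#' missing any collapsed variant is dropped individually.
#'
#' @param gm A [genotype_matrix()].
#' @param nucs A `nuclear_families` object.
#' @param variant_ids Variants to collapse (size M >= 1).
#' @param weights Positive weights, one per variant.
#' @return A `collapsed_marker`: list with `offspring` (data frame
#'   `offspring_id`, `nuc_id`, `x`, `expected`, `variance`), `variant_ids`,
#'   `weights`, `n_variants`, and drop counters
#'   `n_families_parent_missing`, `n_offspring_missing`.
#' @export
collapse_genotypes <- function(gm, nucs, variant_ids, weights) {
  stopifnot(inherits(nucs, "nuclear_families"),
            length(variant_ids) >= 1L,
            length(weights) == length(variant_ids),
            all(is.finite(weights)), all(weights > 0))
  C <- subset_variants(gm, variant_ids)$counts
  w <- as.numeric(weights)

  present <- nucs$offspring_id %in% rownames(C) &
    nucs$father_id %in% rownames(C) & nucs$mother_id %in% rownames(C)
  nf <- nucs[present, , drop = FALSE]

  fc <- C[nf$father_id, , drop = FALSE]
  mc <- C[nf$mother_id, , drop = FALSE]
  oc <- C[nf$offspring_id, , drop = FALSE]

  parent_ok <- !(rowSums(is.na(fc)) > 0L | rowSums(is.na(mc)) > 0L)
  n_fam_dropped <- length(unique(nf$nuc_id[!parent_ok]))
  off_ok <- parent_ok & rowSums(is.na(oc)) == 0L
  n_off_dropped <- sum(parent_ok & !off_ok)

  fc <- fc[off_ok, , drop = FALSE] / 2
  mc <- mc[off_ok, , drop = FALSE] / 2
  oc <- oc[off_ok, , drop = FALSE]

  offspring <- data.frame(
    offspring_id = nf$offspring_id[off_ok],
    nuc_id = nf$nuc_id[off_ok],
    x = as.numeric(oc %*% w),
    expected = as.numeric((fc + mc) %*% w),
    variance = as.numeric((fc * (1 - fc) + mc * (1 - mc)) %*% (w^2)),
    stringsAsFactors = FALSE)

  structure(list(offspring = offspring, variant_ids = variant_ids,
                 weights = w, n_variants = length(variant_ids),
                 n_families_parent_missing = n_fam_dropped,
                 n_offspring_missing = n_off_dropped),
            class = "collapsed_marker")
}

# Run the FBAT score test for one collapsed marker against one replicate's
# trait vector (named by individual id).
fbat_unit_test <- function(cm, traits, config, unit_name,
                           chrom = NA_character_, start = NA_integer_,
                           end = NA_integer_) {
  off <- cm$offspring
  tr <- traits[off$offspring_id]
  keep <- !is.na(tr)
  off <- off[keep, , drop = FALSE]
  tr <- as.numeric(tr[keep])

  if (nrow(off) == 0L) {
    res <- fbat_test(data.frame(u = numeric(0), v_model = numeric(0),
                                informative = logical(0)),
                     variance_mode = config$variance_mode,
                     min_informative = config$min_informative,
                     unit_name = unit_name)
  } else {
    tc <- center_trait(tr, config$offset)
    u <- rowsum(tc * (off$x - off$expected), off$nuc_id)
    v <- rowsum(tc^2 * off$variance, off$nuc_id)
    res <- fbat_test(data.frame(u = as.numeric(u), v_model = as.numeric(v),
                                informative = as.numeric(v) > 0),
                     variance_mode = config$variance_mode,
                     min_informative = config$min_informative,
                     unit_name = unit_name)
  }
  res$n_variants <- cm$n_variants
  res$chrom <- chrom
  res$start <- start
  res$end <- end
  res[, c("unit_name", "chrom", "start", "end", "n_variants",
          "n_informative_families", "score_u", "variance_v", "z", "p",
          "status")]
}

# Empty / untestable unit result with an explicit status.
empty_unit_result <- function(unit_name, chrom, start, end, status = "uninformative") {
  data.frame(unit_name = unit_name, chrom = chrom, start = start, end = end,
             n_variants = 0L, n_informative_families = 0L,
             score_u = 0, variance_v = 0, z = NA_real_, p = NA_real_,
             status = status, stringsAsFactors = FALSE)
}

#' Gene-level collapsed rare-variant test
#'
#' Runs the full pipeline for one region: select rare variants inside the
#' region (VCF positions converted to 0-based before intersection), compute
#' weights, collapse, and test.
#'
#' @param gm A [genotype_matrix()].
#' @param nucs A `nuclear_families` object (its family count is the v1
#'   `zeta`).
#' @param traits Named numeric vector of trait values (individual id ->
#'   value) for one replicate.
#' @param region One-row data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `name`.
#' @param config A [fbat_config()].
#' @return One-row result data frame (columns as in [fbat_test()], plus
#'   `chrom`, `start`, `end`); status `"uninformative"` with `n_variants =
#'   0` when the region holds no rare variant.
#' @export
gene_test <- function(gm, nucs, traits, region, config = fbat_config()) {
  region <- as.data.frame(region)
  v <- gm$variants
  inside <- v$chrom == region$chrom[1L] &
    (v$pos - 1L) >= region$start[1L] & (v$pos - 1L) < region$end[1L]
  sub_ids <- v$variant_id[inside]
  rare <- intersect(select_rare_variants(gm, config$maf_threshold), sub_ids)
  if (!length(rare)) {
    return(empty_unit_result(region$name[1L], region$chrom[1L],
                             region$start[1L], region$end[1L]))
  }
  maf <- stats::setNames(v$founder_maf[match(rare, v$variant_id)], rare)
  w <- compute_weights(maf, scheme = config$scheme,
                       zeta = n_nuclear_families(nucs),
                       weight_form = config$weight_form)
  cm <- collapse_genotypes(gm, nucs, rare, w)
  fbat_unit_test(cm, traits, config, unit_name = region$name[1L],
                 chrom = region$chrom[1L], start = region$start[1L],
                 end = region$end[1L])
}

#' Tile a chromosome into disjoint fixed-size windows
#'
#' Windows are anchored at absolute coordinate 0 (never at gene starts):
#' \[0, size), \[size, 2 size), ..., through the window containing
#' `max_position`.
#'
#' @param chromosome Chromosome label.
#' @param max_position Largest coordinate to cover (>= 1).
#' @param size Window width in bp (default 100 kb).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `id` (`"chrom:start-end"`), sorted and disjoint.
#' @export
tile_windows <- function(chromosome, max_position, size = 100000L) {
  stopifnot(max_position >= 1L, size >= 1L)
  n <- max_position %/% size + 1L
  start <- (seq_len(n) - 1L) * as.numeric(size)
  data.frame(chrom = chromosome, start = start, end = start + size,
             id = sprintf("%s:%d-%d", chromosome, start, start + size),
             stringsAsFactors = FALSE)
}

#' Disjoint-window rare-variant scan of a chromosome
#'
#' Tiles the chromosome with [tile_windows()], assigns each rare variant to
#' the window containing its 0-based position (a variant exactly on a
#' boundary belongs to the right-hand window), and runs the collapsed test
#' per variant-bearing window, exactly as [gene_test()] does for genes.
#'
#' @inheritParams gene_test
#' @param chromosome Chromosome to scan.
#' @return Result data frame with one row per tested window (window id as
#'   `unit_name`) plus a `p_bonferroni` column adjusted by the number of
#'   tested windows in the scan.  Attributes `n_windows_total`,
#'   `n_windows_tested` and `n_windows_empty` record the tiling.  Zero rows
#'   when the chromosome has no rare variants.
#' @export
window_scan <- function(gm, nucs, traits, chromosome, config = fbat_config()) {
  v <- gm$variants
  rare <- select_rare_variants(gm, config$maf_threshold)
  rare <- rare[v$chrom[match(rare, v$variant_id)] == chromosome]
  on_chrom <- v[v$chrom == chromosome, , drop = FALSE]
  if (!nrow(on_chrom) || !length(rare)) {
    out <- empty_unit_result("x", chrom = chromosome, start = 0L, end = 0L)
    out$p_bonferroni <- NA_real_
    out <- out[0L, , drop = FALSE]
    attr(out, "n_windows_total") <- 0L
    attr(out, "n_windows_tested") <- 0L
    attr(out, "n_windows_empty") <- 0L
    return(out)
  }
  wins <- tile_windows(chromosome, max(on_chrom$pos), size = config$window_size)
  pos0 <- v$pos[match(rare, v$variant_id)] - 1L
  widx <- pos0 %/% config$window_size + 1L
  tested <- sort(unique(widx))

  zeta <- n_nuclear_families(nucs)
  rows <- lapply(tested, function(i) {
    ids <- sort(rare[widx == i])
    maf <- stats::setNames(v$founder_maf[match(ids, v$variant_id)], ids)
    w <- compute_weights(maf, scheme = config$scheme, zeta = zeta,
                         weight_form = config$weight_form)
    cm <- collapse_genotypes(gm, nucs, ids, w)
    fbat_unit_test(cm, traits, config, unit_name = wins$id[i],
                   chrom = chromosome, start = wins$start[i],
                   end = wins$end[i])
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- ifelse(is.na(out$p), NA_real_,
                             pmin(1, out$p * length(tested)))
  rownames(out) <- NULL
  attr(out, "n_windows_total") <- nrow(wins)
  attr(out, "n_windows_tested") <- length(tested)
  attr(out, "n_windows_empty") <- nrow(wins) - length(tested)
  out
}

#' Bonferroni adjustment for a window scan
#'
#' `min(1, p * n_tests)`; with a gene spanning two tested windows this
#' doubles the p-value.
#'
#' @param p P-value(s) in (0, 1\].
#' @param n_tests Number of tests (>= 1); for a gene's window scan, the
#'   number of tested (variant-bearing) windows overlapping the gene.
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1L) {
    stop("n_tests must be a single integer >= 1", call. = FALSE)
  }
  stopifnot(all(p > 0 & p <= 1))
  pmin(1, p * n_tests)
}

#' Windows overlapping a region
#'
#' @param region One-row region (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param window_size Window width in bp.
#' @return Data frame of the tiling windows intersecting the region.
#' @export
windows_overlapping <- function(region, window_size = 100000L) {
  region <- as.data.frame(region)
  first <- region$start[1L] %/% window_size
  last <- (region$end[1L] - 1L) %/% window_size
  start <- (first:last) * as.numeric(window_size)
  data.frame(chrom = region$chrom[1L], start = start,
             end = start + window_size,
             id = sprintf("%s:%d-%d", region$chrom[1L], start,
                          start + window_size),
             stringsAsFactors = FALSE)
}
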