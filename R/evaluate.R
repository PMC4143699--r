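#' Fraction of replicate p-values below each threshold
#'
#' Across phenotype replicates, the power of a unit (gene or window) at
#' threshold `tau` is the fraction of its p-values strictly below `tau`.
#' Replicates where the unit is untestable (`NA` p-value: uninformative or
#' below the family threshold) count as non-detections.
#'
#' @param pvalues One p-value per replicate (`NA` allowed).
#' @param thresholds Decreasing-series thresholds; default the powers of
#'   ten 1e-7 ... 1e-4.
#' @param unit_name Label carried into the summary.
#' @return A `power_summary` list: `unit_name`, `thresholds`,
#'   `fraction_below`, `n_replicates`.
#' @export
power_at_thresholds <- function(pvalues, thresholds = 10^-(7:4),
                                unit_name = NA_character_) {
  if (!length(pvalues)) stop("no replicate p-values supplied", call. = FALSE)
  thresholds <- sort(as.numeric(thresholds))
  frac <- vapply(thresholds,
                 function(tau) sum(pvalues < tau, na.rm = TRUE) / length(pvalues),
                 numeric(1))
  structure(list(unit_name = unit_name, thresholds = thresholds,
                 fraction_below = stats::setNames(frac, as.character(thresholds)),
                 n_replicates = length(pvalues)),
            class = "power_summary")
}

#' Summary detection threshold of a unit
#'
#' The smallest threshold (tightest power of ten) at which the fraction of
#' replicate p-values below it is strictly above 0.5; `NA` when no
#' threshold qualifies (the unit is not detected).
#'
#' @param ps A `power_summary` from [power_at_thresholds()].
#' @return The qualifying threshold, or `NA_real_`.
#' @export
summary_power <- function(ps) {
  stopifnot(inherits(ps, "power_summary"))
  hit <- which(ps$fraction_below > 0.5)
  if (!length(hit)) NA_real_ else ps$thresholds[min(hit)]
}

#' Pooled type-I-error rate over noncausal tests
#'
#' Pools all noncausal unit x replicate tests; the rate at each threshold
#' is the fraction of testable results (non-`NA` p) falling strictly below
#' it.  Untestable results are excluded from the denominator.
#'
#' @param pvalues P-values of noncausal unit x replicate tests.
#' @param thresholds Thresholds to evaluate; default 1e-6 ... 1e-3.
#' @param n_units,n_replicates Optional bookkeeping counts.
#' @return A `type1_report` list: `thresholds`, `rate`, `n_tests` (testable
#'   count), `n_units`, `n_replicates`.
#' @export
type1_error_rate <- function(pvalues, thresholds = 10^-(6:3),
                             n_units = NA_integer_, n_replicates = NA_integer_) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no testable noncausal results", call. = FALSE)
  thresholds <- sort(as.numeric(thresholds))
  rate <- vapply(thresholds, function(tau) mean(p < tau), numeric(1))
  structure(list(thresholds = thresholds,
                 rate = stats::setNames(rate, as.character(thresholds)),
                 n_tests = length(p), n_units = n_units,
                 n_replicates = n_replicates),
            class = "type1_report")
}

#' Covariate-adjust a quantitative phenotype
#'
#' Replaces the trait by the residuals of an ordinary least-squares fit on
#' intercept + sex + age + medication, computed per replicate (the analogue
#' of deriving an adjusted blood-pressure trait before testing).  Constant
#' (rank-deficient) covariates are dropped with a warning; rows with
#' missing covariates are dropped with a message.
#'
#' @param pheno Long-format data frame with columns `individual_id`,
#'   `replicate`, `trait` and the covariate columns.
#' @param covariates Covariate column names (default sex, age, medication).
#' @return `pheno` with `trait` replaced by per-replicate OLS residuals.
#' @export
adjust_phenotype <- function(pheno, covariates = c("sex", "age", "medication")) {
  stopifnot(all(c("individual_id", "replicate", "trait") %in% names(pheno)),
            all(covariates %in% names(pheno)))
  ok <- stats::complete.cases(pheno[, covariates, drop = FALSE])
  if (!all(ok)) {
    message(sum(!ok), " row(s) with missing covariates dropped")
    pheno <- pheno[ok, , drop = FALSE]
  }
  # covariates are per-individual constants across replicates, so one QR
  # factorisation of the design serves every replicate
  ind <- unique(pheno[, c("individual_id", covariates), drop = FALSE])
  if (anyDuplicated(ind$individual_id)) {
    stop("covariates differ across replicates for the same individual",
         call. = FALSE)
  }
  keep <- covariates[vapply(covariates,
                            function(cv) length(unique(ind[[cv]])) > 1L,
                            logical(1))]
  if (length(keep) < length(covariates)) {
    warning("constant covariate(s) dropped: ",
            paste(setdiff(covariates, keep), collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(ind[, keep, drop = FALSE]))
  storage.mode(X) <- "double"
  qrX <- qr(X)

  Y <- matrix(NA_real_, nrow = nrow(ind),
              ncol = length(unique(pheno$replicate)),
              dimnames = list(ind$individual_id,
                              sort(unique(pheno$replicate))))
  Y[cbind(match(pheno$individual_id, ind$individual_id),
          match(pheno$replicate, colnames(Y)))] <- pheno$trait
  R <- qr.resid(qrX, Y)
  pheno$trait <- R[cbind(match(pheno$individual_id, ind$individual_id),
                         match(pheno$replicate, colnames(Y)))]
  pheno
}

# Named trait vector for one replicate.
replicate_traits <- function(pheno, r) {
  rows <- pheno$replicate == r
  stats::setNames(pheno$trait[rows], pheno$individual_id[rows])
}

#' Run the full multi-replicate power / type-I experiment
#'
#' Crosses units (gene regions) x weighting schemes x phenotype replicates,
#' reusing the collapsed pseudo-marker of each unit across replicates
#' (genotypes are fixed; only the trait changes).  Emits the full result
#' table, per-unit power summaries, and pooled plus per-unit type-I-error
#' reports over the noncausal units.
#'
#' @param dataset A `fbat_dataset` (see [simulate_dataset()]) or any list
#'   with elements `pedigree`, `genotypes`, `pheno`, `regions` and
#'   optionally `truth` (list with `genes`: data frame `gene`, `causal`).
#' @param regions Regions to test; defaults to `dataset$regions`.
#' @param schemes Weighting schemes to run (subset of `c("v0", "v1")`).
#' @param replicates Replicate ids; defaults to all present.
#' @param config A [fbat_config()]; its `scheme` field is overridden by
#'   `schemes`.
#' @param adjust Adjust the phenotype with [adjust_phenotype()] first?
#' @param causal_units Character vector naming causal units; defaults to
#'   the truth table's causal genes (empty when no truth is available).
#' @param power_thresholds,type1_thresholds Threshold grids for the two
#'   summaries.
#' @return List with `results` (unit x scheme x replicate rows), `power`
#'   (one row per unit x scheme: per-threshold fractions and the summary
#'   detection threshold), `type1` (pooled `type1_report` per scheme over
#'   noncausal units) and `type1_by_unit` (per-unit rates).
#' @export
run_experiment <- function(dataset, regions = dataset$regions,
                           schemes = c("v0", "v1"), replicates = NULL,
                           config = fbat_config(), adjust = FALSE,
                           causal_units = NULL,
                           power_thresholds = 10^-(7:4),
                           type1_thresholds = 10^-(6:3)) {
  gm <- dataset$genotypes
  ped <- dataset$pedigree
  nucs <- if (!is.null(dataset$nucs)) dataset$nucs else decompose_nuclear_families(ped)
  pheno <- dataset$pheno
  if (adjust) pheno <- adjust_phenotype(pheno)
  if (is.null(replicates)) replicates <- sort(unique(pheno$replicate))
  if (!length(replicates)) stop("no replicates to analyse", call. = FALSE)
  if (is.null(causal_units)) {
    causal_units <- if (!is.null(dataset$truth)) {
      dataset$truth$genes$gene[dataset$truth$genes$causal]
    } else {
      character(0)
    }
  }
  zeta <- n_nuclear_families(nucs)
  v <- gm$variants
  rare_all <- select_rare_variants(gm, config$maf_threshold)

  # precompute the collapsed marker of every unit x scheme once
  units <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, , drop = FALSE]
    inside <- v$chrom == reg$chrom & (v$pos - 1L) >= reg$start &
      (v$pos - 1L) < reg$end
    rare <- intersect(rare_all, v$variant_id[inside])
    cms <- lapply(stats::setNames(schemes, schemes), function(s) {
      if (!length(rare)) return(NULL)
      maf <- stats::setNames(v$founder_maf[match(rare, v$variant_id)], rare)
      w <- compute_weights(maf, scheme = s, zeta = zeta,
                           weight_form = config$weight_form)
      collapse_genotypes(gm, nucs, rare, w)
    })
    list(region = reg, markers = cms)
  })

  res <- vector("list", length(units) * length(schemes) * length(replicates))
  k <- 0L
  for (r in replicates) {
    tr <- replicate_traits(pheno, r)
    for (u in units) {
      for (s in schemes) {
        cm <- u$markers[[s]]
        row <- if (is.null(cm)) {
          empty_unit_result(u$region$name, u$region$chrom, u$region$start,
                            u$region$end)
        } else {
          fbat_unit_test(cm, tr, config, unit_name = u$region$name,
                         chrom = u$region$chrom, start = u$region$start,
                         end = u$region$end)
        }
        row$scheme <- s
        row$replicate <- r
        k <- k + 1L
        res[[k]] <- row
      }
    }
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL

  power <- do.call(rbind, lapply(unique(results$unit_name), function(un) {
    do.call(rbind, lapply(schemes, function(s) {
      p <- results$p[results$unit_name == un & results$scheme == s]
      ps <- power_at_thresholds(p, power_thresholds, unit_name = un)
      out <- data.frame(unit_name = un, scheme = s,
                        causal = un %in% causal_units,
                        n_replicates = ps$n_replicates,
                        t(ps$fraction_below), check.names = FALSE,
                        stringsAsFactors = FALSE)
      out$summary_threshold <- summary_power(ps)
      out
    }))
  }))
  rownames(power) <- NULL

  noncausal <- !(results$unit_name %in% causal_units)
  type1 <- lapply(stats::setNames(schemes, schemes), function(s) {
    p <- results$p[noncausal & results$scheme == s]
    if (all(is.na(p))) return(NULL)
    type1_error_rate(p, type1_thresholds,
                     n_units = length(unique(results$unit_name[noncausal])),
                     n_replicates = length(replicates))
  })
  type1_by_unit <- do.call(rbind, lapply(
    unique(results$unit_name[noncausal]), function(un) {
      do.call(rbind, lapply(schemes, function(s) {
        p <- results$p[results$unit_name == un & results$scheme == s]
        p <- p[!is.na(p)]
        if (!length(p)) return(NULL)
        taus <- sort(type1_thresholds)
        rates <- vapply(taus, function(tau) mean(p < tau), numeric(1))
        cbind(data.frame(unit_name = un, scheme = s, n_tests = length(p),
                         stringsAsFactors = FALSE),
              stats::setNames(as.data.frame(t(rates)), as.character(taus)))
      }))
    }))
  rownames(type1_by_unit) <- NULL

  list(results = results, power = power, type1 = type1,
       type1_by_unit = type1_by_unit, schemes = schemes, config = config,
       adjusted = adjust)
}
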