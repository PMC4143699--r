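#' Conditional offspring genotype distribution given parental genotypes
#'
#' Under independent Mendelian transmission of one allele from each parent,
#' a parent carrying `c` copies of the minor allele transmits it with
#' probability `c/2`; the offspring count is the sum of the two transmitted
#' indicators.
#'
#' @param father_count,mother_count Minor-allele counts in \{0, 1, 2\}.
#' @return An `offspring_moments` list with elements `support` (0:2),
#'   `prob`, `expected` and `variance`.
#' @export
#' @examples
#' offspring_conditional_dist(1, 1)  # het x het: 1/4, 1/2, 1/4
offspring_conditional_dist <- function(father_count, mother_count) {
  if (length(father_count) != 1L || length(mother_count) != 1L ||
      is.na(father_count) || is.na(mother_count)) {
    stop(structure(class = c("fbat_missing_parent", "error", "condition"),
                   list(message = "missing parental genotype: family is uninformative",
                        call = sys.call(-1))))
  }
  stopifnot(father_count %in% 0:2, mother_count %in% 0:2)
  tf <- father_count / 2
  tm <- mother_count / 2
  structure(list(
    support = 0:2,
    prob = c((1 - tf) * (1 - tm), tf * (1 - tm) + (1 - tf) * tm, tf * tm),
    expected = tf + tm,
    variance = tf * (1 - tf) + tm * (1 - tm)
  ), class = "offspring_moments")
}

#' Trait offset policy for the FBAT score
#'
#' The FBAT score multiplies the genotype deviation of each offspring by a
#' centred trait `T = Y - mu`.  `sample_mean` subtracts the mean trait over
#' all offspring entering the test; `fixed` subtracts a user constant.
#'
#' @param mode `"sample_mean"` or `"fixed"`.
#' @param value The constant offset, required iff `mode = "fixed"`.
#' @return A `trait_offset` object.
#' @export
trait_offset <- function(mode = c("sample_mean", "fixed"), value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(value) || !is.finite(value))) {
    stop("fixed offset requires a finite value", call. = FALSE)
  }
  if (mode == "sample_mean" && !is.null(value)) {
    stop("sample_mean offset takes no value", call. = FALSE)
  }
  structure(list(mode = mode, value = value), class = "trait_offset")
}

#' Centre trait values according to an offset policy
#'
#' @param traits Numeric trait values over the tested offspring; `NA`s are
#'   ignored when computing the sample mean and propagated in the output.
#' @param policy A [trait_offset()].
#' @return Centred values `T = Y - mu`.
#' @export
center_trait <- function(traits, policy = trait_offset("sample_mean")) {
  stopifnot(inherits(policy, "trait_offset"))
  if (all(is.na(traits))) stop("all trait values are missing", call. = FALSE)
  mu <- if (policy$mode == "fixed") policy$value else mean(traits, na.rm = TRUE)
  traits - mu
}

#' Score contribution of one nuclear family
#'
#' `u_i = sum_j T_j (X_j - E[X_j])` over the offspring of the family, with
#' model variance `v_i = sum_j T_j^2 Var(X_j)` from the conditional moments.
#' A family is informative when its model variance is positive.  Families
#' with any missing input are returned with `informative = FALSE`.
#'
#' @param genotype Offspring (pseudo-)marker values `X_j`.
#' @param expected,variance Conditional moments `E[X_j]`, `Var(X_j)` given
#'   the parental genotypes.
#' @param trait Centred traits `T_j`.
#' @return List with `u`, `v_model`, `informative`.
#' @export
family_score_contribution <- function(genotype, expected, variance, trait) {
  stopifnot(length(genotype) == length(trait),
            length(expected) == length(genotype),
            length(variance) == length(genotype))
  if (anyNA(genotype) || anyNA(expected) || anyNA(variance) || anyNA(trait)) {
    return(list(u = 0, v_model = 0, informative = FALSE))
  }
  v <- sum(trait^2 * variance)
  list(u = sum(trait * (genotype - expected)), v_model = v,
       informative = v > 0)
}

#' FBAT score test over nuclear-family contributions
#'
#' Sums family scores into `U`, forms the variance `V` either from the
#' conditional model (`sum v_i`, exact under independent transmissions) or
#' empirically (`sum u_i^2`, robust to correlated transmissions of collapsed
#' linked variants), and reports the two-sided normal p-value of
#' `Z = U / sqrt(V)`.
#'
#' @param contributions Data frame with columns `u`, `v_model`,
#'   `informative`, one row per nuclear family (see
#'   [family_score_contribution()]).
#' @param variance_mode `"model"` or `"empirical"`.
#' @param min_informative Minimum number of informative families for a
#'   reportable p-value (conventional FBAT reporting threshold).
#' @param unit_name Label (gene or window id) carried into the result.
#' @return A one-row `fbat_result` data frame with columns `unit_name`,
#'   `score_u`, `variance_v`, `z`, `p`, `n_informative_families`,
#'   `n_variants` (filled by collapsing callers) and `status` (`"ok"`,
#'   `"uninformative"` or `"below_min_families"`); `z` and `p` are `NA`
#'   unless status is `"ok"`.
#' @export
fbat_test <- function(contributions, variance_mode = c("model", "empirical"),
                      min_informative = 10L, unit_name = NA_character_) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(is.data.frame(contributions),
            all(c("u", "v_model", "informative") %in% names(contributions)),
            min_informative >= 0L)
  inf <- which(contributions$informative)
  u <- contributions$u[inf]
  U <- sum(u)
  V <- if (variance_mode == "model") sum(contributions$v_model[inf]) else sum(u^2)
  n_inf <- length(inf)

  status <- if (n_inf == 0L || V <= 0) {
    "uninformative"
  } else if (n_inf < min_informative) {
    "below_min_families"
  } else {
    "ok"
  }
  z <- p <- NA_real_
  if (status == "ok") {
    z <- U / sqrt(V)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(data.frame(unit_name = unit_name, score_u = U, variance_v = V,
                       z = z, p = p, n_informative_families = n_inf,
                       n_variants = NA_integer_, status = status,
                       stringsAsFactors = FALSE),
            class = c("fbat_result", "data.frame"))
}
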