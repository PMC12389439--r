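#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Tests observed dominant/recessive phenotype counts against an expected
#' segregation ratio (3:1 by default for an F2 of a monogenic dominant
#' trait). The statistic is the uncorrected Pearson chi-square,
#' sum((obs - exp)^2 / exp), with df = 1; no Yates continuity correction is
#' applied.
#'
#' @param n_dom,n_rec Observed counts of the dominant (papilla) and recessive
#'   (non-papilla) phenotype classes.
#' @param ratio Expected ratio as a length-2 numeric, e.g. `c(3, 1)`.
#' @return One-row tibble: `n_dom`, `n_rec`, `total`, `observed_ratio`
#'   (string, see [format_ratio()]), `expected_ratio`, `chisq`, `df`,
#'   `p_value`.
#' @examples
#' chisq_goodness_of_fit(128, 36) # F2 of 164 plants
#' @export
chisq_goodness_of_fit <- function(n_dom, n_rec, ratio = c(3, 1)) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  if (n_dom < 0 || n_rec < 0 || n_dom + n_rec == 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  ht <- stats::chisq.test(c(n_dom, n_rec), p = ratio / sum(ratio))
  tibble::tibble(
    n_dom = n_dom,
    n_rec = n_rec,
    total = n_dom + n_rec,
    observed_ratio = format_ratio(n_dom, n_rec),
    expected_ratio = sprintf("%g:%g", ratio[1], ratio[2]),
    chisq = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}

#' Segregation tests for a table of populations
#'
#' Data-frame-first wrapper around [chisq_goodness_of_fit()]: one test per
#' row, mirroring the layout of an F2 segregation table.
#'
#' @param data Data frame with one row per population.
#' @param dominant,recessive Columns holding the dominant / recessive counts
#'   (tidy-eval; defaults `papilla`, `non_papilla`).
#' @param ratio Expected ratio as a length-2 numeric.
#' @return `data` with `observed_ratio`, `expected_ratio`, `chisq`, `df` and
#'   `p_value` columns appended.
#' @examples
#' f2 <- tibble::tibble(
#'   population = c("pop1", "pop2"),
#'   papilla = c(128, 139), non_papilla = c(36, 43)
#' )
#' segregation_test(f2)
#' @export
segregation_test <- function(data, dominant = "papilla",
                             recessive = "non_papilla", ratio = c(3, 1)) {
  nd <- data[[dominant]]
  nr <- data[[recessive]]
  res <- purrr::map2_dfr(nd, nr, chisq_goodness_of_fit, ratio = ratio)
  dplyr::bind_cols(
    tibble::as_tibble(data),
    res[c("observed_ratio", "expected_ratio", "chisq", "df", "p_value")]
  )
}

#' Format an observed segregation ratio as "x.x:1"
#'
#' @param n_dom,n_rec Phenotype class counts (vectorized).
#' @return Character: dominant/recessive rounded to one decimal, e.g.
#'   `"3.6:1"`; `"all-dominant"` when the recessive count is zero.
#' @examples
#' format_ratio(128, 36)
#' @export
format_ratio <- function(n_dom, n_rec) {
  ifelse(
    n_rec == 0,
    "all-dominant",
    sprintf("%.1f:1", n_dom / ifelse(n_rec == 0, NA, n_rec))
  )
}

#' Seed water uptake as percent weight increase
#'
#' Wr = (Wa - Wb) / Wb x 100, where Wb is the dry-seed weight and Wa the
#' weight after contact with water.
#'
#' @param wet Weight after imbibition, Wa (g); must be >= `dry`.
#' @param dry Dry-seed weight, Wb (g); must be positive.
#' @return Water uptake Wr in percent (vectorized).
#' @examples
#' water_uptake(wet = 5.85, dry = 5.00) # 17 percent
#' @export
water_uptake <- function(wet, dry) {
  if (any(dry <= 0)) stop("dry weight must be positive", call. = FALSE)
  if (any(wet < dry)) stop("wet weight cannot be below dry weight", call. = FALSE)
  (wet - dry) / dry * 100
}

#' Germination fraction
#'
#' @param germinated,total Germinated and total seed counts;
#'   `0 <= germinated <= total`, `total > 0`.
#' @return `germinated / total` (vectorized).
#' @examples
#' germination_fraction(25, 100)
#' @export
germination_fraction <- function(germinated, total) {
  if (any(total <= 0)) stop("total seed count must be positive", call. = FALSE)
  if (any(germinated < 0 | germinated > total)) {
    stop("germinated count must lie in [0, total]", call. = FALSE)
  }
  germinated / total
}
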