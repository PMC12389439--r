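#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Glance at an F2 population
#'
#' @param x An `f2_population`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_markers`, `n_papilla`, `n_non_papilla`,
#'   `causal_chrom`, `causal_pos`.
#' @export
glance.f2_population <- function(x, ...) {
  tibble::tibble(
    n = ncol(x$genotype),
    n_markers = nrow(x$genotype),
    n_papilla = sum(x$phenotype == "papilla"),
    n_non_papilla = sum(x$phenotype == "non_papilla"),
    causal_chrom = if (is.na(x$spec$causal)) NA_character_ else x$spec$markers$chrom[x$spec$causal],
    causal_pos = if (is.na(x$spec$causal)) NA_integer_ else x$spec$markers$pos[x$spec$causal]
  )
}
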