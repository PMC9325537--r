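#' The twelve canonical reaction-norm expression-pattern categories
#'
#' Genes are classified on a three-way grid: whether genotypes differ in mean
#' expression across environments (differentially expressed, DE; the genotype
#' term), whether genotypes differ in their expression response to the
#' environment (differentially plastic, DP; the genotype-by-environment term),
#' and the direction of the across-genotype mean response along the gradient
#' (up, down, or none). The 2 (DE) x 2 (DP) x 3 (direction) grid yields exactly
#' twelve categories. Panel lettering in published figures is arbitrary, so the
#' package defines its own canonical ordering and label strings rather than
#' claiming a letter-for-letter correspondence.
#'
#' @return `grn_categories()` returns the twelve labels in canonical order;
#'   `grn_category_info()` returns a data frame with one row per category and
#'   columns `category`, `de`, `dp`, `direction` and `description`.
#' @examples
#' grn_categories()
#' grn_category_info()
#' @export
grn_categories <- function() {
  grn_category_info()$category
}

#' @rdname grn_categories
#' @export
grn_category_info <- function() {
  grid <- expand.grid(
    direction = c("none", "up", "down"),
    dp = c(FALSE, TRUE),
    de = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )[, c("de", "dp", "direction")]
  grid$category <- category_label(grid$de, grid$dp, grid$direction)
  grid$description <- paste0(
    ifelse(grid$de, "differentially expressed", "no mean genotype difference"),
    "; ",
    ifelse(grid$dp, "differentially plastic", "parallel response"),
    "; mean environmental response ",
    grid$direction
  )
  # canonical order: null first, then plastic-only, DE, DP, DE+DP
  ord <- order(grid$de, grid$dp, match(grid$direction, c("none", "up", "down")))
  out <- grid[ord, c("category", "de", "dp", "direction", "description")]
  rownames(out) <- NULL
  out
}

# Deterministic label for a cell of the DE x DP x direction grid. Vectorized.
category_label <- function(de, dp, direction) {
  stopifnot(all(direction %in% c("none", "up", "down")))
  base <- ifelse(
    !de & !dp, ifelse(direction == "none", "null", paste0("plastic_", direction)),
    ifelse(de & !dp,
      ifelse(direction == "none", "de", paste0("de_plastic_", direction)),
      ifelse(!de & dp, paste0("dp_mean_", direction), paste0("de_dp_mean_", direction))
    )
  )
  base
}
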