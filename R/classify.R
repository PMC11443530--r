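#' Cell typing by largest-droplet diameter
#'
#' Cells are typed by the equivalent diameter of the largest condensate they
#' contain: type 1 below `boundaries[1]` (default 1.0 um), type 2 in the
#' closed interval `[boundaries[1], boundaries[2]]` (default 1.0-3.6 um),
#' type 3 above `boundaries[2]`. Both boundary values are assigned to
#' type 2. The diameter is the equivalent diameter of the largest detected
#' cluster (area-derived in 2D, volume-derived in 3D). Cells without any
#' detected cluster are not typed; summarize them with [presence_summary].
#'
#' @param largest_d_um largest-droplet equivalent diameter(s), um; vectorized.
#' @param boundaries the two type boundaries in um, default `c(1.0, 3.6)`.
#' @return integer vector of types (1, 2 or 3).
#' @export
classify_cell <- function(largest_d_um, boundaries = c(1.0, 3.6)) {
  if (any(!is.finite(largest_d_um)) || any(largest_d_um <= 0))
    stop("largest_d_um must be positive and finite; cells without clusters ",
         "are summarized by presence_summary, not typed")
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  ifelse(largest_d_um < boundaries[1], 1L,
         ifelse(largest_d_um <= boundaries[2], 2L, 3L))
}

#' Population summary of droplet presence and cell types
#'
#' Fraction of cells containing at least one detected condensate, and the
#' type distribution among cluster-positive cells. Reported with the
#' `n = replicates/cells` convention used for live-cell population counts.
#'
#' @param largest_d_um per-cell largest-droplet diameter; `NA` marks a cell
#'   with no detected cluster.
#' @param n_replicates number of independent experiments the cells came
#'   from (for the `n = X/x` annotation; default 1).
#' @param boundaries passed to [classify_cell].
#' @return list with `n_cells`, `n_replicates`, `n_label` (the "X/x"
#'   string), `fraction_positive`, `type_counts` (named 1/2/3),
#'   `type_distribution` (proportions among positive cells) and
#'   `population_fractions` (no_cluster/type1/type2/type3, summing to 1).
#' @export
presence_summary <- function(largest_d_um, n_replicates = 1L,
                             boundaries = c(1.0, 3.6)) {
  n <- length(largest_d_um)
  if (n < 1L) stop("need at least one cell")
  pos <- !is.na(largest_d_um)
  types <- integer(0)
  if (any(pos)) types <- classify_cell(largest_d_um[pos], boundaries)
  tc <- vapply(1:3, function(k) sum(types == k), integer(1))
  names(tc) <- c("type1", "type2", "type3")
  pf <- c(no_cluster = sum(!pos), tc) / n
  list(n_cells = n, n_replicates = n_replicates,
       n_label = paste0(n_replicates, "/", n),
       fraction_positive = mean(pos),
       type_counts = tc,
       type_distribution = if (any(pos)) tc / sum(pos) else tc * NA_real_,
       population_fractions = pf)
}
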