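#' Grouped-category percentages per site
#'
#' Collapses the five Likert categories into the three grouped categories
#' (D = disagreement, N = neutral, A = agreement, per the coding's grouping
#' map) and computes, for each site and attribute, the percentage of responses
#' falling in each group. Percentages for a (site, attribute) cell sum to 100.
#'
#' @param table An `lc_survey` table.
#' @param coding A [coding_config()]; only the grouping map is used.
#' @return An `lc_grouped` object: a numeric matrix `n_sites x 24` whose
#'   columns are named `<attribute>.<group>` (groups D, N, A), with sites as
#'   row names, plus a `sites` attribute.
#' @export
group_percentages <- function(table, coding = coding_config()) {
  sites <- survey_sites(table)
  grouping <- coding$grouping
  out <- matrix(0, nrow = length(sites), ncol = 24,
                dimnames = list(sites, node_names()))
  for (s in sites) {
    sub <- table[table$site_id == s, , drop = FALSE]
    for (attr in attribute_names()) {
      g <- grouping[as.character(sub[[attr]])]
      for (grp in group_names()) {
        out[s, paste(attr, grp, sep = ".")] <- 100 * mean(g == grp)
      }
    }
  }
  structure(out, class = "lc_grouped", sites = sites)
}

#' Cross-site association matrices of grouped percentages
#'
#' For every unordered pair of the 24 grouped-category variables, computes the
#' Pearson correlation across sites, its two-sided p-value from the t
#' distribution with n-2 degrees of freedom, and both directional OLS slopes.
#' Zero-variance variables leave their pairs undefined (NA) and are excluded
#' from edge admissibility.
#'
#' @param gp An `lc_grouped` matrix from [group_percentages()].
#' @param min_sites Hard floor on the number of sites (default 5).
#' @return An `lc_assoc` object: list with 24x24 matrices `r`, `p`, `slope`
#'   (where `slope[i, j]` is the OLS slope of variable i regressed on
#'   variable j) and `n_sites`.
#' @export
association_matrices <- function(gp, min_sites = 5) {
  n <- nrow(gp)
  if (n < min_sites) {
    lc_stop("min_sites", "association matrices need at least %d sites (got %d)",
            min_sites, n)
  }
  sds <- apply(gp, 2, stats::sd)
  if (any(sds == 0)) {
    message("zero-variance variable(s): ",
            paste(colnames(gp)[sds == 0], collapse = ", "))
  }
  ok <- sds > 0
  r <- matrix(NA_real_, 24, 24, dimnames = list(colnames(gp), colnames(gp)))
  r[ok, ok] <- stats::cor(gp[, ok, drop = FALSE])
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- 0  # |r| = 1 exactly
  # slope[i, j]: regress i on j -> r * sd_i / sd_j
  slope <- r * outer(sds, sds, "/")
  diag(r) <- NA; diag(p) <- NA; diag(slope) <- NA
  structure(list(r = r, p = p, slope = slope, n_sites = n), class = "lc_assoc")
}

#' Admissible association edges
#'
#' Filters the association matrices to the edges retained by the method:
#' `|r| >= r_min` and `p < alpha`. Edges are returned sorted by descending
#' `|r|` with a deterministic tie-break (attribute order as in
#' [circumplex_attributes()], then group order D < N < A, for both endpoints).
#'
#' The magnitude `|r|` is used (rather than signed r) because strongly
#' negative correlations carry the same metric information through their
#' negative slopes.
#'
#' @param m An `lc_assoc` object.
#' @param r_min Minimum correlation magnitude (default 0.7).
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of edges: `node_x`, `node_y` (node_x ranks before
#'   node_y), `r`, `p`, `slope_y_on_x`, `slope_x_on_y`, `beta`
#'   (= `atan(slope_y_on_x)`, radians). May be empty.
#' @export
admissible_edges <- function(m, r_min = 0.7, alpha = 0.05) {
  nodes <- colnames(m$r)
  idx <- which(upper.tri(m$r), arr.ind = TRUE)
  keep <- !is.na(m$r[idx]) & abs(m$r[idx]) >= r_min & m$p[idx] < alpha
  idx <- idx[keep, , drop = FALSE]
  edges <- data.frame(
    node_x = nodes[idx[, 1]],
    node_y = nodes[idx[, 2]],
    r = m$r[idx],
    p = m$p[idx],
    slope_y_on_x = m$slope[idx[, 2:1, drop = FALSE]],
    slope_x_on_y = m$slope[idx],
    stringsAsFactors = FALSE
  )
  edges$beta <- atan(edges$slope_y_on_x)
  ord <- order(-abs(edges$r), node_rank(edges$node_x), node_rank(edges$node_y))
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
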