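#' Propagate grouped-category values through the association graph
#'
#' Builds a maximum-|r| spanning forest over the 24 grouped-category nodes
#' (Kruskal's algorithm over `|r|`, with the deterministic tie-break of
#' [admissible_edges()]) and propagates a signed value from the anchor node
#' along the unique tree paths. Traversing an edge from a valued node u to an
#' unvalued node v multiplies the value by the directional OLS slope of v on u
#' (mode `"proportional"`), or by the angle-linear factor
#' `atan(slope_v_on_u) / (pi/4)` (mode `"angle"`), which preserves sign.
#'
#' Nodes not connected to the anchor are reported as unreachable, never
#' silently defaulted. If the agreement or disagreement node of any attribute
#' is unreachable the propagation fails hard, listing the disconnected
#' attributes: pole extents are the headline output and must not be imputed.
#'
#' @param edges Edge data.frame from [admissible_edges()].
#' @param anchor_node Anchor node name (default `"pleasant.D"`).
#' @param anchor_value Anchor value (default -1).
#' @param mode `"proportional"` (default) or `"angle"`.
#' @return A list: `values` (named numeric over the 24 nodes, NA when
#'   unreachable), `unreachable` (character), `spanning_edges` (edges of the
#'   forest actually traversed, with the slope factor used), `anchor_node`,
#'   `anchor_value`, `mode`.
#' @export
propagate_values <- function(edges, anchor_node = "pleasant.D",
                             anchor_value = -1,
                             mode = c("proportional", "angle")) {
  mode <- match.arg(mode)
  nodes <- node_names()
  if (!anchor_node %in% nodes) lc_stop("config", "unknown anchor node '%s'", anchor_node)
  if (nrow(edges) == 0) lc_stop("disconnected", "empty admissible edge list")
  edges <- edges[!duplicated(edges[, c("node_x", "node_y")]), , drop = FALSE]
  ord <- order(-abs(edges$r), node_rank(edges$node_x), node_rank(edges$node_y))
  edges <- edges[ord, , drop = FALSE]

  # Kruskal: greedy max-|r| spanning forest via union-find
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  forest <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- find(node_rank(edges$node_x[k])); j <- find(node_rank(edges$node_y[k]))
    if (i != j) { parent[i] <- j; forest[k] <- TRUE }
  }
  fe <- edges[forest, , drop = FALSE]

  adj <- lapply(nodes, function(n) which(fe$node_x == n | fe$node_y == n))
  names(adj) <- nodes
  values <- stats::setNames(rep(NA_real_, 24), nodes)
  values[anchor_node] <- anchor_value
  factor_of <- function(slope) if (mode == "angle") atan(slope) / (pi / 4) else slope
  used <- data.frame()
  queue <- anchor_node
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]
    for (k in adj[[u]]) {
      v <- if (fe$node_x[k] == u) fe$node_y[k] else fe$node_x[k]
      if (!is.na(values[v])) next
      slope_v_on_u <- if (fe$node_y[k] == v) fe$slope_y_on_x[k] else fe$slope_x_on_y[k]
      values[v] <- values[u] * factor_of(slope_v_on_u)
      used <- rbind(used, data.frame(from = u, to = v, r = fe$r[k],
                                     slope = slope_v_on_u,
                                     factor = factor_of(slope_v_on_u),
                                     stringsAsFactors = FALSE))
      queue <- c(queue, v)
    }
  }
  unreachable <- nodes[is.na(values)]
  poles <- unreachable[node_group(unreachable) %in% c("A", "D")]
  if (length(poles) > 0) {
    lc_stop("disconnected",
            "pole node(s) unreachable from anchor for attribute(s): %s",
            paste(unique(node_attribute(poles)), collapse = ", "))
  }
  list(values = values, unreachable = unreachable, spanning_edges = used,
       anchor_node = anchor_node, anchor_value = anchor_value, mode = mode)
}

#' Sign of the neutral point
#'
#' Determines on which side of the barycenter the neutral point sits for one
#' attribute: `z = +1` if across sites the neutral percentage correlates at
#' least as strongly with the agreement percentage as with the disagreement
#' percentage (`r(N, A) >= r(N, D)`, raw correlations, no significance
#' filtering), else `z = -1`. An exact tie gives +1; a zero-variance neutral
#' series gives +1 with a warning.
#'
#' @param gp An `lc_grouped` matrix.
#' @param attribute Attribute name.
#' @return -1 or +1.
#' @export
neutral_sign <- function(gp, attribute) {
  nn <- gp[, paste0(attribute, ".N")]
  if (stats::sd(nn) == 0) {
    lc_warn("neutral_sign", "zero-variance neutral series for '%s'; z = +1", attribute)
    return(1)
  }
  ra <- stats::cor(nn, gp[, paste0(attribute, ".A")])
  rd <- stats::cor(nn, gp[, paste0(attribute, ".D")])
  if (is.na(ra)) ra <- 0
  if (is.na(rd)) rd <- 0
  # ties (within fp noise) resolve toward the agreement side
  if (ra >= rd - 1e-12) 1 else -1
}

#' Build one corrected-metric row from pole extents
#'
#' Given the signed agreement-pole extent `a0`, disagreement-pole extent `d0`,
#' neutral interval width `n0` (may be absent) and neutral sign `z`, derives
#' the barycenter `b = (a0 + d0) / 2` and the five corrected category values:
#' `aa = a0 - b`, `dd = d0 - b` (hence `aa = -dd`), `n = z * |b|`, and the
#' intermediate categories `d = n - n0/2`, `a = n + n0/2` when `n0` is known,
#' or the equal-range fallback `d = (n + dd)/2`, `a = (n + aa)/2` otherwise.
#'
#' The formulas above are stated in the scale's own agree-increasing frame.
#' Negative-valence attributes arrive with inverted orientation (`a0 < d0`,
#' acquired naturally through negative propagation slopes); they are oriented
#' into the agree-increasing frame, built there, and mapped back, so that the
#' corrected values are always monotone along the scale and the neutral sign
#' `z` keeps its meaning (+1 = neutral leans toward the agreement pole).
#'
#' @param a0,d0 Signed pole extents; `a0 == d0` is a degenerate scale.
#' @param n0 Neutral interval width (unsigned), or NA when unknown.
#' @param z Neutral sign, -1 or +1.
#' @return A one-row data.frame with fields `a0, d0, n0, b, z, dd, d, n, a,
#'   aa, n0_fallback_used`.
#' @export
build_correction <- function(a0, d0, n0 = NA_real_, z = 1) {
  if (!z %in% c(-1, 1)) lc_stop("config", "z must be -1 or +1")
  if (a0 == d0) lc_stop("degenerate_scale", "a0 == d0: zero scale span")
  s <- sign(a0 - d0)                      # orientation of the scale
  b <- (a0 + d0) / 2
  aa <- a0 - b
  dd <- d0 - b
  n <- s * z * abs(b)
  fallback <- is.na(n0)
  if (fallback) {
    d <- (n + dd) / 2
    a <- (n + aa) / 2
  } else {
    d <- n - s * n0 / 2
    a <- n + s * n0 / 2
  }
  data.frame(a0 = a0, d0 = d0, n0 = if (fallback) NA_real_ else n0,
             b = b, z = z, dd = dd, d = d, n = n, a = a, aa = aa,
             n0_fallback_used = fallback)
}

#' Derive the full correction table from a survey
#'
#' Runs the whole derivation pipeline: grouped percentages, cross-site
#' association matrices, edge admissibility, anchored propagation through the
#' maximum-correlation spanning forest, neutral-sign determination, and
#' per-attribute metric construction. The neutral interval width `n0` of an
#' attribute is the magnitude of its propagated neutral-node value when that
#' node is reachable; otherwise the equal-range fallback is used and flagged.
#'
#' Per-attribute checks that fail produce warnings, not errors: a corrected
#' metric whose values are not strictly monotone along the scale
#' (`lc_warning_monotonicity`), and an attribute whose strong-agree value
#' disagrees in sign with its valence polarity (`lc_warning_orientation`).
#'
#' @param table An `lc_survey` table.
#' @param coding A [coding_config()].
#' @param r_min,alpha Edge admissibility thresholds (defaults 0.7, 0.05).
#' @param anchor_node,anchor_value Propagation anchor (default pleasant.D = -1).
#' @param mode Slope-to-dilation mode, `"proportional"` or `"angle"`.
#' @param min_sites Minimum number of sites (default 5).
#' @return An `lc_correction` table with provenance (anchor, spanning edges,
#'   unreachable nodes, thresholds).
#' @export
derive_correction <- function(table, coding = coding_config(),
                              r_min = 0.7, alpha = 0.05,
                              anchor_node = "pleasant.D", anchor_value = -1,
                              mode = c("proportional", "angle"),
                              min_sites = 5) {
  mode <- match.arg(mode)
  gp <- group_percentages(table, coding)
  m <- association_matrices(gp, min_sites = min_sites)
  edges <- admissible_edges(m, r_min = r_min, alpha = alpha)
  if (nrow(edges) == 0) lc_stop("disconnected", "no admissible edges")
  prop <- propagate_values(edges, anchor_node = anchor_node,
                           anchor_value = anchor_value, mode = mode)
  rows <- lapply(attribute_names(), function(attr) {
    a0 <- prop$values[paste0(attr, ".A")]
    d0 <- prop$values[paste0(attr, ".D")]
    nv <- prop$values[paste0(attr, ".N")]
    n0 <- if (is.na(nv)) NA_real_ else abs(nv)
    z <- neutral_sign(gp, attr)
    cbind(attribute = attr, build_correction(a0, d0, n0 = n0, z = z))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  attrs <- circumplex_attributes()
  for (i in seq_len(nrow(out))) {
    vals <- unlist(out[i, c("dd", "d", "n", "a", "aa")])
    dir <- sign(out$aa[i] - out$dd[i])
    if (any(dir * diff(vals) <= 0)) {
      lc_warn("monotonicity", "corrected values for '%s' are not monotone along the scale",
              out$attribute[i])
    }
    pol <- attrs$valence_polarity[attrs$name == out$attribute[i]]
    if (sign(out$aa[i]) != pol && !out$attribute[i] %in% c("eventful", "uneventful")) {
      lc_warn("orientation", "strong-agree value of '%s' disagrees with its valence polarity",
              out$attribute[i])
    }
  }
  correction_table(out, provenance = list(
    anchor_node = anchor_node, anchor_value = anchor_value, mode = mode,
    r_min = r_min, alpha = alpha, n_sites = m$n_sites,
    spanning_edges = prop$spanning_edges, unreachable = prop$unreachable))
}

#' Project responses with a corrected metric
#'
#' Replaces each 1..5 response by its corrected category value and computes
#' the corrected circumplex coordinates. The valence (corrected pleasantness)
#' is the sum of the corrected values over the six valence-bearing attributes
#' (pleasant, annoying, vibrant, monotonous, calm, chaotic); the arousal
#' (corrected eventfulness) sums eventful, uneventful, vibrant and monotonous
#' and subtracts calm and chaotic. Each coordinate is normalised by the sum,
#' over its six attributes, of the maximum positive (sign-adjusted) corrected
#' category value, so coordinates lie in [-1, 1].
#'
#' @param table An `lc_survey` table (or data.frame with attribute columns).
#' @param ct An `lc_correction` table.
#' @return A data.frame like [project_iso()]'s but with `space = "corrected"`.
#' @export
apply_correction <- function(table, ct) {
  val <- function(attr) {
    v <- unlist(ct[attr, c("dd", "d", "n", "a", "aa")])
    v[table[[attr]]]
  }
  val_attrs <- c("pleasant", "annoying", "vibrant", "monotonous", "calm", "chaotic")
  aro_sign <- c(eventful = 1, uneventful = 1, vibrant = 1, monotonous = 1,
                calm = -1, chaotic = -1)
  max_pos <- function(attr, s = 1) max(s * unlist(ct[attr, c("dd", "d", "n", "a", "aa")]))
  norm_v <- sum(vapply(val_attrs, max_pos, numeric(1)))
  norm_a <- sum(vapply(names(aro_sign), function(a) max_pos(a, aro_sign[[a]]), numeric(1)))
  if (norm_v <= 0 || norm_a <= 0) {
    lc_stop("degenerate_correction", "non-positive coordinate normaliser")
  }
  valence <- Reduce(`+`, lapply(val_attrs, val))
  arousal <- Reduce(`+`, lapply(names(aro_sign), function(a) aro_sign[[a]] * val(a)))
  data.frame(
    site_id = if (!is.null(table$site_id)) as.character(table$site_id) else NA_character_,
    respondent_id = if (!is.null(table$respondent_id)) as.character(table$respondent_id) else NA_character_,
    pleasantness = valence / norm_v,
    eventfulness = arousal / norm_a,
    space = "corrected",
    normalized = TRUE,
    stringsAsFactors = FALSE
  )
}
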