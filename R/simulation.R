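#' Uniform-response simulation
#'
#' Draws `n` synthetic respondents whose eight attribute responses are
#' independent and uniform on the integers 1..5 — raw Likert responses that
#' uniformly cover each scale. Used to study the density that the circumplex
#' projection induces on the coordinate axes.
#'
#' @param n Number of respondents.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return An `lc_survey` table with a single site `"sim"`.
#' @export
simulate_uniform <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  rng <- local_rng(seed)
  on.exit(rng())
  resp <- matrix(sample.int(5L, n * 8L, replace = TRUE), nrow = n)
  colnames(resp) <- attribute_names()
  survey_table(data.frame(site_id = "sim",
                          respondent_id = as.character(seq_len(n)),
                          resp, stringsAsFactors = FALSE))
}

# Save/restore the global RNG around a seeded computation.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# Per-category coordinate contributions of the six attributes entering an
# axis, as a 6 x 5 matrix (rows: attributes, cols: categories 1..5), plus the
# normaliser, for either space.
axis_contributions <- function(axis = c("pleasantness", "eventfulness"),
                               space = c("iso", "corrected"), ct = NULL) {
  axis <- match.arg(axis)
  space <- match.arg(space)
  c45 <- cos(pi / 4)
  if (space == "iso") {
    w <- if (axis == "pleasantness") {
      c(pleasant = 1, annoying = -1, calm = c45, chaotic = -c45,
        vibrant = c45, monotonous = -c45)
    } else {
      c(eventful = 1, uneventful = -1, chaotic = c45, calm = -c45,
        vibrant = c45, monotonous = -c45)
    }
    contrib <- outer(w, 1:5)
    return(list(contrib = contrib, denom = 4 + sqrt(32)))
  }
  if (is.null(ct)) lc_stop("config", "corrected space requires a correction table")
  s <- if (axis == "pleasantness") {
    c(pleasant = 1, annoying = 1, vibrant = 1, monotonous = 1, calm = 1, chaotic = 1)
  } else {
    c(eventful = 1, uneventful = 1, vibrant = 1, monotonous = 1, calm = -1, chaotic = -1)
  }
  vals <- t(vapply(names(s), function(a) {
    s[[a]] * unlist(ct[a, c("dd", "d", "n", "a", "aa")])
  }, numeric(5)))
  denom <- sum(apply(vals, 1, max))
  if (denom <= 0) lc_stop("degenerate_correction", "non-positive coordinate normaliser")
  list(contrib = vals, denom = denom)
}

#' Exact tail probability of a circumplex coordinate under uniform responses
#'
#' Computes \eqn{P(\mathrm{coordinate} > t)} exactly, for iid uniform 1..5
#' responses, by full enumeration of the 5^6 = 15625 combinations of the six
#' attributes entering the chosen axis (the two attributes orthogonal to the
#' axis are marginalised out). Outcome counting is exact integer arithmetic;
#' e.g. for the ISO pleasantness axis, `exact_tail(0.6)` equals 327/15625.
#'
#' @param threshold Coordinate threshold; values outside [-1, 1] return 0 or 1.
#' @param axis `"pleasantness"` or `"eventfulness"`.
#' @param space `"iso"` or `"corrected"`.
#' @param ct Correction table, required for the corrected space.
#' @param lower If TRUE, return \eqn{P(\mathrm{coordinate} < t)} instead.
#' @return A probability.
#' @export
exact_tail <- function(threshold, axis = "pleasantness", space = "iso",
                       ct = NULL, lower = FALSE) {
  if (threshold >= 1) return(if (lower) 1 else 0)
  if (threshold <= -1) return(if (lower) 0 else 1)
  ax <- axis_contributions(axis, space, ct)
  # full enumeration of the 5^6 outcomes of the six relevant attributes
  grid <- as.matrix(expand.grid(rep(list(1:5), 6)))
  sums <- numeric(nrow(grid))
  for (i in 1:6) sums <- sums + ax$contrib[i, grid[, i]]
  coord <- sums / ax$denom
  tol <- 1e-12
  if (lower) mean(coord < threshold - tol) else mean(coord > threshold + tol)
}

#' Moments, histogram and tail fractions of projected simulated responses
#'
#' Projects every record of a survey table (ISO projection or corrected
#' projection), and summarises one axis at a time: mean, standard deviation,
#' skewness, excess kurtosis, a histogram over [-1, 1], and Monte-Carlo tail
#' fractions at the requested thresholds.
#'
#' @param table An `lc_survey` table, typically from [simulate_uniform()].
#' @param space `"iso"` or `"corrected"`.
#' @param ct Correction table for the corrected space.
#' @param thresholds Numeric vector of tail thresholds.
#' @param bins Number of histogram bins over [-1, 1] (default 50).
#' @param seed Seed recorded in the summary (not used for computation).
#' @return An `lc_simsummary` list with per-axis summaries.
#' @export
summarize_simulation <- function(table, space = "iso", ct = NULL,
                                 thresholds = numeric(), bins = 50L,
                                 seed = NA_integer_) {
  stopifnot(nrow(table) > 0)
  proj <- if (space == "iso") project_iso(table) else apply_correction(table, ct)
  edges <- seq(-1, 1, length.out = bins + 1)
  one_axis <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    zc <- (x - m) / s
    counts <- graphics::hist(pmin(pmax(x, -1), 1), breaks = edges, plot = FALSE)$counts
    list(mean = m, sd = s,
         skewness = mean(zc^3),
         excess_kurtosis = mean(zc^4) - 3,
         histogram = list(breaks = edges, counts = counts),
         tails = stats::setNames(vapply(thresholds, function(t) mean(x > t),
                                        numeric(1)),
                                 as.character(thresholds)))
  }
  structure(list(n = nrow(table), seed = seed, space = space,
                 pleasantness = one_axis(proj$pleasantness),
                 eventfulness = one_axis(proj$eventfulness)),
            class = "lc_simsummary")
}
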