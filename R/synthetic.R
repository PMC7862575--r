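#' Ground truth for synthetic multi-site surveys
#'
#' Defines the stated world of the synthetic generator: per-attribute true
#' category values (the metric the population "uses", i.e. what the
#' derivation pipeline should recover), site mean positions on the circumplex,
#' and the two noise scales.
#'
#' The distortion of attribute i is expressed as a scalar extent factor
#' `extents[i]` multiplying the equidistant base values: true values
#' `c = f * (-1, -0.5, 0, 0.5, 1)`. A compressed true metric (f < 1) means the
#' population *interprets* the category steps of that scale as wider than
#' nominal, so its latent response thresholds are the midpoints of the
#' reciprocal, interpreted positions `q = base / f`. (Placing response
#' thresholds at midpoints of the true values themselves would leave the
#' cross-site percentage slopes — the only signal the derivation sees —
#' unchanged under any f, making the truth unrecoverable by construction;
#' see the methods vignette.)
#'
#' Default geometry: site means on an elongated elliptical band (major radius
#' 0.5, minor radius 0.2) tilted 22.5 degrees from the valence axis and offset
#' toward the vibrant quadrant, with Gaussian jitter. The band emulates the
#' empirical observation that surveyed locations cluster in a narrow oblique
#' region of the circumplex; the 22.5-degree tilt keeps every attribute axis
#' at most 67.5 degrees from the band so that no attribute family is
#' orthogonal to the dominant site variation (a circular, isotropic layout
#' caps cross-attribute percentage correlations at cos 45 ~ 0.707 and the
#' admissible graph at r >= 0.7 disconnects; see the methods vignette).
#'
#' @param n_sites Number of sites (>= 5, default 30).
#' @param extents Named numeric vector of per-attribute extent factors
#'   (default all 1: equidistant truth). Unnamed scalars recycle.
#' @param base_values The equidistant base metric (strictly increasing,
#'   length 5).
#' @param band_major,band_minor Major/minor radii of the site band
#'   (defaults 0.5, 0.2).
#' @param band_angle_deg Tilt of the band's major axis from the valence axis
#'   (default 22.5).
#' @param center Circumplex position of the band's center (default
#'   `c(0.15, 0.15)`).
#' @param site_jitter SD of Gaussian jitter on site means (default 0.05).
#' @param respondent_sd SD of the bivariate Gaussian respondent noise around
#'   the site mean (default 0.15).
#' @param attribute_sd SD of the per-attribute scoring noise (default 0.15).
#' @param seed Integer seed used for the jitter (and recorded for generation).
#' @return An `lc_truth` object: list with `values` (8 x 5 matrix of true
#'   category values), `thresholds` (8 x 4 latent response thresholds),
#'   `extents`, `site_means` (n_sites x 2), `respondent_sd`, `attribute_sd`,
#'   `seed`.
#' @export
synthetic_truth <- function(n_sites = 30, extents = 1,
                            base_values = c(-1, -0.5, 0, 0.5, 1),
                            band_major = 0.5, band_minor = 0.2,
                            band_angle_deg = 22.5, center = c(0.15, 0.15),
                            site_jitter = 0.05,
                            respondent_sd = 0.15, attribute_sd = 0.15,
                            seed = 1L) {
  if (n_sites < 5) lc_stop("config", "need at least 5 sites")
  if (any(diff(base_values) <= 0) || length(base_values) != 5) {
    lc_stop("degenerate_thresholds", "base_values must be 5 strictly increasing values")
  }
  ex <- stats::setNames(rep(1, 8), attribute_names())
  if (is.null(names(extents))) ex[] <- extents
  else ex[names(extents)] <- extents
  if (any(ex <= 0)) lc_stop("config", "extents must be positive")
  values <- outer(ex, base_values)            # true metric, rows = attributes
  interpreted <- outer(1 / ex, base_values)   # positions the population reads
  thresholds <- (interpreted[, -5] + interpreted[, -1]) / 2
  rng <- local_rng(seed)
  on.exit(rng())
  angle <- seq(0, 2 * pi, length.out = n_sites + 1)[seq_len(n_sites)]
  tilt <- band_angle_deg * pi / 180
  u <- band_major * cos(angle)
  w <- band_minor * sin(angle)
  site_means <- cbind(
    valence = center[1] + u * cos(tilt) - w * sin(tilt) +
      stats::rnorm(n_sites, 0, site_jitter),
    arousal = center[2] + u * sin(tilt) + w * cos(tilt) +
      stats::rnorm(n_sites, 0, site_jitter)
  )
  structure(list(values = values, thresholds = thresholds, extents = ex,
                 site_means = site_means, respondent_sd = respondent_sd,
                 attribute_sd = attribute_sd, seed = as.integer(seed)),
            class = "lc_truth")
}

#' Generate a synthetic survey from a known truth
#'
#' For each respondent, a latent circumplex position is drawn as the site mean
#' plus bivariate Gaussian noise; for each attribute with circumplex angle
#' theta, the latent score is the projection onto the attribute's direction
#' (`valence * cos(theta) + arousal * sin(theta)`) plus attribute noise, and
#' the response is the category whose latent threshold interval (from the
#' truth) contains the score. Reproducible given the truth's seed.
#'
#' @param truth An `lc_truth` object.
#' @param respondents_per_site Number of respondents per site (>= 10).
#' @return An `lc_survey` table with sites `site01`, `site02`, ...
#' @export
generate_survey <- function(truth, respondents_per_site = 100) {
  if (respondents_per_site < 10) lc_stop("config", "need >= 10 respondents per site")
  if (any(apply(truth$thresholds, 1, function(t) any(diff(t) <= 0)))) {
    lc_stop("degenerate_thresholds", "thresholds must be strictly increasing")
  }
  rng <- local_rng(truth$seed + 1L)
  on.exit(rng())
  attrs <- circumplex_attributes()
  theta <- attrs$angle_deg * pi / 180
  n_sites <- nrow(truth$site_means)
  recs <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    v <- truth$site_means[s, 1] + stats::rnorm(respondents_per_site, 0, truth$respondent_sd)
    ar <- truth$site_means[s, 2] + stats::rnorm(respondents_per_site, 0, truth$respondent_sd)
    resp <- matrix(0L, respondents_per_site, 8, dimnames = list(NULL, attrs$name))
    for (i in 1:8) {
      score <- v * cos(theta[i]) + ar * sin(theta[i]) +
        stats::rnorm(respondents_per_site, 0, truth$attribute_sd)
      resp[, i] <- findInterval(score, truth$thresholds[i, ]) + 1L
    }
    recs[[s]] <- data.frame(site_id = sprintf("site%02d", s),
                            respondent_id = as.character(seq_len(respondents_per_site)),
                            resp, stringsAsFactors = FALSE)
  }
  survey_table(do.call(rbind, recs))
}

#' Population-level grouped percentages implied by a truth
#'
#' Computes the exact expected D/N/A percentages per site and attribute under
#' the generator's model (Gaussian respondent and attribute noise integrate in
#' closed form), using the canonical grouping (bottom two categories = D,
#' midpoint = N, top two = A). These are the percentages an infinite sample
#' per site would produce.
#'
#' @param truth An `lc_truth` object.
#' @return An `lc_grouped`-style matrix, sites x 24.
#' @export
expected_group_percentages <- function(truth) {
  attrs <- circumplex_attributes()
  theta <- attrs$angle_deg * pi / 180
  sigma <- sqrt(truth$respondent_sd^2 + truth$attribute_sd^2)
  n_sites <- nrow(truth$site_means)
  sites <- sprintf("site%02d", seq_len(n_sites))
  out <- matrix(0, n_sites, 24, dimnames = list(sites, node_names()))
  for (i in 1:8) {
    mu <- truth$site_means[, 1] * cos(theta[i]) + truth$site_means[, 2] * sin(theta[i])
    lo <- stats::pnorm((truth$thresholds[i, 2] - mu) / sigma)
    hi <- stats::pnorm((truth$thresholds[i, 3] - mu) / sigma)
    out[, paste0(attrs$name[i], ".D")] <- 100 * lo
    out[, paste0(attrs$name[i], ".N")] <- 100 * (hi - lo)
    out[, paste0(attrs$name[i], ".A")] <- 100 * (1 - hi)
  }
  structure(out, class = "lc_grouped", sites = sites)
}

#' Score recovery of a known truth by a derived correction
#'
#' Compares the 8 x 5 true category values with the derived corrected values
#' after two alignments: orientation (true values are stated in each scale's
#' own agree-increasing direction, while derived values carry circumplex
#' valence signs, so derived values are multiplied by the attribute's valence
#' polarity) and scale (both sets divided by their pleasant strong-agree
#' extent, since the derivation is anchored arbitrarily).
#'
#' @param truth An `lc_truth` object.
#' @param derived An `lc_correction` table.
#' @return A list: `correlation` (Pearson, over the 40 aligned values),
#'   `true_aligned`, `derived_aligned` (8 x 5 matrices), `extent_ratio`
#'   (named per-attribute `|aa|` ratio to pleasant's), `z_agreement` (logical
#'   per attribute: derived z equals the population-level z implied by the
#'   truth, i.e. the [neutral_sign()] rule applied to the exact expected
#'   percentages of [expected_group_percentages()]), `max_abs_deviation`
#'   (from the true aligned values).
#' @export
recovery_score <- function(truth, derived) {
  attrs <- circumplex_attributes()
  pol <- attrs$valence_polarity
  dv <- as.matrix(derived[attribute_names(), c("dd", "d", "n", "a", "aa")])
  dv <- dv * pol
  ta <- truth$values / abs(truth$values["pleasant", 5])
  da <- dv / abs(dv["pleasant", 5])
  egp <- expected_group_percentages(truth)
  z_true <- vapply(attribute_names(), function(a) neutral_sign(egp, a), numeric(1))
  list(
    correlation = stats::cor(as.vector(ta), as.vector(da)),
    true_aligned = ta,
    derived_aligned = da,
    extent_ratio = abs(dv[, 5]) / abs(dv["pleasant", 5]),
    z_agreement = stats::setNames(derived$z == z_true, attribute_names()),
    max_abs_deviation = max(abs(da - ta))
  )
}
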