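#' ISO circumplex projection
#'
#' Projects eight-attribute responses onto the two circumplex coordinates
#' (ISO Pleasantness and ISO Eventfulness). With responses \eqn{p, a, v, m,
#' ca, ch, e, u} on the canonical 1..5 coding,
#' \deqn{P = [(p-a) + \cos 45^\circ (ca-ch) + \cos 45^\circ (v-m)] / (4+\sqrt{32})}
#' \deqn{E = [(e-u) + \cos 45^\circ (ch-ca) + \cos 45^\circ (v-m)] / (4+\sqrt{32})}
#' The \eqn{1/(4+\sqrt{32})} normalisation is the unique constant scaling the
#' extreme symmetric response to exactly \eqn{\pm 1}, so both coordinates lie
#' in \eqn{[-1, 1]}.
#'
#' @param table An `lc_survey` table (or a data.frame with the eight attribute
#'   columns in canonical coding).
#' @return A data.frame with columns `site_id`, `respondent_id`,
#'   `pleasantness`, `eventfulness`, `space` (`"iso"`), `normalized` (TRUE).
#' @export
project_iso <- function(table) {
  c45 <- cos(pi / 4)
  denom <- 4 + sqrt(32)
  p <- (table$pleasant - table$annoying) +
    c45 * (table$calm - table$chaotic) +
    c45 * (table$vibrant - table$monotonous)
  e <- (table$eventful - table$uneventful) +
    c45 * (table$chaotic - table$calm) +
    c45 * (table$vibrant - table$monotonous)
  data.frame(
    site_id = if (!is.null(table$site_id)) as.character(table$site_id) else NA_character_,
    respondent_id = if (!is.null(table$respondent_id)) as.character(table$respondent_id) else NA_character_,
    pleasantness = p / denom,
    eventfulness = e / denom,
    space = "iso",
    normalized = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Per-site mean response profile
#'
#' Arithmetic mean of the canonical 1..5 responses per attribute and site
#' (the "soundscape profile" shown on radar plots).
#'
#' @param table An `lc_survey` table.
#' @return A data.frame with `site_id` and one mean column per attribute,
#'   sites in order of first appearance.
#' @export
site_mean_profile <- function(table) {
  sites <- survey_sites(table)
  prof <- do.call(rbind, lapply(sites, function(s) {
    sub <- table[table$site_id == s, attribute_names(), drop = FALSE]
    colMeans(sub)
  }))
  out <- data.frame(site_id = sites, prof, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Paired-attribute site-mean regression
#'
#' For an antiparallel attribute pair, regresses the negative attribute's site
#' means on the positive attribute's site means (ordinary least squares) and
#' reports the Pearson correlation of the two series. Under a perfectly
#' reciprocal interpretation the fit is `negative = -1 * positive + 6`.
#'
#' @param profiles Output of [site_mean_profile()].
#' @param pair A positive attribute name (`"pleasant"`, `"vibrant"`, `"calm"`,
#'   `"eventful"`); its partner is the dependent variable.
#' @return A one-row data.frame: `pair`, `r`, `intercept`, `slope`, `n_sites`.
#' @export
paired_means_fit <- function(profiles, pair) {
  attrs <- circumplex_attributes()
  if (!pair %in% attrs$name[attrs$valence_polarity == 1]) {
    lc_stop("config", "`pair` must be a positive attribute name")
  }
  neg <- attrs$partner[attrs$name == pair]
  x <- profiles[[pair]]
  y <- profiles[[neg]]
  if (length(x) < 3) lc_stop("min_sites", "paired fit needs at least 3 sites")
  if (stats::sd(x) == 0) lc_stop("undefined_fit", "constant site means for '%s'", pair)
  if (stats::sd(y) == 0) lc_stop("undefined_fit", "constant site means for '%s'", neg)
  slope <- stats::cov(x, y) / stats::var(x)
  data.frame(pair = paste(neg, "vs", pair),
             r = stats::cor(x, y),
             intercept = mean(y) - slope * mean(x),
             slope = slope,
             n_sites = length(x),
             stringsAsFactors = FALSE)
}

#' @rdname paired_means_fit
#' @export
paired_means_table <- function(profiles) {
  pos <- c("pleasant", "vibrant", "calm", "eventful")
  do.call(rbind, lapply(pos, function(p) paired_means_fit(profiles, p)))
}
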