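# fixture builders used across the suite

# survey table from a responses matrix (rows = respondents, cols = attributes)
make_survey <- function(responses, site_id = "s1") {
  responses <- as.data.frame(responses)
  names(responses) <- attribute_names()
  survey_table(data.frame(
    site_id = rep_len(site_id, nrow(responses)),
    respondent_id = as.character(seq_len(nrow(responses))),
    responses, stringsAsFactors = FALSE))
}

# one record with every attribute at `fill`, selected attributes overridden
make_record <- function(..., fill = 3L) {
  resp <- stats::setNames(rep(fill, 8), attribute_names())
  over <- list(...)
  resp[names(over)] <- unlist(over)
  make_survey(matrix(resp, nrow = 1))
}

random_survey <- function(n, seed) {
  set.seed(seed)
  make_survey(matrix(sample.int(5L, n * 8L, replace = TRUE), ncol = 8))
}

# symmetric equidistant correction table in circumplex orientation:
# positive attributes run -1..1, negative attributes 1..-1
identity_correction <- function() {
  attrs <- circumplex_attributes()
  rows <- lapply(seq_len(8), function(i) {
    s <- attrs$valence_polarity[i]
    data.frame(attribute = attrs$name[i], a0 = s, d0 = -s, n0 = 1, b = 0,
               z = 1, dd = -0.5 * s * 2, d = -0.5 * s, n = 0, a = 0.5 * s,
               aa = s, n0_fallback_used = FALSE, stringsAsFactors = FALSE)
  })
  correction_table(do.call(rbind, rows))
}

# grouped-percentage matrix from raw columns (filling D/N/A consistently)
make_gp <- function(columns, n_sites) {
  m <- matrix(50, nrow = n_sites, ncol = 24,
              dimnames = list(sprintf("s%02d", seq_len(n_sites)), likertcirc:::node_names()))
  for (nm in names(columns)) m[, nm] <- columns[[nm]]
  structure(m, class = "lc_grouped", sites = rownames(m))
}

write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
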