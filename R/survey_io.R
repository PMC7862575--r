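#' Construct and validate a survey table
#'
#' A survey table holds one row per respondent with a site identifier, a
#' respondent identifier, and one canonical five-point category per perceptual
#' attribute (1 = strongly disagree ... 5 = strongly agree).
#'
#' @param data A data.frame with columns `site_id`, `respondent_id` and one
#'   column per attribute in [attribute_names()]. Extra columns are dropped.
#' @return The validated data.frame with class `lc_survey`.
#' @export
survey_table <- function(data) {
  need <- c("site_id", "respondent_id", attribute_names())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    lc_stop("missing_column", "missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(data) == 0) lc_stop("empty_file", "survey table has no records")
  out <- data[, need]
  out$site_id <- as.character(out$site_id)
  out$respondent_id <- as.character(out$respondent_id)
  for (a in attribute_names()) {
    v <- out[[a]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != as.integer(v))) {
      lc_stop("non_integer", "attribute '%s' has non-integer or missing responses", a)
    }
    if (any(v < 1 | v > 5)) {
      lc_stop("out_of_range", "attribute '%s' has categories outside 1..5", a)
    }
    out[[a]] <- as.integer(v)
  }
  rownames(out) <- NULL
  class(out) <- c("lc_survey", "data.frame")
  out
}

#' @rdname survey_table
#' @export
survey_sites <- function(table) unique(table$site_id)

#' Read a survey CSV
#'
#' Reads a comma-separated survey file with header
#' `site_id,respondent_id,pleasant,annoying,vibrant,monotonous,calm,chaotic,eventful,uneventful`
#' and converts responses to the canonical coding (5 = strongly agree)
#' according to `coding`. Extra columns (e.g. demographics) are ignored with a
#' message; row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param coding A [coding_config()] describing the raw cell coding.
#' @return An `lc_survey` table.
#' @export
read_survey_table <- function(path, coding = coding_config()) {
  if (!file.exists(path)) lc_stop("empty_file", "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) lc_stop("empty_file", "no survey records in %s", path)
  need <- c("site_id", "respondent_id", attribute_names())
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    lc_stop("missing_column", "missing column(s): %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), need)
  if (length(extra) > 0) {
    message("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  for (a in attribute_names()) {
    raw[[a]] <- decode_column(raw[[a]], coding, a)
  }
  survey_table(raw)
}

decode_column <- function(x, coding, attr) {
  x <- trimws(x)
  if (coding$input_coding == "labels") {
    idx <- match(tolower(x), tolower(names(coding$labels)))
    if (anyNA(idx)) {
      bad <- unique(x[is.na(idx)])
      lc_stop("unknown_label", "attribute '%s': unknown label(s): %s",
              attr, paste(utils::head(bad, 3), collapse = ", "))
    }
    return(as.integer(coding$labels[idx]))
  }
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v) || any(v != as.integer(v))) {
    lc_stop("non_integer", "attribute '%s' has non-integer responses", attr)
  }
  v <- as.integer(v)
  if (any(v < 1L | v > 5L)) {
    lc_stop("out_of_range", "attribute '%s' has categories outside 1..5", attr)
  }
  if (coding$input_coding == "agree_low") v <- 6L - v
  v
}

#' Write a survey table to CSV
#'
#' @param table An `lc_survey` table.
#' @param path Output path.
#' @export
write_survey_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- correction table I/O ----------------------------------------------------

ct_fields <- function() c("a0", "d0", "n0", "b", "z", "dd", "d", "n", "a", "aa",
                          "n0_fallback_used")

#' Construct and validate a correction table
#'
#' A correction table holds, per attribute, the derived pole extents `a0`
#' (agreement) and `d0` (disagreement), the neutral interval width `n0` (NA
#' when no neutral information was recovered), the barycenter `b`, the neutral
#' sign `z`, and the five corrected category values `dd`, `d`, `n`, `a`, `aa`.
#'
#' @param data A data.frame with a row per attribute (column `attribute`) and
#'   the columns listed above plus logical `n0_fallback_used`.
#' @param provenance Optional list recording the anchor and edges used.
#' @return The data.frame with class `lc_correction`.
#' @export
correction_table <- function(data, provenance = NULL) {
  need <- c("attribute", ct_fields())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    lc_stop("malformed_correction", "correction table missing field(s): %s",
            paste(missing, collapse = ", "))
  }
  missing_attr <- setdiff(attribute_names(), data$attribute)
  if (length(missing_attr) > 0) {
    lc_stop("malformed_correction", "correction table missing attribute(s): %s",
            paste(missing_attr, collapse = ", "))
  }
  data <- data[match(attribute_names(), data$attribute), need]
  if (!all(abs(data$z) == 1)) {
    lc_stop("malformed_correction", "z must be -1 or +1")
  }
  # negative-valence attributes legitimately run aa < dd (circumplex-signed
  # values); warn only when an attribute's strong-agree sign contradicts its
  # valence polarity (eventful/uneventful are arousal-oriented and skipped)
  attrs <- circumplex_attributes()
  chk <- !data$attribute %in% c("eventful", "uneventful")
  pol <- attrs$valence_polarity[match(data$attribute, attrs$name)]
  bad <- chk & data$aa * pol < 0
  if (any(bad)) {
    lc_warn("orientation", "attribute(s) with inverted orientation: %s",
            paste(data$attribute[bad], collapse = ", "))
  }
  rownames(data) <- data$attribute
  structure(data, class = c("lc_correction", "data.frame"),
            provenance = provenance)
}

#' Write / read a correction table as JSON
#'
#' The JSON layout is one object per attribute with keys
#' `a0,d0,n0,b,z,dd,d,n,a,aa,n0_fallback_used` (`n0` may be null). A
#' write/read round trip is value identical.
#'
#' @param ct An `lc_correction` table.
#' @param path File path.
#' @export
write_correction_table <- function(ct, path) {
  rows <- lapply(seq_len(nrow(ct)), function(i) {
    row <- as.list(ct[i, ct_fields()])
    if (is.na(row$n0)) row["n0"] <- list(NULL)
    row
  })
  names(rows) <- ct$attribute
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_correction_table
#' @export
read_correction_table <- function(path) {
  if (!file.exists(path)) lc_stop("malformed_correction", "file not found: %s", path)
  rows <- jsonlite::read_json(path)
  recs <- lapply(names(rows), function(attr) {
    row <- rows[[attr]]
    missing <- setdiff(ct_fields(), names(row))
    if (length(missing) > 0) {
      lc_stop("malformed_correction", "attribute '%s' missing field(s): %s",
              attr, paste(missing, collapse = ", "))
    }
    n0 <- if (is.null(row$n0)) NA_real_ else as.numeric(row$n0)
    data.frame(attribute = attr, a0 = as.numeric(row$a0), d0 = as.numeric(row$d0),
               n0 = n0, b = as.numeric(row$b), z = as.numeric(row$z),
               dd = as.numeric(row$dd), d = as.numeric(row$d),
               n = as.numeric(row$n), a = as.numeric(row$a),
               aa = as.numeric(row$aa),
               n0_fallback_used = as.logical(row$n0_fallback_used),
               stringsAsFactors = FALSE)
  })
  correction_table(do.call(rbind, recs))
}
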