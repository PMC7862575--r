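#' The eight circumplex perceptual attributes
#'
#' Returns the canonical attribute set used throughout the package: the eight
#' perceptual attributes of the soundscape circumplex, their angular position
#' (degrees, counter-clockwise from the positive valence axis), their valence
#' polarity, and their opposing partner attribute.
#'
#' Attributes come in four antiparallel pairs (pleasant--annoying,
#' vibrant--monotonous, calm--chaotic, eventful--uneventful); partner angles
#' differ by 180 degrees.
#'
#' @return A data.frame with columns `name`, `angle_deg`, `valence_polarity`
#'   (+1 or -1) and `partner`, one row per attribute, in canonical order.
#' @export
#' @examples
#' circumplex_attributes()
circumplex_attributes <- function() {
  data.frame(
    name = c("pleasant", "annoying", "vibrant", "monotonous",
             "calm", "chaotic", "eventful", "uneventful"),
    angle_deg = c(0, 180, 45, 225, 315, 135, 90, 270),
    valence_polarity = c(1L, -1L, 1L, -1L, 1L, -1L, 1L, -1L),
    partner = c("annoying", "pleasant", "monotonous", "vibrant",
                "chaotic", "calm", "uneventful", "eventful"),
    stringsAsFactors = FALSE
  )
}

#' @rdname circumplex_attributes
#' @export
attribute_names <- function() circumplex_attributes()$name

# canonical grouped-category labels, in fixed order
group_names <- function() c("D", "N", "A")

# the 24 grouped-category variable names, attribute-major, groups D < N < A
node_names <- function() {
  as.vector(t(outer(attribute_names(), group_names(), paste, sep = ".")))
}

node_attribute <- function(node) sub("\\.[DNA]$", "", node)
node_group <- function(node) sub("^.*\\.", "", node)

# deterministic rank of a node: attribute order as in circumplex_attributes(),
# then group order D < N < A
node_rank <- function(node) match(node, node_names())

#' Survey coding configuration
#'
#' Describes how raw survey cells map to the canonical category coding
#' (1 = strongly disagree ... 5 = strongly agree) and how categories collapse
#' into the three grouped categories D (disagreement), N (neutral),
#' A (agreement).
#'
#' @param input_coding Either `"agree_high"` (raw integers already canonical,
#'   5 = strongly agree), `"agree_low"` (raw 1 = strongly agree; canonical
#'   value is `6 - raw`), or `"labels"` (cells are text labels translated via
#'   `labels`).
#' @param labels Named integer vector mapping text labels to canonical
#'   categories in 1..5. Required when `input_coding = "labels"`. A default
#'   English label map is supplied.
#' @param grouping Named integer/character map from category (as character
#'   "1".."5") to group in `c("D","N","A")`. Must cover all five categories
#'   and assign exactly one category to N.
#' @return An object of class `lc_coding`.
#' @export
coding_config <- function(input_coding = c("agree_high", "agree_low", "labels"),
                          labels = default_labels(),
                          grouping = default_grouping()) {
  input_coding <- match.arg(input_coding)
  if (input_coding == "labels") {
    if (is.null(names(labels)) || !all(labels %in% 1:5)) {
      lc_stop("config", "`labels` must be a named vector with values in 1..5")
    }
  }
  grouping <- vapply(grouping, as.character, character(1))
  if (!setequal(names(grouping), as.character(1:5))) {
    lc_stop("config", "`grouping` must map every category \"1\"..\"5\"")
  }
  if (!all(grouping %in% group_names())) {
    lc_stop("config", "`grouping` values must be in {D, N, A}")
  }
  if (sum(grouping == "N") != 1L) {
    lc_stop("config", "exactly one category must map to the neutral group N")
  }
  structure(list(input_coding = input_coding, labels = labels,
                 grouping = grouping[as.character(1:5)]),
            class = "lc_coding")
}

#' @rdname coding_config
#' @export
default_labels <- function() {
  c("strongly disagree" = 1L, "somewhat disagree" = 2L, "disagree" = 2L,
    "neither agree nor disagree" = 3L, "neutral" = 3L,
    "somewhat agree" = 4L, "agree" = 4L, "strongly agree" = 5L)
}

#' @rdname coding_config
#' @export
default_grouping <- function() {
  c("1" = "D", "2" = "D", "3" = "N", "4" = "A", "5" = "A")
}

# --- condition helpers -------------------------------------------------------

lc_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("lc_error_", class), "lc_error")))
}

lc_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("lc_warning_", class), "lc_warning")))
}
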