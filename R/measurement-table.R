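#' Names of the 19 facial landmarks
#'
#' Standard frontal-photograph anthropometric points used by the default
#' measurement table. The two iris centers are carried separately (they
#' define the normalization, not a landmark), giving 19 landmarks + 2 iris
#' points per photo.
#'
#' @return Character vector of 19 landmark names.
#' @export
landmark_names <- function() {
  c(
    "exocanthion_L", "endocanthion_L", "endocanthion_R", "exocanthion_R",
    "palpebrale_sup_L", "palpebrale_inf_L", "palpebrale_sup_R",
    "palpebrale_inf_R",
    "nasion", "pronasale", "subnasale", "alare_L", "alare_R",
    "labiale_sup", "labiale_inf", "cheilion_L", "cheilion_R",
    "gnathion", "trichion"
  )
}

#' Default facial measurement table (10 horizontal + 11 vertical distances)
#'
#' Defines the 21 landmark pairs whose interocular-normalized Euclidean
#' distances form the phenotype vector: a horizontal index H1-H10 (widths and
#' width-like diagonals) and a vertical index V1-V11 (heights). The exact
#' pair definitions are a documented, configurable convention over standard
#' facial landmarks -- eye corners and lids, nasal points, lips, chin and
#' hairline; users with their own protocol can load a replacement via
#' [read_measurement_table()].
#'
#' @return A data frame with columns `name`, `point_a`, `point_b`, `axis`.
#' @examples
#' default_measurement_table()
#' @export
default_measurement_table <- function() {
  tab <- rbind(
    c("H1",  "exocanthion_L",    "endocanthion_L",  "horizontal"),
    c("H2",  "endocanthion_R",   "exocanthion_R",   "horizontal"),
    c("H3",  "endocanthion_L",   "endocanthion_R",  "horizontal"),
    c("H4",  "exocanthion_L",    "exocanthion_R",   "horizontal"),
    c("H5",  "alare_L",          "alare_R",         "horizontal"),
    c("H6",  "cheilion_L",       "cheilion_R",      "horizontal"),
    c("H7",  "subnasale",        "alare_L",         "horizontal"),
    c("H8",  "subnasale",        "alare_R",         "horizontal"),
    c("H9",  "exocanthion_L",    "cheilion_L",      "horizontal"),
    c("H10", "exocanthion_R",    "cheilion_R",      "horizontal"),
    c("V1",  "palpebrale_sup_L", "palpebrale_inf_L", "vertical"),
    c("V2",  "palpebrale_sup_R", "palpebrale_inf_R", "vertical"),
    c("V3",  "trichion",         "nasion",          "vertical"),
    c("V4",  "nasion",           "subnasale",       "vertical"),
    c("V5",  "nasion",           "pronasale",       "vertical"),
    c("V6",  "pronasale",        "subnasale",       "vertical"),
    c("V7",  "subnasale",        "labiale_sup",     "vertical"),
    c("V8",  "labiale_sup",      "labiale_inf",     "vertical"),
    c("V9",  "labiale_inf",      "gnathion",        "vertical"),
    c("V10", "subnasale",        "gnathion",        "vertical"),
    c("V11", "nasion",           "gnathion",        "vertical")
  )
  out <- data.frame(name = tab[, 1], point_a = tab[, 2], point_b = tab[, 3],
                    axis = tab[, 4], stringsAsFactors = FALSE)
  validate_measurement_table(out, require_default_shape = TRUE)
  out
}

#' Read a measurement table from a delimited file
#'
#' @param path TSV/CSV file with columns `name`, `point_a`, `point_b`, `axis`.
#' @param sep Field separator (default tab).
#' @param landmarks Allowed landmark names; pairs may also reference
#'   `iris_L` / `iris_R`.
#' @return Validated measurement table data frame.
#' @export
read_measurement_table <- function(path, sep = "\t",
                                   landmarks = landmark_names()) {
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_measurement_table(tab, landmarks = landmarks)
  tab
}

validate_measurement_table <- function(tab, landmarks = landmark_names(),
                                       require_default_shape = FALSE) {
  need <- c("name", "point_a", "point_b", "axis")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_eafg("measurement table is missing column(s): ",
              paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$name)) {
    stop_eafg("measurement names must be unique")
  }
  if (!all(tab$axis %in% c("horizontal", "vertical"))) {
    stop_eafg("axis must be 'horizontal' or 'vertical'")
  }
  allowed <- c(landmarks, "iris_L", "iris_R")
  bad <- setdiff(c(tab$point_a, tab$point_b), allowed)
  if (length(bad)) {
    stop_eafg("unknown landmark name(s) in measurement table: ",
              paste(unique(bad), collapse = ", "))
  }
  if (require_default_shape &&
      !(sum(tab$axis == "horizontal") == 10L &&
        sum(tab$axis == "vertical") == 11L)) {
    stop_eafg("default table must have 10 horizontal and 11 vertical entries")
  }
  invisible(tab)
}
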