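## Landmark CSV schema: person_id, photo_id, age, current_age,
## iris_L_x, iris_L_y, iris_R_x, iris_R_y, then <landmark>_x, <landmark>_y
## for each of the 19 landmarks.

landmark_columns <- function(landmarks = landmark_names()) {
  pts <- c("iris_L", "iris_R", landmarks)
  c("person_id", "photo_id", "age", "current_age",
    as.vector(rbind(paste0(pts, "_x"), paste0(pts, "_y"))))
}

#' Read and validate a landmark coordinate table
#'
#' One row per photo: person and photo identifiers, the age at which the
#' photo was taken, the person's current age, the two iris centers and the
#' 19 named landmarks as planar coordinates. Rows violating the schema are
#' rejected with row-numbered diagnostics.
#'
#' @param path CSV file path.
#' @param max_age Maximum admissible current age in years (default 25).
#' @param landmarks Expected landmark names.
#' @return A validated data frame of landmark sets (one per photo).
#' @export
read_landmarks <- function(path, max_age = 25, landmarks = landmark_names()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_landmarks(df, max_age = max_age, landmarks = landmarks)
}

#' Validate an in-memory landmark data frame
#'
#' @param df Data frame in the landmark CSV schema.
#' @inheritParams read_landmarks
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_landmarks <- function(df, max_age = 25,
                               landmarks = landmark_names()) {
  cols <- landmark_columns(landmarks)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_eafg("landmark table is missing column(s): ",
              paste(miss, collapse = ", "))
  }
  num_cols <- setdiff(cols, c("person_id", "photo_id"))
  for (cn in num_cols) {
    if (!is.numeric(df[[cn]])) {
      bad <- suppressWarnings(as.numeric(df[[cn]]))
      if (anyNA(bad)) {
        stop_eafg("non-numeric values in column '", cn, "' (rows ",
                  paste(utils::head(which(is.na(bad)), 5), collapse = ", "),
                  ")")
      }
      df[[cn]] <- bad
    }
    if (anyNA(df[[cn]])) {
      stop_eafg("missing values in column '", cn, "' (rows ",
                paste(utils::head(which(is.na(df[[cn]])), 5), collapse = ", "),
                ")")
    }
  }
  key <- paste(df$person_id, df$photo_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_eafg("duplicate (person_id, photo_id): rows ",
              paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  bad_age <- which(!(df$age > 0 & df$age <= df$current_age &
                       df$current_age <= max_age))
  if (length(bad_age)) {
    stop_eafg("age invariant 0 < age <= current_age <= ", max_age,
              " violated at rows ",
              paste(utils::head(bad_age, 5), collapse = ", "))
  }
  iod <- sqrt((df$iris_L_x - df$iris_R_x)^2 + (df$iris_L_y - df$iris_R_y)^2)
  if (any(iod <= 0)) {
    stop_eafg("degenerate interocular distance (identical iris centers) ",
              "at rows ", paste(utils::head(which(iod <= 0), 5),
                                collapse = ", "))
  }
  df
}

#' Compute interocular-normalized distance phenotypes for landmark sets
#'
#' For each photo and each measurement-table entry, the Euclidean distance
#' between the two named points is divided by that photo's interocular
#' distance (distance between the iris centers), so a measurement whose pair
#' is the iris centers themselves is exactly 1 and all phenotypes are
#' invariant to translation, rotation and uniform scaling.
#'
#' @param landmarks Landmark data frame (validated schema; one row per photo)
#'   or a single-row subset.
#' @param table Measurement table (default [default_measurement_table()]).
#' @return Long-format data frame: `person_id`, `photo_id`, `age`,
#'   `current_age`, `phenotype`, `value`.
#' @examples
#' fx <- gen_landmark_fixtures(2, seed = 1)
#' head(compute_phenotypes(fx$landmarks))
#' @export
compute_phenotypes <- function(landmarks, table = default_measurement_table()) {
  validate_measurement_table(table)
  df <- landmarks
  pts <- unique(c(table$point_a, table$point_b))
  miss <- setdiff(c(paste0(pts, "_x"), paste0(pts, "_y")), names(df))
  if (length(miss)) {
    stop_eafg("landmark table lacks coordinates for measurement points: ",
              paste(miss, collapse = ", "))
  }
  iod <- sqrt((df$iris_L_x - df$iris_R_x)^2 + (df$iris_L_y - df$iris_R_y)^2)
  if (any(iod <= 0)) stop_eafg("degenerate interocular distance")
  out <- lapply(seq_len(nrow(table)), function(i) {
    a <- table$point_a[i]
    b <- table$point_b[i]
    d <- sqrt((df[[paste0(a, "_x")]] - df[[paste0(b, "_x")]])^2 +
                (df[[paste0(a, "_y")]] - df[[paste0(b, "_y")]])^2)
    data.frame(person_id = df$person_id, photo_id = df$photo_id,
               age = df$age, current_age = df$current_age,
               phenotype = table$name[i], value = d / iod,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$person_id, out$photo_id, match(out$phenotype, table$name)), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write a long-format phenotype table to TSV
#' @param phenotypes Data frame from [compute_phenotypes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype TSV
#' @param path File written by [write_phenotypes()].
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
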