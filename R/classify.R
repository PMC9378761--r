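#' Growth-pattern labels and ordinal codes
#'
#' The five early-age facial growth patterns and their ordinal codes:
#' DD = 1 (continued decrease), DI = 2 (decrease to increase),
#' CC = 3 (constant), ID = 4 (increase to decrease),
#' II = 5 (continued increase).
#'
#' @return Named integer vector mapping label to code.
#' @export
pattern_codes <- function() {
  c(DD = 1L, DI = 2L, CC = 3L, ID = 4L, II = 5L)
}

#' @rdname pattern_codes
#' @param code Integer vector of codes 1-5.
#' @return For `pattern_label()`, the character labels.
#' @export
pattern_label <- function(code) {
  if (!all(code %in% 1:5)) stop_eafg("pattern codes must be in 1..5")
  names(pattern_codes())[code]
}

#' Build per-person, per-phenotype growth trajectories
#'
#' Converts QC-passed phenotype records into trajectories on relative age
#' (photo age minus current age; the current photo sits at 0). Duplicate
#' observations at the same relative age are averaged. Trajectories with
#' fewer than `min_obs` observations, or whose current-photo (relative age 0)
#' record was removed by QC, are reported as unclassifiable rather than
#' raising an error; a person with no current photo anywhere in the input is
#' an error.
#'
#' @param phenotypes Long-format phenotype data frame (optionally carrying a
#'   `qc_pass` column from [apply_measurement_qc()]; failing records are
#'   dropped first).
#' @param min_obs Minimum observations needed to fit (default 3).
#' @param require_current If `TRUE` (default), a trajectory must retain its
#'   relative-age-0 observation.
#' @return List with `trajectories` (list of data frames with columns
#'   `relative_age`, `value` and attributes `person_id`, `phenotype`) and
#'   `unclassifiable` (data frame `person_id`, `phenotype`, `reason`).
#' @export
build_trajectories <- function(phenotypes, min_obs = 3,
                               require_current = TRUE) {
  ph <- phenotypes
  cur_ok <- tapply(ph$age == ph$current_age, ph$person_id, any)
  if (require_current && !all(cur_ok)) {
    stop_eafg("person(s) lacking a current photo (age == current_age): ",
              paste(utils::head(names(cur_ok)[!cur_ok], 5), collapse = ", "))
  }
  if (!is.null(ph$qc_pass)) ph <- ph[ph$qc_pass, , drop = FALSE]
  ph$relative_age <- ph$age - ph$current_age
  key <- interaction(ph$person_id, ph$phenotype, drop = TRUE, sep = "\r")
  groups <- split(ph[, c("person_id", "phenotype", "relative_age", "value")],
                  key)
  trajectories <- list()
  unclass <- list()
  for (g in groups) {
    agg <- aggregate(value ~ relative_age, data = g, FUN = mean)
    agg <- agg[order(agg$relative_age), , drop = FALSE]
    pid <- g$person_id[1]
    phen <- g$phenotype[1]
    reason <- NULL
    if (nrow(agg) < min_obs) {
      reason <- "too_few_observations"
    } else if (require_current && max(agg$relative_age) != 0) {
      reason <- "no_current_observation"
    }
    if (is.null(reason)) {
      tr <- data.frame(relative_age = agg$relative_age, value = agg$value)
      attr(tr, "person_id") <- pid
      attr(tr, "phenotype") <- phen
      trajectories[[length(trajectories) + 1L]] <- tr
    } else {
      unclass[[length(unclass) + 1L]] <- data.frame(
        person_id = pid, phenotype = phen, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  unclassifiable <- if (length(unclass)) do.call(rbind, unclass) else
    data.frame(person_id = character(), phenotype = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(trajectories = trajectories, unclassifiable = unclassifiable)
}

#' Fit a quadratic growth curve to one trajectory
#'
#' Ordinary least squares of value on relative age `t` and `t^2`
#' (`value = a + b1 t + b2 t^2`). With exactly three distinct ages the fit
#' interpolates. Returns the fitted endpoint slopes `b1 + 2 b2 t` at the
#' first and last observed relative ages and the fitted total change across
#' the span, which drive pattern classification.
#'
#' @param traj Data frame with columns `relative_age`, `value` (>= 3 rows,
#'   distinct ages).
#' @return A `growth_fit` list: `a`, `b1`, `b2`, `residual_sd`, `t_min`,
#'   `t_max`, `s_start`, `s_end`, `total_change`, `n_obs`.
#' @examples
#' fit_growth(data.frame(relative_age = c(-10, -5, 0),
#'                       value = c(100, 25, 0) / 10))
#' @export
fit_growth <- function(traj) {
  t <- traj$relative_age
  y <- traj$value
  n <- length(t)
  if (n < 3) stop_eafg("fit_growth: need >= 3 observations")
  if (length(unique(t)) < 3) {
    stop_eafg("fit_growth: need >= 3 distinct relative ages ",
              "(de-duplicate with build_trajectories first)")
  }
  X <- cbind(1, t, t^2)
  fit <- stats::lm.fit(X, y)
  cf <- unname(fit$coefficients)
  res <- fit$residuals
  rsd <- if (n > 3) sqrt(sum(res^2) / (n - 3)) else 0
  t_min <- min(t)
  t_max <- max(t)
  val <- function(tt) cf[1] + cf[2] * tt + cf[3] * tt^2
  out <- list(
    a = cf[1], b1 = cf[2], b2 = cf[3], residual_sd = rsd,
    t_min = t_min, t_max = t_max,
    s_start = cf[2] + 2 * cf[3] * t_min,
    s_end = cf[2] + 2 * cf[3] * t_max,
    total_change = val(t_max) - val(t_min),
    n_obs = n
  )
  class(out) <- "growth_fit"
  out
}

fitted_scale <- function(fit, floor = 1e-8) {
  ## largest |fitted value| over the span: endpoints plus interior vertex
  tt <- c(fit$t_min, fit$t_max)
  if (fit$b2 != 0) {
    tv <- -fit$b1 / (2 * fit$b2)
    if (tv > fit$t_min && tv < fit$t_max) tt <- c(tt, tv)
  }
  max(abs(fit$a + fit$b1 * tt + fit$b2 * tt^2), floor)
}

#' Classify a fitted growth curve into one of the five patterns
#'
#' A slope `s` counts as flat when the change it implies over the whole span,
#' `|s| (t_max - t_min)`, is below `eps_rel` times the magnitude of the
#' fitted values (a scale-relative tolerance, so classification is invariant
#' to uniform rescaling). Label logic: both endpoint slopes flat gives CC;
#' two non-flat slopes give DD/DI/ID/II by their signs (a symmetric
#' decrease-then-recover parabola is DI even though its net change is zero);
#' exactly one flat slope is resolved by the sign of the fitted total change
#' (negative DD, positive II, flat CC).
#'
#' @param fit A `growth_fit` from [fit_growth()].
#' @param eps_rel Relative flatness tolerance (default 0.02, i.e. a 2%
#'   change of the trajectory magnitude over the full span is "constant").
#' @return List with `label` (DD/DI/CC/ID/II) and `code` (1-5).
#' @export
classify_pattern <- function(fit, eps_rel = 0.02) {
  stopifnot(inherits(fit, "growth_fit"))
  span <- fit$t_max - fit$t_min
  if (!(span > 0)) stop_eafg("classify_pattern: degenerate age span")
  thr <- eps_rel * fitted_scale(fit)
  flat_start <- abs(fit$s_start) * span < thr
  flat_end <- abs(fit$s_end) * span < thr
  flat_total <- abs(fit$total_change) < thr
  label <-
    if (flat_start && flat_end) {
      "CC"
    } else if (!flat_start && !flat_end) {
      if (fit$s_start < 0 && fit$s_end < 0) "DD"
      else if (fit$s_start < 0 && fit$s_end > 0) "DI"
      else if (fit$s_start > 0 && fit$s_end < 0) "ID"
      else "II"
    } else {
      if (flat_total) "CC"
      else if (fit$total_change < 0) "DD"
      else "II"
    }
  list(label = label, code = unname(pattern_codes()[label]))
}

#' Fit and classify all trajectories
#'
#' @param built Output of [build_trajectories()].
#' @param eps_rel Flatness tolerance passed to [classify_pattern()].
#' @return Data frame: `person_id`, `phenotype`, `label`, `code`, `n_obs`,
#'   `a`, `b1`, `b2`, `residual_sd`, `s_start`, `s_end`, `total_change`.
#' @export
classify_trajectories <- function(built, eps_rel = 0.02) {
  rows <- lapply(built$trajectories, function(tr) {
    fit <- fit_growth(tr)
    cl <- classify_pattern(fit, eps_rel = eps_rel)
    data.frame(person_id = attr(tr, "person_id"),
               phenotype = attr(tr, "phenotype"),
               label = cl$label, code = cl$code, n_obs = fit$n_obs,
               a = fit$a, b1 = fit$b1, b2 = fit$b2,
               residual_sd = fit$residual_sd,
               s_start = fit$s_start, s_end = fit$s_end,
               total_change = fit$total_change,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(person_id = character(), phenotype = character(),
               label = character(), code = integer(), n_obs = integer(),
               a = numeric(), b1 = numeric(), b2 = numeric(),
               residual_sd = numeric(), s_start = numeric(),
               s_end = numeric(), total_change = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pattern frequency table (phenotype x codes 1..5)
#'
#' Counts and proportions of each growth-pattern code per phenotype, with the
#' modal pattern marked (ties broken toward the lower code and flagged).
#'
#' @param patterns Data frame with columns `phenotype` and `code`
#'   (e.g. from [classify_trajectories()]).
#' @param cohort_label Optional label recorded in the `cohort` column.
#' @param phenotype_levels Optional phenotype ordering/universe; phenotypes
#'   without observations get a zero row and an `NA` mode.
#' @return Data frame: `cohort`, `phenotype`, `n`, `code1`..`code5`,
#'   `prop1`..`prop5`, `modal_code`, `modal_tied`.
#' @export
pattern_table <- function(patterns, cohort_label = NA_character_,
                          phenotype_levels = NULL) {
  levs <- phenotype_levels %||% unique(patterns$phenotype)
  rows <- lapply(levs, function(ph) {
    codes <- patterns$code[patterns$phenotype == ph]
    cnt <- tabulate(codes, nbins = 5)
    n <- sum(cnt)
    prop <- if (n > 0) cnt / n else rep(NA_real_, 5)
    if (n > 0) {
      modal <- which.max(cnt)  # ties -> lowest code
      tied <- sum(cnt == max(cnt)) > 1L
    } else {
      modal <- NA_integer_
      tied <- NA
    }
    cbind(data.frame(cohort = cohort_label, phenotype = ph, n = n,
                     stringsAsFactors = FALSE),
          setNames(as.data.frame(t(cnt)), paste0("code", 1:5)),
          setNames(as.data.frame(t(prop)), paste0("prop", 1:5)),
          data.frame(modal_code = modal, modal_tied = tied))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
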