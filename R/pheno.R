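#' Trapezoidal area under a tolerance-test curve
#'
#' Total AUC of a glucose (or insulin) tolerance series by trapezoidal
#' summation: `sum over consecutive pairs of (t[i+1] - t[i]) * (v[i] +
#' v[i+1]) / 2`, in mg.min/dL for glucose in mg/dL and time in minutes.
#' With `baseline_subtract = TRUE` the time-zero value is subtracted from
#' every point first (incremental AUC; can be negative).
#'
#' @param timepoints strictly increasing times in minutes (>= 2 points;
#'   canonical tolerance-test design is 0, 30, 60, 120).
#' @param values measurements at those times (>= 0).
#' @param baseline_subtract subtract the first value before integrating.
#' @return the area (scalar).
#' @examples
#' auc_trapezoid(c(0, 30, 60, 120), c(100, 200, 150, 100))  # 17250
#' @export
auc_trapezoid <- function(timepoints, values, baseline_subtract = FALSE) {
  if (length(timepoints) < 2L) {
    stop("need at least 2 timepoints", call. = FALSE)
  }
  if (length(timepoints) != length(values)) {
    stop("timepoints and values differ in length", call. = FALSE)
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  if (baseline_subtract) values <- values - values[1]
  sum(diff(timepoints) * (head(values, -1) + tail(values, -1)) / 2)
}

#' Per-animal AUC from a long-format tolerance table
#'
#' @param df long-format data frame with columns `animal_id`, `test`
#'   (e.g. "ipgtt"/"ipitt"), `minute`, `glucose`.
#' @param baseline_subtract see [auc_trapezoid()].
#' @return data frame with one row per (animal_id, test) and column `auc`,
#'   plus any constant per-animal columns (e.g. `diet`) carried through.
#' @export
auc_by_animal <- function(df, baseline_subtract = FALSE) {
  need <- c("animal_id", "test", "minute", "glucose")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column ", miss[1], call. = FALSE)
  keys <- interaction(df$animal_id, df$test, drop = TRUE)
  parts <- lapply(split(df, keys), function(d) {
    d <- d[order(d$minute), ]
    out <- data.frame(animal_id = d$animal_id[1], test = d$test[1],
                      auc = auc_trapezoid(d$minute, d$glucose,
                                          baseline_subtract),
                      stringsAsFactors = FALSE)
    for (extra in setdiff(names(d), c(need))) {
      if (length(unique(d[[extra]])) == 1L) out[[extra]] <- d[[extra]][1]
    }
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Read a long-format tolerance-test table
#'
#' Headered TSV with columns animal_id, test, minute, glucose.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tolerance_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "test", "minute", "glucose")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column ", miss[1], call. = FALSE)
  df
}
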