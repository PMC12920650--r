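#' Fill BMI and log-BMI columns of a long-format measurement table
#'
#' The long phenotype table has one row per measurement with columns
#' \code{iid}, \code{sex} (M/F), \code{age} (years), \code{source}
#' (questionnaire/clinic) and either \code{bmi} (kg/m^2) or \code{weight}
#' (kg) plus \code{height} (m). This fills \code{bmi = weight / height^2}
#' where absent and \code{log_bmi = log(bmi)} (natural log; BMI is
#' log-transformed for analysis because of its right skew).
#'
#' @param table Data frame in long format.
#' @return The table with \code{bmi} and \code{log_bmi} columns filled.
#' @export
derive_log_bmi <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"bmi" %in% names(table)) table$bmi <- NA_real_
  need <- is.na(table$bmi)
  if (any(need)) {
    if (!all(c("weight", "height") %in% names(table))) {
      stop("rows without bmi need weight and height columns")
    }
    w <- table$weight[need]; h <- table$height[need]
    bad <- which(!is.finite(w) | !is.finite(h) | w <= 0 | h <= 0)
    if (length(bad)) {
      i <- which(need)[bad[1]]
      stop(sprintf("non-positive or missing weight/height for iid %s at age %s",
                   table$iid[i], format(table$age[i])))
    }
    table$bmi[need] <- w / h^2
  }
  bad <- which(!is.finite(table$bmi) | table$bmi <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive BMI for iid %s at age %s",
                 table$iid[bad[1]], format(table$age[bad[1]])))
  }
  table$log_bmi <- log(table$bmi)
  table
}

#' Flag biologically implausible measurements
#'
#' A lightweight stand-in for dedicated growth-record cleaning: each
#' measurement is compared with an exponentially weighted average (EWA) of the
#' same individual's other measurements, with weights decaying with age
#' distance (half-life \code{window} years). A measurement is flagged when its
#' absolute deviation from the EWA exceeds \code{z_threshold} robust standard
#' deviations of that individual's leave-one-out residuals (1.4826 x MAD,
#' floored at half the cohort-wide robust SD so that individuals with few
#' measurements do not produce degenerate scales). Individuals with a single
#' measurement are never flagged.
#'
#' @param table Long phenotype table with \code{iid}, \code{age} and
#'   \code{log_bmi} (run \code{\link{derive_log_bmi}} first if needed).
#' @param window Age-distance half-life of the weights, in years (> 0).
#' @param z_threshold Robust z-score threshold (> 0). Default 4.
#' @param value_col Column to screen (default \code{"log_bmi"}).
#' @return Logical vector, one element per row, TRUE = flagged.
#' @export
flag_implausible <- function(table, window = 2, z_threshold = 4,
                             value_col = "log_bmi") {
  stopifnot(is.data.frame(table))
  if (window <= 0) stop("window must be positive")
  if (z_threshold <= 0) stop("z_threshold must be positive")
  y <- table[[value_col]]
  age <- table$age
  n <- nrow(table)
  resid <- rep(NA_real_, n)
  rows_by_id <- split(seq_len(n), table$iid)
  for (rows in rows_by_id) {
    if (length(rows) < 2) next
    for (r in rows) {
      others <- setdiff(rows, r)
      w <- 2^(-abs(age[others] - age[r]) / window)
      resid[r] <- y[r] - sum(w * y[others]) / sum(w)
    }
  }
  pooled <- 1.4826 * stats::median(abs(resid), na.rm = TRUE)
  flags <- rep(FALSE, n)
  for (rows in rows_by_id) {
    if (length(rows) < 2) next
    s <- 1.4826 * stats::median(abs(resid[rows]))
    s <- max(s, pooled / 2, .Machine$double.eps)
    flags[rows] <- abs(resid[rows]) > z_threshold * s
  }
  flags
}

#' Apply the longitudinal inclusion filters
#'
#' Applies the two inclusion rules in fixed order: (1) drop measurements
#' outside the analysis age window \code{[min_age, max_age]} years; (2) drop
#' whole individuals left with fewer than \code{min_measurements} rows. The
#' minimum of four measurements guarantees enough data per individual to fit a
#' cubic polynomial within the window.
#'
#' @param table Long phenotype table.
#' @param min_age,max_age Analysis window in years (default 1 and 18).
#' @param min_measurements Minimum retained measurements per individual
#'   (default 4).
#' @return List with \code{table} (filtered), and \code{report}: rows removed
#'   by the age window, individuals (and their rows) removed by the
#'   measurement-count rule, and totals. Report row counts sum exactly to
#'   input rows minus output rows.
#' @export
apply_inclusion_filters <- function(table, min_age = 1, max_age = 18,
                                    min_measurements = 4) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  if (min_age >= max_age) stop("min_age must be less than max_age")
  n_in <- nrow(table)
  in_window <- table$age >= min_age & table$age <= max_age
  rows_age_removed <- sum(!in_window)
  t2 <- table[in_window, , drop = FALSE]
  counts <- table(t2$iid)
  keep_ids <- names(counts)[counts >= min_measurements]
  drop_ids <- setdiff(unique(as.character(t2$iid)), keep_ids)
  t3 <- t2[as.character(t2$iid) %in% keep_ids, , drop = FALSE]
  report <- list(
    rows_in = n_in,
    rows_removed_age_window = rows_age_removed,
    individuals_removed_min_measurements = length(drop_ids),
    rows_removed_min_measurements = nrow(t2) - nrow(t3),
    rows_out = nrow(t3),
    individuals_out = length(keep_ids))
  list(table = t3, report = report)
}

#' Read / write long-format phenotype tables
#'
#' Tab-delimited, one row per measurement, with columns \code{iid},
#' \code{sex}, \code{age}, \code{source} and \code{bmi}/\code{log_bmi}
#' (optionally \code{weight}, \code{height}).
#'
#' @param path File path.
#' @return \code{read_pheno}: a data frame.
#' @export
read_pheno <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @param table Data frame to write.
#' @rdname read_pheno
#' @export
write_pheno <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
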