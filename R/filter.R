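#' Percentile outlier filtering of numeric features
#'
#' Per numeric feature (static and temporal), percentile bounds are computed
#' on observed values only; observed values strictly outside the bounds are
#' either masked to missing (`mode = "mask_value"`, the default, which
#' preserves cohort size and missingness structure) or cause the whole
#' patient record to be dropped (`mode = "drop_patient"`). Features with
#' fewer than two observed values are skipped with a warning.
#'
#' @param data an `ehr_cohort`.
#' @param masks its `ehr_masks`.
#' @param low_pct,high_pct percentile bounds as fractions,
#'   `0 <= low_pct < high_pct <= 1`. Defaults keep the central 99.8%.
#' @param mode `"mask_value"` or `"drop_patient"`.
#' @return list with filtered `data` and `masks`.
#' @export
filter_outliers <- function(data, masks = derive_masks(data),
                            low_pct = 0.001, high_pct = 0.999,
                            mode = c("mask_value", "drop_patient")) {
  mode <- match.arg(mode)
  stopifnot(low_pct >= 0, high_pct <= 1, low_pct < high_pct)
  validate_cohort(data, masks)
  sch <- data$schema
  drop <- logical(n_records(data))

  apply_bounds <- function(vals) {
    obs <- !is.na(vals)
    if (sum(obs) < 2L) return(NULL)
    q <- stats::quantile(vals[obs], c(low_pct, high_pct), names = FALSE)
    obs & (vals < q[1] | vals > q[2])
  }
  for (f in sch$static_numeric) {
    out <- apply_bounds(data$static_num[, f])
    if (is.null(out)) { warning("outlier filter skipped '", f,
                                "': fewer than 2 observed values"); next }
    if (mode == "mask_value") data$static_num[out, f] <- NA_real_
    else drop <- drop | out
  }
  for (f in sch$temporal_numeric) {
    v <- matrix(data$temporal_num[, , f], n_records(data), sch$max_seq_len)
    out <- apply_bounds(as.vector(v))
    if (is.null(out)) { warning("outlier filter skipped '", f,
                                "': fewer than 2 observed values"); next }
    if (mode == "mask_value") {
      v[matrix(out, nrow(v))] <- NA_real_
      data$temporal_num[, , f] <- v
    } else drop <- drop | apply(matrix(out, nrow(v)), 1, any)
  }
  if (mode == "drop_patient" && any(drop))
    data <- subset_cohort(data, !drop)
  list(data = data, masks = derive_masks(data))
}

#' Truncate and pad sequences to a fixed length
#'
#' Sequences longer than `t_max` keep only their last `t_max` steps; all
#' records are padded to `t_max` with missing entries and
#' `step_present = 0`. The pre-truncation lengths are preserved in the
#' `orig_lengths` attribute of the returned cohort. Idempotent for a fixed
#' `t_max`.
#'
#' @param data an `ehr_cohort`.
#' @param masks its `ehr_masks`.
#' @param t_max positive integer target length.
#' @return list with truncated/padded `data` and `masks`.
#' @export
truncate_pad <- function(data, masks = derive_masks(data), t_max) {
  stopifnot(t_max >= 1)
  t_max <- as.integer(t_max)
  validate_cohort(data, masks)
  sch <- data$schema
  orig <- attr(data, "orig_lengths") %||% data$lengths
  n <- n_records(data)
  new_len <- pmin(data$lengths, t_max)
  sch2 <- sch
  sch2$max_seq_len <- t_max

  tim <- matrix(NA_real_, n, t_max)
  tn <- array(NA_real_, c(n, t_max, length(sch$temporal_numeric)),
              dimnames = list(NULL, NULL, sch$temporal_numeric))
  tc <- array(NA_character_, c(n, t_max, length(sch$temporal_categorical)),
              dimnames = list(NULL, NULL, names(sch$temporal_categorical)))
  for (i in seq_len(n)) {
    src <- seq.int(data$lengths[i] - new_len[i] + 1L, data$lengths[i])
    dst <- seq_len(new_len[i])
    tim[i, dst] <- data$time[i, src]
    if (length(sch$temporal_numeric))
      tn[i, dst, ] <- data$temporal_num[i, src, ]
    if (length(sch$temporal_categorical))
      tc[i, dst, ] <- data$temporal_cat[i, src, ]
  }
  out <- ehr_cohort(sch2, data$ids, data$static_num, data$static_cat,
                    new_len, tim, tn, tc)
  attr(out, "orig_lengths") <- orig
  validate_cohort(out)
  list(data = out, masks = derive_masks(out))
}
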