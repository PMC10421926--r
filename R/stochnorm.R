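#' Frequency-proportional ("stochastic") normalization
#'
#' Numeric EHR features often have cumulative distribution functions with
#' discrete jumps (values recorded on a grid, e.g. multiples of 5) or heavy
#' skew. Plain min-max scaling leaves most of the probability mass condensed
#' in a narrow band of the unit interval, which encourages mode collapse in
#' adversarial training. Stochastic normalization instead assigns each unique
#' observed value a sub-interval of \[0, 1\] whose width equals the value's
#' empirical frequency, and replaces every occurrence by a uniform draw from
#' its interval. The normalized marginal is (asymptotically) Uniform(0, 1),
#' and the map is exactly invertible: every point of \[0, 1\] belongs to
#' exactly one value's interval.
#'
#' `fit_normalizer` estimates the interval map from an observed sample.
#' Intervals are assigned in ascending value order, so the transform is
#' monotone in distribution and inversion is an interval search.
#'
#' @param values numeric vector of observed values (no `NA`; callers drop
#'   missing entries before fitting).
#' @param max_unique optional cap on the number of intervals; when the number
#'   of unique values exceeds it, values are first grouped into
#'   (approximately) equal-frequency bins and each bin is represented by its
#'   median. Default `Inf` (no binning); fully continuous features then
#'   degenerate to an empirical-CDF rank transform with 1/n jitter buckets.
#' @return an object of class `stochnorm`, a data.frame with columns
#'   `value`, `lower`, `upper`: ascending unique values whose half-open
#'   intervals `[lower, upper)` tile `[0, 1]` (the final interval is closed).
#' @examples
#' p <- fit_normalizer(c(1, 2, 2, 2, 2, 2, 2, 2, 3, 3))
#' p$upper  # 0.1 0.8 1.0
#' x <- c(1, 2, 3, 2, 2)
#' xn <- normalize_values(x, p, seed = 1)
#' all(renormalize_values(xn, p) == x)
#' @export
fit_normalizer <- function(values, max_unique = Inf) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("cannot fit a normalizer on an empty sample or a sample with NA; ",
         "drop missing entries first")
  }
  if (is.finite(max_unique) && length(unique(values)) > max_unique) {
    # equal-frequency binning: group ranks into max_unique buckets and
    # represent each bucket by its median value
    r <- rank(values, ties.method = "min")
    bin <- ceiling(r / length(values) * max_unique)
    values <- stats::ave(values, bin, FUN = stats::median)
  }
  tab <- sort(unique(values))
  freq <- tabulate(match(values, tab), nbins = length(tab)) / length(values)
  upper <- cumsum(freq)
  upper[length(upper)] <- 1.0  # guard against accumulated rounding
  params <- data.frame(value = tab,
                       lower = c(0, upper[-length(upper)]),
                       upper = upper)
  class(params) <- c("stochnorm", "data.frame")
  params
}

validate_normalizer <- function(params) {
  stopifnot(inherits(params, "stochnorm"),
            all(diff(params$value) > 0),
            params$lower[1] == 0,
            params$upper[nrow(params)] == 1,
            all(params$lower[-1] == params$upper[-nrow(params)]))
  invisible(params)
}

#' Normalize a numeric sample into \[0, 1) with uniform jitter
#'
#' Each value is replaced by an independent draw from
#' `Uniform(lower, upper)` over its fitted interval. Missing (`NA`) entries
#' pass through unchanged.
#'
#' @param x numeric vector; every non-missing value must be present in
#'   `params` unless `nearest = TRUE`.
#' @param params a [fit_normalizer()] object.
#' @param seed integer seed for the jitter draws (one stream per call).
#' @param nearest if `TRUE`, values absent from `params` are mapped to the
#'   nearest fitted value instead of erroring (synthesis-time robustness).
#' @return numeric vector of the same length, draws in `[0, 1)`.
#' @export
normalize_values <- function(x, params, seed, nearest = FALSE) {
  validate_normalizer(params)
  out <- as.numeric(x)
  obs <- which(!is.na(out))
  if (length(obs) == 0L) return(out)
  idx <- match(out[obs], params$value)
  if (anyNA(idx)) {
    if (!nearest) {
      bad <- unique(out[obs][is.na(idx)])
      stop("values not in the fitted support: ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "")
    }
    miss <- which(is.na(idx))
    for (j in miss) {
      idx[j] <- which.min(abs(params$value - out[obs][j]))
    }
  }
  with_substream(seed, "stochnorm-jitter", {
    u <- stats::runif(length(obs))
  })
  lo <- params$lower[idx]
  hi <- params$upper[idx]
  draw <- lo + u * (hi - lo)
  # keep draws strictly below the upper bound so intervals stay half-open
  draw <- pmin(draw, hi - (hi - lo) * .Machine$double.eps)
  out[obs] <- draw
  out
}

#' Invert stochastic normalization exactly
#'
#' Maps each point of \[0, 1\] back to the unique value whose interval
#' contains it; intervals are half-open `[lower, upper)` with the final
#' interval closed at 1. Inputs outside \[0, 1\] are clipped first, so the
#' map is total. `renormalize_values(normalize_values(x, p), p)` recovers
#' `x` exactly for any `x` in the fitted support.
#'
#' @param x numeric vector in (or clipped to) \[0, 1\]; `NA` passes through.
#' @param params a [fit_normalizer()] object.
#' @return numeric vector of original-space values.
#' @export
renormalize_values <- function(x, params) {
  validate_normalizer(params)
  out <- as.numeric(x)
  obs <- which(!is.na(out))
  if (length(obs) == 0L) return(out)
  z <- clamp(out[obs], 0, 1)
  # interval j is [lower_j, upper_j) = [lower_j, lower_{j+1}); findInterval
  # on the lower bounds returns exactly that j, and z = 1 falls in the last.
  idx <- findInterval(z, params$lower)
  out[obs] <- params$value[idx]
  out
}

#' Fit normalizers for every numeric feature of a cohort
#'
#' One [fit_normalizer()] per static numeric feature, temporal numeric
#' feature, and the measurement-time field, fitted on observed entries only
#' (and, for temporal features, only on steps within each record's true
#' length). Features never observed raise an error naming the feature.
#'
#' @param data an `ehr_cohort`.
#' @param masks the matching `ehr_masks`.
#' @param max_unique per-feature cap passed to [fit_normalizer()].
#' @return named list of class `stochnorm_set` with one `stochnorm` per
#'   feature, plus the time field under the schema's `time_name`.
#' @export
fit_cohort_normalizers <- function(data, masks, max_unique = Inf) {
  sch <- data$schema
  out <- list()
  for (f in sch$static_numeric) {
    v <- data$static_num[, f][masks$m_sn[, f] == 1]
    if (length(v) == 0L) stop("feature never observed: ", f)
    out[[f]] <- fit_normalizer(v, max_unique)
  }
  for (f in sch$temporal_numeric) {
    v <- data$temporal_num[, , f][masks$m_tn[, , f] == 1]
    if (length(v) == 0L) stop("feature never observed: ", f)
    out[[f]] <- fit_normalizer(v, max_unique)
  }
  u <- data$time[masks$step_present == 1]
  out[[sch$time_name]] <- fit_normalizer(u, max_unique)
  class(out) <- "stochnorm_set"
  out
}

#' Serialize / restore normalization parameters
#'
#' Plain-JSON container: feature name mapped to its `(value, lower, upper)`
#' triples at full double precision, so a write/read round trip is bit-exact.
#'
#' @param params a `stochnorm_set` (or single `stochnorm`).
#' @param path file path.
#' @export
write_normalizers <- function(params, path) {
  # doubles are written as 17-significant-digit strings: decimal JSON numbers
  # do not round-trip the last bit through every writer, strings do
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  as_list <- function(p) list(value = fmt(p$value), lower = fmt(p$lower),
                              upper = fmt(p$upper))
  payload <- if (inherits(params, "stochnorm")) {
    list(.single = as_list(params))
  } else lapply(params, as_list)
  jsonlite::write_json(payload, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_normalizers
#' @export
read_normalizers <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(p) {
    d <- data.frame(value = as.numeric(p$value), lower = as.numeric(p$lower),
                    upper = as.numeric(p$upper))
    class(d) <- c("stochnorm", "data.frame")
    validate_normalizer(d)
  }
  if (identical(names(payload), ".single")) return(mk(payload$.single))
  out <- lapply(payload, mk)
  class(out) <- "stochnorm_set"
  out
}

#' Min-max scaling fallback (ablation of stochastic normalization)
#'
#' Drop-in replacement used by the `stochastic_norm = FALSE` ablation: a
#' linear map of the observed range onto \[0, 1\] whose inverse does not
#' restrict values to the training support.
#' @param values numeric sample (no NA).
#' @return object of class `minmaxnorm`.
#' @keywords internal
fit_minmax <- function(values) {
  stopifnot(length(values) > 0L, !anyNA(values))
  r <- range(values)
  structure(list(min = r[1], max = r[2], span = max(r[2] - r[1], 1e-12)),
            class = "minmaxnorm")
}

minmax_normalize <- function(x, p) (x - p$min) / p$span

minmax_renormalize <- function(x, p) clamp(x, 0, 1) * p$span + p$min
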