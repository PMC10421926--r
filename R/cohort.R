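#' Heterogeneous EHR cohort container
#'
#' An `ehr_cohort` holds N patient records padded to the schema's
#' `max_seq_len` (`T_max`): static numeric and categorical blocks, a
#' measurement-time matrix, temporal numeric and categorical arrays, and the
#' per-record true sequence length. Missing entries are `NA`; the aligned
#' binary masks live in a separate `ehr_masks` object (see [derive_masks()]),
#' where mask 1 means observed. Steps beyond a record's length are padding:
#' all-`NA` with `step_present = 0`.
#'
#' @param schema an `ehr_schema`.
#' @param ids patient identifiers (length N, unique).
#' @param static_num N x (#static numeric) matrix, `NA` = missing.
#' @param static_cat N x (#static categorical) character matrix of vocabulary
#'   entries, `NA` = missing.
#' @param lengths integer vector of true sequence lengths, in `[1, T_max]`.
#' @param time N x T_max matrix of measurement times, non-decreasing within
#'   each record over its first `lengths[i]` steps, `NA` beyond.
#' @param temporal_num N x T_max x (#temporal numeric) array.
#' @param temporal_cat N x T_max x (#temporal categorical) character array.
#' @return an `ehr_cohort`.
#' @export
ehr_cohort <- function(schema, ids, static_num, static_cat, lengths, time,
                       temporal_num, temporal_cat) {
  validate_schema(schema)
  n <- length(ids)
  tmax <- schema$max_seq_len
  shape <- function(x, d3) {
    if (is.null(dim(x))) dim(x) <- c(n, tmax, d3)
    x
  }
  obj <- structure(list(
    schema = schema,
    ids = ids,
    static_num = matrix(as.numeric(static_num), n,
                        length(schema$static_numeric),
                        dimnames = list(NULL, schema$static_numeric)),
    static_cat = matrix(as.character(static_cat), n,
                        length(schema$static_categorical),
                        dimnames = list(NULL, names(schema$static_categorical))),
    lengths = as.integer(lengths),
    time = matrix(as.numeric(time), n, tmax),
    temporal_num = shape(array(as.numeric(temporal_num),
                               c(n, tmax, length(schema$temporal_numeric)),
                               dimnames = list(NULL, NULL, schema$temporal_numeric)), NULL),
    temporal_cat = shape(array(as.character(temporal_cat),
                               c(n, tmax, length(schema$temporal_categorical)),
                               dimnames = list(NULL, NULL, names(schema$temporal_categorical))), NULL)
  ), class = "ehr_cohort")
  obj
}

#' Number of records in a cohort
#' @param data an `ehr_cohort`.
#' @export
n_records <- function(data) length(data$ids)

#' Derive the observation masks of a cohort
#'
#' Masks are 1 exactly where the aligned entry is non-missing; the
#' `step_present` channel is 1 on the first `lengths[i]` steps of record i
#' and 0 on padding. Time carries no mask of its own: it is defined at every
#' present step.
#'
#' @param data an `ehr_cohort`.
#' @return an `ehr_masks` list with binary members `m_sn`, `m_sc`, `m_tn`,
#'   `m_tc`, `step_present`, aligned entrywise with `data`.
#' @export
derive_masks <- function(data) {
  n <- n_records(data)
  tmax <- data$schema$max_seq_len
  sp <- matrix(0, n, tmax)
  for (i in seq_len(n)) sp[i, seq_len(data$lengths[i])] <- 1
  m <- structure(list(
    m_sn = (!is.na(data$static_num)) + 0,
    m_sc = (!is.na(data$static_cat)) + 0,
    m_tn = (!is.na(data$temporal_num)) + 0,
    m_tc = (!is.na(data$temporal_cat)) + 0,
    step_present = sp
  ), class = "ehr_masks")
  dimnames(m$m_sn) <- dimnames(data$static_num)
  dimnames(m$m_sc) <- dimnames(data$static_cat)
  dimnames(m$m_tn) <- dimnames(data$temporal_num)
  dimnames(m$m_tc) <- dimnames(data$temporal_cat)
  m
}

#' Validate a cohort and its masks against the schema invariants
#'
#' Checks: lengths in `[1, T_max]`; time defined and non-decreasing at every
#' present step, `NA` on padding; categorical values in vocabulary or `NA`;
#' entry missing exactly where mask is 0; `step_present` a contiguous prefix
#' of ones of the declared length; all shapes consistent.
#'
#' @param data an `ehr_cohort`.
#' @param masks its `ehr_masks` (default: re-derived).
#' @return `data`, invisibly; errors otherwise.
#' @export
validate_cohort <- function(data, masks = derive_masks(data)) {
  stopifnot(inherits(data, "ehr_cohort"), inherits(masks, "ehr_masks"))
  sch <- data$schema
  n <- n_records(data)
  tmax <- sch$max_seq_len
  if (anyDuplicated(data$ids)) stop("duplicate patient ids")
  if (length(data$lengths) != n) stop("lengths/ids size mismatch")
  if (n == 0L) return(invisible(data))
  if (any(data$lengths < 1L | data$lengths > tmax))
    stop("sequence lengths must lie in [1, T_max]")
  for (i in seq_len(n)) {
    ti <- data$lengths[i]
    u <- data$time[i, seq_len(ti)]
    if (anyNA(u)) stop("time undefined at a present step (record ", i, ")")
    if (is.unsorted(u)) stop("time not non-decreasing (record ", i, ")")
    if (ti < tmax && !all(is.na(data$time[i, (ti + 1):tmax])))
      stop("time defined on padded steps (record ", i, ")")
  }
  for (f in names(sch$static_categorical)) {
    v <- data$static_cat[, f]
    bad <- setdiff(unique(v[!is.na(v)]), sch$static_categorical[[f]])
    if (length(bad)) stop("out-of-vocabulary value(s) for '", f, "': ",
                          paste(bad, collapse = ", "))
  }
  for (f in names(sch$temporal_categorical)) {
    v <- data$temporal_cat[, , f]
    bad <- setdiff(unique(v[!is.na(v)]), sch$temporal_categorical[[f]])
    if (length(bad)) stop("out-of-vocabulary value(s) for '", f, "': ",
                          paste(bad, collapse = ", "))
  }
  ref <- derive_masks(data)
  for (blk in c("m_sn", "m_sc", "m_tn", "m_tc", "step_present")) {
    if (!isTRUE(all.equal(unname(as.vector(masks[[blk]])),
                          unname(as.vector(ref[[blk]])))))
      stop("mask/value inconsistency in block ", blk)
  }
  # padding must be all-missing
  pad <- ref$step_present == 0
  for (f in sch$temporal_numeric) {
    if (any(!is.na(data$temporal_num[, , f][pad])))
      stop("temporal numeric '", f, "' observed on a padded step")
  }
  for (f in names(sch$temporal_categorical)) {
    if (any(!is.na(data$temporal_cat[, , f][pad])))
      stop("temporal categorical '", f, "' observed on a padded step")
  }
  invisible(data)
}

#' Subset a cohort by record index
#' @param data an `ehr_cohort`.
#' @param idx integer or logical index over records.
#' @return the subsetted `ehr_cohort`.
#' @export
subset_cohort <- function(data, idx) {
  ehr_cohort(data$schema, data$ids[idx],
             data$static_num[idx, , drop = FALSE],
             data$static_cat[idx, , drop = FALSE],
             data$lengths[idx],
             data$time[idx, , drop = FALSE],
             data$temporal_num[idx, , , drop = FALSE],
             data$temporal_cat[idx, , , drop = FALSE])
}

#' Per-patient random train/test split
#'
#' @param data an `ehr_cohort`.
#' @param frac fraction of records assigned to the training split.
#' @param seed integer seed.
#' @return list with `ehr_cohort` members `train` and `test`.
#' @export
split_cohort <- function(data, frac = 0.8, seed = 1L) {
  n <- n_records(data)
  with_substream(seed, "split", {
    idx <- sample.int(n, size = round(frac * n))
  })
  list(train = subset_cohort(data, sort(idx)),
       test = subset_cohort(data, sort(setdiff(seq_len(n), idx))))
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort> ", n_records(x), " records, T_max=", x$schema$max_seq_len,
      ", lengths ", if (n_records(x)) paste0(min(x$lengths), "-", max(x$lengths)) else "-",
      "\n", sep = "")
  invisible(x)
}
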