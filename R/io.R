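#' Read a cohort from a static table and a temporal long table
#'
#' The static table has one row per patient (`id` column plus every static
#' feature declared in the schema). The temporal table is in long format
#' with columns `id`, `time`, `feature`, `value`; rows whose `feature`
#' equals the schema's time field define the step grid of each record
#' (one row per step), and every other row attaches an observed value to
#' the step with the matching time. Tied timestamps are allowed: the k-th
#' row of a feature at a tied time maps to the k-th step carrying that time
#' (stable order). Absent entries become missing with mask 0.
#'
#' Records are sorted by id and steps by time (stable). Records longer than
#' `max_seq_len` keep their last `max_seq_len` steps, as in
#' [truncate_pad()]. A patient present in the static table with zero
#' temporal steps is rejected (the minimum sequence length is 1).
#'
#' @param static_path,temporal_path delimited files (comma or tab separated,
#'   header row).
#' @param schema an `ehr_schema`.
#' @return list with members `data` (`ehr_cohort`) and `masks` (`ehr_masks`).
#' @export
read_cohort <- function(static_path, temporal_path, schema) {
  validate_schema(schema)
  st <- data.table::fread(static_path, colClasses = list(character = "id"),
                          na.strings = c("", "NA"))
  tp <- data.table::fread(temporal_path, colClasses = list(character = c("id", "feature", "value")),
                          na.strings = c("", "NA"))
  if (!"id" %in% names(st)) stop("static table needs an 'id' column")
  need <- c("id", "time", "feature", "value")
  if (!all(need %in% names(tp)))
    stop("temporal table needs columns: ", paste(need, collapse = ", "))
  sch_feats <- c(schema$static_numeric, names(schema$static_categorical))
  extra <- setdiff(names(st), c("id", sch_feats))
  if (length(extra)) stop("unknown static column(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(sch_feats, names(st))
  if (length(miss)) stop("static column(s) missing from table: ",
                         paste(miss, collapse = ", "))
  tfeats <- c(schema$temporal_numeric, names(schema$temporal_categorical))
  unknown <- setdiff(unique(tp$feature), c(tfeats, schema$time_name))
  if (length(unknown)) stop("unknown temporal feature(s): ",
                            paste(unknown, collapse = ", "))

  st <- st[order(st$id), ]
  ids <- as.character(st$id)
  if (anyDuplicated(ids)) stop("duplicate ids in static table")
  n <- length(ids)

  # step grid from the time rows, stably sorted by (id, time)
  tm <- tp[tp$feature == schema$time_name, ]
  tm$tval <- as.numeric(tm$value)
  tm <- tm[order(tm$id, tm$tval, method = "radix"), ]
  no_steps <- setdiff(ids, unique(tm$id))
  if (length(no_steps)) stop("patient(s) with zero temporal steps rejected: ",
                             paste(utils::head(no_steps, 5), collapse = ", "))
  orphan <- setdiff(unique(tm$id), ids)
  if (length(orphan)) stop("temporal rows for unknown id(s): ",
                           paste(utils::head(orphan, 5), collapse = ", "))
  tm <- data.table::as.data.table(tm)
  tm[, step := seq_len(.N), by = "id"]
  lens_full <- tm[, list(len = .N), by = "id"]
  lens <- lens_full$len[match(ids, lens_full$id)]

  # truncate to the LAST max_seq_len steps where needed
  tmax <- schema$max_seq_len
  keep_from <- pmax(lens - tmax, 0L)
  tm <- tm[tm$step > keep_from[match(tm$id, ids)], ]
  tm[, step := seq_len(.N), by = "id"]
  tm[, occ := seq_len(.N), by = c("id", "tval")]
  lengths <- pmin(lens, tmax)

  fv <- data.table::as.data.table(tp[tp$feature != schema$time_name, ])
  if (nrow(fv)) {
    fv$tval <- as.numeric(fv$time)
    fv <- fv[order(fv$id, fv$tval, method = "radix"), ]
    fv[, occ := seq_len(.N), by = c("id", "tval", "feature")]
    fv <- merge(fv, tm[, c("id", "tval", "occ", "step")],
                by = c("id", "tval", "occ"), all.x = TRUE)
    dropped <- is.na(fv$step)  # rows on steps removed by truncation, or unmatched
    if (any(dropped)) {
      # a row whose time is outside the (possibly truncated) grid of its
      # record is an input error unless truncation removed the step
      bad <- fv[dropped & lens[match(fv$id, ids)] <= tmax, ]
      if (nrow(bad)) stop("temporal value row(s) with no matching time step, e.g. id=",
                          bad$id[1], " feature=", bad$feature[1], " time=", bad$time[1])
      fv <- fv[!dropped, ]
    }
  }

  tn <- array(NA_real_, c(n, tmax, length(schema$temporal_numeric)),
              dimnames = list(NULL, NULL, schema$temporal_numeric))
  tc <- array(NA_character_, c(n, tmax, length(schema$temporal_categorical)),
              dimnames = list(NULL, NULL, names(schema$temporal_categorical)))
  tim <- matrix(NA_real_, n, tmax)
  tim[cbind(match(tm$id, ids), tm$step)] <- tm$tval
  if (nrow(fv)) {
    for (f in schema$temporal_numeric) {
      r <- fv[fv$feature == f, ]
      if (nrow(r)) tn[cbind(match(r$id, ids), r$step, match(f, schema$temporal_numeric))] <-
          as.numeric(r$value)
    }
    for (f in names(schema$temporal_categorical)) {
      r <- fv[fv$feature == f, ]
      if (nrow(r)) tc[cbind(match(r$id, ids), r$step,
                            match(f, names(schema$temporal_categorical)))] <- r$value
    }
  }

  sn <- as.matrix(st[, schema$static_numeric, with = FALSE])
  if (length(schema$static_numeric) == 0L) sn <- matrix(NA_real_, n, 0)
  storage.mode(sn) <- "double"
  sc <- as.matrix(st[, names(schema$static_categorical), with = FALSE])
  if (length(schema$static_categorical) == 0L) sc <- matrix(NA_character_, n, 0)
  storage.mode(sc) <- "character"

  data <- ehr_cohort(schema, ids, sn, sc, lengths, tim, tn, tc)
  validate_cohort(data)
  list(data = data, masks = derive_masks(data))
}

#' Write a cohort to the two-table delimited format
#'
#' Emits `static.csv` (one row per patient) and `temporal.csv` (long format
#' `id,time,feature,value`). Missing entries are omitted from the temporal
#' rows and written as empty cells in the static table, so the masks are
#' exactly recoverable on re-reading; each present step contributes one row
#' under the schema's time field. `read_cohort(write_cohort(x))` is the
#' identity on the cohort and its masks.
#'
#' @param data an `ehr_cohort`.
#' @param masks its `ehr_masks` (consistency is validated).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(data, masks = derive_masks(data), out_dir) {
  validate_cohort(data, masks)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  sch <- data$schema
  n <- n_records(data)

  st <- data.table::data.table(id = data$ids)
  for (f in sch$static_numeric) st[[f]] <- data$static_num[, f]
  for (f in names(sch$static_categorical)) st[[f]] <- data$static_cat[, f]
  static_path <- file.path(out_dir, "static.csv")
  data.table::fwrite(st, static_path, na = "")

  rows <- vector("list", 1 + length(sch$temporal_numeric) +
                   length(sch$temporal_categorical))
  present <- which(masks$step_present == 1, arr.ind = TRUE)
  fmt_num <- function(x) formatC(x, digits = 17, format = "g")
  rows[[1]] <- data.table::data.table(
    id = data$ids[present[, 1]], time = fmt_num(data$time[present]),
    feature = sch$time_name, value = fmt_num(data$time[present]),
    .i = present[, 1], .s = present[, 2])
  k <- 1
  for (f in sch$temporal_numeric) {
    obs <- which(masks$m_tn[, , f] == 1, arr.ind = TRUE)
    k <- k + 1
    rows[[k]] <- data.table::data.table(
      id = data$ids[obs[, 1]], time = fmt_num(data$time[obs]),
      feature = f, value = fmt_num(data$temporal_num[, , f][obs]),
      .i = obs[, 1], .s = obs[, 2])
  }
  for (f in names(sch$temporal_categorical)) {
    obs <- which(masks$m_tc[, , f] == 1, arr.ind = TRUE)
    k <- k + 1
    rows[[k]] <- data.table::data.table(
      id = data$ids[obs[, 1]], time = fmt_num(data$time[obs]),
      feature = f, value = data$temporal_cat[, , f][obs],
      .i = obs[, 1], .s = obs[, 2])
  }
  long <- data.table::rbindlist(rows)
  long <- long[order(long$.i, long$.s, method = "radix"), ]
  long[, c(".i", ".s") := NULL]
  temporal_path <- file.path(out_dir, "temporal.csv")
  data.table::fwrite(long, temporal_path, na = "")
  invisible(c(static = static_path, temporal = temporal_path))
}
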