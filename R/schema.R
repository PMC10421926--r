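#' Feature schema for heterogeneous EHR cohorts
#'
#' A schema declares, for every feature, which of the five categories it
#' belongs to: static numeric, static categorical, temporal numeric,
#' temporal categorical, or the measurement-time field. Categorical features
#' carry an ordered vocabulary; `max_seq_len` bounds the number of time
#' steps per record.
#'
#' @param static_numeric character vector of feature names.
#' @param static_categorical named list: feature name -> character vocabulary.
#' @param temporal_numeric character vector of feature names.
#' @param temporal_categorical named list: feature name -> vocabulary.
#' @param time_name name of the measurement-time field.
#' @param max_seq_len positive integer, the maximum sequence length.
#' @return an `ehr_schema` object.
#' @export
ehr_schema <- function(static_numeric = character(),
                       static_categorical = list(),
                       temporal_numeric = character(),
                       temporal_categorical = list(),
                       time_name = "time",
                       max_seq_len = 1L) {
  dedup_vocab <- function(vocs) lapply(vocs, function(v) unique(as.character(v)))
  s <- structure(list(
    static_numeric = as.character(static_numeric),
    static_categorical = dedup_vocab(static_categorical),
    temporal_numeric = as.character(temporal_numeric),
    temporal_categorical = dedup_vocab(temporal_categorical),
    time_name = as.character(time_name),
    max_seq_len = as.integer(max_seq_len)
  ), class = "ehr_schema")
  validate_schema(s)
}

validate_schema <- function(s) {
  stopifnot(inherits(s, "ehr_schema"))
  nms <- c(s$static_numeric, names(s$static_categorical),
           s$temporal_numeric, names(s$temporal_categorical))
  dup <- nms[duplicated(nms)]
  if (length(dup)) stop("duplicate feature name(s) in schema: ",
                        paste(unique(dup), collapse = ", "))
  if (s$time_name %in% nms) stop("time field '", s$time_name,
                                 "' clashes with a feature name")
  for (f in names(s$static_categorical)) {
    if (length(s$static_categorical[[f]]) < 2L)
      stop("categorical vocabulary for '", f, "' needs >= 2 entries")
  }
  for (f in names(s$temporal_categorical)) {
    if (length(s$temporal_categorical[[f]]) < 2L)
      stop("categorical vocabulary for '", f, "' needs >= 2 entries")
  }
  if (length(s$max_seq_len) != 1L || is.na(s$max_seq_len) || s$max_seq_len < 1L)
    stop("max_seq_len must be a positive integer")
  s
}

#' @export
print.ehr_schema <- function(x, ...) {
  cat("<ehr_schema>\n",
      "  static numeric:      ", length(x$static_numeric), "\n",
      "  static categorical:  ", length(x$static_categorical), "\n",
      "  temporal numeric:    ", length(x$temporal_numeric), "\n",
      "  temporal categorical:", length(x$temporal_categorical), "\n",
      "  time field:          ", x$time_name, "\n",
      "  max sequence length: ", x$max_seq_len, "\n", sep = "")
  invisible(x)
}

#' Read / write a schema config file
#'
#' The on-disk format is YAML with keys `static_numeric`,
#' `static_categorical` (map of name to vocabulary list), `temporal_numeric`,
#' `temporal_categorical`, `time_name` and `max_seq_len`. Vocabularies are
#' deduplicated preserving declared order.
#'
#' @param path path to a YAML schema file.
#' @return [load_schema()]: a validated `ehr_schema`.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  y <- yaml::read_yaml(path)
  ehr_schema(
    static_numeric = unlist(y$static_numeric) %||% character(),
    static_categorical = y$static_categorical %||% list(),
    temporal_numeric = unlist(y$temporal_numeric) %||% character(),
    temporal_categorical = y$temporal_categorical %||% list(),
    time_name = y$time_name %||% "time",
    max_seq_len = y$max_seq_len %||% 1L
  )
}

#' @rdname load_schema
#' @param schema an `ehr_schema`.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  yaml::write_yaml(list(
    time_name = schema$time_name,
    max_seq_len = schema$max_seq_len,
    static_numeric = as.list(schema$static_numeric),
    static_categorical = lapply(schema$static_categorical, as.list),
    temporal_numeric = as.list(schema$temporal_numeric),
    temporal_categorical = lapply(schema$temporal_categorical, as.list)
  ), path)
  invisible(path)
}
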