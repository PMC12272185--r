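# Readers/writers for the pipeline's on-disk formats: a binary array
# container (float64 little-endian payload + JSON sidecar header) and plain
# CSV tables.

.write_payload <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 8, endian = "little")
}

.read_payload <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 8, endian = "little")
}

#' Write / read a numeric array container
#'
#' The payload is raw float64 little-endian in R column-major order; the
#' sidecar `<path>.json` records kind, shape, units and any extra metadata,
#' making the round trip bit-exact and self-describing.
#'
#' @param arr numeric vector, matrix or array.
#' @param path payload path (sidecar written next to it).
#' @param kind container kind string.
#' @param meta named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_array_container <- function(arr, path, kind = "array", meta = list()) {
  header <- c(list(kind = kind, shape = if (is.null(dim(arr))) length(arr)
                   else dim(arr), dtype = "float64", byte_order = "little"),
              meta)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  .write_payload(arr, path)
  invisible(path)
}

#' @rdname write_array_container
#' @export
read_array_container <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath)) abort_schema("missing JSON sidecar: " %+% hpath)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (key in c("kind", "shape", "dtype"))
    if (is.null(header[[key]])) abort_schema("header missing key: " %+% key)
  if (!identical(header$dtype, "float64"))
    abort_schema("unsupported dtype: " %+% header$dtype)
  n <- prod(header$shape)
  values <- .read_payload(path, n)
  if (length(values) != n) abort_schema("payload size does not match header shape")
  if (length(header$shape) > 1) dim(values) <- header$shape
  attr(values, "header") <- header
  values
}

#' Write / read a sensor recording container
#'
#' @param rec a [sensor_recording()].
#' @param path payload path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [sensor_recording()].
#' @export
write_sensor_container <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  write_array_container(rec$data, path, kind = "sensor_recording",
                        meta = list(rate = rec$rate, units = "fT",
                                    channel_names = rec$channel_names,
                                    subject_id = rec$subject_id %||% ""))
}

#' @rdname write_sensor_container
#' @export
read_sensor_container <- function(path) {
  values <- read_array_container(path)
  h <- attr(values, "header")
  if (!identical(h$kind, "sensor_recording"))
    abort_schema("container is not a sensor recording")
  if (is.null(h$rate)) abort_schema("header missing key: rate")
  if (!identical(h$units, "fT")) abort_schema("unexpected units: " %+% h$units)
  attr(values, "header") <- NULL
  sensor_recording(values, h$rate, h$channel_names,
                   if (nzchar(h$subject_id %||% "")) h$subject_id else NULL)
}

#' Metadata and feature table CSV I/O
#'
#' Plain comma-separated UTF-8 with a header row. The metadata reader
#' enforces unique subject ids and a numeric age column.
#'
#' @param metadata data frame with subject_id, age, sex, cohort.
#' @param path file path.
#' @return Reader returns the data frame; writers return `path` invisibly.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "age") %in% names(md)))
    abort_schema("metadata must have subject_id and age columns")
  if (anyDuplicated(md$subject_id))
    abort("duplicate subject_id in metadata", "oscillage_integrity_error")
  md$age <- as.numeric(md$age)
  md
}

#' @rdname write_metadata_csv
#' @param table wide band-power data frame (subject_id + node_band columns).
#' @export
write_band_power_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_band_power_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(tab)) abort_schema("missing subject_id column")
  if (anyDuplicated(tab$subject_id))
    abort("duplicate subject_id in band-power table", "oscillage_integrity_error")
  tab
}

#' Long-form connectivity conversion
#'
#' `aec_to_long` emits the strict upper triangle as rows (node_i, node_j,
#' band, r); `long_to_aec` rebuilds the symmetric zero-diagonal matrix. The
#' two are mutually inverse.
#'
#' @param cm a [aec_matrix()] result.
#' @return A data frame (long form) or `connectivity_matrix`.
#' @export
aec_to_long <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  ut <- which(upper.tri(cm$values), arr.ind = TRUE)
  data.frame(node_i = cm$nodes[ut[, 1]], node_j = cm$nodes[ut[, 2]],
             band = cm$band, r = cm$values[ut], stringsAsFactors = FALSE)
}

#' @rdname aec_to_long
#' @param long long-form data frame as produced by `aec_to_long`.
#' @export
long_to_aec <- function(long) {
  nodes <- sort(unique(c(long$node_i, long$node_j)))
  M <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(long)))
    M[long$node_i[i], long$node_j[i]] <- long$r[i]
  M <- M + t(M)
  diag(M) <- 0
  structure(list(values = M, band = unique(long$band)[1], nodes = nodes),
            class = "connectivity_matrix")
}
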