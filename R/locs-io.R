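#' Construct a localization table
#'
#' The molecular-coordinate list a STORM reconstruction produces: one row
#' per fitted fluorophore position, coordinates in nm. `z_nm` and `frame`
#' are optional.
#'
#' @param x_nm,y_nm numeric coordinate vectors (required, equal length).
#' @param z_nm optional numeric vector.
#' @param frame optional nonnegative integer vector (camera frame index).
#' @param axon_id single identifier shared by all rows.
#' @param meta free-form provenance list (seed, generative parameters, ...).
#' @return data.frame of class `loc_table` with an `axon_id` column first
#'   and a `meta` attribute.
#' @export
loc_table <- function(x_nm, y_nm, z_nm = NULL, frame = NULL,
                      axon_id = "axon", meta = list()) {
  stopifnot(is.numeric(x_nm), is.numeric(y_nm),
            length(x_nm) == length(y_nm))
  if (length(x_nm) > 0 && (!all(is.finite(x_nm)) || !all(is.finite(y_nm))))
    stop("coordinates must be finite", call. = FALSE)
  if (!is.character(axon_id) || length(axon_id) != 1L)
    stop("axon_id must be a single string", call. = FALSE)
  df <- data.frame(axon_id = rep(axon_id, length(x_nm)),
                   x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   stringsAsFactors = FALSE)
  if (!is.null(z_nm)) {
    stopifnot(length(z_nm) == length(x_nm))
    if (length(z_nm) > 0 && !all(is.finite(z_nm)))
      stop("coordinates must be finite", call. = FALSE)
    df$z_nm <- as.numeric(z_nm)
  }
  if (!is.null(frame)) {
    stopifnot(length(frame) == length(x_nm), all(frame >= 0))
    df$frame <- as.integer(frame)
  }
  attr(df, "meta") <- meta
  class(df) <- c("loc_table", "data.frame")
  df
}

loc_columns <- c("axon_id", "x_nm", "y_nm", "z_nm", "frame")

#' Write a localization table as delimited text
#'
#' Native format: comma-separated, header from
#' `axon_id,x_nm,y_nm,z_nm,frame` restricted to the columns present, Unix
#' line endings. Coordinates are printed with 17 significant digits so a
#' write/read round trip reproduces every double bit-exactly, and repeated
#' writes of the same table are byte-identical. A `<path>.meta` sidecar in
#' `key: value` lines records the metadata.
#'
#' @param table a [loc_table()].
#' @param path output file path.
#' @param sidecar write the metadata sidecar? (default TRUE when metadata
#'   is present).
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path, sidecar = length(attr(table, "meta")) > 0) {
  stopifnot(inherits(table, "loc_table"))
  cols <- intersect(loc_columns, names(table))
  fmt_num <- function(v) sprintf("%.17g", v)
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(vapply(cols, function(cn) {
      v <- table[[cn]][i]
      if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v)
    }, character(1)), collapse = ",")
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","), body), con, sep = "\n")
  if (sidecar)
    write_meta_sidecar(attr(table, "meta"), paste0(path, ".meta"))
  invisible(path)
}

write_meta_sidecar <- function(meta, path) {
  flat <- unlist(meta)
  lines <- sprintf("%s: %s", names(flat),
                   vapply(flat, function(v)
                     if (is.numeric(v)) sprintf("%.17g", v) else as.character(v),
                     character(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a localization table from delimited text
#'
#' `dialect = "native"` expects the format written by [write_locs()].
#' `dialect = "generic"` reads any delimited file given a column `mapping`
#' from native names to the file's column names, e.g.
#' `c(x_nm = "x [nm]", y_nm = "y [nm]")`; coordinates are multiplied by
#' `scale` to coerce them to nm.
#'
#' @param path file to read.
#' @param dialect `"native"` or `"generic"`.
#' @param mapping named character vector for `"generic"`; must map at
#'   least `x_nm` and `y_nm`.
#' @param scale unit factor applied to mapped coordinates (e.g. 1000 for a
#'   file in microns).
#' @param axon_id identifier to assign when the file carries none.
#' @return a [loc_table()]; unmapped columns are preserved in the `meta`
#'   attribute under `extra_columns`.
#' @export
read_locs <- function(path, dialect = c("native", "generic"),
                      mapping = NULL, scale = 1, axon_id = "axon") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("format error: empty localization file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L)
    stop("format error: no localization rows in ", path, call. = FALSE)
  if (dialect == "generic") {
    if (is.null(mapping) || !all(c("x_nm", "y_nm") %in% names(mapping)))
      stop("generic dialect needs a mapping for at least x_nm and y_nm",
           call. = FALSE)
    missing_cols <- setdiff(unname(mapping), names(raw))
    if (length(missing_cols) > 0)
      stop("format error: mapped columns absent from file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    out <- data.frame(row.names = seq_len(nrow(raw)))
    for (nm in names(mapping)) out[[nm]] <- raw[[mapping[[nm]]]]
    extra <- raw[setdiff(names(raw), unname(mapping))]
    raw <- out
    attr_extra <- if (ncol(extra) > 0) extra else NULL
  } else {
    if (!all(c("x_nm", "y_nm") %in% names(raw)))
      stop("format error: native table must contain x_nm and y_nm columns",
           call. = FALSE)
    attr_extra <- NULL
  }
  for (cn in intersect(c("x_nm", "y_nm", "z_nm"), names(raw))) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("format error: non-numeric %s at row %d", cn, bad[1]),
             call. = FALSE)
      raw[[cn]] <- coerced
    }
    if (cn %in% names(mapping) || dialect == "generic")
      raw[[cn]] <- raw[[cn]] * scale
  }
  id <- if ("axon_id" %in% names(raw)) as.character(raw$axon_id[1]) else axon_id
  meta <- list()
  if (!is.null(attr_extra)) meta$extra_columns <- attr_extra
  loc_table(x_nm = raw$x_nm, y_nm = raw$y_nm,
            z_nm = if ("z_nm" %in% names(raw)) raw$z_nm else NULL,
            frame = if ("frame" %in% names(raw)) raw$frame else NULL,
            axon_id = id, meta = meta)
}
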