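# Data-of-record container: one archive file per lens slice.
#
# The container is an RDS-serialized named list mirroring the namespace
# layout axes/ pixels/ mask/ truth/ raw/ meta; RDS gives bit-identical
# round trips without extra dependencies. All derived tables are written
# as plain TSV so results stay diffable.

CUBE_FORMAT_VERSION <- "1.0"

#' Write a tissue cube to its container file
#'
#' @param cube A \code{TissueCube}.
#' @param path Output file path (conventionally \code{.rds}).
#' @param raw Optional raw time-domain record stored under \code{raw}.
#' @return \code{path}, invisibly.
#' @export
write_cube <- function(cube, path, raw = NULL) {
  if (prod(dim(cube$amplitude)[1:2]) == 0) stop("empty cube")
  obj <- list(format_version = CUBE_FORMAT_VERSION,
              axes = list(pump_axis = cube$pump_axis,
                          probe_axis = cube$probe_axis),
              pixels = cube$amplitude,
              mask = cube$mask,
              truth = cube$truth,
              raw = raw,
              meta = cube$meta)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a tissue cube from its container file
#'
#' Validates the format version and array-shape consistency; corrupt or
#' truncated files produce a named format error rather than a crash.
#'
#' @param path Container file path.
#' @return A \code{TissueCube}; any raw record is attached as attribute
#'   \code{"raw"}.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("unreadable or truncated cube container '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version))
    stop("not a cube container (missing format_version): ", path)
  if (obj$format_version != CUBE_FORMAT_VERSION)
    stop("unsupported cube format_version '", obj$format_version,
         "' (supported: ", CUBE_FORMAT_VERSION, ")")
  d <- dim(obj$pixels)
  if (length(d) != 4L || d[3] != length(obj$axes$pump_axis) ||
      d[4] != length(obj$axes$probe_axis))
    stop("cube container shape inconsistency: pixel stack ",
         paste(d, collapse = "x"), " does not match axes")
  if (prod(d[1:2]) == 0) stop("empty cube: ", path)
  cube <- tissue_cube(obj$axes$pump_axis, obj$axes$probe_axis, obj$pixels,
                      obj$mask, truth = obj$truth, meta = obj$meta)
  attr(cube, "raw") <- obj$raw
  cube
}

#' Write a feature map (or any matrix) as plain matrix text
#'
#' @param m A \code{FeatureMap} or numeric matrix.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_map_tsv <- function(m, path) {
  values <- if (inherits(m, "FeatureMap")) m$values else m
  utils::write.table(values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
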