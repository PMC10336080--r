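#' Minimal NetCDF (classic CDF-1) reader and writer
#'
#' The gridded product is stored in the NetCDF classic binary format
#' (magic `CDF\\x01`, big-endian, fixed dimensions), which every mainstream
#' NetCDF stack reads. No NetCDF library bindings ship with this
#' environment, so the package carries its own codec for the small subset
#' it needs: fixed (non-record) dimensions, `char`/`int`/`float`/`double`
#' variables and attributes. Round-trips are checked in the test suite,
#' including against an independent SciPy reader.
#'
#' @name netcdf_io
NULL

.NC_TYPES <- c(char = 2L, int = 4L, float = 5L, double = 6L)
.NC_SIZE <- c(char = 1L, int = 4L, float = 4L, double = 8L)

.nc_put_int <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "big")

.nc_put_name <- function(con, name) {
  b <- charToRaw(name)
  .nc_put_int(con, length(b))
  writeBin(b, con)
  if (length(b) %% 4) writeBin(raw(4 - length(b) %% 4), con)
}

.nc_put_values <- function(con, type, values) {
  nb <- switch(type,
    char = { b <- charToRaw(values); writeBin(b, con); length(b) },
    int = { .nc_put_int(con, values); 4L * length(values) },
    float = { writeBin(as.numeric(values), con, size = 4L, endian = "big")
              4L * length(values) },
    double = { writeBin(as.numeric(values), con, size = 8L, endian = "big")
               8L * length(values) })
  if (nb %% 4) writeBin(raw(4 - nb %% 4), con)
}

.nc_put_attrs <- function(con, attrs, num_type = "double") {
  if (length(attrs) == 0) { .nc_put_int(con, 0L); .nc_put_int(con, 0L); return(invisible()) }
  .nc_put_int(con, 12L)             # NC_ATTRIBUTE
  .nc_put_int(con, length(attrs))
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    type <- if (is.character(v)) "char" else if (nm == "_FillValue") num_type else "double"
    .nc_put_name(con, nm)
    .nc_put_int(con, .NC_TYPES[[type]])
    .nc_put_int(con, if (type == "char") nchar(v, type = "bytes") else length(v))
    .nc_put_values(con, type, v)
  }
}

#' Write a NetCDF classic file
#'
#' @param path output path.
#' @param dims named list of coordinate vectors (e.g. `time`, `lat`, `lon`);
#'   each also becomes a `double` coordinate variable.
#' @param vars named list; each element is a list with `data` (array whose
#'   dimensions follow `dims`, slowest first), `dims` (character vector of
#'   dimension names, slowest first), optional `type`
#'   (`"float"`/`"double"`, default `"float"`) and `attrs` (named list).
#'   `NA` values are stored as the `_FillValue` (default NaN).
#' @param global_attrs named list of global attributes.
#' @param dim_attrs optional named list of attribute lists for coordinate
#'   variables.
#' @return invisibly, `path`.
#' @export
nc_write <- function(path, dims, vars, global_attrs = list(),
                     dim_attrs = list()) {
  dim_names <- names(dims)
  dim_sizes <- vapply(dims, length, integer(1))
  all_vars <- c(
    stats::setNames(lapply(dim_names, function(d)
      list(data = as.numeric(dims[[d]]), dims = d, type = "double",
           attrs = dim_attrs[[d]] %||% list())), dim_names),
    vars)
  for (nm in names(all_vars)) {
    v <- all_vars[[nm]]
    v$type <- v$type %||% "float"
    v$attrs <- v$attrs %||% list()
    want <- unname(dim_sizes[v$dims])
    got <- if (is.null(dim(v$data))) length(v$data) else dim(v$data)
    if (!identical(as.integer(got), as.integer(want)))
      stopf("variable %s: data shape (%s) does not match dims (%s)", nm,
            paste(got, collapse = "x"), paste(want, collapse = "x"))
    if (v$type %in% c("float", "double") && anyNA(v$data)) {
      fill <- v$attrs[["_FillValue"]] %||% NaN
      v$attrs[["_FillValue"]] <- fill
      v$data[is.na(v$data)] <- fill
    }
    all_vars[[nm]] <- v
  }
  serialize_header <- function(con, begins) {
    writeBin(charToRaw("CDF"), con); writeBin(as.raw(1L), con)
    .nc_put_int(con, 0L)                       # numrecs
    .nc_put_int(con, 10L)                      # NC_DIMENSION
    .nc_put_int(con, length(dims))
    for (d in dim_names) { .nc_put_name(con, d); .nc_put_int(con, dim_sizes[[d]]) }
    .nc_put_attrs(con, global_attrs)
    .nc_put_int(con, 11L)                      # NC_VARIABLE
    .nc_put_int(con, length(all_vars))
    for (nm in names(all_vars)) {
      v <- all_vars[[nm]]
      .nc_put_name(con, nm)
      .nc_put_int(con, length(v$dims))
      for (d in v$dims) .nc_put_int(con, match(d, dim_names) - 1L)
      .nc_put_attrs(con, v$attrs, num_type = v$type)
      .nc_put_int(con, .NC_TYPES[[v$type]])
      nbytes <- .NC_SIZE[[v$type]] * prod(unname(dim_sizes[v$dims]))
      .nc_put_int(con, as.integer(ceiling(nbytes / 4) * 4))  # vsize
      .nc_put_int(con, begins[[nm]])
    }
  }
  # pass 1: measure header, then lay out data offsets
  con <- rawConnection(raw(0), "wb")
  serialize_header(con, stats::setNames(rep(0L, length(all_vars)), names(all_vars)))
  header_len <- length(rawConnectionValue(con))
  close(con)
  begins <- list(); pos <- header_len
  for (nm in names(all_vars)) {
    v <- all_vars[[nm]]
    begins[[nm]] <- pos
    nbytes <- .NC_SIZE[[v$type]] * prod(unname(dim_sizes[v$dims]))
    pos <- pos + as.integer(ceiling(nbytes / 4) * 4)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  serialize_header(con, begins)
  for (nm in names(all_vars)) {
    v <- all_vars[[nm]]
    x <- v$data
    if (length(v$dims) > 1)                     # C order: last dim fastest
      x <- as.vector(aperm(x, rev(seq_along(v$dims))))
    .nc_put_values(con, v$type, x)
  }
  invisible(path)
}

#' Read a NetCDF classic file written by [nc_write()] (or any CDF-1/2 file
#' using fixed dimensions)
#'
#' @param path file path.
#' @return list with `dims` (named coordinate vectors where a matching
#'   coordinate variable exists, else sizes), `vars` (named list of
#'   `data`/`dims`/`type`/`attrs`; `_FillValue` and NaN become `NA`), and
#'   `global_attrs`.
#' @export
nc_read <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  pos <- 0L
  take <- function(n) { r <- raw_all[(pos + 1L):(pos + n)]; pos <<- pos + n; r }
  get_int <- function(n = 1L) readBin(take(4L * n), "integer", n, size = 4L, endian = "big")
  get_name <- function() {
    n <- get_int()
    s <- rawToChar(take(n))
    if (n %% 4) take(4L - n %% 4L)
    s
  }
  get_values <- function(type_id, nelems) {
    type <- names(.NC_TYPES)[match(type_id, .NC_TYPES)]
    nb <- .NC_SIZE[[type]] * nelems
    v <- switch(type,
      char = rawToChar(take(nelems)),
      int = readBin(take(nb), "integer", nelems, size = 4L, endian = "big"),
      float = readBin(take(nb), "numeric", nelems, size = 4L, endian = "big"),
      double = readBin(take(nb), "numeric", nelems, size = 8L, endian = "big"))
    if (nb %% 4) take(4L - nb %% 4L)
    list(values = v, type = type)
  }
  get_attrs <- function() {
    tag <- get_int(); n <- get_int()
    if (tag == 0L || n == 0L) return(list())
    out <- list()
    for (i in seq_len(n)) {
      nm <- get_name()
      out[[nm]] <- get_values(get_int(), get_int())$values
    }
    out
  }
  magic <- take(4L)
  if (rawToChar(magic[1:3]) != "CDF") stopf("%s is not a classic NetCDF file", path)
  version <- as.integer(magic[4])
  if (!version %in% c(1L, 2L)) stopf("unsupported NetCDF variant")
  get_int()                                     # numrecs
  tag <- get_int(); ndims <- get_int()
  dim_names <- character(ndims); dim_sizes <- integer(ndims)
  if (tag == 10L) for (i in seq_len(ndims)) {
    dim_names[i] <- get_name(); dim_sizes[i] <- get_int()
  }
  global_attrs <- get_attrs()
  tag <- get_int(); nvars <- get_int()
  vars <- list()
  if (tag == 11L) for (i in seq_len(nvars)) {
    nm <- get_name()
    nd <- get_int()
    dimids <- if (nd > 0) get_int(nd) + 1L else integer(0)
    attrs <- get_attrs()
    type_id <- get_int()
    get_int()                                   # vsize
    begin <- if (version == 2L) {
      hi <- get_int(); lo <- get_int(); hi * 2^32 + (lo %% 2^32)
    } else get_int()
    vars[[nm]] <- list(dimids = dimids, attrs = attrs, type_id = type_id,
                       begin = begin)
  }
  out_vars <- list()
  for (nm in names(vars)) {
    v <- vars[[nm]]
    pos <- as.integer(v$begin)
    sizes <- dim_sizes[v$dimids]
    gv <- get_values(v$type_id, as.integer(prod(sizes)))
    data <- gv$values
    if (gv$type %in% c("float", "double")) {
      fill <- v$attrs[["_FillValue"]]
      if (!is.null(fill) && !is.nan(fill))
        data[!is.na(data) & data == fill] <- NA_real_
      data[is.nan(data)] <- NA_real_
    }
    if (length(sizes) > 1) {
      data <- array(data, dim = rev(sizes))     # stream is last-dim fastest
      data <- aperm(data, rev(seq_along(sizes)))
    }
    out_vars[[nm]] <- list(data = data, dims = dim_names[v$dimids],
                           type = gv$type, attrs = v$attrs)
  }
  dims_out <- stats::setNames(as.list(dim_sizes), dim_names)
  for (d in dim_names)
    if (!is.null(out_vars[[d]])) dims_out[[d]] <- out_vars[[d]]$data
  list(dims = dims_out, vars = out_vars[setdiff(names(out_vars), dim_names)],
       global_attrs = global_attrs)
}
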