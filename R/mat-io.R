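# Minimal MATLAB Level-5 (.mat) reader/writer for numeric arrays.
#
# No MAT-file package ships with this environment, so the package carries the
# small subset of the Level-5 container that NinaPro files use: little-endian
# files holding real numeric arrays (double, single, 8/16/32-bit integers),
# plain or zlib-compressed elements, and the "small data element" packing used
# for short subelements such as array names.  Character, cell, struct, sparse
# and complex arrays are out of scope and rejected with a clear error.

# MAT-file data type codes
.MI_INT8 <- 1L; .MI_UINT8 <- 2L; .MI_INT16 <- 3L; .MI_UINT16 <- 4L
.MI_INT32 <- 5L; .MI_UINT32 <- 6L; .MI_SINGLE <- 7L; .MI_DOUBLE <- 9L
.MI_MATRIX <- 14L; .MI_COMPRESSED <- 15L
.MX_DOUBLE <- 6L

.mi_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
              `7` = 4L, `9` = 8L)

.read_u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

.read_i32 <- function(raw, at) {
  readBin(raw[at:(at + 3L)], "integer", size = 4L, endian = "little")
}

# Parse one tagged data element starting at `pos` (1-based).  Returns
# list(type, data = raw payload, next_pos).
.mat_element <- function(raw, pos) {
  if (pos + 3L > length(raw)) stopf("corrupted MAT file: truncated element tag")
  small_nb <- .read_u16(raw, pos + 2L)
  if (small_nb > 0L) {                      # small data element format
    type <- .read_u16(raw, pos)
    nb <- small_nb
    dat <- if (nb > 0L) raw[(pos + 4L):(pos + 3L + nb)] else raw(0)
    list(type = type, data = dat, next_pos = pos + 8L)
  } else {
    type <- .read_i32(raw, pos)
    nb <- .read_i32(raw, pos + 4L)
    dat <- if (nb > 0L) raw[(pos + 8L):(pos + 7L + nb)] else raw(0)
    pad <- (8L - nb %% 8L) %% 8L
    list(type = type, data = dat, next_pos = pos + 8L + nb + pad)
  }
}

.decode_numeric <- function(type, dat) {
  n <- length(dat) %/% .mi_size[[as.character(type)]]
  switch(as.character(type),
    `9` = readBin(dat, "double", n = n, size = 8L, endian = "little"),
    `7` = readBin(dat, "double", n = n, size = 4L, endian = "little"),
    `1` = as.numeric(readBin(dat, "integer", n = n, size = 1L, signed = TRUE)),
    `2` = as.numeric(readBin(dat, "integer", n = n, size = 1L, signed = FALSE)),
    `3` = as.numeric(readBin(dat, "integer", n = n, size = 2L, signed = TRUE,
                             endian = "little")),
    `4` = as.numeric(readBin(dat, "integer", n = n, size = 2L, signed = FALSE,
                             endian = "little")),
    `5` = as.numeric(readBin(dat, "integer", n = n, size = 4L, endian = "little")),
    `6` = {
      v <- as.numeric(readBin(dat, "integer", n = n, size = 4L, endian = "little"))
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    stopf("unsupported MAT numeric data type code %d", type))
}

.parse_mi_matrix <- function(dat) {
  el <- .mat_element(dat, 1L)               # array flags
  if (el$type != .MI_UINT32) stopf("corrupted MAT file: bad array-flags element")
  mx_class <- as.integer(el$data[1L])
  flags <- as.integer(el$data[2L])
  if (bitwAnd(flags, 8L) != 0L) stopf("complex MAT arrays are not supported")
  el <- .mat_element(dat, el$next_pos)      # dimensions
  dims <- readBin(el$data, "integer", n = length(el$data) %/% 4L,
                  size = 4L, endian = "little")
  el <- .mat_element(dat, el$next_pos)      # array name
  name <- rawToChar(el$data)
  if (!(mx_class %in% c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)))
    return(list(name = name, value = NULL))   # skip non-numeric classes
  el <- .mat_element(dat, el$next_pos)      # real part
  v <- .decode_numeric(el$type, el$data)
  if (length(v) != prod(dims))
    stopf("corrupted MAT file: array '%s' has %d values for dims [%s]",
          name, length(v), paste(dims, collapse = "x"))
  if (length(dims) == 2L && dims[2L] == 1L) dim(v) <- NULL
  else dim(v) <- dims
  list(name = name, value = v)
}

#' Read numeric arrays from a MATLAB Level-5 .mat file
#'
#' Supports the subset of the format that NinaPro recordings use: real numeric
#' arrays (stored as double/single/integer), optionally zlib-compressed.
#' Column vectors are returned as plain vectors; everything else keeps its
#' stored dimensions (MATLAB and R share column-major order).
#'
#' @param path path to a `.mat` file.
#' @return named list of numeric vectors/arrays.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L) stopf("not a MAT v5 file (too short): %s", path)
  endian_mark <- rawToChar(raw[127:128])
  if (endian_mark != "IM")
    stopf("unsupported MAT file (big-endian or not v5): %s", path)
  out <- list()
  pos <- 129L
  while (pos <= length(raw) - 7L) {
    # top-level elements are miMATRIX or miCOMPRESSED; skip alignment zeros
    if (raw[pos] == as.raw(0L)) { pos <- pos + 1L; next }
    el <- .mat_element(raw, pos)
    payload <- el$data
    type <- el$type
    if (type == .MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- .mat_element(payload, 1L)
      type <- inner$type
      payload <- inner$data
      # compressed elements are written unpadded (scipy, MATLAB)
      el$next_pos <- pos + 8L + length(el$data)
    }
    if (type == .MI_MATRIX) {
      m <- .parse_mi_matrix(payload)
      if (!is.null(m$value)) out[[m$name]] <- m$value
    }
    pos <- el$next_pos
  }
  out
}

.pad8 <- function(con, nbytes) {
  pad <- (8L - nbytes %% 8L) %% 8L
  if (pad > 0L) writeBin(raw(pad), con)
}

.write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
}

#' Write numeric arrays to a MATLAB Level-5 .mat file
#'
#' All values are stored as doubles (mxDOUBLE_CLASS), uncompressed.  Vectors
#' are written as n-by-1 column vectors, matching MATLAB convention.
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    stopf("write_mat() needs a fully named list")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by semgfusion on %s",
                           format(Sys.time(), "%Y-%m-%d")))
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                  # subsys offset
  writeBin(as.integer(0x0100), con, size = 2L, endian = "little")
  writeChar("IM", con, eos = NULL)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v)) stopf("variable '%s' is not numeric", nm)
    dims <- if (is.null(dim(v))) c(length(v), 1L) else dim(v)
    name_raw <- charToRaw(nm)
    sz_dims <- 8L + 4L * length(dims); sz_dims <- sz_dims + (8L - sz_dims %% 8L) %% 8L
    sz_name <- 8L + length(name_raw); sz_name <- sz_name + (8L - sz_name %% 8L) %% 8L
    sz_data <- 8L + 8L * length(v)
    total <- 16L + sz_dims + sz_name + sz_data
    .write_tag(con, .MI_MATRIX, total)
    .write_tag(con, .MI_UINT32, 8L)                       # array flags
    writeBin(as.integer(c(.MX_DOUBLE, 0L)), con, size = 4L, endian = "little")
    .write_tag(con, .MI_INT32, 4L * length(dims))         # dimensions
    writeBin(as.integer(dims), con, size = 4L, endian = "little")
    .pad8(con, 4L * length(dims))
    .write_tag(con, .MI_INT8, length(name_raw))           # name
    writeBin(name_raw, con)
    .pad8(con, length(name_raw))
    .write_tag(con, .MI_DOUBLE, 8L * length(v))           # real part
    writeBin(as.double(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}
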