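# Minimal MAT-file (level 5) reader/writer for numeric arrays.
#
# Covers what the DEAP per-subject files need: named double/integer arrays at
# the top level, little- or big-endian, including the zlib-compressed elements
# of the v7 variant (decompressed with memDecompress). Cell/struct/char
# variables are skipped. Writing always produces uncompressed little-endian
# v5 double arrays.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mat5_pad8 <- function(r) c(r, raw((8L - length(r) %% 8L) %% 8L))

mat5_element <- function(type, payload) {
  tag <- writeBin(as.integer(c(type, length(payload))), raw(),
                  size = 4L, endian = "little")
  c(tag, mat5_pad8(payload))
}

mat5_matrix_element <- function(name, x) {
  x <- as.array(x)
  dims <- dim(x) %||% length(x)
  if (length(dims) == 1) dims <- c(dims, 1L)
  flags <- writeBin(as.integer(c(6L, 0L)), raw(), size = 4L,
                    endian = "little")  # mxDOUBLE_CLASS
  sub <- c(
    mat5_element(MI_UINT32, flags),
    mat5_element(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L,
                                    endian = "little")),
    mat5_element(MI_INT8, charToRaw(name)),
    mat5_element(MI_DOUBLE, writeBin(as.numeric(x), raw(), size = 8L,
                                     endian = "little"))
  )
  mat5_element(MI_MATRIX, sub)
}

#' Write numeric arrays to a MATLAB v5 file
#'
#' @param path output path.
#' @param vars named list of numeric vectors/matrices/arrays.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(path, vars) {
  stopifnot(length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- charToRaw(paste0("MATLAB 5.0 MAT-file, written by dbfn, ",
                           format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  desc <- c(desc, rep(charToRaw(" "), 116L - length(desc)))
  writeBin(desc, con)
  writeBin(raw(8L), con)  # subsystem data offset
  writeBin(writeBin(as.integer(256L), raw(), size = 2L, endian = "little"), con)
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) writeBin(mat5_matrix_element(nm, vars[[nm]]), con)
  invisible(path)
}

# parse one tagged element; returns list(type, data raw, next_pos)
mat5_read_tag <- function(r, pos, endian) {
  hi <- if (endian == "little") r[pos + 2:3] else r[pos + 0:1]
  if (any(hi != as.raw(0))) {  # small data element: type/size packed in 4 bytes
    if (endian == "little") {
      type <- readBin(r[pos + 0:1], "integer", size = 2L, endian = endian)
      nb <- readBin(r[pos + 2:3], "integer", size = 2L, endian = endian)
    } else {
      nb <- readBin(r[pos + 2:3], "integer", size = 2L, endian = endian)
      type <- readBin(r[pos + 0:1], "integer", size = 2L, endian = endian)
    }
    dat <- if (nb > 0) r[(pos + 4):(pos + 3 + nb)] else raw(0)
    list(type = type, data = dat, next_pos = pos + 8L)
  } else {
    type <- readBin(r[pos + 0:3], "integer", size = 4L, endian = endian)
    nb <- readBin(r[pos + 4:7], "integer", size = 4L, endian = endian)
    dat <- if (nb > 0) r[(pos + 8):(pos + 7 + nb)] else raw(0)
    pad <- (8L - nb %% 8L) %% 8L
    list(type = type, data = dat, next_pos = pos + 8L + nb + pad)
  }
}

mat5_decode_numeric <- function(type, data, endian) {
  dec <- function(what, size, signed = TRUE)
    readBin(data, what, n = length(data) %/% size, size = size,
            signed = signed, endian = endian)
  switch(as.character(type),
         "1" = dec("integer", 1L),
         "2" = dec("integer", 1L, signed = FALSE),
         "3" = dec("integer", 2L),
         "4" = dec("integer", 2L, signed = FALSE),
         "5" = dec("integer", 4L),
         "6" = dec("integer", 4L),  # uint32; values beyond 2^31 unsupported
         "7" = dec("double", 4L),
         "9" = dec("double", 8L),
         stop("unsupported MAT data type: ", type))
}

mat5_parse_matrix <- function(payload, endian) {
  pos <- 1L
  flags <- mat5_read_tag(payload, pos, endian)
  cls <- as.integer(readBin(flags$data[1:4], "integer", size = 4L,
                            endian = endian)) %% 256L
  pos <- flags$next_pos
  dims_el <- mat5_read_tag(payload, pos, endian)
  dims <- readBin(dims_el$data, "integer",
                  n = length(dims_el$data) %/% 4L, size = 4L, endian = endian)
  pos <- dims_el$next_pos
  name_el <- mat5_read_tag(payload, pos, endian)
  name <- rawToChar(name_el$data)
  pos <- name_el$next_pos
  if (!cls %in% 6:13)  # only numeric classes are supported
    return(list(name = name, value = NULL))
  pr <- mat5_read_tag(payload, pos, endian)
  vals <- as.numeric(mat5_decode_numeric(pr$type, pr$data, endian))
  if (length(vals) != prod(dims))
    stop("array '", name, "': expected ", prod(dims),
         " values, found ", length(vals))
  dim(vals) <- dims
  list(name = name, value = vals)
}

#' Read numeric arrays from a MATLAB v5/v7 file
#'
#' @param path path to the `.mat` file.
#' @return named list of numeric arrays (non-numeric variables are skipped).
#' @export
read_mat5 <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 136L) stop("not a MAT v5 file (too short): ", path)
  mark <- rawToChar(r[127:128])
  endian <- if (mark == "IM") "little" else if (mark == "MI") "big"
            else stop("not a MAT v5 file (bad endian mark): ", path)
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(r)) {
    el <- mat5_read_tag(r, pos, endian)
    payload <- el$data
    type <- el$type
    if (type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- mat5_read_tag(payload, 1L, endian)
      type <- inner$type
      payload <- inner$data
    }
    if (type == MI_MATRIX) {
      v <- mat5_parse_matrix(payload, endian)
      if (!is.null(v$value)) out[[v$name]] <- v$value
    }
    pos <- el$next_pos
  }
  out
}
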