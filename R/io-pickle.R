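# Bridge to the pickled-Python DEAP dialect through the system Python
# interpreter (numpy + pickle). Arrays cross the bridge as a flat
# little-endian float64 stream in column-major (Fortran) order, so no pickle
# parsing happens in R.

python_bin <- function() {
  p <- Sys.getenv("DBFN_PYTHON", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    w <- Sys.which(cand)
    if (nzchar(w)) return(w)
  }
  stop("no python interpreter on PATH; needed for the pickled dialect ",
       "(set DBFN_PYTHON to override)")
}

run_python <- function(code, args) {
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script))
  writeLines(code, script)
  res <- suppressWarnings(
    system2(python_bin(), c(script, args), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0)
    stop("python bridge failed: ", paste(res, collapse = "\n"))
  invisible(res)
}

# binary exchange layout: int32 n_arrays, then per array:
#   int32 name_len, name bytes, int32 ndim, int32 dims..., float64 values (F order)

read_exchange_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", size = 4L, endian = "little")
  out <- list()
  for (i in seq_len(n)) {
    nl <- readBin(con, "integer", size = 4L, endian = "little")
    nm <- rawToChar(readBin(con, "raw", nl))
    nd <- readBin(con, "integer", size = 4L, endian = "little")
    dims <- readBin(con, "integer", n = nd, size = 4L, endian = "little")
    v <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
    dim(v) <- dims
    out[[nm]] <- v
  }
  out
}

write_exchange_bin <- function(path, vars) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(vars), con, size = 4L, endian = "little")
  for (nm in names(vars)) {
    x <- as.array(vars[[nm]])
    writeBin(nchar(nm, type = "bytes"), con, size = 4L, endian = "little")
    writeBin(charToRaw(nm), con)
    writeBin(length(dim(x)), con, size = 4L, endian = "little")
    writeBin(as.integer(dim(x)), con, size = 4L, endian = "little")
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  invisible(path)
}

py_unpickle_code <- "
import pickle, struct, sys
import numpy as np
with open(sys.argv[1], 'rb') as f:
    d = pickle.load(f, encoding='latin1')
keys = [k for k in d if isinstance(d[k], np.ndarray) or hasattr(d[k], '__array__')]
with open(sys.argv[2], 'wb') as out:
    out.write(struct.pack('<i', len(keys)))
    for k in keys:
        a = np.asarray(d[k], dtype=np.float64)
        kb = k.encode('utf-8')
        out.write(struct.pack('<i', len(kb)))
        out.write(kb)
        out.write(struct.pack('<i', a.ndim))
        out.write(struct.pack('<%di' % a.ndim, *a.shape))
        out.write(a.tobytes(order='F'))
"

py_pickle_code <- "
import pickle, struct, sys
import numpy as np
d = {}
with open(sys.argv[1], 'rb') as f:
    n, = struct.unpack('<i', f.read(4))
    for _ in range(n):
        nl, = struct.unpack('<i', f.read(4))
        name = f.read(nl).decode('utf-8')
        nd, = struct.unpack('<i', f.read(4))
        dims = struct.unpack('<%di' % nd, f.read(4 * nd))
        cnt = int(np.prod(dims))
        a = np.frombuffer(f.read(8 * cnt), dtype='<f8').reshape(dims, order='F')
        d[name] = a
with open(sys.argv[2], 'wb') as out:
    pickle.dump(d, out, protocol=2)
"

#' Read numeric arrays from a pickled-Python file
#'
#' Unpickles (with `encoding = "latin1"`, matching the Python-2-era DEAP
#' release) a dict of numpy arrays via the system Python interpreter.
#'
#' @param path path to the pickle file.
#' @return named list of numeric arrays.
#' @export
read_pickle_arrays <- function(path) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  run_python(py_unpickle_code, c(path, tmp))
  read_exchange_bin(tmp)
}

#' Write numeric arrays to a pickled-Python file
#'
#' @param path output path.
#' @param vars named list of numeric arrays.
#' @return `path`, invisibly.
#' @export
write_pickle_arrays <- function(path, vars) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  write_exchange_bin(tmp, vars)
  run_python(py_pickle_code, c(tmp, path))
  invisible(path)
}
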