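# Serialization of task sequences: a directory of per-task arrays
# (X_t / Y_t as NPY, with a CSV mirror for the labels) plus a JSON manifest
# holding the protocol, parameters and seed. The NPY reader/writer below
# covers the subset of the format the package needs — version 1.0, C-order,
# 1-D/2-D numeric arrays — so sequences interoperate with numpy without an
# external dependency.

#' Write a numeric vector or matrix as an NPY file
#'
#' NPY version 1.0, little-endian float64 (`<f8`), C (row-major) order.
#'
#' @param x numeric vector or matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  dims <- if (is.matrix(x)) dim(x) else length(x)
  shape <- if (length(dims) == 1) sprintf("(%d,)", dims) else
    sprintf("(%d, %d)", dims[1], dims[2])
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  if (pad == 64) pad <- 0
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  vals <- if (is.matrix(x)) as.vector(t(x)) else as.numeric(x)
  writeBin(vals, con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY file written by numpy or by [write_npy()]
#'
#' Supports version 1.0/2.0 headers, C or Fortran order, and numeric
#' dtypes `<f8`, `<f4`, `<i8`, `<i4`, `|u1` (returned as doubles).
#'
#' @param path NPY file path.
#' @return a numeric vector (1-D) or matrix (2-D).
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  assert_that(identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))),
              sprintf("%s is not an NPY file", path))
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  assert_that(length(shape) %in% c(1L, 2L),
              sprintf("unsupported NPY rank %d", length(shape)))
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4, endian = "little"),
    "<i8" = {
      # decode little-endian two's-complement int64 via raw bytes (values
      # beyond 2^53 are not expected in task data); negatives are decoded
      # from the complemented bytes to avoid forming 2^64 in a double
      m <- matrix(as.integer(readBin(con, "raw", 8 * n)), nrow = 8)
      neg <- m[8, ] >= 128L
      pw <- 2^(8 * (0:7))
      pos_v <- colSums(m * pw)
      neg_v <- -(colSums((255L - m) * pw) + 1)
      ifelse(neg, neg_v, pos_v)
    },
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "|u1" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    stop(sprintf("unsupported NPY dtype '%s'", descr), call. = FALSE)
  )
  if (length(shape) == 1) return(vals)
  if (fortran) matrix(vals, nrow = shape[1], ncol = shape[2])
  else t(matrix(vals, nrow = shape[2], ncol = shape[1]))
}

#' Save a task sequence to a directory
#'
#' Writes `X_<t>.npy`, `Y_<t>.npy` and `Y_<t>.csv` per task plus
#' `manifest.json` (protocol, parameters, seed, per-task metadata).
#'
#' @param seq a [task_sequence()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "task_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(seq$tasks)) {
    tk <- seq$tasks[[t]]
    write_npy(tk$X, file.path(dir, sprintf("X_%d.npy", t)))
    write_npy(tk$Y, file.path(dir, sprintf("Y_%d.npy", t)))
    utils::write.csv(data.frame(y = tk$Y),
                     file.path(dir, sprintf("Y_%d.csv", t)), row.names = FALSE)
  }
  manifest <- list(
    protocol = seq$protocol,
    params = seq$params,
    seed = seq$seed,
    T_tasks = length(seq$tasks),
    P = seq$P, N0 = seq$N0,
    task_meta = lapply(seq$tasks, function(tk) tk$meta)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a task sequence saved by [save_sequence()]
#'
#' @param dir directory containing `X_<t>.npy` / `Y_<t>.npy` and
#'   `manifest.json`.
#' @return a [task_sequence()].
#' @export
load_sequence <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  tasks <- lapply(seq_len(mf$T_tasks), function(t) {
    task_dataset(read_npy(file.path(dir, sprintf("X_%d.npy", t))),
                 read_npy(file.path(dir, sprintf("Y_%d.npy", t))),
                 task_id = t,
                 meta = if (length(mf$task_meta) >= t) as.list(mf$task_meta[[t]]) else list())
  })
  task_sequence(tasks, protocol = mf$protocol %||% "custom",
                params = as.list(mf$params), seed = mf$seed %||% NA_integer_)
}

#' Read a matrix from NPY or headerless CSV
#'
#' Dispatches on the file extension; CSV files are read without a header,
#' one example per row.
#'
#' @param path file path ending in `.npy` or `.csv`.
#' @return a numeric matrix.
#' @export
read_input_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "npy") {
    m <- read_npy(path)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    m
  } else if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    stop(sprintf("unsupported input format '.%s' (expected .npy or .csv)", ext),
         call. = FALSE)
  }
}

#' Read an IDX (MNIST-style) image or label file
#'
#' Images are flattened row-major to one example per row and scaled to
#' `[0, 1]`; label files yield an integer vector.
#'
#' @param path IDX file path (uncompressed).
#' @return a numeric matrix (images) or integer vector (labels).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  assert_that(all(magic == c(0L, 0L)), sprintf("%s is not an IDX file", path))
  dtype <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  ndim <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  dims <- vapply(seq_len(ndim), function(i) {
    readBin(con, "integer", 1, size = 4, endian = "big")
  }, integer(1))
  assert_that(dtype == 8L, "only unsigned-byte IDX files are supported")
  vals <- as.numeric(readBin(con, "integer", prod(dims), size = 1, signed = FALSE))
  if (ndim == 1) return(as.integer(vals))
  t(matrix(vals / 255, nrow = prod(dims[-1]), ncol = dims[1]))
}
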