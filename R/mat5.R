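# Minimal MAT-file (level 5) reader and writer.
#
# Scope: named 2-D numeric arrays, which is all the NinaPro container layout
# uses at the variables this package needs (emg, stimulus, restimulus,
# repetition, rerepetition, frequency, ...). The reader understands the
# common numeric storage types and zlib-compressed elements; the writer emits
# uncompressed miDOUBLE arrays. v7.3 (HDF5) containers are not supported and
# raise an explicit error.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mat5_pad <- function(n) (8L - n %% 8L) %% 8L

#' Write named numeric arrays to a MAT v5 file
#'
#' Low-level writer used by [write_fixture()]. Every element is stored as an
#' uncompressed double-precision 2-D array; vectors are written as column
#' vectors.
#'
#' @param vars Named list of numeric vectors or matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  if (is.null(names(vars)) || any(names(vars) == "")) {
    stop("all MAT variables must be named", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by emgsynergy on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  if (length(hdr) > 116L) hdr <- hdr[1:116]
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                                  # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                   # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)                         # endian indicator
  for (nm in names(vars)) {
    x <- vars[[nm]]
    if (!is.numeric(x)) stop(sprintf("variable '%s' is not numeric", nm), call. = FALSE)
    dims <- if (is.matrix(x)) dim(x) else c(length(x), 1L)
    vals <- as.double(x)
    name_raw <- charToRaw(nm)
    body_len <- 16L +                                    # array flags
      8L + 8L +                                          # dims (2 ints + pad)
      8L + length(name_raw) + mat5_pad(length(name_raw)) +
      8L + 8L * length(vals)
    writeBin(c(MI_MATRIX, body_len), con, size = 4L, endian = "little")
    writeBin(c(MI_UINT32, 8L), con, size = 4L, endian = "little")
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")   # mxDOUBLE_CLASS
    writeBin(c(MI_INT32, 8L), con, size = 4L, endian = "little")
    writeBin(as.integer(dims), con, size = 4L, endian = "little")
    writeBin(c(MI_INT8, length(name_raw)), con, size = 4L, endian = "little")
    writeBin(name_raw, con)
    if (mat5_pad(length(name_raw)) > 0L) writeBin(raw(mat5_pad(length(name_raw))), con)
    writeBin(c(MI_DOUBLE, 8L * length(vals)), con, size = 4L, endian = "little")
    writeBin(vals, con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_le_int <- function(bytes, size, signed = TRUE) {
  readBin(bytes, "integer", n = length(bytes) %/% size, size = size,
          signed = signed, endian = "little")
}

mat5_read_numeric <- function(type, bytes) {
  switch(as.character(type),
    "1" = read_le_int(bytes, 1L, TRUE),
    "2" = read_le_int(bytes, 1L, FALSE),
    "3" = read_le_int(bytes, 2L, TRUE),
    "4" = read_le_int(bytes, 2L, FALSE),
    "5" = read_le_int(bytes, 4L, TRUE),
    "6" = {
      # uint32 exceeds R's integer range: assemble from two uint16 words
      w <- matrix(read_le_int(bytes, 2L, FALSE), nrow = 2L)
      w[1L, ] + 65536 * w[2L, ]
    },
    "7" = readBin(bytes, "double", n = length(bytes) %/% 4L, size = 4L, endian = "little"),
    "9" = readBin(bytes, "double", n = length(bytes) %/% 8L, size = 8L, endian = "little"),
    stop(sprintf("unsupported MAT data type %d", type), call. = FALSE)
  )
}

# Parse one data-element tag at offset `pos` (1-based) of raw vector `r`.
# Returns list(type, nbytes, data_start, next_pos, small).
mat5_tag <- function(r, pos) {
  word1 <- read_le_int(r[pos:(pos + 3L)], 4L)
  upper <- word1 %/% 65536L
  if (upper != 0L) {                                     # small element format
    list(type = word1 %% 65536L, nbytes = upper, data_start = pos + 4L,
         next_pos = pos + 8L, small = TRUE)
  } else {
    nb <- read_le_int(r[(pos + 4L):(pos + 7L)], 4L)
    list(type = word1, nbytes = nb, data_start = pos + 8L,
         next_pos = pos + 8L + nb + mat5_pad(nb), small = FALSE)
  }
}

mat5_parse_matrix <- function(body) {
  pos <- 1L
  tg <- mat5_tag(body, pos)                              # array flags
  flags <- read_le_int(body[tg$data_start:(tg$data_start + 3L)], 4L)
  mx_class <- flags %% 256L
  pos <- tg$next_pos
  tg <- mat5_tag(body, pos)                              # dimensions
  dims <- read_le_int(body[tg$data_start:(tg$data_start + tg$nbytes - 1L)], 4L)
  pos <- tg$next_pos
  tg <- mat5_tag(body, pos)                              # name
  nm <- if (tg$nbytes > 0L) {
    rawToChar(body[tg$data_start:(tg$data_start + tg$nbytes - 1L)])
  } else ""
  pos <- tg$next_pos
  if (!(mx_class %in% 6:13)) {
    return(list(name = nm, value = NULL))                # non-numeric: skip
  }
  tg <- mat5_tag(body, pos)                              # real part
  vals <- if (tg$nbytes > 0L) {
    mat5_read_numeric(tg$type, body[tg$data_start:(tg$data_start + tg$nbytes - 1L)])
  } else numeric(0)
  if (length(dims) == 2L) {
    value <- matrix(as.double(vals), nrow = dims[1L], ncol = dims[2L])
  } else {
    value <- array(as.double(vals), dim = dims)
  }
  list(name = nm, value = value)
}

#' Read numeric variables from a MAT v5 file
#'
#' @param path Path to a MAT-file (level 5; v7.3/HDF5 is not supported).
#' @return Named list of numeric matrices. Non-numeric variables are skipped.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 128L) stop("not a MAT v5 file: header too short", call. = FALSE)
  magic <- rawToChar(r[1:4])
  if (identical(magic, "MATL") && grepl("7.3", rawToChar(r[1:30]), fixed = TRUE)) {
    stop("MAT v7.3 (HDF5) containers are not supported; save as v5/v7", call. = FALSE)
  }
  endian <- rawToChar(r[127:128])
  if (identical(endian, "MI")) {
    stop("big-endian MAT files are not supported", call. = FALSE)
  }
  if (!identical(endian, "IM")) {
    stop("not a MAT v5 file (missing endian indicator); v7.3/HDF5 is not supported",
         call. = FALSE)
  }
  vars <- list()
  pos <- 129L
  n <- length(r)
  while (pos + 7L <= n) {
    tg <- mat5_tag(r, pos)
    if (tg$nbytes == 0L && tg$type == 0L) break
    body <- r[tg$data_start:(tg$data_start + tg$nbytes - 1L)]
    if (tg$type == MI_COMPRESSED) {
      body <- memDecompress(body, type = "gzip")
      itag <- mat5_tag(body, 1L)
      if (itag$type == MI_MATRIX) {
        el <- mat5_parse_matrix(body[itag$data_start:(itag$data_start + itag$nbytes - 1L)])
        if (!is.null(el$value)) vars[[el$name]] <- el$value
      }
    } else if (tg$type == MI_MATRIX) {
      el <- mat5_parse_matrix(body)
      if (!is.null(el$value)) vars[[el$name]] <- el$value
    }
    pos <- tg$next_pos
  }
  vars
}
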