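#' Read a 3D volume from NRRD or multi-page TIFF
#'
#' NRRD files carry their own spacing metadata. TIFF stacks do not: the voxel
#' size is taken from a YAML sidecar `<path>.yaml` (key `voxel_size_um`) or
#' from the `voxel_size_um` argument; it is an error to omit both.
#'
#' @param path file path (`.nrrd`, `.tif`, `.tiff`).
#' @param voxel_size_um optional voxel size override (µm), scalar or length 3.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    nr <- read_nrrd(path)
    vs <- voxel_size_um %||% nr$spacing
    if (is.null(vs)) {
      stop("NRRD file has no spacing metadata; supply `voxel_size_um`",
           call. = FALSE)
    }
    if (length(dim(nr$data)) != 3) {
      stop("expected a scalar (3D) NRRD volume", call. = FALSE)
    }
    return(image_volume(nr$data, vs))
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    d1 <- dim(pages[[1]])
    arr <- array(0, dim = c(d1[2], d1[1], nz)) # pages are [y, x]
    for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
    vs <- voxel_size_um %||% read_voxel_sidecar(path)
    if (is.null(vs)) {
      stop(sprintf(
        "no voxel size for '%s': supply `voxel_size_um` or a sidecar %s.yaml",
        path, path), call. = FALSE)
    }
    return(image_volume(arr, vs))
  }
  stop(sprintf("unknown volume format '.%s' (use .nrrd, .tif or .tiff)", ext),
       call. = FALSE)
}

#' Write a 3D volume to NRRD or multi-page TIFF
#'
#' NRRD output (raw encoding, little-endian) stores the voxel size in the
#' header. TIFF output writes intensities rescaled to 16-bit greyscale pages
#' plus a YAML voxel-size sidecar; integer-valued volumes within 0..65535
#' round-trip losslessly.
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nrrd`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    write_nrrd(volume$values, path, spacing = volume$voxel_size_um,
               type = "double")
  } else if (ext %in% c("tif", "tiff")) {
    v <- volume$values
    if (any(v != round(v)) || min(v) < 0 || max(v) > 65535) {
      stop("TIFF output supports integer volumes in 0..65535; ",
           "use NRRD for float data", call. = FALSE)
    }
    pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
    yaml::write_yaml(list(voxel_size_um = volume$voxel_size_um),
                     paste0(path, ".yaml"))
  } else {
    stop(sprintf("unknown volume format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

read_voxel_sidecar <- function(path) {
  sc <- paste0(path, ".yaml")
  if (!file.exists(sc)) return(NULL)
  y <- yaml::read_yaml(sc)
  y$voxel_size_um
}

# ---- minimal NRRD reader/writer (raw | gzip | ascii encodings) -------------

nrrd_types <- c(
  "uint8" = "integer", "uchar" = "integer", "int16" = "integer",
  "short" = "integer", "uint16" = "integer", "int32" = "integer",
  "int" = "integer", "float" = "double", "double" = "double"
)
nrrd_sizes <- c(
  "uint8" = 1L, "uchar" = 1L, "int16" = 2L, "short" = 2L, "uint16" = 2L,
  "int32" = 4L, "int" = 4L, "float" = 4L, "double" = 8L
)

#' Read an NRRD file
#'
#' Supports attached-data NRRD with `raw`, `gzip` or `ascii`/`text` encodings
#' and scalar or vector (component-first) fields.
#'
#' @param path file path.
#' @return a list with `data` (array), `spacing` (per-axis µm or `NULL`) and
#'   `type`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  # byte-wise line reader: keeps the connection position exactly at the start
  # of the binary payload once the blank header terminator is seen
  read_line <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0) return(NULL)
      if (b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }
  magic <- read_line()
  if (is.null(magic) || !grepl("^NRRD000", magic)) {
    stop(sprintf("'%s' is not an NRRD file", path), call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- read_line()
    if (is.null(line)) stop("truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  if (is.null(type) || !type %in% names(nrrd_types)) {
    stop(sprintf("unsupported NRRD type '%s'", type %||% "<missing>"),
         call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  enc <- fields[["encoding"]] %||% "raw"
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  what <- nrrd_types[[type]]
  size <- nrrd_sizes[[type]]
  signed <- !type %in% c("uint8", "uchar", "uint16")
  if (enc == "raw") {
    vals <- readBin(con, what = what, n = n, size = size, signed = signed,
                    endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    vals <- readBin(memDecompress(comp, type = "gzip"), what = what, n = n,
                    size = size, signed = signed, endian = endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    stop(sprintf("unsupported NRRD encoding '%s'", enc), call. = FALSE)
  }
  if (length(vals) < n) {
    stop(sprintf("truncated NRRD data in '%s'", path), call. = FALSE)
  }
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.double(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(
      fields[["space directions"]],
      gregexpr("\\(([^)]*)\\)", fields[["space directions"]])
    )[[1]]
    spacing <- vapply(toks, function(t) {
      v <- as.double(strsplit(gsub("[()]", "", t), ",")[[1]])
      sqrt(sum(v^2))
    }, 0)
    names(spacing) <- NULL
  }
  if (!is.null(spacing)) spacing <- spacing[is.finite(spacing) & spacing > 0]
  list(data = array(vals, dim = sizes), spacing = spacing, type = type)
}

#' Write an NRRD file
#'
#' @param data numeric/integer array (any dimension; for vector fields put the
#'   component axis first).
#' @param path output path.
#' @param spacing per-spatial-axis voxel size (µm); assumed to apply to the
#'   trailing 3 axes when `data` has more than 3 dimensions.
#' @param type one of `"uint8"`, `"int16"`, `"int32"`, `"float"`, `"double"`.
#' @param encoding `"raw"` (default) or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(data, path, spacing = NULL, type = "double",
                       encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  if (!type %in% names(nrrd_sizes)) {
    stop(sprintf("unsupported NRRD type '%s'", type), call. = FALSE)
  }
  d <- dim(data) %||% length(data)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    sprintf("dimension: %d", length(d)),
    sprintf("sizes: %s", paste(d, collapse = " ")),
    sprintf("encoding: %s", encoding),
    "endian: little"
  )
  if (!is.null(spacing)) {
    sp <- rep(NA_real_, length(d))
    sp[(length(d) - length(spacing) + 1):length(d)] <- spacing
    hdr <- c(hdr, sprintf(
      "spacings: %s",
      paste(ifelse(is.na(sp), "nan", format(sp, digits = 10)), collapse = " ")
    ))
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n\n"), con, eos = NULL)
  vals <- as.vector(data)
  if (type %in% c("float", "double")) {
    payload <- writeBin(as.double(vals), raw(), size = nrrd_sizes[[type]],
                        endian = "little")
  } else {
    payload <- writeBin(as.integer(vals), raw(), size = nrrd_sizes[[type]],
                        endian = "little")
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}
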