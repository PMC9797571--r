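# Volume and table I/O. Two on-disk formats are supported for volumes:
# multi-page TIFF stacks (one page per z-slice; pitch kept in a JSON sidecar,
# since baseline TIFF has no voxel-size field) and NRRD (raw encoding, pitch
# in the `spacings` header field). Grey data are persisted as unsigned
# 16-bit, label data as unsigned 8-bit.

#' Read a greyscale or label volume
#'
#' @param path File path. For `format = "tiff-stack"` a multi-page TIFF; for
#'   `format = "nrrd"` an NRRD file with raw encoding.
#' @param format One of `"tiff-stack"`, `"nrrd"`. Defaults from the file
#'   extension (`.nrrd` vs `.tif`/`.tiff`).
#' @param pitch_um Optional voxel-pitch override in micrometres. Required for
#'   TIFF stacks without a metadata sidecar; ignored when the file carries a
#'   pitch unless explicitly supplied.
#' @param kind `"grey"`, `"label"`, or `"auto"` (use stored metadata, falling
#'   back to grey).
#' @return A [grey_volume()] or [label_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff-stack", "nrrd"),
                        pitch_um = NULL, kind = c("auto", "grey", "label")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "nrrd") "nrrd" else "tiff-stack"
  }
  if (format == "nrrd") read_nrrd(path, pitch_um, kind)
  else read_tiff_stack(path, pitch_um, kind)
}

#' Write a greyscale or label volume
#'
#' Grey values are rounded to the nearest integer and stored as unsigned
#' 16-bit; label codes are stored as unsigned 8-bit. The round trip
#' `read_volume(write_volume(v))` is the identity for integer-valued data.
#'
#' @param volume A [grey_volume()] or [label_volume()].
#' @param path Output path.
#' @param format `"tiff-stack"` or `"nrrd"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "tiff-stack", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "nrrd") "nrrd" else "tiff-stack"
  }
  is_label <- inherits(volume, "label_volume")
  if (!is_label && !inherits(volume, "grey_volume"))
    stop("write_volume: need a grey_volume or label_volume")
  if (format == "nrrd") write_nrrd(volume, path, is_label)
  else write_tiff_stack(volume, path, is_label)
  invisible(path)
}

read_tiff_stack <- function(path, pitch_um, kind) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("read_volume: TIFF pages must be single-channel 2D images")
  d2 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) any(dim(p) != d2), logical(1))))
    stop("read_volume: TIFF pages differ in shape")
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  meta <- read_sidecar(path)
  if (is.null(pitch_um)) pitch_um <- meta$voxel_pitch_um
  if (is.null(pitch_um))
    stop("read_volume: TIFF stack carries no pitch; supply `pitch_um`")
  if (kind == "auto") kind <- if (!is.null(meta$kind)) meta$kind else "grey"
  finish_volume(arr, pitch_um, kind)
}

write_tiff_stack <- function(volume, path, is_label) {
  arr <- as_plain_array(volume)
  scale <- if (is_label) 255 else 65535
  bps <- if (is_label) 8L else 16L
  pages <- lapply(seq_len(dim(arr)[1]), function(z) {
    round(arr[z, , , drop = TRUE]) / scale
  })
  # single-slice volumes still produce matrices
  pages <- lapply(pages, function(p) if (is.matrix(p)) p else matrix(p, dim(arr)[2], dim(arr)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none")
  write_sidecar(path, voxel_pitch(volume), if (is_label) "label" else "grey")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

write_sidecar <- function(path, pitch, kind) {
  jsonlite::write_json(list(voxel_pitch_um = pitch, kind = kind),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp) else list()
}

# --- NRRD (raw encoding, little endian). Minimal but standard-conforming:
# header is "NRRD000N" magic, then "field: value" lines and "key:=value"
# pairs up to a blank line, then the raw data with the first `sizes` axis
# fastest. Our (z,y,x) arrays are column-major in z, so sizes are written
# (nz, ny, nx).

write_nrrd <- function(volume, path, is_label) {
  arr <- as_plain_array(volume)
  d <- dim(arr)
  type <- if (is_label) "uint8" else "uint16"
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    "encoding: raw",
    "endian: little",
    paste0("spacings: ", paste(rep(format(voxel_pitch(volume)), 3), collapse = " ")),
    paste0("toothcrack_kind:=", if (is_label) "label" else "grey"),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vals <- as.integer(round(as.vector(arr)))
  writeBin(vals, con, size = if (is_label) 1L else 2L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path, pitch_um, kind) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("read_volume: not an NRRD file: ", path)
  fields <- list(); kv <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    if (grepl(":=", ln, fixed = TRUE)) {
      p <- strsplit(ln, ":=", fixed = TRUE)[[1]]
      kv[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = ":="))
    } else if (grepl(": ", ln, fixed = TRUE)) {
      p <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
      fields[[tolower(trimws(p[1]))]] <- trimws(p[2])
    }
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn) || dimn != 3L) stop("read_volume: NRRD data must be 3-D")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L || any(sizes <= 0L)) stop("read_volume: bad NRRD sizes")
  enc <- tolower(fields[["encoding"]])
  if (enc != "raw") stop("read_volume: only raw NRRD encoding is supported")
  type <- tolower(fields[["type"]])
  sz <- switch(type, "uint8" = 1L, "uchar" = 1L, "uint16" = 2L,
               "unsigned short" = 2L,
               stop("read_volume: unsupported NRRD type: ", type))
  endian <- if (!is.null(fields[["endian"]])) tolower(fields[["endian"]]) else "little"
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (length(unique(round(sp, 9))) != 1L)
      stop("read_volume: anisotropic voxel spacing is not supported")
    if (is.null(pitch_um)) pitch_um <- sp[1]
  }
  if (is.null(pitch_um))
    stop("read_volume: NRRD header carries no spacings; supply `pitch_um`")
  n <- prod(sizes)
  vals <- readBin(con, "integer", n = n, size = sz, signed = FALSE,
                  endian = endian)
  if (length(vals) != n) stop("read_volume: truncated NRRD data")
  arr <- array(as.numeric(vals), sizes)
  if (kind == "auto")
    kind <- if (!is.null(kv[["toothcrack_kind"]])) kv[["toothcrack_kind"]] else "grey"
  finish_volume(arr, pitch_um, kind)
}

finish_volume <- function(arr, pitch_um, kind) {
  if (kind == "label") label_volume(arr, pitch_um) else grey_volume(arr, pitch_um)
}

#' Write a crack-component table to CSV
#'
#' @param table A data frame as produced by [component_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a crack-component table from CSV
#' @param path CSV path written by [write_component_table()].
#' @return A data frame.
#' @export
read_component_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
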