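#' Read a height map from disk
#'
#' Reads a regular-grid height map in one of three formats, chosen by file
#' extension: 32-bit float TIFF (`.tif`/`.tiff`, heights in mm, pixel pitch
#' from the TIFF resolution tags), headerless CSV grid (`.csv`, one row per
#' grid row), or gridded ASCII PLY (`.ply`, one vertex per cell; the grid and
#' pitch are reconstructed from the vertex coordinates). Non-finite cells
#' become mask-invalid. Truly scattered (non-gridded) PLY clouds are rejected.
#'
#' @param path Path to the file.
#' @param pitch_mm Optional positive scalar; pixel pitch in mm. Used when the
#'   file itself carries no pitch metadata (always required for CSV); file
#'   metadata wins when present.
#' @return A [height_field()].
#' @export
read_heightfield <- function(path, pitch_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(pitch_mm)) {
    if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || !is.finite(pitch_mm) || pitch_mm <= 0)
      stop("`pitch_mm` must be a positive scalar")
  }
  switch(file_format(path),
    tiff = read_hf_tiff(path, pitch_mm),
    csv = read_hf_csv(path, pitch_mm),
    ply = read_hf_ply(path, pitch_mm)
  )
}

#' Write a height map to disk
#'
#' Writes a [height_field()] in the format chosen by the file extension:
#' 32-bit float TIFF (uncompressed, heights in mm, pitch stored in the
#' resolution tags), CSV grid (full precision, invalid cells as `NaN`), or
#' ASCII PLY with one `(x, y, z)` mm vertex per *valid* cell.
#'
#' @param field A [height_field()].
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_heightfield <- function(field, path) {
  stopifnot_height_field(field)
  switch(file_format(path),
    tiff = write_hf_tiff(field, path),
    csv = write_hf_csv(field, path),
    ply = write_hf_ply(field, path)
  )
  invisible(path)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    csv = "csv",
    ply = "ply",
    stop("unknown height-map format: .", ext,
         " (supported: .tif/.tiff, .csv, .ply)")
  )
}

## ---- CSV -------------------------------------------------------------------

read_hf_csv <- function(path, pitch_mm) {
  if (is.null(pitch_mm))
    stop("CSV grids carry no pitch metadata; supply `pitch_mm`")
  df <- utils::read.table(path, sep = ",", header = FALSE, fill = FALSE,
                          na.strings = c("NA", "NaN", "nan"),
                          colClasses = "numeric")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (length(m) == 0L) stop("empty grid in ", path)
  height_field(m, pitch = pitch_mm)
}

write_hf_csv <- function(field, path) {
  h <- field$heights
  h[!field$mask] <- NaN
  utils::write.table(h, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "NaN")
}

## ---- TIFF ------------------------------------------------------------------

read_hf_tiff <- function(path, pitch_mm) {
  img <- tiff::readTIFF(path, info = TRUE, all = FALSE)
  m <- unclass(img)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop("multi-channel TIFF is not a height map: ", path)
    m <- m[, , 1L]
  }
  pitch <- tiff_pitch(img)
  if (is.null(pitch)) pitch <- pitch_mm
  if (is.null(pitch))
    stop("no pixel pitch in TIFF resolution tags and no `pitch_mm` given")
  attributes(m) <- list(dim = dim(m))
  height_field(m, pitch = pitch)
}

tiff_pitch <- function(img) {
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  per_mm <- switch(ifelse(is.null(unit), "none", unit),
                   cm = xres / 10, inch = xres / 25.4, NULL)
  if (is.null(per_mm)) return(NULL)
  1 / per_mm
}

# Minimal single-strip uncompressed 32-bit float TIFF writer. The installed
# TIFF bindings read float TIFFs fine but cannot write them, so the dozen IFD
# tags are emitted directly. Little-endian, SampleFormat = IEEE float,
# pitch encoded as pixels-per-centimetre in the resolution tags.
write_hf_tiff <- function(field, path) {
  h <- field$heights
  h[!field$mask] <- NaN
  nr <- nrow(h); nc <- ncol(h)
  data_bytes <- 4L * nr * nc
  n_tags <- 14L
  ifd_off <- 8L + data_bytes
  extra_off <- ifd_off + 2L + n_tags * 12L + 4L
  desc <- "sptread height map; units mm"
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  # resolution rational: pixels per cm = 10 / pitch = 1e8 / (pitch * 1e7)
  res_den <- round(field$pitch * 1e7)
  res_num <- 1e8

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wle <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  tag <- function(id, type, count, value) {
    wle(id, 2); wle(type, 2); wle(count, 4)
    if (type == 3) { wle(value, 2); wle(0L, 2) } else wle(value, 4)
  }
  writeBin(charToRaw("II"), con); wle(42L, 2); wle(ifd_off, 4)
  writeBin(as.vector(t(h)), con, size = 4, endian = "little")
  wle(n_tags, 2)
  tag(256L, 4L, 1L, nc)                               # ImageWidth
  tag(257L, 4L, 1L, nr)                               # ImageLength
  tag(258L, 3L, 1L, 32L)                              # BitsPerSample
  tag(259L, 3L, 1L, 1L)                               # Compression: none
  tag(262L, 3L, 1L, 1L)                               # Photometric: min-is-black
  tag(270L, 2L, length(desc_raw), extra_off + 16L)    # ImageDescription
  tag(273L, 4L, 1L, 8L)                               # StripOffsets
  tag(277L, 3L, 1L, 1L)                               # SamplesPerPixel
  tag(278L, 4L, 1L, nr)                               # RowsPerStrip
  tag(279L, 4L, 1L, data_bytes)                       # StripByteCounts
  tag(282L, 5L, 1L, extra_off)                        # XResolution
  tag(283L, 5L, 1L, extra_off + 8L)                   # YResolution
  tag(296L, 3L, 1L, 3L)                               # ResolutionUnit: cm
  tag(339L, 3L, 1L, 3L)                               # SampleFormat: float
  wle(0L, 4)                                          # next IFD
  wle(res_num, 4); wle(res_den, 4)
  wle(res_num, 4); wle(res_den, 4)
  writeBin(desc_raw, con)
}

## ---- PLY -------------------------------------------------------------------

# ASCII vertex-only PLY; one vertex per valid cell. No installed package
# handles PLY, hence the minimal reader/writer here.
write_hf_ply <- function(field, path) {
  df <- as_tibble.height_field(field)
  df <- df[df$valid, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "ply",
    "format ascii 1.0",
    "comment sptread height map export; units mm",
    sprintf("comment pitch_mm %.9g", field$pitch),
    sprintf("comment origin_mm %.9g %.9g", field$origin[1], field$origin[2]),
    sprintf("element vertex %d", nrow(df)),
    "property float x",
    "property float y",
    "property float z",
    "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", df$x, df$y, df$z), con)
}

read_hf_ply <- function(path, pitch_mm) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header has no end_header: ", path)
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  vline <- grep("^element vertex ", header, value = TRUE)
  if (length(vline) != 1L) stop("PLY must declare exactly one vertex element")
  n_vert <- as.integer(sub("^element vertex ", "", vline))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  ixyz <- match(c("x", "y", "z"), props)
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z properties")
  pcomment <- grep("^comment pitch_mm ", header, value = TRUE)
  pitch_file <- if (length(pcomment)) as.numeric(sub("^comment pitch_mm ", "", pcomment[1])) else NULL

  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vert) stop("PLY declares ", n_vert, " vertices, found ", length(body))
  vals <- utils::read.table(text = body[seq_len(n_vert)], header = FALSE)
  x <- vals[[ixyz[1]]]; y <- vals[[ixyz[2]]]; z <- vals[[ixyz[3]]]
  if (length(x) == 0L) stop("empty PLY vertex list")

  pitch <- pitch_file %||% pitch_mm %||% infer_grid_pitch(x, y)
  if (is.null(pitch) || !is.finite(pitch) || pitch <= 0)
    stop("cannot determine grid pitch for PLY; supply `pitch_mm`")
  ox <- min(x); oy <- min(y)
  ci <- (x - ox) / pitch
  ri <- (y - oy) / pitch
  if (max(abs(ci - round(ci)), abs(ri - round(ri))) > 1e-3)
    stop("PLY vertices do not lie on a regular grid (scattered clouds are out of scope)")
  ci <- round(ci) + 1L; ri <- round(ri) + 1L
  if (anyDuplicated(cbind(ri, ci))) stop("duplicate grid positions in PLY")
  m <- matrix(NA_real_, max(ri), max(ci))
  m[cbind(ri, ci)] <- z
  height_field(m, pitch = pitch, origin = c(ox, oy))
}

# Pitch from nearest-neighbour spacing of the coordinate lattice.
infer_grid_pitch <- function(x, y) {
  ux <- sort(unique(round(x, 9))); uy <- sort(unique(round(y, 9)))
  d <- c(diff(ux), diff(uy))
  d <- d[d > 1e-12]
  if (!length(d)) return(NULL)
  stats::median(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- measurement reports ---------------------------------------------------

#' Write a wheal measurement report
#'
#' Writes the table produced by [measure_spt()] to CSV (diameters formatted to
#' 2 decimals, matching clinical reporting practice) or JSON (full precision,
#' lossless round-trip via [read_report()]).
#'
#' @param measurements A data frame of wheal measurements (see [measure_spt()]);
#'   may have zero rows.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(measurements, path, format = c("csv", "json")) {
  format <- match.arg(format)
  measurements <- tibble::as_tibble(measurements)
  if (format == "csv") {
    out <- measurements
    if ("diameter_mm" %in% names(out))
      out$diameter_mm <- sprintf("%.2f", out$diameter_mm)
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(measurements, path, dataframe = "columns",
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON wheal measurement report
#'
#' Inverse of [write_report()] for the JSON format.
#'
#' @param path Path to a JSON report.
#' @return A tibble of wheal measurements.
#' @export
read_report <- function(path) {
  lst <- jsonlite::fromJSON(path)
  tibble::as_tibble(lapply(lst, unlist))
}
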