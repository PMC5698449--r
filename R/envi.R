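#' Read and write ENVI-style hyperspectral cubes
#'
#' `write_cube()` stores a [hypercube()] as a band-sequential (BSQ) float32
#' raster next to an ASCII header (`<path>.hdr` with `samples`, `lines`,
#' `bands`, `data type = 4`, `interleave = bsq`, `byte order = 0` and the
#' wavelength list). `read_cube()` reads BSQ, BIL or BIP float32 rasters
#' written by this package or other ENVI tools.
#'
#' @param cube a [hypercube()].
#' @param path data-file path (e.g. `"scene.img"`); the header is written to
#'   the same path with extension `.hdr`.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` returns a
#'   [hypercube()].
#' @name envi_io
NULL

#' @rdname envi_io
#' @export
write_cube <- function(cube, path) {
  if (!inherits(cube, "hypercube")) abort("`cube` must be a hypercube.")
  d <- dim(cube$data)
  hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  hdr <- c(
    "ENVI",
    "description = {hyperseed reflectance cube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    "wavelength units = Nanometers",
    paste0(
      "wavelength = {",
      paste(sprintf("%.6f", cube$wavelengths), collapse = ", "),
      "}"
    )
  )
  writeLines(hdr, hdr_path)
  # BSQ: band-major, line, then sample fastest.
  vec <- as.vector(aperm(cube$data, c(2L, 1L, 3L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vec, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname envi_io
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  if (!file.exists(hdr_path)) {
    abort(sprintf("ENVI header not found: %s", hdr_path))
  }
  fields <- parse_envi_header(hdr_path)
  need <- function(key) {
    if (is.null(fields[[key]])) {
      abort(sprintf("malformed ENVI header: missing field `%s`.", key))
    }
    fields[[key]]
  }
  samples <- as.integer(need("samples"))
  lines <- as.integer(need("lines"))
  bands <- as.integer(need("bands"))
  dtype <- as.integer(need("data type"))
  if (!identical(dtype, 4L)) {
    abort(sprintf("unsupported ENVI field `data type` = %d (only 4/float32).",
                  dtype))
  }
  interleave <- tolower(trimws(need("interleave")))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    abort(sprintf("unsupported ENVI field `interleave` = '%s'.", interleave))
  }
  wl_raw <- need("wavelength")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1L]])
  if (length(wl) != bands || anyNA(wl)) {
    abort("malformed ENVI header: field `wavelength` does not match `bands`.")
  }
  byte_order <- if (is.null(fields[["byte order"]])) 0L else
    as.integer(fields[["byte order"]])
  endian <- if (byte_order == 0L) "little" else "big"

  n <- samples * lines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = "numeric", n = n, size = 4L, endian = endian)
  if (length(vec) != n) {
    abort("ENVI data file is shorter than the header promises.")
  }
  data <- switch(interleave,
    bsq = aperm(array(vec, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vec, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(vec, c(bands, samples, lines)), c(3L, 2L, 1L))
  )
  kind <- fields[["cube kind"]]
  if (is.null(kind) || !kind %in% c("raw", "reflectance")) kind <- "raw"
  hypercube(data, wl, kind = kind)
}

# key = value pairs; values in {...} may span lines.
parse_envi_header <- function(hdr_path) {
  lines_in <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines_in, collapse = "\n")
  fields <- list()
  # fold multi-line brace groups onto one line
  pos <- gregexpr("\\{[^}]*\\}", txt)[[1L]]
  if (pos[1L] != -1L) {
    lens <- attr(pos, "match.length")
    for (i in seq_along(pos)) {
      chunk <- substr(txt, pos[i], pos[i] + lens[i] - 1L)
      txt <- sub(chunk, gsub("\n", " ", chunk, fixed = TRUE), txt, fixed = TRUE)
    }
  }
  for (ln in strsplit(txt, "\n")[[1L]]) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  fields
}
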