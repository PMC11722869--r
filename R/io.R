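#' Load a grayscale image from PNG, TIFF or PGM
#'
#' Reads an image file and normalizes it to a [gray_image] on the `[0, 1]`
#' intensity scale: 8-bit values are divided by 255, 16-bit by 65535, and RGB
#' input is converted to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B) before normalization.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, or `.pgm` file.
#' @param as_gray convert RGB input to luminance (default `TRUE`; `FALSE`
#'   raises an error on multi-channel input).
#' @return A [gray_image].
#' @export
load_image <- function(path, as_gray = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext, " (PNG, TIFF, PGM supported)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    if (!as_gray) stop("multi-channel image; set as_gray = TRUE", call. = FALSE)
    nch <- dim(arr)[3]
    if (nch >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (is.null(dim(arr)) || length(dim(arr)) != 2 || any(dim(arr) == 0)) {
    stop("not a 2-D image: ", path, call. = FALSE)
  }
  gray_image(clip01(arr))
}

#' Save a grayscale image at 8-bit depth
#'
#' Writes PNG, TIFF or PGM. Intensities in `[0, 1]` are quantized to 8 bits,
#' so a save/load round trip reproduces them to within half a quantization
#' step (1/510).
#'
#' @param img [gray_image] (or coercible matrix).
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_gray_image(img)
  m <- as_plain_matrix(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    # writeTIFF truncates when quantizing; pre-round to the 8-bit grid and
    # center each value in its bin so truncation lands on the rounded level
    tiff = tiff::writeTIFF(pmin((round(m * 255) + 0.5) / 255, 1), path,
                           bits.per.sample = 8L),
    pgm = write_pgm(m, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Load a stored ground-truth edge map
#'
#' Reads an image and binarizes it: pixels whose normalized intensity exceeds
#' `threshold` become edge pixels. Ground-truth maps stored as 0/255 PNG pass
#' through unchanged at the default threshold.
#'
#' @param path image file (PNG, TIFF, PGM).
#' @param threshold binarization cut in `(0, 1)`; default 0.5.
#' @return An [edge_map].
#' @export
load_edge_map <- function(path, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  img <- load_image(path)
  edge_map(as_plain_matrix(img) > threshold)
}

#' Save an edge map as an image with values \{0, 255\}
#'
#' @param em [edge_map].
#' @param path output path (PNG, TIFF or PGM).
#' @return `path`, invisibly.
#' @export
save_edge_map <- function(em, path) {
  m <- as_plain_matrix(em)
  storage.mode(m) <- "double"
  save_image(gray_image(m), path)
}

# ---- PGM (portable graymap), plain P2 and raw P5 ------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic ", magic, "): ", path, call. = FALSE)
  }
  # header tokens: width height maxval, with '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]
  h <- tokens[2]
  maxval <- tokens[3]
  if (w < 1 || h < 1 || maxval < 1) stop("invalid PGM header", call. = FALSE)
  if (magic == "P5") {
    if (maxval > 255) {
      raw16 <- readBin(con, "integer", n = w * h, size = 2, signed = FALSE,
                       endian = "big")
      vals <- raw16
    } else {
      vals <- as.integer(readBin(con, "raw", n = w * h))
    }
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  }
  if (length(vals) < w * h) stop("truncated PGM data", call. = FALSE)
  matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE) / maxval
}

write_pgm <- function(m, path) {
  vals <- as.integer(round(clip01(m) * 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.raw(as.vector(t(matrix(vals, nrow(m), ncol(m))))), con)
  invisible(path)
}
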