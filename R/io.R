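#' Read a grayscale image from disk
#'
#' Supported formats: PNG (via the \pkg{png} package; multi-channel images are
#' reduced to their first channel), plain-text PGM (`P2`), and headerless CSV
#' matrices. CSV is the lossless quantitative interchange format; PGM and PNG
#' quantize intensities and are intended for visualization and exchange with
#' external tools. TIFF is not supported because no TIFF reader is available
#' in the target R stack.
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.pgm`, `.csv`).
#' @return numeric matrix, row = image row (y, downwards), col = image column
#'   (x, rightwards).
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      a
    },
    pgm = read_pgm(path),
    csv = {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      m
    },
    stop_data(sprintf("unsupported image format: .%s", ext))
  )
}

#' Write a grayscale image to disk
#'
#' @param image numeric matrix.
#' @param path output path; `.png`, `.pgm` or `.csv` (see [read_image()]).
#' @param maxval integer maximum for PGM quantization.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, maxval = 255L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      rng <- range(image, finite = TRUE)
      z <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
      png::writePNG(z, path)
    },
    pgm = write_pgm(image, path, maxval = maxval),
    csv = utils::write.table(image, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    stop_data(sprintf("unsupported image format: .%s", ext))
  )
  invisible(path)
}

# Plain (P2) PGM reader. Comments (#) allowed after the magic number.
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2") stop_data("not a plain (P2) PGM file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop_data("PGM pixel count does not match header")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path, maxval = 255L) {
  rng <- range(image, finite = TRUE)
  z <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  q <- round(z * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  utils::write.table(q, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
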