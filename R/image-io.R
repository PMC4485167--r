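# Raster I/O.  Images are numeric matrices (grayscale, rows = y) or
# h x w x 3 arrays (RGB) on the 0-255 scale.  PNG goes through the png
# package; plain-text PGM/PPM (P2/P3) are written by hand so fixtures can
# stay text.

#' Read a raster image
#'
#' @param path PNG, PGM (P2) or PPM (P3) file.
#' @return Grayscale matrix or RGB array on the 0-255 scale (a PNG alpha
#'   channel is dropped; single-channel input collapses to a matrix).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path) * 255
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] >= 3L) a <- a[, , 1:3] else a <- a[, , 1]
    }
    return(a)
  }
  if (ext %in% c("pgm", "ppm")) return(.read_pnm(path))
  stop(sprintf("unsupported image format: .%s (use png, pgm or ppm)", ext),
       call. = FALSE)
}

#' Write a raster image
#'
#' @param image Grayscale matrix or RGB array, values 0-255.
#' @param path Output file; format chosen by extension (png, pgm, ppm).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image, 0), 255)
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    if (!is.matrix(img)) stop("PGM holds grayscale; got an RGB array",
                              call. = FALSE)
    .write_pnm(round(img), path, "P2")
  } else if (ext == "ppm") {
    if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
    .write_pnm(round(img), path, "P3")
  } else {
    stop(sprintf("unsupported image format: .%s (use png, pgm or ppm)", ext),
         call. = FALSE)
  }
  invisible(path)
}

.read_pnm <- function(path) {
  txt <- readLines(path)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3"))
    stop("only plain-text PGM (P2) / PPM (P3) are supported", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) * (255 / maxval)
  if (magic == "P2") {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3))
    m <- matrix(vals, ncol = 3, byrow = TRUE)
    for (k in 1:3) a[, , k] <- matrix(m[, k], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

.write_pnm <- function(img, path, magic) {
  con <- file(path, "w")
  on.exit(close(con))
  if (magic == "P2") {
    writeLines(c(magic, paste(ncol(img), nrow(img)), "255"), con)
    utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(c(magic, paste(dim(img)[2], dim(img)[1]), "255"), con)
    flat <- matrix(aperm(img, c(3, 2, 1)), nrow = 3)
    writeLines(paste(apply(flat, 2, paste, collapse = " "), collapse = " "),
               con)
  }
}
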