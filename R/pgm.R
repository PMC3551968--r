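#' Read and write 8-bit greyscale PGM images
#'
#' Supports the plain (`P2`) and binary (`P5`) portable greymap formats with
#' a maximum grey value of up to 255.  `write_pgm` writes plain `P2` by
#' default so outputs remain text.
#'
#' @param path file path
#' @return `read_pgm` returns a [grey_image()]; `write_pgm` returns `path`
#'   invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not an 8-bit PGM file (expected magic P2 or P5)", call. = FALSE)
  }
  ## header token reader: skips whitespace and '#' comments
  next_token <- function() {
    tok <- character(0)
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0 || ch == "") stop("truncated PGM header", call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch %in% c("\n", "\r")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(width) || is.na(height) || is.na(maxval) || maxval < 1 ||
      maxval > 255) {
    stop("unsupported PGM header (need 8-bit, maxval <= 255)", call. = FALSE)
  }
  n <- width * height
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE, comment.char = "#")
  }
  if (length(vals) != n) stop("truncated PGM pixel data", call. = FALSE)
  lev <- round(vals / maxval * 255)
  grey_image(matrix(lev, nrow = height, ncol = width, byrow = TRUE))
}

#' @rdname read_pgm
#' @param img a [grey_image()] (or matrix of levels in `[0, 255]`)
#' @param binary write binary `P5` instead of plain `P2`
#' @export
write_pgm <- function(img, path, binary = FALSE) {
  if (!inherits(img, "grey_image")) img <- grey_image(img)
  h <- nrow(img); w <- ncol(img)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", w, h)), con)
    writeBin(as.raw(as.integer(t(img))), con)
  } else {
    lines <- c(sprintf("P2"), sprintf("%d %d", w, h), "255",
               apply(unclass(img), 1L, paste, collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and write 8-bit greyscale PNG images
#'
#' Thin wrappers over the `png` package; colour inputs are converted to
#' luma (Rec. 601 weights).
#'
#' @param path file path
#' @return `read_grey_png` returns a [grey_image()]; `write_grey_png`
#'   returns `path` invisibly.
#' @export
read_grey_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  grey_image(round(a * 255))
}

#' @rdname read_grey_png
#' @param img a [grey_image()] (or matrix of levels in `[0, 255]`)
#' @export
write_grey_png <- function(img, path) {
  if (!inherits(img, "grey_image")) img <- grey_image(img)
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
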