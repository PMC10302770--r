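#' Read a grayscale image
#'
#' Supported formats: PGM (ASCII `P2` or binary `P5`, 8-bit) and PNG (via the
#' png package; color images are converted to luma with the Rec. 601
#' weights). Intensities are returned in \[0, 1\].
#'
#' @param path Image file path (`.pgm` or `.png`).
#' @return A numeric matrix (rows = image rows, top to bottom) in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste0("input not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      nch <- dim(img)[3]
      img <- if (nch >= 3L) {
        0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      } else {
        img[, , 1]
      }
    }
    return(img)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop_invalid_input(paste0("unsupported image format: ", ext))
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop_invalid_input("not a PGM file (expected magic P2 or P5)")
  }
  # header tokens, skipping whitespace and '#' comments
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (!length(ch) || !nzchar(ch)) break
      if (ch == "#") {
        repeat {
          ch2 <- rawToChar(readBin(con, "raw", 1L))
          if (!nzchar(ch2) || ch2 == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (any(is.na(c(w, h, maxval))) || w < 1 || h < 1 || maxval < 1) {
    stop_invalid_input("malformed PGM header")
  }
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval > 255) stop_invalid_input("16-bit PGM not supported")
    as.integer(readBin(con, "raw", n))
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    txt <- gsub("#[^\n]*", " ", txt)
    as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  if (length(vals) < n || any(is.na(vals))) {
    stop_invalid_input("PGM pixel data truncated or malformed")
  }
  # PGM raster order: rows top to bottom, left to right
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image as ASCII PGM
#'
#' @param img Numeric matrix in \[0, 1\] (rows = image rows).
#' @param path Output path.
#' @param maxval Maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  if (!is.matrix(img) || any(!is.finite(img)) || any(img < 0) || any(img > 1)) {
    stop_invalid_input("'img' must be a numeric matrix in [0, 1]")
  }
  q <- round(img * maxval)
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

# Bilinear sampling of an image (rows = y from top) at unit-square grid
# nodes. Returns an nx x ny matrix aligned with sim_grid indexing
# (row = x, col = y measured from the top edge of the image).
resample_to_grid <- function(img, grid) {
  h <- nrow(img); w <- ncol(img)
  # pixel centers at (k - 0.5)/n, k = 1..n
  px <- function(u, n) pmin(pmax(u * n + 0.5, 1), n)
  out <- matrix(0, grid$nx, grid$ny)
  cx <- px(grid$x, w)  # image column position for each grid x
  cy <- px(grid$y, h)  # image row position for each grid y
  x0 <- floor(cx); x1 <- pmin(x0 + 1, w); fx <- cx - x0
  y0 <- floor(cy); y1 <- pmin(y0 + 1, h); fy <- cy - y0
  for (j in seq_len(grid$ny)) {
    r0 <- y0[j]; r1 <- y1[j]; g <- fy[j]
    top <- img[r0, x0] * (1 - fx) + img[r0, x1] * fx
    bot <- img[r1, x0] * (1 - fx) + img[r1, x1] * fx
    out[, j] <- top * (1 - g) + bot * g
  }
  out
}

#' Initialize the cell-concentration field from an image
#'
#' Resamples a grayscale image (bright = cells) onto the simulation grid,
#' classifies nodes as cell vs medium by Otsu's threshold on the resampled
#' intensities (or a user-supplied fixed threshold), and seeds every cell
#' node with `alpha_seed`. Medium nodes get `alpha = 0` and form the
#' `medium_mask` on which the oxygen concentration is pinned at 1.
#'
#' @param img A grayscale matrix in \[0, 1\] (e.g. from [read_gray_image] or
#'   [generate_blob_image]).
#' @param grid A [sim_grid] (its `medium_mask` is replaced).
#' @param alpha_seed Concentration assigned to cell nodes (default 0.5).
#' @param threshold Optional fixed intensity threshold in (0, 1); when `NULL`
#'   (default) Otsu's method ([EBImage::otsu]) is used. A constant-intensity
#'   image with no fixed threshold is an error (the histogram has a single
#'   mode and the threshold is undefined).
#' @return An [initial_state]; the chosen threshold is attached as attribute
#'   `"threshold"`.
#' @export
image_to_alpha0 <- function(img, grid, alpha_seed = 0.5, threshold = NULL) {
  if (!is.matrix(img) || length(img) == 0L) {
    stop_invalid_input("'img' must be a nonempty matrix")
  }
  rng <- range(img)
  if (any(!is.finite(rng))) stop_invalid_input("'img' has non-finite intensities")
  if (rng[1] < 0 || rng[2] > 1) img <- (img - rng[1]) / (rng[2] - rng[1])
  if (!is.finite(alpha_seed) || alpha_seed < 0 || alpha_seed > 1) {
    stop_invalid_input("'alpha_seed' must lie in [0, 1]")
  }
  sampled <- resample_to_grid(img, grid)
  if (is.null(threshold)) {
    if (diff(range(sampled)) < .Machine$double.eps) {
      stop_invalid_input(
        "constant-intensity image: Otsu threshold undefined, supply 'threshold'")
    }
    threshold <- EBImage::otsu(sampled, range = c(0, 1))
  }
  mask <- sampled <= threshold  # TRUE = medium (dark)
  if (!any(mask)) {
    stop_invalid_input("no medium nodes below threshold (oxygen source required)")
  }
  grid <- sim_grid(grid$nx, grid$ny, medium_mask = mask)
  alpha <- matrix(0, grid$nx, grid$ny)
  alpha[!mask] <- alpha_seed
  st <- initial_state(alpha, grid)
  attr(st, "threshold") <- as.numeric(threshold)
  st
}
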