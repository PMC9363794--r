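# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

#' Nearest-neighbour resize of a label mask
#'
#' Rescales an integer label mask to a new size without introducing new
#' label values, using nearest-neighbour sampling with the half-pixel
#' convention. Used to move predicted masks between network resolution and
#' native image resolution.
#'
#' @param mask Integer matrix of class labels.
#' @param height,width Target size in pixels.
#' @return An integer matrix of size `height` x `width`.
#' @export
resize_mask <- function(mask, height, width) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(H, pmax(1L, floor((seq_len(height) - 0.5) * H / height) + 1L))
  ci <- pmin(W, pmax(1L, floor((seq_len(width) - 0.5) * W / width) + 1L))
  mask[ri, ci, drop = FALSE]
}

# Bilinear resize of an H x W x C image array (values on any scale).
resize_image <- function(img, height, width) {
  stopifnot(length(dim(img)) == 3)
  d <- dim(img)
  x <- array(img, c(d[1], d[2], d[3], 1L))
  y <- nn_resize_bilinear(x, dim(x), as.integer(height), as.integer(width))
  array(y, c(height, width, d[3]))
}

# Read/write helpers for 8-bit PNG images and {0,1,2} label masks.
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

write_image_png <- function(img, path) {
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, target = path)
  invisible(path)
}
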