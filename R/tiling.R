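#' Resize an image to the nearest tileable dimensions
#'
#' Each dimension is truncated down to the largest multiple of `tile_size`
#' not exceeding it (so a 1000 x 500 image with 34-pixel tiles becomes
#' 986 x 476) and the pixel content is rescaled by bilinear interpolation.
#' Images already tileable are returned unchanged, which makes the
#' operation idempotent.
#'
#' @param image A [taa_frame()] or bare pixel array.
#' @param tile_size Tile edge length in pixels (default 34).
#' @return Same type as the input, with both dimensions exact multiples of
#'   `tile_size`.
#' @export
resize_to_tile_multiple <- function(image, tile_size = 34) {
  px <- if (inherits(image, "taa_frame")) image$pixels else image
  d <- dim(px)[1:2]
  if (any(d < tile_size))
    stop(sprintf("image (%d x %d) too small to tile at %d px", d[1], d[2],
                 tile_size))
  nd <- (d %/% tile_size) * tile_size
  out <- rescale_pixels(px, nd[1], nd[2])
  if (inherits(image, "taa_frame")) { image$pixels <- out; image } else out
}

#' Partition a tileable image into a grid of square tiles
#'
#' @inheritParams resize_to_tile_multiple
#' @return An object of class `taa_tile_grid`: a list with `tile_size`,
#'   `n_rows`, `n_cols`, `tiles` (row-major list of pixel arrays) and
#'   `origin_map` (matrix of 0-based row/col offsets per tile).
#' @export
tile_image <- function(image, tile_size = 34) {
  px <- if (inherits(image, "taa_frame")) image$pixels else image
  d <- dim(px)[1:2]
  if (any(d %% tile_size != 0))
    stop(sprintf(paste0("image dimensions (%d x %d) are not multiples of %d;",
                        " call resize_to_tile_multiple() first"),
                 d[1], d[2], tile_size))
  n_rows <- d[1] %/% tile_size
  n_cols <- d[2] %/% tile_size
  origins <- cbind(row = rep(seq_len(n_rows) - 1L, times = n_cols) * tile_size,
                   col = rep(seq_len(n_cols) - 1L, each = n_rows) * tile_size)
  tiles <- lapply(seq_len(nrow(origins)), function(i) {
    r0 <- origins[i, 1]; c0 <- origins[i, 2]
    if (is_rgb(px)) px[r0 + seq_len(tile_size), c0 + seq_len(tile_size), ,
                       drop = FALSE]
    else px[r0 + seq_len(tile_size), c0 + seq_len(tile_size), drop = FALSE]
  })
  structure(list(tile_size = tile_size, n_rows = n_rows, n_cols = n_cols,
                 tiles = tiles, origin_map = origins, image_dim = d),
            class = "taa_tile_grid")
}

#' Reassemble a tile grid into the original image
#'
#' The inverse of [tile_image()]: placing every tile back at its
#' `origin_map` offset reproduces the tiled image bit-exactly.
#'
#' @param grid A `taa_tile_grid`.
#' @return A pixel array of the original tiled dimensions.
#' @export
untile_image <- function(grid) {
  stopifnot(inherits(grid, "taa_tile_grid"))
  ch <- n_channels(grid$tiles[[1]])
  d <- grid$image_dim
  out <- if (ch == 3L) array(0, c(d, 3L)) else array(0, d)
  for (i in seq_along(grid$tiles)) {
    r0 <- grid$origin_map[i, 1]; c0 <- grid$origin_map[i, 2]
    idx_r <- r0 + seq_len(grid$tile_size)
    idx_c <- c0 + seq_len(grid$tile_size)
    if (ch == 3L) out[idx_r, idx_c, ] <- grid$tiles[[i]]
    else out[idx_r, idx_c] <- grid$tiles[[i]]
  }
  if (ch == 1L) out <- matrix(out, d[1], d[2])
  out
}

#' Extract labelled crops from a frame
#'
#' Cuts each annotated bounding box out of the image and rescales it to
#' `out_size` x `out_size` by bilinear interpolation, preserving channel
#' structure and annotation order.
#'
#' @param image A [taa_frame()] or pixel array.
#' @param annotations An annotation data frame from [parse_annotations()].
#' @param out_size Output crop edge length in pixels (default 34).
#' @return A list with `crops` (list of pixel arrays) and `labels`
#'   (character vector parallel to `crops`).
#' @export
extract_crops <- function(image, annotations, out_size = 34) {
  px <- if (inherits(image, "taa_frame")) image$pixels else image
  validate_annotations(annotations, dim(px)[1:2])
  crops <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    sub <- if (is_rgb(px))
      px[(a$row_min + 1):a$row_max, (a$col_min + 1):a$col_max, , drop = FALSE]
    else px[(a$row_min + 1):a$row_max, (a$col_min + 1):a$col_max, drop = FALSE]
    rescale_pixels(sub, out_size, out_size)
  })
  list(crops = crops, labels = as.character(annotations$label))
}
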