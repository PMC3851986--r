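#' @title Semantic-zoom view chains and tile pyramids
#' @description A map atlas shows the same network at several zoom
#'   levels: level 0 is the least detailed (top-level) view and each
#'   deeper level doubles the pixel dimensions. Views supplied by the
#'   map manager are *semantic* (content redrawn for the scale); missing
#'   intermediate levels can be synthesized by factor-2 area-averaged
#'   downscaling of the most detailed image. Each level is cut into
#'   fixed-size square tiles (256 px by default) for the tiled viewer,
#'   and marker coordinates scale between levels by powers of two so
#'   markers persist when zooming.
#' @name zoomtiles
NULL

#' Create a zoom view
#'
#' @param level Integer zoom level, 0 = least detailed top-level view,
#'   increasing toward detail.
#' @param image Raster as a numeric array `height x width x channels`
#'   with values in `[0, 1]` (the [png::readPNG()] layout), or `NULL`
#'   for metadata-only views.
#' @param width,height Pixel dimensions; taken from `image` when
#'   omitted.
#' @param semantic `TRUE` for manager-supplied semantic views, `FALSE`
#'   for auto-generated downscales.
#' @return An object of class `pa_zoom_view`.
#' @export
zoom_view <- function(level, image = NULL, width = NULL, height = NULL,
                      semantic = TRUE) {
  if (!is.null(image)) {
    if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1)
    height <- dim(image)[1]
    width <- dim(image)[2]
  }
  if (is.null(width) || is.null(height) || width <= 0 || height <= 0) {
    stop("zoom view needs positive width and height")
  }
  structure(
    list(level = as.integer(level), width = as.integer(width),
         height = as.integer(height), image = image,
         semantic = isTRUE(semantic)),
    class = "pa_zoom_view"
  )
}

#' Validate a chain of zoom views
#'
#' Checks the tiled-viewer requirements on a list of views sorted by
#' level: consecutive views must differ by exactly a factor of 2 in both
#' dimensions (half-size rule), the aspect ratio must not drift (a
#' proxy for "relative object position must not change"), and
#' dimensions not divisible by the tile edge draw a warning only, since
#' divisibility is preferable but not required (edge tiles are padded).
#'
#' @param views List of [zoom_view()] objects sorted by level.
#' @param tile_edge Tile edge in pixels used for the divisibility check.
#' @return An object of class `pa_validation`: list with `valid`
#'   (logical), `errors` and `warnings` (character vectors).
#' @export
validate_view_chain <- function(views, tile_edge = 256) {
  if (length(views) == 0) stop("precondition: need at least one view")
  errors <- character()
  warns <- character()
  lv <- vapply(views, `[[`, integer(1), "level")
  if (is.unsorted(lv, strictly = TRUE)) {
    errors <- c(errors, "views are not sorted by strictly increasing level")
  }
  # a dimension meshes with the tile grid when it is a multiple of the
  # tile edge, or (for the small top levels) an exact divisor of it
  meshes <- function(d) d %% tile_edge == 0 || tile_edge %% d == 0
  for (i in seq_along(views)) {
    v <- views[[i]]
    if (!meshes(v$width) || !meshes(v$height)) {
      warns <- c(warns, sprintf(
        "level %d: %dx%d does not mesh with the %d-px tile grid; edge tiles will be padded",
        v$level, v$width, v$height, tile_edge))
    }
    if (i == 1) next
    p <- views[[i - 1]]
    if (v$width != 2 * p$width || v$height != 2 * p$height) {
      errors <- c(errors, sprintf(
        "pair (%d,%d): %dx%d -> %dx%d is not an exact factor-2 step",
        i - 2, i - 1, p$width, p$height, v$width, v$height))
    }
    if (v$width * p$height != v$height * p$width) {
      errors <- c(errors, sprintf(
        "pair (%d,%d): aspect ratio drifts (%d:%d vs %d:%d)",
        i - 2, i - 1, p$width, p$height, v$width, v$height))
    }
  }
  structure(list(valid = length(errors) == 0, errors = errors,
                 warnings = warns),
            class = "pa_validation")
}

#' @export
print.pa_validation <- function(x, ...) {
  cat(if (x$valid) "valid" else "INVALID",
      sprintf("(%d error(s), %d warning(s))\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:   ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

## factor-2 area-averaged downscale; deterministic and alias-free
downscale_half <- function(img) {
  d <- dim(img)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("downscale_half needs even dimensions, got ", d[1], "x", d[2])
  }
  o <- seq_len(d[1] / 2) * 2
  e <- seq_len(d[2] / 2) * 2
  (img[o - 1, e - 1, , drop = FALSE] + img[o - 1, e, , drop = FALSE] +
     img[o, e - 1, , drop = FALSE] + img[o, e, , drop = FALSE]) / 4
}

#' Generate intermediate zoom views
#'
#' Given the most detailed view and the top-level view, synthesizes the
#' chain of intermediate levels by repeated factor-2 area-averaged
#' downscaling of the detailed image. The two supplied views are kept
#' as-is (manager-supplied imagery is never overwritten); synthesized
#' views carry `semantic = FALSE`.
#'
#' @param detailed The most detailed [zoom_view()]; its width must be
#'   `top$width * 2^k` for an integer `k >= 0`.
#' @param top The top-level (least detailed) view.
#' @return List of `k + 1` views with levels `0 ... k`, least detailed
#'   first.
#' @export
autogenerate_intermediates <- function(detailed, top) {
  ratio <- detailed$width / top$width
  k <- round(log2(ratio))
  if (ratio <= 0 || 2^k != ratio ||
      detailed$height != top$height * 2^k) {
    stop("width ", detailed$width, " is not a power-of-two multiple of ",
         "top-level width ", top$width)
  }
  k <- as.integer(k)
  views <- vector("list", k + 1)
  views[[k + 1]] <- zoom_view(k, detailed$image, detailed$width,
                              detailed$height, semantic = detailed$semantic)
  img <- detailed$image
  if (k > 0) {
    for (lev in (k - 1):0) {
      if (!is.null(img)) img <- downscale_half(img)
      views[[lev + 1]] <- if (lev == 0) {
        zoom_view(0, top$image, top$width, top$height,
                  semantic = top$semantic)
      } else {
        zoom_view(lev, img, detailed$width / 2^(k - lev),
                  detailed$height / 2^(k - lev), semantic = FALSE)
      }
    }
  }
  views
}

#' Cut one view into fixed-size tiles
#'
#' The view raster is cut into `ceiling(width / tile_edge) x
#' ceiling(height / tile_edge)` square tiles. Interior tiles are exact
#' crops; right/bottom edge tiles are padded to the full tile edge with
#' the fill color.
#'
#' @param view A [zoom_view()] carrying an image.
#' @param tile_edge Tile edge in pixels (> 0), default 256.
#' @param fill Padding fill, a single grey value or per-channel vector
#'   in `[0, 1]`; default opaque white (map exports have white
#'   backgrounds).
#' @return List of tiles, each `list(level, tx, ty, raster)`, row-major
#'   (`ty` slow, `tx` fast), 0-based tile indices.
#' @export
cut_tiles <- function(view, tile_edge = 256, fill = 1) {
  stopifnot(tile_edge > 0)
  img <- view$image
  if (is.null(img)) stop("view at level ", view$level, " has no image")
  d <- dim(img)
  nx <- ceiling(d[2] / tile_edge)
  ny <- ceiling(d[1] / tile_edge)
  fill <- rep(fill, length.out = d[3])
  tiles <- vector("list", nx * ny)
  k <- 0
  for (ty in 0:(ny - 1)) {
    for (tx in 0:(nx - 1)) {
      x0 <- tx * tile_edge + 1
      y0 <- ty * tile_edge + 1
      x1 <- min(d[2], x0 + tile_edge - 1)
      y1 <- min(d[1], y0 + tile_edge - 1)
      tile <- array(rep(fill, each = tile_edge * tile_edge),
                    dim = c(tile_edge, tile_edge, d[3]))
      tile[seq_len(y1 - y0 + 1), seq_len(x1 - x0 + 1), ] <-
        img[y0:y1, x0:x1, , drop = FALSE]
      k <- k + 1
      tiles[[k]] <- list(level = view$level, tx = tx, ty = ty,
                         raster = tile)
    }
  }
  tiles
}

#' Scale a point between zoom levels
#'
#' Coordinates live on the pixel grid of each level; because levels
#' differ by powers of two, a point maps between levels by
#' `x' = x * 2^(to_level - from_level)` (and likewise for y). This is
#' what keeps persistent markers anchored while zooming: the single
#' most-detailed coordinate record is rescaled to whatever level is on
#' screen.
#'
#' @param p Numeric `c(x, y)`.
#' @param from_level,to_level Zoom levels (must exist in `levels` when
#'   given).
#' @param levels Optional integer vector of known levels; when supplied,
#'   unknown levels raise an error.
#' @return Numeric `c(x, y)` at `to_level`.
#' @export
scale_point <- function(p, from_level, to_level, levels = NULL) {
  if (!is.null(levels) &&
      (!from_level %in% levels || !to_level %in% levels)) {
    stop("unknown zoom level: ",
         paste(setdiff(c(from_level, to_level), levels), collapse = ", "))
  }
  as.numeric(p) * 2^(to_level - from_level)
}

#' Build a tile pyramid from a view chain
#'
#' Validates the chain (errors abort; divisibility warnings pass
#' through), then cuts every level into tiles.
#'
#' @param views List of [zoom_view()]s sorted by level, each with an
#'   image.
#' @param tile_edge Tile edge in pixels.
#' @param fill Edge-padding fill passed to [cut_tiles()].
#' @return An object of class `pa_tile_pyramid`: list with `tile_edge`,
#'   `levels` (per-level metadata: level, width, height, semantic,
#'   n_tiles_x, n_tiles_y) and `tiles` (flat list of tile records).
#' @export
build_tile_pyramid <- function(views, tile_edge = 256, fill = 1) {
  rep_ <- validate_view_chain(views, tile_edge)
  if (!rep_$valid) {
    stop("invalid view chain:\n  ", paste(rep_$errors, collapse = "\n  "))
  }
  tiles <- list()
  levels <- list()
  for (v in views) {
    levels[[length(levels) + 1]] <- list(
      level = v$level, width = v$width, height = v$height,
      semantic = v$semantic,
      n_tiles_x = as.integer(ceiling(v$width / tile_edge)),
      n_tiles_y = as.integer(ceiling(v$height / tile_edge)))
    tiles <- c(tiles, cut_tiles(v, tile_edge, fill))
  }
  structure(list(tile_edge = as.integer(tile_edge), levels = levels,
                 tiles = tiles),
            class = "pa_tile_pyramid")
}

#' @export
print.pa_tile_pyramid <- function(x, ...) {
  cat("<tile pyramid> ", length(x$levels), " level(s), tile edge ",
      x$tile_edge, " px, ", length(x$tiles), " tiles\n", sep = "")
  for (l in x$levels) {
    cat(sprintf("  level %d: %dx%d px, %dx%d tiles%s\n", l$level,
                l$width, l$height, l$n_tiles_x, l$n_tiles_y,
                if (l$semantic) " (semantic)" else " (auto)"))
  }
  invisible(x)
}

#' Write a tile pyramid to disk
#'
#' Tiles go to `<dir>/<level>/<tx>_<ty>.png` and the pyramid metadata
#' (levels, sizes, tile edge) to `<dir>/pyramid.json`.
#'
#' @param pyramid A `pa_tile_pyramid`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the metadata file path.
#' @export
write_tile_pyramid <- function(pyramid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in pyramid$tiles) {
    ldir <- file.path(dir, t$level)
    dir.create(ldir, showWarnings = FALSE)
    png::writePNG(t$raster, file.path(ldir, paste0(t$tx, "_", t$ty,
                                                   ".png")))
  }
  meta <- list(tile_edge = pyramid$tile_edge,
               levels = lapply(pyramid$levels, function(l)
                 l[c("level", "width", "height", "semantic",
                     "n_tiles_x", "n_tiles_y")]))
  path <- file.path(dir, "pyramid.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## reassemble a level from its tiles (test support): returns the
## unpadded raster of the level
assemble_tiles <- function(pyramid, level) {
  li <- Filter(function(l) l$level == level, pyramid$levels)
  if (length(li) == 0) stop("unknown level ", level)
  li <- li[[1]]
  te <- pyramid$tile_edge
  nch <- dim(pyramid$tiles[[1]]$raster)[3]
  out <- array(0, dim = c(li$n_tiles_y * te, li$n_tiles_x * te, nch))
  for (t in pyramid$tiles) {
    if (t$level != level) next
    out[t$ty * te + seq_len(te), t$tx * te + seq_len(te), ] <- t$raster
  }
  out[seq_len(li$height), seq_len(li$width), , drop = FALSE]
}
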