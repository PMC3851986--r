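mk_view <- function(level, w, h, val = 0.5) {
  zoom_view(level, array(val, dim = c(h, w, 3)))
}

test_that("view chains are checked for the half-size rule", {
  chain <- list(mk_view(0, 256, 128), mk_view(1, 512, 256),
                mk_view(2, 1024, 512), mk_view(3, 2048, 1024))
  rep <- validate_view_chain(chain)
  expect_true(rep$valid)
  expect_length(rep$errors, 0)
  expect_length(rep$warnings, 0)

  bad <- validate_view_chain(list(mk_view(0, 700, 350),
                                  mk_view(1, 1000, 500)))
  expect_false(bad$valid)
  expect_match(bad$errors[1], "factor-2")

  single <- validate_view_chain(list(mk_view(0, 300, 300)))
  expect_true(single$valid)
  expect_length(single$warnings, 1)
  expect_match(single$warnings, "tile grid")

  expect_error(validate_view_chain(list()), "at least one view")
})

test_that("intermediate levels are synthesized by factor-2 downscaling", {
  det <- mk_view(0, 2048, 1024)
  top <- mk_view(0, 256, 128)
  chain <- autogenerate_intermediates(det, top)
  expect_length(chain, 4)
  expect_identical(vapply(chain, `[[`, integer(1), "width"),
                   c(256L, 512L, 1024L, 2048L))
  expect_identical(vapply(chain, `[[`, logical(1), "semantic"),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_true(validate_view_chain(chain)$valid)

  same <- autogenerate_intermediates(det, det)
  expect_length(same, 1)
  expect_identical(same[[1]]$image, det$image)

  two <- autogenerate_intermediates(mk_view(1, 512, 256),
                                    mk_view(0, 256, 128))
  expect_length(two, 2)

  expect_error(
    autogenerate_intermediates(mk_view(1, 768, 384), mk_view(0, 256, 128)),
    "768.*256|256.*768")
})

test_that("downscaling averages 2x2 blocks and keeps aspect ratio", {
  img <- array(0, dim = c(2, 4, 1))
  img[1, 1, 1] <- 1  # one bright pixel in the first block
  down <- pathatlas:::downscale_half(img)
  expect_identical(dim(down), c(1L, 2L, 1L))
  expect_equal(down[1, 1, 1], 0.25)
  expect_equal(down[1, 2, 1], 0)
  # chain conserves aspect exactly
  chain <- autogenerate_intermediates(mk_view(0, 1024, 256),
                                      mk_view(0, 128, 32))
  ratios <- vapply(chain, function(v) v$width / v$height, numeric(1))
  expect_true(all(ratios == 4))
})

test_that("tile counts follow the ceiling formula and edges are padded", {
  t8 <- cut_tiles(mk_view(0, 1024, 512), 256)
  expect_length(t8, 8)
  expect_true(all(vapply(t8, function(t)
    identical(dim(t$raster)[1:2], c(256L, 256L)), logical(1))))

  t1 <- cut_tiles(mk_view(0, 256, 256), 256)
  expect_length(t1, 1)

  t4 <- cut_tiles(mk_view(0, 300, 300, val = 0.2), 256)
  expect_length(t4, 4)
  # right tile: columns beyond 300 hold the white fill
  right <- Filter(function(t) t$tx == 1 && t$ty == 0, t4)[[1]]
  expect_equal(right$raster[1, 300 - 256, 1], 0.2)
  expect_equal(right$raster[1, 300 - 256 + 1, 1], 1)
})

test_that("interior tiles reassemble the level byte-exactly", {
  set.seed(7)
  img <- array(stats::runif(600 * 300 * 3), dim = c(300, 600, 3))
  pyr <- build_tile_pyramid(list(zoom_view(0, img)), 256)
  expect_identical(pathatlas:::assemble_tiles(pyr, 0), img)
})

test_that("points scale between levels by powers of two", {
  expect_equal(scale_point(c(512, 256), 3, 0), c(64, 32))
  expect_equal(scale_point(c(13.5, 7), 2, 2), c(13.5, 7))
  expect_equal(scale_point(c(0, 0), 0, 5), c(0, 0))
  expect_error(scale_point(c(1, 1), 0, 9, levels = 0:3),
               "unknown zoom level")
  # composition equals direct scaling
  set.seed(11)
  for (i in 1:25) {
    p <- stats::runif(2, 0, 2048)
    lv <- sample(0:4, 3, replace = TRUE)
    expect_equal(
      scale_point(scale_point(p, lv[1], lv[2]), lv[2], lv[3]),
      scale_point(p, lv[1], lv[3]))
  }
})

test_that("pyramids persist to disk with a metadata descriptor", {
  chain <- autogenerate_intermediates(mk_view(0, 512, 256),
                                      mk_view(0, 256, 128))
  pyr <- build_tile_pyramid(chain)
  d <- withr::local_tempdir()
  write_tile_pyramid(pyr, d)
  expect_true(file.exists(file.path(d, "pyramid.json")))
  expect_true(file.exists(file.path(d, "1", "1_0.png")))
  meta <- jsonlite::read_json(file.path(d, "pyramid.json"))
  expect_equal(meta$tile_edge, 256)
  expect_length(meta$levels, 2)
})
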