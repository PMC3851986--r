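build_cdc_bundle <- function(dir, modules = list(CellCycle = NULL,
                                                 RB = NULL)) {
  doc <- mk_cdc_doc()
  views <- render_views(doc, 2, canvas = c(512, 256))
  pyr <- build_tile_pyramid(views)
  build_site(doc, modules = modules, pyramid = pyr, config = list(),
             out_dir = dir)
}

test_that("a bundle with modules cross-links pages in both directions", {
  d <- withr::local_tempdir()
  b <- build_cdc_bundle(d)
  expect_length(b$pages, 3)
  expect_true(all(file.exists(file.path(d, b$pages))))
  idx <- paste(readLines(file.path(d, "index.html")), collapse = "\n")
  expect_match(idx, 'href="modules/CellCycle.html"', fixed = TRUE)
  expect_match(idx, 'href="modules/RB.html"', fixed = TRUE)
  mod <- paste(readLines(file.path(d, "modules", "RB.html")),
               collapse = "\n")
  expect_match(mod, 'href="../index.html"', fixed = TRUE)
  expect_length(check_bundle_links(d), 0)
})

test_that("a module-less map yields a single page without module section", {
  d <- withr::local_tempdir()
  fx <- make_map(small_spec(4, n_modules = 0))
  views <- render_views(fx$doc, 2, canvas = c(1024, 512))
  b <- build_site(fx$doc, modules = list(),
                  pyramid = build_tile_pyramid(views),
                  config = list(), out_dir = d)
  expect_length(b$pages, 1)
  idx <- paste(readLines(file.path(d, "index.html")), collapse = "\n")
  expect_no_match(idx, "<h3>Modules</h3>", fixed = TRUE)
  expect_length(check_bundle_links(d), 0)
})

test_that("entities assigned to undeclared modules abort the build", {
  d <- withr::local_tempdir()
  expect_error(build_cdc_bundle(d, modules = list(CellCycle = NULL)),
               "build error.*RB")
})

test_that("every alias gets exactly one callout with its links", {
  d <- withr::local_tempdir()
  b <- build_cdc_bundle(d)
  doc <- mk_cdc_doc()
  expect_identical(
    unname(sort(vapply(b$callouts$index, `[[`, character(1),
                       "alias_id"))),
    sort(names(doc$aliases)))
  # an entity in a module lists the module link; the complex callout
  # carries the canonical name and a post link
  co <- b$callouts$index[["a2"]]
  expect_identical(co$name, "Cdc13:Cdc2|Thr167_pho@cytoplasm")
  expect_match(co$html, 'href="modules/CellCycle.html"', fixed = TRUE)
  expect_match(co$html, 'posts/entity_p_cdc13.html', fixed = TRUE)
  # marker anchor is the bbox center
  expect_equal(co$anchor, c(192 + 64, 96 + 32))
})

test_that("module pages list only member entities", {
  d <- withr::local_tempdir()
  b <- build_cdc_bundle(d)
  expect_setequal(unlist(b$panel_index$RB, use.names = FALSE), "RB")
  expect_setequal(unlist(b$panel_index$CellCycle, use.names = FALSE),
                  c("Cdc25", "Cdc13", "Cdc2"))
  mod <- paste(readLines(file.path(d, "modules", "RB.html")),
               collapse = "\n")
  expect_no_match(mod, ">MYC<", fixed = TRUE)
})

test_that("panel entries cover the page's entity set exactly", {
  d <- withr::local_tempdir()
  b <- build_cdc_bundle(d)
  doc <- mk_cdc_doc()
  expect_setequal(
    unlist(b$panel_index$master, use.names = FALSE),
    vapply(doc$entities, `[[`, character(1), "display_name"))
})

test_that("search matches any substring, case-insensitively", {
  idx <- build_search_index(mk_cdc_doc())
  hits <- search_entities(idx, "cdc")
  expect_setequal(hits$name, c("Cdc25", "Cdc2", "Cdc13"))
  expect_identical(nrow(search_entities(idx, "")), 0L)
  expect_identical(nrow(search_entities(idx, "zzz")), 0L)
  # annotation words are searchable too
  expect_true("RB" %in% search_entities(idx, "retinoblastoma")$name)
  # order: match position first, then name
  expect_identical(hits$name[1], "Cdc13")
})

test_that("longer queries only narrow the result set", {
  idx <- build_search_index(mk_cdc_doc())
  q1 <- search_entities(idx, "cdc")
  q2 <- search_entities(idx, "cdc2")
  q3 <- search_entities(idx, "cdc25")
  expect_true(all(q2$entity_id %in% q1$entity_id))
  expect_true(all(q3$entity_id %in% q2$entity_id))
})

test_that("the source file download link follows the config flag", {
  d1 <- withr::local_tempdir()
  doc <- mk_cdc_doc()
  xml_path <- file.path(d1, "src.xml")
  write_map(doc, xml_path)
  d2 <- withr::local_tempdir()
  build_site(doc, modules = list(CellCycle = NULL, RB = NULL),
             pyramid = NULL,
             config = list(include_source_xml = TRUE,
                           map_xml = xml_path),
             out_dir = d2)
  idx <- paste(readLines(file.path(d2, "index.html")), collapse = "\n")
  expect_match(idx, 'href="map.xml"', fixed = TRUE)
  expect_true(file.exists(file.path(d2, "map.xml")))
  expect_length(check_bundle_links(d2), 0)
})

test_that("the link checker reports dangling references", {
  d <- withr::local_tempdir()
  build_cdc_bundle(d)
  writeLines('<html><body><a href="missing.html">x</a></body></html>',
             file.path(d, "broken.html"))
  dang <- check_bundle_links(d)
  expect_length(dang, 1)
  expect_match(dang, "missing.html")
})
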