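test_that("entity posts list forms and reactions with roles", {
  doc <- mk_cdc_doc()
  # Cdc2 occurs free and inside the complex; it is reactant in r1 via
  # its free form and (through the complex) product of r1
  post <- generate_post("p_cdc2", doc)
  expect_identical(post$kind, "entity")
  expect_match(post$html, "Cdc2", fixed = TRUE)
  expect_match(post$html, "Cdc13:Cdc2|Thr167_pho@cytoplasm", fixed = TRUE)
  expect_match(post$html, "REACTANT")
  expect_match(post$html, "pa-globe")

  # a protein that is reactant in one reaction and modifier in another
  doc2 <- mk_cdc_doc()
  doc2$reactions[["r2"]]$participants[[3]] <-
    reaction_participant("s_cdc25p", "MODIFIER", "INHIBITION")
  p2 <- generate_post("p_cdc25", doc2)
  expect_match(p2$html, "MODIFIER \\(CATALYSIS\\)")
  expect_match(p2$html, "MODIFIER \\(INHIBITION\\)")

  # an entity with no reactions keeps an (empty) reactions section
  p3 <- generate_post("g_myc", mk_cdc_doc())
  expect_match(p3$html, "<h3>Reactions</h3>")
  p4 <- generate_post("p_rb", doc)
  expect_match(p4$html, "REACTANT")

  expect_error(generate_post("nope", doc), "unknown post key")
})

test_that("complex forms carry the modification in their canonical name", {
  doc <- mk_cdc_doc()
  post <- generate_post("p_cdc13", doc)
  expect_match(post$html, "Thr167_pho", fixed = TRUE)
})

test_that("module and reaction posts exist and link to the map", {
  doc <- mk_cdc_doc()
  pm <- generate_post("CellCycle", doc)
  expect_identical(pm$kind, "module")
  expect_match(pm$html, "Cdc25|Pho@cytoplasm", fixed = TRUE)
  pr <- generate_post("r1", doc)
  expect_identical(pr$kind, "reaction")
  expect_match(pr$html, "MODIFIER \\(CATALYSIS\\)")
})

test_that("a removed entity archives its post; nothing is deleted", {
  doc <- mk_cdc_doc()
  st <- sync_store(post_store(), doc)$store
  n0 <- length(st$records)
  # release 2: RB leaves the map
  doc2 <- map_document(
    doc$name,
    unname(doc$entities[names(doc$entities) != "p_rb"]),
    unname(doc$species[names(doc$species) != "s_rb"]),
    unname(doc$aliases[!vapply(doc$aliases, function(a)
      a$species_id == "s_rb", logical(1))]),
    unname(doc$reactions["r1"]))
  res <- sync_store(st, doc2)
  expect_true(length(res$store$records) >= n0)
  rb <- Filter(function(r) r$key == "entity:p_rb", res$store$records)
  expect_length(rb, 1)
  expect_identical(rb[[1]]$status, "ARCHIVED")
  expect_true("archived" %in% res$report$action)
})

test_that("an edited annotation archives the old version with its comments", {
  doc <- mk_cdc_doc()
  st <- sync_store(post_store(), doc)$store
  st <- add_comment(st, "entity:p_cdc25", "alice", "please check residue",
                    "2026-01-02T10:00:00")
  doc2 <- doc
  doc2$entities[["p_cdc25"]]$annotation_text <-
    paste0(doc2$entities[["p_cdc25"]]$annotation_text,
           "\nRevised after review.")
  res <- sync_store(st, doc2)
  recs <- Filter(function(r) r$key == "entity:p_cdc25",
                 res$store$records)
  vers <- vapply(recs, `[[`, integer(1), "version")
  stat <- vapply(recs, `[[`, character(1), "status")
  expect_identical(sort(vers), 1:2)
  expect_identical(stat[vers == 1], "ARCHIVED")
  expect_identical(stat[vers == 2], "ACTIVE")
  expect_length(recs[vers == 1][[1]]$comments, 1)
  expect_length(recs[vers == 2][[1]]$comments, 0)
})

test_that("synchronizing an identical release is a no-op", {
  doc <- mk_cdc_doc()
  r1 <- sync_store(post_store(), doc)
  r2 <- sync_store(r1$store, doc)
  expect_identical(r2$store, r1$store)
  expect_identical(nrow(r2$report), 0L)
})

test_that("history is monotone and comments conserved across releases", {
  doc <- mk_cdc_doc()
  st <- sync_store(post_store(), doc)$store
  st <- add_comment(st, "entity:p_cdc2", "bob", "form list ok?",
                    "2026-01-03T09:00:00")
  st <- add_comment(st, "entity:p_rb", "carol", "missing E2F partner",
                    "2026-01-03T09:05:00")
  count_comments <- function(s) {
    sum(vapply(s$records, function(r) length(r$comments), integer(1)))
  }
  n_rec <- length(st$records)
  n_com <- count_comments(st)

  # release: edit Cdc2, remove RB, add a new protein
  doc2 <- mk_cdc_doc()
  doc2$entities[["p_cdc2"]]$annotation_text <- "New annotation."
  new_e <- entity("p_wee1", "PROTEIN", "Wee1")
  doc3 <- map_document(
    doc2$name,
    c(unname(doc2$entities[names(doc2$entities) != "p_rb"]),
      list(new_e)),
    c(unname(doc2$species[names(doc2$species) != "s_rb"]),
      list(species_state("s_wee1",
                         list(species_component("p_wee1", "Wee1"))))),
    unname(doc2$aliases[!vapply(doc2$aliases, function(a)
      a$species_id == "s_rb", logical(1))]),
    unname(doc2$reactions["r1"]))
  res <- sync_store(st, doc3)
  expect_gte(length(res$store$records), n_rec)
  expect_identical(count_comments(res$store), n_com)
  # and once more, idempotent again
  res2 <- sync_store(res$store, doc3)
  expect_identical(res2$store, res$store)
  expect_gte(length(res2$store$records), length(res$store$records))
})

test_that("the store survives a save/load cycle and renders to HTML", {
  doc <- mk_cdc_doc()
  st <- sync_store(post_store(), doc)$store
  st <- add_comment(st, "entity:p_cdc25", "alice", "note",
                    "2026-01-01T00:00:00")
  d <- withr::local_tempdir()
  p <- file.path(d, "store.json")
  save_post_store(st, p)
  back <- load_post_store(p)
  expect_identical(back, st)
  render_post_store(back, file.path(d, "blog"))
  expect_true(file.exists(file.path(d, "blog", "index.html")))
  expect_true(file.exists(file.path(d, "blog", "archive", "index.html")))
  expect_true(file.exists(file.path(d, "blog", "entity_p_cdc25.html")))
})

test_that("a corrupt store with duplicate active records is refused", {
  doc <- mk_cdc_doc()
  st <- sync_store(post_store(), doc)$store
  st$records[[length(st$records) + 1]] <- st$records[[1]]
  expect_error(sync_store(st, doc), "integrity error")
})

test_that("the remote blog adapter is an inert interface stub", {
  ad <- remote_blog_adapter()
  ad$create_post(list(key = "entity:x"))
  ad$archive_post("entity:x", 1)
  lg <- ad$log()
  expect_length(lg, 2)
  expect_identical(lg[[1]]$op, "create_post")
})
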