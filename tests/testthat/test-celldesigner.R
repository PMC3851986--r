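test_that("a written map reparses to an equal document", {
  doc <- mk_cdc_doc()
  back <- parse_map(write_map(doc))
  expect_true(map_equal(doc, back))
  # four entity classes survive (class multiset identical)
  expect_identical(
    sort(vapply(back$entities, `[[`, character(1), "entity_class")),
    sort(vapply(doc$entities, `[[`, character(1), "entity_class")))
  # modifier role and subtype preserved
  p <- back$reactions[["r1"]]$participants
  roles <- vapply(p, `[[`, character(1), "role")
  expect_setequal(roles, c("REACTANT", "PRODUCT", "MODIFIER"))
  expect_identical(p[[which(roles == "MODIFIER")]]$modifier_subtype,
                   "CATALYSIS")
})

test_that("parse materializes species, states, compartments and names", {
  doc <- parse_map(write_map(mk_cdc_doc()))
  expect_identical(format_name(doc$species[["s_cdc25p"]]),
                   "Cdc25|Pho@cytoplasm")
  expect_identical(format_name(doc$species[["s_cplx"]]),
                   "Cdc13:Cdc2|Thr167_pho@cytoplasm")
  expect_length(doc$species[["s_cplx"]]$components, 2)
  # species without explicit compartment stay compartment-less
  expect_true(is.na(doc$species[["s_cdc2"]]$compartment))
  # entities lacking annotations get empty annotation_text
  expect_identical(doc$entities[["p_cdc2"]]$annotation_text, "")
  # one species drawn twice keeps both aliases
  owners <- vapply(doc$aliases, `[[`, character(1), "species_id")
  expect_identical(sum(owners == "s_cdc2"), 2L)
})

test_that("an empty map parses to zero entities and reactions", {
  doc <- parse_map(write_map(map_document("empty")))
  expect_length(doc$entities, 0)
  expect_length(doc$reactions, 0)
  expect_length(doc$species, 0)
})

test_that("round trip holds across generated fixture maps", {
  for (seed in 1:3) {
    fx <- make_map(small_spec(seed))
    back <- expect_no_warning(parse_map(fx$xml))
    expect_true(map_equal(fx$doc, back))
    expect_true(map_equal(back, parse_map(write_map(back))))
  }
})

test_that("malformed or foreign XML is rejected with a specific error", {
  expect_error(parse_map("<sbml><model></sbml>"), "parse error")
  expect_error(
    parse_map('<?xml version="1.0"?><foo><bar/></foo>'),
    "unsupported dialect")
  plain_sbml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2"',
    ' version="4"><model id="m"/></sbml>')
  expect_error(parse_map(plain_sbml), "unsupported dialect")
})

test_that("dangling internal references are an integrity error", {
  xml <- write_map(mk_cdc_doc())
  broken <- sub('species="s_rb"', 'species="s_gone"', xml)
  expect_error(parse_map(broken), "integrity error.*s_gone")
})

test_that("documents validate referential closure on construction", {
  e <- entity("e1", "PROTEIN", "A")
  s <- species_state("s1", list(species_component("e_missing", "A")))
  expect_error(map_document("m", list(e), list(s)),
               "integrity error.*e_missing")
  a <- map_alias("a1", "s_missing", c(0, 0, 10, 10))
  expect_error(
    map_document("m", list(e),
                 list(species_state("s1",
                                    list(species_component("e1", "A")))),
                 list(a)),
    "integrity error.*s_missing")
})

test_that("class grouping partitions the entity set", {
  doc <- mk_cdc_doc()
  groups <- group_entities_by_class(doc)
  expect_identical(lengths(groups), c(PROTEIN = 4L, GENE = 1L))
  expect_setequal(
    unlist(groups, use.names = FALSE),
    vapply(doc$entities, `[[`, character(1), "display_name"))
  # a protein with several aliases is still listed once
  expect_identical(sum(unlist(groups) == "Cdc2"), 1L)
  expect_identical(group_entities_by_class(map_document("empty")),
                   list())
  # classes come out in the fixed panel order
  fx <- make_map(small_spec(2))
  expect_identical(
    names(group_entities_by_class(fx$doc)),
    intersect(c("PROTEIN", "GENE", "RNA", "ANTISENSE_RNA",
                "SIMPLE_MOLECULE", "ION", "PHENOTYPE", "DRUG",
                "UNKNOWN", "DEGRADED", "COMPLEX"),
              names(group_entities_by_class(fx$doc))))
})

test_that("modules derive from Maps_Modules annotation sections", {
  doc <- mk_cdc_doc()
  expect_setequal(names(doc$modules), c("CellCycle", "RB"))
  # the complex joins CellCycle through its Cdc13 component
  expect_setequal(doc$modules[["CellCycle"]]$member_species,
                  c("s_cdc25p", "s_cplx"))
  expect_identical(doc$modules[["RB"]]$member_species, "s_rb")
})
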