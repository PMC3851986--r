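test_that("sectioned annotations parse into ordered named sections", {
  raw <- paste("Identifiers:", "HUGO:CDC25A", "Maps_Modules:", "RB",
               "References:", "PMID:18319725 free comment", sep = "\n")
  doc <- parse_annotation(raw)
  expect_true(doc$sectioned)
  expect_identical(vapply(doc$sections, `[[`, character(1), "name"),
                   c("Identifiers", "Maps_Modules", "References"))
  expect_identical(annotation_section(doc, "Maps_Modules"), "RB")
})

test_that("non-matching text stays a single unsectioned block", {
  prose <- "Cdc25 is a phosphatase.\nIt activates Cdk1."
  doc <- parse_annotation(prose)
  expect_false(doc$sectioned)
  expect_length(doc$sections, 1)
  expect_identical(doc$sections[[1]]$body, prose)

  empty <- parse_annotation("")
  expect_false(empty$sectioned)
  expect_identical(empty$sections[[1]]$body, "")
})

test_that("parsing loses no characters", {
  cases <- c(
    "Identifiers:\nHUGO:X\nMaps_Modules:\nM1\nM2\nReferences:\nPMID:1",
    "Identifiers:\nHUGO:X\n",
    "A:\n\nB:\nx",
    "B:",
    "free prose, no headers at all",
    ""
  )
  for (raw in cases) {
    expect_identical(annotation_text(parse_annotation(raw)), raw)
  }
})

test_that("module membership comes from the Maps_Modules section", {
  expect_identical(
    extract_module_membership("Maps_Modules:\nRB"), "RB")
  expect_identical(
    extract_module_membership("Maps_Modules:\nRB\nCellCycle"),
    c("RB", "CellCycle"))
  expect_identical(extract_module_membership("Identifiers:\nHUGO:X"),
                   character())
  expect_identical(extract_module_membership("free prose"), character())
})

test_that("registered prefix tags expand to resolver anchors", {
  out <- expand_tags("PMID:18319725")
  expect_match(out, '<a href="[^"]*18319725[^"]*"')
  expect_match(out, "pubmed")
  expect_match(out, ">PMID:18319725</a>")

  out2 <- expand_tags("see HUGO:CDC25A and UNIPROT:P30304.")
  expect_match(out2, "genenames")
  expect_match(out2, "uniprot")
  expect_match(out2, "P30304")
})

test_that("MIRIAM registry tags keep colons inside the id", {
  out <- expand_tags("@biocyc:YEAST:G3O-30431")
  expect_match(out, 'href="https://identifiers.org/biocyc:YEAST:G3O-30431"',
               fixed = TRUE)
  expect_match(out, ">@biocyc:YEAST:G3O-30431</a>")
})

test_that("unknown MIRIAM resources pass through with a warning", {
  expect_warning(out <- expand_tags("@nosuchdb:XYZ:1"),
                 "unknown MIRIAM resource")
  expect_identical(out, "@nosuchdb:XYZ:1")
})

test_that("plain text passes through unmodified and expansion is idempotent", {
  expect_identical(expand_tags("no tags here."), "no tags here.")
  txts <- c("PMID:18319725 and @biocyc:YEAST:G3O-30431 in prose",
            "a < b & c > d with UNIPROT:P30304")
  for (txt in txts) {
    once <- expand_tags(txt)
    expect_identical(expand_tags(once), once)
  }
  # escaping without tags is also stable
  esc <- expand_tags("a < b & c")
  expect_identical(expand_tags(esc), esc)
})

test_that("user-defined tags extend the registry", {
  reg <- default_tag_registry(c(WIKI = "https://example.org/wiki/%s"))
  expect_match(expand_tags("WIKI:Cdc25", reg),
               'href="https://example.org/wiki/Cdc25"', fixed = TRUE)
  expect_error(tag_registry(c(BAD = "https://example.org/none")),
               "placeholder")
  expect_error(tag_registry(c(A = "%s", A = "%s")), "unique")
})
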