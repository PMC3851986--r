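test_that("canonical names serialize modifications and compartments", {
  s <- species_state(
    "s1", list(species_component("e1", "Cdc25",
                                 list(modification("Pho")))),
    compartment = "cytoplasm")
  expect_identical(format_name(s), "Cdc25|Pho@cytoplasm")

  cplx <- species_state(
    "s2",
    list(species_component("e2", "Cdc13"),
         species_component("e3", "Cdc2",
                           list(modification("pho", "Thr167")))),
    compartment = "cytoplasm")
  expect_identical(format_name(cplx), "Cdc13:Cdc2|Thr167_pho@cytoplasm")

  bare <- species_state("s3", list(species_component("e4", "RB")))
  expect_identical(format_name(bare), "RB")
})

test_that("reserved characters in names are an encoding error", {
  bad <- species_state("s", list(species_component("e", "A|B")))
  expect_error(format_name(bad), "encoding error")
  bad2 <- species_state("s", list(species_component("e", "A")),
                        compartment = "cyto@plasm")
  expect_error(format_name(bad2), "encoding error")
})

test_that("parsing recovers components, residues and compartment", {
  s <- parse_name("Cdc13:Cdc2|Thr167_pho@cytoplasm")
  expect_length(s$components, 2)
  expect_identical(s$components[[1]]$name, "Cdc13")
  m <- s$components[[2]]$modifications[[1]]
  expect_identical(m$residue_label, "Thr167")
  expect_identical(m$residue_position, 167L)
  expect_identical(m$state_label, "pho")
  expect_identical(s$compartment, "cytoplasm")

  s2 <- parse_name("Cdc25|Pho@cytoplasm")
  expect_length(s2$components, 1)
  expect_identical(s2$components[[1]]$modifications[[1]]$state_label,
                   "Pho")
  expect_identical(s2$compartment, "cytoplasm")

  s3 <- parse_name("A")
  expect_length(s3$components, 1)
  expect_length(s3$components[[1]]$modifications, 0)
  expect_true(is.na(s3$compartment))
})

test_that("ill-formed names raise grammar errors with position info", {
  expect_error(parse_name(""), "grammar error")
  expect_error(parse_name("A@"), "grammar error")
  expect_error(parse_name("A@x@y"), "grammar error")
  expect_error(parse_name("A:"), "grammar error")
  expect_error(parse_name("A|"), "grammar error")
  expect_error(parse_name("A|x_"), "grammar error")
})

test_that("state label case is preserved, not normalized", {
  expect_identical(
    parse_name("X|Pho")$components[[1]]$modifications[[1]]$state_label,
    "Pho")
  expect_identical(
    parse_name("X|pho")$components[[1]]$modifications[[1]]$state_label,
    "pho")
})

test_that("parse and format are mutually inverse on generated states", {
  set.seed(42)
  for (i in 1:200) {
    s <- gen_state()
    txt <- format_name(s)
    back <- parse_name(txt)
    expect_identical(norm_state(back), norm_state(s))
    expect_identical(format_name(back), txt)
  }
})

test_that("distinct fixture species get distinct names", {
  doc <- mk_cdc_doc()
  nms <- vapply(doc$species, format_name, character(1))
  expect_identical(anyDuplicated(nms), 0L)
})

test_that("multiple modifications order deterministically", {
  a <- species_component("e", "X", list(modification("pho", "Thr167"),
                                        modification("ub", "Lys48")))
  b <- species_component("e", "X", list(modification("ub", "Lys48"),
                                        modification("pho", "Thr167")))
  sa <- species_state("s", list(a))
  sb <- species_state("s", list(b))
  expect_identical(format_name(sa), format_name(sb))
  expect_identical(format_name(sa), "X|Lys48_ub|Thr167_pho")
})
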