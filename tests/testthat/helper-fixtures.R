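# hand-built cell-cycle style map used across the suite: three Cdc
# proteins, the Cdc13:Cdc2 complex, RB, one gene, reactions with a
# catalyst
mk_cdc_doc <- function() {
  ents <- list(
    entity("p_cdc25", "PROTEIN", "Cdc25",
           paste("Identifiers:", "HUGO:CDC25A UNIPROT:P30304",
                 "Maps_Modules:", "CellCycle", "References:",
                 "PMID:18319725 @biocyc:YEAST:G3O-30431",
                 "Cdc25 activates the cyclin B kinase.", sep = "\n")),
    entity("p_cdc2", "PROTEIN", "Cdc2"),
    entity("p_cdc13", "PROTEIN", "Cdc13",
           "Maps_Modules:\nCellCycle\nReferences:\nMitotic cyclin."),
    entity("p_rb", "PROTEIN", "RB",
           "Maps_Modules:\nRB\nReferences:\nRetinoblastoma protein."),
    entity("g_myc", "GENE", "MYC")
  )
  sps <- list(
    species_state("s_cdc25p",
                  list(species_component("p_cdc25", "Cdc25",
                                         list(modification("Pho")))),
                  "cytoplasm"),
    species_state("s_cplx",
                  list(species_component("p_cdc13", "Cdc13"),
                       species_component(
                         "p_cdc2", "Cdc2",
                         list(modification("pho", "Thr167")))),
                  "cytoplasm"),
    species_state("s_cdc2",
                  list(species_component("p_cdc2", "Cdc2"))),
    species_state("s_rb", list(species_component("p_rb", "RB")),
                  "nucleus"),
    species_state("s_myc", list(species_component("g_myc", "MYC")))
  )
  als <- list(
    map_alias("a1", "s_cdc25p", c(32, 32, 96, 48)),
    map_alias("a2", "s_cplx", c(192, 96, 128, 64)),
    map_alias("a3", "s_cdc2", c(352, 32, 96, 48)),
    map_alias("a3b", "s_cdc2", c(352, 160, 96, 48)),
    map_alias("a4", "s_rb", c(32, 160, 96, 48)),
    map_alias("a5", "s_myc", c(192, 224, 96, 48))
  )
  rxs <- list(
    map_reaction("r1", list(
      reaction_participant("s_cdc2", "REACTANT"),
      reaction_participant("s_cplx", "PRODUCT"),
      reaction_participant("s_cdc25p", "MODIFIER", "CATALYSIS"))),
    map_reaction("r2", list(
      reaction_participant("s_rb", "REACTANT"),
      reaction_participant("s_myc", "PRODUCT")))
  )
  map_document("cdc_fixture", ents, sps, als, rxs)
}

# random canonical species state (modifications canonically ordered by
# the constructor), for naming round-trip properties
gen_state <- function() {
  n_comp <- sample(1:3, 1)
  comps <- lapply(seq_len(n_comp), function(i) {
    nm <- paste(sample(LETTERS, sample(2:5, 1), TRUE), collapse = "")
    mods <- lapply(seq_len(sample(0:2, 1)), function(j) {
      if (stats::runif(1) < 0.4) {
        modification(sample(c("pho", "Pho", "ub", "ace"), 1))
      } else {
        modification(sample(c("pho", "gly"), 1),
                     residue_label = paste0(
                       sample(c("Thr", "Ser", "Tyr"), 1),
                       sample(1:400, 1)))
      }
    })
    species_component("", nm, mods)
  })
  cpt <- if (stats::runif(1) < 0.5) NA_character_ else
    sample(c("cytoplasm", "nucleus", "plasma_membrane"), 1)
  species_state("x", comps, compartment = cpt)
}

# species-state skeleton stripped of ids, for comparing parse output
# with the state that produced the name
norm_state <- function(s) {
  list(
    comps = lapply(s$components, function(c) list(
      name = c$name,
      mods = lapply(c$modifications, function(m)
        list(res = m$residue_label, pos = m$residue_position,
             st = m$state_label)))),
    compartment = s$compartment
  )
}

# small fixture spec that keeps raster work cheap in unit tests
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_proteins = 5, n_genes = 2, n_rnas = 1, n_antisense = 1,
         n_complexes = 1, n_reactions = 4, n_modules = 2,
         canvas = c(1024, 512), seed = seed),
    list(...))
  do.call(fixture_spec, args)
}
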