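#' @title Synthetic map fixtures
#' @description Generates small synthetic CellDesigner maps — entities
#'   of the four primary classes plus small molecules, complexes,
#'   modification states, compartments, reactions with catalysts, and
#'   structured annotations with identifier tags — together with
#'   schematically rendered zoom-view images, so the whole factory
#'   pipeline runs and is testable without any external map. Rendering
#'   is deliberately schematic (colored rectangles, no SBGN glyphs):
#'   downstream stages care about geometry and metadata, not glyph
#'   semantics, and no claim of biological realism is made.
#' @name fixtures
NULL

#' Describe a synthetic map
#'
#' @param n_proteins,n_genes,n_rnas,n_antisense Entity counts per class.
#' @param n_complexes Number of two-component protein complexes.
#' @param n_reactions Number of reactions.
#' @param n_modules Number of modules; module membership covers all
#'   modules.
#' @param modification_rate Probability that a protein species carries a
#'   modification state.
#' @param canvas Canvas `c(width, height)` in pixels of the most
#'   detailed view; powers of two times 256 by default so view chains
#'   tile without padding.
#' @param seed Integer seed; generation is deterministic for a given
#'   seed.
#' @return An object of class `pa_fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 12, n_genes = 4, n_rnas = 3,
                         n_antisense = 1, n_complexes = 2,
                         n_reactions = 8, n_modules = 2,
                         modification_rate = 0.3,
                         canvas = c(2048, 1024), seed = 1) {
  counts <- c(n_proteins, n_genes, n_rnas, n_antisense, n_complexes,
              n_reactions, n_modules)
  stopifnot(all(counts >= 0), length(canvas) == 2, all(canvas > 0),
            modification_rate >= 0, modification_rate <= 1)
  structure(
    list(n_proteins = n_proteins, n_genes = n_genes, n_rnas = n_rnas,
         n_antisense = n_antisense, n_complexes = n_complexes,
         n_reactions = n_reactions, n_modules = n_modules,
         modification_rate = modification_rate,
         canvas = as.integer(canvas), seed = as.integer(seed)),
    class = "pa_fixture_spec"
  )
}

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

FIXTURE_STATES <- c("pho", "Pho", "ace", "ub")
FIXTURE_RESIDUES <- c("Thr", "Ser", "Tyr")
FIXTURE_COMPARTMENTS <- c(NA, "cytoplasm", "nucleus")

#' Generate a synthetic CellDesigner map
#'
#' Entities get structured annotations (`Identifiers` with HUGO and
#' UNIPROT tags, `Maps_Modules` listing their modules, `References`
#' with a PMID and a MIRIAM registry tag plus a free comment); species
#' get compartments and (for proteins, at `modification_rate`)
#' modification states; complexes combine two protein components;
#' reactions connect species with reactant/product roles and
#' occasionally a catalyst or inhibitor. Aliases are laid out on a
#' regular grid of the canvas.
#'
#' @param spec A [fixture_spec()].
#' @return List with `doc` (the [map_document()]) and `xml` (its
#'   CellDesigner serialization; byte-identical across runs with the
#'   same spec).
#' @export
make_map <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "pa_fixture_spec"))
  with_seed(spec$seed, function() {
    classes <- rep(c("PROTEIN", "GENE", "RNA", "ANTISENSE_RNA"),
                   c(spec$n_proteins, spec$n_genes, spec$n_rnas,
                     spec$n_antisense))
    prefixes <- c(PROTEIN = "PRO", GENE = "GEN", RNA = "RNA",
                  ANTISENSE_RNA = "ASR")
    nm <- paste0(prefixes[classes],
                 unlist(lapply(c(spec$n_proteins, spec$n_genes,
                                 spec$n_rnas, spec$n_antisense),
                               seq_len)))
    modules <- if (spec$n_modules > 0) paste0("M", seq_len(spec$n_modules))
               else character()
    entities <- vector("list", length(nm))
    for (i in seq_along(nm)) {
      eid <- paste0("e", i)
      # round-robin plus occasional double membership covers all modules
      mods <- if (length(modules)) {
        first <- modules[(i - 1) %% length(modules) + 1]
        if (length(modules) > 1 && stats::runif(1) < 0.25) {
          c(first, modules[i %% length(modules) + 1])
        } else first
      } else character()
      entities[[i]] <- entity(eid, classes[i], nm[i],
                              fixture_annotation(nm[i], mods))
    }
    names(entities) <- nm

    species <- list()
    k <- 0
    for (i in seq_along(nm)) {
      k <- k + 1
      mods <- list()
      if (classes[i] == "PROTEIN" &&
          stats::runif(1) < spec$modification_rate) {
        mods <- list(fixture_modification())
      }
      species[[k]] <- species_state(
        paste0("s", k),
        list(species_component(paste0("e", i), nm[i], mods)),
        compartment = sample(FIXTURE_COMPARTMENTS, 1))
    }
    prot_idx <- which(classes == "PROTEIN")
    for (j in seq_len(spec$n_complexes)) {
      k <- k + 1
      pick <- sample(prot_idx, 2)
      comps <- lapply(seq_along(pick), function(q) {
        i <- pick[q]
        mods <- if (q == 2 && stats::runif(1) < spec$modification_rate) {
          list(fixture_modification())
        } else list()
        species_component(paste0("e", i), nm[i], mods)
      })
      species[[k]] <- species_state(
        paste0("s", k), comps,
        compartment = sample(FIXTURE_COMPARTMENTS, 1))
    }

    aliases <- fixture_layout(species, spec$canvas)

    reactions <- list()
    sids <- vapply(species, `[[`, character(1), "species_id")
    if (spec$n_reactions > 0 && length(sids) >= 2) {
      for (r in seq_len(spec$n_reactions)) {
        pick <- sample(sids, 2)
        parts <- list(reaction_participant(pick[1], "REACTANT"),
                      reaction_participant(pick[2], "PRODUCT"))
        if (stats::runif(1) < 0.5 && length(sids) >= 3) {
          m <- sample(setdiff(sids, pick), 1)
          parts[[3]] <- reaction_participant(
            m, "MODIFIER", sample(c("CATALYSIS", "INHIBITION"), 1))
        }
        reactions[[r]] <- map_reaction(paste0("r", r), parts)
      }
    }

    doc <- map_document(paste0("fixture_seed", spec$seed),
                        unname(entities), species, aliases, reactions)
    list(doc = doc, xml = write_map(doc))
  })
}

fixture_modification <- function() {
  if (stats::runif(1) < 0.5) {
    modification("Pho")
  } else {
    modification("pho",
                 residue_label = paste0(sample(FIXTURE_RESIDUES, 1),
                                        sample(50:500, 1)))
  }
}

fixture_annotation <- function(name, modules) {
  parts <- c(
    "Identifiers:",
    sprintf("HUGO:%s UNIPROT:P%05d", name, sample(10000:99999, 1)))
  if (length(modules)) {
    parts <- c(parts, "Maps_Modules:", modules)
  }
  c(parts,
    "References:",
    sprintf("PMID:%d @biocyc:YEAST:G3O-%05d",
            sample(10000000:30000000, 1), sample(10000:99999, 1)),
    sprintf("%s is a synthetic fixture entity.", name)) |>
    paste(collapse = "\n")
}

## one alias per species on a regular grid; boxes never touch so
## raster probes are unambiguous
fixture_layout <- function(species, canvas) {
  cell_w <- 160
  cell_h <- 96
  per_row <- max(1, canvas[1] %/% cell_w)
  lapply(seq_along(species), function(k) {
    row <- (k - 1) %/% per_row
    col <- (k - 1) %% per_row
    if ((row + 1) * cell_h > canvas[2]) {
      stop("canvas too small for ", length(species), " aliases")
    }
    map_alias(paste0("a", k), species[[k]]$species_id,
              c(col * cell_w + 20, row * cell_h + 24, 120, 48))
  })
}

FIXTURE_CLASS_COLORS <- list(
  PROTEIN = c(0.62, 0.79, 0.93),
  GENE = c(0.98, 0.91, 0.56),
  RNA = c(0.69, 0.89, 0.64),
  ANTISENSE_RNA = c(0.95, 0.72, 0.52),
  COMPLEX = c(0.80, 0.68, 0.90),
  DEFAULT = c(0.85, 0.85, 0.85)
)

#' Render schematic zoom views for a map
#'
#' The most detailed view draws one filled rectangle per alias, colored
#' by entity class (purple for complexes), at exactly the alias bounding
#' box. Each coarser view halves the pixel dimensions and drops the
#' rectangles that would become too small to read — a schematic stand-in
#' for semantic zooming, where detail vanishes rather than shrinks.
#' The chain always passes [validate_view_chain()] with zero errors.
#'
#' @param doc A [map_document()].
#' @param k_levels Number of zoom levels (>= 1).
#' @param canvas Pixel size `c(width, height)` of the most detailed
#'   view; must be divisible by `2^(k_levels - 1)`.
#' @param min_area Scaled-box area (px^2) below which a box is dropped
#'   from a coarser view.
#' @return List of `k_levels` [zoom_view()]s, level 0 (coarsest) first.
#' @export
render_views <- function(doc, k_levels = 4, canvas = c(2048, 1024),
                         min_area = 24) {
  stopifnot(k_levels >= 1)
  f <- 2^(k_levels - 1)
  if (any(canvas %% f != 0)) {
    stop("canvas ", canvas[1], "x", canvas[2],
         " is not divisible by 2^(k_levels-1) = ", f)
  }
  lapply(seq_len(k_levels) - 1L, function(lev) {
    scale <- 2^(lev - (k_levels - 1))  # 1 at the detailed level
    w <- canvas[1] * scale
    h <- canvas[2] * scale
    img <- array(1, dim = c(h, w, 3))
    for (al in doc$aliases) {
      bb <- al$bbox * scale
      if (bb[["w"]] * bb[["h"]] < min_area && scale < 1) next
      x0 <- max(1, floor(bb[["x"]]) + 1)
      y0 <- max(1, floor(bb[["y"]]) + 1)
      x1 <- min(w, ceiling(bb[["x"]] + bb[["w"]]))
      y1 <- min(h, ceiling(bb[["y"]] + bb[["h"]]))
      if (x1 < x0 || y1 < y0) next
      col <- alias_color(doc, al)
      for (ch in 1:3) img[y0:y1, x0:x1, ch] <- col[ch]
    }
    zoom_view(lev, img, semantic = TRUE)
  })
}

alias_color <- function(doc, al) {
  sp <- doc$species[[al$species_id]]
  if (length(sp$components) > 1) return(FIXTURE_CLASS_COLORS$COMPLEX)
  cls <- doc$entities[[sp$components[[1]]$entity_id]]$entity_class
  FIXTURE_CLASS_COLORS[[cls]] %||% FIXTURE_CLASS_COLORS$DEFAULT
}

#' Extract a module submap
#'
#' Builds a standalone map document for one module of a master map:
#' member species, the entities behind them, their aliases, and the
#' reactions whose reactants and products all belong to the module.
#' The master layout is kept (module maps in practice get their own
#' simplified layout; for synthetic fixtures the subset layout serves).
#'
#' @param doc Master [map_document()].
#' @param module_name Name of a module of `doc`.
#' @return A [map_document()] for the module.
#' @export
derive_submap <- function(doc, module_name) {
  mod <- doc$modules[[module_name]]
  if (is.null(mod)) stop("unknown module: ", module_name)
  keep_sp <- mod$member_species
  eids <- unique(unlist(lapply(doc$species[keep_sp], function(sp)
    vapply(sp$components, `[[`, character(1), "entity_id"))))
  keep_rx <- Filter(function(rx) {
    core <- vapply(rx$participants, `[[`, character(1), "species_id")
    all(core %in% keep_sp)
  }, doc$reactions)
  keep_al <- Filter(function(al) al$species_id %in% keep_sp, doc$aliases)
  map_document(
    paste0(doc$name, "_", module_name),
    entities = unname(doc$entities[eids]),
    species = unname(doc$species[keep_sp]),
    aliases = unname(keep_al),
    reactions = unname(keep_rx)
  )
}
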