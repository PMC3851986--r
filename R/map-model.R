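#' @title Typed model of a CellDesigner map
#' @description Constructors and validators for the in-memory map model:
#'   entities, species states, aliases, reactions, modules and the
#'   enclosing map document. All containers are plain lists carrying S3
#'   classes; collections are named lists keyed by id.
#' @name map-model
NULL

ENTITY_CLASSES <- c(
  "PROTEIN", "GENE", "RNA", "ANTISENSE_RNA",
  "SIMPLE_MOLECULE", "ION", "PHENOTYPE", "DRUG",
  "UNKNOWN", "DEGRADED", "COMPLEX"
)

## the four classes CellDesigner stores behind reference elements
REFERENCED_CLASSES <- c("PROTEIN", "GENE", "RNA", "ANTISENSE_RNA")

REACTION_ROLES <- c("REACTANT", "PRODUCT", "MODIFIER")

#' Create a biological entity
#'
#' An entity is one named biological object (a protein, gene, RNA,
#' antisense RNA, small molecule, ...) independent of modification state,
#' compartment or drawing position.
#'
#' @param entity_id Opaque unique id string.
#' @param entity_class One of the supported CellDesigner entity classes
#'   (`PROTEIN`, `GENE`, `RNA`, `ANTISENSE_RNA`, `SIMPLE_MOLECULE`, `ION`,
#'   `PHENOTYPE`, `DRUG`, `UNKNOWN`, `DEGRADED`, `COMPLEX`).
#' @param display_name Human-readable name shown on the map and used in
#'   canonical species names. Must not contain the reserved grammar
#'   characters `@`, `|`, `:`.
#' @param annotation_text Raw annotation text (may be empty; structured
#'   sections are parsed by [parse_annotation()]).
#' @return An object of class `pa_entity`.
#' @export
entity <- function(entity_id, entity_class, display_name = "",
                   annotation_text = "") {
  stopifnot(is.character(entity_id), nchar(entity_id) > 0)
  if (!entity_class %in% ENTITY_CLASSES) {
    stop("unknown entity class: ", entity_class)
  }
  if (entity_class %in% c(REFERENCED_CLASSES) && !nzchar(display_name)) {
    stop("display_name required for class ", entity_class)
  }
  structure(
    list(
      entity_id = entity_id,
      entity_class = entity_class,
      display_name = display_name,
      annotation_text = annotation_text
    ),
    class = "pa_entity"
  )
}

#' Create a modification state
#'
#' One post-translational (or analogous) modification on a component of a
#' species: an optional residue label such as `"Thr167"` plus a state
#' label such as `"pho"`. The residue position, when the label embeds an
#' integer, is extracted as the first maximal digit run.
#'
#' @param state_label State label, e.g. `"pho"` or `"Pho"`. Case is
#'   preserved exactly as given.
#' @param residue_label Optional residue label, e.g. `"Thr167"`.
#' @return An object of class `pa_modification`.
#' @export
modification <- function(state_label, residue_label = NA_character_) {
  stopifnot(is.character(state_label), nzchar(state_label))
  pos <- residue_position(residue_label)
  structure(
    list(
      residue_label = residue_label,
      residue_position = pos,
      state_label = state_label
    ),
    class = "pa_modification"
  )
}

## first maximal digit run in a residue label, NA when none
residue_position <- function(residue_label) {
  if (is.na(residue_label) || !nzchar(residue_label)) return(NA_integer_)
  m <- regmatches(residue_label, regexpr("[0-9]+", residue_label))
  if (length(m) == 0) return(NA_integer_)
  as.integer(m)
}

#' Create one component of a species state
#'
#' @param entity_id Id of the entity this component instantiates.
#' @param name Display name of that entity (kept alongside the id so that
#'   naming works on detached states).
#' @param modifications List of [modification()] objects.
#' @return An object of class `pa_component`.
#' @export
species_component <- function(entity_id, name, modifications = list()) {
  stopifnot(is.character(name))
  structure(
    list(entity_id = entity_id, name = name,
         modifications = sort_modifications(modifications)),
    class = "pa_component"
  )
}

## deterministic modification order: residue position, then lexical
sort_modifications <- function(mods) {
  if (length(mods) < 2) return(mods)
  pos <- vapply(mods, function(m) {
    if (is.na(m$residue_position)) Inf else as.numeric(m$residue_position)
  }, numeric(1))
  key <- vapply(mods, function(m) {
    paste0(ifelse(is.na(m$residue_label), "", m$residue_label), "_",
           m$state_label)
  }, character(1))
  mods[order(pos, key)]
}

#' Create a species state
#'
#' A species state is one biological entity (or an ordered assembly of
#' entities, for a complex) in a specific modification state and
#' compartment. It is the unit that the canonical naming grammar
#' serializes and the unit aliases point to.
#'
#' @param species_id Opaque unique id string.
#' @param components List of [species_component()] objects; component
#'   order is meaningful (it is preserved into canonical names). A
#'   non-complex state has exactly one component.
#' @param compartment Compartment name, or `NA` when the species has no
#'   explicit compartment (the canonical name then omits the `@` part).
#' @return An object of class `pa_species_state`.
#' @export
species_state <- function(species_id, components,
                          compartment = NA_character_) {
  if (length(components) < 1) stop("species state needs >= 1 component")
  structure(
    list(species_id = species_id, components = components,
         compartment = compartment),
    class = "pa_species_state"
  )
}

#' Create a map alias
#'
#' One drawn occurrence of a species state on the map canvas. Bounding
#' boxes are in pixels of the most-detailed zoom view, origin top-left,
#' y increasing downward (the CellDesigner canvas convention).
#'
#' @param alias_id Opaque unique id string.
#' @param species_id Id of the species state drawn.
#' @param bbox Numeric `c(x, y, width, height)`, width and height > 0.
#' @return An object of class `pa_alias`.
#' @export
map_alias <- function(alias_id, species_id, bbox) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= 0 || bbox[4] <= 0) {
    stop("bbox must be c(x, y, w, h) with w, h > 0")
  }
  names(bbox) <- c("x", "y", "w", "h")
  structure(
    list(alias_id = alias_id, species_id = species_id, bbox = bbox),
    class = "pa_alias"
  )
}

#' Create a reaction
#'
#' @param reaction_id Unique id string.
#' @param participants List of participant records, each built with
#'   [reaction_participant()]. At least one reactant or product is
#'   required.
#' @return An object of class `pa_reaction`.
#' @export
map_reaction <- function(reaction_id, participants) {
  roles <- vapply(participants, `[[`, character(1), "role")
  if (!all(roles %in% REACTION_ROLES)) {
    stop("roles must be one of ", paste(REACTION_ROLES, collapse = ", "))
  }
  if (!any(roles %in% c("REACTANT", "PRODUCT"))) {
    stop("reaction needs at least one reactant or product")
  }
  # canonical participant order: reactants, products, modifiers (stable
  # within role) — the order the file dialect serializes
  ord <- order(match(roles, REACTION_ROLES))
  structure(
    list(reaction_id = reaction_id, participants = participants[ord]),
    class = "pa_reaction"
  )
}

#' Create a reaction participant
#'
#' @param species_id Id of the participating species state.
#' @param role `"REACTANT"`, `"PRODUCT"` or `"MODIFIER"`.
#' @param modifier_subtype Optional subtype for modifiers, e.g.
#'   `"CATALYSIS"` or `"INHIBITION"`.
#' @return A participant record (plain list).
#' @export
reaction_participant <- function(species_id, role,
                                 modifier_subtype = NA_character_) {
  stopifnot(role %in% REACTION_ROLES)
  list(species_id = species_id, role = role,
       modifier_subtype = modifier_subtype)
}

#' Create a module definition
#'
#' A module is a functional submap of the master map. Membership is
#' recorded as species ids of the master map; the module may carry its
#' own simplified layout as a separate map document.
#'
#' @param module_name Module name.
#' @param member_species Character vector of member species ids.
#' @param submap Optional [map_document()] holding the module's own
#'   layout.
#' @return An object of class `pa_module`.
#' @export
module_def <- function(module_name, member_species = character(),
                       submap = NULL) {
  structure(
    list(module_name = module_name,
         member_species = as.character(member_species),
         submap = submap),
    class = "pa_module"
  )
}

#' Create a map document
#'
#' The complete typed model of one CellDesigner map: entities, species
#' states, aliases, reactions, modules and a content digest of the
#' source file.
#'
#' @param name Map name.
#' @param entities,species,aliases,reactions Lists of the respective
#'   objects; they are re-keyed by id internally.
#' @param modules Named list of [module_def()] objects; when `NULL`
#'   (default) module membership is derived from the `Maps_Modules`
#'   sections of the entity annotations, as [parse_map()] does.
#' @param source_digest Content hash of the source XML (filled by
#'   [parse_map()]; `NA` for documents built in code).
#' @return An object of class `pa_map`, validated for referential
#'   closure and id uniqueness.
#' @export
map_document <- function(name, entities = list(), species = list(),
                         aliases = list(), reactions = list(),
                         modules = NULL, source_digest = NA_character_) {
  entities <- key_by(entities, "entity_id")
  species <- key_by(species, "species_id")
  if (is.null(modules)) modules <- derive_modules(entities, species)
  doc <- structure(
    list(
      name = name,
      entities = entities,
      species = species,
      aliases = key_by(aliases, "alias_id"),
      reactions = key_by(reactions, "reaction_id"),
      modules = key_by(modules, "module_name"),
      source_digest = source_digest
    ),
    class = "pa_map"
  )
  validate_map(doc)
  doc
}

key_by <- function(xs, field) {
  if (length(xs) == 0) return(structure(list(), names = character()))
  ids <- vapply(xs, `[[`, character(1), field)
  if (anyDuplicated(ids)) {
    stop("duplicate ", field, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(xs) <- ids
  xs
}

#' Validate a map document
#'
#' Checks id uniqueness and referential closure: every component's
#' entity id, every alias's species id, every reaction participant's
#' species id and every module member must resolve within the document.
#'
#' @param doc A `pa_map` object.
#' @return `doc`, invisibly; stops with an integrity error listing the
#'   dangling ids otherwise.
#' @export
validate_map <- function(doc) {
  dangling <- character()
  eids <- names(doc$entities)
  sids <- names(doc$species)
  for (sp in doc$species) {
    for (cmp in sp$components) {
      if (!cmp$entity_id %in% eids) {
        dangling <- c(dangling, paste0(sp$species_id, " -> entity ",
                                       cmp$entity_id))
      }
    }
  }
  for (al in doc$aliases) {
    if (!al$species_id %in% sids) {
      dangling <- c(dangling, paste0(al$alias_id, " -> species ",
                                     al$species_id))
    }
  }
  for (rx in doc$reactions) {
    for (p in rx$participants) {
      if (!p$species_id %in% sids) {
        dangling <- c(dangling, paste0(rx$reaction_id, " -> species ",
                                       p$species_id))
      }
    }
  }
  for (mod in doc$modules) {
    bad <- setdiff(mod$member_species, sids)
    if (length(bad)) {
      dangling <- c(dangling, paste0("module ", mod$module_name,
                                     " -> species ",
                                     paste(bad, collapse = "+")))
    }
  }
  if (length(dangling)) {
    stop("map integrity error; dangling references:\n  ",
         paste(dangling, collapse = "\n  "))
  }
  invisible(doc)
}

#' @export
print.pa_map <- function(x, ...) {
  cat("<pathway map> ", x$name, "\n", sep = "")
  cat("  entities:  ", length(x$entities), "\n", sep = "")
  cat("  species:   ", length(x$species), "\n", sep = "")
  cat("  aliases:   ", length(x$aliases), "\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  cat("  modules:   ", length(x$modules), "\n", sep = "")
  invisible(x)
}

## canonical form used for structural equality: collections sorted by id,
## submaps and digests dropped, modification order already deterministic
normalize_map <- function(doc) {
  ord <- function(xs) xs[order(names(xs))]
  mods <- lapply(ord(doc$modules), function(m) {
    list(module_name = m$module_name,
         member_species = sort(m$member_species))
  })
  list(
    name = doc$name,
    entities = ord(doc$entities),
    species = ord(doc$species),
    aliases = ord(doc$aliases),
    reactions = ord(doc$reactions),
    modules = mods
  )
}

#' Structural equality of two map documents
#'
#' Compares two maps up to collection ordering, ignoring source digests
#' and module submap layouts.
#'
#' @param a,b `pa_map` objects.
#' @return `TRUE` or `FALSE`.
#' @export
map_equal <- function(a, b) {
  identical(normalize_map(a), normalize_map(b))
}

#' Group entities by class
#'
#' Produces the grouping behind the atlas selection panel: an ordered
#' mapping from entity class to the display names of entities of that
#' class. Every entity appears in exactly one group; classes follow a
#' fixed panel order and empty classes are dropped.
#'
#' @param doc A `pa_map` object.
#' @return Named list, class -> character vector of entity display names
#'   (sorted; each entity listed once even when drawn as several
#'   aliases).
#' @export
group_entities_by_class <- function(doc) {
  out <- list()
  for (cl in ENTITY_CLASSES) {
    nm <- vapply(
      Filter(function(e) e$entity_class == cl, doc$entities),
      `[[`, character(1), "display_name"
    )
    if (length(nm)) out[[cl]] <- sort(unname(nm))
  }
  out
}

## md5 content hash of a character scalar or raw vector; used for source
## digests and post change detection (no digest package dependency)
content_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  if (is.raw(x)) {
    writeBin(x, tf)
  } else {
    con <- file(tf, open = "wb")
    writeBin(charToRaw(enc2utf8(paste(x, collapse = "\n"))), con)
    close(con)
  }
  unname(tools::md5sum(tf))
}
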