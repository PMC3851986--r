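#' @title CellDesigner XML input/output
#' @description Reads CellDesigner map files (SBML Level 2 carrying the
#'   CellDesigner extension namespace, 4.x dialect with `speciesAlias` /
#'   `complexSpeciesAlias` layout elements) into the typed map model,
#'   and writes model documents back out in the same dialect for
#'   fixtures and round-trip testing. Other dialects are rejected
#'   explicitly rather than part-parsed.
#' @name celldesigner-io
NULL

CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"
SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

## class -> (list element, entry element, reference element) in the
## CellDesigner extension
CD_REFCLASS <- list(
  PROTEIN = c("listOfProteins", "protein", "proteinReference"),
  GENE = c("listOfGenes", "gene", "geneReference"),
  RNA = c("listOfRNAs", "RNA", "rnaReference"),
  ANTISENSE_RNA = c("listOfAntisenseRNAs", "AntisenseRNA",
                    "antisensernaReference")
)

## deterministic entity id for classes the dialect identifies by name
name_based_entity_id <- function(entity_class, name) {
  paste0("e_", entity_class, "_", gsub("[^A-Za-z0-9]", "_", name))
}

# =====================================================================
# parsing

#' Parse a CellDesigner map file
#'
#' @param xml Path to a CellDesigner XML file, an XML string, or a raw
#'   vector of XML bytes.
#' @return A [map_document()] with all entities, species states
#'   (including complexes), aliases, compartments, modification
#'   residues, reactions with roles, and modules derived from
#'   `Maps_Modules` annotation sections. Entities without annotations
#'   get empty `annotation_text`.
#' @details Errors are specific: malformed XML raises a parse error
#'   naming the offending line; a file without the CellDesigner
#'   extension namespace (or with a pre-4.x model version) raises an
#'   unsupported-dialect error; unresolvable internal references raise
#'   an integrity error listing the dangling ids.
#' @export
parse_map <- function(xml) {
  x <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  raw_text <- as.character(x)
  nsdefs <- xml2::xml_ns(x)
  s_uri <- as.character(nsdefs[grepl("^http://www\\.sbml\\.org/sbml/",
                                     nsdefs)])
  if (length(s_uri) == 0) stop("unsupported dialect: not an SBML document")
  cd_uri <- as.character(nsdefs[grepl("celldesigner", nsdefs)])
  if (length(cd_uri) == 0) {
    stop("unsupported dialect: missing CellDesigner extension namespace")
  }
  ns <- c(s = s_uri[1], cd = cd_uri[1])
  model <- xml2::xml_find_first(x, "./s:model", ns)
  if (inherits(model, "xml_missing")) {
    stop("unsupported dialect: no <model> element")
  }
  ext <- xml2::xml_find_first(model, "./s:annotation/cd:extension", ns)
  if (inherits(ext, "xml_missing")) {
    stop("unsupported dialect: model carries no CellDesigner extension")
  }
  mv <- xml2::xml_find_first(ext, "./cd:modelVersion", ns)
  if (!inherits(mv, "xml_missing") &&
      !grepl("^4", xml2::xml_text(mv))) {
    stop("unsupported dialect: CellDesigner model version ",
         xml2::xml_text(mv), " (only 4.x is supported)")
  }

  comp_names <- parse_compartments(model, ns)
  refs <- parse_reference_entities(ext, ns)
  entities <- refs$entities
  residues <- refs$residues    # residue id -> label (or NA)
  included <- parse_included_species(ext, ns, residues)

  species <- list()
  for (sp in xml2::xml_find_all(model,
                                "./s:listOfSpecies/s:species", ns)) {
    sid <- xml2::xml_attr(sp, "id")
    comp_attr <- xml2::xml_attr(sp, "compartment")
    compartment <- if (is.na(comp_attr) || comp_attr == "default") {
      NA_character_
    } else {
      comp_names[[comp_attr]] %||% comp_attr
    }
    notes <- species_notes_text(sp, ns)
    ident <- xml2::xml_find_first(
      sp, "./s:annotation/cd:extension/cd:speciesIdentity", ns)
    if (inherits(ident, "xml_missing")) {
      stop("unsupported dialect: species ", sid,
           " carries no CellDesigner speciesIdentity")
    }
    cls <- xml2::xml_text(xml2::xml_find_first(ident, "./cd:class", ns))
    if (identical(cls, "COMPLEX")) {
      members <- Filter(function(m) m$complex == sid, included)
      if (length(members) == 0) {
        stop("map integrity error; dangling references:\n  complex ",
             sid, " has no included species")
      }
      for (m in members) {
        entities <- ensure_entity(entities, m$entity, m$notes)
      }
      skels <- lapply(members, `[[`, "component")
    } else {
      got <- parse_identity_component(ident, ns, residues, sid)
      skels <- list(got$component)
      entities <- ensure_entity(entities, got$entity, notes)
    }
    comps <- lapply(skels, function(sk) species_component(
      sk$entity_id, entities[[sk$entity_id]]$display_name, sk$mods))
    species[[length(species) + 1]] <- species_state(
      sid, comps, compartment = compartment)
  }

  aliases <- parse_aliases(ext, ns, included)
  reactions <- parse_reactions(model, ns)

  map_document(
    name = xml2::xml_attr(model, "name") %||NA% xml2::xml_attr(model, "id"),
    entities = finalize_entities(entities),
    species = species,
    aliases = aliases,
    reactions = reactions,
    source_digest = content_digest(raw_text)
  )
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a

parse_compartments <- function(model, ns) {
  out <- list()
  for (cp in xml2::xml_find_all(
    model, "./s:listOfCompartments/s:compartment", ns)) {
    id <- xml2::xml_attr(cp, "id")
    out[[id]] <- xml2::xml_attr(cp, "name") %||NA% id
  }
  out
}

## reference entities: proteins, genes, RNAs, antisense RNAs.
## returns entity skeletons keyed by id plus the residue id -> label map
parse_reference_entities <- function(ext, ns) {
  entities <- list()
  residues <- list()
  for (cls in names(CD_REFCLASS)) {
    el <- CD_REFCLASS[[cls]]
    xp <- sprintf("./cd:%s/cd:%s", el[1], el[2])
    for (nd in xml2::xml_find_all(ext, xp, ns)) {
      id <- xml2::xml_attr(nd, "id")
      notes_nd <- xml2::xml_find_first(nd, "./cd:notes", ns)
      ann <- if (inherits(notes_nd, "xml_missing")) "" else
        xml2::xml_text(notes_nd)
      entities[[id]] <- entity(id, cls, xml2::xml_attr(nd, "name"), ann)
      for (mr in xml2::xml_find_all(
        nd, "./cd:listOfModificationResidues/cd:modificationResidue",
        ns)) {
        residues[[xml2::xml_attr(mr, "id")]] <-
          xml2::xml_attr(mr, "name")  # may be NA: unnamed residue
      }
    }
  }
  list(entities = entities, residues = residues)
}

parse_state_modifications <- function(node, ns, residues, where) {
  mods <- list()
  for (md in xml2::xml_find_all(
    node, "./cd:state/cd:listOfModifications/cd:modification", ns)) {
    rid <- xml2::xml_attr(md, "residue")
    if (!is.na(rid) && !rid %in% names(residues)) {
      stop("map integrity error; dangling references:\n  ", where,
           " -> modification residue ", rid)
    }
    lab <- if (is.na(rid)) NA_character_ else residues[[rid]]
    mods[[length(mods) + 1]] <- modification(
      xml2::xml_attr(md, "state"), residue_label = lab)
  }
  mods
}

## one identity element -> component skeleton + entity skeleton
parse_identity_component <- function(ident, ns, residues, where) {
  cls <- xml2::xml_text(xml2::xml_find_first(ident, "./cd:class", ns))
  mods <- parse_state_modifications(ident, ns, residues, where)
  if (cls %in% names(CD_REFCLASS)) {
    ref_el <- CD_REFCLASS[[cls]][3]
    ref <- xml2::xml_find_first(ident, sprintf("./cd:%s", ref_el), ns)
    if (inherits(ref, "xml_missing")) {
      stop("unsupported dialect: ", where, " identity of class ", cls,
           " lacks a ", ref_el)
    }
    eid <- xml2::xml_text(ref)
    list(entity = list(entity_id = eid, entity_class = cls, name = NULL),
         component = list(entity_id = eid, mods = mods))
  } else {
    nm <- xml2::xml_text(xml2::xml_find_first(ident, "./cd:name", ns))
    if (is.na(nm) || !nzchar(nm)) {
      stop("unsupported dialect: ", where, " identity of class ", cls,
           " lacks a name")
    }
    eid <- name_based_entity_id(cls, nm)
    list(entity = list(entity_id = eid, entity_class = cls, name = nm),
         component = list(entity_id = eid, mods = mods, name = nm))
  }
}

parse_included_species <- function(ext, ns, residues) {
  out <- list()
  for (nd in xml2::xml_find_all(
    ext, "./cd:listOfIncludedSpecies/cd:species", ns)) {
    id <- xml2::xml_attr(nd, "id")
    ann <- xml2::xml_find_first(nd, "./cd:annotation", ns)
    cplx <- xml2::xml_text(
      xml2::xml_find_first(ann, "./cd:complexSpecies", ns))
    ident <- xml2::xml_find_first(ann, "./cd:speciesIdentity", ns)
    got <- parse_identity_component(ident, ns, residues, id)
    notes_nd <- xml2::xml_find_first(nd, "./cd:notes", ns)
    notes <- if (inherits(notes_nd, "xml_missing")) "" else
      xml2::xml_text(notes_nd)
    out[[length(out) + 1]] <- list(
      id = id, complex = cplx, entity = got$entity,
      component = got$component, notes = notes)
  }
  out
}

## register/enrich an entity skeleton; name-based entities pick up their
## annotation from the first species that instantiates them
ensure_entity <- function(entities, skel, notes) {
  eid <- skel$entity_id
  if (is.null(skel$name)) {  # referenced class: must pre-exist
    if (!eid %in% names(entities)) {
      stop("map integrity error; dangling references:\n  ",
           "species identity -> ", eid)
    }
    return(entities)
  }
  if (!eid %in% names(entities)) {
    entities[[eid]] <- entity(eid, skel$entity_class, skel$name, notes)
  } else if (!nzchar(entities[[eid]]$annotation_text) && nzchar(notes)) {
    entities[[eid]]$annotation_text <- notes
  }
  entities
}

finalize_entities <- function(entities) {
  lapply(entities, function(e) {
    if (is.na(e$annotation_text)) e$annotation_text <- ""
    e
  })
}

species_notes_text <- function(sp, ns) {
  # read the xhtml body element directly so that serializer indentation
  # around it never leaks into the annotation text
  body <- xml2::xml_find_first(sp, "./s:notes/*[local-name()='body']", ns)
  if (inherits(body, "xml_missing")) {
    body <- xml2::xml_find_first(sp, "./s:notes", ns)
  }
  if (inherits(body, "xml_missing")) "" else xml2::xml_text(body)
}

parse_aliases <- function(ext, ns, included) {
  inc_ids <- vapply(included, `[[`, character(1), "id")
  out <- list()
  for (xp in c("./cd:listOfSpeciesAliases/cd:speciesAlias",
               "./cd:listOfComplexSpeciesAliases/cd:complexSpeciesAlias")) {
    for (nd in xml2::xml_find_all(ext, xp, ns)) {
      aid <- xml2::xml_attr(nd, "id")
      sid <- xml2::xml_attr(nd, "species")
      if (sid %in% inc_ids) {
        # an alias of a species nested inside a complex: the dialect is
        # ambiguous about whether the inner species also exists free
        warning("alias ", aid, " points at included species ", sid,
                "; skipped", call. = FALSE)
        next
      }
      b <- xml2::xml_find_first(nd, "./cd:bounds", ns)
      out[[length(out) + 1]] <- map_alias(
        aid, sid,
        as.numeric(c(xml2::xml_attr(b, "x"), xml2::xml_attr(b, "y"),
                     xml2::xml_attr(b, "w"), xml2::xml_attr(b, "h"))))
    }
  }
  out
}

parse_reactions <- function(model, ns) {
  out <- list()
  for (rx in xml2::xml_find_all(model,
                                "./s:listOfReactions/s:reaction", ns)) {
    rid <- xml2::xml_attr(rx, "id")
    subtype <- list()
    for (md in xml2::xml_find_all(
      rx, "./s:annotation/cd:extension/cd:listOfModification/cd:modification",
      ns)) {
      subtype[[xml2::xml_attr(md, "modifiers")]] <-
        xml2::xml_attr(md, "type")
    }
    parts <- list()
    grab <- function(xp, role, elem) {
      for (sr in xml2::xml_find_all(rx, xp, ns)) {
        sid <- xml2::xml_attr(sr, "species")
        parts[[length(parts) + 1]] <<- reaction_participant(
          sid, role,
          if (role == "MODIFIER") subtype[[sid]] %||% NA_character_
          else NA_character_)
      }
    }
    grab("./s:listOfReactants/s:speciesReference", "REACTANT")
    grab("./s:listOfProducts/s:speciesReference", "PRODUCT")
    grab("./s:listOfModifiers/s:modifierSpeciesReference", "MODIFIER")
    out[[length(out) + 1]] <- map_reaction(rid, parts)
  }
  out
}

## modules are declared through Maps_Modules annotation sections: a
## species belongs to every module any of its component entities lists
derive_modules <- function(entities, species) {
  ent_mods <- lapply(entities, function(e)
    extract_module_membership(e$annotation_text))
  mod_names <- unique(unlist(ent_mods, use.names = FALSE))
  lapply(mod_names, function(mn) {
    member_ents <- names(ent_mods)[vapply(ent_mods, function(m)
      mn %in% m, logical(1))]
    members <- vapply(species, function(sp) {
      any(vapply(sp$components, function(c) c$entity_id %in% member_ents,
                 logical(1)))
    }, logical(1))
    module_def(mn, vapply(species[members], `[[`, character(1),
                          "species_id"))
  })
}

# =====================================================================
# writing

#' Write a map document as CellDesigner XML
#'
#' Inverse of [parse_map()] on documents the dialect can represent:
#' `parse_map(write_map(doc))` reproduces `doc` up to field ordering.
#' Validation runs before any output.
#'
#' @param doc A [map_document()].
#' @param file Optional path; when given the XML is also written there.
#' @return XML text (character scalar), invisibly when `file` is given.
#' @details Dialect limits, enforced as validation errors: modification
#'   residues attach to `PROTEIN` components only; entities of the
#'   name-identified classes (everything except protein / gene / RNA /
#'   antisense RNA) must use the canonical derived id and occur in at
#'   least one species; `COMPLEX`-class entities are implicit (a complex
#'   is written as its member components) and cannot be written.
#' @export
write_map <- function(doc, file = NULL) {
  validate_map(doc)
  validate_writable(doc)
  x <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:celldesigner" = CD_NS,
    level = "2", version = "4")
  model <- xml2::xml_add_child(x, "model", id = "model1", name = doc$name)
  ann <- xml2::xml_add_child(model, "annotation")
  ext <- xml2::xml_add_child(ann, "celldesigner:extension")
  xml2::xml_add_child(ext, "celldesigner:modelVersion", "4.0")

  write_included_species(ext, doc)
  write_alias_lists(ext, doc)
  residue_ids <- write_reference_entities(ext, doc)
  write_compartments(model, doc)
  write_species(model, doc, residue_ids)
  write_reactions(model, doc)

  txt <- as.character(x)
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

validate_writable <- function(doc) {
  for (e in doc$entities) {
    if (e$entity_class == "COMPLEX") {
      stop("validation error: COMPLEX entities are implicit in the ",
           "dialect and cannot be written (", e$entity_id, ")")
    }
    if (!e$entity_class %in% names(CD_REFCLASS)) {
      want <- name_based_entity_id(e$entity_class, e$display_name)
      if (e$entity_id != want) {
        stop("validation error: entity ", e$entity_id, " of class ",
             e$entity_class, " must use the name-derived id ", want)
      }
      seen <- any(vapply(doc$species, function(sp)
        any(vapply(sp$components, function(c)
          c$entity_id == e$entity_id, logical(1))), logical(1)))
      if (!seen) {
        stop("validation error: name-identified entity ", e$entity_id,
             " occurs in no species and would be lost")
      }
    }
  }
  for (sp in doc$species) {
    for (cmp in sp$components) {
      if (length(cmp$modifications) &&
          doc$entities[[cmp$entity_id]]$entity_class != "PROTEIN") {
        stop("validation error: modification states are writable on ",
             "PROTEIN components only (species ", sp$species_id, ")")
      }
    }
  }
  invisible(doc)
}

## residue-id table: per protein entity, one modificationResidue per
## distinct residue label used anywhere in the document; the label-less
## ("unnamed") residue is keyed "(none)"
residue_key <- function(m) {
  if (is.na(m$residue_label) || !nzchar(m$residue_label)) "(none)"
  else m$residue_label
}

collect_residues <- function(doc) {
  out <- list()
  for (sp in doc$species) {
    for (cmp in sp$components) {
      for (m in cmp$modifications) {
        out[[cmp$entity_id]] <- union(out[[cmp$entity_id]],
                                      residue_key(m))
      }
    }
  }
  lapply(out, function(keys) {
    keys <- sort(keys)
    ids <- paste0("mr", seq_along(keys))
    names(ids) <- keys
    ids
  })
}

write_reference_entities <- function(ext, doc) {
  residue_tab <- collect_residues(doc)
  for (cls in names(CD_REFCLASS)) {
    el <- CD_REFCLASS[[cls]]
    ents <- Filter(function(e) e$entity_class == cls, doc$entities)
    if (length(ents) == 0) next
    lst <- xml2::xml_add_child(ext, paste0("celldesigner:", el[1]))
    for (e in ents) {
      nd <- xml2::xml_add_child(lst, paste0("celldesigner:", el[2]),
                                id = e$entity_id, name = e$display_name)
      if (nzchar(e$annotation_text)) {
        nn <- xml2::xml_add_child(nd, "celldesigner:notes")
        xml2::xml_text(nn) <- e$annotation_text
      }
      resids <- residue_tab[[e$entity_id]]
      if (length(resids)) {
        rl <- xml2::xml_add_child(
          nd, "celldesigner:listOfModificationResidues")
        for (key in names(resids)) {
          mr <- xml2::xml_add_child(rl, "celldesigner:modificationResidue",
                                    id = paste0(e$entity_id, "_",
                                                resids[[key]]))
          if (key != "(none)") xml2::xml_attr(mr, "name") <- key
        }
      }
    }
  }
  residue_tab
}

write_compartments <- function(model, doc) {
  comps <- unique(stats::na.omit(vapply(doc$species, `[[`, character(1),
                                        "compartment")))
  lst <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lst, "compartment", id = "default", size = "1")
  for (cn in sort(comps)) {
    xml2::xml_add_child(lst, "compartment", id = cn, name = cn,
                        size = "1")
  }
}

is_complex_state <- function(sp) length(sp$components) > 1

## species display name used in the file (informational for complexes)
species_display_name <- function(sp, doc) {
  paste(vapply(sp$components, function(c)
    doc$entities[[c$entity_id]]$display_name, character(1)),
    collapse = ":")
}

write_identity <- function(parent, doc, cmp, residue_tab) {
  e <- doc$entities[[cmp$entity_id]]
  ident <- xml2::xml_add_child(parent, "celldesigner:speciesIdentity")
  xml2::xml_add_child(ident, "celldesigner:class", e$entity_class)
  if (e$entity_class %in% names(CD_REFCLASS)) {
    xml2::xml_add_child(
      ident, paste0("celldesigner:", CD_REFCLASS[[e$entity_class]][3]),
      e$entity_id)
  } else {
    xml2::xml_add_child(ident, "celldesigner:name", e$display_name)
  }
  if (length(cmp$modifications)) {
    st <- xml2::xml_add_child(ident, "celldesigner:state")
    lm <- xml2::xml_add_child(st, "celldesigner:listOfModifications")
    for (m in cmp$modifications) {
      rid <- paste0(cmp$entity_id, "_",
                    residue_tab[[cmp$entity_id]][[residue_key(m)]])
      xml2::xml_add_child(lm, "celldesigner:modification",
                          residue = rid, state = m$state_label)
    }
  }
}

write_included_species <- function(ext, doc) {
  complexes <- Filter(is_complex_state, doc$species)
  if (length(complexes) == 0) return()
  residue_tab <- collect_residues(doc)
  # which name-based entities pick their annotation up from an included
  # species (no free species carries them)
  free_ents <- unlist(lapply(Filter(Negate(is_complex_state), doc$species),
                             function(sp) sp$components[[1]]$entity_id))
  lst <- xml2::xml_add_child(ext, "celldesigner:listOfIncludedSpecies")
  k <- 0
  noted <- character()
  for (sp in complexes) {
    for (cmp in sp$components) {
      k <- k + 1
      e <- doc$entities[[cmp$entity_id]]
      nd <- xml2::xml_add_child(lst, "celldesigner:species",
                                id = paste0("is", k),
                                name = e$display_name)
      if (!e$entity_class %in% names(CD_REFCLASS) &&
          !e$entity_id %in% free_ents &&
          !e$entity_id %in% noted && nzchar(e$annotation_text)) {
        nn <- xml2::xml_add_child(nd, "celldesigner:notes")
        xml2::xml_text(nn) <- e$annotation_text
        noted <- c(noted, e$entity_id)
      }
      ann <- xml2::xml_add_child(nd, "celldesigner:annotation")
      xml2::xml_add_child(ann, "celldesigner:complexSpecies",
                          sp$species_id)
      write_identity(ann, doc, cmp, residue_tab)
    }
  }
}

write_alias_lists <- function(ext, doc) {
  is_cplx <- vapply(doc$aliases, function(al)
    is_complex_state(doc$species[[al$species_id]]), logical(1))
  clx <- xml2::xml_add_child(ext,
                             "celldesigner:listOfComplexSpeciesAliases")
  for (al in doc$aliases[is_cplx]) write_alias(clx, al, TRUE)
  slx <- xml2::xml_add_child(ext, "celldesigner:listOfSpeciesAliases")
  for (al in doc$aliases[!is_cplx]) write_alias(slx, al, FALSE)
}

write_alias <- function(lst, al, complex) {
  nd <- xml2::xml_add_child(
    lst,
    if (complex) "celldesigner:complexSpeciesAlias"
    else "celldesigner:speciesAlias",
    id = al$alias_id, species = al$species_id)
  xml2::xml_add_child(nd, "celldesigner:bounds",
                      x = format(al$bbox[["x"]]), y = format(al$bbox[["y"]]),
                      w = format(al$bbox[["w"]]), h = format(al$bbox[["h"]]))
}

write_species <- function(model, doc, residue_tab) {
  lst <- xml2::xml_add_child(model, "listOfSpecies")
  noted_name_based <- character()
  for (sp in doc$species) {
    comp_attr <- if (is.na(sp$compartment)) "default" else sp$compartment
    nd <- xml2::xml_add_child(lst, "species", id = sp$species_id,
                              name = species_display_name(sp, doc),
                              compartment = comp_attr)
    if (!is_complex_state(sp)) {
      e <- doc$entities[[sp$components[[1]]$entity_id]]
      # name-identified entities carry their annotation on their first
      # free species; referenced classes carry it on the reference element
      if (!e$entity_class %in% names(CD_REFCLASS) &&
          !e$entity_id %in% noted_name_based && nzchar(e$annotation_text)) {
        nn <- xml2::xml_add_child(nd, "notes")
        body <- xml2::xml_add_child(nn, "body", xmlns = XHTML_NS)
        xml2::xml_text(body) <- e$annotation_text
        noted_name_based <- c(noted_name_based, e$entity_id)
      }
    }
    ann <- xml2::xml_add_child(nd, "annotation")
    ext <- xml2::xml_add_child(ann, "celldesigner:extension")
    if (is_complex_state(sp)) {
      ident <- xml2::xml_add_child(ext, "celldesigner:speciesIdentity")
      xml2::xml_add_child(ident, "celldesigner:class", "COMPLEX")
      xml2::xml_add_child(ident, "celldesigner:name",
                          species_display_name(sp, doc))
    } else {
      write_identity(ext, doc, sp$components[[1]], residue_tab)
    }
  }
}

write_reactions <- function(model, doc) {
  if (length(doc$reactions) == 0) return()
  lst <- xml2::xml_add_child(model, "listOfReactions")
  for (rx in doc$reactions) {
    nd <- xml2::xml_add_child(lst, "reaction", id = rx$reaction_id,
                              reversible = "false")
    roles <- vapply(rx$participants, `[[`, character(1), "role")
    mods <- rx$participants[roles == "MODIFIER"]
    typed <- Filter(function(p) !is.na(p$modifier_subtype), mods)
    ann <- xml2::xml_add_child(nd, "annotation")
    ext <- xml2::xml_add_child(ann, "celldesigner:extension")
    xml2::xml_add_child(ext, "celldesigner:reactionType",
                        "STATE_TRANSITION")
    if (length(typed)) {
      lm <- xml2::xml_add_child(ext, "celldesigner:listOfModification")
      for (p in typed) {
        xml2::xml_add_child(lm, "celldesigner:modification",
                            modifiers = p$species_id,
                            type = p$modifier_subtype)
      }
    }
    add_refs <- function(role, list_el, ref_el) {
      ps <- rx$participants[roles == role]
      if (length(ps) == 0) return()
      rl <- xml2::xml_add_child(nd, list_el)
      for (p in ps) {
        xml2::xml_add_child(rl, ref_el, species = p$species_id)
      }
    }
    add_refs("REACTANT", "listOfReactants", "speciesReference")
    add_refs("PRODUCT", "listOfProducts", "speciesReference")
    add_refs("MODIFIER", "listOfModifiers", "modifierSpeciesReference")
  }
}
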