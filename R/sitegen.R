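#' @title Static atlas bundle generation
#' @description Assembles the deliverable a map manager publishes: a
#'   self-contained directory of HTML, JSON and PNG files openable from
#'   local disk. The master page carries the tiled viewer, a selection
#'   panel grouping entities by class, substring search and per-alias
#'   callouts; each module submap gets its own page whose panel lists
#'   only the module's members; annotation posts are rendered as static
#'   pages and cross-linked from the callouts.
#' @name sitegen
NULL

html_page <- function(title, body, css = "assets/style.css",
                      script = NULL, data_json = NULL) {
  head <- c(
    "<!DOCTYPE html>", "<html>", "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", escape_html(title)),
    if (!is.null(css)) sprintf('<link rel="stylesheet" href="%s"/>', css),
    "</head>", "<body>")
  tail <- c(
    if (!is.null(data_json)) sprintf(
      '<script type="application/json" id="pa-data">%s</script>',
      data_json),
    if (!is.null(script)) sprintf('<script src="%s"></script>', script),
    "</body>", "</html>")
  paste(c(head, body, tail), collapse = "\n")
}

# ---------------------------------------------------------------------
# search

#' Build the substring-search index of a map
#'
#' Indexes every entity under its display name, the canonical names of
#' all its species states, and the words of its annotation. Queries run
#' as case-insensitive substring matches against these raw strings.
#'
#' @param doc A [map_document()].
#' @return An object of class `pa_search_index`.
#' @export
build_search_index <- function(doc) {
  entries <- lapply(doc$entities, function(e) {
    forms <- vapply(species_of_entity(e$entity_id, doc), format_name,
                    character(1))
    list(entity_id = e$entity_id, name = e$display_name,
         text = tolower(paste(c(e$display_name, forms,
                                e$annotation_text), collapse = " ")))
  })
  structure(list(entries = unname(entries)), class = "pa_search_index")
}

#' Query the search index
#'
#' Case-insensitive substring search over entity names, canonical
#' species names and annotation text. Results are ordered by match
#' position (earlier is better), then entity name. The empty query
#' matches nothing.
#'
#' @param index A [build_search_index()] result.
#' @param query Query string.
#' @return Data frame with columns `entity_id`, `name`, `position`.
#' @export
search_entities <- function(index, query) {
  empty <- data.frame(entity_id = character(), name = character(),
                      position = integer(), stringsAsFactors = FALSE)
  if (!nzchar(query)) return(empty)
  q <- tolower(query)
  hits <- Filter(Negate(is.null), lapply(index$entries, function(en) {
    p <- regexpr(q, en$text, fixed = TRUE)
    if (p < 0) NULL else
      data.frame(entity_id = en$entity_id, name = en$name,
                 position = as.integer(p), stringsAsFactors = FALSE)
  }))
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  out[order(out$position, out$name), , drop = FALSE]
}

# ---------------------------------------------------------------------
# callouts

short_description <- function(e) {
  ann <- parse_annotation(e$annotation_text)
  txt <- if (ann$sectioned) {
    # last free-text line of References, else the first section body
    body <- annotation_section(ann, "References") %||%
      ann$sections[[1]]$body
    ln <- Filter(nzchar, trimws(split_lines(body)))
    if (length(ln)) ln[[length(ln)]] else ""
  } else {
    trimws(e$annotation_text)
  }
  if (nchar(txt) > 200) paste0(substr(txt, 1, 197), "...") else txt
}

## one callout record per alias of `doc`; hrefs are relative to the page
## the callout lives on (rel = path prefix to bundle root)
build_callouts <- function(doc, registry, rel = "") {
  lapply(doc$aliases, function(al) {
    sp <- doc$species[[al$species_id]]
    e1 <- doc$entities[[sp$components[[1]]$entity_id]]
    in_modules <- names(Filter(function(m)
      al$species_id %in% m$member_species, doc$modules))
    mod_links <- vapply(in_modules, function(mn) sprintf(
      '<a href="%smodules/%s.html">%s</a>', rel, mn, escape_html(mn)),
      character(1), USE.NAMES = FALSE)
    ident <- annotation_section(parse_annotation(e1$annotation_text),
                                "Identifiers")
    list(
      alias_id = al$alias_id,
      species_id = al$species_id,
      name = format_name(sp),
      anchor = unname(c(al$bbox[["x"]] + al$bbox[["w"]] / 2,
                        al$bbox[["y"]] + al$bbox[["h"]] / 2)),
      html = paste0(
        sprintf('<h4>%s</h4>', escape_html(format_name(sp))),
        sprintf('<p>%s</p>', escape_html(short_description(e1))),
        if (!is.null(ident)) sprintf(
          '<p class="pa-ids">%s</p>', expand_tags(ident, registry)),
        if (length(mod_links)) sprintf(
          '<p>Modules: %s</p>', paste(mod_links, collapse = " ")),
        sprintf('<p><a href="%sposts/entity_%s.html">Annotation post</a></p>',
                rel, e1$entity_id))
    )
  })
}

# ---------------------------------------------------------------------
# pages

panel_html <- function(doc) {
  groups <- group_entities_by_class(doc)
  blocks <- vapply(names(groups), function(cl) {
    items <- vapply(groups[[cl]], function(nm) sprintf(
      '<li><a href="#entity=%s" class="pa-panel-entry">%s</a></li>',
      utils::URLencode(nm, reserved = TRUE), escape_html(nm)),
      character(1))
    sprintf('<h3>%s</h3>\n<ul class="pa-panel-group">\n%s\n</ul>',
            escape_html(gsub("_", " ", cl)),
            paste(items, collapse = "\n"))
  }, character(1))
  paste(blocks, collapse = "\n")
}

page_data_json <- function(doc, pyramid, callouts, index) {
  levels <- if (is.null(pyramid)) list() else
    lapply(pyramid$levels, function(l)
      l[c("level", "width", "height", "n_tiles_x", "n_tiles_y")])
  jsonlite::toJSON(list(
    map = doc$name,
    tile_edge = if (is.null(pyramid)) NULL else pyramid$tile_edge,
    levels = levels,
    markers = lapply(unname(callouts), function(co)
      list(alias = co$alias_id, species = co$species_id, name = co$name,
           anchor = co$anchor, callout = co$html)),
    search = if (is.null(index)) list() else index$entries
  ), auto_unbox = TRUE, null = "null")
}

#' Build the static atlas bundle
#'
#' @param master Master [map_document()].
#' @param modules Named list of module submaps (`pa_map` objects, keyed
#'   by module name); an entry may be `NULL`, in which case the submap
#'   is derived from the master with [derive_submap()]. Every module an
#'   entity is assigned to (via `Maps_Modules`) must appear here —
#'   offenders abort the build.
#' @param pyramid A validated [build_tile_pyramid()] for the master map,
#'   or `NULL` for a bundle without a tile layer.
#' @param config List of options: `mode` (`"simple"` or `"complete"`),
#'   `tile_edge`, `include_source_xml` (adds a download link for the
#'   source file; map-manager policy), `map_xml` (path to the source
#'   file, used when `include_source_xml`), `tags` (named character
#'   vector of extra tag templates).
#' @param out_dir Output directory; created, existing files
#'   overwritten.
#' @return An object of class `pa_site_bundle`: `dir`, `pages` (name ->
#'   relative path), `panel_index`, `search_index`, `callouts` (one
#'   record per alias per page) and `manifest` (all files written,
#'   relative paths).
#' @export
build_site <- function(master, modules = list(), pyramid = NULL,
                       config = list(), out_dir) {
  registry <- default_tag_registry(config$tags %||% character())
  declared <- names(modules) %||% character()
  used <- names(master$modules)
  offenders <- setdiff(used, declared)
  if (length(offenders)) {
    members <- lapply(master$modules[offenders], `[[`, "member_species")
    stop("build error: entities assigned to nonexistent module(s): ",
         paste(sprintf("%s (%d species)", offenders, lengths(members)),
               collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("assets", "data", "posts")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  if (length(declared)) {
    dir.create(file.path(out_dir, "modules"), showWarnings = FALSE)
  }
  copy_assets(out_dir)

  # resolve module docs
  mod_docs <- lapply(declared, function(mn)
    modules[[mn]] %||% derive_submap(master, mn))
  names(mod_docs) <- declared

  # posts for every entity, module, reaction of the master map
  post_files <- character()
  for (key in doc_post_keys(master)) {
    content <- generate_post(key, master, registry,
                             map_href = "../index.html")
    fn <- paste0(gsub(":", "_", content$key), ".html")
    writeLines(html_page(content$title, content$html,
                         css = "../assets/style.css"),
               file.path(out_dir, "posts", fn))
    post_files <- c(post_files, file.path("posts", fn))
  }

  # tiles
  tile_files <- character()
  if (!is.null(pyramid)) {
    write_tile_pyramid(pyramid, file.path(out_dir, "tiles"))
    tile_files <- list.files(file.path(out_dir, "tiles"),
                             recursive = TRUE)
    tile_files <- file.path("tiles", tile_files)
  }

  src_link <- NULL
  if (isTRUE(config$include_source_xml) && !is.null(config$map_xml)) {
    file.copy(config$map_xml, file.path(out_dir, "map.xml"),
              overwrite = TRUE)
    src_link <- '<p><a href="map.xml">Download source XML</a></p>'
  }

  index <- build_search_index(master)
  master_callouts <- build_callouts(master, registry, rel = "")
  module_section <- if (length(declared)) paste0(
    '<h3>Modules</h3>\n<ul class="pa-panel-group">\n',
    paste(vapply(declared, function(mn) sprintf(
      '<li><a href="modules/%s.html">%s</a></li>', mn, escape_html(mn)),
      character(1)), collapse = "\n"),
    '\n</ul>') else ""

  master_body <- c(
    sprintf("<h1>%s</h1>", escape_html(master$name)),
    '<div class="pa-layout">',
    '<div id="pa-map" class="pa-map"></div>',
    '<div class="pa-side">',
    '<input id="pa-search" type="search" placeholder="search entities"/>',
    '<div id="pa-results"></div>',
    '<div class="pa-panel">', panel_html(master), module_section,
    "</div>", "</div>", "</div>", src_link)
  writeLines(html_page(
    master$name, master_body, css = "assets/style.css",
    script = "assets/viewer.js",
    data_json = NULL), file.path(out_dir, "index.html"))
  writeLines(page_data_json(master, pyramid, master_callouts, index),
             file.path(out_dir, "data", "index.json"))

  pages <- c(master = "index.html")
  callouts <- list(index = master_callouts)
  panel_index <- list(master = group_entities_by_class(master))
  for (mn in declared) {
    md <- mod_docs[[mn]]
    mcall <- build_callouts(md, registry, rel = "../")
    others <- setdiff(declared, mn)
    xlinks <- if (length(others)) paste0(
      "<p>Other modules: ",
      paste(vapply(others, function(o) sprintf(
        '<a href="%s.html">%s</a>', o, escape_html(o)), character(1)),
        collapse = " "), "</p>") else ""
    body <- c(
      sprintf("<h1>Module %s</h1>", escape_html(mn)),
      '<p><a href="../index.html">&larr; master map</a></p>', xlinks,
      '<div class="pa-panel">', panel_html(md), "</div>")
    writeLines(html_page(paste("Module", mn), body,
                         css = "../assets/style.css"),
               file.path(out_dir, "modules", paste0(mn, ".html")))
    writeLines(page_data_json(md, NULL, mcall, NULL),
               file.path(out_dir, "data", paste0("module_", mn, ".json")))
    pages[mn] <- file.path("modules", paste0(mn, ".html"))
    callouts[[file.path("modules", paste0(mn, ".html"))]] <- mcall
    panel_index[[mn]] <- group_entities_by_class(md)
  }

  manifest <- c(unname(pages),
                file.path("data", "index.json"),
                if (length(declared)) file.path(
                  "data", paste0("module_", declared, ".json")),
                post_files, tile_files,
                file.path("assets", c("style.css", "viewer.js")),
                if (!is.null(src_link)) "map.xml")
  structure(
    list(dir = out_dir, pages = pages, panel_index = panel_index,
         search_index = index, callouts = callouts, manifest = manifest),
    class = "pa_site_bundle"
  )
}

#' @export
print.pa_site_bundle <- function(x, ...) {
  cat("<site bundle> ", x$dir, "\n  pages: ",
      paste(names(x$pages), collapse = ", "), "\n  files: ",
      length(x$manifest), "\n", sep = "")
  invisible(x)
}

copy_assets <- function(out_dir) {
  src <- system.file("assets", package = "pathatlas")
  for (f in c("style.css", "viewer.js")) {
    file.copy(file.path(src, f), file.path(out_dir, "assets", f),
              overwrite = TRUE)
  }
}

# ---------------------------------------------------------------------
# link closure

#' Check a bundle for dangling internal links
#'
#' Crawls every HTML page (anchors, stylesheets, scripts, images) and
#' every JSON page descriptor (hrefs inside callout hypertext) and
#' resolves each internal reference against the bundle directory.
#' External (`http(s)`, `mailto`) and fragment-only links are ignored.
#'
#' @param dir Bundle directory.
#' @return Character vector of dangling references, `file -> target`
#'   (empty when the bundle is closed).
#' @export
check_bundle_links <- function(dir) {
  dangling <- character()
  probe <- function(from, href) {
    if (grepl("^(https?:|mailto:|data:)", href) || grepl("^#", href)) {
      return()
    }
    target <- sub("[#?].*$", "", href)
    if (!nzchar(target)) return()
    path <- file.path(dirname(from), target)
    if (!file.exists(path)) {
      dangling <<- c(dangling,
                     paste0(sub(paste0("^", dir, "/?"), "", from),
                            " -> ", href))
    }
  }
  for (f in list.files(dir, pattern = "\\.html$", recursive = TRUE,
                       full.names = TRUE)) {
    x <- xml2::read_html(f)
    hrefs <- c(
      xml2::xml_attr(xml2::xml_find_all(x, "//a"), "href"),
      xml2::xml_attr(xml2::xml_find_all(x, "//link"), "href"),
      xml2::xml_attr(xml2::xml_find_all(x, "//script[@src]"), "src"),
      xml2::xml_attr(xml2::xml_find_all(x, "//img"), "src"))
    for (h in hrefs[!is.na(hrefs)]) probe(f, h)
  }
  for (f in list.files(file.path(dir, "data"), pattern = "\\.json$",
                       full.names = TRUE)) {
    # a descriptor's hrefs are written relative to the page it feeds:
    # index.json -> index.html (root), module_X.json -> modules/X.html
    from <- if (grepl("^module_", basename(f))) {
      file.path(dir, "modules",
                sub("^module_(.*)\\.json$", "\\1.html", basename(f)))
    } else {
      file.path(dir, "index.html")
    }
    txt <- paste(readLines(f, warn = FALSE), collapse = "")
    m <- gregexpr('href=\\\\?"[^"\\\\]+', txt)[[1]]
    if (m[1] != -1) {
      for (i in seq_along(m)) {
        h <- substring(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
        h <- sub('^href=\\\\?"', "", h)
        probe(from, h)
      }
    }
  }
  dangling
}
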