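#' @title Annotation posts and release synchronization
#' @description Every map entity, module and reaction gets an annotation
#'   post: a hypertext record holding the expanded annotation, the list
#'   of the entity's forms (its species states, named canonically), the
#'   reactions it participates in with its role in each, and map-link
#'   anchors that jump to the object on the map. Posts live in a local
#'   versioned store with archive semantics: when a map release removes
#'   an object its post is archived (never deleted), and when an
#'   object's generated content changes the old version is archived
#'   together with its comments and a fresh version becomes active.
#'   Change detection works on a digest of the generated content, so
#'   layout-only map edits do not spam the archive. A remote-blog
#'   adapter interface is defined for hosted blog systems; only the
#'   local store ships.
#' @name postsync
NULL

post_key <- function(kind, id) paste0(kind, ":", id)

resolve_key <- function(key, doc) {
  if (grepl(":", key, fixed = TRUE)) {
    kind <- sub(":.*$", "", key)
    id <- sub("^[^:]*:", "", key)
    ok <- switch(kind,
                 entity = id %in% names(doc$entities),
                 module = id %in% names(doc$modules),
                 reaction = id %in% names(doc$reactions),
                 FALSE)
    if (!ok) stop("unknown post key: ", key)
    return(list(kind = kind, id = id))
  }
  if (key %in% names(doc$entities)) return(list(kind = "entity", id = key))
  if (key %in% names(doc$modules)) return(list(kind = "module", id = key))
  if (key %in% names(doc$reactions)) {
    return(list(kind = "reaction", id = key))
  }
  stop("unknown post key: ", key)
}

## every post key a document defines
doc_post_keys <- function(doc) {
  c(vapply(names(doc$entities), function(i) post_key("entity", i),
           character(1), USE.NAMES = FALSE),
    vapply(names(doc$modules), function(i) post_key("module", i),
           character(1), USE.NAMES = FALSE),
    vapply(names(doc$reactions), function(i) post_key("reaction", i),
           character(1), USE.NAMES = FALSE))
}

globe_anchor <- function(target, map_href) {
  sprintf('<a class="pa-globe" href="%s#%s" title="show on map">&#127758;</a>',
          map_href, target)
}

#' Generate the content of an annotation post
#'
#' @param key Entity id, module name or reaction id of `doc` (optionally
#'   prefixed `entity:` / `module:` / `reaction:`).
#' @param doc A [map_document()].
#' @param registry Tag registry for hyperlink expansion.
#' @param map_href Relative href of the map page the post's map-link
#'   ("globe") anchors point at.
#' @return An object of class `pa_post_content`: list with `key`,
#'   `kind`, `title`, `html` and `digest` (content hash used for change
#'   detection).
#' @details An entity post contains the expanded annotation, every
#'   species state of the entity (each with its canonical name and a
#'   map link), and every reaction referencing any of those states,
#'   each with the state's role (reactant, product or modifier with its
#'   subtype) and a map link. A module post lists the member species; a
#'   reaction post lists the participants with roles.
#' @export
generate_post <- function(key, doc, registry = default_tag_registry(),
                          map_href = "../index.html") {
  r <- resolve_key(key, doc)
  html <- switch(
    r$kind,
    entity = entity_post_html(r$id, doc, registry, map_href),
    module = module_post_html(r$id, doc, registry, map_href),
    reaction = reaction_post_html(r$id, doc, registry, map_href))
  title <- switch(
    r$kind,
    entity = doc$entities[[r$id]]$display_name,
    module = paste("Module", r$id),
    reaction = paste("Reaction", r$id))
  structure(
    list(key = post_key(r$kind, r$id), kind = r$kind, title = title,
         html = html, digest = content_digest(html)),
    class = "pa_post_content"
  )
}

species_of_entity <- function(eid, doc) {
  Filter(function(sp) any(vapply(sp$components, function(c)
    c$entity_id == eid, logical(1))), doc$species)
}

reactions_of_species <- function(sids, doc) {
  Filter(function(rx) any(vapply(rx$participants, function(p)
    p$species_id %in% sids, logical(1))), doc$reactions)
}

role_label <- function(p) {
  if (p$role == "MODIFIER" && !is.na(p$modifier_subtype)) {
    paste0("MODIFIER (", p$modifier_subtype, ")")
  } else p$role
}

reaction_line <- function(rx, sids, doc, map_href) {
  mine <- Filter(function(p) p$species_id %in% sids, rx$participants)
  roles <- unique(vapply(mine, role_label, character(1)))
  all_names <- vapply(rx$participants, function(p)
    format_name(doc$species[[p$species_id]]), character(1))
  sprintf(
    '<li>%s %s &mdash; role: %s <span class="pa-eq">%s</span></li>',
    escape_html(rx$reaction_id),
    globe_anchor(paste0("reaction=", rx$reaction_id), map_href),
    escape_html(paste(roles, collapse = ", ")),
    escape_html(paste(all_names, collapse = " + ")))
}

entity_post_html <- function(eid, doc, registry, map_href) {
  e <- doc$entities[[eid]]
  sps <- species_of_entity(eid, doc)
  sids <- vapply(sps, `[[`, character(1), "species_id")
  forms <- vapply(sps, function(sp) {
    sprintf('<li>%s %s</li>', escape_html(format_name(sp)),
            globe_anchor(paste0("species=", sp$species_id), map_href))
  }, character(1))
  rxs <- reactions_of_species(sids, doc)
  rx_lines <- vapply(rxs, reaction_line, character(1), sids = sids,
                     doc = doc, map_href = map_href)
  paste0(
    sprintf('<h2>%s</h2>\n<p class="pa-class">%s</p>\n',
            escape_html(e$display_name), e$entity_class),
    '<div class="pa-post-annotation">\n',
    render_annotation_html(e$annotation_text, registry),
    '\n</div>\n<h3>Forms</h3>\n<ul>\n',
    paste(forms, collapse = "\n"),
    '\n</ul>\n<h3>Reactions</h3>\n<ul>\n',
    paste(rx_lines, collapse = "\n"),
    '\n</ul>\n')
}

module_post_html <- function(mid, doc, registry, map_href) {
  mod <- doc$modules[[mid]]
  members <- vapply(doc$species[mod$member_species], function(sp) {
    sprintf('<li>%s %s</li>', escape_html(format_name(sp)),
            globe_anchor(paste0("species=", sp$species_id), map_href))
  }, character(1))
  paste0(sprintf('<h2>Module %s</h2>\n<h3>Member species</h3>\n<ul>\n',
                 escape_html(mid)),
         paste(members, collapse = "\n"), '\n</ul>\n')
}

reaction_post_html <- function(rid, doc, registry, map_href) {
  rx <- doc$reactions[[rid]]
  parts <- vapply(rx$participants, function(p) {
    sprintf('<li>%s &mdash; %s %s</li>',
            escape_html(format_name(doc$species[[p$species_id]])),
            escape_html(role_label(p)),
            globe_anchor(paste0("species=", p$species_id), map_href))
  }, character(1))
  paste0(sprintf('<h2>Reaction %s</h2>\n%s\n<h3>Participants</h3>\n<ul>\n',
                 escape_html(rid),
                 globe_anchor(paste0("reaction=", rid), map_href)),
         paste(parts, collapse = "\n"), '\n</ul>\n')
}

# =====================================================================
# the store

#' Create an empty post store
#'
#' @return An object of class `pa_post_store` holding no records.
#' @export
post_store <- function() {
  structure(list(records = list()), class = "pa_post_store")
}

#' @export
print.pa_post_store <- function(x, ...) {
  st <- vapply(x$records, `[[`, character(1), "status")
  cat("<post store> ", length(x$records), " record(s): ",
      sum(st == "ACTIVE"), " active, ", sum(st == "ARCHIVED"),
      " archived\n", sep = "")
  invisible(x)
}

active_index <- function(store, key) {
  for (i in seq_along(store$records)) {
    r <- store$records[[i]]
    if (r$key == key && r$status == "ACTIVE") return(i)
  }
  NA_integer_
}

validate_store <- function(store) {
  keys <- vapply(store$records, `[[`, character(1), "key")
  st <- vapply(store$records, `[[`, character(1), "status")
  act <- keys[st == "ACTIVE"]
  if (anyDuplicated(act)) {
    stop("store integrity error: duplicate ACTIVE records for ",
         paste(unique(act[duplicated(act)]), collapse = ", "))
  }
  for (k in unique(keys)) {
    v <- sort(vapply(store$records[keys == k], `[[`, numeric(1),
                     "version"))
    if (!identical(as.integer(v), seq_along(v))) {
      stop("store integrity error: versions of ", k,
           " are not consecutive from 1")
    }
  }
  invisible(store)
}

new_record <- function(content, version) {
  list(key = content$key, kind = content$kind, title = content$title,
       version = as.integer(version), status = "ACTIVE",
       content = content$html, content_digest = content$digest,
       comments = list())
}

#' Synchronize the post store with a map release
#'
#' Regenerates the post content for every entity, module and reaction of
#' `doc` and reconciles the store: a key no longer present has its
#' active record archived (nothing is ever deleted); a key whose
#' content digest changed has the old record archived together with all
#' its comments and a fresh active record added at the next version
#' with empty comments; an unchanged key is left untouched; a new key
#' gets a version-1 active record. Synchronizing the same release twice
#' is a no-op.
#'
#' @param store A [post_store()].
#' @param doc The new map release, a [map_document()].
#' @param registry,map_href Passed to [generate_post()].
#' @return List with `store` (updated) and `report` (data frame with
#'   columns `key`, `action` in added / updated / archived; unchanged
#'   keys are not reported).
#' @export
sync_store <- function(store, doc, registry = default_tag_registry(),
                       map_href = "../index.html") {
  stopifnot(inherits(store, "pa_post_store"))
  validate_store(store)
  actions <- list()
  note <- function(key, action) {
    actions[[length(actions) + 1]] <<- data.frame(
      key = key, action = action, stringsAsFactors = FALSE)
  }
  new_keys <- doc_post_keys(doc)
  old_keys <- vapply(store$records, `[[`, character(1), "key")
  # archive posts whose object left the map
  for (k in setdiff(unique(old_keys), new_keys)) {
    i <- active_index(store, k)
    if (!is.na(i)) {
      store$records[[i]]$status <- "ARCHIVED"
      note(k, "archived")
    }
  }
  for (k in new_keys) {
    content <- generate_post(k, doc, registry, map_href)
    i <- active_index(store, k)
    if (is.na(i)) {
      v <- sum(old_keys == k) + 1L
      store$records[[length(store$records) + 1]] <- new_record(content, v)
      note(k, if (v == 1L) "added" else "updated")
    } else if (store$records[[i]]$content_digest != content$digest) {
      store$records[[i]]$status <- "ARCHIVED"
      store$records[[length(store$records) + 1]] <-
        new_record(content, store$records[[i]]$version + 1L)
      note(k, "updated")
    }
  }
  report <- if (length(actions)) do.call(rbind, actions) else
    data.frame(key = character(), action = character(),
               stringsAsFactors = FALSE)
  validate_store(store)
  list(store = store, report = report)
}

#' Add a user comment to the active post of a key
#'
#' @param store A [post_store()].
#' @param key Post key (as reported by [sync_store()], e.g.
#'   `"entity:e1"`).
#' @param author,text Comment author and hypertext body.
#' @param timestamp Comment timestamp string.
#' @return The updated store.
#' @export
add_comment <- function(store, key, author, text,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  i <- active_index(store, key)
  if (is.na(i)) stop("no active post for key ", key)
  r <- store$records[[i]]
  r$comments[[length(r$comments) + 1]] <- list(
    author = author, timestamp = timestamp, text = text)
  store$records[[i]] <- r
  store
}

#' Save / load a post store as JSON
#'
#' @param store A [post_store()].
#' @param path File path.
#' @return `save_post_store` returns `path` invisibly;
#'   `load_post_store` returns the store.
#' @export
save_post_store <- function(store, path) {
  jsonlite::write_json(list(records = store$records), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_post_store
#' @export
load_post_store <- function(path) {
  raw <- jsonlite::read_json(path)
  st <- structure(list(records = lapply(raw$records, function(r) {
    r$version <- as.integer(r$version)
    r$comments <- lapply(r$comments, function(cm)
      cm[c("author", "timestamp", "text")])
    r[c("key", "kind", "title", "version", "status", "content",
        "content_digest", "comments")]
  })), class = "pa_post_store")
  validate_store(st)
  st
}

#' Render the post store as static HTML pages
#'
#' Active posts go to `<dir>/<key>.html` (with their comments), the
#' archive to `<dir>/archive/<key>_v<version>.html`, plus index pages
#' for both — the archive stays accessible so all discussion and change
#' history remains traceable.
#'
#' @param store A [post_store()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_post_store <- function(store, dir) {
  dir.create(file.path(dir, "archive"), recursive = TRUE,
             showWarnings = FALSE)
  fname <- function(r) paste0(gsub(":", "_", r$key), "_v", r$version,
                              ".html")
  written <- character()
  idx_act <- character()
  idx_arc <- character()
  for (r in store$records) {
    cm <- vapply(r$comments, function(c) sprintf(
      '<div class="pa-comment"><b>%s</b> <i>%s</i><div>%s</div></div>',
      escape_html(c$author), escape_html(c$timestamp), c$text),
      character(1))
    body <- paste0(r$content, '\n<h3>Comments</h3>\n',
                   paste(cm, collapse = "\n"))
    if (r$status == "ACTIVE") {
      p <- file.path(dir, paste0(gsub(":", "_", r$key), ".html"))
      idx_act <- c(idx_act, sprintf('<li><a href="%s">%s (v%d)</a></li>',
                                    basename(p), escape_html(r$title),
                                    r$version))
    } else {
      p <- file.path(dir, "archive", fname(r))
      idx_arc <- c(idx_arc, sprintf('<li><a href="%s">%s (v%d)</a></li>',
                                    fname(r), escape_html(r$title),
                                    r$version))
    }
    writeLines(html_page(r$title, body, css = NULL), p)
    written <- c(written, p)
  }
  writeLines(html_page("Posts", paste0(
    '<h2>Annotation posts</h2>\n<ul>\n',
    paste(idx_act, collapse = "\n"),
    '\n</ul>\n<p><a href="archive/index.html">Archive</a></p>\n'),
    css = NULL), file.path(dir, "index.html"))
  writeLines(html_page("Post archive", paste0(
    '<h2>Archived post versions</h2>\n<ul>\n',
    paste(idx_arc, collapse = "\n"), '\n</ul>\n'), css = NULL),
    file.path(dir, "archive", "index.html"))
  invisible(c(written, file.path(dir, "index.html"),
              file.path(dir, "archive", "index.html")))
}

#' Remote blog adapter interface (stub)
#'
#' Defines the operations a hosted blog platform must implement to
#' mirror the local post lifecycle: create a post, update it to a new
#' version, archive it, and append a comment. The shipped implementation
#' is a stub that records intended calls without talking to any server;
#' the local JSON store is the system of record.
#'
#' @return List of functions `create_post(record)`,
#'   `update_post(record)`, `archive_post(key, version)`,
#'   `push_comment(key, comment)`; each stub appends to the returned
#'   environment's `log` and returns `NULL`.
#' @export
remote_blog_adapter <- function() {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  record <- function(op) function(...) {
    env$log[[length(env$log) + 1]] <- list(op = op, args = list(...))
    invisible(NULL)
  }
  list(create_post = record("create_post"),
       update_post = record("update_post"),
       archive_post = record("archive_post"),
       push_comment = record("push_comment"),
       log = function() env$log)
}
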