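#' @title Structured entity annotations and identifier tags
#' @description Entity annotations can be structured into named sections
#'   (conventionally `Identifiers`, `Maps_Modules`, `References`, plus
#'   arbitrary user sections), each introduced by a header line of the
#'   form `Name:` alone on a line. Free-form annotations that do not
#'   start with a header are kept as a single unsectioned block. Inside
#'   the text, identifier tags such as `PMID:18319725` and
#'   MIRIAM-registry tags such as `@biocyc:YEAST:G3O-30431` expand into
#'   hyperlinks.
#' @name annotation
NULL

HEADER_RE <- "^[A-Za-z][A-Za-z0-9_]*:[[:space:]]*$"

#' Parse an annotation into sections
#'
#' A line consisting of `Name:` (nothing else) is a section header; the
#' lines up to the next header form its body. If the first non-empty
#' line is not a header the whole text is one unnamed, unsectioned
#' block — annotations in other formats are passed through untouched.
#' No characters are lost: headers and bodies concatenate back to the
#' input.
#'
#' @param raw Annotation text.
#' @return An object of class `pa_annotation`: list with `sectioned`
#'   (logical) and `sections` (ordered list of `list(name, body)`;
#'   `name` is `NA` for the unsectioned block).
#' @export
parse_annotation <- function(raw) {
  if (is.null(raw) || is.na(raw)) raw <- ""
  lines <- split_lines(raw)
  first <- Find(nzchar, trimws(lines))
  sectioned <- !is.null(first) && grepl(HEADER_RE, first)
  if (!sectioned) {
    return(structure(
      list(sectioned = FALSE,
           sections = list(list(name = NA_character_, body = raw))),
      class = "pa_annotation"
    ))
  }
  sections <- list()
  cur_name <- NULL
  cur_body <- character()
  flush <- function() {
    if (!is.null(cur_name)) {
      sections[[length(sections) + 1]] <<- list(
        name = sub(":[[:space:]]*$", "", trimws(cur_name)),
        body = paste(cur_body, collapse = "\n"),
        n_lines = length(cur_body)
      )
    }
  }
  preamble <- character()  # blank lines before the first header
  for (ln in lines) {
    if (grepl(HEADER_RE, trimws(ln)) && nzchar(trimws(ln))) {
      flush()
      cur_name <- ln
      cur_body <- character()
    } else if (is.null(cur_name)) {
      preamble <- c(preamble, ln)
    } else {
      cur_body <- c(cur_body, ln)
    }
  }
  flush()
  structure(
    list(sectioned = TRUE, sections = sections,
         preamble = paste(preamble, collapse = "\n"),
         trailing_newline = grepl("\n$", raw)),
    class = "pa_annotation"
  )
}

split_lines <- function(raw) {
  if (!nzchar(raw)) return(character())
  strsplit(raw, "\n", fixed = TRUE)[[1]]
}

#' Reassemble an annotation to its source text
#'
#' @param doc A `pa_annotation`.
#' @return The original raw text (lossless inverse of
#'   [parse_annotation()]).
#' @export
annotation_text <- function(doc) {
  if (!doc$sectioned) return(doc$sections[[1]]$body)
  parts <- vapply(doc$sections, function(s) {
    if ((s$n_lines %||% 0) > 0) paste0(s$name, ":\n", s$body)
    else paste0(s$name, ":")
  }, character(1))
  pre <- if (nzchar(doc$preamble %||% "")) paste0(doc$preamble, "\n") else ""
  out <- paste0(pre, paste(parts, collapse = "\n"))
  if (isTRUE(doc$trailing_newline)) out <- paste0(out, "\n")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Section body by name
#'
#' @param doc A `pa_annotation`.
#' @param name Section name.
#' @return Body string, or `NULL` when absent.
#' @export
annotation_section <- function(doc, name) {
  for (s in doc$sections) {
    if (!is.na(s$name) && s$name == name) return(s$body)
  }
  NULL
}

#' Module membership listed in an annotation
#'
#' Reads the `Maps_Modules` section: one module name per non-empty line,
#' in order. Entities may belong to several modules.
#'
#' @param doc A `pa_annotation` (or raw text, parsed on the fly).
#' @return Character vector of module names (empty when the section is
#'   absent).
#' @export
extract_module_membership <- function(doc) {
  if (is.character(doc)) doc <- parse_annotation(doc)
  body <- annotation_section(doc, "Maps_Modules")
  if (is.null(body)) return(character())
  ln <- trimws(split_lines(body))
  ln[nzchar(ln)]
}

# ---------------------------------------------------------------------
# identifier tag registry

#' Create a tag registry
#'
#' Maps tag prefixes (e.g. `PMID`) to URL templates with exactly one
#' `%s` placeholder, plus the set of MIRIAM-registry resource names
#' accepted in `@resource:id` tags.
#'
#' @param entries Named character vector, prefix -> template.
#' @param miriam_resources Character vector of accepted registry
#'   resource names.
#' @return An object of class `pa_tag_registry`.
#' @export
tag_registry <- function(entries = character(),
                         miriam_resources = character()) {
  if (length(entries)) {
    if (is.null(names(entries)) || anyDuplicated(names(entries))) {
      stop("registry prefixes must be unique and named")
    }
    n_ph <- vapply(entries,
                   function(t) length(gregexpr("%s", t, fixed = TRUE)[[1]]) *
                     (regexpr("%s", t, fixed = TRUE) > 0),
                   numeric(1))
    if (any(n_ph != 1)) {
      stop("each template must contain exactly one %s placeholder: ",
           paste(names(entries)[n_ph != 1], collapse = ", "))
    }
  }
  structure(list(entries = entries,
                 miriam_resources = tolower(miriam_resources)),
            class = "pa_tag_registry")
}

#' Default tag registry
#'
#' Ships the standard prefixes `PMID`, `HUGO` and `UNIPROT` with their
#' canonical resolvers, plus a set of common MIRIAM registry resources
#' resolved through identifiers.org. User-defined tags are added via
#' `extra`.
#'
#' @param extra Named character vector of additional prefix -> template
#'   entries.
#' @return A `pa_tag_registry`.
#' @export
default_tag_registry <- function(extra = character()) {
  entries <- c(
    PMID = "https://pubmed.ncbi.nlm.nih.gov/%s/",
    HUGO = "https://www.genenames.org/data/gene-symbol-report/#!/symbol/%s",
    UNIPROT = "https://www.uniprot.org/uniprotkb/%s",
    extra
  )
  tag_registry(
    entries,
    miriam_resources = c(
      "biocyc", "chebi", "ensembl", "go", "hgnc", "interpro", "kegg.compound",
      "kegg.pathway", "ncbigene", "pdb", "pubmed", "reactome", "uniprot"
    )
  )
}

# ---------------------------------------------------------------------
# tag expansion

## html-escape a text fragment; idempotent (existing entities untouched)
escape_html <- function(x) {
  x <- gsub("&(?![A-Za-z][A-Za-z0-9]*;|#[0-9]+;)", "&amp;", x, perl = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

MIRIAM_RE <- "@([A-Za-z][A-Za-z0-9._-]*):([A-Za-z0-9][A-Za-z0-9._:-]*)"

#' Expand identifier tags into hyperlinks
#'
#' Every `PREFIX:ID` token whose prefix is registered becomes an anchor
#' whose target embeds the id; every `@resource:id` token becomes an
#' identifiers-registry anchor (the resource name ends at the first
#' `":"`; remaining colons belong to the id, so
#' `@biocyc:YEAST:G3O-30431` resolves resource `biocyc`, id
#' `YEAST:G3O-30431`). All other text passes through HTML-escaped but
#' unmodified. Unknown `@resource` names are left as plain text with a
#' warning. Expansion is idempotent: text already inside an anchor is
#' never re-expanded.
#'
#' @param text Input text (plain or previously expanded hypertext).
#' @param registry A `pa_tag_registry`, default [default_tag_registry()].
#' @return Hypertext string.
#' @examples
#' expand_tags("PMID:18319725")
#' @export
expand_tags <- function(text, registry = default_tag_registry()) {
  stopifnot(inherits(registry, "pa_tag_registry"))
  # protect existing anchors so expansion is idempotent
  segs <- split_on_anchors(text)
  out <- vapply(segs, function(s) {
    if (s$anchor) s$text else expand_segment(s$text, registry)
  }, character(1))
  paste(out, collapse = "")
}

split_on_anchors <- function(text) {
  m <- gregexpr("<a\\b[^>]*>.*?</a>", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(list(list(text = text, anchor = FALSE)))
  segs <- list()
  pos <- 1
  for (i in seq_along(m)) {
    st <- m[i]
    en <- st + attr(m, "match.length")[i] - 1
    if (st > pos) {
      segs[[length(segs) + 1]] <- list(
        text = substring(text, pos, st - 1), anchor = FALSE)
    }
    segs[[length(segs) + 1]] <- list(
      text = substring(text, st, en), anchor = TRUE)
    pos <- en + 1
  }
  if (pos <= nchar(text)) {
    segs[[length(segs) + 1]] <- list(
      text = substring(text, pos), anchor = FALSE)
  }
  segs
}

expand_segment <- function(text, registry) {
  if (!nzchar(text)) return(text)
  hits <- find_tag_hits(text, registry)
  if (nrow(hits) == 0) return(escape_html(text))
  hits <- hits[order(hits$start), , drop = FALSE]
  out <- character()
  pos <- 1
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$start < pos) next  # overlapped by an earlier, longer hit
    if (h$start > pos) {
      out <- c(out, escape_html(substring(text, pos, h$start - 1)))
    }
    out <- c(out, sprintf('<a href="%s" class="pa-tag">%s</a>',
                          h$url, escape_html(h$token)))
    pos <- h$end + 1
  }
  if (pos <= nchar(text)) out <- c(out, escape_html(substring(text, pos)))
  paste(out, collapse = "")
}

find_tag_hits <- function(text, registry) {
  rows <- list()
  add <- function(start, end, token, url) {
    rows[[length(rows) + 1]] <<- data.frame(
      start = start, end = end, token = token, url = url,
      stringsAsFactors = FALSE)
  }
  # MIRIAM registry tags first (they start with "@" so cannot collide
  # with prefix tags at the same offset)
  m <- gregexpr(MIRIAM_RE, text, perl = TRUE)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      st <- m[i]
      en <- st + attr(m, "match.length")[i] - 1
      tok <- substring(text, st, en)
      tok <- sub("[.,;]+$", "", tok)  # trailing punctuation is prose
      en <- st + nchar(tok) - 1
      body <- substring(tok, 2)
      colon <- regexpr(":", body, fixed = TRUE)
      resource <- substring(body, 1, colon - 1)
      id <- substring(body, colon + 1)
      if (tolower(resource) %in% registry$miriam_resources) {
        add(st, en, tok,
            sprintf("https://identifiers.org/%s:%s", tolower(resource), id))
      } else {
        warning("unknown MIRIAM resource \"", resource,
                "\"; tag left as plain text", call. = FALSE)
      }
    }
  }
  if (length(registry$entries)) {
    pre_alt <- paste(vapply(names(registry$entries), rx_escape,
                            character(1)), collapse = "|")
    re <- sprintf("(?<![A-Za-z0-9@])(%s):([A-Za-z0-9][A-Za-z0-9._-]*)",
                  pre_alt)
    m <- gregexpr(re, text, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (i in seq_along(m)) {
        st <- m[i]
        en <- st + attr(m, "match.length")[i] - 1
        tok <- sub("[.,;]+$", "", substring(text, st, en))
        en <- st + nchar(tok) - 1
        colon <- regexpr(":", tok, fixed = TRUE)
        prefix <- substring(tok, 1, colon - 1)
        id <- substring(tok, colon + 1)
        add(st, en, tok, sprintf(registry$entries[[prefix]], id))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      token = character(), url = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Render an annotation as an HTML fragment
#'
#' Sections become titled blocks colored from a fixed palette keyed by
#' section order; bodies are tag-expanded. Unsectioned annotations
#' render as a single block.
#'
#' @param doc A `pa_annotation` or raw text.
#' @param registry Tag registry for [expand_tags()].
#' @return HTML fragment string.
#' @export
render_annotation_html <- function(doc, registry = default_tag_registry()) {
  if (is.character(doc)) doc <- parse_annotation(doc)
  palette <- c("#eef5ff", "#eefaee", "#fff7e6", "#f6eefa", "#f0f0f0")
  blocks <- character()
  for (i in seq_along(doc$sections)) {
    s <- doc$sections[[i]]
    body <- expand_tags(s$body, registry)
    body <- gsub("\n", "<br/>\n", body, fixed = TRUE)
    if (is.na(s$name)) {
      blocks <- c(blocks, sprintf('<div class="pa-ann">%s</div>', body))
    } else {
      col <- palette[((i - 1) %% length(palette)) + 1]
      blocks <- c(blocks, sprintf(
        '<div class="pa-ann-section" style="background:%s"><h4>%s</h4>%s</div>',
        col, escape_html(s$name), body))
    }
  }
  paste(blocks, collapse = "\n")
}
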