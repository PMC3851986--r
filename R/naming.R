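#' @title Canonical species-name grammar
#' @description The naming convention (adopted from BiNoM) serializes a
#'   species state into one string: complex components are delimited by
#'   `":"`, modifications are appended to their component with `"|"`, and
#'   the compartment, when present, is appended once with `"@"`. A
#'   modification token is either a bare state label (`"Pho"`) or
#'   `residue_state` with an underscore (`"Thr167_pho"`), e.g.
#'   `"Cdc13:Cdc2|Thr167_pho@cytoplasm"`.
#' @name naming
NULL

RESERVED_NAME_CHARS <- c("@", "|", ":")

#' Format the canonical name of a species state
#'
#' @param s A [species_state()] (components must carry their entity
#'   names).
#' @return Canonical name string.
#' @examples
#' s <- species_state("s1",
#'   list(species_component("e1", "Cdc25", list(modification("Pho")))),
#'   compartment = "cytoplasm")
#' format_name(s)  # "Cdc25|Pho@cytoplasm"
#' @export
format_name <- function(s) {
  stopifnot(inherits(s, "pa_species_state"))
  comp_txt <- vapply(s$components, format_component, character(1))
  out <- paste(comp_txt, collapse = ":")
  if (!is.na(s$compartment) && nzchar(s$compartment)) {
    check_reserved(s$compartment, "compartment")
    out <- paste0(out, "@", s$compartment)
  }
  out
}

format_component <- function(cmp) {
  check_reserved(cmp$name, "entity name")
  toks <- vapply(cmp$modifications, function(m) {
    if (is.na(m$residue_label) || !nzchar(m$residue_label)) {
      m$state_label
    } else {
      paste0(m$residue_label, "_", m$state_label)
    }
  }, character(1))
  paste(c(cmp$name, toks), collapse = "|")
}

check_reserved <- function(x, what) {
  hit <- RESERVED_NAME_CHARS[vapply(RESERVED_NAME_CHARS, grepl, logical(1),
                                    x = x, fixed = TRUE)]
  if (length(hit)) {
    stop("encoding error: ", what, " \"", x,
         "\" contains reserved character(s) ", paste(hit, collapse = " "))
  }
  invisible(x)
}

#' Parse a canonical species name
#'
#' Inverse of [format_name()] on grammar-conformant strings. The returned
#' skeleton carries component names, modification labels (with the
#' residue position extracted when the residue label embeds an integer)
#' and the compartment; entity ids are left empty.
#'
#' Modification tokens split at the last underscore: the final field is
#' the state label and everything before it is the residue label, so both
#' `"Pho"` and `"Thr167_pho"` parse. State-label case is preserved.
#'
#' @param text Canonical name string.
#' @return A `pa_species_state` with empty `species_id` and component
#'   `entity_id`s.
#' @examples
#' s <- parse_name("Cdc13:Cdc2|Thr167_pho@cytoplasm")
#' s$components[[2]]$modifications[[1]]$residue_position  # 167
#' @export
parse_name <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("grammar error at position 0: empty name")
  }
  at <- gregexpr("@", text, fixed = TRUE)[[1]]
  if (length(at) > 1 && at[1] != -1) {
    stop("grammar error at position ", at[2], ": more than one \"@\"")
  }
  compartment <- NA_character_
  body <- text
  if (at[1] != -1) {
    compartment <- substring(text, at[1] + 1)
    if (!nzchar(compartment)) {
      stop("grammar error at position ", at[1], ": dangling \"@\"")
    }
    body <- substring(text, 1, at[1] - 1)
  }
  if (!nzchar(body)) stop("grammar error at position 1: empty component list")
  comp_txt <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (any(!nzchar(comp_txt)) || grepl(":$", body)) {
    stop("grammar error: dangling \":\" separator in \"", body, "\"")
  }
  components <- lapply(comp_txt, parse_component)
  species_state("", components, compartment = compartment)
}

parse_component <- function(txt) {
  fields <- strsplit(txt, "|", fixed = TRUE)[[1]]
  if (any(!nzchar(fields)) || grepl("\\|$", txt)) {
    stop("grammar error: dangling \"|\" in component \"", txt, "\"")
  }
  nm <- fields[1]
  mods <- lapply(fields[-1], function(tok) {
    us <- gregexpr("_", tok, fixed = TRUE)[[1]]
    if (us[1] == -1) {
      modification(tok)
    } else {
      last <- us[length(us)]
      res <- substring(tok, 1, last - 1)
      st <- substring(tok, last + 1)
      if (!nzchar(st)) stop("grammar error: dangling \"_\" in \"", tok, "\"")
      modification(st, residue_label = res)
    }
  })
  species_component("", nm, mods)
}
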