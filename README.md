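# pathatlas

Comprehensive molecular-interaction maps — hundreds of species, reactions
and complexes drawn in [CellDesigner](http://www.celldesigner.org/) — are
effectively unreadable as a single static image. `pathatlas` is a map
"factory" for curators of such maps: it converts a CellDesigner XML file
plus a chain of zoom-view images into a self-contained static web atlas
that can be browsed like a geographical map — panned, zoomed semantically
(content is *redrawn*, not just shrunk, at each scale), searched by
substring, and annotated through per-entity callouts and versioned
annotation posts.

## What it implements

* **CellDesigner 4.x dialect IO** — SBML Level 2 with the
  `celldesigner` extension namespace (`speciesAlias` /
  `complexSpeciesAlias` layout, `speciesIdentity` classes, modification
  residues, included species of complexes). Files are parsed into a
  typed map model and can be written back; other dialects are rejected
  explicitly rather than part-parsed.
* **Canonical species naming.** A species state is serialized as

  ```
  name      := component (":" component)* ("@" compartment)?
  component := entity_name ("|" modification)*
  modification := (residue "_")? state
  ```

  so `Cdc25|Pho@cytoplasm` is phosphorylated Cdc25 in the cytoplasm and
  `Cdc13:Cdc2|Thr167_pho@cytoplasm` is the Cdc13–Cdc2 complex whose
  Cdc2 component is phosphorylated at threonine 167. `parse_name()` and
  `format_name()` are mutually inverse on this grammar.
* **Structured annotations.** Sections (`Identifiers`, `Maps_Modules`,
  `References`, plus arbitrary user sections) introduced by a `Name:`
  header line; identifier tags (`PMID:…`, `HUGO:…`, `UNIPROT:…`, and
  MIRIAM registry tags `@resource:id`) expand into resolver hyperlinks.
* **Semantic-zoom tile pyramids.** View chains are validated against the
  tiled-viewer requirements (each level exactly twice the previous in
  both dimensions, stable aspect ratio, tile-grid divisibility
  preferred), missing intermediate levels are synthesized by factor-2
  area-averaged downscaling, and every level is cut into 256-px tiles.
  Marker coordinates are stored once at the most detailed level and
  rescaled by `2^(Δlevel)`, so markers persist while zooming.
* **Atlas bundle generation** — master page with tiled viewer, selection
  panel grouped by entity class, substring search, per-alias callouts;
  one page per module submap whose panel lists only the module's
  members; all cross-links verified closed.
* **Annotation-post store.** One post per entity, module and reaction
  (annotation, list of forms, reactions with roles, map-link anchors).
  Across map releases the store archives rather than deletes: removed
  objects flip to `ARCHIVED`, edited content archives the old version
  *with its comments* and starts a fresh one — change detection is by
  content digest, so layout-only edits do not spam the archive.
* **Synthetic fixtures** — a deterministic generator for small
  CellDesigner maps with annotations, complexes, modifications and
  schematically rendered zoom views, so the entire pipeline runs
  offline.

## Worked example

```r
library(pathatlas)

fx <- make_map(fixture_spec(seed = 1))   # synthetic 20-entity map
fx$doc
#> <pathway map> fixture_seed1
#>   entities:  20
#>   species:   22
#>   aliases:   22
#>   reactions: 8
#>   modules:   2

s <- parse_name("Cdc13:Cdc2|Thr167_pho@cytoplasm")
s$components[[2]]$modifications[[1]]$residue_position
#> [1] 167

expand_tags("PMID:18319725")
#> <a href="https://pubmed.ncbi.nlm.nih.gov/18319725/" class="pa-tag">PMID:18319725</a>

views <- render_views(fx$doc, 4)          # 4 semantic zoom levels
pyr <- build_tile_pyramid(views)
pyr
#> <tile pyramid> 4 level(s), tile edge 256 px, 43 tiles
#>   level 0: 256x128 px, 1x1 tiles (semantic)
#>   level 1: 512x256 px, 2x1 tiles (semantic)
#>   level 2: 1024x512 px, 4x2 tiles (semantic)
#>   level 3: 2048x1024 px, 8x4 tiles (semantic)

bundle <- build_site(fx$doc, modules = list(M1 = NULL, M2 = NULL),
                     pyramid = pyr, out_dir = "atlas")
bundle
#> <site bundle> atlas
#>   pages: master, M1, M2
#>   files: 82
length(check_bundle_links("atlas"))
#> [1] 0
```

The numbers read as: the fixture map has 20 entities drawn as 22
species (two of them complexes) at 22 canvas positions; the four-level
pyramid holds 1 + 2 + 8 + 32 = 43 tiles of 256 px; the bundle consists
of a master page, two module pages and their tiles, data descriptors,
posts and assets, with zero dangling internal links.

The same pipeline is scriptable from a shell via
`inst/cli/pathatlas.R` (`fixture`, `validate`, `tiles`, `build`,
`posts-sync` subcommands driven by one JSON configuration file).

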