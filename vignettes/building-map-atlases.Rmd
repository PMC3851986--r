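---
title: "Building navigable atlases from CellDesigner pathway maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building navigable atlases from CellDesigner pathway maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathatlas)
```

## The problem

Large molecular-interaction maps drawn in CellDesigner hold far more
content than a screen can display legibly. The practical answer,
borrowed from geographical mapping, is an atlas: a pyramid of views at
increasing detail, browsed through a tiled viewer, with the biological
metadata (who a species is, its modification states and compartment,
its reactions, its module membership, its literature) attached to the
drawn objects rather than lost in the export. `pathatlas` is the
factory that turns a curated CellDesigner file plus a set of zoom-view
images into such an atlas, and keeps the accompanying annotation posts
synchronized as the map evolves through releases.

Two roles shape the design. The *map manager* curates the map, decides
what each zoom level shows, and runs the factory; the *map user* only
navigates the output, which is deliberately a static bundle — openable
from local disk, hostable on any web server, no server-side code.

## The map model and the file dialect

The factory parses SBML Level 2 files carrying the CellDesigner
extension namespace, dialect 4.x (`speciesAlias` and
`complexSpeciesAlias` layout elements). Files without the extension
namespace, or with a pre-4.x model version, are rejected with an
unsupported-dialect error rather than part-parsed: downstream naming
and layout depend on extension content, and a silently partial parse
would corrupt them.

The in-memory model separates four ideas that the file format
interleaves:

* an **entity** — one named biological object (protein, gene, RNA,
  antisense RNA, small molecule, ion, phenotype, drug, …) with its
  annotation text;
* a **species state** — an entity (or an ordered list of entities, for
  a complex) in a specific modification state and compartment;
* an **alias** — one drawn occurrence of a species state, with a pixel
  bounding box (top-left origin, y down — the CellDesigner canvas
  convention, taken verbatim because the zoom views are exported from
  that same canvas);
* a **reaction** — participants with roles (reactant, product,
  modifier) plus the modifier subtype (catalysis, inhibition, …).

Referential closure is validated on construction and after every
parse: a dangling id is an error listing the offender, not a warning.

Dialect limits worth knowing: modification residues are written for
protein components only (that is where CellDesigner attaches
`modificationResidue` elements); entity classes without reference
elements (small molecules, ions, …) are identified by name, so they
use a deterministic name-derived id and must occur in at least one
species to be writable; complexes are written as their member
components, so a `COMPLEX`-class entity is implicit and cannot be
serialized itself.

## The naming grammar

A species state serializes to one string: components joined by `:`,
modifications appended to their component with `|`, the compartment
appended once with `@`. A modification token is either a bare state
label (`Pho`) or `residue_state` (`Thr167_pho`). Choices the grammar
leaves open were fixed as follows:

* **Token splitting.** The *last* underscore-separated field of a
  modification token is the state label; everything before it is the
  residue label. This accepts both `Pho` and `Thr167_pho`, and keeps
  residue labels containing underscores representable.
* **Residue position** is the first maximal digit run in the residue
  label (167 out of `Thr167`), kept as an integer alongside the label.
* **Modification order.** Multiple modifications on one component are
  ordered by residue position, then lexically — names must be
  deterministic, and no convention is imposed by the inputs.
* **Case is preserved.** Both `Pho` and `pho` occur in real
  annotation practice; the grammar does not normalize case, it
  round-trips what it was given.
* Reserved characters (`@`, `|`, `:`) inside an entity or compartment
  name are an *encoding error*. Silent escaping would produce names
  that no longer match what other tools derive from the same file.

`parse_name()` accepts modifications in any order and canonicalizes;
`format_name()` always emits the canonical order, so the two are
mutually inverse on canonical strings (property-tested over generated
names) and `parse ∘ format` is the identity on every species state.

## Structured annotations and identifier tags

Annotation text may be structured into named sections. The section
delimiter in the original annotation corpus is not fixed by any
specification available to the package, so one unambiguous convention
is fixed and documented: a line consisting of `Name:` alone introduces
a section; everything up to the next header is its body. Arbitrary
user section names are accepted. Text whose first non-empty line is
not a header is kept as a single unsectioned block — maps annotated in
other formats pass through untouched. Parsing is lossless: headers and
bodies concatenate back to the input byte-for-byte.

Three sections carry semantics: `Identifiers` feeds the callout's
identifier links, `Maps_Modules` (one module name per line) assigns
the entity to modules, `References` holds literature and free
comments. Section colors in the rendered HTML come from a fixed
palette keyed by section order; they are presentation, not semantics.

Tag expansion turns `PREFIX:ID` tokens into resolver anchors. The
default registry ships `PMID`, `HUGO` and `UNIPROT` with their current
canonical resolvers and is user-extensible (each template must contain
exactly one `%s`). Registry tags of the form `@resource:id` resolve
through identifiers.org; the resource name ends at the *first* colon
and all remaining colons belong to the id, which is what ids like
`YEAST:G3O-30431` require. Unknown registry resources are left as
plain text with a warning — annotation text must never be destroyed by
a typo. Expansion is idempotent (text inside an existing anchor is
never re-expanded), so pipelines may expand defensively.

## Zoom levels, tiles and coordinates

Level 0 is the coarsest (top-level) view and each deeper level doubles
both pixel dimensions — the convention of tiled map viewers, and the
entry point a user lands on. The validator enforces what the viewer
contract actually needs: consecutive views exactly a factor 2 apart in
both dimensions (error), stable aspect ratio (error — a proxy for
"objects must not move between views", which cannot be checked
pixel-wise), and tile-grid divisibility (warning only). A dimension
"meshes" with the grid when it is a multiple of the tile edge *or* an
exact divisor of it: a 256×128 top level is standard and pads
predictably, whereas 300×300 earns a warning. Non-meshing edges are
padded with opaque white by default — CellDesigner exports have white
backgrounds — and the fill is configurable.

When only the top and the most detailed view are supplied, the
intermediate levels are synthesized by repeated factor-2 downscaling
of the detailed image using area averaging (each output pixel is the
mean of a 2×2 block): deterministic, alias-free at factor 2, and free
of filter parameters. Synthesized views are flagged `semantic = FALSE`;
manager-supplied imagery is never overwritten.

Tiles default to 256-px squares. Marker coordinates are recorded once,
at the most detailed level, with the marker anchored at the alias
bounding-box center (symmetric, and robust to how the box was drawn);
every other level gets them by `x' = x·2^(to − from)`, which composes
exactly across levels. The viewer applies the same scaling
client-side, so markers persist while zooming from one source of
truth.

## The bundle

`build_site()` writes a directory that is complete in itself: the
master page, one page per module, JSON data descriptors, the tile
tree, post pages and static assets. The interactive viewer is a single
static JavaScript asset bundled verbatim; generation only fills data,
which keeps all logic in R and the output hostable anywhere.

The selection panel groups entities by class in a fixed class order
(proteins, genes, RNAs, antisense RNAs, then the small-molecule and
remaining classes); the ordering is a documented choice, since nothing
in the inputs prescribes one. A module page's panel lists only that
module's members. Module membership comes from the `Maps_Modules`
sections; an entity assigned to a module that no configured submap
provides aborts the build with the offenders listed — a module link
that cannot resolve is a curation error, not a rendering detail.

Search is a case-insensitive substring match over the raw indexed
strings (entity names, canonical species names, annotation text),
ordered by match position then name. Substring semantics — rather than
token prefix — is what makes queries like `cdc` find `Cdc25`, `Cdc2`
and `Cdc13` at once; the empty query deliberately matches nothing.
Link closure of the bundle (pages, assets, tiles, callout hypertext)
is checked by an exhaustive crawl, and the build command fails on any
dangling reference.

## Posts and release synchronization

Every entity, module and reaction gets a post: expanded annotation,
the entity's forms (all species states containing it, canonically
named), the reactions those states participate in with the state's
role in each, and a map-link anchor per form and reaction. Reactions
get standalone posts because posts link reactions as first-class map
objects.

The store reconciles against each map release by regenerated content,
not by comparing XML: the digest covers annotation, forms and
reactions, so a layout-only edit (moving an alias) changes nothing and
triggers nothing. A removed key archives its active record; a changed
digest archives the old version together with all its comments and
starts version n+1 with an empty comment list; an unchanged key is
untouched, making synchronization idempotent. Nothing is ever deleted
— the archive is the traceability mechanism, and the record count is
monotone by construction. Hosting the posts on a blog platform is out
of scope: a remote adapter interface (create / update / archive /
push-comment) is defined with an inert stub, and the local JSON store
plus rendered HTML pages is the system of record.

## The fixture generator

`make_map()` emulates the *inputs* a map manager would provide: a map
with the four primary entity classes, two-component protein complexes,
modification states at a configurable rate, compartments, reactions
with occasional catalysts or inhibitors, and sectioned annotations
carrying HUGO/UNIPROT/PMID and registry tags plus module assignments
that cover every module. Defaults (12 proteins, 4 genes, 3 RNAs, 1
antisense RNA, 2 complexes, 8 reactions, 2 modules, 30% modification
rate, 2048×1024 canvas) give a 20-entity map — small enough to build
in seconds, large enough that every code path (complexes, multi-module
membership, modifier subtypes) is exercised. Generation is
deterministic per seed, down to byte-identical XML.

`render_views()` is schematic on purpose: filled class-colored
rectangles at exactly the alias bounding boxes, with boxes dropped
(not shrunk) below a size threshold at coarser levels. That reproduces
the geometric facts the pipeline depends on — boxes coincide with
recorded bounding boxes, levels halve exactly, detail vanishes with
scale — and nothing else. What passing tests on these fixtures shows
is therefore that the *machinery* is correct: parsing, naming,
tiling, coordinate scaling, link closure, store lifecycle. What they
cannot show is robustness to the full variety of real CellDesigner
exports (hand-edited files, other tool versions, SBGN glyph
variation, very large maps) or the readability judgments a manager
makes when curating real semantic-zoom views.

## Numerical and degenerate-input choices

* Downscaling requires even dimensions at every halving step; the
  power-of-two chain guarantees this, and a violation is an error, not
  a silent crop.
* Tile cutting interprets boxes on the pixel grid with 0-based tile
  indices; interior tiles are exact crops (reassembly is byte-exact,
  and tested as such), edge tiles are padded.
* An empty map is valid everywhere: it parses, writes, groups into an
  empty panel and builds a one-page bundle.
* Species without an explicit compartment have *no* compartment (the
  name omits `@…`); the file dialect's `default` compartment maps to
  absent on parse.
* Complex component order is the file's declaration order and is
  preserved — it is part of the canonical name.
* Content digests (source files, post change detection) use MD5 via
  base R's `tools::md5sum`; the digest is an identity check, not a
  security boundary.

## Problem sizes used in the shipped checks

The test suite and the end-to-end checks run on the generator's
conditions: the 20-entity default map on a 2048×1024 canvas with four
zoom levels (43 tiles) for the full-pipeline check, and a reduced
1024×512 canvas with 9-entity maps for the per-module unit tests,
chosen so the whole suite completes in well under a minute on one CPU.
Naming and store properties are exercised over a few hundred generated
cases under fixed seeds.

## Known limitations

* Only the CellDesigner 4.x dialect subset described above is read and
  written; BioPAX and other SBML dialects are out of scope (external
  converters exist for that step).
* SBGN glyph rendering and validation are not attempted; view imagery
  is the map manager's responsibility, and the fixture renderer is
  schematic.
* Modification states on gene/RNA components parse and name correctly
  but are not writable to the dialect (CellDesigner models those as
  structural states, which this subset omits).
* The post store is local; pushing to a hosted blog requires
  implementing the adapter interface.
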