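---
title: "Constructing a merged biomedical knowledge graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a merged biomedical knowledge graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgforge)
```

`kgforge` builds one labelled property graph out of many biomedical
sources that disagree about identifiers, names, and scope. This vignette
explains the procedure the package implements, the parameters that matter,
the design decisions taken where the design was genuinely open, and what
the bundled fixture corpus does and does not demonstrate.

## The construction procedure

The pipeline has four stages, mirroring how production biomedical graph
databases are assembled:

1. **Preparation.** Each source's raw files are parsed (OBO, SDF, FASTA,
   GMT, GAF-style annotation TSV, plain TSV, GraphML) and pushed through a
   per-source chain of quality filters and transforms, emitting normalized
   node/edge/link tables. Adapter specs are declarative YAML
   (`inst/extdata/adapters.yaml`), one per source, and every filter is a
   pure, idempotent, order-preserving function whose removals are logged
   so that run reports telescope (input − removed = output).
2. **Integration.** All prepared sources are loaded into a single store as
   *disconnected subgraphs*: their labels are namespaced
   (`mondo.Term`, `reactome.Pathway`, …) and every entity carries a
   `source` marker property. The seed graph — a small hetnet with
   Compound/Disease/Gene/SideEffect/Symptom/Pathway/GO/PharmacologicalClass
   nodes — is loaded unmarked.
3. **Merging.** A fixed-order plan of per-source routines maps source
   entities onto the merged schema through cascades of resolution
   strategies and applies the merge primitives: node replacement that
   preserves incident edges, edge match-or-create, edge nodes for n-ary
   relations, bulk edge-type renames, the label-hierarchy closure, and
   finally cross-label EQUAL edges and allele edges. The order matters —
   disease ontologies must land before annotation sources that refer to
   diseases, chemicals before the steps that link variants or treatments
   to them — and the default plan encodes that dependency order.
4. **Validation and extraction.** Three validators run over the merged
   graph (edge-name grammar against incident node labels, resource/tag
   contract, human-only taxon check), and `extract_merged_subgraph()`
   emits a clean graph without the source subgraphs and without dangling
   edges.

### The edge-type grammar

All merged edge types follow one grammar: the uppercase relation name,
an underscore, then the source-label abbreviation, the lowercased initials
of the relation words, and the target-label abbreviation:

```{r}
generate_edge_type("MIGHT_SUBCELLULAR_LOCATES", "Interaction", "CellularComponent")
parse_edge_type("ASSOCIATES_TO_EFFICACY_DOSAGE_VatedCH")[c("relation", "src_label", "dst_label")]
```

Because abbreviations are all-uppercase and relation initials all-lowercase,
the rendered form parses unambiguously (`^([A-Z]+)([a-z]+)([A-Z]+)$` on the
final underscore-separated component). The package ships a transcribed
corpus of 163 edge-type strings (`edge_type_corpus()`); the regression
suite requires every one to parse and regenerate byte-identically.

One schema inconsistency deserves a note: the historical phenotype–gene
association type is printed as `ASSOCIATES_PaG`, in which `P` is the
*Protein* abbreviation, not Phenotype (`PT`). The string still parses under
the registry (as Protein→Gene) and is kept in the corpus, but the merge
routines generate the grammar-consistent `ASSOCIATES_PTaG` for
phenotype–gene edges — emitting the literal string between Phenotype and
Gene nodes would make the package's own naming validator reject its own
output. We treat the grammar, not the literal string, as normative.

### Entity resolution

A `mapping_cascade()` is an ordered list of strategies for one entity
class / target label pair:

* `identifier` — exact string equality on a shared key property (CAS,
  UMLS, RxNorm, UNII, InChIKey, MeSH, DrugBank id, Entrez id, gene symbol,
  dbSNP rs-id, …);
* `xref` — bridging through a generic two-column cross-reference table
  (this is how licensed mapping systems are represented: as plain tables,
  never as service calls);
* `name` — comparison of normalized names and synonyms
  (`normalize_name()` lowercases, trims, collapses whitespace and strips a
  fixed punctuation set; it is idempotent);
* `structure` — fingerprint similarity against fingerprinted chemical
  nodes at a configurable threshold (0.75 by default).

The first strategy producing at least one candidate wins and later
strategies are never consulted. The status is `unique`, `ambiguous`, or
`unmatched`; **ambiguous matches are never auto-merged** — the merge
engine treats them as unmatched, and `mapping_report()` surfaces them,
together with unique matches whose normalized names disagree, for manual
review. This is deliberately conservative: a wrong merge contaminates
every downstream edge, whereas an unmatched entity merely duplicates.
When several graph nodes legitimately share a key (two alleles of one
rs-id), routines that need a single node pick the lexicographically
smallest identifier — an arbitrary but deterministic convention.

### Quality rules and their defaults

| Rule | Default | Why |
|---|---|---|
| taxon filter | keep NCBI taxon 9606 | "human" gene files also carry archaic-human subspecies records |
| outcome signal | frequency ≥ 0.1 % AND ≥ 100 reports (inclusive) | drops drug–outcome pairs likely to be reporting noise |
| clinical annotations | evidence level ∈ {1, 2, 3} | excludes the weakest curation tiers |
| variant annotations | significance = "yes" | keeps only calls the curators committed to |
| literature references | at least one id in the reference list cell | unreferenced edges are not traceable |
| interaction evidence | evidence-type cell contains `"exp"` | intent is "experimental, not predicted"; the substring rule is our concrete reading |
| protein / rs-id reconciliation | semi-join against the current list | retired accessions would create orphan nodes |
| similarity retention | max(Tanimoto, Dice) ≥ 0.75 | keeps only strong structural resemblance |

The drug–outcome frequency is taken *as given* in the input column (the
filter does not re-derive the denominator), and the combination rule for
multiple fingerprint schemes/measures is *max over configured
combinations* — both points are underdetermined in the schema we follow,
and these are our documented choices.

### Chemical similarity

Fingerprinting delegates to ChemmineR's atom-pair descriptors folded into
a 1024-bit vector. Atom-pair fingerprints are canonical in the atom graph,
so the same molecule with permuted atom numbering yields an identical
bitvector — a property the test suite checks with a renumbered duplicate.
Tanimoto and Dice are implemented directly on the bit sets
(`|A∩B|/|A∪B|` and `2|A∩B|/(|A|+|B|)`), with the convention that two
empty fingerprints score 0, not 1: a missing structure must never count as
evidence of resemblance. `ChemmineR::fpSim` serves as an independent
cross-check in the tests (with its `addone` smoothing disabled), never as
the implementation. Resemblance-edge direction is deterministic
(lexicographically smaller compound identifier as source).

### Merge primitives and conflict handling

* `replace_or_remove_nodes()` updates a whole label from a replacement
  table: matched nodes keep their surrogate id — hence all incident
  edges — while unmatched existing nodes are removed with their edges and
  novel rows become new nodes. Only nodes whose *primary* label matches
  are candidates, so a Salt that carries Compound through the hierarchy is
  not swept up by a Compound replacement. Matching tries the replacement
  identifier before the declared match key, which is what makes repeated
  merges stable.
* `merge_edge()` matches on (type, endpoints, declared `match_on`
  properties); on a match it unions list properties and extends the
  resource list.
* Property conflicts keep the existing value and store the incoming one
  under `<name>_<source>` — no information is discarded, and the first
  source to assert a value wins, which follows the merge order's notion of
  source precedence.
* Every contributing source is recorded in a `resource` list and a
  `<source>_id` tag property; the tag contract is exactly what
  `validate_resource_tags()` checks.
* Edge nodes (`Interaction`, `Treatment`, `ClinicalAnnotation`,
  `VariantAnnotation`) reify n-ary relations as a node plus one typed edge
  per participant. For a protein pair the smaller identifier receives the
  node→protein edge (`INTERACTS_IiP`) and the larger the protein→node edge
  (`INTERACTS_PiI`) — the direction is not specified by the schema, so a
  deterministic convention is used.
* EQUAL edges link equal-meaning nodes across the phenotype-class labels
  (shared UMLS id or normalized name), once per unordered pair, with the
  direction fixed by the edge type (e.g. `EQUAL_DeSE` always runs
  Disease→SideEffect). Classes are read as *primary* labels so the
  Phenotype grouping label cannot duplicate pairs. Allele edges pair
  variants sharing an rs-id.

The whole plan is **idempotent on its own output**: re-running the merge
changes neither the node set nor the edge set. This required three
specific mechanisms — identifier-first matching in replacement, match-or-
create for every node and edge-node creation, and existence checks in the
EQUAL/allele generators — and it is property-tested end to end.

## The fixture corpus

`generate_corpus()` writes a 19-source miniature corpus plus a hetnet seed
graph and generic xref tables. Its *core design is fixed*: which entities
exist, which overlap across sources, and what each filter must drop are
hard-coded, so the correct merged graph (55 nodes, 93 edges, with label
sets and endpoints) can be enumerated constructively at generation time —
by set arithmetic over the design, never by running the pipeline. The seed
drives only what must not change the answer: decoy rows (wrong taxa, empty
evidence cells, sub-threshold signal pairs, stale rs-ids), row shuffling,
and random case jitter on names (exercising normalization). The
`fixture_manifest()` scales decoy counts; `empty = TRUE` produces
structurally valid but empty files.

The corpus exercises every parser, every filter rule, every mapping
strategy kind (identifier, xref bridge, name, with structure similarity
exercised in unit tests), and every merge routine, including deferred
steps (chemical links added only after chemicals exist) and the
rs-id-driven variant pruning that cascades to adverse-event edges.

What passing these tests does **not** show: robustness to the real
sources' scale (millions of rows), their malformed edge cases, real
chemistry (the toy molecules only need to be parseable and to give one
identical pair above the similarity threshold and all other pairs below
it), or the semantic correctness of any particular biological assertion.
The corpus demonstrates the *mechanics* — parsing, filtering, resolution,
merging, validation — under conditions where the right answer is known.

Problem sizes used by the verification suite were chosen to keep the
right answers enumerable: the corpus merges to 55 nodes and 93 edges;
oracle-equivalence checks run resolution against a 300-node scan,
similarity against exhaustive rescoring of 150 compounds, and path search
against walk enumeration on 40-node graphs; round-trip and conservation
properties are repeated across 100 random seeds.

## Numerical and degenerate-input choices

* Table cells are UTF-8 strings; list cells use `|`; embedded newlines and
  tabs (SDF structure blocks) are backslash-escaped through TSV round
  trips.
* GraphML carries node labels as a `:`-prefixed concatenation in a
  `labels` attribute, the edge type in `label`, numeric properties as
  `long`/`double` keys, and list properties as `|`-joined strings flagged
  with `attr.list` — `read_graphml(write_graphml(g))` is the identity on
  any graph the toolkit produces.
* Path search is bounded-depth DFS with lexicographic tie-breaking on
  (identifier, edge id); results are walks (node revisits allowed), and an
  empty match is an empty list, not an error.
* Unresolvable edge endpoints during loading are skipped and logged on the
  store — integration must survive partial inputs, but silently dropping
  rows would make debugging impossible.
* Obsolete ontology terms become node rows flagged `is_obsolete` and emit
  no edges; `alt_id` tags are folded into the xref column (an assumption —
  the OBO spec gives them no merge semantics here).
* An unparseable structure is an error for a single `fingerprint()` call
  but a logged skip in batch `fingerprint_set()`.

## Known limitations

* Merge routines cover the node and edge classes the schema names per
  source; exotic per-source properties pass through untyped.
* The xref tables are generic two-column stand-ins; licensed
  vocabularies' richer semantics (term types, suppressible synonyms) are
  out of scope.
* The structure strategy scores against pre-fingerprinted candidates only;
  there is no substructure or 3D similarity.
* The store is in-memory and single-threaded; persistence, transactions,
  and query languages belong to the database engines this toolkit feeds,
  not to the construction method itself.
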