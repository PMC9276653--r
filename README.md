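# kgforge

Forging a merged heterogeneous biomedical knowledge graph from many
disagreeing sources.

Pharmacological questions — *which gene variants change a drug's effect?
which drugs might cause this adverse reaction?* — need information that no
single database holds: drug–target relations live in one resource,
drug–adverse-event signals in another, variant–gene–disease links in a
third. `kgforge` implements the construction method for such a graph as a
reusable R toolkit. Starting from a hetnet-style seed graph, it parses
miniature emulations of the usual source formats (OBO ontologies, SDF
structure files, FASTA, GMT gene sets, GAF-style annotations, TSV link
tables, GraphML subgraphs), applies per-source quality rules, resolves
each incoming entity onto the graph through an ordered mapping cascade,
and merges everything into one labelled property graph that a validator
can certify.

It is aimed at bioinformaticians who want to study, test, or extend the
mechanics of multi-source graph integration at desk scale — every stage is
an exported function, and a deterministic fixture generator provides a
corpus whose correct merged graph is known in advance.

## The method in brief

* **Edge-type grammar.** Every merged edge type is
  `RELATION_<SRC><initials><DST>`, where `SRC`/`DST` are uppercase label
  abbreviations (Chemical → CH, Disease → D, …) and the middle part is the
  lowercased initials of the relation — `TREATS` from a Chemical to a
  Disease renders as `TREATS_CHtD`. `parse_edge_type()` inverts
  `generate_edge_type()` exactly, which is what makes the final naming
  validator possible.
* **Mapping cascades.** An incoming entity is resolved by trying
  strategies in order — exact identifiers (CAS, UMLS, RxNorm, UNII,
  InChIKey, MeSH, dbSNP rs-ids, …), cross-reference table bridging,
  normalized name/synonym comparison, and chemical-structure similarity.
  The first strategy with a candidate wins; ambiguous matches are reported
  and never auto-merged.
* **Quality rules.** Human-taxon filtering (NCBI 9606), direct-evidence
  and literature-reference requirements, drug–outcome signal thresholds
  (frequency ≥ 0.1 % and ≥ 100 reports, inclusive), clinical-annotation
  evidence levels 1–3, significance = "yes" for variant annotations, and
  reconciliation against current protein and rs-id lists.
* **Structure similarity.** Compounds are fingerprinted (atom-pair
  fingerprints folded to 1024 bits, invariant under atom renumbering) and
  every pair scoring Tanimoto/Dice ≥ 0.75 receives a `RESEMBLES_CrC`
  edge; `tanimoto = |A∩B| / |A∪B|`, `dice = 2|A∩B| / (|A|+|B|)`.
* **Label hierarchy.** `Salt ⊂ Compound ⊂ Chemical` plus grouping labels
  (`Phenotype` over Disease/Symptom/SideEffect, `Variant` over
  GeneVariant/Haplotype/Genotype, `ReactionLikeEvent` over the reaction
  labels), applied as an idempotent closure.
* **Validation and extraction.** Three validators (naming grammar vs.
  incident labels, resource/tag contract, human-only check) plus
  extraction of the merged subgraph — source subgraphs are dropped, and no
  dangling edge survives.

## Worked example

The classic pharmacogenomic triangle: warfarin dosing depends on variants
of *CYP2C9* (which encodes warfarin's metabolizing enzyme) and *VKORC1*
(whose product warfarin inhibits). The bundled example graph encodes the
drug, both genes, their proteins, and three gene variants:

```r
library(kgforge)

generate_edge_type("TREATS", "Chemical", "Disease")
#> [1] "TREATS_CHtD"

s <- fig_example_store()
paths <- find_paths(s, variant_drug_pattern("DB00682"))
length(paths)
#> [1] 3
for (p in paths) {
  cat(paste(vapply(p$nodes, function(n) gs_get_node(s, n)$properties$name, ""),
            collapse = " -> "), "\n")
}
#> NM_000771.3(CYP2C9):c.1075A>C (p.Ile359Leu) -> CYP2C9 -> Cytochrome P450 2C9 -> Warfarin
#> NM_024006.4(VKORC1):c.-1639G>A -> VKORC1 -> Vitamin K epoxide reductase 1 -> Warfarin
#> NM_000771.3(CYP2C9):c.430C>T (p.Arg144Cys) -> CYP2C9 -> Cytochrome P450 2C9 -> Warfarin
```

Each variant reaches the drug through its gene and the gene's protein —
three variant→gene→protein→drug paths, one per variant, flagging a
genotype-dependent drug response.

Running the whole pipeline on the deterministic fixture corpus:

```r
corpus <- tempfile("corpus")
generate_corpus(corpus, fixture_manifest(seed = 42))
run <- forge_pipeline(corpus)
gs_counts(run$merged)
#> $nodes
#> [1] 55
#> $edges
#> [1] 93
nrow(run$validation$edge_names$violations)
#> [1] 0
compare_to_truth(run$merged, read_truth(corpus))$edges_equal
#> [1] TRUE
```

The merged graph matches the generator's constructive ground truth
node-for-node and edge-for-edge, and passes all validators.

A thin command-line front-end over the same functions is available at
`inst/scripts/forge.R` (`fixtures`, `prepare`, `merge`, `validate`,
`extract` subcommands).

## Package layout

| Path | Contents |
|---|---|
| `R/graph-store.R`, `R/graphml.R`, `R/paths.R` | property graph, GraphML I/O, path search |
| `R/parsers.R` | OBO / SDF / FASTA / GMT / GAF converters |
| `R/filters.R`, `R/adapters.R` | quality-rule catalogue and per-source preparation |
| `R/resolver.R` | mapping cascades and entity resolution |
| `R/naming.R`, `R/merge.R`, `R/routines.R` | naming grammar and the merge engine |
| `R/chem.R` | fingerprints and Tanimoto/Dice resemblance edges |
| `R/validate.R` | validators, merged-subgraph extraction |
| `R/fixtures.R`, `R/pipeline.R` | fixture corpus with ground truth; orchestration |
| `vignettes/constructing-biomedical-knowledge-graphs.Rmd` | methods vignette |
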