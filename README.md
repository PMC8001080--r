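# ontoslim

Reference ontologies of small chemical compounds (ChEBI and its kin) are
built for chemists: rigorous, deep, and exhausting to browse. A database
that curates a few thousand of those compounds — say, non-peptidic epitopes
in an immunology resource — needs the opposite: a shallow, intuitive tree
that contains exactly the curated entities plus the grouping classes
required to organize them. Reaching a single hexose through 18 levels of
single-child grouping classes helps nobody.

`ontoslim` derives such an application view from an OBO ontology, and keeps
it alive release after release. The pipeline:

1. **Extract** — keep only the curated ("seed") terms, their ancestors, and
   the closure of their role assertions.
2. **Prune** — iteratively splice out every uncurated grouping class whose
   *source-bearing-children* count (direct children that are, or lead to,
   seeds) is at most a threshold (default 1), re-attaching its children to
   all of its parents. Seed ancestry through surviving classes is
   preserved, and no seed ever gets deeper.
3. **Bucket** — under any parent mixing named grouping subclasses with a
   clutter of ungrouped curated leaves, collect those leaves into an
   `other <parent>` class, always rendered last among its siblings.
4. **Edit** — replay a reviewed, ordered edit script (move / merge /
   rename / create / splice, each step with a rationale) so every manual
   curation judgment is reproducible.
5. **Mirror roles** — materialize the existential axioms
   *structure subClassOf "has role" some role* into a browsable
   "chemical entity by role" branch whose compound classes
   (`hormone compound`, ...) mirror the in-use part of the role hierarchy;
   each seed attaches under its most specific inherited roles only.
6. **Report and maintain** — role-gap worklists for curators (with a
   persistent "no role" disposition), duplicate-placement checks at level
   2, naming-convention lint (lower case, singular), tree-complexity
   metrics (source depths, source children per parent), and a
   release-validation gate that classifies every used identifier as
   valid / replaced / obsolete-without-replacement / merged-via-alt-id /
   missing.

A deterministic synthetic-ontology generator reproduces the pathologies
this pipeline exists for (deep single-child chains, multi-parent terms,
sparse role assertions, obsolete ids), so the whole machinery is testable
without downloading anything.

## Model

The ontology is a rooted acyclic multi-parent class graph: terms with
`is_a` parents, plus one modeled relationship (`has_role`). Depth of a
term is the number of `is_a` edges from a root; in a DAG this is
path-dependent, so both shortest-path (default) and longest-path depths
are exposed. The complexity of a tree for a seed set *S* is summarized by
the distribution of seed depths and, over every ancestor *p* of a seed
with at least one child, the count
`|source_bearing_children(p, S)|` — the "parents with one source child"
statistic is the number of such parents with count exactly 1.

## Worked example

The package ships a small OBO file in which glucose sits nine levels deep
under a chain of grouping classes:

```r
library(ontoslim)
o     <- read_obo(system.file("extdata", "example.obo", package = "ontoslim"))
seeds <- read_seeds(system.file("extdata", "example-seeds.txt", package = "ontoslim"))
script <- parse_edit_script(system.file("extdata", "example-edits.yaml", package = "ontoslim"))

tree_metrics(o, seeds)
#> <tree_metrics> (shortest-path depths; 4 sources, 10 parents)
#>   source depth: avg 6.2, median 6, max 9, min 4
#>   source children per parent: avg 1.3, median 1, max 3
#>   parents with one source child: 8

res <- slim(o, seeds, script = script)
res$rendered
#> chemical entity (4)
#>   organic molecular entity (4)
#>     monosaccharide (3)
#>       fructose (1)
#>       glucose (1)
#>       ribose (1)
#>     steroid (1)
#>       progesterone (1)
#> role (0)
#>   biological role (0)
#>     hormone (0)
```

Every branch label carries its distinct curated-entry count. The maximum
seed depth fell from 9 to 3 and the single-source-child parents from 8 to
2 (`compare_metrics(tree_metrics(o, seeds), res$metrics)` prints the full
old/new/delta table). Roles become browsable with:

```r
mr <- mirror_roles(res$ontology, seeds)
render_tree(mr$ontology, seeds, roots = "IEDB:by-role")
#> chemical entity by role (1)
#>   hormone compound (1)
#>     progesterone (1)

role_gap_report(res$ontology, seeds, "all")[, c("id", "name", "parents")]
#>        id     name        parents
#> 2 EX:0021 fructose monosaccharide
#> 1 EX:0020  glucose monosaccharide
#> 3 EX:0022   ribose monosaccharide
```

The three sugars have no role anywhere in their ancestry, so they land on
the curators' review worklist; a filled assignment file (`NR`, an existing
role CURIE, or `NEW:name|parent`) is ingested with
`apply_role_assignments()`.

## Command line

Every stage is also a subcommand of the installed `exec/ontoslim` script
(`slim`, `extract`, `prune`, `buckets`, `apply-script`, `check-duplicates`,
`render`, `roles mirror|gaps|apply`, `metrics`, `compare`, `validate`,
`lint`, `synth`); `ontoslim --help` lists flags and config keys. `validate`
exits with status 2 when any used id is obsolete without replacement or
missing, which is what a weekly build gate wants.

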