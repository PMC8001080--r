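---
title: "Slimming a chemical ontology into an application hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slimming a chemical ontology into an application hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoslim)
```

## The problem

Curated databases that reference a large reference ontology face a
recurring tension: the reference classifies everything, rigorously, while
the application needs a browsable view of only its few thousand curated
entities. In a chemistry ontology the symptoms are characteristic — long
single-child chains of grouping classes ("each level consisting of just
one new child node"), entities with dozens of ancestors, role information
locked in non-browsable existential axioms, and identifiers that are
retired or merged with every release. `ontoslim` is a pipeline for
deriving and maintaining such an application view.

## The model

An ontology here is a rooted, acyclic, multi-parent class graph. Each
term carries: a CURIE identifier, a name, `is_a` parents, `has_role`
assertion targets, alternative (merged-in) ids, an obsolete flag with an
optional replacement id, and OBO subset tags. Two subset tags have
pipeline meaning: curated-seed membership (`iedb_curated` by default) and
the persistent "reviewed, no role" disposition (`no_role`). Invariants
enforced at construction: every reference resolves, the `is_a` graph is
acyclic, obsolete terms carry no edges, and the roots are exactly the
live parentless terms.

Only `is_a` and one existential relationship are modeled. This is a
deliberate non-goal boundary: the pipeline needs subclass reachability
and role assertions, not OWL reasoning.

**Depth in a DAG.** "Level" is well defined in a tree but not in a
multi-parent graph, and the counting convention is genuinely open. We
default to shortest-path depth — a browser user reaches a term through
its shallowest placement — and expose longest-path depth as an option.
All metrics record which mode produced them and refuse to be compared
across modes.

## Pipeline stages and their parameters

**Extraction** keeps the seeds, their structural ancestors, role terms
referenced by any retained term, and those roles' ancestors. Obsolete
terms are never retained (they stay only in the full release file, where
the validation step needs them).

**Pruning** splices every non-seed, non-protected, non-root grouping
class whose source-bearing-children count is `<= max_spliceable_children`
(default 1), iterated to a fixpoint. The threshold quantifies "only a
limited number of other classes as children": at 1, single-lineage chains
collapse while genuinely branching groupers survive, which is also the
reading under which "parents with one source child" is the natural
companion statistic. Counting only source-bearing children (rather than
all children) is itself a choice; a `count_mode = "raw"` switch provides
the alternative. Splicing re-attaches orphaned children to *all* parents
of the removed class, preserving every browse path in the DAG, and pushes
the removed class's own role assertions down to its children so that
descendants' inherited roles are unchanged. Role-branch terms (role
targets, their ancestors, and descendants of a root named "role") are
never spliced — they are not structure-tree grouping classes. The
`protected` set models manually retained checkpoint classes: the
canonical 18-level chain collapses to depth 1 bare, or to depth 6 with 5
evenly spaced checkpoints.

**Buckets.** A parent that mixes named grouping subclasses with
`>= other_bucket_min` (default 3) ungrouped curated leaves gets an
`other <parent>` class collecting those leaves. "Ungrouped" means: a seed
or childless child none of whose other parents is a grouping class below
the same parent. Three is the smallest clutter worth a catch-all; at two,
the bucket label costs as much attention as it saves. Buckets never nest,
reuse an existing same-named sibling, sort last among siblings in every
rendering, and the operation is idempotent. Bucket ids are minted
deterministically in a dedicated namespace (`IEDB:other-<parent id>`), so
re-runs regenerate identical ids.

**Edit scripts** carry every manual reorganization as data: an ordered
YAML list of steps (`move_term`, `merge_classes`, `rename`,
`create_class`, `create_other_bucket`, `add_parent`, `remove_parent`,
`remove_class`/`splice_class` — the last two are aliases for the same
splice), each with a free-text rationale. Steps resolve targets by id or
unique name at application time; a step that would create a cycle aborts
with the cycle path. Keeping these as reviewable data rather than code
matters because they are release-specific curation judgments.

**Role mirroring.** Role axioms are assertion-level: a compound inherits
a role from any structural ancestor, but the role hierarchy itself is
*not* closed over when computing inheritance. That asymmetry is
intentional: placement wants minimal (most specific) roles, and
reachability through more general roles is delivered by the mirrored
subclass edges instead. The mirror adds a "chemical entity by role" top
class as a sibling of the structural root; for each role in use by at
least one seed it mints a compound class (template `"{role} compound"`,
overridable per role — real trees use both "hormone compound" and bare
"antibacterial drug" styles); compound edges follow the in-use role
subgraph, bridging over not-in-use intermediates to the nearest in-use
ancestor; seeds attach under the compounds of their minimal inherited
roles only. Compound ids are deterministic functions of role ids, which
makes the whole operation idempotent.

**Gap reports and the review loop.** The `other_only` mode reproduces the
triage order a curation team actually uses: first the seeds that have
neither a good structural parent (every parent an "other" bucket) nor any
role, then all roleless seeds. Review dispositions are `NR` (persisted as
a subset tag so the term leaves the worklist across releases), an
existing role id, or `NEW:name|parent` where the parent must sit inside
the role branch (its application / biological / chemical categories).

**Maintenance.** `validate_ids` classifies every used id against a new
release as valid, replaced (via `replaced_by`), obsolete without
replacement, merged (found in another term's `alt_id` — checked before
declaring a loss, since merges are how OBO retires duplicates), or
missing; the CLI exits 2 on the last two, which is the build-gate
behavior a weekly update loop needs. No fuzzy name matching is attempted
beyond these two mechanisms. `lint_names` enforces the naming conventions
(lower case unless the word would be capitalized mid-sentence; singular
form) as warnings only; the plural check is a heuristic (final token ends
in "s" but not "ss", with a whitelist), because true plural detection was
human work and should stay reviewable.

## Determinism and numerical conventions

- All sets serialize sorted; siblings order by (name, id) with "other "
  names last; reports sort by (name, id). Outputs are byte-reproducible,
  which keeps weekly release diffs minimal.
- The OBO writer is canonical (terms by id, tags in fixed order) and a
  serialization fixpoint: `parse(write(x))` equals `x` and re-writing
  reproduces the bytes.
- Medians use the lower-middle element for even counts — integer-valued
  for level counts, and the choice is documented rather than consequential.
- Averages keep full precision in the model; rendered reports round to
  one decimal.
- Degenerate inputs: an empty seed set is an error for metrics and
  extraction (the statistics are undefined), valid everywhere else; an
  empty ontology serializes to a header-only document; an empty prune or
  edit script is the identity.

## What the synthetic generator does and does not emulate

`generate_ontology()` builds, deterministically under an explicit private
RNG seed: a structural root and a "role" branch root; a small role
hierarchy; grouping classes attached to random earlier structural terms
(acyclic by construction), with a second parent at probability
`p_multiparent`; one guaranteed single-child chain of length
`max_chain_len` ending in a seed; seed leaves under random groupers; role
assertions at probability `p_role_assertion`; and a few obsolete terms,
half with replacements. The defaults (40 groupers, 15 seeds, chain length
18, multi-parent probability 0.2, 6 roles, role-assertion probability
0.3, obsolete fraction 0.05) are chosen to produce, at desk scale, the
same qualitative pathologies the pipeline targets: pre-slim maximum seed
depths near 19, a majority of single-source-child parents, and a mix of
roleless and role-bearing seeds.

It does **not** attempt statistical fidelity to a real release: degree
distributions, the 100k-term scale, multiple relationship types, textual
definitions and synonym density are all absent. Passing the property
suites therefore demonstrates the algorithms' invariants (ancestry
preservation, depth monotonicity, mirror isomorphism, round-trip
identity), not fitness of any particular real tree — the real tree's
shape also depends on curator judgment encoded in edit scripts.

Test problem sizes: the property corpora use ontologies of ~40 terms
(20 groupers, 8 seeds, chain 6, 5 roles) — 200 of them for ancestry
preservation, 100 for the metrics-oracle, role-mirror, gap and
round-trip suites — with independent oracles implemented as boolean
matrix-power closures and exhaustive path enumeration.

## Known limitations

- OBO 1.4 only; OWL serializations are out of scope, as are
  `intersection_of` and xref semantics.
- One relationship type is modeled. Ontologies whose browse structure
  depends on partonomy or other relations need a different extraction.
- Role inheritance is computed within the extracted ontology; roles
  asserted on ancestors that extraction dropped (because no seed needs
  them structurally) do not contribute. In practice extraction retains
  all seed ancestors, so this only matters for deliberately partial
  inputs.
- The duplicate-placement check reports identical term ids placed under
  multiple branches at one level; it does not detect near-duplicate
  *names*, which remains a lint/curation concern.
- `validate_ids` trusts `replaced_by` and `alt_id`; it will not find a
  replacement that curators renamed without either mechanism.
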