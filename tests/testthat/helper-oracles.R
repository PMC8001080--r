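# Independent oracles and fixture builders for property-style tests.
# The oracles deliberately use different algorithms from the package
# (boolean matrix powers, exhaustive path enumeration, pairwise scans,
# igraph) so agreement is evidence, not tautology.

# build an ontology from a parent map: list(child_id = parent_ids),
# optional role map, seed ids get the curated subset tag, optional names
mk_onto <- function(parents = list(), roles = list(), seeds = character(0),
                    nm = character(0)) {
  ids <- unique(c(names(parents), unlist(parents),
                  names(roles), unlist(roles)))
  terms <- lapply(ids, function(id) {
    onto_term(id,
              name = if (id %in% names(nm)) nm[[id]] else id,
              is_a = if (id %in% names(parents)) parents[[id]] else character(0),
              roles = if (id %in% names(roles)) roles[[id]] else character(0),
              subsets = if (id %in% seeds) "iedb_curated" else character(0))
  })
  ontology(terms)
}

# boolean-matrix transitive closure: M[a, b] TRUE iff b is a strict
# ancestor of a, via repeated boolean matrix products to a fixpoint
closure_oracle <- function(o) {
  ids <- names(o$terms)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (t in o$terms) for (p in t$is_a) A[t$id, p] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# exhaustive enumeration of all root-to-term path lengths (edge counts)
all_root_path_lengths <- function(o, id) {
  ps <- o$terms[[id]]$is_a
  if (length(ps) == 0) {
    return(if (id %in% o$roots) 0L else integer(0))
  }
  unlist(lapply(ps, function(p) all_root_path_lengths(o, p) + 1L))
}

oracle_depth <- function(o, id, mode) {
  L <- all_root_path_lengths(o, id)
  if (mode == "shortest") min(L) else max(L)
}

# brute-force source-bearing children using the closure matrix
oracle_source_bearing <- function(o, id, seeds, R = closure_oracle(o)) {
  kids <- names(o$terms)[vapply(o$terms, function(t) id %in% t$is_a,
                                logical(1))]
  sort(kids[vapply(kids, function(k) {
    k %in% seeds || any(vapply(seeds, function(s) isTRUE(R[s, k]),
                               logical(1)))
  }, logical(1))])
}

lower_median_oracle <- function(x) sort(x)[[(length(x) + 1L) %/% 2L]]

# full independent recomputation of the eight complexity statistics
oracle_metrics <- function(o, seeds, mode) {
  depths <- vapply(seeds, function(s) oracle_depth(o, s, mode), integer(1))
  R <- closure_oracle(o)
  anc <- unique(unlist(lapply(seeds, function(s) names(which(R[s, ])))))
  has_child <- vapply(anc, function(a)
    any(vapply(o$terms, function(t) a %in% t$is_a, logical(1))), logical(1))
  parents <- anc[has_child]
  counts <- vapply(parents, function(p)
    length(oracle_source_bearing(o, p, seeds, R)), integer(1))
  list(source_depth_avg = mean(depths),
       source_depth_median = lower_median_oracle(depths),
       source_depth_max = max(depths),
       source_depth_min = min(depths),
       children_per_parent_avg = mean(counts),
       children_per_parent_median = lower_median_oracle(counts),
       children_per_parent_max = max(counts),
       parents_with_one_source_child = sum(counts == 1L),
       n_sources = length(depths), n_parents = length(counts))
}

# distinct seed descendants of a node (incl. itself), by closure matrix
oracle_entry_count <- function(o, id, seeds, R = closure_oracle(o)) {
  below <- seeds[vapply(seeds, function(s)
    s == id || isTRUE(R[s, id]), logical(1))]
  length(unique(below))
}

live_terms <- function(o) {
  names(o$terms)[!vapply(o$terms, function(t) t$obsolete, logical(1))]
}

# small random-ontology corpus parameters (kept under 60 terms)
corpus_params <- function(seed) {
  generator_params(n_grouping = 20L, n_seeds = 8L, max_chain_len = 6L,
                   p_multiparent = 0.25, n_roles = 5L,
                   p_role_assertion = 0.4, p_obsolete = 0.05,
                   rng_seed = seed)
}

# induced subclass relation among in-use roles, computed with the closure
# oracle: r' is an induced parent of r iff r' is an in-use strict ancestor
# of r and no other in-use strict ancestor of r lies below r'
oracle_induced_role_edges <- function(o, in_use) {
  R <- closure_oracle(o)
  edges <- list()
  for (r in in_use) {
    anc <- in_use[vapply(in_use, function(a) isTRUE(R[r, a]), logical(1))]
    nearest <- anc[vapply(anc, function(a)
      !any(vapply(setdiff(anc, a), function(b) isTRUE(R[b, a]), logical(1))),
      logical(1))]
    for (p in nearest) edges[[length(edges) + 1L]] <- c(r, p)
  }
  if (length(edges) == 0) return(character(0))
  sort(vapply(edges, function(e) paste(e, collapse = "->"), character(1)))
}
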