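#' @keywords internal
"_PACKAGE"

# ---- identifiers -----------------------------------------------------------

#' Check that identifiers are well-formed CURIEs
#'
#' A CURIE is a compact identifier of the form \code{PREFIX:LOCALID}
#' (e.g. \code{"CHEBI:17552"}): exactly one colon separating a non-empty
#' prefix from a non-empty local id. Comparison is always case-sensitive
#' exact string equality.
#'
#' @param ids character vector of candidate identifiers.
#' @return logical vector, one element per input.
#' @examples
#' is_curie(c("CHEBI:17552", "bad", "A:B:C", ":x"))
#' @export
is_curie <- function(ids) {
  if (length(ids) == 0) return(logical(0))
  ok <- !is.na(ids) & nzchar(ids)
  ok & grepl("^[^:]+:[^:]+$", ids)
}

assert_curie <- function(ids, what = "term id") {
  bad <- ids[!is_curie(ids)]
  if (length(bad) > 0) {
    stop(sprintf("malformed %s (not a CURIE): %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

# normalize a character "ordered set": unique, sorted, no NA/empty
norm_set <- function(x) {
  if (is.null(x) || length(x) == 0) return(character(0))
  sort(unique(x[!is.na(x) & nzchar(x)]))
}

# ---- terms -----------------------------------------------------------------

#' Construct a single ontology term
#'
#' @param id CURIE identifier of the term.
#' @param name human-readable class name.
#' @param is_a character vector of structural parent ids (subclass-of edges).
#' @param roles character vector of role-term ids asserted on this term via
#'   the existential pattern \emph{structure subClassOf "has role" some role}.
#' @param alt_ids alternative (merged-in) identifiers.
#' @param obsolete logical; obsolete terms carry no edges in written output.
#' @param replaced_by replacement term id, only meaningful when obsolete.
#' @param subsets OBO subset tags (used e.g. for seed membership and the
#'   persistent "no role" review annotation).
#' @param synonyms synonym lines preserved verbatim.
#' @return a list of class \code{onto_term}.
#' @export
onto_term <- function(id, name = id, is_a = character(0),
                      roles = character(0), alt_ids = character(0),
                      obsolete = FALSE, replaced_by = NA_character_,
                      subsets = character(0), synonyms = character(0)) {
  assert_curie(id)
  is_a <- norm_set(is_a)
  roles <- norm_set(roles)
  if (length(intersect(is_a, roles)) > 0) {
    stop(sprintf("term %s: id(s) appear in both is_a and roles: %s", id,
                 paste(intersect(is_a, roles), collapse = ", ")), call. = FALSE)
  }
  if (!obsolete && !is.na(replaced_by)) {
    stop(sprintf("term %s: replaced_by set on a non-obsolete term", id),
         call. = FALSE)
  }
  if (obsolete) {
    # obsolete terms carry no structural or role edges
    is_a <- character(0)
    roles <- character(0)
  }
  structure(list(
    id = id, name = as.character(name), is_a = is_a, roles = roles,
    alt_ids = norm_set(alt_ids), obsolete = isTRUE(obsolete),
    replaced_by = as.character(replaced_by),
    subsets = norm_set(subsets), synonyms = as.character(synonyms)
  ), class = "onto_term")
}

# ---- ontology container ----------------------------------------------------

#' Construct an ontology from a list of terms
#'
#' The ontology is a rooted, acyclic, multi-parent class graph. Roots are
#' computed, not designated: exactly the non-obsolete terms with no
#' structural parent. Construction validates referential integrity (every
#' id referenced by an \code{is_a} or role assertion must resolve) and
#' acyclicity of the \code{is_a} graph.
#'
#' @param terms list of \code{\link{onto_term}} objects.
#' @param allow_dangling if TRUE, dangling \code{is_a}/role references are
#'   dropped (with a message) instead of raising an error.
#' @return an object of class \code{ontology}: list with elements
#'   \code{terms} (named list, sorted by id) and \code{roots}
#'   (character vector, sorted).
#' @export
ontology <- function(terms = list(), allow_dangling = FALSE) {
  ids <- vapply(terms, function(t) t$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate term id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  names(terms) <- ids
  terms <- terms[order(ids)]
  # referential integrity
  for (t in terms) {
    refs <- c(t$is_a, t$roles)
    dangling <- setdiff(refs, names(terms))
    if (length(dangling) > 0) {
      if (allow_dangling) {
        message(sprintf("dropping dangling reference(s) from %s: %s",
                        t$id, paste(dangling, collapse = ", ")))
        terms[[t$id]]$is_a <- setdiff(t$is_a, dangling)
        terms[[t$id]]$roles <- setdiff(t$roles, dangling)
      } else {
        stop(sprintf("dangling reference(s) from %s: %s",
                     t$id, paste(dangling, collapse = ", ")), call. = FALSE)
      }
    }
  }
  o <- structure(list(terms = terms, roots = character(0)), class = "ontology")
  o$roots <- compute_roots(o)
  assert_acyclic(o)
  o
}

compute_roots <- function(o) {
  r <- vapply(o$terms, function(t) !t$obsolete && length(t$is_a) == 0,
              logical(1))
  if (length(r) == 0) return(character(0))
  sort(names(o$terms)[r])
}

# rebuild derived fields after structural surgery on $terms
rebuild <- function(o) {
  o$terms <- o$terms[order(names(o$terms))]
  o$roots <- compute_roots(o)
  o
}

#' @export
print.ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) t$obsolete, logical(1)))
  cat(sprintf("<ontology> %d terms (%d obsolete), %d root(s): %s\n",
              length(x$terms), n_obs, length(x$roots),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' @export
format.onto_term <- function(x, ...) {
  sprintf("<term %s \"%s\"%s>", x$id, x$name,
          if (x$obsolete) " (obsolete)" else "")
}

#' @export
print.onto_term <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

term_ids <- function(o) names(o$terms)

live_ids <- function(o) {
  ids <- names(o$terms)
  ids[!vapply(o$terms, function(t) t$obsolete, logical(1))]
}

check_known <- function(o, ids) {
  unknown <- setdiff(ids, names(o$terms))
  if (length(unknown) > 0) {
    stop(sprintf("unknown term id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

# ---- graph queries ---------------------------------------------------------

#' Direct structural parents of a term
#'
#' @param o an \code{\link{ontology}}.
#' @param id a term id.
#' @return character vector of parent ids (empty for roots).
#' @export
onto_parents <- function(o, id) {
  check_known(o, id)
  o$terms[[id]]$is_a
}

# child index: named list id -> character vector of direct children.
# Obsolete terms have no is_a, so they contribute no edges.
child_index <- function(o) {
  idx <- lapply(o$terms, function(t) character(0))
  for (t in o$terms) {
    for (p in t$is_a) idx[[p]] <- c(idx[[p]], t$id)
  }
  lapply(idx, sort)
}

#' Direct structural children of a term
#'
#' @inheritParams onto_parents
#' @return character vector of child ids, sorted.
#' @export
onto_children <- function(o, id) {
  check_known(o, id)
  kids <- character(0)
  for (t in o$terms) if (id %in% t$is_a) kids <- c(kids, t$id)
  sort(kids)
}

#' Ancestors (transitive closure of parents)
#'
#' Subclass-of is transitive: an owl is a bird and a bird is a vertebrate,
#' so the owl's ancestors include both. The term itself is excluded.
#'
#' @inheritParams onto_parents
#' @return sorted character vector of strict ancestor ids.
#' @export
onto_ancestors <- function(o, id) {
  check_known(o, id)
  seen <- character(0)
  frontier <- o$terms[[id]]$is_a
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, function(p) o$terms[[p]]$is_a),
                         use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(seen)
}

#' Descendants (transitive closure of children)
#'
#' @inheritParams onto_parents
#' @return sorted character vector of strict descendant ids.
#' @export
onto_descendants <- function(o, id) {
  check_known(o, id)
  idx <- child_index(o)
  seen <- character(0)
  frontier <- idx[[id]]
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    nxt <- unique(unlist(idx[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(seen)
}

# full ancestor closure for every term at once (repeated-BFS-free DP over a
# topological order); returns named list id -> sorted ancestor ids
ancestor_closure <- function(o) {
  ord <- topo_order(o)
  anc <- lapply(o$terms, function(t) character(0))
  for (id in ord) {
    ps <- o$terms[[id]]$is_a
    if (length(ps) > 0) {
      anc[[id]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
    }
  }
  anc
}

# topological order of the is_a graph, parents before children
topo_order <- function(o) {
  ids <- names(o$terms)
  indeg <- vapply(o$terms, function(t) length(t$is_a), integer(1))
  idx <- child_index(o)
  queue <- sort(ids[indeg == 0])
  out <- character(0)
  while (length(queue) > 0) {
    id <- queue[1]; queue <- queue[-1]
    out <- c(out, id)
    for (k in idx[[id]]) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- sort(c(queue, k))
    }
  }
  if (length(out) != length(ids)) {
    stop("is_a graph contains a cycle", call. = FALSE)
  }
  out
}

#' Verify that the is_a graph is acyclic
#'
#' Returns invisibly on success; on failure raises an error reporting one
#' full cycle path (e.g. \code{A -> B -> A}).
#'
#' @param o an \code{\link{ontology}}.
#' @export
assert_acyclic <- function(o) {
  ids <- names(o$terms)
  color <- stats::setNames(rep(0L, length(ids)), ids)  # 0 white 1 grey 2 black
  # iterative DFS keeping the grey path for cycle reporting
  for (start in ids) {
    if (color[[start]] != 0L) next
    stack <- list(list(id = start, next_i = 1L))
    color[[start]] <- 1L
    path <- start
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      ps <- o$terms[[top$id]]$is_a
      if (top$next_i > length(ps)) {
        color[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      } else {
        stack[[length(stack)]]$next_i <- top$next_i + 1L
        nxt <- ps[[top$next_i]]
        if (color[[nxt]] == 1L) {
          cyc <- c(path[which(path == nxt):length(path)], nxt)
          stop(sprintf("cycle in is_a graph: %s", paste(cyc, collapse = " -> ")),
               call. = FALSE)
        } else if (color[[nxt]] == 0L) {
          color[[nxt]] <- 1L
          stack[[length(stack) + 1L]] <- list(id = nxt, next_i = 1L)
          path <- c(path, nxt)
        }
      }
    }
  }
  invisible(o)
}

#' Direct children that are, or lead to, curated seed terms
#'
#' A child of \code{id} is \emph{source-bearing} when it is itself a seed
#' or has at least one seed among its descendants. This is the child count
#' behind the "parents with one source child" complexity statistic.
#'
#' @inheritParams onto_parents
#' @param seeds character vector of seed (curated "source") term ids.
#' @return sorted character vector of source-bearing child ids.
#' @export
source_bearing_children <- function(o, id, seeds) {
  check_known(o, id)
  kids <- onto_children(o, id)
  if (length(kids) == 0 || length(seeds) == 0) return(character(0))
  bearing <- source_bearing_set(o, seeds)
  sort(intersect(kids, bearing))
}

# all terms that are seeds or have a seed descendant
source_bearing_set <- function(o, seeds) {
  if (length(seeds) == 0) return(character(0))
  seen <- intersect(seeds, names(o$terms))
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(s) o$terms[[s]]$is_a),
                         use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- union(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Depth of a term below the roots
#'
#' Each subclass-of edge creates a new level; a root sits at depth 0.
#' In a multi-parent graph a term may be reachable along several paths,
#' so both the shortest-path depth (default; the shallowest placement a
#' browser user can reach) and the longest-path depth are available.
#'
#' @inheritParams onto_parents
#' @param mode \code{"shortest"} or \code{"longest"}.
#' @return integer edge count from a root to \code{id}.
#' @export
onto_depth <- function(o, id, mode = c("shortest", "longest")) {
  mode <- match.arg(mode)
  check_known(o, id)
  d <- depth_table(o, mode)
  if (is.na(d[[id]])) {
    stop(sprintf("term %s is not reachable from any root", id), call. = FALSE)
  }
  d[[id]]
}

# depths of all terms at once; NA for unreachable (e.g. obsolete) terms
depth_table <- function(o, mode = c("shortest", "longest")) {
  mode <- match.arg(mode)
  ids <- names(o$terms)
  d <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  d[o$roots] <- 0L
  comb <- if (mode == "shortest") min else max
  for (id in topo_order(o)) {
    ps <- o$terms[[id]]$is_a
    if (length(ps) == 0) next
    pd <- d[ps]
    pd <- pd[!is.na(pd)]
    if (length(pd) > 0) d[[id]] <- comb(pd) + 1L
  }
  d
}

#' Most-specific members of a term set
#'
#' Drops every member that is a strict ancestor of another member, leaving
#' only minimal (most specific) terms. Used to place a compound under its
#' most specific role only.
#'
#' @inheritParams onto_parents
#' @param ids character vector of term ids.
#' @return sorted character vector, subset of \code{ids}.
#' @export
minimal_terms <- function(o, ids) {
  ids <- unique(ids)
  check_known(o, ids)
  if (length(ids) <= 1) return(sort(ids))
  keep <- vapply(ids, function(a) {
    # drop a if a is a strict ancestor of some other member
    !any(vapply(setdiff(ids, a),
                function(b) a %in% onto_ancestors(o, b), logical(1)))
  }, logical(1))
  sort(ids[keep])
}
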