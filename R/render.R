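# Browsable tree rendering: a DAG viewed as a tree (a term with k parents
# appears once under each parent), each node labelled with its number of
# distinct curated entries, "other ..." catch-all nodes always listed last
# among their siblings.

is_other_name <- function(nm) startsWith(tolower(nm), "other ")

# sibling ordering: lexicographic by name, "other ..." last, id tiebreak
order_siblings <- function(o, ids) {
  if (length(ids) == 0) return(ids)
  nms <- vapply(ids, function(i) o$terms[[i]]$name, character(1))
  oth <- vapply(nms, is_other_name, logical(1))
  ids[order(oth, nms, ids, method = "radix")]
}

#' Render an ontology as a browsable tree
#'
#' Produces the nested view a tree browser shows: every node carries its
#' name and the number of distinct curated (seed) entries below it,
#' counting the node itself when it is a seed — the per-branch entry count
#' displayed at the end of each branch label. Children are ordered
#' alphabetically except that \code{"other ..."} buckets sort last.
#' A multi-parent term appears once under each of its parents.
#'
#' @param o an \code{\link{ontology}}.
#' @param seeds character vector of curated seed ids.
#' @param roots ids to render from; defaults to the ontology roots.
#' @return an object of class \code{rendered_tree}: list of nested nodes,
#'   each \code{list(id, name, entry_count, children)}.
#' @export
render_tree <- function(o, seeds, roots = NULL) {
  if (is.null(roots)) roots <- o$roots
  check_known(o, roots)
  seeds <- intersect(seeds, names(o$terms))
  idx <- child_index(o)
  # distinct-seed-descendant count per term (incl. self if seed)
  desc_seeds <- new.env(parent = emptyenv())
  count_for <- function(id) {
    if (!is.null(desc_seeds[[id]])) return(desc_seeds[[id]])
    s <- if (id %in% seeds) id else character(0)
    s <- union(s, unlist(lapply(idx[[id]], count_for_set), use.names = FALSE))
    desc_seeds[[id]] <- s
    s
  }
  count_for_set <- function(id) count_for(id)
  build <- function(id) {
    kids <- order_siblings(o, idx[[id]])
    list(id = id, name = o$terms[[id]]$name,
         entry_count = length(count_for(id)),
         children = lapply(kids, build))
  }
  structure(lapply(order_siblings(o, roots), build), class = "rendered_tree")
}

#' Format a rendered tree as an indented plain-text outline
#' @param x a \code{rendered_tree}.
#' @param ... unused.
#' @return character scalar, one line per node occurrence.
#' @export
format.rendered_tree <- function(x, ...) {
  lines <- character(0)
  walk <- function(node, depth) {
    lines <<- c(lines, sprintf("%s%s (%d)", strrep("  ", depth),
                               node$name, node$entry_count))
    for (k in node$children) walk(k, depth + 1L)
  }
  for (n in x) walk(n, 0L)
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.rendered_tree <- function(x, ...) { cat(format(x)); invisible(x) }

#' Flatten a rendered tree to a structured list (JSON-ready)
#' @param x a \code{rendered_tree}.
#' @param ... unused.
#' @return plain nested list without the class attribute.
#' @export
as.list.rendered_tree <- function(x, ...) lapply(unclass(x), identity)
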