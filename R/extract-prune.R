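# The structure-tree slimming pipeline: seed-closure extraction, automatic
# pruning of uncurated grouping chains, "other"-bucket synthesis, scripted
# manual reorganization, and duplicate-placement checking.

#' Pruning configuration
#'
#' @param max_spliceable_children a non-seed grouping class is spliced out
#'   when its source-bearing-children count is at most this (default 1:
#'   remove single-lineage chains, keep genuinely branching groupers).
#' @param other_bucket_min minimum number of ungrouped leaf children needed
#'   before an "other ..." bucket is created under a parent (default 3).
#' @param protected term ids never removed (manually retained checkpoints).
#' @param level_cap_for_duplicates tree level at which repeated placements
#'   are reported (default 2: no level-2 node should be repeated).
#' @param count_mode \code{"source_bearing"} counts only children that are
#'   or lead to seeds (default); \code{"raw"} counts all children.
#' @param namespace CURIE prefix for minted ids (buckets, created classes).
#' @return a list of class \code{prune_config}.
#' @export
prune_config <- function(max_spliceable_children = 1L,
                         other_bucket_min = 3L,
                         protected = character(0),
                         level_cap_for_duplicates = 2L,
                         count_mode = c("source_bearing", "raw"),
                         namespace = "IEDB") {
  stopifnot(max_spliceable_children >= 0, other_bucket_min >= 1,
            level_cap_for_duplicates >= 1)
  structure(list(
    max_spliceable_children = as.integer(max_spliceable_children),
    other_bucket_min = as.integer(other_bucket_min),
    protected = norm_set(protected),
    level_cap_for_duplicates = as.integer(level_cap_for_duplicates),
    count_mode = match.arg(count_mode),
    namespace = namespace
  ), class = "prune_config")
}

# terms belonging to the role hierarchy: role-assertion targets, their
# ancestors, and all descendants of any root named "role". These are never
# structure-tree grouping classes, so pruning leaves them alone.
role_branch_terms <- function(o) {
  targets <- unique(unlist(lapply(o$terms, function(t) t$roles),
                           use.names = FALSE))
  out <- targets
  for (r in targets) out <- union(out, onto_ancestors(o, r))
  for (rt in o$roots) {
    if (identical(tolower(o$terms[[rt]]$name), "role")) {
      out <- union(out, c(rt, onto_descendants(o, rt)))
    }
  }
  sort(out)
}

#' Extract the curated subset of an ontology
#'
#' Keeps only the seeds, their structural ancestors (the grouping classes
#' needed to organize them), the role terms any retained term points at,
#' and those roles' ancestors. Obsolete terms are never retained. All
#' is_a and role references of retained terms are restricted to the
#' retained set.
#'
#' @param o an \code{\link{ontology}}.
#' @param seeds non-empty character vector of curated term ids.
#' @return the extracted \code{\link{ontology}}.
#' @export
extract_subset <- function(o, seeds) {
  if (length(seeds) == 0) stop("seed set is empty", call. = FALSE)
  missing <- setdiff(seeds, names(o$terms))
  if (length(missing) > 0) {
    stop(sprintf("unresolvable seed id(s): %s",
                 paste(sort(missing), collapse = ", ")), call. = FALSE)
  }
  keep <- seeds
  for (s in seeds) keep <- union(keep, onto_ancestors(o, s))
  roles <- unique(unlist(lapply(keep, function(i) o$terms[[i]]$roles),
                         use.names = FALSE))
  for (r in roles) keep <- union(keep, c(r, onto_ancestors(o, r)))
  keep <- keep[!vapply(keep, function(i) o$terms[[i]]$obsolete, logical(1))]
  terms <- lapply(sort(keep), function(i) {
    t <- o$terms[[i]]
    t$is_a <- intersect(t$is_a, keep)
    t$roles <- intersect(t$roles, keep)
    t
  })
  ontology(terms)
}

# splice one term: remove it, re-attach its children to all of its parents
# (duplicate edges collapse), push its role assertions down to the children
# so descendants' inherited roles are preserved.
splice_term <- function(o, id) {
  t <- o$terms[[id]]
  parents <- t$is_a
  kids <- onto_children(o, id)
  for (c in kids) {
    ct <- o$terms[[c]]
    ct$is_a <- norm_set(c(setdiff(ct$is_a, id), parents))
    ct$roles <- norm_set(c(ct$roles, setdiff(t$roles, ct$is_a)))
    o$terms[[c]] <- ct
  }
  o$terms[[id]] <- NULL
  # drop role assertions pointing at the removed term (it is no grouping
  # class's role target in practice; defensive)
  for (i in names(o$terms)) {
    if (id %in% o$terms[[i]]$roles) {
      o$terms[[i]]$roles <- setdiff(o$terms[[i]]$roles, id)
    }
  }
  list(ontology = rebuild(o), parents = parents, children = kids)
}

#' Automatically prune uncurated grouping chains
#'
#' Iterates to a fixpoint: every non-seed, non-protected, non-root grouping
#' class whose source-bearing-children count is at most
#' \code{max_spliceable_children} is spliced out, its children re-attached
#' to all of its parents. This removes the "dig down one level at a time"
#' chains of intermediate classes while preserving every seed, all
#' seed-to-surviving-class ancestry, and never increasing any seed's depth.
#' Role-branch terms are left untouched.
#'
#' @param o an \code{\link{ontology}} (typically the output of
#'   \code{\link{extract_subset}}; a superset is tolerated).
#' @param seeds curated term ids.
#' @param config a \code{\link{prune_config}}.
#' @return list with elements \code{ontology} and \code{log} (a data.frame
#'   with one row per removed term: id, parents and children at removal,
#'   semicolon-joined).
#' @export
prune_chains <- function(o, seeds, config = prune_config()) {
  check_known(o, intersect(seeds, names(o$terms)))
  log_rows <- list()
  repeat {
    changed <- FALSE
    untouchable <- union(config$protected, union(seeds, role_branch_terms(o)))
    for (id in names(o$terms)) {
      t <- o$terms[[id]]
      if (t$obsolete || id %in% untouchable || length(t$is_a) == 0) next
      n <- if (config$count_mode == "raw") length(onto_children(o, id)) else
        length(source_bearing_children(o, id, seeds))
      if (n <= config$max_spliceable_children) {
        res <- splice_term(o, id)
        o <- res$ontology
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          removed = id,
          parents = paste(res$parents, collapse = ";"),
          children = paste(res$children, collapse = ";"),
          stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  log <- if (length(log_rows) == 0) {
    data.frame(removed = character(0), parents = character(0),
               children = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, log_rows)
  list(ontology = o, log = log)
}

mint_bucket_id <- function(namespace, parent_id) {
  sprintf("%s:other-%s", namespace, gsub(":", "-", parent_id, fixed = TRUE))
}

#' Synthesize "other" catch-all classes
#'
#' For every parent that mixes named grouping subclasses with a clutter of
#' ungrouped bottom-level children, collects those children under a new
#' \code{"other <parent name>"} class (e.g. the 14 monosaccharides that fit
#' none of monosaccharide's 7 named categories go under
#' \code{"other monosaccharide"}). A child is \emph{ungrouped} when it is a
#' seed or a leaf and none of its other parents is a grouping class below
#' the same parent. Buckets never nest inside other buckets, reuse an
#' existing \code{"other ..."} sibling of the same name, and the operation
#' is idempotent.
#'
#' @inheritParams prune_chains
#' @return the updated \code{\link{ontology}}.
#' @export
make_other_buckets <- function(o, seeds, config = prune_config()) {
  seeds <- intersect(seeds, names(o$terms))
  role_terms <- role_branch_terms(o)
  for (pid in names(o$terms)) {
    p <- o$terms[[pid]]
    if (p$obsolete || is_other_name(p$name) || pid %in% role_terms) next
    kids <- onto_children(o, pid)
    kids <- kids[!vapply(kids, function(k)
      is_other_name(o$terms[[k]]$name), logical(1))]
    if (length(kids) == 0) next
    is_candidate <- vapply(kids, function(k) {
      if (!(k %in% seeds) && length(onto_children(o, k)) > 0) return(FALSE)
      # other parents that are grouping classes under pid would already
      # give this child a specific placement within the branch
      below <- onto_descendants(o, pid)
      others <- setdiff(o$terms[[k]]$is_a, pid)
      !any(others %in% setdiff(below, seeds))
    }, logical(1))
    grouping_kids <- kids[!(kids %in% seeds) & !is_candidate]
    candidates <- kids[is_candidate]
    if (length(grouping_kids) == 0 ||
        length(candidates) < config$other_bucket_min) next
    bucket_name <- paste0("other ", p$name)
    existing <- onto_children(o, pid)
    reuse <- existing[vapply(existing, function(k)
      identical(o$terms[[k]]$name, bucket_name), logical(1))]
    bid <- if (length(reuse) > 0) reuse[[1]] else
      mint_bucket_id(config$namespace, pid)
    if (is.null(o$terms[[bid]])) {
      o$terms[[bid]] <- onto_term(bid, name = bucket_name, is_a = pid)
    }
    for (k in candidates) {
      o$terms[[k]]$is_a <- norm_set(c(setdiff(o$terms[[k]]$is_a, pid), bid))
    }
    o <- rebuild(o)
  }
  o
}

# ---- edit scripts ----------------------------------------------------------

resolve_target <- function(o, x, step_i) {
  if (is.null(x)) {
    stop(sprintf("edit script step %d: missing target", step_i), call. = FALSE)
  }
  if (!is.null(o$terms[[x]])) return(x)
  hits <- names(o$terms)[vapply(o$terms, function(t)
    identical(t$name, x), logical(1))]
  if (length(hits) == 1) return(hits)
  stop(sprintf("edit script step %d: target '%s' %s", step_i, x,
               if (length(hits) == 0) "does not resolve"
               else "is ambiguous"), call. = FALSE)
}

as_chr <- function(x) if (is.null(x)) character(0) else
  unlist(x, use.names = FALSE)

#' Apply a reviewed edit script
#'
#' Replays manual reorganizations (moves, merges, renames, class creation,
#' splices, bucket creation) in order. Each step must resolve at its
#' application time; a step that would introduce a subclass cycle aborts
#' with an error naming the cycle.
#'
#' @param o an \code{\link{ontology}}.
#' @param script an \code{edit_script} from \code{\link{parse_edit_script}}.
#' @param config a \code{\link{prune_config}} (namespace for minted ids).
#' @return the edited \code{\link{ontology}}.
#' @export
apply_edit_script <- function(o, script, config = prune_config()) {
  for (i in seq_along(script)) {
    s <- script[[i]]
    o <- tryCatch(
      apply_edit_step(o, s, i, config),
      error = function(e) {
        stop(sprintf("edit script step %d (%s): %s", i, s$op,
                     conditionMessage(e)), call. = FALSE)
      })
  }
  o
}

apply_edit_step <- function(o, s, i, config) {
  op <- s$op
  if (op %in% c("remove_class", "splice_class")) {
    id <- resolve_target(o, s$target, i)
    o <- splice_term(o, id)$ontology
  } else if (op == "rename") {
    id <- resolve_target(o, s$target, i)
    o$terms[[id]]$name <- as.character(s$new_name)
  } else if (op == "move_term") {
    id <- resolve_target(o, s$target, i)
    t <- o$terms[[id]]
    if (!is.null(s$new_parents)) {
      t$is_a <- norm_set(vapply(as_chr(s$new_parents),
                                resolve_target, character(1), o = o, step_i = i))
    } else {
      add <- vapply(as_chr(s$add_parent), resolve_target, character(1),
                    o = o, step_i = i)
      rem <- vapply(as_chr(s$remove_parent), resolve_target, character(1),
                    o = o, step_i = i)
      t$is_a <- norm_set(c(setdiff(t$is_a, rem), add))
    }
    o$terms[[id]] <- t
  } else if (op == "add_parent") {
    id <- resolve_target(o, s$target, i)
    p <- resolve_target(o, s$parent, i)
    o$terms[[id]]$is_a <- norm_set(c(o$terms[[id]]$is_a, p))
  } else if (op == "remove_parent") {
    id <- resolve_target(o, s$target, i)
    p <- resolve_target(o, s$parent, i)
    o$terms[[id]]$is_a <- setdiff(o$terms[[id]]$is_a, p)
  } else if (op == "merge_classes") {
    survivor <- resolve_target(o, s$target, i)
    merged <- vapply(as_chr(s$merge), resolve_target, character(1),
                     o = o, step_i = i)
    for (m in setdiff(merged, survivor)) {
      mt <- o$terms[[m]]
      for (k in onto_children(o, m)) {
        o$terms[[k]]$is_a <- norm_set(
          c(setdiff(o$terms[[k]]$is_a, m), survivor))
      }
      st <- o$terms[[survivor]]
      st$alt_ids <- norm_set(c(st$alt_ids, m, mt$alt_ids))
      st$roles <- norm_set(c(st$roles, setdiff(mt$roles, st$is_a)))
      o$terms[[survivor]] <- st
      o$terms[[m]] <- NULL
      for (j in names(o$terms)) {
        if (m %in% o$terms[[j]]$roles) {
          o$terms[[j]]$roles <- norm_set(
            c(setdiff(o$terms[[j]]$roles, m), survivor))
        }
        if (m %in% o$terms[[j]]$is_a) {
          o$terms[[j]]$is_a <- norm_set(
            c(setdiff(o$terms[[j]]$is_a, m), survivor))
        }
      }
    }
  } else if (op == "create_class") {
    id <- if (!is.null(s$id)) s$id else
      sprintf("%s:%s", config$namespace,
              gsub("[^A-Za-z0-9]+", "-", tolower(s$name)))
    parents <- vapply(as_chr(s$parents), resolve_target, character(1),
                      o = o, step_i = i)
    if (is.null(o$terms[[id]])) {
      o$terms[[id]] <- onto_term(id, name = s$name, is_a = parents)
    } else {
      o$terms[[id]]$name <- as.character(s$name)
      o$terms[[id]]$is_a <- norm_set(c(o$terms[[id]]$is_a, parents))
    }
  } else if (op == "create_other_bucket") {
    pid <- resolve_target(o, s$target, i)
    bucket_name <- paste0("other ", o$terms[[pid]]$name)
    bid <- mint_bucket_id(config$namespace, pid)
    if (is.null(o$terms[[bid]])) {
      o$terms[[bid]] <- onto_term(bid, name = bucket_name, is_a = pid)
    }
    for (m in as_chr(s$members)) {
      mid <- resolve_target(o, m, i)
      o$terms[[mid]]$is_a <- norm_set(
        c(setdiff(o$terms[[mid]]$is_a, pid), bid))
    }
  } else {
    stop(sprintf("unknown op '%s'", op))
  }
  o <- rebuild(o)
  assert_acyclic(o)
  o
}

# ---- duplicate placements --------------------------------------------------

#' Report terms repeated across branches at a given level
#'
#' A design goal of the simplified tree is that no level-2 node is repeated
#' (with reviewed exceptions such as glycolipid, reachable from both the
#' lipid and the carbohydrate branches). This reports every term that sits
#' at the given level under two or more distinct parents.
#'
#' @param o an \code{\link{ontology}}.
#' @param level tree level to check (root = level 0; default 2).
#' @param exceptions term ids excluded from the report.
#' @return data.frame with columns id, name, placements (parent names,
#'   semicolon-joined), sorted by (name, id).
#' @export
duplicate_placement_report <- function(o, level = 2L,
                                       exceptions = character(0)) {
  stopifnot(level >= 1)
  d <- depth_table(o, "shortest")
  rows <- list()
  for (id in names(o$terms)) {
    if (id %in% exceptions || o$terms[[id]]$obsolete) next
    ps <- o$terms[[id]]$is_a
    at_level <- ps[!is.na(d[ps]) & d[ps] == level - 1L]
    if (length(at_level) >= 2) {
      nms <- sort(vapply(at_level, function(p) o$terms[[p]]$name,
                         character(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, name = o$terms[[id]]$name,
        placements = paste(nms, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(id = character(0), name = character(0),
               placements = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out[order(out$name, out$id), , drop = FALSE]
}

# ---- orchestrator ----------------------------------------------------------

#' Run the full slimming pipeline
#'
#' Composition, in order: \code{\link{extract_subset}} (seed closure),
#' \code{\link{prune_chains}} (automatic chain removal),
#' \code{\link{make_other_buckets}} (catch-all synthesis),
#' \code{\link{apply_edit_script}} (reviewed manual reorganizations), then
#' the duplicate-placement check, a rendered tree, and complexity metrics.
#'
#' @inheritParams prune_chains
#' @param script optional \code{edit_script}.
#' @param level_exceptions ids excluded from the duplicate report.
#' @return list: \code{ontology}, \code{log}, \code{duplicates},
#'   \code{rendered}, \code{metrics}.
#' @export
slim <- function(o, seeds, config = prune_config(), script = NULL,
                 level_exceptions = character(0)) {
  o <- extract_subset(o, seeds)
  pr <- prune_chains(o, seeds, config)
  o <- make_other_buckets(pr$ontology, seeds, config)
  if (!is.null(script) && length(script) > 0) {
    o <- apply_edit_script(o, script, config)
  }
  list(
    ontology = o,
    log = pr$log,
    duplicates = duplicate_placement_report(
      o, config$level_cap_for_duplicates, level_exceptions),
    rendered = render_tree(o, seeds),
    metrics = if (length(intersect(seeds, names(o$terms))) > 0)
      tree_metrics(o, intersect(seeds, names(o$terms))) else NULL
  )
}
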