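# Role materialization: turn "has role" existential assertions into a
# browsable "chemical entity by role" hierarchy, report curated compounds
# lacking any role, and ingest reviewed role assignments.

#' Roles asserted directly on a term
#'
#' The targets of the term's own \emph{"has role" some ...} assertions
#' (e.g. amoxicillin has role antibacterial drug).
#'
#' @param o an \code{\link{ontology}}.
#' @param id a term id.
#' @return sorted character vector of role term ids.
#' @export
direct_roles <- function(o, id) {
  check_known(o, id)
  o$terms[[id]]$roles
}

#' Roles inherited through the structural hierarchy
#'
#' A compound belongs in the role-browsing hierarchy when it, or one of its
#' structural ancestors, carries a role axiom. This is the assertion-level
#' union over the term and its ancestors; the role hierarchy itself is not
#' closed over (reachability across roles is delivered by the mirrored
#' subclass edges instead).
#'
#' @inheritParams direct_roles
#' @return sorted character vector of role term ids.
#' @export
inherited_roles <- function(o, id) {
  check_known(o, id)
  scope <- c(id, onto_ancestors(o, id))
  norm_set(unlist(lapply(scope, function(i) o$terms[[i]]$roles),
                  use.names = FALSE))
}

#' Role-mirroring configuration
#'
#' @param namespace CURIE prefix for minted compound-class ids.
#' @param structural_root id of the "chemical entity"-like root; when NULL
#'   it is auto-detected (the unique root that is not the role branch or a
#'   previously minted compound top).
#' @param role_root id of the role branch root; when NULL, a root named
#'   "role" is used if present.
#' @param top_name name of the browsable top class added as a sibling of
#'   the structural root.
#' @param template compound-class naming template; \code{\{role\}} is
#'   replaced by the role name.
#' @param overrides named character vector role id -> compound name,
#'   overriding the template per role.
#' @return a list of class \code{mirror_config}.
#' @export
mirror_config <- function(namespace = "IEDB", structural_root = NULL,
                          role_root = NULL,
                          top_name = "chemical entity by role",
                          template = "{role} compound",
                          overrides = character(0)) {
  structure(list(namespace = namespace, structural_root = structural_root,
                 role_root = role_root, top_name = top_name,
                 template = template, overrides = overrides),
            class = "mirror_config")
}

compound_top_id <- function(cfg) sprintf("%s:by-role", cfg$namespace)

compound_id_for <- function(cfg, role_id) {
  sprintf("%s:cmp-%s", cfg$namespace, gsub(":", "-", role_id, fixed = TRUE))
}

compound_name_for <- function(cfg, o, role_id) {
  if (role_id %in% names(cfg$overrides)) return(cfg$overrides[[role_id]])
  sub("{role}", o$terms[[role_id]]$name, cfg$template, fixed = TRUE)
}

detect_structural_root <- function(o, cfg) {
  if (!is.null(cfg$structural_root)) {
    check_known(o, cfg$structural_root)
    return(cfg$structural_root)
  }
  cand <- setdiff(o$roots, compound_top_id(cfg))
  cand <- cand[!vapply(cand, function(r)
    identical(tolower(o$terms[[r]]$name), "role"), logical(1))]
  if (length(cand) != 1) {
    stop(sprintf(
      "cannot designate the structural root (candidates: %s); set structural_root",
      paste(cand, collapse = ", ")), call. = FALSE)
  }
  cand
}

detect_role_root <- function(o, cfg) {
  if (!is.null(cfg$role_root)) {
    check_known(o, cfg$role_root)
    return(cfg$role_root)
  }
  cand <- o$roots[vapply(o$roots, function(r)
    identical(tolower(o$terms[[r]]$name), "role"), logical(1))]
  if (length(cand) == 1) return(cand)
  stop("cannot locate the role branch root; set role_root", call. = FALSE)
}

#' Materialize roles into a browsable compound hierarchy
#'
#' Role axioms are anonymous-parent assertions and cannot be browsed. This
#' adds a top class (by default "chemical entity by role") as a sibling of
#' the structural root and, for every role held directly or by inheritance
#' by at least one seed, a mirrored compound class (by default named
#' \emph{"<role> compound"}, so progesterone becomes browsable under
#' "hormone compound"). Compound subclass edges mirror the role hierarchy
#' restricted to in-use roles: a role whose nearest in-use ancestors are
#' deeper in the hierarchy is bridged to their compounds, and roles with no
#' in-use ancestor attach to the top class. Each seed is attached under the
#' compounds of its minimal (most specific) inherited roles only; its
#' structural placements are untouched. Re-running on a mirrored ontology
#' changes nothing.
#'
#' @param o an \code{\link{ontology}}.
#' @param seeds curated term ids.
#' @param cfg a \code{\link{mirror_config}}.
#' @return list: \code{ontology} (mirrored) and \code{map} (data.frame
#'   role id -> compound id + name).
#' @export
mirror_roles <- function(o, seeds, cfg = mirror_config()) {
  seeds <- intersect(seeds, names(o$terms))
  sroot <- detect_structural_root(o, cfg)
  top_id <- compound_top_id(cfg)
  inh <- stats::setNames(lapply(seeds, function(s) inherited_roles(o, s)),
                         seeds)
  in_use <- norm_set(unlist(inh, use.names = FALSE))
  # top class: sibling of the structural root
  if (is.null(o$terms[[top_id]])) {
    o$terms[[top_id]] <- onto_term(top_id, name = cfg$top_name,
                                   is_a = o$terms[[sroot]]$is_a)
  }
  map <- data.frame(role = character(0), compound = character(0),
                    name = character(0), stringsAsFactors = FALSE)
  for (r in in_use) {
    cid <- compound_id_for(cfg, r)
    cname <- compound_name_for(cfg, o, r)
    # bridge to the nearest (most specific) in-use ancestor roles
    anc_in_use <- intersect(onto_ancestors(o, r), in_use)
    nearest <- if (length(anc_in_use) > 0) minimal_terms(o, anc_in_use)
               else character(0)
    cparents <- if (length(nearest) > 0)
      vapply(nearest, function(a) compound_id_for(cfg, a), character(1))
    else top_id
    if (is.null(o$terms[[cid]])) {
      o$terms[[cid]] <- onto_term(cid, name = cname, is_a = cparents)
    } else {
      o$terms[[cid]]$name <- cname
      o$terms[[cid]]$is_a <- norm_set(cparents)
    }
    map <- rbind(map, data.frame(role = r, compound = cid, name = cname,
                                 stringsAsFactors = FALSE))
  }
  # attach each seed under its minimal inherited roles' compounds
  for (s in seeds) {
    rs <- inh[[s]]
    if (length(rs) == 0) next
    mins <- minimal_terms(o, rs)
    cids <- vapply(mins, function(r) compound_id_for(cfg, r), character(1))
    o$terms[[s]]$is_a <- norm_set(c(o$terms[[s]]$is_a, cids))
  }
  o <- rebuild(o)
  assert_acyclic(o)
  list(ontology = o, map = map[order(map$role), , drop = FALSE])
}

#' Report curated compounds with no assigned role
#'
#' The curation loop's work queue: seeds whose inherited role set is empty
#' (and that have not already been reviewed and marked "no role"). The
#' first-pass mode \code{"other_only"} restricts to seeds without a good
#' structural parent — those sitting only under "other ..." catch-all
#' classes. Columns follow the review-spreadsheet layout: id, a
#' database-link string, name, structural parent names, and disposition.
#'
#' @param o an \code{\link{ontology}}.
#' @param seeds curated term ids.
#' @param mode \code{"all"} or \code{"other_only"}.
#' @param link_template link column template; \code{\{id\}} is substituted.
#' @param nr_subset subset tag that marks reviewed no-role terms.
#' @return data.frame with columns id, link, name, parents, disposition,
#'   sorted by (name, id).
#' @export
role_gap_report <- function(o, seeds, mode = c("all", "other_only"),
                            link_template = "https://www.iedb.org/epitope/{id}",
                            nr_subset = "no_role") {
  mode <- match.arg(mode)
  seeds <- intersect(seeds, names(o$terms))
  rows <- list()
  for (s in sort(seeds)) {
    t <- o$terms[[s]]
    if (t$obsolete || nr_subset %in% t$subsets) next
    if (length(inherited_roles(o, s)) > 0) next
    if (mode == "other_only") {
      ps <- t$is_a
      if (length(ps) == 0) next
      if (!all(vapply(ps, function(p) is_other_name(o$terms[[p]]$name),
                      logical(1)))) next
    }
    pnames <- sort(vapply(t$is_a, function(p) o$terms[[p]]$name, character(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      id = s,
      link = sub("{id}", s, link_template, fixed = TRUE),
      name = t$name,
      parents = paste(pnames, collapse = ";"),
      disposition = "unreviewed",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(id = character(0), link = character(0), name = character(0),
               parents = character(0), disposition = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out[order(out$name, out$id), , drop = FALSE]
}

#' Read a reviewed role-assignment file
#'
#' Tab-separated with a header; needs an id column and a disposition
#' column (\code{disposition} or \code{assigned_disposition}, so a filled
#' gap report can be fed straight back). Disposition grammar:
#' \code{"NR"} | an existing role CURIE | \code{"NEW:name|parentCURIE"}.
#'
#' @param text file path or TSV text.
#' @return data.frame with columns id, disposition.
#' @export
read_role_assignments <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(id = character(0), disposition = character(0),
                      stringsAsFactors = FALSE))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  dcol <- intersect(c("disposition", "assigned_disposition"), header)
  if (!("id" %in% header) || length(dcol) == 0) {
    stop("assignment file needs 'id' and 'disposition' columns", call. = FALSE)
  }
  recs <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  data.frame(
    id = vapply(recs, function(r) r[[match("id", header)]], character(1)),
    disposition = vapply(recs, function(r) r[[match(dcol[[1]], header)]],
                         character(1)),
    stringsAsFactors = FALSE)
}

#' Apply reviewed role assignments
#'
#' Processes the filled review spreadsheet: \code{NR} rows get a persistent
#' no-role annotation (an OBO subset tag) that excludes the term from
#' future gap reports; existing-role rows gain a has-role assertion;
#' \code{NEW:name|parent} rows first create the role under the named
#' parent — which must live inside the role branch (application, biological
#' or chemical category) — then assert it.
#'
#' @param o an \code{\link{ontology}}.
#' @param rows data.frame with columns id, disposition (see
#'   \code{\link{read_role_assignments}}).
#' @param cfg a \code{\link{mirror_config}} (namespace / role root).
#' @param nr_subset subset tag used for the persistent NR annotation.
#' @return list: \code{ontology} and \code{summary}
#'   (\code{list(nr, assigned, created)}).
#' @export
apply_role_assignments <- function(o, rows, cfg = mirror_config(),
                                   nr_subset = "no_role") {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) > 0) {
    check_known(o, rows$id)
    key <- paste(rows$id, rows$disposition, sep = "\r")
    rows <- rows[!duplicated(key), , drop = FALSE]
    nr_terms <- rows$id[rows$disposition == "NR"]
    conflict <- intersect(nr_terms, rows$id[rows$disposition != "NR"])
    if (length(conflict) > 0) {
      stop(sprintf("conflicting duplicate assignment rows for: %s",
                   paste(sort(conflict), collapse = ", ")), call. = FALSE)
    }
  }
  n_nr <- 0L; n_assigned <- 0L; n_created <- 0L
  role_root <- NULL
  for (i in seq_len(nrow(rows))) {
    id <- rows$id[[i]]; disp <- rows$disposition[[i]]
    if (disp == "NR") {
      o$terms[[id]]$subsets <- norm_set(c(o$terms[[id]]$subsets, nr_subset))
      n_nr <- n_nr + 1L
    } else if (startsWith(disp, "NEW:")) {
      body <- sub("^NEW:", "", disp)
      parts <- strsplit(body, "|", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop(sprintf("row %d: malformed NEW disposition '%s'", i, disp),
             call. = FALSE)
      }
      rname <- trimws(parts[[1]]); parent <- trimws(parts[[2]])
      check_known(o, parent)
      if (is.null(role_root)) role_root <- detect_role_root(o, cfg)
      if (!(parent == role_root || role_root %in% onto_ancestors(o, parent))) {
        stop(sprintf("row %d: NEW role parent %s is outside the role branch",
                     i, parent), call. = FALSE)
      }
      # reuse an existing same-named role in the branch, else mint one
      branch <- c(role_root, onto_descendants(o, role_root))
      hit <- branch[vapply(branch, function(b)
        identical(o$terms[[b]]$name, rname), logical(1))]
      rid <- if (length(hit) > 0) hit[[1]] else
        sprintf("%s:role-%s", cfg$namespace,
                gsub("[^A-Za-z0-9]+", "-", tolower(rname)))
      if (is.null(o$terms[[rid]])) {
        o$terms[[rid]] <- onto_term(rid, name = rname, is_a = parent)
        n_created <- n_created + 1L
      }
      o$terms[[id]]$roles <- norm_set(c(o$terms[[id]]$roles, rid))
      n_assigned <- n_assigned + 1L
    } else {
      check_known(o, disp)
      o$terms[[id]]$roles <- norm_set(c(o$terms[[id]]$roles, disp))
      n_assigned <- n_assigned + 1L
    }
  }
  o <- rebuild(o)
  list(ontology = o,
       summary = list(nr = n_nr, assigned = n_assigned, created = n_created))
}
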