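# OBO 1.4 flat-file reading and writing.
#
# Only the tags the pipeline needs are interpreted: [Term], id, name, is_a,
# relationship: has_role, alt_id, subset, synonym, is_obsolete, replaced_by.
# Other stanza types ([Typedef], ...) and unknown tags are skipped. is_a and
# relationship lines may carry trailing "! name" comments (ChEBI style);
# these are stripped on read and regenerated on write.

strip_obo_comment <- function(x) sub("\\s*!.*$", "", x)

#' Parse an OBO 1.4 flat file into an ontology
#'
#' @param text OBO document: a single string or a character vector of lines.
#' @param allow_dangling drop (and message about) is_a/role targets that do
#'   not resolve, instead of erroring.
#' @return an \code{\link{ontology}}.
#' @seealso \code{\link{write_obo}}, \code{\link{read_obo}}
#' @export
parse_obo <- function(text, allow_dangling = FALSE) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)

  terms <- list()
  cur <- NULL       # accumulating fields for the current [Term]
  cur_line <- 0L    # line where the stanza started
  in_term <- FALSE

  flush_term <- function() {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id)) {
      stop(sprintf("line %d: [Term] stanza without an id tag", cur_line),
           call. = FALSE)
    }
    if (!is.null(terms[[cur$id]])) {
      stop(sprintf("line %d: duplicate term id %s", cur_line, cur$id),
           call. = FALSE)
    }
    obsolete <- isTRUE(cur$obsolete)
    terms[[cur$id]] <<- onto_term(
      id = cur$id,
      name = if (is.null(cur$name)) cur$id else cur$name,
      is_a = if (obsolete) character(0) else cur$is_a,
      roles = if (obsolete) character(0) else cur$roles,
      alt_ids = cur$alt_ids,
      obsolete = obsolete,
      replaced_by = if (is.null(cur$replaced_by)) NA_character_ else cur$replaced_by,
      subsets = cur$subsets,
      synonyms = cur$synonyms
    )
    invisible()
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush_term()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(is_a = character(0), roles = character(0),
                    alt_ids = character(0), subsets = character(0),
                    synonyms = character(0))
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0) next
    tag <- m[[2]]; val <- m[[3]]
    if (tag == "id") {
      id <- strip_obo_comment(val)
      if (!is_curie(id)) {
        stop(sprintf("line %d: malformed id '%s'", i, id), call. = FALSE)
      }
      cur$id <- id
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "is_a") {
      cur$is_a <- c(cur$is_a, trimws(strip_obo_comment(val)))
    } else if (tag == "relationship") {
      rel <- strsplit(trimws(strip_obo_comment(val)), "\\s+")[[1]]
      if (length(rel) >= 2 && rel[[1]] == "has_role") {
        cur$roles <- c(cur$roles, rel[[2]])
      }
    } else if (tag == "alt_id") {
      cur$alt_ids <- c(cur$alt_ids, trimws(strip_obo_comment(val)))
    } else if (tag == "subset") {
      cur$subsets <- c(cur$subsets, trimws(val))
    } else if (tag == "synonym") {
      cur$synonyms <- c(cur$synonyms, val)
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(trimws(val), "true")
    } else if (tag == "replaced_by") {
      cur$replaced_by <- trimws(strip_obo_comment(val))
    }
    # unknown tags skipped
  }
  flush_term()
  ontology(unname(terms), allow_dangling = allow_dangling)
}

#' Read an OBO file from disk
#' @param path path to an OBO flat file.
#' @inheritParams parse_obo
#' @return an \code{\link{ontology}}.
#' @export
read_obo <- function(path, allow_dangling = FALSE) {
  parse_obo(readLines(path, warn = FALSE), allow_dangling = allow_dangling)
}

#' Serialize an ontology to canonical OBO text
#'
#' The serialization is canonical: terms sorted by id, tags in a fixed
#' order (id, name, alt_id, subset, synonym, is_a, relationship,
#' is_obsolete, replaced_by), set-valued tags sorted. Canonical output is a
#' fixpoint: parsing and re-serializing reproduces the bytes, so weekly
#' release diffs are minimal.
#'
#' @param o an \code{\link{ontology}}.
#' @param path optional file path; when given the text is also written there.
#' @return the OBO document as a single string (invisibly when \code{path}
#'   is given).
#' @export
write_obo <- function(o, path = NULL) {
  out <- c("format-version: 1.4", "")
  name_of <- function(id) o$terms[[id]]$name
  for (id in names(o$terms)) {  # already sorted by id
    t <- o$terms[[id]]
    stanza <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    for (a in t$alt_ids) stanza <- c(stanza, paste0("alt_id: ", a))
    for (s in t$subsets) stanza <- c(stanza, paste0("subset: ", s))
    for (s in t$synonyms) stanza <- c(stanza, paste0("synonym: ", s))
    if (!t$obsolete) {
      for (p in t$is_a) {
        stanza <- c(stanza, paste0("is_a: ", p, " ! ", name_of(p)))
      }
      for (r in t$roles) {
        stanza <- c(stanza,
                    paste0("relationship: has_role ", r, " ! ", name_of(r)))
      }
    } else {
      stanza <- c(stanza, "is_obsolete: true")
      if (!is.na(t$replaced_by)) {
        stanza <- c(stanza, paste0("replaced_by: ", t$replaced_by))
      }
    }
    out <- c(out, stanza, "")
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  # single trailing newline, no double blank at EOF
  txt <- sub("\n\n$", "\n", txt)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

# ---- seed lists ------------------------------------------------------------

#' Read a seed list (one CURIE per line)
#'
#' Blank lines and \code{#} comment lines are ignored. A malformed CURIE is
#' an error reported with its line number.
#'
#' @param text a file path, or the list contents as a string / line vector.
#' @return character vector of seed term ids, sorted, unique.
#' @export
read_seeds <- function(text) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  ids <- character(0)
  for (i in seq_along(lines)) {
    s <- trimws(lines[[i]])
    if (!nzchar(s) || startsWith(s, "#")) next
    if (!is_curie(s)) {
      stop(sprintf("seed list line %d: malformed CURIE '%s'", i, s),
           call. = FALSE)
    }
    ids <- c(ids, s)
  }
  norm_set(ids)
}

#' Seed membership recorded as an OBO subset tag
#'
#' Seed (curated "source") membership may be carried inside the ontology
#' file itself as a subset annotation instead of a side file.
#'
#' @param o an \code{\link{ontology}}.
#' @param subset_name the subset tag marking curated terms.
#' @return character vector of term ids carrying the tag.
#' @export
seeds_from_subset <- function(o, subset_name = "iedb_curated") {
  ids <- names(o$terms)[vapply(o$terms, function(t)
    subset_name %in% t$subsets, logical(1))]
  sort(ids)
}

# ---- tabular reports -------------------------------------------------------

#' Write a tab-separated report
#'
#' All reports the pipeline emits (role gaps, duplicate placements,
#' validation, metric comparisons) share this shape: a header row then one
#' tab-separated row per record, in deterministic order.
#'
#' @param rows a data.frame.
#' @param path optional output file path.
#' @return the report text (invisibly when \code{path} is given).
#' @export
write_report <- function(rows, path = NULL) {
  stopifnot(is.data.frame(rows))
  header <- paste(names(rows), collapse = "\t")
  body <- if (nrow(rows) == 0) character(0) else
    apply(rows, 1, function(r) paste(as.character(r), collapse = "\t"))
  txt <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

# ---- edit scripts ----------------------------------------------------------

edit_ops <- c("remove_class", "splice_class", "move_term", "merge_classes",
              "rename", "create_class", "create_other_bucket",
              "remove_parent", "add_parent")

#' Parse an edit script
#'
#' Edit scripts make manual tree reorganizations reproducible and
#' reviewable: each curation judgment (move a term, merge classes, rename a
#' node, ...) is one ordered step with a free-text rationale, applied by
#' \code{\link{apply_edit_script}}. The on-disk format is a YAML list of
#' steps, e.g.
#'
#' \preformatted{
#' - op: rename
#'   target: "CHEBI:25698"
#'   new_name: non-aromatic ether
#'   rationale: aromatic ethers live in the aromatic branch
#' - op: add_parent
#'   target: "CHEBI:33563"
#'   parent: "CHEBI:16646"
#'   rationale: glycolipids reachable from both lipid and carbohydrate
#' }
#'
#' @param text YAML text (string or lines) or a path to a script file.
#' @return an object of class \code{edit_script}: list of validated steps.
#' @export
parse_edit_script <- function(text) {
  raw <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    yaml::read_yaml(text)
  } else {
    yaml::yaml.load(paste(as.character(text), collapse = "\n"))
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("edit script must be a YAML list of steps",
                          call. = FALSE)
  steps <- lapply(seq_along(raw), function(i) {
    s <- raw[[i]]
    if (is.null(s$op) || !(s$op %in% edit_ops)) {
      stop(sprintf("edit script step %d: unknown op '%s'", i,
                   if (is.null(s$op)) "<missing>" else s$op), call. = FALSE)
    }
    if (is.null(s$rationale)) s$rationale <- ""
    s
  })
  structure(steps, class = "edit_script")
}

#' Serialize an edit script back to YAML
#' @param script an \code{edit_script}.
#' @return YAML text.
#' @export
format_edit_script <- function(script) {
  yaml::as.yaml(lapply(unclass(script), function(s) s))
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("<edit_script> %d step(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  %d. %s %s\n", i, x[[i]]$op,
                if (!is.null(x[[i]]$target)) x[[i]]$target else ""))
  }
  invisible(x)
}
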