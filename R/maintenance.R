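# Release-over-release maintenance: validate that every identifier the
# application uses is still live in a new ontology release, and lint class
# names against the naming conventions (lower case, singular form).

#' Validate used identifiers against a new ontology release
#'
#' The weekly-build gate: every id the application's data uses is checked
#' against the new release. An id is \code{valid} when present and live;
#' \code{replaced} when obsolete with a replacement term;
#' \code{obsolete_no_replacement} when obsolete without one;
#' \code{merged_via_alt_id} when absent as a primary id but found among
#' another term's alternative ids (the standard merge mechanism, with the
#' host term reported as replacement); otherwise \code{missing}.
#'
#' @param used_ids character vector of ids in use.
#' @param new_ontology the newly released \code{\link{ontology}}.
#' @return data.frame with columns id, status, replacement (empty string
#'   when not applicable); one row per distinct used id, in input order.
#' @export
validate_ids <- function(used_ids, new_ontology) {
  o <- new_ontology
  used_ids <- unique(as.character(used_ids))
  alt_host <- list()
  for (t in o$terms) for (a in t$alt_ids) {
    if (is.null(alt_host[[a]])) alt_host[[a]] <- t$id
  }
  status <- character(length(used_ids))
  repl <- character(length(used_ids))
  for (i in seq_along(used_ids)) {
    id <- used_ids[[i]]
    t <- o$terms[[id]]
    if (!is.null(t)) {
      if (!t$obsolete) {
        status[[i]] <- "valid"; repl[[i]] <- ""
      } else if (!is.na(t$replaced_by)) {
        status[[i]] <- "replaced"; repl[[i]] <- t$replaced_by
      } else {
        status[[i]] <- "obsolete_no_replacement"; repl[[i]] <- ""
      }
    } else if (!is.null(alt_host[[id]])) {
      status[[i]] <- "merged_via_alt_id"; repl[[i]] <- alt_host[[id]]
    } else {
      status[[i]] <- "missing"; repl[[i]] <- ""
    }
  }
  data.frame(id = used_ids, status = status, replacement = repl,
             stringsAsFactors = FALSE)
}

#' Naming-convention lint configuration
#'
#' @param case_exceptions first tokens allowed to start with a capital
#'   (element symbols, stereo-descriptors, proper-noun-like abbreviations).
#' @param plural_whitelist final tokens allowed to end in "s".
#' @return a list of class \code{lint_config}.
#' @export
lint_config <- function(
    case_exceptions = c("Al", "As", "Ba", "Be", "Br", "Ca", "Cd", "Cl",
                        "Co", "Cr", "Cu", "Fe", "He", "Hg", "Li", "Mg",
                        "Mn", "Mo", "Na", "Ni", "Pb", "Se", "Si", "Sn",
                        "Ti", "Zn", "D-", "L-", "N-", "O-", "S-"),
    plural_whitelist = c("bis", "tris", "gas", "lens", "virus",
                         "consensus", "apparatus")) {
  structure(list(case_exceptions = case_exceptions,
                 plural_whitelist = plural_whitelist),
            class = "lint_config")
}

#' Lint class names against the naming conventions
#'
#' The conventions for the simplified tree: names use lower case unless
#' the word would be capitalized mid-sentence (names, atom symbols,
#' abbreviations), and the singular form (pyridine, not pyridines). This
#' emits warnings only; it never mutates the ontology. A case warning
#' fires when the first character is uppercase, the second is lowercase,
#' and the first token is not in the exception lexicon (all-caps
#' abbreviations like "DNP" never trigger it). A plural warning fires when
#' the final token ends in "s" but not "ss" and is not whitelisted.
#'
#' @param o an \code{\link{ontology}}.
#' @param config a \code{\link{lint_config}}.
#' @return data.frame with columns id, name, check ("case" or "plural"),
#'   message; sorted by (id, check).
#' @export
lint_names <- function(o, config = lint_config()) {
  rows <- list()
  add <- function(id, name, check, msg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, name = name, check = check, message = msg,
      stringsAsFactors = FALSE)
  }
  for (id in names(o$terms)) {
    nm <- o$terms[[id]]$name
    if (!nzchar(nm)) next
    tokens <- strsplit(nm, "\\s+")[[1]]
    first <- tokens[[1]]
    chars <- strsplit(nm, "")[[1]]
    exempt <- first %in% config$case_exceptions ||
      substr(first, 1, 2) %in% config$case_exceptions
    if (length(chars) >= 2 &&
        grepl("^[A-Z]$", chars[[1]]) && grepl("^[a-z]$", chars[[2]]) &&
        !exempt) {
      add(id, nm, "case",
          sprintf("name starts with a capital letter: '%s'", nm))
    }
    last <- tokens[[length(tokens)]]
    if (grepl("s$", last) && !grepl("ss$", last) &&
        !(tolower(last) %in% tolower(config$plural_whitelist))) {
      add(id, nm, "plural",
          sprintf("name may be plural (final token '%s')", last))
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(id = character(0), name = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out[order(out$id, out$check), , drop = FALSE]
}
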