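# Synthetic ontologies emulating the pathologies of a large chemical
# ontology: deep single-child grouping chains above curated leaves,
# multi-parent terms, a separate role branch with scattered role
# assertions, and obsolete / replaced identifiers. Every stage of the
# pipeline is testable on these without any external download.

# run expr under a private RNG stream; the caller's stream is untouched
with_local_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generator parameters
#'
#' Defaults emulate the shape of the legacy curated-chemical tree: a few
#' dozen grouping classes, an 18-deep single-child grouping chain over a
#' curated leaf, occasional multi-parent placements, a small role branch
#' with sparse role assertions, and a few percent obsolete identifiers.
#'
#' @param n_grouping number of grouping classes (outside the chain).
#' @param n_seeds number of curated seed leaves.
#' @param max_chain_len length of the guaranteed single-child grouping
#'   chain (0 disables it).
#' @param p_multiparent probability that a grouping class or seed gets a
#'   second structural parent.
#' @param n_roles number of role classes under the role branch root.
#' @param p_role_assertion probability that a seed or grouping class
#'   carries a role assertion.
#' @param p_obsolete expected fraction (of \code{n_grouping}) of extra
#'   obsolete terms.
#' @param rng_seed integer seed; identical parameters and seed give a
#'   byte-identical ontology.
#' @return a list of class \code{generator_params}.
#' @export
generator_params <- function(n_grouping = 40L, n_seeds = 15L,
                             max_chain_len = 18L, p_multiparent = 0.2,
                             n_roles = 6L, p_role_assertion = 0.3,
                             p_obsolete = 0.05, rng_seed = 1L) {
  p <- list(n_grouping = as.integer(n_grouping),
            n_seeds = as.integer(n_seeds),
            max_chain_len = as.integer(max_chain_len),
            p_multiparent = p_multiparent, n_roles = as.integer(n_roles),
            p_role_assertion = p_role_assertion, p_obsolete = p_obsolete,
            rng_seed = as.integer(rng_seed))
  if (any(vapply(p[c("n_grouping", "n_seeds", "max_chain_len", "n_roles")],
                 function(x) x < 0, logical(1)))) {
    stop("generator counts must be non-negative", call. = FALSE)
  }
  probs <- unlist(p[c("p_multiparent", "p_role_assertion", "p_obsolete")])
  if (any(probs < 0 | probs > 1)) {
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "generator_params")
}

syn_id <- function(n) sprintf("SYN:%07d", n)

syn_name <- function(kind, i) {
  stems <- c("gluco", "galacto", "ribo", "xylo", "manno", "arabino",
             "fructo", "lipo", "amino", "nitro", "sulfo", "phospho",
             "chloro", "benzo", "cyclo", "oxo")
  tails <- c("side", "sane", "sene", "sol", "sate", "sine", "furan", "pyran")
  stem <- stems[[1L + (i * 7L) %% length(stems)]]
  tail <- tails[[1L + (i * 3L) %% length(tails)]]
  sprintf("%s%s %s %d", stem, tail, kind, i)
}

#' Generate a synthetic ontology with curated seeds
#'
#' Builds, deterministically under \code{rng_seed}: one structural root
#' ("chemical entity") and one role branch root ("role"); a role
#' sub-hierarchy; grouping classes attached to random earlier structural
#' terms (guaranteeing acyclicity), each with an extra parent with
#' probability \code{p_multiparent}; at least one single-child grouping
#' chain of length \code{max_chain_len} ending in a seed; seed leaves
#' under random grouping classes; role assertions sprinkled on seeds and
#' grouping classes; and extra obsolete terms, some with replacements.
#'
#' @param params a \code{\link{generator_params}}.
#' @return list: \code{ontology}, \code{seeds} (character vector),
#'   \code{chain} (ids of the guaranteed chain, possibly empty),
#'   \code{multiparent_eligible} (ids that drew the extra-parent coin).
#' @export
generate_ontology <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_local_rng(params$rng_seed, {
    terms <- list()
    n <- 0L
    mint <- function() { n <<- n + 1L; syn_id(n) }
    add <- function(t) terms[[t$id]] <<- t

    sroot <- mint(); add(onto_term(sroot, name = "chemical entity"))
    rroot <- mint(); add(onto_term(rroot, name = "role"))

    roles <- character(0)
    for (i in seq_len(params$n_roles)) {
      id <- mint()
      parent <- if (length(roles) > 0 && stats::runif(1) < 0.5)
        sample(roles, 1) else rroot
      add(onto_term(id, name = syn_name("role", n), is_a = parent))
      roles <- c(roles, id)
    }

    chain <- character(0)
    if (params$max_chain_len >= 1) {
      prev <- sroot
      for (i in seq_len(params$max_chain_len)) {
        id <- mint()
        add(onto_term(id, name = syn_name("grouping", n), is_a = prev))
        chain <- c(chain, id)
        prev <- id
      }
    }

    # grouping classes: attach only to root or earlier non-chain grouping
    # classes, so the guaranteed chain stays single-child
    grouping <- character(0)
    eligible <- character(0)
    for (i in seq_len(params$n_grouping)) {
      id <- mint()
      pool <- c(sroot, grouping)
      parents <- sample(pool, 1)
      eligible <- c(eligible, id)
      if (stats::runif(1) < params$p_multiparent && length(pool) > 1) {
        parents <- union(parents, sample(setdiff(pool, parents), 1))
      }
      add(onto_term(id, name = syn_name("grouping", n), is_a = parents))
      grouping <- c(grouping, id)
    }

    seeds <- character(0)
    n_free_seeds <- params$n_seeds
    if (params$max_chain_len >= 1 && params$n_seeds >= 1) {
      id <- mint()
      add(onto_term(id, name = syn_name("compound", n),
                    is_a = chain[[length(chain)]],
                    subsets = "iedb_curated"))
      seeds <- c(seeds, id)
      n_free_seeds <- n_free_seeds - 1L
    }
    for (i in seq_len(max(0L, n_free_seeds))) {
      id <- mint()
      pool <- if (length(grouping) > 0) grouping else sroot
      parents <- if (length(pool) == 1) pool else sample(pool, 1)
      eligible <- c(eligible, id)
      if (stats::runif(1) < params$p_multiparent && length(pool) > 1) {
        parents <- union(parents, sample(setdiff(pool, parents), 1))
      }
      add(onto_term(id, name = syn_name("compound", n), is_a = parents,
                    subsets = "iedb_curated"))
      seeds <- c(seeds, id)
    }

    if (length(roles) > 0 && params$p_role_assertion > 0) {
      for (id in c(seeds, grouping)) {
        if (stats::runif(1) < params$p_role_assertion) {
          terms[[id]]$roles <- sample(roles, 1)
        }
      }
    }

    n_obsolete <- stats::rbinom(1, params$n_grouping, params$p_obsolete)
    live <- c(sroot, grouping, seeds)
    for (i in seq_len(n_obsolete)) {
      id <- mint()
      repl <- if (stats::runif(1) < 0.5)
        sample(live, 1) else NA_character_
      add(onto_term(id, name = syn_name("retired", n), obsolete = TRUE,
                    replaced_by = repl))
    }

    list(ontology = ontology(unname(terms)), seeds = sort(seeds),
         chain = chain, multiparent_eligible = eligible)
  })
}

#' Canonical deep-chain regression fixture
#'
#' The textbook pathology: a root, a single-child chain of grouping
#' classes, and one curated seed at the bottom (reaching the seed takes
#' \code{chain_len + 1} levels). \code{n_protected} evenly spaced chain
#' classes are marked protected, emulating manually retained intuitive
#' checkpoint classes; pruning with the rest spliced out leaves the seed
#' at depth \code{n_protected + 1}.
#'
#' @param chain_len number of grouping classes in the chain (>= 1).
#' @param n_protected number of evenly spaced protected classes
#'   (0 <= n_protected <= chain_len).
#' @return list: \code{ontology}, \code{seeds}, \code{protected}.
#' @export
legacy_chain_fixture <- function(chain_len, n_protected = 0L) {
  stopifnot(chain_len >= 1, n_protected >= 0, n_protected <= chain_len)
  root <- "LEG:0000000"
  chain_ids <- sprintf("LEG:%07d", seq_len(chain_len))
  seed <- "LEG:9999999"
  terms <- list(onto_term(root, name = "chemical entity"))
  prev <- root
  for (i in seq_len(chain_len)) {
    terms[[length(terms) + 1L]] <- onto_term(
      chain_ids[[i]], name = sprintf("grouping level %d", i), is_a = prev)
    prev <- chain_ids[[i]]
  }
  terms[[length(terms) + 1L]] <- onto_term(
    seed, name = "curated compound", is_a = prev, subsets = "iedb_curated")
  # evenly spaced protected checkpoints, deduplicated for short chains
  pos <- integer(0)
  if (n_protected > 0) {
    pos <- unique(pmin(chain_len, pmax(1L, round(
      seq_len(n_protected) * chain_len / (n_protected + 1)))))
    extra <- setdiff(seq_len(chain_len), pos)
    while (length(pos) < n_protected && length(extra) > 0) {
      pos <- sort(c(pos, extra[[1]])); extra <- extra[-1]
    }
  }
  list(ontology = ontology(terms), seeds = seed,
       protected = chain_ids[pos])
}
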