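# Tree-complexity metrics: the depth and breadth statistics used to
# quantify how much simpler a slimmed hierarchy is than the original
# (source depths; source-bearing children per parent; parents with a
# single source child).

# lower-middle median: for even counts, the lower of the two middle
# elements (documented convention; integer-friendly for level counts)
lower_median <- function(x) {
  s <- sort(x)
  s[[(length(s) + 1L) %/% 2L]]
}

#' Depths of all curated seed terms
#'
#' One depth value per seed: the number of subclass edges from a root,
#' along the shortest (default) or longest path.
#'
#' @param o an \code{\link{ontology}}.
#' @param seeds curated term ids; all must be reachable from a root.
#' @param mode \code{"shortest"} or \code{"longest"}.
#' @return named integer vector, one element per seed.
#' @export
source_depths <- function(o, seeds, mode = c("shortest", "longest")) {
  mode <- match.arg(mode)
  check_known(o, seeds)
  d <- depth_table(o, mode)[seeds]
  bad <- seeds[is.na(d)]
  if (length(bad) > 0) {
    stop(sprintf("seed(s) not reachable from any root: %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  d
}

#' Source-bearing children per parent
#'
#' The parents considered are all terms that are ancestors of at least one
#' seed and have at least one child. For each, the number of its direct
#' children that are or lead to seeds is counted; deep single-lineage
#' chains show up as long runs of parents with exactly one source child.
#'
#' @inheritParams source_depths
#' @param count_mode \code{"source_bearing"} (default) or \code{"raw"}
#'   (all direct children).
#' @return list: \code{counts} (named integer vector per parent) and
#'   \code{parents_with_one_source_child}.
#' @export
parent_child_stats <- function(o, seeds, count_mode = c("source_bearing",
                                                        "raw")) {
  count_mode <- match.arg(count_mode)
  check_known(o, seeds)
  anc <- norm_set(unlist(lapply(seeds, function(s) onto_ancestors(o, s)),
                         use.names = FALSE))
  idx <- child_index(o)
  parents <- anc[vapply(anc, function(a) length(idx[[a]]) > 0, logical(1))]
  counts <- vapply(parents, function(p) {
    if (count_mode == "raw") length(idx[[p]])
    else length(source_bearing_children(o, p, seeds))
  }, integer(1))
  list(counts = counts,
       parents_with_one_source_child = sum(counts == 1L))
}

#' Tree complexity metrics
#'
#' Aggregates the depth and breadth statistics of the curated terms in a
#' hierarchy: average / median / maximum / minimum source depth, average /
#' median / maximum source-bearing children per parent, and the number of
#' parents with exactly one source child. Medians use the lower-middle
#' convention for even counts. Averages keep full precision in the model
#' and are rounded to one decimal in rendered reports.
#'
#' @inheritParams parent_child_stats
#' @param mode depth mode, \code{"shortest"} or \code{"longest"}.
#' @return a list of class \code{tree_metrics}.
#' @export
tree_metrics <- function(o, seeds, mode = c("shortest", "longest"),
                         count_mode = c("source_bearing", "raw")) {
  mode <- match.arg(mode)
  count_mode <- match.arg(count_mode)
  if (length(seeds) == 0) {
    stop("metrics are undefined for an empty seed set", call. = FALSE)
  }
  depths <- source_depths(o, seeds, mode)
  pcs <- parent_child_stats(o, seeds, count_mode)
  counts <- pcs$counts
  structure(list(
    source_depth_avg = mean(depths),
    source_depth_median = lower_median(depths),
    source_depth_max = max(depths),
    source_depth_min = min(depths),
    children_per_parent_avg = if (length(counts) > 0) mean(counts) else 0,
    children_per_parent_median = if (length(counts) > 0)
      lower_median(counts) else 0L,
    children_per_parent_max = if (length(counts) > 0) max(counts) else 0L,
    parents_with_one_source_child = pcs$parents_with_one_source_child,
    n_sources = length(depths),
    n_parents = length(counts),
    depth_mode = mode
  ), class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<tree_metrics> (%s-path depths; %d sources, %d parents)\n",
           "  source depth: avg %.1f, median %d, max %d, min %d\n",
           "  source children per parent: avg %.1f, median %d, max %d\n",
           "  parents with one source child: %d\n"),
    x$depth_mode, x$n_sources, x$n_parents,
    x$source_depth_avg, x$source_depth_median, x$source_depth_max,
    x$source_depth_min, x$children_per_parent_avg,
    x$children_per_parent_median, x$children_per_parent_max,
    x$parents_with_one_source_child))
  invisible(x)
}

metric_labels <- c(
  source_depth_avg = "Average source depth",
  source_depth_median = "Median source depth",
  source_depth_max = "Maximum source depth",
  source_depth_min = "Minimum source depth",
  children_per_parent_avg = "Average source count per parent",
  children_per_parent_median = "Median source count per parent",
  children_per_parent_max = "Maximum source count per parent",
  parents_with_one_source_child = "Parents with one source child")

#' Compare complexity metrics of two trees
#'
#' Produces the old-vs-new comparison report: one row per statistic with
#' old value, new value and delta. Averages are rounded to one decimal.
#'
#' @param metrics_old,metrics_new \code{\link{tree_metrics}} computed with
#'   the same depth mode.
#' @return data.frame with columns statistic, old, new, delta.
#' @export
compare_metrics <- function(metrics_old, metrics_new) {
  if (!identical(metrics_old$depth_mode, metrics_new$depth_mode)) {
    stop("depth modes differ between the two metric sets", call. = FALSE)
  }
  fields <- names(metric_labels)
  old <- vapply(fields, function(f) round(as.numeric(metrics_old[[f]]), 1),
                numeric(1))
  new <- vapply(fields, function(f) round(as.numeric(metrics_new[[f]]), 1),
                numeric(1))
  data.frame(statistic = unname(metric_labels), old = unname(old),
             new = unname(new), delta = unname(round(new - old, 1)),
             stringsAsFactors = FALSE)
}
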