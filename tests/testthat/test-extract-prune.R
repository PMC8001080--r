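test_that("extraction keeps seeds, ancestors, and the role closure", {
  o <- mk_onto(list(`X:g` = "X:root", `X:s` = "X:g",
                    `X:h` = "X:root", `X:t` = "X:h"))
  out <- extract_subset(o, "X:s")
  expect_setequal(names(out$terms), c("X:root", "X:g", "X:s"))
  # role closure: s has role r, r below a role root
  o2 <- mk_onto(list(`X:g` = "X:root", `X:s` = "X:g",
                     `X:r` = "X:rr", `X:h` = "X:root"),
                roles = list(`X:s` = "X:r"),
                nm = c(`X:rr` = "role"))
  out2 <- extract_subset(o2, "X:s")
  expect_setequal(names(out2$terms),
                  c("X:root", "X:g", "X:s", "X:r", "X:rr"))
  expect_error(extract_subset(o, "X:nope"), "unresolvable seed")
  expect_error(extract_subset(o, character(0)), "empty")
})

test_that("extracting with every term as seed is the identity minus obsolete", {
  gen <- generate_ontology(corpus_params(7))
  o <- gen$ontology
  out <- extract_subset(o, live_terms(o))
  expect_setequal(names(out$terms), live_terms(o))
  for (id in names(out$terms)) {
    expect_equal(out$terms[[id]]$is_a, o$terms[[id]]$is_a)
  }
})

test_that("chain pruning collapses single-lineage grouping chains", {
  fx <- legacy_chain_fixture(18, 0)
  res <- prune_chains(fx$ontology, fx$seeds)
  expect_equal(onto_depth(res$ontology, fx$seeds), 1L)
  expect_equal(nrow(res$log), 18L)
  expect_false(any(res$log$removed %in% fx$seeds))
  # protected checkpoints survive: 18 levels become 6
  fx5 <- legacy_chain_fixture(18, 5)
  res5 <- prune_chains(fx5$ontology, fx5$seeds,
                       prune_config(protected = fx5$protected))
  expect_equal(onto_depth(res5$ontology, fx5$seeds), 6L)
  expect_equal(nrow(res5$log), 13L)
  expect_true(all(fx5$protected %in% names(res5$ontology$terms)))
})

test_that("a grouping class above the splice threshold is retained", {
  o <- mk_onto(list(`X:g` = "X:root", `X:s1` = "X:g", `X:s2` = "X:g"))
  res <- prune_chains(o, c("X:s1", "X:s2"))
  expect_true("X:g" %in% names(res$ontology$terms))
  expect_equal(nrow(res$log), 0L)
  # threshold raised to 2: now spliceable
  res2 <- prune_chains(o, c("X:s1", "X:s2"),
                       prune_config(max_spliceable_children = 2))
  expect_false("X:g" %in% names(res2$ontology$terms))
})

test_that("pruning preserves seed ancestry through surviving classes", {
  for (seed in c(31, 32, 33, 34, 35)) {
    gen <- generate_ontology(corpus_params(seed))
    o <- extract_subset(gen$ontology, gen$seeds)
    res <- prune_chains(o, gen$seeds)
    R_before <- closure_oracle(o)
    R_after <- closure_oracle(res$ontology)
    surv <- names(res$ontology$terms)
    for (s in gen$seeds) {
      expect_true(s %in% surv)
      for (b in intersect(names(which(R_before[s, ])), surv)) {
        expect_true(isTRUE(R_after[s, b]),
                    info = sprintf("seed %d: %s lost ancestor %s", seed, s, b))
      }
      # no new ancestry either
      anc_new <- intersect(names(which(R_after[s, ])), names(o$terms))
      expect_true(all(R_before[s, anc_new]),
                  info = sprintf("seed %d: %s gained ancestry", seed, s))
      # depth never increases
      expect_lte(onto_depth(res$ontology, s), onto_depth(o, s))
    }
  }
})

test_that("pruning is a structural fixpoint", {
  gen <- generate_ontology(corpus_params(12))
  o <- extract_subset(gen$ontology, gen$seeds)
  once <- prune_chains(o, gen$seeds)
  twice <- prune_chains(once$ontology, gen$seeds)
  expect_equal(twice$ontology$terms, once$ontology$terms)
  expect_equal(nrow(twice$log), 0L)
})

# parent with named grouping subclasses plus ungrouped curated leaves;
# shaped like monosaccharide: 7 grouping categories, 14 extra entities
bucket_fixture <- function(n_grouping = 7, n_loose = 3) {
  parents <- list(`B:p` = "B:root")
  seeds <- character(0)
  for (i in seq_len(n_grouping)) {
    g <- sprintf("B:g%02d", i); s <- sprintf("B:gs%02d", i)
    parents[[g]] <- "B:p"
    parents[[s]] <- g
    seeds <- c(seeds, s)
  }
  for (i in seq_len(n_loose)) {
    l <- sprintf("B:l%02d", i)
    parents[[l]] <- "B:p"
    seeds <- c(seeds, l)
  }
  nm <- c(`B:p` = "monosaccharide")
  list(ontology = mk_onto(parents, seeds = seeds, nm = nm), seeds = seeds,
       loose = sprintf("B:l%02d", seq_len(n_loose)))
}

test_that("other-buckets collect exactly the ungrouped leaves", {
  fx <- bucket_fixture(7, 14)
  out <- make_other_buckets(fx$ontology, fx$seeds)
  bucket <- names(out$terms)[vapply(out$terms, function(t)
    identical(t$name, "other monosaccharide"), logical(1))]
  expect_length(bucket, 1)
  expect_setequal(onto_children(out, bucket), fx$loose)
  expect_equal(onto_parents(out, bucket), "B:p")
  # loose leaves no longer sit directly under the parent
  expect_false(any(fx$loose %in% onto_children(out, "B:p")))
})

test_that("buckets respect the minimum-size threshold", {
  fx <- bucket_fixture(2, 2)
  out <- make_other_buckets(fx$ontology, fx$seeds)  # default min 3
  expect_identical(names(out$terms), names(fx$ontology$terms))
  out2 <- make_other_buckets(fx$ontology, fx$seeds,
                             prune_config(other_bucket_min = 2))
  expect_true(any(vapply(out2$terms, function(t)
    identical(t$name, "other monosaccharide"), logical(1))))
})

test_that("no bucket is created without grouping siblings, and the op is idempotent", {
  # only grouping children: nothing to collect
  o <- mk_onto(list(`B:g1` = "B:p", `B:g2` = "B:p",
                    `B:s1` = "B:g1", `B:s2` = "B:g2"),
               seeds = c("B:s1", "B:s2"))
  out <- make_other_buckets(o, c("B:s1", "B:s2"))
  expect_identical(names(out$terms), names(o$terms))
  fx <- bucket_fixture(7, 14)
  once <- make_other_buckets(fx$ontology, fx$seeds)
  twice <- make_other_buckets(once, fx$seeds)
  expect_equal(twice$terms, once$terms)
})

test_that("edit scripts rename, re-parent and reject cycles", {
  o <- mk_onto(list(`E:eth` = "E:root", `E:lip` = "E:root",
                    `E:carb` = "E:root", `E:gly` = "E:lip"),
               nm = c(`E:eth` = "ethers", `E:lip` = "lipid",
                      `E:carb` = "carbohydrate", `E:gly` = "glycolipid"))
  s <- parse_edit_script(paste(
    "- op: rename",
    "  target: ethers",
    "  new_name: non-aromatic ether",
    "- op: add_parent",
    "  target: E:gly",
    "  parent: E:carb",
    "  rationale: reachable from both lipid and carbohydrate", sep = "\n"))
  out <- apply_edit_script(o, s)
  expect_equal(out$terms[["E:eth"]]$name, "non-aromatic ether")
  expect_setequal(onto_parents(out, "E:gly"), c("E:lip", "E:carb"))
  # the dual-parent term appears once under each branch in the render
  rt <- render_tree(out, character(0))
  txt <- format(rt)
  expect_equal(lengths(regmatches(txt, gregexpr("glycolipid", txt))), 2L)
  # moving a term under its own descendant is a cycle error
  bad <- parse_edit_script(
    "- op: move_term\n  target: E:lip\n  new_parents: [E:gly]")
  expect_error(apply_edit_script(o, bad), "cycle")
})

test_that("merge and splice steps rewire children and references", {
  o <- mk_onto(list(`E:a` = "E:root", `E:b` = "E:root",
                    `E:ca` = "E:a", `E:cb` = "E:b"))
  merged <- apply_edit_script(o, parse_edit_script(
    "- op: merge_classes\n  target: E:a\n  merge: [E:b]"))
  expect_false("E:b" %in% names(merged$terms))
  expect_setequal(onto_children(merged, "E:a"), c("E:ca", "E:cb"))
  expect_true("E:b" %in% merged$terms[["E:a"]]$alt_ids)
  spliced <- apply_edit_script(o, parse_edit_script(
    "- op: remove_class\n  target: E:a"))
  expect_false("E:a" %in% names(spliced$terms))
  expect_equal(onto_parents(spliced, "E:ca"), "E:root")
  expect_error(apply_edit_script(o, parse_edit_script(
    "- op: rename\n  target: E:nope\n  new_name: x")), "step 1")
})

test_that("duplicate placements at level 2 are reported, exceptions honoured", {
  o <- mk_onto(list(`D:lip` = "D:root", `D:carb` = "D:root",
                    `D:gly` = c("D:lip", "D:carb"), `D:uni` = "D:lip"),
               nm = c(`D:lip` = "lipid", `D:carb` = "carbohydrate",
                      `D:gly` = "glycolipid", `D:uni` = "unique"))
  rep0 <- duplicate_placement_report(o, 2)
  expect_equal(rep0$id, "D:gly")
  expect_equal(rep0$placements, "carbohydrate;lipid")
  expect_equal(nrow(duplicate_placement_report(o, 2, exceptions = "D:gly")),
               0L)
  # unique placements only
  o2 <- mk_onto(list(`D:a` = "D:root", `D:b` = "D:a"))
  expect_equal(nrow(duplicate_placement_report(o2, 2)), 0L)
})

test_that("slim composes the stages and is idempotent on structure", {
  fx <- legacy_chain_fixture(12, 2)
  res <- slim(fx$ontology, fx$seeds, prune_config(protected = fx$protected))
  expect_true(fx$seeds %in% names(res$ontology$terms))
  expect_lt(onto_depth(res$ontology, fx$seeds),
            onto_depth(fx$ontology, fx$seeds))
  expect_gt(nrow(res$log), 0)
  # empty script: slim is buckets . prune . extract
  gen <- generate_ontology(corpus_params(19))
  res1 <- slim(gen$ontology, gen$seeds)
  manual <- make_other_buckets(
    prune_chains(extract_subset(gen$ontology, gen$seeds), gen$seeds)$ontology,
    gen$seeds)
  expect_equal(res1$ontology$terms, manual$terms)
  # second run is a structural no-op
  res2 <- slim(res1$ontology, gen$seeds)
  expect_equal(res2$ontology$terms, res1$ontology$terms)
})

test_that("no pipeline stage ever removes a seed", {
  for (seed in c(41, 45, 49)) {
    gen <- generate_ontology(corpus_params(seed))
    res <- slim(gen$ontology, gen$seeds)
    expect_true(all(gen$seeds %in% names(res$ontology$terms)))
    expect_false(any(res$log$removed %in% gen$seeds))
  }
})
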