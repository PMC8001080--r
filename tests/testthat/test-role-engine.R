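# fixture: structural branch with a penicillin family, role branch with a
# small hierarchy (drug -> antibacterial), assertions at several levels
role_fixture <- function() {
  mk_onto(
    parents = list(
      `R:pen` = "R:ce", `R:amox` = "R:pen", `R:prog` = "R:ce",
      `R:loose` = "R:ce",
      `R:drug` = "R:role", `R:antibact` = "R:drug",
      `R:hormone` = "R:role", `R:application` = "R:role"),
    roles = list(`R:pen` = "R:antibact", `R:prog` = "R:hormone"),
    seeds = c("R:amox", "R:prog", "R:loose"),
    nm = c(`R:ce` = "chemical entity", `R:role` = "role",
           `R:pen` = "penicillin", `R:amox` = "amoxicillin",
           `R:prog` = "progesterone", `R:hormone` = "hormone",
           `R:drug` = "drug", `R:antibact` = "antibacterial drug",
           `R:loose` = "hapten x", `R:application` = "application"))
}

test_that("direct roles are the term's own assertions", {
  o <- role_fixture()
  expect_equal(direct_roles(o, "R:pen"), "R:antibact")
  expect_equal(direct_roles(o, "R:amox"), character(0))
  expect_error(direct_roles(o, "R:nope"), "unknown")
})

test_that("inherited roles union assertions over structural ancestors only", {
  o <- role_fixture()
  expect_equal(inherited_roles(o, "R:amox"), "R:antibact")  # via penicillin
  expect_equal(inherited_roles(o, "R:loose"), character(0))
  # the role hierarchy itself is not closed over: drug is not inherited
  expect_false("R:drug" %in% inherited_roles(o, "R:amox"))
  # oracle comparison on generated ontologies
  for (seed in c(23, 24)) {
    gen <- generate_ontology(corpus_params(seed))
    o2 <- gen$ontology
    R <- closure_oracle(o2)
    for (s in gen$seeds) {
      scope <- c(s, names(which(R[s, ])))
      want <- sort(unique(unlist(lapply(scope, function(i)
        o2$terms[[i]]$roles))))
      expect_equal(inherited_roles(o2, s), want,
                   info = sprintf("seed %d %s", seed, s))
    }
  }
})

test_that("mirroring places seeds under their role compounds", {
  o <- role_fixture()
  seeds <- seeds_from_subset(o)
  res <- mirror_roles(o, seeds)
  m <- res$ontology
  top <- "IEDB:by-role"
  expect_true(top %in% m$roots)  # sibling of the structural root
  expect_equal(m$terms[[top]]$name, "chemical entity by role")
  # progesterone browsable under "hormone compound"
  hc <- res$map$compound[res$map$role == "R:hormone"]
  expect_equal(m$terms[[hc]]$name, "hormone compound")
  expect_true(hc %in% onto_parents(m, "R:prog"))
  # roleless seed stays outside the compound branch
  expect_false(top %in% onto_ancestors(m, "R:loose"))
  expect_true(top %in% onto_ancestors(m, "R:amox"))
  # structural placements untouched
  expect_true("R:pen" %in% onto_parents(m, "R:amox"))
})

test_that("a seed with comparable roles attaches under the specific one only", {
  o <- mk_onto(
    parents = list(`M:s` = "M:ce", `M:r2` = "M:r1", `M:r1` = "M:role"),
    roles = list(`M:s` = c("M:r1", "M:r2")),
    seeds = "M:s",
    nm = c(`M:ce` = "chemical entity", `M:role` = "role"))
  res <- mirror_roles(o, "M:s")
  m <- res$ontology
  c1 <- res$map$compound[res$map$role == "M:r1"]
  c2 <- res$map$compound[res$map$role == "M:r2"]
  expect_true(c2 %in% onto_parents(m, "M:s"))
  expect_false(c1 %in% onto_parents(m, "M:s"))
  # still reachable from the general compound via mirrored is_a
  expect_true(c1 %in% onto_ancestors(m, "M:s"))
})

test_that("mirroring with no roles in use adds only the empty top class", {
  o <- mk_onto(parents = list(`M:s` = "M:ce", `M:r1` = "M:role"),
               seeds = "M:s",
               nm = c(`M:ce` = "chemical entity", `M:role` = "role"))
  res <- mirror_roles(o, "M:s")
  expect_setequal(setdiff(names(res$ontology$terms), names(o$terms)),
                  "IEDB:by-role")
  expect_equal(nrow(res$map), 0L)
})

test_that("mirroring is idempotent and needs a designated structural root", {
  o <- role_fixture()
  seeds <- seeds_from_subset(o)
  once <- mirror_roles(o, seeds)
  twice <- mirror_roles(once$ontology, seeds)
  expect_equal(twice$ontology$terms, once$ontology$terms)
  expect_equal(twice$map, once$map)
  # two structural roots and no designation: config error
  o2 <- mk_onto(parents = list(`M:a` = "M:r1", `M:b` = "M:r2"),
                seeds = "M:a")
  expect_error(mirror_roles(o2, "M:a"), "structural root")
})

test_that("role gaps list roleless seeds; other_only needs all-other parents", {
  o <- mk_onto(
    parents = list(`G:s1` = "G:oth", `G:s2` = "G:named", `G:s3` = "G:ce",
                   `G:oth` = "G:ce", `G:named` = "G:ce", `G:r` = "G:role"),
    roles = list(`G:s3` = "G:r"),
    seeds = c("G:s1", "G:s2", "G:s3"),
    nm = c(`G:ce` = "chemical entity", `G:role` = "role",
           `G:oth` = "other carbohydrate", `G:named` = "monosaccharide"))
  seeds <- c("G:s1", "G:s2", "G:s3")
  all_rows <- role_gap_report(o, seeds, "all")
  expect_setequal(all_rows$id, c("G:s1", "G:s2"))
  other_rows <- role_gap_report(o, seeds, "other_only")
  expect_equal(other_rows$id, "G:s1")
  expect_equal(other_rows$parents, "other carbohydrate")
  expect_match(other_rows$link, "G:s1", fixed = TRUE)
  expect_named(all_rows, c("id", "link", "name", "parents", "disposition"))
})

test_that("gap reports equal brute-force set differences on random fixtures", {
  for (seed in c(51, 55, 59)) {
    gen <- generate_ontology(corpus_params(seed))
    o <- gen$ontology
    R <- closure_oracle(o)
    roleless <- gen$seeds[vapply(gen$seeds, function(s) {
      scope <- c(s, names(which(R[s, ])))
      length(unlist(lapply(scope, function(i) o$terms[[i]]$roles))) == 0
    }, logical(1))]
    expect_setequal(role_gap_report(o, gen$seeds, "all")$id, roleless)
    oth <- roleless[vapply(roleless, function(s) {
      ps <- o$terms[[s]]$is_a
      length(ps) > 0 && all(startsWith(tolower(
        vapply(ps, function(p) o$terms[[p]]$name, character(1))), "other "))
    }, logical(1))]
    expect_setequal(role_gap_report(o, gen$seeds, "other_only")$id, oth)
  }
})

test_that("role assignments: NR annotates, existing assigns, NEW creates", {
  o <- role_fixture()
  seeds <- seeds_from_subset(o)
  rows <- data.frame(
    id = c("R:loose", "R:amox"),
    disposition = c("NR", "NEW:pesticide|R:application"),
    stringsAsFactors = FALSE)
  res <- apply_role_assignments(o, rows)
  expect_equal(res$summary, list(nr = 1L, assigned = 1L, created = 1L))
  m <- res$ontology
  expect_true("no_role" %in% m$terms[["R:loose"]]$subsets)
  new_role <- names(m$terms)[vapply(m$terms, function(t)
    identical(t$name, "pesticide"), logical(1))]
  expect_length(new_role, 1)
  expect_equal(onto_parents(m, new_role), "R:application")
  expect_true(new_role %in% direct_roles(m, "R:amox"))
  # NR terms leave the gap report for good
  expect_false("R:loose" %in% role_gap_report(m, seeds, "all")$id)
  # empty row set is the identity
  res0 <- apply_role_assignments(o, rows[0, , drop = FALSE])
  expect_equal(res0$ontology$terms, o$terms)
  expect_equal(res0$summary, list(nr = 0L, assigned = 0L, created = 0L))
})

test_that("bad assignments are rejected", {
  o <- role_fixture()
  expect_error(apply_role_assignments(o, data.frame(
    id = "R:amox", disposition = "NEW:x|R:pen")), "outside the role branch")
  expect_error(apply_role_assignments(o, data.frame(
    id = "R:amox", disposition = "R:nosuchrole")), "unknown")
  expect_error(apply_role_assignments(o, data.frame(
    id = c("R:amox", "R:amox"), disposition = c("NR", "R:hormone"))),
    "conflicting")
})

test_that("assignment files round-trip the gap-report columns", {
  txt <- "id\tdisposition\nX:1\tNR\n"
  rows <- read_role_assignments(txt)
  expect_equal(rows$id, "X:1")
  expect_equal(rows$disposition, "NR")
  txt2 <- "id\tlink\tname\tparents\tassigned_disposition\nX:1\tu\tn\tp\tNR\n"
  expect_equal(read_role_assignments(txt2)$disposition, "NR")
  expect_error(read_role_assignments("foo\tbar\n"), "columns")
})
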