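test_that("newick parsing validates ultrametricity and structure", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "clade_tree")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(max(ape::branching.times(tr)), 2)

  expect_error(parse_newick("((A:1,B:2):1,C:2);"), "not ultrametric.*tip")
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "malformed")
  expect_error(parse_newick("(A:1);"), "at least 2 tips")
  expect_error(parse_newick("((A:1,B:1):1,C:2);", tol = 0), NA)

  ## polytomies rejected by default, resolvable on request
  poly <- "((A:1,B:1,C:1):1,D:2);"
  expect_error(parse_newick(poly), "polytomies")
  expect_warning(tr2 <- parse_newick(poly, resolve_polytomies = TRUE),
                 "zero-length")
  expect_true(ape::is.binary(tr2))
  expect_equal(sort(ape::branching.times(tr2), decreasing = TRUE)[1:2],
               c(2, 1), ignore_attr = TRUE)
})

test_that("round-trip through newick preserves branching times", {
  set.seed(5)
  lam <- rate_spec("speciation", "constant", 0.4)
  mu <- rate_spec("extinction", "constant", 0.1)
  tr <- simulate_tree(lam, mu, 10, 1, seed = 3)
  txt <- ape::write.tree(tr)
  tr2 <- parse_newick(txt)
  expect_equal(branching_times(tr)$ages, branching_times(tr2)$ages,
               tolerance = 1e-9)
})

test_that("branching times read off the topology, sorted descending", {
  expect_equal(branching_times(parse_newick("((A:1,B:1):1,C:2);"))$ages,
               c(2, 1))
  expect_equal(branching_times(parse_newick("(A:5,B:5);"))$ages, 5)
  bal <- parse_newick("((A:3,B:3):7,(C:6,D:6):4);")
  expect_equal(branching_times(bal)$ages, c(10, 6, 3))
  expect_error(new_branching_times(c(10, 6), n_tips = 4), "n_tips - 1")
})

test_that("lineage counting uses the half-open (age, crown] convention", {
  bt <- new_branching_times(c(10, 6, 3))
  expect_equal(lineage_count_at(bt, 7), 2L)
  expect_equal(lineage_count_at(bt, 0), 4L)
  expect_equal(lineage_count_at(bt, 10), 2L)
  expect_equal(lineage_count_at(bt, 6), 2L)   # event at 6 not yet occurred
  expect_equal(lineage_count_at(bt, 5.999), 3L)
  expect_error(lineage_count_at(bt, 11), "0, crown_age")
  expect_error(lineage_count_at(bt, -1), "0, crown_age")
})

test_that("lineage counts from branching times match direct LTT at random ages", {
  lam <- rate_spec("speciation", "constant", 0.5)
  mu <- rate_spec("extinction", "constant", 0.2)
  for (s in 1:3) {
    tr <- simulate_tree(lam, mu, 8, 1, seed = 40 + s)
    bt <- branching_times(tr)
    nt <- ape::Ntip(tr)
    node_ages <- ape::branching.times(tr)
    set.seed(s)
    for (age in runif(100, 0, bt$ages[1])) {
      ## direct traversal: lineages crossing `age` = 2 + events older than age
      ## counted from the node ages themselves
      direct <- 1L + sum(node_ages > age)
      expect_equal(lineage_count_at(bt, age), direct)
    }
  }
})

test_that("truncation age marks the event creating the (m+1)-th lineage", {
  ## 12 tips: brute-force LTT scan says count > 10 strictly below ages[10]
  set.seed(7)
  ages <- sort(runif(11, 0.5, 20), decreasing = TRUE)
  bt <- new_branching_times(ages, 12L)
  tr <- truncation_age(bt, 10L)
  expect_true(tr$analyzable)
  expect_equal(tr$age, ages[10])
  expect_gt(lineage_count_at(bt, tr$age * 0.999), 10L)
  expect_lte(lineage_count_at(bt, tr$age * 1.001), 10L)

  bt8 <- new_branching_times(sort(runif(7, 1, 10), decreasing = TRUE), 8L)
  tr8 <- truncation_age(bt8, 10L)
  expect_false(tr8$analyzable)
  expect_equal(tr8$age, 0)

  expect_equal(truncation_age(bt, 2L)$age, ages[2])
  expect_error(truncation_age(bt, 1L), ">= 2")
})

test_that("maximal region-enriched clades are found and are maximal", {
  tr <- parse_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  flags <- c(A = "in", B = "in", C = "out", D = "in")
  out <- extract_neotropical_clades(tr, flags, threshold = 0.8, min_tips = 2)
  expect_length(out, 1L)
  expect_setequal(out[[1]]$tip.label, c("A", "B"))

  all_in <- extract_neotropical_clades(tr, c(A = "in", B = "in", C = "in",
                                             D = "in"))
  expect_length(all_in, 1L)
  expect_equal(ape::Ntip(all_in[[1]]), 4L)

  expect_error(extract_neotropical_clades(tr, character(0)), "empty")
  expect_error(extract_neotropical_clades(tr, c(A = "in")), "unflagged")
})

test_that("extracted clades form an antichain meeting the threshold (brute force)", {
  lam <- rate_spec("speciation", "constant", 0.6)
  mu <- rate_spec("extinction", "constant", 0.1)
  for (s in 1:5) {
    tr <- simulate_tree(lam, mu, 6, 1, seed = 90 + s, max_lineages = 64)
    if (ape::Ntip(tr) < 6) next
    set.seed(s)
    flags <- setNames(sample(c("in", "out"), ape::Ntip(tr), TRUE,
                             prob = c(0.7, 0.3)), tr$tip.label)
    for (thr in c(0.8, 1.0)) {
      out <- extract_neotropical_clades(tr, flags, threshold = thr)
      sets <- lapply(out, function(x) sort(x$tip.label))
      ## every returned clade meets the threshold
      for (ts in sets)
        expect_gte(mean(flags[ts] == "in"), thr)
      ## antichain: no returned clade nested in another
      if (length(sets) > 1) {
        for (i in seq_along(sets)) for (j in seq_along(sets)) {
          if (i != j) expect_false(all(sets[[i]] %in% sets[[j]]))
        }
      }
      ## maximality vs brute-force enumeration: every qualifying clade is
      ## contained in some returned clade
      for (ts in all_clade_tipsets(tr)) {
        if (length(ts) >= 2 && mean(flags[ts] == "in") >= thr) {
          expect_true(any(vapply(sets, function(x) all(ts %in% x), TRUE)))
        }
      }
    }
  }
})
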