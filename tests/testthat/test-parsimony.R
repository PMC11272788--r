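toy_matrix <- function() {
  new_character_matrix_from_df(data.frame(
    taxon = c("A", "B", "C", "D"), c1 = c("0", "0", "1", "1")
  ))
}

test_that("TNT xread matrices round-trip taxa, states, polymorphism and ccode", {
  path <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c(
    "xread", "'toy data'", "4 4",
    "A 0100", "B 0[01]01", "C 11?2", "D 1-12", ";",
    "cc + 1 3;"
  ), path)
  cm <- read_character_matrix(path)
  expect_equal(cm$taxa, c("A", "B", "C", "D"))
  expect_equal(cm$n_char, 4L)
  expect_equal(unname(cm$states["B", 2]), "01")
  expect_equal(unname(cm$states["C", 3]), "?")
  expect_equal(unname(cm$states["D", 2]), "-")
  expect_equal(cm$symbols, c("0", "1", "2"))
  # ccode indices are 0-based
  expect_equal(cm$ordered, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("NEXUS matrices parse dimensions, polymorphism and interleaving", {
  path <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=3 NCHAR=4;",
    "FORMAT MISSING=? GAP=- SYMBOLS=\"012\";",
    "MATRIX",
    "t1 0(01)", "t2 11", "t3 20",
    "t1 1?", "t2 11", "t3 -0",
    ";", "END;"
  ), path)
  cm <- read_character_matrix(path)
  expect_equal(cm$taxa, c("t1", "t2", "t3"))
  expect_equal(cm$n_char, 4L)
  expect_equal(cm$states["t1", ], c("0", "01", "1", "?"), ignore_attr = TRUE)
  expect_equal(unname(cm$states["t3", 3]), "-")
})

test_that("malformed matrices are rejected with informative errors", {
  ragged <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c("xread", "3 2", "A 010", "B 01", ";"), ragged)
  expect_error(read_character_matrix(ragged), "expected 3")
  wrong_n <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c("xread", "2 3", "A 01", "B 01", ";"), wrong_n)
  expect_error(read_character_matrix(wrong_n), "taxa")
})

test_that("a single shared derived state costs one step on the matching topology", {
  ps <- fitch_length("((A,B),(C,D));", toy_matrix())
  expect_equal(ps$tree_length, 1L)
  expect_equal(ps$ci, 1)
  expect_equal(ps$ri, 1)
  per <- tidy(ps)
  expect_equal(per$min_steps, 1L)
  expect_equal(per$max_steps, 2L)
  # the same character on the conflicting topology costs two steps
  ps2 <- fitch_length("((A,C),(B,D));", toy_matrix())
  expect_equal(ps2$tree_length, 2L)
})

test_that("constant characters cost nothing and leave CI/RI undefined when alone", {
  cm <- new_character_matrix_from_df(data.frame(
    taxon = c("A", "B", "C", "D"), c1 = rep("1", 4)
  ))
  ps <- fitch_length("((A,B),(C,D));", cm)
  expect_equal(ps$tree_length, 0L)
  expect_true(is.na(ps$ci))
  expect_true(is.na(ps$ri))
  expect_equal(nrow(map_changes("((A,B),(C,D));", cm)), 0L)
})

test_that("missing data and polymorphism are free at the tip", {
  cm <- new_character_matrix_from_df(data.frame(
    taxon = c("A", "B", "C", "D"),
    c1 = c("01", "?", "1", "1"), # everything compatible with all-1
    c2 = c("0", "0", "0", "-")
  ))
  ps <- fitch_length("((A,B),(C,D));", cm)
  expect_equal(ps$tree_length, 0L)
})

test_that("ordered characters accumulate the state range", {
  cm <- new_character_matrix_from_df(
    data.frame(taxon = c("A", "B", "C", "D"), c1 = c("0", "0", "2", "2")),
    ordered = TRUE
  )
  ps <- fitch_length("((A,B),(C,D));", cm)
  expect_equal(ps$tree_length, 2L) # one 0->2 transition costs two steps
  unord <- fitch_length(
    "((A,B),(C,D));",
    new_character_matrix_from_df(
      data.frame(taxon = c("A", "B", "C", "D"), c1 = c("0", "0", "2", "2"))
    )
  )
  expect_equal(unord$tree_length, 1L)
})

test_that("mapped changes land on the right branch and conserve the tree length", {
  changes <- map_changes("((A,B),(C,D));", toy_matrix())
  expect_equal(nrow(changes), 1L)
  # the single change is on an internal branch, not at a tip
  expect_match(changes$child_label, "^node:")
  set.seed(202)
  for (i in 1:20) {
    inst <- random_parsimony_instance(sample(4:7, 1), 3, 4)
    cm <- new_character_matrix_from_df(inst$states)
    ps <- fitch_length(inst$phy, cm)
    ch <- map_changes(inst$phy, cm)
    expect_equal(sum(ch$cost), ps$tree_length)
  }
})

test_that("tree length equals the exhaustive minimum over internal assignments", {
  set.seed(404)
  for (i in 1:40) {
    n_tip <- sample(4:7, 1)
    inst <- random_parsimony_instance(n_tip, sample(2:4, 1), 2)
    cm <- new_character_matrix_from_df(inst$states)
    cm$ordered[1] <- sample(c(TRUE, FALSE), 1)
    mine <- fitch_length(inst$phy, cm)
    brute <- sum(vapply(seq_len(cm$n_char), function(j) {
      W <- clawmorph:::step_matrix(cm$symbols, cm$ordered[j])
      sets <- clawmorph:::cell_state_sets(
        cm$states[match(inst$phy$tip.label, cm$taxa), j], cm$symbols
      )
      brute_force_steps(inst$phy, sets, W)
    }, numeric(1)))
    expect_equal(mine$tree_length, as.integer(brute))
  }
})

test_that("tree length agrees with phangorn's Fitch implementation", {
  set.seed(77)
  for (i in 1:20) {
    n_tip <- sample(4:10, 1)
    inst <- random_parsimony_instance(n_tip, 3, 6)
    cm <- new_character_matrix_from_df(inst$states)
    mine <- fitch_length(inst$phy, cm)$tree_length
    pd <- phangorn::phyDat(inst$states, type = "USER", levels = c("0", "1", "2"))
    expect_equal(mine, as.integer(phangorn::parsimony(inst$phy, pd)))
  }
})

test_that("the score is invariant to re-rooting the topology", {
  set.seed(31)
  inst <- random_parsimony_instance(7, 3, 5)
  cm <- new_character_matrix_from_df(inst$states)
  base <- fitch_length(inst$phy, cm)$tree_length
  for (node in c(2, 5, 9)) {
    rerooted <- ape::root(inst$phy, outgroup = inst$phy$tip.label[node %% 7 + 1], resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, cm)$tree_length, base)
  }
})

test_that("CI and RI are 1 for a perfectly hierarchical matrix", {
  # nested synapomorphies on a pectinate tree: no homoplasy
  taxa <- paste0("t", 1:6)
  states <- sapply(1:5, function(j) ifelse(seq_along(taxa) > j, "1", "0"))
  rownames(states) <- taxa
  cm <- new_character_matrix_from_df(states)
  tree <- "(t1,(t2,(t3,(t4,(t5,t6)))));"
  ps <- fitch_length(tree, cm)
  expect_equal(ps$tree_length, 5L)
  expect_equal(ps$ci, 1)
  expect_equal(ps$ri, 1)
})

test_that("fitch_length validates tips against the matrix", {
  expect_error(fitch_length("((A,B),(C,E));", toy_matrix()), "absent from matrix")
})
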