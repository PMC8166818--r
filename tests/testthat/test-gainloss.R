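test_that("textbook reconstructions place gains and losses correctly", {
  tr <- read_newick(text = "((A,B),(C,D));")

  all_on <- dollo_reconstruct(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_true(all_on$at_root)
  expect_equal(all_on$n_losses, 0L)

  cherry <- dollo_reconstruct(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(cherry$gain_edge, "A|B")
  expect_equal(cherry$n_losses, 0L)

  split <- dollo_reconstruct(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_true(split$at_root)
  expect_equal(sort(split$loss_edges), c("B", "D"))
  expect_equal(split$n_losses,
               oracle_dollo_min_losses(tr, c(A = 1, B = 0, C = 1, D = 0)))

  one <- dollo_reconstruct(tr, c(A = 0, B = 0, C = 1, D = 0))
  expect_equal(one$gain_edge, "C")
  expect_equal(one$n_losses, 0L)

  expect_error(dollo_reconstruct(tr, c(A = 0, B = 0, C = 0, D = 0)),
               "absent")
  expect_error(dollo_reconstruct(ape::unroot(read_newick(text = "((A,B),(C,D),E);",
                                                         require_rooted = FALSE)),
                                 c(A = 1, B = 1, C = 0, D = 0, E = 0)),
               "rooted")
})

test_that("reconstruction is loss-minimal and fits the leaves exactly", {
  for (seed in 1:12) {
    n <- sample(4:6, 1)
    tr <- generate_random_tree(n, seed)
    n_tip <- length(tr$tip.label)
    for (code in seq_len(2^n_tip - 1L)) {
      pres <- setNames(as.integer(intToBits(code)[1:n_tip]), tr$tip.label)
      h <- dollo_reconstruct(tr, pres)
      expect_equal(h$n_losses, oracle_dollo_min_losses(tr, pres))
      expect_equal(unname(h$implied_presence[1:n_tip]), unname(pres))
    }
  }
})

test_that("adding a present leaf never moves the gain edge tipward", {
  for (seed in 1:10) {
    tr <- generate_random_tree(7, seed)
    set.seed(seed)
    pres <- setNames(sample(0:1, 7, replace = TRUE), tr$tip.label)
    if (!any(pres == 1) || all(pres == 1)) next
    h1 <- dollo_reconstruct(tr, pres)
    added <- sample(names(pres)[pres == 0], 1)
    pres2 <- pres; pres2[added] <- 1L
    h2 <- dollo_reconstruct(tr, pres2)
    tips1 <- if (h1$at_root) tr$tip.label else
      tr$tip.label[notchtrace:::tips_under(tr, h1$gain_node)]
    tips2 <- if (h2$at_root) tr$tip.label else
      tr$tip.label[notchtrace:::tips_under(tr, h2$gain_node)]
    expect_true(all(tips1 %in% tips2))
  }
})

test_that("simulated histories round-trip when they are the unique optimum", {
  tr <- read_newick(text = "((A,B),((C,D),(E,F)));")
  sim <- simulate_gainloss(tr, "C|D|E|F", loss_edges = c("D", "F"),
                           family = "fam")
  expect_equal(unname(sim$presence[c("C", "E")]), c(1L, 1L))
  expect_equal(sum(sim$presence), 2L)
  h <- dollo_reconstruct(tr, sim$presence, family = "fam")
  expect_equal(h$gain_edge, sim$truth$gain_edge)
  expect_equal(sort(h$loss_edges), sort(sim$truth$loss_edges))

  # simulator contract errors
  expect_error(simulate_gainloss(tr, "A|B", loss_edges = "C"), "below")
  expect_error(simulate_gainloss(tr, "C|D|E|F", loss_edges = c("C|D", "C")),
               "non-nested")
  # gain at root edge, no losses: everything present
  root_sim <- simulate_gainloss(tr, "A|B|C|D|E|F")
  expect_true(all(root_sim$presence == 1L))
})

test_that("loss annotation names leaves and clades", {
  tr <- read_newick(text = "((A,B),(C,D));")
  h <- dollo_reconstruct(tr, c(A = 1, B = 0, C = 1, D = 1))
  expect_equal(annotate_losses(h, tr), "B")
  h2 <- dollo_reconstruct(tr, c(A = 1, B = 1, C = 0, D = 0))
  # gain sits at A|B: no loss edges at all
  expect_equal(annotate_losses(h2, tr), character(0))
  h3 <- dollo_reconstruct(tr, c(A = 1, B = 0, C = 0, D = 0))
  expect_equal(h3$gain_edge, "A")
})

test_that("matrix-level reconstruction ranks deeper origins first", {
  tr <- read_newick(text = "((A,B),(C,D));")
  m <- rbind(old = c(A = 1, B = 1, C = 1, D = 1),
             young = c(A = 1, B = 1, C = 0, D = 0))
  hl <- gainloss_matrix(tr, m)
  expect_equal(names(hl), c("old", "young"))
  expect_true(attr(hl, "table")$at_root[1])
  bad <- m; colnames(bad) <- c("A", "B", "C", "X")
  expect_error(gainloss_matrix(tr, bad), "mismatch")
})

test_that("the mollusc fixture yields the planted single-gain three-loss history", {
  fix <- mollusc_fixture(seed = 7)
  h <- dollo_reconstruct(fix$tree, fix$presence["Delta2", ], family = "Delta2")
  expect_equal(h$gain_edge, fix$truth$delta2_gain_edge)
  expect_equal(sort(annotate_losses(h, fix$tree)), c("GasC", "GasD", "GasE"))
  expect_equal(h$n_losses, 3L)
  expect_equal(h$n_losses,
               oracle_dollo_min_losses(fix$tree, fix$presence["Delta2", ]))

  hh <- dollo_reconstruct(fix$tree, fix$presence["Helt", ], family = "Helt")
  expect_equal(sort(hh$loss_edges), fix$truth$helt_loss_edges)
})
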