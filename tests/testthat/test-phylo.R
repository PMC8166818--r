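aln_from <- function(...) {
  seqs <- c(...)
  multiple_alignment(data.frame(id = names(seqs), sequence = unname(seqs),
                                stringsAsFactors = FALSE))
}

test_that("gap-fraction trimming retains exactly the passing columns", {
  msa <- aln_from(a = "AC-A", b = "AC-A", c = "A--A", d = "AC-A")
  trimmed <- trim_alignment(msa, 0.5)
  expect_equal(ncol(unclass(trimmed)), 3L)          # col 3 (4/4 gaps) removed
  t2 <- trim_alignment(msa, 1.0)
  expect_equal(ncol(unclass(t2)), 4L)
  gapfree <- aln_from(a = "ACDE", b = "ACDF")
  expect_identical(unclass(trim_alignment(gapfree, 0)), unclass(gapfree))
  all_gap <- aln_from(a = "--", b = "--")
  expect_error(trim_alignment(all_gap, 0.4), "gap-fraction")
})

test_that("p-distance counts mismatches over comparable columns only", {
  m <- p_distance(aln_from(a = "AAAA", b = "AAAT"))
  expect_equal(m["a", "b"], 0.25)
  m2 <- p_distance(aln_from(a = "A-AA", b = "ATAA"))
  expect_equal(m2["a", "b"], 0)
  m3 <- p_distance(aln_from(a = "A---", b = "-TTT"))
  expect_true(is.na(m3["a", "b"]))
  ident <- p_distance(aln_from(a = "ACD", b = "ACD"))
  expect_equal(ident["a", "b"], 0)

  # metric property on gap-free alignments
  set.seed(2)
  for (r in 1:10) {
    seqs <- replicate(4, paste(sample(c("A", "C", "D", "E"), 30, TRUE),
                               collapse = ""))
    names(seqs) <- paste0("t", 1:4)
    d <- p_distance(aln_from(seqs))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_true(d[i, j] <= d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("neighbor joining solves the worked additive case exactly", {
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  # split AB|CD with branch lengths A:1 B:2 C:3 D:1, internal 1
  expect_equal(ape::dist.topo(ape::unroot(tr),
                              ape::unroot(read_newick(text = "((A:1,B:2):1,(C:3,D:1):0);",
                                                      require_rooted = FALSE))),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  got <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                  tr$tip.label[tr$edge[tr$edge[, 2] <= 4, 2]])
  expect_equal(got[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 1))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sum(internal), 1)

  # three taxa: closed-form star
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(d3)
  expect_equal(sort(setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])),
               sort(c(x = 1, y = 1, z = 3)))

  dd <- d; dd["A", "B"] <- NA; dd["B", "A"] <- NA
  expect_error(neighbor_joining(dd), "missing")
})

test_that("NJ recovers the generating topology on additive distances", {
  for (seed in 1:20) {
    tr <- generate_random_tree(8, seed)
    d <- cophenetic(tr)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    est <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0,
                 label = paste("seed", seed))
    # cross-check against the reference NJ implementation
    ref <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(est, ref)), 0)
  }
})

test_that("bootstrap support is exact for pure-signal alignments", {
  groups <- list(left = paste0("L", 1:4), right = paste0("R", 1:4))
  pure <- generate_group_alignment(groups, n_signal = 10, n_shared = 0,
                                   seed = 3)
  st <- bootstrap_support(pure, reps = 7, seed = 11)
  # the left/right split must be present with support 100
  target <- paste(sort(groups$right), collapse = "|")
  expect_true(target %in% names(st$support))
  expect_equal(unname(st$support[target]), 100)

  one <- bootstrap_support(pure, reps = 1, seed = 4)
  expect_true(all(one$support %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to row order given the seed", {
  groups <- list(left = paste0("L", 1:4), right = paste0("R", 1:4))
  msa <- generate_group_alignment(groups, n_signal = 8, n_shared = 12,
                                  seed = 5)
  st1 <- bootstrap_support(msa, reps = 25, seed = 9)
  set.seed(1)
  perm <- unclass(msa)[sample(8), , drop = FALSE]
  class(perm) <- c("multiple_alignment", class(perm))
  st2 <- bootstrap_support(perm, reps = 25, seed = 9)
  common <- intersect(names(st1$support), names(st2$support))
  expect_true(length(common) >= 1)
  expect_equal(st1$support[common], st2$support[common])
})

test_that("monophyly tests root on the outgroup correctly", {
  tr <- read_newick(text = "((d2a,d2b),(d1a,d1b),og);", require_rooted = FALSE)
  expect_true(is_monophyletic(tr, c("d2a", "d2b"), "og"))
  expect_false(is_monophyletic(tr, c("d2a", "d1a"), "og"))
  expect_true(is_monophyletic(tr, c("d2a", "d2b", "d1a", "d1b"), "og"))
  expect_error(is_monophyletic(tr, c("nope"), "og"), "unknown")
  expect_error(is_monophyletic(tr, c("d2a", "og"), "og"), "outgroup")
})

test_that("clade-based subtype assignment recovers planted subtypes", {
  groups <- list(Hes = c("ref_hes1", "ref_hes2", "q_hes"),
                 Hey = c("ref_hey1", "ref_hey2", "q_hey"),
                 Helt = c("ref_helt1", "ref_helt2", "q_helt"),
                 Cwo = c("ref_cwo1", "ref_cwo2", "q_cwo"),
                 out = "og")
  msa <- generate_group_alignment(groups, n_signal = 25, n_shared = 20,
                                  seed = 8)
  nj <- neighbor_joining(p_distance(msa))
  rooted <- ape::root(nj, outgroup = "og", resolve.root = TRUE)
  refs <- c(ref_hes1 = "Hes", ref_hes2 = "Hes", ref_hey1 = "Hey",
            ref_hey2 = "Hey", ref_helt1 = "Helt", ref_helt2 = "Helt",
            ref_cwo1 = "Cwo", ref_cwo2 = "Cwo")
  got <- assign_subtype_by_clade(rooted, refs)
  expect_equal(got[["q_hes"]], "Hes")
  expect_equal(got[["q_hey"]], "Hey")
  expect_equal(got[["q_helt"]], "Helt")
  expect_equal(got[["q_cwo"]], "Cwo")
  # the outgroup query sits outside every reference clade -> ambiguous
  expect_equal(got[["og"]], "ambiguous")
  expect_error(assign_subtype_by_clade(rooted, character(0)), "reference")
})
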