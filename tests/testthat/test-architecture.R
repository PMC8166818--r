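mk_hits <- function(gene_id, specs) {
  # specs: list of c(domain, start, end, e)
  do.call(rbind, lapply(specs, function(s)
    data.frame(gene_id = gene_id, domain_name = s[[1]],
               pfam_accession = "",
               env_start = as.integer(s[[2]]), env_end = as.integer(s[[3]]),
               e_value = as.numeric(s[[4]]), stringsAsFactors = FALSE)))
}

test_that("hit filtering keeps exactly the hits at or below threshold", {
  hits <- mk_hits("g", list(c("EGF", 1, 30, 1e-6), c("EGF", 40, 70, 1e-4),
                            c("DSL", 80, 120, 1e-5)))
  kept <- filter_hits(hits, 1e-5)
  expect_equal(kept$e_value, c(1e-6, 1e-5))
  expect_equal(nrow(filter_hits(hits[0, ], 1e-5)), 0L)

  tab <- random_hit_table(500, seed = 3)
  expect_equal(filter_hits(tab, 1e-5), tab[tab$e_value <= 1e-5, ])
})

test_that("overlap resolution is dominance-correct and matches the oracle", {
  two <- mk_hits("g", list(c("EGF", 10, 40, 1e-10), c("DSL", 10, 40, 1e-3)))
  kept <- resolve_overlaps(two)
  expect_equal(kept$domain_name, "EGF")

  disjoint <- mk_hits("g", list(c("EGF", 1, 30, 1e-3), c("DSL", 40, 80, 1e-4)))
  expect_equal(nrow(resolve_overlaps(disjoint)), 2L)

  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    start <- sample.int(60L, n, replace = TRUE)
    h <- data.frame(gene_id = "g", domain_name = sample(c("EGF", "DSL"), n, TRUE),
                    pfam_accession = "",
                    env_start = start, env_end = start + sample.int(40L, n, TRUE),
                    e_value = 10^runif(n, -12, -2), stringsAsFactors = FALSE)
    expect_equal(resolve_overlaps(h), oracle_resolve(h))
  }
})

test_that("classification follows the family definitions", {
  sigs <- notch_signatures()
  delta_hits <- mk_hits("g", list(c("MNLL", 1, 30, 1e-9), c("DSL", 45, 90, 1e-9),
                                  c("EGF", 100, 130, 1e-9),
                                  c("EGF", 140, 170, 1e-9)))
  g <- gene_model("g", "sp", hits = delta_hits)
  expect_equal(classify_gene(g, sigs)$family, "Delta")

  jag_hits <- rbind(delta_hits,
                    mk_hits("g", list(c("VWC", 200, 260, 1e-9))))
  expect_equal(classify_gene(gene_model("g", "sp", hits = jag_hits),
                             sigs)$family, "Jagged")

  dll <- gene_model("g", "sp", hits = mk_hits("g", list(c("DSL", 10, 60, 1e-9))))
  expect_equal(classify_gene(dll, sigs)$family, "Dll")

  none <- gene_model("g", "sp", hits = empty_domain_hits())
  a <- classify_gene(none, sigs)
  expect_equal(a$family, "unassigned")
  expect_true(nrow(a$failure_reasons) > 0)

  bhlh_only <- gene_model("g", "sp",
                          hits = mk_hits("g", list(c("bHLH", 5, 60, 1e-9))))
  expect_equal(classify_gene(bhlh_only, sigs)$family, "HesHey")
})

test_that("classification is hit-order invariant and decoy-proof", {
  sigs <- notch_signatures()
  for (fam in names(sigs)) {
    g <- generate_gene_with_architecture(fam, sigs, seed = 91)$gene
    base <- classify_gene(g, sigs)$family
    shuffled <- g
    set.seed(1)
    shuffled$hits <- g$hits[sample(nrow(g$hits)), , drop = FALSE]
    expect_equal(classify_gene(shuffled, sigs)$family, base)
    decoyed <- g
    decoyed$hits <- rbind(g$hits, mk_hits(g$gene_id, list(
      c("SH2", nchar(g$protein) - 20, nchar(g$protein) - 1, 1e-8))))
    decoyed$protein <- g$protein
    expect_equal(classify_gene(decoyed, sigs)$family, base)
  }
})

test_that("planted architectures are recovered for all nine families", {
  sigs <- notch_signatures()
  for (fam in names(sigs)) {
    for (seed in 1:5) {
      out <- generate_gene_with_architecture(fam, sigs, seed = seed)
      expect_equal(classify_gene(out$gene, sigs)$family,
                   out$truth$expected_assignment,
                   label = sprintf("%s seed %d", fam, seed))
      # planted hits are non-overlapping and ordered
      h <- out$gene$hits
      expect_true(all(diff(h$env_start) > 0))
      expect_true(all(h$env_start[-1] > h$env_end[-nrow(h)]))
      expect_true(nchar(out$gene$protein) >= max(h$env_end))
    }
  }
})

test_that("DSL instance enumeration and grouping follow the conventions", {
  two_dsl <- gene_model("g", "sp", hits = mk_hits("g", list(
    c("DSL", 100, 150, 1e-9), c("DSL", 10, 60, 1e-9))))
  expect_equal(enumerate_dsl_instances(two_dsl), c("g-1", "g-2"))
  one_dsl <- gene_model("g", "sp",
                        hits = mk_hits("g", list(c("DSL", 10, 60, 1e-9))))
  expect_equal(enumerate_dsl_instances(one_dsl), "g")
  no_dsl <- gene_model("g", "sp",
                       hits = mk_hits("g", list(c("EGF", 10, 40, 1e-9))))
  expect_equal(enumerate_dsl_instances(no_dsl), character(0))

  expect_equal(dsl_group(one_dsl), "dsl_only")
  tandem <- gene_model("g", "sp", hits = mk_hits("g", list(
    c("DSL", 10, 60, 1e-9), c("DSL", 70, 120, 1e-9), c("DSL", 130, 180, 1e-9))))
  expect_equal(dsl_group(tandem), "dsl_tandem")
  egf_other <- gene_model("g", "sp", hits = mk_hits("g", list(
    c("MNLL", 1, 30, 1e-9), c("DSL", 40, 90, 1e-9), c("EGF", 100, 130, 1e-9),
    c("VWC", 140, 199, 1e-9))))
  expect_equal(dsl_group(egf_other), "dsl_egf_other")
  egf <- gene_model("g", "sp", hits = mk_hits("g", list(
    c("DSL", 40, 90, 1e-9), c("EGF", 100, 130, 1e-9))))
  expect_equal(dsl_group(egf), "dsl_egf")
  expect_error(dsl_group(no_dsl), "DSL")
})

test_that("domain counting is additive and matches a hand tally", {
  g1 <- gene_model("a1", "S", hits = mk_hits("a1", list(
    c("EGF", 1, 30, 1e-9), c("EGF", 40, 70, 1e-9))))
  g2 <- gene_model("a2", "S", hits = mk_hits("a2", list(
    c("EGF", 1, 30, 1e-9), c("EGF", 40, 70, 1e-9))))
  tab <- count_domains(list(g1, g2))
  expect_equal(tab$count[tab$species_id == "S" & tab$domain_name == "EGF"], 4L)
  expect_equal(nrow(count_domains(list())), 0L)

  set.seed(5)
  genes <- lapply(1:9, function(i) {
    sp <- c("S1", "S2", "S3")[(i - 1) %% 3 + 1]
    n <- sample(1:4, 1)
    start <- cumsum(sample(30:60, n))
    gene_model(paste0("g", i), sp, hits = data.frame(
      gene_id = paste0("g", i),
      domain_name = sample(c("EGF", "DSL", "bHLH"), n, TRUE),
      pfam_accession = "", env_start = start - 20L, env_end = start,
      e_value = 1e-9, stringsAsFactors = FALSE))
  })
  tab <- count_domains(genes)
  flat <- do.call(rbind, lapply(genes, function(g)
    data.frame(sp = g$species_id, d = g$hits$domain_name)))
  for (r in seq_len(nrow(tab)))
    expect_equal(tab$count[r],
                 sum(flat$sp == tab$species_id[r] & flat$d == tab$domain_name[r]))
})

test_that("presence/absence matrix reflects assignments and duplications", {
  sigs <- notch_signatures()
  mk_assign <- function(gene, sp, fam)
    structure(list(gene_id = gene, species_id = sp, family = fam),
              class = "family_assignment")
  asg <- list(mk_assign("d1", "S", "Delta"), mk_assign("d2", "S", "Delta"),
              mk_assign("n1", "T", "Notch"))
  pa <- build_presence_absence(asg, species = c("S", "T"),
                               families = c("Delta", "Jagged", "Notch"))
  expect_equal(pa["Delta", "S"], 1L)
  expect_equal(attr(pa, "counts")["Delta", "S"], 2L)
  expect_equal(sum(pa["Jagged", ]), 0L)
  expect_error(build_presence_absence(list(mk_assign("x", "U", "Delta")),
                                      c("S"), c("Delta")), "species")
})
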