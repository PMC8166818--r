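sub_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483622L + 1L

#' Emit the complete synthetic fixture bundle
#'
#' Writes a toy dataset with planted truth for every pipeline stage:
#' domain-hit tables and proteins for genes of all nine core families across
#' the mollusc case-study taxa (Delta duplicated where Delta2 is present), a
#' species tree plus presence/absence matrix reproducing the mollusc Delta2
#' single-gain/three-loss pattern, four premature-termination plants (one
#' per mechanism), a planted two-clade ligand alignment, and a
#' developmental expression set in which Delta2 is complementary to Delta1
#' and Jagged tracks Delta2.  A `truth.json` manifest records every planted
#' value.
#'
#' @param seed integer master seed; the bundle is a pure function of it.
#' @param outdir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `outdir`, invisibly; files are written inside it.
#' @export
make_fixtures <- function(seed, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run_config(rng_seed = seed)
  write_config(cfg, file.path(outdir, "config.txt"))
  truth <- list(seed = seed)

  # --- species tree + presence/absence (mollusc case study) ---------------
  fix <- mollusc_fixture(seed = sub_seed(seed, 1L))
  write_newick(fix$tree, file.path(outdir, "species_tree.nwk"))
  write_presence_absence(fix$presence,
                         file.path(outdir, "presence_absence.tsv"),
                         comment = "synthetic mollusc case-study fixture")
  truth$gainloss <- fix$truth
  truth$clades <- fix$clades

  # --- genes for architecture classification -----------------------------
  sigs <- notch_signatures(cfg)
  species <- fix$tree$tip.label
  delta2_sp <- colnames(fix$presence)[fix$presence["Delta2", ] == 1L]
  helt_sp <- colnames(fix$presence)[fix$presence["Helt", ] == 1L]
  plan <- list()
  for (sp in species) {
    fams <- c("Notch", "Delta", "Jagged", "Presenilin", "SuH", "Hes")
    if (sp %in% helt_sp) fams <- c(fams, "Helt")
    for (f in fams) plan[[length(plan) + 1L]] <- list(sp = sp, fam = f,
                                                      tag = f)
    if (sp %in% delta2_sp)
      plan[[length(plan) + 1L]] <- list(sp = sp, fam = "Delta", tag = "Delta2")
  }
  genes <- list(); arch_truth <- list()
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    gid <- sprintf("%s_%s", p$sp, p$tag)
    g <- generate_gene_with_architecture(p$fam, sigs, seed = sub_seed(seed, 100L + i),
                                         species_id = p$sp, gene_id = gid)
    genes[[gid]] <- g$gene
    arch_truth[[gid]] <- g$truth$expected_assignment
  }
  all_hits <- do.call(rbind, lapply(genes, `[[`, "hits"))
  write_domain_hits(all_hits, file.path(outdir, "domain_hits.tsv"))
  write_fasta(data.frame(id = names(genes), description = "",
                         sequence = vapply(genes, `[[`, character(1), "protein"),
                         stringsAsFactors = FALSE),
              file.path(outdir, "proteins.faa"))
  write.table(data.frame(gene_id = names(genes),
                         species_id = vapply(genes, `[[`, character(1),
                                             "species_id")),
              file.path(outdir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth$architecture <- arch_truth

  # --- truncation plants (one per mechanism) ------------------------------
  # The frameshift mechanisms need a stop in the shifted reading of the
  # tail, which a given random reference may lack; retry over references.
  mechs <- c("insertion_stop", "substitution_nonsense",
             "deletion_frameshift", "insertion_frameshift")
  ref <- NULL; plants <- NULL
  for (attempt in 0:24) {
    cand <- generate_random_cds(150L, sub_seed(seed, 2L + 1000L * attempt))
    # plant an anchor arginine a few codons upstream of the targets
    cand <- paste0(substr(cand, 1L, 3L * 99L), "CGA",
                   substr(cand, 3L * 100L + 1L, nchar(cand)))
    ok <- lapply(seq_along(mechs), function(i) {
      for (target in 101L + i + c(0L, 4L, 8L, 12L)) {
        p <- tryCatch(plant_truncation(cand, mechs[[i]], target,
                                       seed = sub_seed(seed, 200L + i)),
                      error = function(e) NULL)
        if (!is.null(p)) return(p)
      }
      NULL
    })
    if (!any(vapply(ok, is.null, logical(1)))) { ref <- cand; plants <- ok; break }
  }
  if (is.null(ref)) stop("could not plant all four mechanisms", call. = FALSE)
  cds_records <- data.frame(id = "delta1_ref", description = "reference CDS",
                            sequence = ref, stringsAsFactors = FALSE)
  pair_rows <- list(); trunc_truth <- list()
  for (i in seq_along(mechs)) {
    planted <- plants[[i]]
    aid <- paste0("delta2_", mechs[[i]])
    cds_records <- rbind(cds_records,
                         data.frame(id = aid, description = "derived CDS",
                                    sequence = planted$cds,
                                    stringsAsFactors = FALSE))
    pair_rows[[i]] <- data.frame(pair_id = aid, ref_id = "delta1_ref",
                                 alt_id = aid, stringsAsFactors = FALSE)
    trunc_truth[[aid]] <- planted$truth
  }
  write_fasta(cds_records, file.path(outdir, "cds.fna"))
  write.table(do.call(rbind, pair_rows),
              file.path(outdir, "truncation_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth$truncation <- trunc_truth

  # --- planted two-clade ligand alignment ---------------------------------
  groups <- list(
    Delta1 = c("d1_BivA", "d1_CephA", "d1_GasA", "d1_Chiton"),
    Delta2 = c("d2_BivA", "d2_CephA", "d2_GasA", "d2_GasB"),
    outgroup = "og_sponge")
  msa <- generate_group_alignment(groups, n_signal = 20L, n_shared = 30L,
                                  seed = sub_seed(seed, 3L))
  write_alignment(msa, file.path(outdir, "ligand_alignment.faa"))
  truth$phylo <- groups

  # --- expression profiles (Delta1/Delta2 complementary, Jagged ~ Delta2) --
  stages <- c("Z", "C", "B", "G", "T", "D", "U", "J")
  pair <- generate_expression_pair(length(stages), "complementary",
                                   noise_sd = 0.25,
                                   seed = sub_seed(seed, 4L))
  d1 <- pair$a; d2 <- pair$b
  jag <- with_seed(sub_seed(seed, 5L),
                   pmax(d2 * runif(1, 0.5, 2) + runif(1, 0, 2) +
                          rnorm(length(stages), 0, 0.25), 0))
  expr <- rbind(Delta1 = d1, Delta2 = d2, Jagged = jag)
  colnames(expr) <- stages
  write_expression_matrix(round(expr, 4), file.path(outdir, "expression.tsv"),
                          comment = "synthetic RPKM-like developmental profiles")
  write.table(data.frame(gene_a = c("Delta1", "Delta1", "Delta2"),
                         gene_b = c("Delta2", "Jagged", "Jagged")),
              file.path(outdir, "expression_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth$expression <- list(Delta1_Delta2 = "complementary",
                           Delta2_Jagged = "similar",
                           jagged_nearest = "Delta2")

  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Build a pipeline manifest for a fixture bundle
#'
#' @param fixture_dir directory written by [make_fixtures()].
#' @param outdir directory for stage outputs.
#' @param stages stages to run.
#' @return a `pipeline_manifest` list.
#' @export
fixture_manifest <- function(fixture_dir, outdir,
                             stages = c("classify", "gainloss", "truncation",
                                        "phylo", "expression")) {
  f <- function(x) file.path(fixture_dir, x)
  manifest <- list(
    config = f("config.txt"),
    domain_hits = f("domain_hits.tsv"),
    proteins = f("proteins.faa"),
    genes = f("genes.tsv"),
    tree = f("species_tree.nwk"),
    presence = f("presence_absence.tsv"),
    cds = f("cds.fna"),
    truncation_pairs = f("truncation_pairs.tsv"),
    alignment = f("ligand_alignment.faa"),
    phylo_outgroup = "og_sponge",
    expression = f("expression.tsv"),
    expression_pairs = f("expression_pairs.tsv"),
    stages = stages,
    outdir = outdir)
  class(manifest) <- "pipeline_manifest"
  manifest
}

stamp <- function(cfg) sprintf("# notchtrace config=%s seed=%d",
                               config_hash(cfg), cfg$rng_seed)

write_stage_table <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp(cfg), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the end-to-end comparative analysis pipeline
#'
#' Executes, in dependency order, the stages named in the manifest:
#' `classify` (hit filtering, overlap resolution, family assignment,
#' presence/absence construction), `gainloss` (Dollo reconstruction of the
#' supplied family matrix on the species tree), `truncation`
#' (premature-termination mechanism typing of the paired CDSs), `phylo`
#' (trimming, NJ, bootstrap, clade monophyly on the supplied alignment),
#' and `expression` (pairwise profile comparisons and peak reports).  All
#' outputs are TSVs stamped with the config hash and seed; a machine-readable
#' JSON run report is written alongside.  Deterministic given the config.
#'
#' @param manifest a `pipeline_manifest` (see [fixture_manifest()]).
#' @return the run report (list), invisibly; outputs under `manifest$outdir`.
#' @export
run_pipeline <- function(manifest) {
  cfg <- if (is.character(manifest$config)) read_config(manifest$config)
  else manifest$config
  dir.create(manifest$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x) file.path(manifest$outdir, x)
  report <- list(config_hash = config_hash(cfg), seed = cfg$rng_seed,
                 stages = list())
  stages <- manifest$stages

  if ("classify" %in% stages) {
    hits <- read_domain_hits(manifest$domain_hits)
    prot <- read_fasta(manifest$proteins, "protein")
    gene_tab <- read.delim(manifest$genes, stringsAsFactors = FALSE)
    sigs <- notch_signatures(cfg)
    n_in <- nrow(hits)
    hits <- filter_hits(hits, cfg$e_value_threshold)
    nt_log("classify: %d hits in, %d pass E <= %g", n_in, nrow(hits),
           cfg$e_value_threshold)
    assignments <- lapply(seq_len(nrow(gene_tab)), function(i) {
      gid <- gene_tab$gene_id[[i]]
      gh <- resolve_overlaps(hits[hits$gene_id == gid, , drop = FALSE])
      gp <- prot$sequence[prot$id == gid]
      g <- gene_model(gid, gene_tab$species_id[[i]],
                      protein = if (length(gp)) gp else NULL, hits = gh)
      classify_gene(g, sigs, cfg)
    })
    adf <- do.call(rbind, lapply(assignments, function(a)
      data.frame(gene_id = a$gene_id, species_id = a$species_id,
                 family = a$family, stringsAsFactors = FALSE)))
    write_stage_table(adf, out("assignments.tsv"), cfg)
    fams <- sort(unique(adf$family[adf$family != "unassigned"]))
    sp <- sort(unique(adf$species_id))
    pa <- build_presence_absence(assignments, sp, fams)
    write_presence_absence(pa, out("presence_absence_classified.tsv"),
                           comment = sub("^# ", "", stamp(cfg)))
    cnt <- attr(pa, "counts")
    write_stage_table(data.frame(family = rownames(cnt), cnt,
                                 check.names = FALSE),
                      out("gene_counts.tsv"), cfg)
    report$stages$classify <- list(n_genes = nrow(adf),
                                   n_hits_in = n_in, n_hits_kept = nrow(hits),
                                   families = fams)
  }

  if ("gainloss" %in% stages) {
    tree <- read_newick(manifest$tree)
    pres <- read_presence_absence(manifest$presence)
    histories <- gainloss_matrix(tree, pres)
    tab <- attr(histories, "table")
    tab$losses_named <- vapply(histories[tab$family], function(h)
      paste(annotate_losses(h, tree), collapse = ";"), character(1))
    write_stage_table(tab, out("gainloss.tsv"), cfg)
    nt_log("gainloss: %d families reconstructed", nrow(tab))
    report$stages$gainloss <- list(n_families = nrow(tab))
    if ("Delta2" %in% tab$family) {
      h <- histories[["Delta2"]]
      report$stages$gainloss$delta2 <- list(
        gain_edge = h$gain_edge, n_losses = h$n_losses,
        losses = annotate_losses(h, tree))
    }
  }

  if ("truncation" %in% stages) {
    cds <- read_fasta(manifest$cds, "dna")
    pairs <- read.delim(manifest$truncation_pairs, stringsAsFactors = FALSE)
    reports <- list()
    for (i in seq_len(nrow(pairs))) {
      pr <- paralog_pair(cds$sequence[cds$id == pairs$ref_id[[i]]],
                         cds$sequence[cds$id == pairs$alt_id[[i]]],
                         ref_id = pairs$ref_id[[i]],
                         alt_id = pairs$alt_id[[i]])
      reports[[pairs$pair_id[[i]]]] <- classify_mechanism(pr, config = cfg)
    }
    write_stage_table(truncation_table(reports), out("truncation.tsv"), cfg)
    nt_log("truncation: %d pairs typed", length(reports))
    report$stages$truncation <- list(
      n_pairs = length(reports),
      mechanisms = vapply(reports, `[[`, character(1), "mechanism"))
  }

  if ("phylo" %in% stages) {
    msa <- read_alignment(manifest$alignment)
    msa <- trim_alignment(msa, cfg$gap_fraction_trim)
    st <- bootstrap_support(msa, reps = min(cfg$bootstrap_reps, 200L),
                            seed = cfg$rng_seed)
    write_newick(st$tree, out("nj_tree.nwk"))
    write_stage_table(data.frame(bipartition = names(st$support),
                                 support = as.numeric(st$support)),
                      out("bootstrap_support.tsv"), cfg)
    report$stages$phylo <- list(n_taxa = nrow(unclass(msa)),
                                n_columns = ncol(unclass(msa)))
    if (!is.null(manifest$phylo_outgroup)) {
      og <- manifest$phylo_outgroup
      grp <- sub("_.*$", "", setdiff(rownames(unclass(msa)), og))
      clades <- split(setdiff(rownames(unclass(msa)), og), grp)
      mono <- vapply(clades, function(cl)
        is_monophyletic(st$tree, cl, og), logical(1))
      report$stages$phylo$monophyly <- as.list(mono)
    }
  }

  if ("expression" %in% stages) {
    expr <- read_expression_matrix(manifest$expression)
    pairs <- read.delim(manifest$expression_pairs, stringsAsFactors = FALSE)
    comps <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      pc <- profile_similarity(expr[pairs$gene_a[[i]], ],
                               expr[pairs$gene_b[[i]], ], config = cfg)
      data.frame(gene_a = pairs$gene_a[[i]], gene_b = pairs$gene_b[[i]],
                 method = pc$method, score = round(pc$score, 6),
                 relation = pc$relation, n_stages = pc$n_stages,
                 stringsAsFactors = FALSE)
    }))
    write_stage_table(comps, out("expression_comparisons.tsv"), cfg)
    write_stage_table(stage_peak_report(expr), out("expression_peaks.tsv"),
                      cfg)
    report$stages$expression <- list(
      n_pairs = nrow(comps),
      low_expression = low_expression_flags(expr),
      relations = setNames(comps$relation,
                           paste(comps$gene_a, comps$gene_b, sep = "-")))
  }

  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
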