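# Small configuration used throughout so unit tests stay fast; the default
# configuration is exercised once by the end-to-end recovery test in
# test-acceptance.R.
small_config <- function(seed = 3L) {
  synthetic_config(
    seed = seed, n_species = 2L, proteins_per_species = 40L,
    domain_vocab_size = 30L, n_tsg = 25L, n_ocg = 15L, n_dual_overlap = 5L,
    n_planted_hubs = 3L, n_planted_secreted_hubs = 2L,
    hub_tsg_partner_target = 10L, frac_gene_annotated = 1
  )
}

test_that("unsatisfiable configurations fail before any file is written", {
  expect_error(synthetic_config(n_dual_overlap = 50, n_tsg = 20, n_ocg = 60),
               "n_dual_overlap")
  expect_error(synthetic_config(ddi_density = 1.5), "probabilities")
  expect_error(
    synthetic_config(ddi_confidence_mix = c(HC = 0.5, MC = 0.2)),
    "summing to 1"
  )
  expect_error(synthetic_config(n_planted_secreted_hubs = 9,
                                n_planted_hubs = 2),
               "n_planted_secreted_hubs")
  out <- tempfile("never")
  expect_error(
    generate_dataset(
      synthetic_config(n_tsg = 30, n_ocg = 10, n_dual_overlap = 5,
                       hub_tsg_partner_target = 100),
      out
    ),
    "unsatisfiable"
  )
  expect_false(dir.exists(out))
})

test_that("the same seed produces byte-identical files", {
  cfg <- small_config(seed = 17L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_true(length(f1) > 5)
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  gen3 <- generate_dataset(small_config(seed = 18L), d3)
  expect_false(identical(readLines(file.path(d1, "ddi.tsv")),
                         readLines(file.path(d3, "ddi.tsv"))))
})

test_that("emitted gene lists honour the configured dual overlap", {
  cfg <- small_config()
  d <- withr::local_tempdir()
  gen <- generate_dataset(cfg, d)
  tsg <- read_gene_list(gen$paths$tsg)
  ocg <- read_gene_list(gen$paths$ocg)
  expect_length(tsg, cfg$n_tsg)
  expect_length(ocg, cfg$n_ocg)
  expect_length(intersect(tsg, ocg), cfg$n_dual_overlap)
  expect_length(union(tsg, ocg), cfg$n_tsg + cfg$n_ocg - cfg$n_dual_overlap)
})

test_that("ground truth equals a brute-force rebuild from the emitted files", {
  cfg <- small_config(seed = 29L)
  d <- withr::local_tempdir()
  gen <- generate_dataset(cfg, d)
  ann <- purrr::map_dfr(seq_len(cfg$n_species), function(s) {
    sp <- sprintf("species%02d", s)
    dplyr::mutate(
      read_domain_annotations(gen$paths[[paste0("annotations_", sp)]],
                              dialect = "tsv"),
      species_id = sp
    )
  })
  catalogue <- suppressMessages(attach_domains(
    merge_cancer_genes(read_gene_list(gen$paths$tsg),
                       read_gene_list(gen$paths$ocg)),
    read_gene2domain(gen$paths$gene2domain), quiet = TRUE
  ))
  ddi <- read_ddi_table(gen$paths$ddi, cfg$accepted_confidence)
  rebuilt <- brute_force_interactome(ann, catalogue, ddi)
  expect_equal(
    paste(rebuilt$species_id, rebuilt$protein_id, rebuilt$gene_symbol),
    paste(gen$truth$interactions$species_id,
          gen$truth$interactions$protein_id,
          gen$truth$interactions$gene_symbol)
  )
})

test_that("zero density leaves only deliberately wired hub interactions", {
  cfg <- synthetic_config(
    seed = 5L, n_species = 2L, proteins_per_species = 30L,
    domain_vocab_size = 25L, n_tsg = 20L, n_ocg = 10L, n_dual_overlap = 2L,
    ddi_density = 0, n_planted_hubs = 2L, n_planted_secreted_hubs = 1L,
    hub_tsg_partner_target = 8L, frac_gene_annotated = 1
  )
  d <- withr::local_tempdir()
  gen <- generate_dataset(cfg, d)
  expect_setequal(unique(gen$truth$interactions$protein_id),
                  gen$truth$planted_hub_ids)
  counts <- dplyr::count(gen$truth$interactions, protein_id)
  expect_true(all(counts$n >= cfg$hub_tsg_partner_target))
})

test_that("verify_against_truth localises a deleted DDI edge", {
  cfg <- small_config(seed = 31L)
  d <- withr::local_tempdir()
  gen <- generate_dataset(cfg, d)
  ann_paths <- unlist(gen$paths[grep("^annotations_", names(gen$paths))])
  names(ann_paths) <- sub("annotations_", "", names(ann_paths))
  run <- function() {
    suppressMessages(run_interactome_pipeline(
      ann_paths, gen$paths$tsg, gen$paths$ocg, gen$paths$gene2domain,
      gen$paths$ddi, gen$paths$signalp, gen$paths$tmhmm,
      accepted_confidence = cfg$accepted_confidence,
      min_tsg_partners = cfg$hub_tsg_partner_target
    ))
  }
  res <- run()
  clean <- verify_against_truth(
    list(interactome = res$interactome,
         domain_profiles = res$domain_profiles,
         secreted_hubs = res$secreted_hubs),
    gen$truth
  )
  expect_true(all(clean$match))

  # drop one accepted DDI edge that the truth relied on: the interaction
  # stage must mismatch, and only with missing (never extra) interactions
  ddi_lines <- readLines(gen$paths$ddi)
  hc <- grep("\tHC$", ddi_lines)
  writeLines(ddi_lines[-hc[1]], gen$paths$ddi)
  res2 <- run()
  broken <- verify_against_truth(
    list(interactome = res2$interactome,
         domain_profiles = res2$domain_profiles,
         secreted_hubs = res2$secreted_hubs),
    gen$truth
  )
  inter <- broken[broken$stage == "interactions", ]
  expect_false(inter$match)
  expect_gt(inter$n_missing, 0L)
  expect_equal(inter$n_extra, 0L)
})

test_that("row order of inputs does not affect the pipeline result", {
  cfg <- small_config(seed = 37L)
  d <- withr::local_tempdir()
  gen <- generate_dataset(cfg, d)
  shuffle_file <- function(path) {
    lines <- readLines(path)
    header <- grepl("^#", lines)
    set.seed(1)
    writeLines(c(lines[header], sample(lines[!header])), path)
  }
  ann_paths <- unlist(gen$paths[grep("^annotations_", names(gen$paths))])
  names(ann_paths) <- sub("annotations_", "", names(ann_paths))
  run <- function() {
    suppressMessages(run_interactome_pipeline(
      ann_paths, gen$paths$tsg, gen$paths$ocg, gen$paths$gene2domain,
      gen$paths$ddi, gen$paths$signalp, gen$paths$tmhmm,
      min_tsg_partners = cfg$hub_tsg_partner_target
    ))
  }
  before <- run()
  for (p in c(ann_paths, gen$paths$gene2domain, gen$paths$ddi)) {
    shuffle_file(p)
  }
  after <- run()
  expect_identical(as.data.frame(before$interactome),
                   as.data.frame(after$interactome))
  expect_identical(before$secreted_hubs$protein_id,
                   after$secreted_hubs$protein_id)
})

test_that("plot helpers return ggplot objects on pipeline output", {
  cfg <- small_config(seed = 41L)
  d <- withr::local_tempdir()
  gen <- generate_dataset(cfg, d)
  ann_paths <- unlist(gen$paths[grep("^annotations_", names(gen$paths))])
  names(ann_paths) <- sub("annotations_", "", names(ann_paths))
  res <- suppressMessages(run_interactome_pipeline(
    ann_paths, gen$paths$tsg, gen$paths$ocg, gen$paths$gene2domain,
    gen$paths$ddi, gen$paths$signalp, gen$paths$tmhmm,
    min_tsg_partners = cfg$hub_tsg_partner_target
  ))
  proteome <- purrr::map_dfr(seq_len(cfg$n_species), function(s) {
    sp <- sprintf("species%02d", s)
    read_proteome(gen$paths[[paste0("fasta_", sp)]], sp)
  })
  annotations <- purrr::imap_dfr(ann_paths, function(p, sp) {
    dplyr::mutate(read_domain_annotations(p, dialect = "tsv"),
                  species_id = sp)
  })
  smry <- summarize_interactome(res$interactome, proteome, annotations)
  expect_s3_class(plot_interactome_summary(smry), "ggplot")
  expect_s3_class(
    plot_domain_ranking(
      rank_domains_by_interactions(res$interactome, res$domain_profiles)
    ),
    "ggplot"
  )
  m <- cross_species_overlaps(res$interactome)
  expect_s3_class(plot_overlap_heatmap(m$partners), "ggplot")
  expect_s3_class(autoplot(res$interactome), "ggplot")
  background <- unique(res$catalogue$gene_symbol)
  terms <- list(some_term = background[1:10])
  expect_s3_class(
    plot_enrichment(enrich(background[1:5], terms, background)),
    "ggplot"
  )
})
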