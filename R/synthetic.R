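# Seeded generator of multi-species toy datasets with planted ground truth.
# Every pipeline stage (annotation parsing, catalogue construction, DDI
# joining, hub filtering, secretome calls) can be validated end-to-end
# against truth that is recomputed from the emitted files by an independent
# reference procedure, without any external download.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the generator emulates: a handful
#' of foreign proteomes sharing a common domain vocabulary, role-labelled
#' cancer gene lists with a controlled dual-role overlap, a
#' confidence-tiered DDI table, and secretion/transmembrane calls; a small
#' number of "hub" proteins are deliberately wired to at least
#' `hub_tsg_partner_target` distinct tumour-suppressor genes, a subset of
#' them additionally secreted.
#'
#' @param seed Integer driving every pseudo-random choice; per-stage
#'   sub-seeds are derived deterministically, so one seed yields one byte
#'   stream.
#' @param n_species Number of synthetic proteomes.
#' @param proteins_per_species Background proteins per species (planted hub
#'   proteins are appended on top of these).
#' @param domain_vocab_size Size of the shared domain vocabulary; synthetic
#'   accessions are `PF9xxxx` so they satisfy the Pfam pattern.
#' @param domains_per_protein Length-2 integer range of domains per
#'   annotated protein.
#' @param n_tsg,n_ocg Sizes of the emitted TSG and OCG symbol lists.
#' @param n_dual_overlap Symbols present on both lists (must not exceed
#'   `min(n_tsg, n_ocg)`).
#' @param ddi_density Fraction of possible unordered domain pairs emitted as
#'   background DDI rows.
#' @param ddi_confidence_mix Named proportions over confidence labels for
#'   background DDI rows; must sum to 1.
#' @param frac_signal_peptide,frac_tm Per-protein probabilities of a signal
#'   peptide call and of carrying transmembrane helices.
#' @param n_planted_hubs Planted hub proteins, spread round-robin over
#'   species.
#' @param n_planted_secreted_hubs How many of the planted hubs are also
#'   secreted (signal peptide, zero helices); the rest are wired identically
#'   but carry a transmembrane helix.
#' @param hub_tsg_partner_target Minimum distinct TSG partners guaranteed
#'   per planted hub via deliberately wired high-confidence DDI edges; also
#'   the hub threshold used for the ground-truth hub set.
#' @param protein_length Length-2 range of protein lengths (residues).
#' @param frac_protein_annotated,frac_gene_annotated Fractions of proteins /
#'   cancer genes receiving at least one domain annotation.
#' @param accepted_confidence Confidence labels the downstream pipeline is
#'   expected to accept; ground truth is computed over this subset.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_species = 5L,
                             proteins_per_species = 200L,
                             domain_vocab_size = 150L,
                             domains_per_protein = c(1L, 3L),
                             n_tsg = 150L,
                             n_ocg = 100L,
                             n_dual_overlap = 20L,
                             ddi_density = 0.02,
                             ddi_confidence_mix = c(HC = 0.5, MC = 0.3, LC = 0.2),
                             frac_signal_peptide = 0.15,
                             frac_tm = 0.25,
                             n_planted_hubs = 10L,
                             n_planted_secreted_hubs = 5L,
                             hub_tsg_partner_target = 100L,
                             protein_length = c(100L, 500L),
                             frac_protein_annotated = 0.9,
                             frac_gene_annotated = 0.95,
                             accepted_confidence = "HC") {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_dual_overlap > min(n_tsg, n_ocg)) {
      stop("n_dual_overlap exceeds min(n_tsg, n_ocg)", call. = FALSE)
    }
    probs <- c(ddi_density, frac_signal_peptide, frac_tm,
               frac_protein_annotated, frac_gene_annotated)
    if (any(probs < 0 | probs > 1)) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(ddi_confidence_mix) - 1) > 1e-8 ||
        any(ddi_confidence_mix < 0) || is.null(names(ddi_confidence_mix))) {
      stop("ddi_confidence_mix must be named non-negative proportions summing to 1",
           call. = FALSE)
    }
    if (n_planted_secreted_hubs > n_planted_hubs) {
      stop("n_planted_secreted_hubs exceeds n_planted_hubs", call. = FALSE)
    }
    if (domain_vocab_size < 2L || domain_vocab_size > 9999L) {
      stop("domain_vocab_size must be in [2, 9999]", call. = FALSE)
    }
    # hubs are wired to TSG-only genes; without enough of them the target
    # is unsatisfiable regardless of randomness
    if (n_planted_hubs > 0L &&
        hub_tsg_partner_target > n_tsg - n_dual_overlap) {
      stop("hub_tsg_partner_target exceeds the number of TSG-only genes; ",
           "configuration unsatisfiable", call. = FALSE)
    }
    invisible(NULL)
  })
}

sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + offset * 99991) %% 2147483647L
}

#' Generate a synthetic multi-species dataset with planted ground truth
#'
#' Emits, under `out_dir`: one FASTA and one 3-column annotation TSV per
#' species, TSG/OCG gene lists with the configured dual-role overlap, a
#' gene-to-domain TSV, a confidence-labelled DDI TSV, SignalP-5-like and
#' TMHMM-2-like tables, and ground-truth TSVs (`truth_interactions.tsv`,
#' `truth_domain_categories.tsv`, `truth_secreted_hubs.tsv`).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (tibbles: `interactions`, `domain_categories`, `secreted_hubs`,
#'   `planted_hub_ids`, `planted_secreted_hub_ids`) and `config`.
#'
#' @details Ground truth is recomputed from the in-memory tables by a
#'   reference procedure (hash-map domain adjacency walk) that shares no
#'   code with [build_interactome()], so agreement between pipeline and
#'   truth is a genuine two-route check. Unsatisfiable configurations abort
#'   before any file is written.
#' @export
generate_dataset <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  data <- withr::with_seed(sub_seed(config$seed, 1L),
                           build_synthetic_tables(config))
  truth <- reference_truth(data, config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_synthetic_files(data, truth, config, out_dir)
  invisible(list(paths = paths, truth = truth, config = config))
}

build_synthetic_tables <- function(cfg) {
  vocab <- sprintf("PF9%04d", seq_len(cfg$domain_vocab_size))
  hub_domain <- vocab[length(vocab)]
  draw_vocab <- vocab[-length(vocab)]

  # --- cancer gene lists ------------------------------------------------
  n_tsg_only <- cfg$n_tsg - cfg$n_dual_overlap
  n_ocg_only <- cfg$n_ocg - cfg$n_dual_overlap
  tsg_only <- sprintf("TSG%04d", seq_len(n_tsg_only))
  ocg_only <- sprintf("OCG%04d", seq_len(n_ocg_only))
  dual <- if (cfg$n_dual_overlap > 0L) {
    sprintf("CGD%04d", seq_len(cfg$n_dual_overlap))
  } else {
    character()
  }
  tsg_list <- c(tsg_only, dual)
  ocg_list <- c(ocg_only, dual)

  all_genes <- sort(c(tsg_only, ocg_only, dual))
  annotated_genes <- sort(sample(
    all_genes, size = round(cfg$frac_gene_annotated * length(all_genes))
  ))
  gene2domain <- purrr::map_dfr(annotated_genes, function(g) {
    k <- sample(seq(cfg$domains_per_protein[1], cfg$domains_per_protein[2]), 1L)
    tibble::tibble(gene_symbol = g,
                   domain_acc = sort(sample(draw_vocab, k)))
  })

  # --- hub wiring (constructive) ---------------------------------------
  hub_edges <- tibble::tibble(domain_a = character(),
                              domain_b = character(),
                              confidence = character())
  if (cfg$n_planted_hubs > 0L) {
    annotated_tsg_only <- intersect(sort(tsg_only), annotated_genes)
    if (length(annotated_tsg_only) < cfg$hub_tsg_partner_target) {
      stop("fewer annotated TSG-only genes (", length(annotated_tsg_only),
           ") than hub_tsg_partner_target; configuration unsatisfiable",
           call. = FALSE)
    }
    wired_genes <- annotated_tsg_only[seq_len(cfg$hub_tsg_partner_target)]
    wired_domains <- gene2domain |>
      dplyr::filter(.data$gene_symbol %in% wired_genes) |>
      dplyr::group_by(.data$gene_symbol) |>
      dplyr::slice_min(.data$domain_acc, n = 1L) |>
      dplyr::pull(.data$domain_acc) |>
      unique()
    hub_edges <- tibble::tibble(
      domain_a = hub_domain, domain_b = wired_domains, confidence = "HC"
    )
  }

  # --- background DDI ---------------------------------------------------
  n_draw <- length(draw_vocab)
  pair_idx <- which(upper.tri(matrix(0L, n_draw, n_draw)), arr.ind = TRUE)
  n_edges <- round(cfg$ddi_density * nrow(pair_idx))
  chosen <- if (n_edges > 0L) {
    pair_idx[sort(sample(nrow(pair_idx), n_edges)), , drop = FALSE]
  } else {
    pair_idx[0, , drop = FALSE]
  }
  background_edges <- tibble::tibble(
    domain_a = draw_vocab[chosen[, "row"]],
    domain_b = draw_vocab[chosen[, "col"]],
    confidence = if (n_edges > 0L) {
      sample(names(cfg$ddi_confidence_mix), n_edges, replace = TRUE,
             prob = cfg$ddi_confidence_mix)
    } else {
      character()
    }
  )
  ddi <- dplyr::bind_rows(hub_edges, background_edges)

  # --- proteomes --------------------------------------------------------
  hub_species <- if (cfg$n_planted_hubs > 0L) {
    ((seq_len(cfg$n_planted_hubs) - 1L) %% cfg$n_species) + 1L
  } else {
    integer()
  }
  secreted_hub <- seq_len(cfg$n_planted_hubs) <= cfg$n_planted_secreted_hubs

  species_tables <- purrr::map(seq_len(cfg$n_species), function(s) {
    sp_id <- sprintf("species%02d", s)
    prot_ids <- sprintf("S%02dP%04d", s, seq_len(cfg$proteins_per_species))
    hubs_here <- which(hub_species == s)
    hub_ids <- sprintf("S%02dHUB%02d", s, hubs_here)
    ids <- c(prot_ids, hub_ids)
    lens <- sample(seq(cfg$protein_length[1], cfg$protein_length[2]),
                   length(ids), replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                   replace = TRUE), collapse = "")
    }, character(1))

    annotated <- runif(length(prot_ids)) < cfg$frac_protein_annotated
    ann <- purrr::map_dfr(which(annotated), function(i) {
      k <- sample(seq(cfg$domains_per_protein[1],
                      cfg$domains_per_protein[2]), 1L)
      tibble::tibble(protein_id = prot_ids[i],
                     domain_acc = sort(sample(draw_vocab, k)))
    })
    hub_ann <- tibble::tibble(
      protein_id = rep(hub_ids, each = 1L),
      domain_acc = rep(hub_domain, length(hub_ids))
    )
    ann <- dplyr::bind_rows(ann, hub_ann)

    # secretion evidence: planted secreted hubs get SP and no helix;
    # other planted hubs get SP plus one helix (subtracted downstream)
    sp_call <- runif(length(ids)) < cfg$frac_signal_peptide
    has_tm <- runif(length(ids)) < cfg$frac_tm
    is_hub <- ids %in% hub_ids
    hub_secreted <- ids %in% hub_ids[secreted_hub[hubs_here]]
    sp_call[hub_secreted] <- TRUE
    has_tm[hub_secreted] <- FALSE
    sp_call[is_hub & !hub_secreted] <- TRUE
    has_tm[is_hub & !hub_secreted] <- TRUE

    tm <- purrr::map(seq_along(ids), function(i) {
      if (!has_tm[i]) return(empty_span_matrix())
      n_h <- sample(1:3, 1L)
      width <- 20L
      max_start <- max(lens[i] - width, 1L)
      starts <- sort(sample(seq_len(max_start), n_h))
      # enforce non-overlapping, ordered helices
      for (j in seq_along(starts)[-1]) {
        starts[j] <- max(starts[j], starts[j - 1] + width + 5L)
      }
      cbind(start = starts, end = starts + width - 1L)
    })

    list(
      species_id = sp_id,
      proteome = tibble::tibble(
        protein_id = ids, species_id = sp_id, sequence = seqs,
        length = as.integer(lens)
      ),
      annotations = dplyr::mutate(ann, species_id = sp_id),
      secretion = tibble::tibble(
        protein_id = ids,
        sp_call = sp_call,
        sp_probability = round(ifelse(sp_call, runif(length(ids), 0.7, 0.99),
                                      runif(length(ids), 0.01, 0.3)), 2),
        tm_helix_count = vapply(tm, nrow, integer(1)),
        tm_helix_spans = tm,
        length = as.integer(lens)
      ),
      hub_ids = hub_ids,
      secreted_hub_ids = hub_ids[secreted_hub[hubs_here]]
    )
  })

  list(
    vocab = vocab,
    hub_domain = hub_domain,
    tsg_list = tsg_list,
    ocg_list = ocg_list,
    gene2domain = gene2domain,
    ddi = ddi,
    species = species_tables,
    planted_hub_ids = unlist(lapply(species_tables, `[[`, "hub_ids")),
    planted_secreted_hub_ids =
      unlist(lapply(species_tables, `[[`, "secreted_hub_ids"))
  )
}

# Reference ground-truth construction: domain-adjacency hash walk, written
# independently of build_interactome() (different algorithm, no joins).
reference_truth <- function(data, cfg) {
  accepted <- data$ddi$confidence %in% cfg$accepted_confidence
  adj <- new.env(parent = emptyenv())
  add_edge <- function(a, b) {
    assign(a, unique(c(if (exists(a, envir = adj)) get(a, envir = adj), b)),
           envir = adj)
  }
  for (i in which(accepted)) {
    a <- data$ddi$domain_a[i]
    b <- data$ddi$domain_b[i]
    add_edge(a, b)
    add_edge(b, a)
  }

  role <- c(
    stats::setNames(rep("TSG", length(data$tsg_list)), data$tsg_list),
    stats::setNames(rep("OCG", length(data$ocg_list)), data$ocg_list)
  )
  dual_syms <- intersect(data$tsg_list, data$ocg_list)
  role[dual_syms] <- "DUAL"

  genes_by_domain <- split(data$gene2domain$gene_symbol,
                           data$gene2domain$domain_acc)

  interactions <- list()
  for (sp in data$species) {
    prot_domains <- split(sp$annotations$domain_acc,
                          sp$annotations$protein_id)
    for (p in names(prot_domains)) {
      partner_genes <- character()
      for (d in unique(prot_domains[[p]])) {
        if (!exists(d, envir = adj)) next
        for (h in get(d, envir = adj)) {
          partner_genes <- c(partner_genes, genes_by_domain[[h]])
        }
      }
      partner_genes <- unique(partner_genes)
      if (length(partner_genes) > 0L) {
        interactions[[length(interactions) + 1L]] <- tibble::tibble(
          species_id = sp$species_id, protein_id = p,
          gene_symbol = sort(partner_genes)
        )
      }
    }
  }
  interactions <- if (length(interactions) > 0L) {
    dplyr::bind_rows(interactions) |>
      dplyr::arrange(.data$species_id, .data$protein_id, .data$gene_symbol)
  } else {
    tibble::tibble(species_id = character(), protein_id = character(),
                   gene_symbol = character())
  }

  # per-domain role categories by direct counting over the gene mapping
  dom_cat <- data$gene2domain |>
    dplyr::mutate(role = unname(role[.data$gene_symbol])) |>
    dplyr::group_by(.data$domain_acc) |>
    dplyr::summarise(
      n_tsg = sum(.data$role %in% c("TSG", "DUAL")),
      n_ocg = sum(.data$role %in% c("OCG", "DUAL")),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_tsg > 0 & .data$n_ocg == 0 ~ "TSG_SPECIFIC",
      .data$n_tsg == 0 & .data$n_ocg > 0 ~ "OCG_SPECIFIC",
      TRUE ~ "DUAL_ROLE"
    )) |>
    dplyr::select("domain_acc", "category") |>
    dplyr::arrange(.data$domain_acc)

  # secreted TSG hubs by direct counting
  tsg_partner_counts <- interactions |>
    dplyr::filter(unname(role[.data$gene_symbol]) == "TSG") |>
    dplyr::count(.data$species_id, .data$protein_id)
  hub_ids <- tsg_partner_counts$protein_id[
    tsg_partner_counts$n >= cfg$hub_tsg_partner_target
  ]
  secreted_ids <- unlist(lapply(data$species, function(sp) {
    sp$secretion$protein_id[sp$secretion$sp_call &
                              sp$secretion$tm_helix_count == 0L]
  }))
  secreted_hubs <- sort(intersect(hub_ids, secreted_ids))

  list(
    interactions = interactions,
    domain_categories = dom_cat,
    secreted_hubs = tibble::tibble(protein_id = secreted_hubs),
    planted_hub_ids = sort(data$planted_hub_ids),
    planted_secreted_hub_ids = sort(data$planted_secreted_hub_ids)
  )
}

write_synthetic_files <- function(data, truth, cfg, out_dir) {
  paths <- list()
  for (sp in data$species) {
    fa <- file.path(out_dir, paste0(sp$species_id, ".fasta"))
    writeLines(
      as.vector(rbind(paste0(">", sp$proteome$protein_id),
                      sp$proteome$sequence)),
      fa
    )
    ann <- file.path(out_dir, paste0(sp$species_id, "_domains.tsv"))
    writeLines(
      c("#protein_id\tdomain_acc\tdomain_name",
        paste(sp$annotations$protein_id, sp$annotations$domain_acc,
              sp$annotations$domain_acc, sep = "\t")),
      ann
    )
    paths[[paste0("fasta_", sp$species_id)]] <- fa
    paths[[paste0("annotations_", sp$species_id)]] <- ann
  }

  paths$tsg <- file.path(out_dir, "tsg_genes.txt")
  writeLines(data$tsg_list, paths$tsg)
  paths$ocg <- file.path(out_dir, "ocg_genes.txt")
  writeLines(data$ocg_list, paths$ocg)

  paths$gene2domain <- file.path(out_dir, "gene2domain.tsv")
  writeLines(
    c("#gene_symbol\tdomain_acc",
      paste(data$gene2domain$gene_symbol, data$gene2domain$domain_acc,
            sep = "\t")),
    paths$gene2domain
  )

  paths$ddi <- file.path(out_dir, "ddi.tsv")
  writeLines(
    c("#domain_a\tdomain_b\tconfidence",
      paste(data$ddi$domain_a, data$ddi$domain_b, data$ddi$confidence,
            sep = "\t")),
    paths$ddi
  )

  secretion <- dplyr::bind_rows(lapply(data$species, `[[`, "secretion"))
  paths$signalp <- file.path(out_dir, "signalp.tsv")
  writeLines(
    c("# ID\tPrediction\tSP(Sec/SPI)\tOTHER",
      paste(secretion$protein_id,
            ifelse(secretion$sp_call, "SP(Sec/SPI)", "OTHER"),
            secretion$sp_probability,
            round(1 - secretion$sp_probability, 2),
            sep = "\t")),
    paths$signalp
  )
  paths$tmhmm <- file.path(out_dir, "tmhmm.tsv")
  tm_lines <- vapply(seq_len(nrow(secretion)), function(i) {
    spans <- secretion$tm_helix_spans[[i]]
    topo <- if (nrow(spans) == 0L) {
      "o"
    } else {
      sides <- rep(c("o", "i"), length.out = nrow(spans) + 1L)
      paste0(paste0(sides[seq_len(nrow(spans))],
                    spans[, "start"], "-", spans[, "end"], collapse = ""),
             sides[nrow(spans) + 1L])
    }
    paste0(secretion$protein_id[i], "\tlen=", secretion$length[i],
           "\tExpAA=", nrow(spans) * 20, "\tFirst60=0\tPredHel=",
           nrow(spans), "\tTopology=", topo)
  }, character(1))
  writeLines(tm_lines, paths$tmhmm)

  paths$truth_interactions <- file.path(out_dir, "truth_interactions.tsv")
  write_pipeline_tsv(truth$interactions, paths$truth_interactions)
  paths$truth_domain_categories <-
    file.path(out_dir, "truth_domain_categories.tsv")
  write_pipeline_tsv(truth$domain_categories, paths$truth_domain_categories)
  paths$truth_secreted_hubs <- file.path(out_dir, "truth_secreted_hubs.tsv")
  write_pipeline_tsv(truth$secreted_hubs, paths$truth_secreted_hubs)
  paths$out_dir <- out_dir
  paths
}

#' Compare pipeline outputs against planted ground truth
#'
#' @param results List with elements `interactome` (a `ddi_interactome`),
#'   `domain_profiles` ([classify_domain_roles()] output) and
#'   `secreted_hubs` (tibble with `protein_id` or character vector).
#' @param truth The `truth` element returned by [generate_dataset()], or an
#'   equivalent list of tibbles.
#'
#' @return Tibble with one row per stage (`interactions`,
#'   `domain_categories`, `secreted_hubs`): columns `stage`, `match`,
#'   `n_missing` (expected but absent), `n_extra` (observed but unexpected).
#'   The symmetric differences themselves are attached as attribute `diffs`.
#' @export
verify_against_truth <- function(results, truth) {
  key <- function(df, cols) {
    do.call(paste, c(as.list(df[cols]), sep = "\r"))
  }
  diffs <- list()
  compare <- function(stage, expected, observed) {
    missing <- setdiff(expected, observed)
    extra <- setdiff(observed, expected)
    diffs[[stage]] <<- list(missing = missing, extra = extra)
    tibble::tibble(
      stage = stage,
      match = length(missing) == 0L && length(extra) == 0L,
      n_missing = length(missing),
      n_extra = length(extra)
    )
  }
  obs_hubs <- results$secreted_hubs
  if (is.data.frame(obs_hubs)) obs_hubs <- obs_hubs$protein_id
  cat_obs <- results$domain_profiles
  cat_obs <- cat_obs[cat_obs$category != "UNKNOWN", ]
  out <- dplyr::bind_rows(
    compare(
      "interactions",
      key(truth$interactions, c("species_id", "protein_id", "gene_symbol")),
      key(results$interactome, c("species_id", "protein_id", "gene_symbol"))
    ),
    compare(
      "domain_categories",
      key(truth$domain_categories, c("domain_acc", "category")),
      key(cat_obs, c("domain_acc", "category"))
    ),
    compare("secreted_hubs", truth$secreted_hubs$protein_id, obs_hubs)
  )
  attr(out, "diffs") <- diffs
  out
}

#' Run the full pipeline on files emitted by the generator (or real data)
#'
#' Convenience composition of the package's stages: read annotations and
#' gene lists, build the catalogue and the interactome, classify domains,
#' filter TSG hubs, call the secretome and intersect.
#'
#' @param annotation_paths Named character vector (names = species ids) of
#'   3-column annotation TSVs.
#' @param tsg_path,ocg_path Gene list files.
#' @param gene2domain_path Gene-to-domain TSV.
#' @param ddi_path DDI TSV.
#' @param signalp_path,tmhmm_path Secretion prediction tables.
#' @param accepted_confidence Confidence labels retained from the DDI table.
#' @param min_tsg_partners Hub threshold (inclusive).
#' @param include_dual Count DUAL genes toward the hub threshold.
#'
#' @return List with `catalogue`, `domain_profiles`, `interactome`, `hubs`,
#'   `secretion_calls`, `secreted_hubs`.
#' @export
run_interactome_pipeline <- function(annotation_paths, tsg_path, ocg_path,
                                     gene2domain_path, ddi_path,
                                     signalp_path, tmhmm_path,
                                     accepted_confidence = "HC",
                                     min_tsg_partners = 100L,
                                     include_dual = FALSE) {
  annotations <- purrr::imap_dfr(
    annotation_paths,
    function(p, sp) {
      dplyr::mutate(read_domain_annotations(p, dialect = "tsv"),
                    species_id = sp)
    }
  )
  catalogue <- merge_cancer_genes(read_gene_list(tsg_path),
                                  read_gene_list(ocg_path)) |>
    attach_domains(read_gene2domain(gene2domain_path), quiet = TRUE)
  ddi <- read_ddi_table(ddi_path, accepted_confidence = accepted_confidence)
  interactome <- build_interactome(annotations, catalogue, ddi)
  profiles <- classify_domain_roles(catalogue)
  hubs <- filter_tsg_hubs(interactome, min_tsg_partners = min_tsg_partners,
                          include_dual = include_dual)
  calls <- call_secreted(read_secretion_tables(signalp_path, tmhmm_path))
  list(
    catalogue = catalogue,
    domain_profiles = profiles,
    interactome = interactome,
    hubs = hubs,
    secretion_calls = calls,
    secreted_hubs = secreted_tsg_hubs(calls, hubs)
  )
}
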