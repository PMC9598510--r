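# Bipartite putative interactome between foreign proteins and human cancer
# genes, linked through a domain-domain interaction (DDI) table: protein p
# putatively interacts with gene g iff some domain on p and some domain on g
# form an unordered pair present in the DDI table.

#' Build the putative cross-species interactome
#'
#' A (protein, gene) pair enters the interactome iff there exist a domain
#' `a` annotated on the protein and a domain `b` annotated on the gene with
#' the unordered pair `{a, b}` in the DDI table. Every such supporting
#' domain pair is recorded directionally as (foreign accession, human
#' accession); a DDI self-pair `(a, a)` therefore yields the supporting
#' pair `(a, a)`.
#'
#' @param annotations Tibble of foreign protein domain annotations with
#'   columns `protein_id`, `domain_acc`, and optionally `species_id`
#'   (defaulted to `"unknown"` when absent), e.g. from
#'   [read_domain_annotations()].
#' @param catalogue Cancer gene catalogue with attached domains
#'   ([attach_domains()]).
#' @param ddi Canonicalised DDI table ([read_ddi_table()]).
#'
#' @return A tibble of class `ddi_interactome` with one row per distinct
#'   (`species_id`, `protein_id`, `gene_symbol`) pair, columns `gene_role`,
#'   `n_domain_links`, and list-column `supporting_pairs` (tibbles with
#'   columns `foreign_acc`, `human_acc`). Rows are sorted by species,
#'   protein, gene, so output is a pure function of the data.
#'
#' @examples
#' ann <- tibble::tibble(
#'   species_id = "sp1", protein_id = c("p1", "p2", "p2"),
#'   domain_acc = c("A", "A", "B")
#' )
#' cat <- attach_domains(
#'   merge_cancer_genes(c("g1"), c("g2")),
#'   tibble::tibble(gene_symbol = c("g1", "g2"), domain_acc = c("X", "Y")),
#'   quiet = TRUE
#' )
#' ddi <- tibble::tibble(domain_a = c("A", "B"), domain_b = c("X", "Y"))
#' build_interactome(ann, cat, ddi)
#' @export
build_interactome <- function(annotations, catalogue, ddi) {
  stopifnot(all(c("protein_id", "domain_acc") %in% names(annotations)))
  if (!"domain_accs" %in% names(catalogue)) {
    stop("catalogue has no attached domains; call attach_domains() first",
         call. = FALSE)
  }
  if (!"species_id" %in% names(annotations)) {
    annotations$species_id <- "unknown"
  }
  if (nrow(ddi) == 0L) {
    warning("empty DDI table: interactome is empty", call. = FALSE)
    return(new_ddi_interactome(empty_interactome_tbl()))
  }

  # directed view of the unordered DDI pairs: foreign side can match either
  # member, so emit both orientations (self-pairs collapse to one)
  edges <- dplyr::bind_rows(
    tibble::tibble(foreign_acc = ddi$domain_a, human_acc = ddi$domain_b),
    tibble::tibble(foreign_acc = ddi$domain_b, human_acc = ddi$domain_a)
  ) |>
    dplyr::distinct()

  gene_dom <- tibble::tibble(
    gene_symbol = rep(catalogue$gene_symbol, lengths(catalogue$domain_accs)),
    gene_role = rep(catalogue$role, lengths(catalogue$domain_accs)),
    human_acc = unlist(catalogue$domain_accs, use.names = FALSE)
  ) |>
    dplyr::distinct()

  prot_dom <- dplyr::distinct(
    annotations, .data$species_id, .data$protein_id,
    foreign_acc = .data$domain_acc
  )

  links <- prot_dom |>
    dplyr::inner_join(edges, by = "foreign_acc",
                      relationship = "many-to-many") |>
    dplyr::inner_join(gene_dom, by = "human_acc",
                      relationship = "many-to-many") |>
    dplyr::distinct(
      .data$species_id, .data$protein_id, .data$gene_symbol,
      .data$gene_role, .data$foreign_acc, .data$human_acc
    ) |>
    dplyr::arrange(
      .data$species_id, .data$protein_id, .data$gene_symbol,
      .data$foreign_acc, .data$human_acc
    )

  out <- links |>
    tidyr::nest(supporting_pairs = c("foreign_acc", "human_acc")) |>
    dplyr::mutate(n_domain_links = vapply(.data$supporting_pairs, nrow,
                                          integer(1))) |>
    dplyr::select(
      "species_id", "protein_id", "gene_symbol", "gene_role",
      "n_domain_links", "supporting_pairs"
    ) |>
    dplyr::arrange(.data$species_id, .data$protein_id, .data$gene_symbol)
  new_ddi_interactome(out)
}

empty_interactome_tbl <- function() {
  tibble::tibble(
    species_id = character(), protein_id = character(),
    gene_symbol = character(), gene_role = character(),
    n_domain_links = integer(), supporting_pairs = list()
  )
}

new_ddi_interactome <- function(x) {
  class(x) <- c("ddi_interactome", class(x))
  x
}

#' @export
print.ddi_interactome <- function(x, ...) {
  cat(
    "<ddi_interactome> ", nrow(x), " putative interactions | ",
    dplyr::n_distinct(x$protein_id), " proteins | ",
    dplyr::n_distinct(x$gene_symbol), " cancer genes | ",
    dplyr::n_distinct(x$species_id), " species\n",
    sep = ""
  )
  NextMethod()
}

#' Per-species summary of a putative interactome
#'
#' @param interactome Output of [build_interactome()].
#' @param proteome Tibble with columns `protein_id` and optionally
#'   `species_id` covering the full proteome(s), e.g. from
#'   [read_proteome()].
#' @param annotations The domain annotations the interactome was built from.
#'
#' @return One tibble row per species with: `n_proteins_total`,
#'   `n_proteins_with_domains`, `n_interacting_proteins`,
#'   `n_cancer_partners`, `n_interactions` (distinct protein-gene pairs),
#'   `n_domain_links` (supporting-pair multiplicities summed), and
#'   `n_proteins_vs_tsg` / `n_proteins_vs_ocg` / `n_proteins_vs_dual` — the
#'   number of interacting proteins with at least one partner of that role
#'   (a protein with partners of several roles is counted in each group, so
#'   these three can sum to more than `n_interacting_proteins`).
#' @export
summarize_interactome <- function(interactome, proteome, annotations) {
  if (!"species_id" %in% names(proteome)) proteome$species_id <- "unknown"
  if (!"species_id" %in% names(annotations)) annotations$species_id <- "unknown"
  species <- sort(unique(c(
    proteome$species_id, annotations$species_id, interactome$species_id
  )))
  purrr::map_dfr(species, function(sp) {
    prot <- proteome[proteome$species_id == sp, ]
    ann <- annotations[annotations$species_id == sp, ]
    ia <- interactome[interactome$species_id == sp, ]
    role_count <- function(role) {
      dplyr::n_distinct(ia$protein_id[ia$gene_role == role])
    }
    tibble::tibble(
      species_id = sp,
      n_proteins_total = dplyr::n_distinct(prot$protein_id),
      n_proteins_with_domains = dplyr::n_distinct(ann$protein_id),
      n_interacting_proteins = dplyr::n_distinct(ia$protein_id),
      n_cancer_partners = dplyr::n_distinct(ia$gene_symbol),
      n_interactions = nrow(ia),
      n_domain_links = sum(ia$n_domain_links),
      n_proteins_vs_tsg = role_count("TSG"),
      n_proteins_vs_ocg = role_count("OCG"),
      n_proteins_vs_dual = role_count("DUAL")
    )
  })
}

#' Rank foreign domains by the interactions they support
#'
#' A domain's interaction count is the number of distinct (protein, gene)
#' pairs whose supporting pairs include that accession on the foreign side.
#' Ties break by accession, ascending, so rankings are reproducible.
#'
#' @param interactome Output of [build_interactome()].
#' @param domain_profiles Optional output of [classify_domain_roles()]; when
#'   supplied, the ranking is annotated with each domain's category and
#'   dual-role ratio (accessions without a profile get `UNKNOWN` / `NA`).
#' @param k Number of top domains to return (default 20); values beyond the
#'   domain universe return the full ranking.
#'
#' @return Tibble with columns `domain_acc`, `n_interactions`, `category`,
#'   `ratio`, ordered by decreasing count.
#' @export
rank_domains_by_interactions <- function(interactome, domain_profiles = NULL,
                                         k = 20L) {
  stopifnot(k >= 1L)
  counts <- interactome |>
    dplyr::select("species_id", "protein_id", "gene_symbol",
                  "supporting_pairs") |>
    tidyr::unnest("supporting_pairs") |>
    dplyr::distinct(.data$species_id, .data$protein_id, .data$gene_symbol,
                    .data$foreign_acc) |>
    dplyr::count(domain_acc = .data$foreign_acc, name = "n_interactions") |>
    dplyr::arrange(dplyr::desc(.data$n_interactions), .data$domain_acc)
  if (is.null(domain_profiles)) {
    counts$category <- "UNKNOWN"
    counts$ratio <- NA_real_
  } else {
    counts <- counts |>
      dplyr::left_join(
        dplyr::select(domain_profiles, "domain_acc", "category", "ratio"),
        by = "domain_acc"
      ) |>
      dplyr::mutate(category = dplyr::coalesce(.data$category, "UNKNOWN"))
  }
  utils::head(counts, k)
}

#' Proteins interacting with many tumour suppressors (TSG hubs)
#'
#' @param interactome Output of [build_interactome()].
#' @param min_tsg_partners Inclusive threshold on the number of distinct
#'   TSG partner genes (default 100, i.e. "100 or more").
#' @param include_dual Count DUAL-role partner genes toward the threshold
#'   (default `FALSE`: TSG-specific partners only).
#'
#' @return Tibble with columns `species_id`, `protein_id`,
#'   `n_tsg_partners`, sorted by species then protein.
#' @export
filter_tsg_hubs <- function(interactome, min_tsg_partners = 100L,
                            include_dual = FALSE) {
  stopifnot(min_tsg_partners >= 1L)
  roles <- if (include_dual) c("TSG", "DUAL") else "TSG"
  interactome |>
    dplyr::filter(.data$gene_role %in% roles) |>
    dplyr::distinct(.data$species_id, .data$protein_id, .data$gene_symbol) |>
    dplyr::count(.data$species_id, .data$protein_id,
                 name = "n_tsg_partners") |>
    dplyr::filter(.data$n_tsg_partners >= min_tsg_partners) |>
    dplyr::arrange(.data$species_id, .data$protein_id)
}

#' Cross-species overlap matrices
#'
#' For every species pair, counts shared cancer partner genes and shared
#' interacting foreign domains (accessions appearing on the foreign side of
#' at least one supporting pair). Diagonals are per-species set sizes.
#'
#' @param interactome A `ddi_interactome` covering at least two species, or
#'   a list of per-species interactomes to be row-bound.
#'
#' @return A list of two symmetric integer matrices, `partners` and
#'   `domains`, with species ids as dimnames.
#' @export
cross_species_overlaps <- function(interactome) {
  if (is.list(interactome) && !is.data.frame(interactome)) {
    interactome <- dplyr::bind_rows(interactome)
  }
  species <- sort(unique(interactome$species_id))
  if (length(species) < 2L) {
    stop("need interactomes for at least 2 species", call. = FALSE)
  }
  partner_sets <- lapply(species, function(sp) {
    unique(interactome$gene_symbol[interactome$species_id == sp])
  })
  dom_long <- interactome |>
    dplyr::select("species_id", "supporting_pairs") |>
    tidyr::unnest("supporting_pairs")
  domain_sets <- lapply(species, function(sp) {
    unique(dom_long$foreign_acc[dom_long$species_id == sp])
  })
  overlap_matrix <- function(sets) {
    n <- length(sets)
    m <- matrix(0L, n, n, dimnames = list(species, species))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
      }
    }
    m
  }
  list(
    partners = overlap_matrix(partner_sets),
    domains = overlap_matrix(domain_sets)
  )
}

#' Write an interactome as TSV
#'
#' One row per (species, protein, gene) with supporting pairs serialised as
#' semicolon-joined `foreign:human` tokens, after the package's commented
#' header convention.
#'
#' @param interactome Output of [build_interactome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(interactome, path) {
  write_pipeline_tsv(interactome, path)
}

#' Read an interactome written by [write_interactome()]
#'
#' @param path Path to the TSV.
#' @return A `ddi_interactome` tibble equal to the one written.
#' @export
read_interactome <- function(path) {
  raw <- read_pipeline_tsv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    protein_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    gene_role = readr::col_character(),
    n_domain_links = readr::col_integer(),
    supporting_pairs = readr::col_character()
  ))
  raw$supporting_pairs <- lapply(raw$supporting_pairs, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(foreign_acc = character(),
                            human_acc = character()))
    }
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    tibble::tibble(
      foreign_acc = vapply(parts, `[[`, character(1), 1L),
      human_acc = vapply(parts, `[[`, character(1), 2L)
    )
  })
  new_ddi_interactome(raw)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a putative interactome into one row per supporting domain link
#'
#' @param x A `ddi_interactome`.
#' @param ... Unused.
#' @return Tibble with one row per (species, protein, gene, foreign domain,
#'   human domain) link.
#' @exportS3Method generics::tidy
tidy.ddi_interactome <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("species_id", "protein_id", "gene_symbol", "gene_role",
                  "supporting_pairs") |>
    tidyr::unnest("supporting_pairs")
}

#' One-row overview of a putative interactome
#'
#' @param x A `ddi_interactome`.
#' @param ... Unused.
#' @return Tibble with `n_species`, `n_proteins`, `n_cancer_partners`,
#'   `n_interactions` and `n_domain_links`.
#' @exportS3Method generics::glance
glance.ddi_interactome <- function(x, ...) {
  tibble::tibble(
    n_species = dplyr::n_distinct(x$species_id),
    n_proteins = dplyr::n_distinct(x$protein_id),
    n_cancer_partners = dplyr::n_distinct(x$gene_symbol),
    n_interactions = nrow(x),
    n_domain_links = sum(x$n_domain_links)
  )
}
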