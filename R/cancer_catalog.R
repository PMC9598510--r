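# Role-labelled cancer gene catalogue and per-domain role classification.
#
# Genes come in as two symbol lists (tumour suppressors and oncogenes);
# genes on both lists are context-dependent "dual role" genes. Domains
# inherit roles from the genes that carry them, summarised by the dual-role
# ratio: #TSG / (#TSG + #OCG).

#' Merge tumour-suppressor and oncogene lists into a role-labelled catalogue
#'
#' @param tsg_symbols Character vector of tumour-suppressor gene symbols.
#' @param ocg_symbols Character vector of oncogene symbols.
#'
#' @return A tibble with columns `gene_symbol` and `role`
#'   (`"TSG"`, `"OCG"` or `"DUAL"`), one row per distinct symbol. A symbol
#'   present on both input lists is labelled `DUAL`. The catalogue size is
#'   always `|set(tsg)| + |set(ocg)| - |intersection|`.
#'
#' @details Within-list duplicates are collapsed with a warning; matching is
#'   exact and case-sensitive (alias resolution is out of scope).
#'
#' @examples
#' merge_cancer_genes(c("TP53", "RB1", "PTEN"), c("PTEN", "KRAS"))
#' @export
merge_cancer_genes <- function(tsg_symbols, ocg_symbols) {
  for (nm in c("tsg_symbols", "ocg_symbols")) {
    v <- get(nm)
    if (length(v) == 0L) stop(nm, " is empty", call. = FALSE)
    if (!is.character(v) || any(is.na(v)) || any(!nzchar(v))) {
      stop(nm, " must be non-empty strings", call. = FALSE)
    }
  }
  if (anyDuplicated(tsg_symbols)) {
    warning(sum(duplicated(tsg_symbols)),
            " duplicate TSG symbol(s) collapsed", call. = FALSE)
  }
  if (anyDuplicated(ocg_symbols)) {
    warning(sum(duplicated(ocg_symbols)),
            " duplicate OCG symbol(s) collapsed", call. = FALSE)
  }
  tsg <- unique(tsg_symbols)
  ocg <- unique(ocg_symbols)
  dual <- intersect(tsg, ocg)
  tibble::tibble(
    gene_symbol = c(setdiff(tsg, dual), setdiff(ocg, dual), dual),
    role = c(
      rep("TSG", length(tsg) - length(dual)),
      rep("OCG", length(ocg) - length(dual)),
      rep("DUAL", length(dual))
    )
  ) |>
    dplyr::arrange(.data$gene_symbol)
}

#' Attach domain annotations to a cancer gene catalogue
#'
#' @param catalogue Output of [merge_cancer_genes()].
#' @param gene2domain Tibble with columns `gene_symbol`, `domain_acc`
#'   (multiple rows per gene), e.g. from [read_gene2domain()].
#' @param quiet Suppress the coverage message.
#'
#' @return The catalogue with a list-column `domain_accs` (character vector
#'   of accessions per gene; empty for genes absent from the mapping) and an
#'   attribute `coverage`, a list with `n_annotated` and `n_total`.
#'
#' @details Matching is case-sensitive; mapping keys that match no catalogue
#'   symbol are counted and reported, never fatal.
#' @export
attach_domains <- function(catalogue, gene2domain, quiet = FALSE) {
  stopifnot(all(c("gene_symbol", "role") %in% names(catalogue)))
  stopifnot(all(c("gene_symbol", "domain_acc") %in% names(gene2domain)))
  g2d <- dplyr::distinct(gene2domain, .data$gene_symbol, .data$domain_acc)
  by_gene <- split(g2d$domain_acc, g2d$gene_symbol)
  accs <- by_gene[catalogue$gene_symbol]
  accs[vapply(accs, is.null, logical(1))] <- list(character())
  out <- catalogue
  out$domain_accs <- unname(accs)
  n_annotated <- sum(lengths(out$domain_accs) > 0L)
  unmatched <- setdiff(names(by_gene), catalogue$gene_symbol)
  attr(out, "coverage") <- list(
    n_annotated = n_annotated,
    n_total = nrow(out),
    n_unmatched_mapping_keys = length(unmatched)
  )
  if (!quiet) {
    message(
      "domain annotation coverage: ", n_annotated, "/", nrow(out),
      " genes; ", length(unmatched), " mapping key(s) matched no symbol"
    )
  }
  out
}

#' Dual-role ratio of a domain
#'
#' The ratio of associated tumour suppressors to all associated tumour
#' suppressors and oncogenes: 1 means purely tumour-suppressive, 0 purely
#' oncogenic, values strictly between mark dual-role domains. Undefined
#' (returned as `NA`, rendered "Not available" by the writer) when a domain
#' has no associated cancer gene at all — distinct from 0.
#'
#' @param tsg_gene_count,ocg_gene_count Non-negative integer vectors
#'   (recycled) of associated TSG and OCG gene counts.
#' @return Numeric vector in `[0, 1]`, `NA` where both counts are zero.
#' @examples
#' dual_role_ratio(c(5, 0, 1, 0), c(0, 4, 1, 0))
#' @export
dual_role_ratio <- function(tsg_gene_count, ocg_gene_count) {
  if (any(tsg_gene_count < 0, na.rm = TRUE) ||
      any(ocg_gene_count < 0, na.rm = TRUE)) {
    stop("gene counts must be non-negative", call. = FALSE)
  }
  total <- tsg_gene_count + ocg_gene_count
  dplyr::if_else(total == 0, NA_real_, tsg_gene_count / total)
}

#' Classify every domain's cancer role from an annotated catalogue
#'
#' Counts, for each domain accession, how many TSG and OCG genes carry it,
#' and assigns a category: `TSG_SPECIFIC` (only TSGs), `OCG_SPECIFIC` (only
#' OCGs), `DUAL_ROLE` (both), or `UNKNOWN` (no cancer gene; arises only for
#' accessions supplied via `universe` that no catalogue gene carries).
#'
#' @param catalogue Catalogue with attached domains ([attach_domains()]).
#' @param universe Optional character vector of accessions to profile; by
#'   default the distinct accessions annotated on the catalogue. Accessions
#'   outside the catalogue's annotation get zero counts and `UNKNOWN`.
#' @param dual_counts_both Should a DUAL gene increment both the TSG and the
#'   OCG tally of its domains? Default `TRUE`: the ratio denominator then
#'   counts a dual gene on both sides, which is the convention under which
#'   the three category counts partition the domain universe.
#'
#' @return A tibble with columns `domain_acc`, `tsg_gene_count`,
#'   `ocg_gene_count`, `ratio` (`NA` when undefined) and `category`, one row
#'   per accession, sorted by accession.
#' @export
classify_domain_roles <- function(catalogue, universe = NULL,
                                  dual_counts_both = TRUE) {
  if (!"domain_accs" %in% names(catalogue)) {
    stop("catalogue has no attached domains; call attach_domains() first",
         call. = FALSE)
  }
  long <- tibble::tibble(
    role = rep(catalogue$role, lengths(catalogue$domain_accs)),
    domain_acc = unlist(catalogue$domain_accs, use.names = FALSE)
  )
  counts <- long |>
    dplyr::group_by(.data$domain_acc) |>
    dplyr::summarise(
      tsg_gene_count = sum(.data$role == "TSG") +
        if (dual_counts_both) sum(.data$role == "DUAL") else 0L,
      ocg_gene_count = sum(.data$role == "OCG") +
        if (dual_counts_both) sum(.data$role == "DUAL") else 0L,
      .groups = "drop"
    )
  universe <- sort(unique(c(universe, counts$domain_acc)))
  counts |>
    dplyr::right_join(tibble::tibble(domain_acc = universe), by = "domain_acc") |>
    dplyr::mutate(
      tsg_gene_count = dplyr::coalesce(.data$tsg_gene_count, 0L),
      ocg_gene_count = dplyr::coalesce(.data$ocg_gene_count, 0L),
      ratio = dual_role_ratio(.data$tsg_gene_count, .data$ocg_gene_count),
      category = dplyr::case_when(
        .data$tsg_gene_count > 0 & .data$ocg_gene_count == 0 ~ "TSG_SPECIFIC",
        .data$tsg_gene_count == 0 & .data$ocg_gene_count > 0 ~ "OCG_SPECIFIC",
        .data$tsg_gene_count > 0 & .data$ocg_gene_count > 0 ~ "DUAL_ROLE",
        TRUE ~ "UNKNOWN"
      )
    ) |>
    dplyr::arrange(.data$domain_acc)
}

#' Write a domain role profile table
#'
#' Emits TSV with a commented header; undefined ratios render as
#' `"Not available"`, matching the usual presentation of such tables.
#'
#' @param profiles Output of [classify_domain_roles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_profiles <- function(profiles, path) {
  out <- profiles
  out$ratio <- ifelse(
    is.na(out$ratio), "Not available",
    as.character(round(out$ratio, 6))
  )
  write_pipeline_tsv(out, path)
}
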