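# Readers and writers for every external table and sequence format the
# pipeline touches. All readers return tibbles; all writers emit TSV with a
# single commented header line so downstream shell tools can skip it.

#' Read a proteome from a FASTA file
#'
#' Parses an amino-acid FASTA file into one record per entry. The protein
#' identifier is the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param species_id Opaque species identifier attached to every record.
#' @param keep_sequence Keep the amino-acid string in the output (default
#'   `TRUE`); lengths are always recorded.
#'
#' @return A tibble with columns `protein_id`, `species_id`, `sequence`
#'   (`NA` when `keep_sequence = FALSE`) and `length`.
#'
#' @details Duplicate identifiers within one file are rejected: two FASTA
#'   entries sharing an id would make every downstream per-protein join
#'   ambiguous. An empty file yields an empty tibble with a warning.
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a kinase", "MKTAYIAK", ">p2", "MV"), fa)
#' read_proteome(fa, species_id = "sp1")
#' @export
read_proteome <- function(path, species_id, keep_sequence = TRUE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("proteome file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L || !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warning("no FASTA records in ", path, call. = FALSE)
    return(tibble::tibble(
      protein_id = character(), species_id = character(),
      sequence = character(), length = integer()
    ))
  }
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(
      "duplicate protein id(s) in ", path, ": ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    protein_id = ids,
    species_id = species_id,
    sequence = if (keep_sequence) as.character(unname(seqs)) else NA_character_,
    length = unname(Biostrings::width(seqs))
  )
}

#' Read protein domain annotations
#'
#' Loads protein-to-domain-family assignments either from HMMER3 per-domain
#' tabular output (`dialect = "domtblout"`) or from a plain 3-column TSV
#' (`protein_id`, `domain_acc`, `domain_name`; `dialect = "tsv"`).
#'
#' @param path Path to the annotation file.
#' @param dialect `"domtblout"` or `"tsv"`. Must be stated explicitly.
#' @param evalue_max Maximum independent (per-domain) E-value retained; only
#'   applied to the domtblout dialect. The TSV dialect is assumed to be
#'   pre-thresholded (e.g. by Pfam gathering thresholds) and is loaded
#'   verbatim.
#' @param strict_pfam Require accessions to match `PF` + 5 digits. Off by
#'   default so synthetic or non-Pfam vocabularies pass through.
#'
#' @return A tibble with columns `protein_id`, `domain_acc`, `domain_name`,
#'   `evalue`, `envelope_start`, `envelope_end` (the last three `NA` for the
#'   TSV dialect). Pfam version suffixes (`PF00069.25`) are stripped so the
#'   accessions join directly against unversioned DDI tables.
#'
#' @details The domtblout columns follow the hmmscan orientation: the target
#'   (columns 1-2) is the domain model, the query (column 4) is the protein.
#'   Independent E-value is column 13; envelope coordinates are columns
#'   20-21 (1-based inclusive).
#' @export
read_domain_annotations <- function(path, dialect = c("tsv", "domtblout"),
                                    evalue_max = 1e-5, strict_pfam = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(is.numeric(evalue_max), evalue_max > 0)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_annotation_tbl())
  }
  out <- if (dialect == "domtblout") {
    parse_domtblout(lines, evalue_max)
  } else {
    parse_annotation_tsv(lines)
  }
  out$domain_acc <- strip_pfam_version(out$domain_acc)
  if (strict_pfam) {
    bad <- out$domain_acc[!grepl("^PF\\d{5}$", out$domain_acc)]
    if (length(bad) > 0L) {
      stop(
        "accession(s) not matching PF+5 digits: ",
        paste(unique(bad), collapse = ", "),
        call. = FALSE
      )
    }
  }
  bad_env <- !is.na(out$envelope_start) & !is.na(out$envelope_end) &
    out$envelope_start > out$envelope_end
  if (any(bad_env)) {
    stop("envelope_start > envelope_end in row(s): ",
         paste(which(bad_env), collapse = ", "), call. = FALSE)
  }
  out
}

empty_annotation_tbl <- function() {
  tibble::tibble(
    protein_id = character(), domain_acc = character(),
    domain_name = character(), evalue = double(),
    envelope_start = integer(), envelope_end = integer()
  )
}

parse_domtblout <- function(lines, evalue_max) {
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < 22L)) {
    stop("unparsable domtblout row(s) (fewer than 22 fields): row ",
         paste(which(n_fields < 22L), collapse = ", "), call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  ievalue <- suppressWarnings(as.numeric(col(13L)))
  if (anyNA(ievalue)) {
    stop("non-numeric independent E-value in domtblout row ",
         paste(which(is.na(ievalue)), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    protein_id = col(4L),
    domain_acc = col(2L),
    domain_name = col(1L),
    evalue = ievalue,
    envelope_start = as.integer(col(20L)),
    envelope_end = as.integer(col(21L))
  )
  # accession column is "-" when the HMM file carries no accession; fall
  # back on the model name so the row remains joinable
  out$domain_acc[out$domain_acc == "-"] <- out$domain_name[out$domain_acc == "-"]
  out[out$evalue <= evalue_max, ]
}

parse_annotation_tsv <- function(lines) {
  fields <- strsplit(lines, "\t|\\s{2,}")
  fields <- lapply(fields, function(x) x[nzchar(x)])
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    stop("unparsable annotation TSV row (fewer than 2 columns): row ",
         paste(which(n_fields < 2L), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    protein_id = vapply(fields, `[[`, character(1), 1L),
    domain_acc = vapply(fields, `[[`, character(1), 2L),
    domain_name = vapply(fields, function(x) {
      if (length(x) >= 3L) x[[3L]] else NA_character_
    }, character(1)),
    evalue = NA_real_,
    envelope_start = NA_integer_,
    envelope_end = NA_integer_
  )
}

strip_pfam_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Read and confidence-filter a domain-domain interaction table
#'
#' Loads a DOMINE-like TSV (`domain_a`, `domain_b`, `confidence`), keeps only
#' rows whose confidence label is accepted, canonicalises every pair so that
#' `domain_a <= domain_b` lexicographically, and de-duplicates. Self-pairs
#' (`domain_a == domain_b`) are legitimate: many domain families
#' homo-dimerise.
#'
#' @param path Path to the DDI TSV. Lines starting with `#` are skipped.
#' @param accepted_confidence Non-empty character vector of confidence labels
#'   to retain (e.g. `"HC"` for high confidence only).
#'
#' @return A tibble with columns `domain_a`, `domain_b`, `confidence`, one
#'   row per distinct unordered pair, sorted by (`domain_a`, `domain_b`).
#'   The number of rows dropped by the confidence filter is attached as
#'   attribute `n_dropped_confidence`.
#' @export
read_ddi_table <- function(path, accepted_confidence = "HC") {
  stopifnot(length(accepted_confidence) >= 1L)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- tibble::tibble(
      domain_a = character(), domain_b = character(), confidence = character()
    )
    attr(out, "n_dropped_confidence") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t|\\s+")
  fields <- lapply(fields, function(x) x[nzchar(x)])
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("DDI row(s) with fewer than 3 columns: row ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    domain_a = strip_pfam_version(vapply(fields, `[[`, character(1), 1L)),
    domain_b = strip_pfam_version(vapply(fields, `[[`, character(1), 2L)),
    confidence = vapply(fields, `[[`, character(1), 3L)
  )
  kept <- tbl$confidence %in% accepted_confidence
  n_dropped <- sum(!kept)
  out <- canonicalise_ddi(tbl[kept, ])
  attr(out, "n_dropped_confidence") <- n_dropped
  out
}

#' Canonicalise a DDI table
#'
#' Orders each pair so `domain_a <= domain_b` lexicographically and drops
#' duplicate unordered pairs (keeping the first confidence label seen).
#' Idempotent.
#'
#' @param ddi Tibble with columns `domain_a`, `domain_b` and optionally
#'   `confidence`.
#' @return Canonicalised tibble sorted by (`domain_a`, `domain_b`).
#' @export
canonicalise_ddi <- function(ddi) {
  if (!"confidence" %in% names(ddi)) ddi$confidence <- NA_character_
  ddi |>
    dplyr::mutate(
      .a = pmin(.data$domain_a, .data$domain_b),
      .b = pmax(.data$domain_a, .data$domain_b)
    ) |>
    dplyr::distinct(.data$.a, .data$.b, .keep_all = TRUE) |>
    dplyr::transmute(
      domain_a = .data$.a, domain_b = .data$.b,
      confidence = .data$confidence
    ) |>
    dplyr::arrange(.data$domain_a, .data$domain_b)
}

#' Read SignalP 5 and TMHMM 2 outputs into merged secretion evidence
#'
#' Parses a SignalP-5-like short tabular output (columns: id, prediction,
#' signal-peptide probability) and a TMHMM-2-like short-format output (one
#' line per protein with `PredHel=` and `Topology=` fields), then outer-joins
#' them on protein id. A protein absent from the SignalP table gets
#' `sp_call = FALSE`; absent from the TMHMM table, `tm_helix_count = 0`.
#'
#' @param signalp_path Path to the SignalP-like table (`#` comments skipped).
#' @param tmhmm_path Path to the TMHMM-like short-format output.
#' @param sp_positive_labels Prediction labels counted as a signal-peptide
#'   call; default any label starting with `"SP"` (SignalP 5 emits
#'   `SP(Sec/SPI)` for eukaryotes).
#'
#' @return A tibble with columns `protein_id`, `sp_call`, `sp_probability`,
#'   `tm_helix_count`, `tm_helix_spans` (list-column of integer matrices with
#'   columns start/end, 1-based inclusive).
#' @export
read_secretion_tables <- function(signalp_path, tmhmm_path,
                                  sp_positive_labels = NULL) {
  sp <- parse_signalp(signalp_path, sp_positive_labels)
  tm <- parse_tmhmm(tmhmm_path)
  merged <- dplyr::full_join(sp, tm, by = "protein_id")
  merged$sp_call[is.na(merged$sp_call)] <- FALSE
  merged$tm_helix_count[is.na(merged$tm_helix_count)] <- 0L
  no_span <- vapply(merged$tm_helix_spans, is.null, logical(1))
  merged$tm_helix_spans[no_span] <- list(empty_span_matrix())
  dplyr::arrange(merged, .data$protein_id)
}

empty_span_matrix <- function() {
  matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

parse_signalp <- function(path, sp_positive_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      protein_id = character(), sp_call = logical(), sp_probability = double()
    ))
  }
  fields <- strsplit(trimws(lines), "\t|\\s+")
  short <- lengths(fields) < 2L
  if (any(short)) {
    stop("unparsable SignalP row ", paste(which(short), collapse = ", "),
         call. = FALSE)
  }
  pred <- vapply(fields, `[[`, character(1), 2L)
  call <- if (is.null(sp_positive_labels)) {
    startsWith(pred, "SP")
  } else {
    pred %in% sp_positive_labels
  }
  prob <- vapply(fields, function(x) {
    if (length(x) >= 3L) suppressWarnings(as.numeric(x[[3L]])) else NA_real_
  }, double(1))
  tibble::tibble(
    protein_id = vapply(fields, `[[`, character(1), 1L),
    sp_call = call,
    sp_probability = prob
  ) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE)
}

parse_tmhmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      protein_id = character(), tm_helix_count = integer(),
      tm_helix_spans = list()
    ))
  }
  ids <- vapply(strsplit(trimws(lines), "\\s+"), `[[`, character(1), 1L)
  predhel <- stringr::str_match(lines, "PredHel=(\\d+)")[, 2]
  if (anyNA(predhel)) {
    stop("unparsable PredHel field in TMHMM row ",
         paste(which(is.na(predhel)), collapse = ", "), call. = FALSE)
  }
  topo <- stringr::str_match(lines, "Topology=([io0-9\\-]+)")[, 2]
  spans <- lapply(topo, parse_tmhmm_topology)
  n_helices <- as.integer(predhel)
  n_spans <- vapply(spans, nrow, integer(1))
  mismatch <- !is.na(topo) & n_spans != n_helices & n_helices > 0L
  if (any(mismatch)) {
    stop("TMHMM topology span count disagrees with PredHel in row ",
         paste(which(mismatch), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    protein_id = ids,
    tm_helix_count = n_helices,
    tm_helix_spans = spans
  ) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE)
}

# TMHMM short-format topology grammar: alternating i/o side markers with
# 1-based inclusive helix spans between them, e.g. "o10-32i50-70o".
parse_tmhmm_topology <- function(topology) {
  if (is.na(topology) || topology %in% c("i", "o")) {
    return(empty_span_matrix())
  }
  m <- stringr::str_match_all(topology, "(\\d+)-(\\d+)")[[1]]
  if (nrow(m) == 0L) {
    return(empty_span_matrix())
  }
  out <- cbind(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
  if (any(out[, "start"] > out[, "end"])) {
    stop("invalid TMHMM span in topology '", topology, "'", call. = FALSE)
  }
  out
}

#' Write a pipeline table as TSV with a commented header
#'
#' All pipeline writers share this format: a first line `#col1<TAB>col2...`
#' followed by tab-separated rows. List-columns of domain-pair matrices are
#' serialised as semicolon-joined `a:b` tokens; `NA` is written as the empty
#' string.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_pipeline_tsv()] for the inverse.
#' @export
write_pipeline_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], serialise_cell, character(1))
    }
  }
  header <- paste0("#", paste(names(x), collapse = "\t"))
  body <- do.call(paste, c(lapply(x, format_tsv_col), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

format_tsv_col <- function(v) {
  out <- as.character(v)
  out[is.na(v)] <- ""
  out
}

serialise_cell <- function(cell) {
  if (is.null(cell) || (is.matrix(cell) && nrow(cell) == 0L)) return("")
  if (is.matrix(cell)) {
    return(paste(paste0(cell[, 1], ":", cell[, 2]), collapse = ";"))
  }
  if (is.data.frame(cell)) {
    return(paste(paste0(cell[[1]], ":", cell[[2]]), collapse = ";"))
  }
  paste(as.character(cell), collapse = ";")
}

#' Read a commented-header pipeline TSV
#'
#' @param path Path written by [write_pipeline_tsv()].
#' @param col_types Optional readr-style column specification.
#' @return A tibble with column names taken from the commented header.
#' @export
read_pipeline_tsv <- function(path, col_types = NULL) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  readr::read_tsv(
    path, skip = 1L, col_names = cols,
    col_types = col_types %||% readr::cols(.default = readr::col_guess()),
    na = "", progress = FALSE, show_col_types = FALSE
  )
}

#' Read a one-symbol-per-line (or 2-column) gene list
#'
#' @param path Text file with one gene symbol per line, optionally followed
#'   by a tab-separated annotation column. `#` comments skipped.
#' @return Character vector of symbols, in file order (duplicates retained;
#'   [merge_cancer_genes()] de-duplicates with a warning).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  vapply(strsplit(trimws(lines), "\t|\\s+"), `[[`, character(1), 1L)
}

#' Read a gene-to-domain mapping TSV
#'
#' @param path 2-column TSV (`gene_symbol`, `domain_acc`), multiple rows per
#'   gene allowed; `#` comments skipped. Pfam version suffixes stripped.
#' @return Tibble with columns `gene_symbol`, `domain_acc` (distinct rows).
#' @export
read_gene2domain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(gene_symbol = character(), domain_acc = character()))
  }
  fields <- strsplit(lines, "\t|\\s+")
  fields <- lapply(fields, function(x) x[nzchar(x)])
  short <- lengths(fields) < 2L
  if (any(short)) {
    stop("gene2domain row(s) with fewer than 2 columns: row ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    gene_symbol = vapply(fields, `[[`, character(1), 1L),
    domain_acc = strip_pfam_version(vapply(fields, `[[`, character(1), 2L))
  ) |>
    dplyr::distinct()
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one term per line, tab-separated
#'   `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Tibble with columns `term_id`, `term_name`, `gene` (one row per
#'   term-gene membership, de-duplicated within term).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      term_id = character(), term_name = character(), gene = character()
    ))
  }
  fields <- strsplit(lines, "\t")
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT row(s) with fewer than 3 fields: row ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(fields, function(x) {
    tibble::tibble(
      term_id = x[[1]], term_name = x[[2]],
      gene = unique(x[-(1:2)][nzchar(x[-(1:2)])])
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
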