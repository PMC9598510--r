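# Secreted-protein nomination: a protein is called secreted when it carries
# a predicted signal peptide and no (effective) transmembrane helix —
# transmembrane proteins are subtracted from the signal-peptide-positive set.

#' Call secreted proteins from merged secretion evidence
#'
#' @param evidence Tibble from [read_secretion_tables()]: columns
#'   `protein_id`, `sp_call`, `tm_helix_count` and optionally
#'   `tm_helix_spans` (list-column of start/end matrices).
#' @param nterm_exempt_len Helices lying entirely within residues
#'   `1..nterm_exempt_len` are discounted before the subtraction: signal
#'   peptides are often mis-predicted as a first transmembrane helix.
#'   Default 0 — strict subtraction, where any predicted helix disqualifies.
#'
#' @return Tibble with columns `protein_id`, `is_secreted` and `reason`, one
#'   of `SP_AND_NO_TM` (signal peptide, no helix at all), `SP_TM_EXEMPTED`
#'   (helices present but all inside the exempt window), `HAS_TM`, `NO_SP`.
#'   `is_secreted` is `TRUE` exactly for the first two reasons.
#' @examples
#' ev <- tibble::tibble(
#'   protein_id = c("p1", "p2", "p3"),
#'   sp_call = c(TRUE, TRUE, FALSE),
#'   tm_helix_count = c(0L, 2L, 0L),
#'   tm_helix_spans = list(NULL, cbind(start = c(10L, 50L), end = c(32L, 70L)), NULL)
#' )
#' call_secreted(ev)
#' @export
call_secreted <- function(evidence, nterm_exempt_len = 0L) {
  stopifnot(nterm_exempt_len >= 0L)
  stopifnot(all(c("protein_id", "sp_call", "tm_helix_count") %in%
                  names(evidence)))
  spans <- if ("tm_helix_spans" %in% names(evidence)) {
    evidence$tm_helix_spans
  } else {
    rep(list(NULL), nrow(evidence))
  }
  effective_tm <- vapply(seq_len(nrow(evidence)), function(i) {
    n <- evidence$tm_helix_count[[i]]
    if (n == 0L || nterm_exempt_len == 0L) return(as.integer(n))
    sp <- spans[[i]]
    if (is.null(sp) || nrow(sp) == 0L) return(as.integer(n))
    # a helix is exempt only when wholly within the N-terminal window
    sum(sp[, "end"] > nterm_exempt_len)
  }, integer(1))
  reason <- dplyr::case_when(
    !evidence$sp_call ~ "NO_SP",
    effective_tm > 0L ~ "HAS_TM",
    evidence$tm_helix_count > 0L ~ "SP_TM_EXEMPTED",
    TRUE ~ "SP_AND_NO_TM"
  )
  tibble::tibble(
    protein_id = evidence$protein_id,
    is_secreted = reason %in% c("SP_AND_NO_TM", "SP_TM_EXEMPTED"),
    reason = reason
  )
}

#' Secreted TSG hubs
#'
#' Intersects the secreted-protein set with the TSG hub set; proteins with
#' no secretion evidence are treated as non-secreted.
#'
#' @param secretion_calls Output of [call_secreted()].
#' @param hubs Output of [filter_tsg_hubs()] (tibble with `protein_id` and
#'   optionally `species_id`), or a bare character vector of protein ids.
#'
#' @return The hub rows whose proteins are called secreted, with per-species
#'   counts attached as attribute `per_species` when species ids are present.
#' @export
secreted_tsg_hubs <- function(secretion_calls, hubs) {
  secreted_ids <- secretion_calls$protein_id[secretion_calls$is_secreted]
  if (is.character(hubs)) {
    hubs <- tibble::tibble(protein_id = hubs)
  }
  out <- hubs |>
    dplyr::filter(.data$protein_id %in% secreted_ids) |>
    dplyr::arrange(.data$protein_id)
  if ("species_id" %in% names(out)) {
    out <- dplyr::arrange(out, .data$species_id, .data$protein_id)
    attr(out, "per_species") <- dplyr::count(
      out, .data$species_id, name = "n_secreted_hubs"
    )
  }
  out
}
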