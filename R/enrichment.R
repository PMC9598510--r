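# Hypergeometric over-representation test with Benjamini-Hochberg
# correction, for asking which annotation terms are enriched among a query
# gene set (e.g. the top-ranked cancer partners) relative to a background.
# The statistic is computed exactly in log space from binomial coefficients.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts the query genes falling in a term:
#' `X ~ Hypergeometric(N, K, n)` with `N` background genes, `K` of them in
#' the term, and a query of size `n`. Computed exactly by summing
#' `C(K, i) * C(N - K, n - i) / C(N, n)` for `i = k..min(K, n)` in log
#' space, so deep tails do not underflow.
#'
#' @param k Observed query genes in the term (vectorised).
#' @param K Background genes in the term.
#' @param n Query size.
#' @param N Background size.
#' @return Probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(3, 5, 5, 20) # 1126/15504
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  with(args, {
    if (any(k < 0 | K < 0 | n < 0 | N < 0)) {
      stop("counts must be non-negative", call. = FALSE)
    }
    if (any(n > N) || any(K > N)) {
      stop("query size and term size must not exceed the background",
           call. = FALSE)
    }
    if (any(k > K) || any(k > n)) {
      stop("k cannot exceed the term size or the query size", call. = FALSE)
    }
    vapply(seq_along(k), function(idx) {
      ki <- k[idx]; Ki <- K[idx]; ni <- n[idx]; Ni <- N[idx]
      if (ki == 0) return(1)
      i <- ki:min(Ki, ni)
      i <- i[ni - i <= Ni - Ki] # terms with impossible complements vanish
      if (length(i) == 0L) return(0)
      log_terms <- lchoose(Ki, i) + lchoose(Ni - Ki, ni - i) - lchoose(Ni, ni)
      m <- max(log_terms)
      min(exp(m + log(sum(exp(log_terms - m)))), 1)
    }, double(1))
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Multiplies the i-th smallest p-value by `m / i`, enforces monotonicity
#' from the largest down (the step-up floor), caps at 1, and returns the
#' adjusted values in the input order.
#'
#' @param p_values Numeric vector of raw p-values, all in `(0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  scaled <- p_values[ord] * m / seq_len(m)
  adjusted_sorted <- rev(cummin(rev(pmin(scaled, 1))))
  out <- numeric(m)
  out[ord] <- adjusted_sorted
  out
}

#' Over-representation test of a query gene set against GMT-style terms
#'
#' One exact upper-tail hypergeometric test per term, Benjamini-Hochberg
#' corrected across the tested terms.
#'
#' @param query_genes Character vector of query gene symbols. Genes outside
#'   the background are dropped with a warning.
#' @param term_sets Tibble with columns `term_id`, `term_name`, `gene`
#'   ([read_gmt()]), or a named list of character vectors.
#' @param background_genes Character vector: the gene universe. An explicit
#'   input — there is no built-in default background.
#' @param alpha Adjusted-p significance cutoff (default 0.01).
#'
#' @return Tibble with one row per term having at least one background gene
#'   (`K > 0`): `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adj_p`, `significant` (`adj_p <= alpha`), sorted by `adj_p` then
#'   `term_id`.
#' @export
enrich <- function(query_genes, term_sets, background_genes, alpha = 0.01) {
  if (length(background_genes) == 0L) {
    stop("background gene set is empty", call. = FALSE)
  }
  background <- unique(background_genes)
  query <- unique(query_genes)
  outside <- setdiff(query, background)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    query <- intersect(query, background)
  }
  if (is.list(term_sets) && !is.data.frame(term_sets)) {
    term_sets <- purrr::imap_dfr(term_sets, function(genes, id) {
      tibble::tibble(term_id = id, term_name = id, gene = unique(genes))
    })
  }
  stopifnot(all(c("term_id", "gene") %in% names(term_sets)))
  if (!"term_name" %in% names(term_sets)) {
    term_sets$term_name <- term_sets$term_id
  }
  N <- length(background)
  n <- length(query)
  res <- term_sets |>
    dplyr::filter(.data$gene %in% background) |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$gene) |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      k = sum(.data$gene %in% query),
      K = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$K > 0L)
  if (nrow(res) == 0L) {
    return(tibble::tibble(
      term_id = character(), term_name = character(),
      k = integer(), K = integer(), n = integer(), N = integer(),
      p_value = double(), adj_p = double(), significant = logical()
    ))
  }
  res$n <- n
  res$N <- N
  res$p_value <- hypergeom_upper_tail(res$k, res$K, res$n, res$N)
  res$adj_p <- bh_adjust(res$p_value)
  res$significant <- res$adj_p <= alpha
  dplyr::arrange(res, .data$adj_p, .data$term_id)
}
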