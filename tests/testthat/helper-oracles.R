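# Independent oracles and fixture builders shared across test files.

# Literal triple-loop enumeration of the putative interactome: for every
# protein domain x DDI row x gene domain, record the (protein, gene) pair.
# Intentionally naive and join-free; the reference the fast path must match.
brute_force_interactome <- function(annotations, catalogue, ddi) {
  if (!"species_id" %in% names(annotations)) {
    annotations$species_id <- "unknown"
  }
  rows <- list()
  for (pi in unique(annotations$protein_id)) {
    p_rows <- annotations[annotations$protein_id == pi, ]
    p_doms <- unique(p_rows$domain_acc)
    sp <- p_rows$species_id[1]
    for (gi in seq_len(nrow(catalogue))) {
      g_doms <- catalogue$domain_accs[[gi]]
      hit <- FALSE
      for (a in p_doms) {
        for (r in seq_len(nrow(ddi))) {
          da <- ddi$domain_a[r]
          db <- ddi$domain_b[r]
          partner <- if (a == da) db else if (a == db) da else next
          if (partner %in% g_doms) {
            hit <- TRUE
          }
        }
      }
      if (hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = sp, protein_id = pi,
          gene_symbol = catalogue$gene_symbol[gi],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(species_id = character(), protein_id = character(),
               gene_symbol = character())
  }
  out[order(out$species_id, out$protein_id, out$gene_symbol), ,
      drop = FALSE]
}

# Random small problem instance for property tests.
random_instance <- function(n_proteins = sample(1:50, 1),
                            n_genes = sample(1:30, 1),
                            n_domains = sample(2:20, 1),
                            ddi_frac = runif(1, 0, 0.3)) {
  doms <- sprintf("D%02d", seq_len(n_domains))
  annotations <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    k <- sample(0:min(3L, n_domains), 1)
    if (k == 0) return(NULL)
    data.frame(protein_id = sprintf("p%02d", i),
               domain_acc = sample(doms, k), stringsAsFactors = FALSE)
  }))
  if (is.null(annotations)) {
    annotations <- data.frame(protein_id = character(),
                              domain_acc = character())
  }
  annotations <- tibble::as_tibble(annotations)
  n_tsg <- max(1L, rbinom(1, n_genes, 0.5))
  tsg <- sprintf("g%02d", seq_len(n_tsg))
  ocg <- sprintf("g%02d", seq(n_tsg, n_genes)) # overlap of 1 -> a DUAL gene
  g2d <- do.call(rbind, lapply(unique(c(tsg, ocg)), function(g) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    data.frame(gene_symbol = g, domain_acc = sample(doms, k),
               stringsAsFactors = FALSE)
  }))
  if (is.null(g2d)) {
    g2d <- data.frame(gene_symbol = character(), domain_acc = character())
  }
  catalogue <- suppressMessages(attach_domains(
    merge_cancer_genes(tsg, ocg), tibble::as_tibble(g2d), quiet = TRUE
  ))
  all_pairs <- t(combn(doms, 2))
  n_edges <- round(ddi_frac * nrow(all_pairs))
  ddi <- tibble::tibble(
    domain_a = all_pairs[seq_len(n_edges), 1],
    domain_b = all_pairs[seq_len(n_edges), 2],
    confidence = "HC"
  )
  if (runif(1) < 0.3) { # sometimes include a self-pair
    d <- sample(doms, 1)
    ddi <- rbind(ddi, tibble::tibble(domain_a = d, domain_b = d,
                                     confidence = "HC"))
  }
  list(annotations = annotations, catalogue = catalogue,
       ddi = canonicalise_ddi(ddi))
}

# Exact hypergeometric upper tail by full enumeration of the pmf.
enumerate_upper_tail <- function(k, K, n, N) {
  i <- 0:min(K, n)
  i <- i[n - i <= N - K]
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(pmf[i >= k])
}

# Table of the twenty top-ranked domains with their per-domain TSG and OCG
# gene counts implied by the printed dual-role ratios (count pairs chosen as
# the smallest integers consistent with each printed 6-decimal rendering).
top_domain_reference <- function() {
  tibble::tibble(
    domain_acc = c("PF00069", "PF00400", "PF00515", "PF07714", "PF00271",
                   "PF00023", "PF00072", "PF00270", "PF00076", "PF00560",
                   "PF00595", "PF00071", "PF00169", "PF00070", "PF00571",
                   "PF00168", "PF00989", "PF00097", "PF00249", "PF00149"),
    tsg_count = c(19L, 13L, 0L, 23L, 5L, 0L, 0L, 3L, 5L, 1L,
                  4L, 2L, 3L, 0L, 0L, 12L, 6L, 1L, 2L, 4L),
    ocg_count = c(16L, 5L, 0L, 50L, 1L, 1L, 0L, 1L, 9L, 0L,
                  1L, 3L, 5L, 0L, 0L, 5L, 1L, 0L, 1L, 1L),
    printed_ratio = c("0.542857", "0.722222", NA, "0.315068", "0.833333",
                      "0", NA, "0.75", "0.357143", "1", "0.8", "0.4",
                      "0.375", NA, NA, "0.705882", "0.857143", "1",
                      "0.666667", "0.8")
  )
}
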