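toy_inputs <- function() {
  ann <- tibble::tibble(
    species_id = "sp1",
    protein_id = c("p1", "p2", "p2"),
    domain_acc = c("A", "A", "B")
  )
  catalogue <- tibble::tibble(
    gene_symbol = c("g1", "g2"),
    role = c("TSG", "OCG"),
    domain_accs = list("X", "Y")
  )
  ddi <- canonicalise_ddi(tibble::tibble(
    domain_a = c("A", "B"), domain_b = c("X", "Y"), confidence = "HC"
  ))
  list(ann = ann, catalogue = catalogue, ddi = ddi)
}

test_that("toy interactome enumerates the expected pairs and links", {
  inp <- toy_inputs()
  ia <- build_interactome(inp$ann, inp$catalogue, inp$ddi)
  expect_s3_class(ia, "ddi_interactome")
  key <- paste(ia$protein_id, ia$gene_symbol)
  expect_setequal(key, c("p1 g1", "p2 g1", "p2 g2"))
  expect_equal(nrow(ia), 3L)
  expect_equal(sum(ia$n_domain_links), 3L)
  expect_equal(
    ia$supporting_pairs[[which(key == "p2 g2")]],
    tibble::tibble(foreign_acc = "B", human_acc = "Y")
  )
})

test_that("proteins without domains and empty DDI tables do not interact", {
  inp <- toy_inputs()
  ann <- rbind(inp$ann,
               tibble::tibble(species_id = "sp1", protein_id = "p3",
                              domain_acc = character(0))[0, ])
  ia <- build_interactome(ann, inp$catalogue, inp$ddi)
  expect_false("p3" %in% ia$protein_id)

  empty_ddi <- inp$ddi[0, ]
  expect_warning(ia0 <- build_interactome(inp$ann, inp$catalogue, empty_ddi),
                 "empty DDI")
  expect_equal(nrow(ia0), 0L)
})

test_that("a DDI self-pair supports an interaction as (a, a)", {
  ann <- tibble::tibble(species_id = "s", protein_id = "p", domain_acc = "A")
  catalogue <- tibble::tibble(gene_symbol = "g", role = "TSG",
                              domain_accs = list("A"))
  ddi <- tibble::tibble(domain_a = "A", domain_b = "A", confidence = "HC")
  ia <- build_interactome(ann, catalogue, ddi)
  expect_equal(nrow(ia), 1L)
  expect_equal(ia$supporting_pairs[[1]],
               tibble::tibble(foreign_acc = "A", human_acc = "A"))
})

test_that("build_interactome matches brute-force enumeration on random instances", {
  withr::with_seed(41, {
    for (i in 1:40) {
      inst <- random_instance()
      fast <- suppressWarnings(
        build_interactome(inst$annotations, inst$catalogue, inst$ddi)
      )
      slow <- brute_force_interactome(inst$annotations, inst$catalogue,
                                      inst$ddi)
      expect_identical(
        paste(fast$species_id, fast$protein_id, fast$gene_symbol),
        paste(slow$species_id, slow$protein_id, slow$gene_symbol)
      )
    }
  })
})

test_that("adding DDI edges, annotations or genes never removes interactions", {
  withr::with_seed(43, {
    for (i in 1:10) {
      inst <- random_instance(n_proteins = 15, n_genes = 10, n_domains = 8)
      base <- build_interactome(inst$annotations, inst$catalogue, inst$ddi)
      base_keys <- paste(base$protein_id, base$gene_symbol)

      more_ddi <- canonicalise_ddi(rbind(
        inst$ddi,
        tibble::tibble(domain_a = "D01", domain_b = "D05",
                       confidence = "HC")
      ))
      grown <- build_interactome(inst$annotations, inst$catalogue, more_ddi)
      expect_true(all(base_keys %in%
                        paste(grown$protein_id, grown$gene_symbol)))

      more_ann <- rbind(inst$annotations,
                        tibble::tibble(protein_id = "pNEW",
                                       domain_acc = "D01"))
      grown2 <- build_interactome(more_ann, inst$catalogue, inst$ddi)
      expect_true(all(base_keys %in%
                        paste(grown2$protein_id, grown2$gene_symbol)))
      expect_gte(nrow(grown2), nrow(base))
    }
  })
})

test_that("summaries satisfy the conservation and ordering invariants", {
  withr::with_seed(47, {
    for (i in 1:10) {
      inst <- random_instance()
      ia <- suppressWarnings(
        build_interactome(inst$annotations, inst$catalogue, inst$ddi)
      )
      proteome <- tibble::tibble(
        protein_id = unique(c(inst$annotations$protein_id, "pUNANNOT")),
        species_id = "unknown"
      )
      s <- summarize_interactome(ia, proteome, inst$annotations)
      expect_lte(s$n_interacting_proteins, s$n_proteins_with_domains)
      expect_lte(s$n_proteins_with_domains, s$n_proteins_total)
      expect_lte(s$n_interactions, s$n_domain_links)
      expect_equal(s$n_domain_links, sum(ia$n_domain_links))
      expect_equal(s$n_interactions, nrow(ia))
      for (col in c("n_proteins_vs_tsg", "n_proteins_vs_ocg",
                    "n_proteins_vs_dual")) {
        expect_lte(s[[col]], s$n_interacting_proteins)
      }
      # role groups jointly cover the interacting protein set
      covered <- unique(ia$protein_id)
      by_role <- unique(ia$protein_id[ia$gene_role %in%
                                        c("TSG", "OCG", "DUAL")])
      expect_setequal(by_role, covered)
    }
  })
})

test_that("interactome output is a pure function of the data", {
  withr::with_seed(53, inst <- random_instance(n_proteins = 20))
  ia1 <- build_interactome(inst$annotations, inst$catalogue, inst$ddi)
  shuffled <- inst$annotations[sample(nrow(inst$annotations)), ]
  ia2 <- build_interactome(shuffled, inst$catalogue, inst$ddi)
  expect_identical(as.data.frame(ia1), as.data.frame(ia2))
})

test_that("domain ranking counts interactions per foreign domain with lexical ties", {
  inp <- toy_inputs()
  ia <- build_interactome(inp$ann, inp$catalogue, inp$ddi)
  ranked <- rank_domains_by_interactions(ia, k = 1)
  expect_equal(ranked$domain_acc, "A")
  expect_equal(ranked$n_interactions, 2L)

  full <- rank_domains_by_interactions(ia, k = 100)
  expect_equal(nrow(full), 2L)

  # equal counts break lexicographically
  ann <- tibble::tibble(species_id = "s", protein_id = c("p1", "p2"),
                        domain_acc = c("B", "A"))
  catalogue <- tibble::tibble(gene_symbol = "g", role = "TSG",
                              domain_accs = list("X"))
  ddi <- canonicalise_ddi(tibble::tibble(
    domain_a = c("A", "B"), domain_b = c("X", "X"), confidence = "HC"
  ))
  tie <- rank_domains_by_interactions(
    build_interactome(ann, catalogue, ddi), k = 2
  )
  expect_equal(tie$domain_acc, c("A", "B"))

  profiles <- tibble::tibble(domain_acc = "A", tsg_gene_count = 1L,
                             ocg_gene_count = 0L, ratio = 1,
                             category = "TSG_SPECIFIC")
  annotated <- rank_domains_by_interactions(ia, profiles, k = 2)
  expect_equal(annotated$category, c("TSG_SPECIFIC", "UNKNOWN"))
})

test_that("TSG hub filter uses an inclusive threshold and a dual-role flag", {
  mk_ia <- function(n_tsg, n_ocg = 0, n_dual = 0) {
    genes <- c(sprintf("t%03d", seq_len(n_tsg)),
               sprintf("o%03d", seq_len(n_ocg)),
               sprintf("d%03d", seq_len(n_dual)))
    roles <- c(rep("TSG", n_tsg), rep("OCG", n_ocg), rep("DUAL", n_dual))
    structure(
      tibble::tibble(
        species_id = "s", protein_id = "hub", gene_symbol = genes,
        gene_role = roles, n_domain_links = 1L,
        supporting_pairs = replicate(length(genes), tibble::tibble(
          foreign_acc = "A", human_acc = "X"
        ), simplify = FALSE)
      ),
      class = c("ddi_interactome", class(tibble::tibble()))
    )
  }
  expect_equal(filter_tsg_hubs(mk_ia(100))$protein_id, "hub")
  expect_equal(nrow(filter_tsg_hubs(mk_ia(99, n_ocg = 5))), 0L)
  expect_equal(nrow(filter_tsg_hubs(mk_ia(99, n_dual = 2))), 0L)
  expect_equal(
    filter_tsg_hubs(mk_ia(99, n_dual = 2), include_dual = TRUE)$protein_id,
    "hub"
  )
})

test_that("cross-species overlaps equal brute-force set intersections", {
  inp <- toy_inputs()
  same <- dplyr::bind_rows(
    build_interactome(inp$ann, inp$catalogue, inp$ddi),
    dplyr::mutate(build_interactome(inp$ann, inp$catalogue, inp$ddi),
                  species_id = "sp2")
  )
  m <- cross_species_overlaps(structure(
    same, class = c("ddi_interactome", class(same))
  ))
  expect_equal(m$partners["sp1", "sp2"], m$partners["sp1", "sp1"])
  expect_equal(m$domains["sp1", "sp2"], m$domains["sp2", "sp2"])

  withr::with_seed(59, {
    species <- sprintf("sp%d", 1:3)
    ias <- lapply(species, function(sp) {
      repeat { # draw instances until one yields a non-empty interactome
        inst <- random_instance(n_proteins = 15, n_genes = 12,
                                n_domains = 10, ddi_frac = 0.3)
        ia <- build_interactome(inst$annotations, inst$catalogue, inst$ddi)
        if (nrow(ia) > 0L) break
      }
      dplyr::mutate(ia, species_id = sp)
    })
    combined <- dplyr::bind_rows(ias)
    m <- cross_species_overlaps(structure(
      combined, class = c("ddi_interactome", class(combined))
    ))
    for (i in 1:3) {
      for (j in 1:3) {
        genes_i <- unique(ias[[i]]$gene_symbol)
        genes_j <- unique(ias[[j]]$gene_symbol)
        expect_equal(m$partners[i, j],
                     length(intersect(genes_i, genes_j)))
        dom <- function(ia) {
          unique(unlist(lapply(ia$supporting_pairs,
                               function(sp) sp$foreign_acc)))
        }
        expect_equal(m$domains[i, j],
                     length(intersect(dom(ias[[i]]), dom(ias[[j]]))))
      }
    }
    expect_true(isSymmetric(m$partners))
    expect_true(isSymmetric(m$domains))
  })
})

test_that("interactome writer round-trips through TSV", {
  inp <- toy_inputs()
  ia <- build_interactome(inp$ann, inp$catalogue, inp$ddi)
  path <- withr::local_tempfile()
  write_interactome(ia, path)
  back <- read_interactome(path)
  expect_equal(as.data.frame(back), as.data.frame(ia))
})

test_that("tidy and glance views agree with the nested representation", {
  inp <- toy_inputs()
  ia <- build_interactome(inp$ann, inp$catalogue, inp$ddi)
  long <- tidy(ia)
  expect_equal(nrow(long), sum(ia$n_domain_links))
  g <- glance(ia)
  expect_equal(g$n_interactions, nrow(ia))
  expect_equal(g$n_proteins, 2L)
  expect_equal(g$n_cancer_partners, 2L)
  expect_equal(g$n_domain_links, 3L)
})
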