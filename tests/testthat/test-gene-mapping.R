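test_that("gene-fragment overlap requires at least one shared base", {
  genes <- tibble::tibble(gene_id = "G", gene_name = "G", chrom = "c1",
                          start = 100L, end = 200L, strand = "+", tss = 100L)
  frag_in <- tibble::tibble(chrom = "c1", start = 150L, end = 160L, fragment_id = 0L)
  expect_equal(overlap_genes(frag_in, genes)$gene_id, "G")
  # fragment [200, 300) in 0-based starts just past the gene's last 1-based base (200)
  frag_past <- tibble::tibble(chrom = "c1", start = 200L, end = 300L, fragment_id = 1L)
  expect_equal(nrow(overlap_genes(frag_past, genes)), 0L)
  # fragment [199, 300) still touches base 200
  frag_touch <- tibble::tibble(chrom = "c1", start = 199L, end = 300L, fragment_id = 2L)
  expect_equal(overlap_genes(frag_touch, genes)$gene_id, "G")
  # a fragment spanning two adjacent genes returns both
  two <- dplyr::bind_rows(genes, dplyr::mutate(genes, gene_id = "H", start = 201L,
                                               end = 250L, tss = 201L))
  frag_span <- tibble::tibble(chrom = "c1", start = 150L, end = 230L, fragment_id = 3L)
  expect_setequal(overlap_genes(frag_span, two)$gene_id, c("G", "H"))
})

test_that("cis/trans classification uses chromosomes and a TSS-anchored 1 Mb window", {
  # different chromosomes: always trans (IGF2BP2-region SNP vs RBM47 on chr4)
  expect_equal(classify_cis_trans("3", 185400000, "4", 40425272), "trans")
  expect_equal(classify_cis_trans("7", 100, "7", 500100), "cis")
  expect_equal(classify_cis_trans("7", 1, "7", 1000001), "trans") # exactly 1 Mb
  expect_equal(classify_cis_trans("7", 1, "7", 1000000), "cis")
  # vectorised
  expect_equal(
    classify_cis_trans(c("1", "1"), c(1, 1), c("1", "2"), c(10, 10)),
    c("cis", "trans")
  )
})

test_that("pair building dedups genes across partner fragments and merges cell lines", {
  inst <- tiny_instance()
  # rsA sits on chr1 fragment 0; two contacts reach both genic chr1 fragments
  store <- contact_store(tibble::tibble(
    cell_line = c("L1", "L2", "L1"),
    chrom_a = "chr1", fragment_a = 0L,
    chrom_b = "chr1", fragment_b = c(1L, 1L, 2L)
  ))
  pairs <- suppressMessages(build_pairs(inst$snps[1, ], inst$fragments, store, inst$genes))
  expect_setequal(pairs$gene_id, c("GA", "GB"))
  ga <- pairs[pairs$gene_id == "GA", ]
  expect_equal(ga$cell_lines[[1]], c("L1", "L2"))
  expect_equal(ga$n_cell_lines, 2L)
  # one gene reachable via two partner fragments collapses to one pair
  store2 <- contact_store(tibble::tibble(
    cell_line = "L1", chrom_a = "chr1", fragment_a = 0L,
    chrom_b = c("chr1", "chr1"), fragment_b = c(1L, 2L)
  ))
  genes_wide <- dplyr::mutate(inst$genes[1, ], start = 210L, end = 560L)
  pairs2 <- suppressMessages(build_pairs(inst$snps[1, ], inst$fragments, store2, genes_wide))
  expect_equal(nrow(pairs2), 1L)
  expect_equal(pairs2$n_partner_fragments, 2L)
})

test_that("SNPs with no genic partners or unplaceable positions yield no pairs", {
  inst <- tiny_instance()
  empty_store <- contact_store(tibble::tibble(
    cell_line = character(), chrom_a = character(), fragment_a = integer(),
    chrom_b = character(), fragment_b = integer()
  ))
  # no contacts; self fragment (chr1 frag 0) overlaps no gene
  pairs <- suppressMessages(build_pairs(inst$snps, inst$fragments, empty_store, inst$genes))
  expect_equal(nrow(pairs), 0L)
  # unknown chromosome: skipped with a warning, not an error
  bad <- dplyr::mutate(inst$snps, chrom = "chr99")
  expect_warning(
    pairs_bad <- suppressMessages(
      build_pairs(bad, inst$fragments, empty_store, inst$genes)
    ),
    "skipped"
  )
  expect_equal(nrow(pairs_bad), 0L)
})

test_that("genes on the SNP's own fragment enter the pair set and carry a flag", {
  inst <- tiny_instance()
  snp_on_gene_frag <- tibble::tibble(rsid = "rsC", chrom = "chr1", pos = 220L,
                                     ref = "A", alt = "G")
  empty_store <- contact_store(tibble::tibble(
    cell_line = character(), chrom_a = character(), fragment_a = integer(),
    chrom_b = character(), fragment_b = integer()
  ))
  pairs <- suppressMessages(build_pairs(snp_on_gene_frag, inst$fragments,
                                        empty_store, inst$genes))
  expect_equal(pairs$gene_id, "GA")
  expect_true(pairs$self_fragment)
  off <- suppressMessages(build_pairs(snp_on_gene_frag, inst$fragments,
                                      empty_store, inst$genes,
                                      include_self = FALSE))
  expect_equal(nrow(off), 0L)
})

test_that("pair building matches a brute-force loop over SNPs x contacts x genes", {
  withr::with_seed(99, {
    fragments <- tibble::tibble(
      chrom = rep(c("c1", "c2"), each = 10),
      start = rep(seq(0L, 900L, 100L), 2),
      end = rep(seq(100L, 1000L, 100L), 2),
      fragment_id = rep(0:9, 2)
    )
    genes <- tibble::tibble(
      gene_id = paste0("G", 1:8), gene_name = paste0("G", 1:8),
      chrom = sample(c("c1", "c2"), 8, replace = TRUE),
      start = sample(seq(10L, 900L, 50L), 8)
    ) |>
      dplyr::mutate(end = start + 80L, strand = sample(c("+", "-"), 8, TRUE),
                    tss = ifelse(strand == "-", end, start))
    snps <- tibble::tibble(
      rsid = paste0("rs", 1:6),
      chrom = sample(c("c1", "c2"), 6, replace = TRUE),
      pos = sample(1:1000, 6), ref = "A", alt = "G"
    )
    contacts <- tibble::tibble(
      cell_line = sample(c("L1", "L2"), 15, replace = TRUE),
      chrom_a = sample(c("c1", "c2"), 15, replace = TRUE),
      fragment_a = sample(0:9, 15, replace = TRUE),
      chrom_b = sample(c("c1", "c2"), 15, replace = TRUE),
      fragment_b = sample(0:9, 15, replace = TRUE)
    )
  })
  store <- contact_store(contacts)
  pairs <- suppressMessages(build_pairs(snps, fragments, store, genes))

  # brute force: for every SNP and gene, is some partner fragment (including
  # the SNP's own) overlapping the gene body?
  sym <- dplyr::bind_rows(
    contacts,
    dplyr::rename(contacts, chrom_a = chrom_b, fragment_a = fragment_b,
                  chrom_b = chrom_a, fragment_b = fragment_a)
  )
  expected <- list()
  for (i in seq_len(nrow(snps))) {
    sf <- fragments[fragments$chrom == snps$chrom[i] &
                      fragments$start <= snps$pos[i] - 1 &
                      fragments$end > snps$pos[i] - 1, ]
    part <- sym[sym$chrom_a == sf$chrom & sym$fragment_a == sf$fragment_id, ]
    pf <- unique(rbind(part[, c("chrom_b", "fragment_b")],
                       data.frame(chrom_b = sf$chrom, fragment_b = sf$fragment_id)))
    for (j in seq_len(nrow(genes))) {
      for (r in seq_len(nrow(pf))) {
        fr <- fragments[fragments$chrom == pf$chrom_b[r] &
                          fragments$fragment_id == pf$fragment_b[r], ]
        overlaps <- fr$chrom == genes$chrom[j] &&
          fr$start < genes$end[j] && fr$end > genes$start[j] - 1
        if (overlaps) {
          expected[[paste(snps$rsid[i], genes$gene_id[j])]] <- TRUE
        }
      }
    }
  }
  expect_setequal(paste(pairs$rsid, pairs$gene_id), names(expected))
  # uniqueness and class partition
  expect_equal(anyDuplicated(paste(pairs$rsid, pairs$gene_id)), 0L)
  expect_true(all(pairs$interaction_class %in% c("cis", "trans")))
})
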