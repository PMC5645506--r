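test_that("rank-normalisation hits Blom plotting positions and is odd in rank order", {
  # independent oracle: the standard-normal quantile function at (r - 3/8)/(n + 1/4)
  got <- normalize_expression(c(1, 2, 3))
  want <- qnorm((1:3 - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, want)
  expect_equal(got[2], 0)
  expect_equal(got[1], -got[3])

  withr::with_seed(5, x <- rnorm(40))
  # odd function of rank order: negating the input negates the output,
  # and reversing the input just reverses the output
  expect_equal(normalize_expression(-x), -normalize_expression(x))
  expect_equal(normalize_expression(rev(x)), rev(normalize_expression(x)))
  expect_equal(mean(normalize_expression(x)), 0, tolerance = 1e-12)

  const <- normalize_expression(c(5, 5, 5))
  expect_true(all(is.na(const)))
  expect_true(attr(const, "constant"))
  expect_error(normalize_expression(c(1, 2)), "non-missing")
})

test_that("ties share the mean rank under normalisation", {
  got <- normalize_expression(c(1, 2, 2, 3))
  expect_equal(got[2], got[3])
  expect_equal(got[2], qnorm((2.5 - 3 / 8) / (4 + 1 / 4)))
})

test_that("association on an exact linear relation recovers the slope with zero residual", {
  res <- test_association(c(0, 1, 2, 0, 1, 2), c(0, 0.5, 1, 0, 0.5, 1),
                          min_samples = 5)
  expect_true(res$tested)
  expect_equal(res$beta, 0.5)
  expect_equal(res$se, 0)
  expect_equal(res$p_value, 0)
})

test_that("association equals the lm oracle to 1e-10 relative tolerance", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      n <- sample(10:80, 1)
      x <- rbinom(n, 2, 0.3)
      if (sd(x) == 0) next
      y <- 0.3 * x + rnorm(n)
      got <- test_association(x, y, min_samples = 5)
      want <- oracle_ols(x, y)
      expect_equal(got$beta, want$beta, tolerance = 1e-10)
      expect_equal(got$se, want$se, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    }
  })
})

test_that("untestable inputs return a reason code instead of a fit", {
  expect_equal(test_association(rep(0, 20), rnorm(20))$reason, "constant_dosage")
  few <- test_association(c(0, 1, 2), c(1, 2, 3), min_samples = 10)
  expect_equal(few$reason, "too_few_samples")
  # pairwise missing-data handling drops to the complete pairs
  x <- c(0, 1, 2, NA, 1, 0, 2, 1, 0, 2, 1, 0)
  y <- c(rnorm(11), NA)
  res <- test_association(x, y, min_samples = 5)
  expect_equal(res$n_samples, 10L)
})

test_that("the scan emits one result per pair per tissue measuring the gene", {
  fx <- make_fixture(fixture_spec(seed = 3, n_tissues = 3,
                                  planted_links = tibble::tibble(
                                    snp = 1L, gene = 1L, cell_lines = "CL1"
                                  ),
                                  planted_effects = tibble::tibble(
                                    snp = 1L, gene = 1L, tissue = 1L, beta = 0.8
                                  ),
                                  n_decoy_contacts = 0),
                     withr::local_tempdir())
  pairs <- suppressMessages(build_pairs(fx$snps, fx$fragments, fx$contacts, fx$genes))
  expect_equal(nrow(pairs), 1L)
  res <- suppressMessages(run_eqtl_scan(pairs, fx$genotypes, fx$expression_by_tissue))
  expect_equal(nrow(res), 3L)
  expect_setequal(res$tissue, c("tissue1", "tissue2", "tissue3"))
  # empty pair set scans to an empty result set
  expect_equal(nrow(suppressMessages(
    run_eqtl_scan(pairs[0, ], fx$genotypes, fx$expression_by_tissue)
  )), 0L)
})

test_that("a planted effect is recovered near its true slope", {
  fx <- make_fixture(fixture_spec(seed = 17, n_samples = 200, n_tissues = 1,
                                  noise_sd = 1,
                                  planted_links = tibble::tibble(
                                    snp = 1L, gene = 1L, cell_lines = "CL1"
                                  ),
                                  planted_effects = tibble::tibble(
                                    snp = 1L, gene = 1L, tissue = 1L, beta = 0.8
                                  ),
                                  n_decoy_contacts = 0),
                     withr::local_tempdir())
  pairs <- suppressMessages(build_pairs(fx$snps, fx$fragments, fx$contacts, fx$genes))
  # raw scale (no rank-normalisation) for slope recovery
  res <- suppressMessages(run_eqtl_scan(pairs, fx$genotypes, fx$expression_by_tissue,
                                        normalize = FALSE))
  expect_equal(res$beta, 0.8, tolerance = 0.15 / 0.8)
  expect_lt(res$p_value, 1e-4)
})

test_that("slope bias shrinks as the sample grows", {
  bias <- vapply(c(50, 200, 800), function(n) {
    withr::with_seed(1000 + n, {
      betas <- vapply(1:40, function(i) {
        x <- rbinom(n, 2, 0.3)
        y <- 0.5 * x + rnorm(n)
        test_association(x, y, min_samples = 5)$beta
      }, numeric(1))
    })
    abs(mean(betas) - 0.5)
  }, numeric(1))
  expect_lt(bias[3], 0.05)
  expect_lt(max(bias), 0.12)
})

test_that("a precomputed association table passes through the spatial filter unchanged", {
  inst <- tiny_instance()
  store <- contact_store(tibble::tibble(
    cell_line = "L1", chrom_a = "chr1", fragment_a = 0L,
    chrom_b = "chr1", fragment_b = 1L
  ))
  pairs <- suppressMessages(build_pairs(inst$snps[1, ], inst$fragments, store, inst$genes))
  pre <- tibble::tibble(
    rsid = c("rsA", "rsZ"), gene_id = c("GA", "GA"), tissue = "Whole_Blood",
    beta = c(0.3, 9), p_value = c(1e-6, 1e-9), q_value = c(0.01, 0.001)
  )
  res <- run_eqtl_scan(pairs, precomputed = pre)
  expect_equal(nrow(res), 1L) # rsZ is not a spatial pair
  expect_equal(res$beta, 0.3)
  expect_equal(res$p_value, 1e-6)
  expect_equal(res$q_value, 0.01)
})

test_that("genotype matrices read identically from TSV and VCF dialects", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(rsid = c("rs1", "rs2"),
                                  S1 = c(0, 2), S2 = c(1, NA)), tsv)
  g1 <- read_genotypes(tsv)
  expect_equal(g1$S1, c(0, 2))
  expect_true(is.na(g1$S2[2]))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./."
  ), vcf)
  g2 <- read_genotypes(vcf)
  expect_equal(g2$rsid, c("rs1", "rs2"))
  expect_equal(g2$S1, c(0, 2))
  expect_equal(g2$S2[1], 1)
  expect_true(is.na(g2$S2[2]))
})
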