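# Independent oracles used across tests.  These deliberately avoid the code
# paths they check: digestion by naive substring scan, BH by the direct
# min-over-larger-p formula, OLS by stats::lm.

# all 0-based offsets at which `site` occurs in `seq` (naive windowed scan)
oracle_site_offsets <- function(seq, site) {
  n <- nchar(seq)
  w <- nchar(site)
  if (n < w) return(integer(0))
  starts <- seq_len(n - w + 1)
  which(substring(seq, starts, starts + w - 1) == site) - 1L
}

oracle_fragments <- function(seq, site = "GATC") {
  cuts <- oracle_site_offsets(seq, site)
  bounds <- sort(unique(c(0L, cuts, nchar(seq))))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# q_i = min over {j : p_j >= p_i} of p_j * m / sortrank_j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    j <- which(sp >= pi)
    min(1, min(sp[j] * m / j))
  }, numeric(1))
}

oracle_ols <- function(x, y) {
  fit <- summary(stats::lm(y ~ x))
  co <- stats::coef(fit)["x", ]
  list(beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       p_value = unname(co["Pr(>|t|)"]))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small fully-enumerated instance shared by gene-mapping tests:
# two chromosomes, hand-placed fragments, genes and SNPs
tiny_instance <- function() {
  fragments <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(0L, 200L, 500L, 0L, 300L),
    end = c(200L, 500L, 900L, 300L, 700L),
    fragment_id = c(0L, 1L, 2L, 0L, 1L)
  )
  genes <- tibble::tibble(
    gene_id = c("GA", "GB", "GC"),
    gene_name = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(210L, 520L, 310L),
    end = c(260L, 560L, 350L),
    strand = c("+", "-", "+"),
    tss = c(210L, 560L, 310L)
  )
  snps <- tibble::tibble(
    rsid = c("rsA", "rsB"),
    chrom = c("chr1", "chr2"),
    pos = c(100L, 100L),
    ref = "A", alt = "G", trait = "t", assoc_p = c(1e-9, 1e-6)
  )
  list(fragments = fragments, genes = genes, snps = snps)
}
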