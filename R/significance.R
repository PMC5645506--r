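#' Stepwise Benjamini-Hochberg q-values
#'
#' For each p-value, the q-value is the smallest FDR level at which that
#' test would be rejected under the step-up procedure:
#' `q_i = min over {j : p_j >= p_i} of (p_j * m / rank_j)`, capped at 1,
#' with monotone enforcement.  Output order matches input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_stepwise(c(0.005, 0.04, 0.05))
#' @export
bh_stepwise <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  # step-up: each q is the minimum of its own and all larger-p adjusted values
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  # q >= p holds mathematically; pmax guards the last-ulp rounding of p*m/rank
  pmax(q, p_values)
}

#' Select significant eQTLs with trans and per-gene cis families
#'
#' Applies the stepwise Benjamini-Hochberg correction with the family
#' structure used for spatially filtered eQTL testing: all trans tests form
#' one family (pooled across SNPs, genes and tissues), while cis tests are
#' corrected within per-gene families (all cis tests targeting one gene,
#' pooled across tissues by default).  A result is significant when its
#' q-value is at most `alpha` within its family.
#'
#' @param results eQTL result tibble from [run_eqtl_scan()] (needs
#'   `p_value`, `interaction_class`, `gene_id`).
#' @param alpha FDR level (default 0.05).  The comparison is `q <= alpha`.
#' @param cis_family `"gene"` (default; one family per gene pooled across
#'   tissues) or `"gene_tissue"` (one family per gene-tissue combination).
#' @param recompute_q If `FALSE`, existing `q_value`s (e.g. from a
#'   precomputed association export) are thresholded as-is instead of being
#'   recomputed.
#' @return `results` with `q_value` populated and `significant` set;
#'   filter on `significant` for the selected set.
#' @export
select_significant <- function(results, alpha = 0.05, cis_family = "gene",
                               recompute_q = TRUE) {
  if (nrow(results) == 0) {
    return(mutate(results, q_value = double(0), significant = logical(0)))
  }
  if (recompute_q) {
    is_trans <- results$interaction_class == "trans"
    q <- rep(NA_real_, nrow(results))
    if (any(is_trans)) q[is_trans] <- bh_stepwise(results$p_value[is_trans])
    if (any(!is_trans)) {
      fam <- switch(cis_family,
        gene = results$gene_id[!is_trans],
        gene_tissue = paste(results$gene_id, results$tissue)[!is_trans],
        abort("cis_family must be 'gene' or 'gene_tissue'")
      )
      idx <- which(!is_trans)
      for (f in unique(fam)) {
        sel <- idx[fam == f]
        q[sel] <- bh_stepwise(results$p_value[sel])
      }
    }
    results$q_value <- q
  } else if (!"q_value" %in% names(results) || any(is.na(results$q_value))) {
    abort("recompute_q = FALSE requires a complete q_value column")
  }
  results$significant <- results$q_value <= alpha
  results
}

#' Filter results to expressed genes
#'
#' Keeps results whose gene is expressed above `threshold` RPKM (strictly
#' greater) in the result's tissue.  Genes absent from the RPKM table are
#' dropped with a message.
#'
#' @param results eQTL result tibble.
#' @param rpkm_table Tibble with `gene_id`, `tissue`, `rpkm`.
#' @param threshold RPKM threshold (default 1.0; kept if `rpkm > threshold`).
#' @return Filtered results with an `rpkm` column appended.
#' @export
filter_expressed <- function(results, rpkm_table, threshold = 1.0) {
  joined <- left_join(results, rpkm_table, by = c("gene_id", "tissue"))
  n_absent <- sum(is.na(joined$rpkm))
  if (n_absent > 0) {
    inform(sprintf("%d result(s) dropped: gene/tissue absent from the RPKM table",
                   n_absent))
  }
  if (nrow(joined) > 0 && all(is.na(joined$rpkm))) {
    warn("no result gene was found in the RPKM table")
  }
  filter(joined, !is.na(.data$rpkm) & .data$rpkm > threshold)
}

#' Summarise the regulatory network
#'
#' Computes the standard count vector for a SNP set: input SNPs, spatial
#' SNP-gene pairs, eQTL SNPs (significant with at least one gene), eGenes
#' (genes affected by at least one eQTL SNP), distinct significant
#' SNP-gene pairs, SNP-gene-tissue interactions, and the trans subset of
#' those interactions.
#'
#' @param snps Input SNP tibble (a multiset: duplicates count).
#' @param pairs Spatial pair tibble from [build_pairs()].
#' @param results Result tibble with `significant` set (from
#'   [select_significant()], optionally after [filter_expressed()]).
#' @return One-row tibble of class `spateq_summary`.
#' @export
summarize_network <- function(snps, pairs, results) {
  sig <- filter(results, .data$significant)
  out <- tibble(
    n_snps_input = nrow(snps),
    n_spatial_pairs = nrow(distinct(pairs, .data$rsid, .data$gene_id)),
    n_eqtl_snps = dplyr::n_distinct(sig$rsid),
    n_egenes = dplyr::n_distinct(sig$gene_id),
    n_eqtl_pairs = nrow(distinct(sig, .data$rsid, .data$gene_id)),
    n_interactions = nrow(distinct(sig, .data$rsid, .data$gene_id, .data$tissue)),
    n_trans_interactions = nrow(distinct(
      filter(sig, .data$interaction_class == "trans"),
      .data$rsid, .data$gene_id, .data$tissue
    ))
  )
  structure(out, class = c("spateq_summary", class(out)))
}

summary_metrics <- c(
  "n_snps_input", "n_spatial_pairs", "n_eqtl_snps", "n_egenes",
  "n_eqtl_pairs", "n_interactions", "n_trans_interactions"
)

#' Partition SNPs into association-significance tiers
#'
#' `genome_wide` for association p below the genome-wide threshold,
#' `suggestive` for p between the genome-wide and suggestive bounds
#' (inclusive).  SNPs above the suggestive bound, or with missing p, are
#' excluded with a warning.
#'
#' @param snps SNP tibble with an `assoc_p` column.
#' @param genome_wide Genome-wide threshold (default 5e-8, strict `<`).
#' @param suggestive Upper bound of the suggestive tier (default 9e-6,
#'   inclusive).
#' @return `snps` restricted to tiered SNPs, with a `tier` column.
#' @export
tier_snps <- function(snps, genome_wide = 5e-8, suggestive = 9e-6) {
  if (!"assoc_p" %in% names(snps)) abort("snps must carry an assoc_p column")
  tier <- dplyr::case_when(
    is.na(snps$assoc_p) ~ NA_character_,
    snps$assoc_p < genome_wide ~ "genome_wide",
    snps$assoc_p <= suggestive ~ "suggestive",
    TRUE ~ NA_character_
  )
  n_out <- sum(is.na(tier))
  if (n_out > 0) {
    warn(sprintf("%d SNP(s) excluded: association p missing or above %.1e",
                 n_out, suggestive))
  }
  mutate(snps, tier = tier) |> filter(!is.na(.data$tier))
}
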