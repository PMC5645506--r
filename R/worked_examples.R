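#' Packaged worked-example eQTL records
#'
#' Two small published record sets ship with the package for worked
#' examples and regression tests of the classification and counting logic:
#'
#' \describe{
#'   \item{`"lipid"`}{Tissue-specific eQTL effect slopes for
#'     lipid-metabolism genes mapped from type 2 diabetes and obesity GWAS
#'     SNPs, tidy long form (`rsid`, `disease`, `risk`, `trait`,
#'     `gwas_gene`, `gene`, `tissue`, `slope`, `low_rpkm`).  Five distinct
#'     SNPs map to IRS1 — a single regulatory restriction fragment carrying
#'     several linked variants.}
#'   \item{`"igf2bp2_trans"`}{The three tissue-specific trans-acting eQTL
#'     records anchored in the fine-mapped IGF2BP2 region on chromosome 3
#'     (`rsid`, `snp_chrom`, `snp_pos_approx`, `gene_name`, `gene_chrom`,
#'     `gene_tss`, `tissue`, `p_value`, `q_value`, `cell_line`).  SNP base
#'     positions were not published; `snp_pos_approx` is a synthetic
#'     placement inside the fine-mapped region and the cis/trans call for
#'     these records depends only on the chromosomes.}
#' }
#'
#' @param which `"lipid"` or `"igf2bp2_trans"`.
#' @return A tibble.
#' @examples
#' eqtl_example_records("lipid") |>
#'   dplyr::filter(gene == "IRS1") |>
#'   dplyr::distinct(rsid)
#' @export
eqtl_example_records <- function(which = c("lipid", "igf2bp2_trans")) {
  which <- match.arg(which)
  file <- switch(which,
    lipid = "lipid_eqtl_records.tsv",
    igf2bp2_trans = "igf2bp2_trans_records.tsv"
  )
  path <- system.file("extdata", file, package = "spateqtl", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
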