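#' Read gene annotation from GTF or BED
#'
#' Gene-level records only: for GTF, rows with `type == "gene"` (or all rows
#' if no type column); for BED, every interval, with the `name` field as the
#' gene id.  Coordinates are reported 1-based inclusive as in GTF.  The
#' transcription start site (TSS) is the 5' end of the gene body: `start` on
#' the + strand, `end` on the - strand (unstranded records fall back to
#' `start`).
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` file.
#' @return Tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  if ("type" %in% names(meta) && any(meta$type == "gene")) {
    gr <- gr[meta$type == "gene"]
    meta <- as.data.frame(gr)
  }
  gene_id <- meta$gene_id %||% meta$name %||% as.character(seq_along(gr))
  gene_name <- meta$gene_name %||% gene_id
  genes <- tibble(
    gene_id = as.character(gene_id),
    gene_name = as.character(gene_name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(genes$start > genes$end)) abort("gene annotation with start > end")
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes
}

genes_as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    gene_id = genes$gene_id
  )
}

# fragments are 0-based half-open; GRanges are 1-based inclusive
fragments_as_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L, end = fragments$end)
  )
}

#' Genes overlapping a restriction fragment
#'
#' Returns every gene whose body interval shares at least one base with the
#' fragment's interval; strand is ignored for overlap.
#'
#' @param fragment One-row fragment tibble (`chrom`, `start`, `end`).
#' @param genes Gene annotation tibble from [read_gene_annotation()].
#' @return The overlapping rows of `genes`.
#' @export
overlap_genes <- function(fragment, genes) {
  hits <- GenomicRanges::findOverlaps(
    fragments_as_granges(fragment), genes_as_granges(genes),
    ignore.strand = TRUE
  )
  genes[sort(unique(S4Vectors::subjectHits(hits))), ]
}

# fragment-row -> gene-row overlap map for a whole index, computed once
fragment_gene_map <- function(fragments, genes) {
  hits <- GenomicRanges::findOverlaps(
    fragments_as_granges(fragments), genes_as_granges(genes),
    ignore.strand = TRUE
  )
  tibble(
    chrom = fragments$chrom[S4Vectors::queryHits(hits)],
    fragment_id = fragments$fragment_id[S4Vectors::queryHits(hits)],
    gene_row = S4Vectors::subjectHits(hits)
  )
}

#' Classify a SNP-gene pair as cis or trans
#'
#' Trans if the SNP and the gene TSS are on different chromosomes or at
#' least `cis_window` bp apart; cis if closer.  The distance is anchored on
#' the TSS (the usual eQTL windowing convention); a pair at exactly the
#' window width is trans.  Vectorised.
#'
#' @param snp_chrom,snp_pos SNP coordinates (1-based).
#' @param gene_chrom,gene_tss Gene coordinates (TSS, 1-based).
#' @param cis_window Window width in bp (default 1 Mb).
#' @return Character vector, `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_tss,
                               cis_window = 1e6) {
  ifelse(
    snp_chrom != gene_chrom | abs(snp_pos - gene_tss) >= cis_window,
    "trans", "cis"
  )
}

#' Build spatial SNP-gene pairs
#'
#' For each SNP: locate its restriction fragment, gather partner fragments
#' (the union over cell lines; the SNP's own fragment is included by default
#' since it is trivially co-localised), overlap each partner with genes, and
#' emit one pair per distinct (SNP, gene) with merged supporting cell lines
#' and merged partner fragments.  SNPs on unknown chromosomes, beyond the
#' chromosome end, or with no genic partners produce no pairs and are
#' counted in a message.
#'
#' @param snps SNP tibble (`rsid`, `chrom`, `pos`, and optionally `ref`,
#'   `alt`, `trait`, `assoc_p`).
#' @param fragment_index Fragment tibble from [digest_genome()].
#' @param store Contact store from [load_contacts()].
#' @param genes Gene annotation tibble.
#' @param include_self Include genes on the SNP's own fragment even without
#'   a ligation record (default `TRUE`).  Such pairs are flagged
#'   `self_fragment = TRUE` so sensitivity runs can drop them.
#' @param cis_window Passed to [classify_cis_trans()].
#' @return Tibble with one row per (rsid, gene_id): SNP fields, gene fields,
#'   `interaction_class`, `cell_lines` (list-column), `n_cell_lines`,
#'   `partner_fragments` (list-column of "chrom:id" keys),
#'   `n_partner_fragments`, `self_fragment`.
#' @export
build_pairs <- function(snps, fragment_index, store, genes,
                        include_self = TRUE, cis_window = 1e6) {
  snps <- as_tibble(snps)
  empty <- tibble(
    rsid = character(), snp_chrom = character(), snp_pos = integer(),
    gene_id = character(), gene_name = character(), gene_chrom = character(),
    tss = integer(), interaction_class = character(),
    cell_lines = list(), n_cell_lines = integer(),
    partner_fragments = list(), n_partner_fragments = integer(),
    self_fragment = logical()
  )
  if (nrow(snps) == 0) return(empty)

  snps <- distinct(snps, .data$rsid, .keep_all = TRUE)

  # place SNPs on fragments; unmappable SNPs are skipped with a warning
  frag_of <- purrr::map(seq_len(nrow(snps)), function(i) {
    tryCatch(
      locate_fragment(fragment_index, snps$chrom[i], snps$pos[i]),
      error = function(e) NULL
    )
  })
  unmapped <- purrr::map_lgl(frag_of, is.null)
  if (any(unmapped)) {
    warn(sprintf("%d SNP(s) could not be placed on a fragment and were skipped",
                 sum(unmapped)))
  }
  snp_frag <- bind_rows(purrr::map(which(!unmapped), function(i) {
    tibble(rsid = snps$rsid[i], snp_chrom = snps$chrom[i],
           snp_pos = snps$pos[i],
           frag_chrom = frag_of[[i]]$chrom, frag_id = frag_of[[i]]$fragment_id)
  }))
  if (nrow(snp_frag) == 0) return(empty)

  sym <- symmetric_contacts(store)
  partners <- snp_frag |>
    inner_join(sym,
      by = c(frag_chrom = "chrom_a", frag_id = "fragment_a"),
      relationship = "many-to-many"
    ) |>
    select("rsid", "snp_chrom", "snp_pos", "frag_chrom", "frag_id",
           p_chrom = "chrom_b", p_frag = "fragment_b", "cell_line")
  if (include_self) {
    self <- snp_frag |>
      mutate(p_chrom = .data$frag_chrom, p_frag = .data$frag_id,
             cell_line = NA_character_)
    partners <- bind_rows(partners, self)
  }
  if (nrow(partners) == 0) {
    inform("no partner fragments for any SNP")
    return(empty)
  }

  gene_map <- fragment_gene_map(fragment_index, genes)
  hits <- partners |>
    inner_join(gene_map, by = c(p_chrom = "chrom", p_frag = "fragment_id"),
               relationship = "many-to-many")
  n_no_gene <- dplyr::n_distinct(snp_frag$rsid) - dplyr::n_distinct(hits$rsid)
  if (n_no_gene > 0) {
    inform(sprintf("%d SNP(s) had no genic partner fragments", n_no_gene))
  }
  if (nrow(hits) == 0) return(empty)

  pairs <- hits |>
    mutate(
      gene_id = genes$gene_id[.data$gene_row],
      gene_name = genes$gene_name[.data$gene_row],
      gene_chrom = genes$chrom[.data$gene_row],
      tss = genes$tss[.data$gene_row],
      frag_key = paste0(.data$p_chrom, ":", .data$p_frag),
      is_self = .data$p_chrom == .data$frag_chrom & .data$p_frag == .data$frag_id
    ) |>
    group_by(.data$rsid, .data$snp_chrom, .data$snp_pos, .data$gene_id,
             .data$gene_name, .data$gene_chrom, .data$tss) |>
    summarise(
      cell_lines = list(sort(unique(.data$cell_line[!is.na(.data$cell_line)]))),
      partner_fragments = list(sort(unique(.data$frag_key))),
      self_fragment = all(.data$is_self),
      .groups = "drop"
    ) |>
    mutate(
      interaction_class = classify_cis_trans(
        .data$snp_chrom, .data$snp_pos, .data$gene_chrom, .data$tss,
        cis_window = cis_window
      ),
      n_cell_lines = lengths(.data$cell_lines),
      n_partner_fragments = lengths(.data$partner_fragments)
    ) |>
    select("rsid", "snp_chrom", "snp_pos", "gene_id", "gene_name",
           "gene_chrom", "tss", "interaction_class", "cell_lines",
           "n_cell_lines", "partner_fragments", "n_partner_fragments",
           "self_fragment")

  extra <- setdiff(c("trait", "assoc_p"), names(pairs))
  if (length(extra) > 0 && all(extra %in% names(snps))) {
    pairs <- left_join(pairs, snps[, c("rsid", extra)], by = "rsid")
  }
  arrange(pairs, .data$rsid, .data$gene_id)
}

#' Write the SNP-gene pair table
#'
#' Flattens the list-columns into comma-separated strings for the on-disk
#' TSV.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param path Output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  flat <- pairs |>
    mutate(
      cell_lines = purrr::map_chr(.data$cell_lines, paste, collapse = ","),
      partner_fragments = purrr::map_chr(.data$partner_fragments, paste,
                                         collapse = ",")
    )
  readr::write_tsv(flat, path)
  invisible(path)
}
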