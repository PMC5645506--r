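#' Specify a synthetic input bundle
#'
#' Describes a toy spatial-eQTL study: a genome whose restriction-site
#' positions (and hence fragments) are fully controlled, SNPs and genes on
#' disjoint fragments, chromatin contacts realising exactly the planted
#' SNP-gene links, Hardy-Weinberg genotypes, and per-tissue expression where
#' planted (SNP, gene, tissue) triples have `expression = beta * dosage +
#' Normal(0, noise_sd)` and everything else is independent noise.  Decoy
#' contacts join random fragments that host no SNP, stressing deduplication
#' and overlap logic without changing the planted pair set.
#'
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 60 kb).
#' @param site_density Expected recognition sites per kb (default 4, the
#'   expectation for a 4-base site in random sequence).
#' @param n_snps,n_genes,n_cell_lines,n_tissues,n_samples Panel sizes.
#' @param planted_links Tibble `snp`, `gene` (1-based indices), `cell_lines`
#'   (comma string or list); `NULL` plants one random gene for 60% of SNPs.
#' @param planted_effects Tibble `snp`, `gene`, `tissue` (index), `beta`;
#'   `NULL` plants `beta = 0.8` in one tissue for half the linked SNPs.
#' @param n_decoy_contacts Decoy contact records (default 20).
#' @param maf Minor-allele frequency in (0, 0.5], scalar or per-SNP.
#' @param noise_sd Expression noise SD (> 0, default 1).
#' @param low_rpkm_genes Gene indices given RPKM 0.5 everywhere (default
#'   none; all genes get RPKM 5.0, comfortably expressed).
#' @param separate_chromosomes If `TRUE`, SNPs are placed on the first
#'   chromosome and genes on the remaining ones, so every planted link is an
#'   inter-chromosomal (trans) connection and all tests share one
#'   correction family.  Default `FALSE`: fragments are drawn genome-wide
#'   and the cis/trans mix falls out of the placement.
#' @param seed Integer seed; the bundle is byte-identical given the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chromosomes = 2, chrom_length = 60000,
                         site_density = 4, n_snps = 30, n_genes = 12,
                         n_cell_lines = 2, n_tissues = 2, n_samples = 100,
                         planted_links = NULL, planted_effects = NULL,
                         n_decoy_contacts = 20, maf = 0.3, noise_sd = 1,
                         low_rpkm_genes = integer(0),
                         separate_chromosomes = FALSE, seed = 1) {
  if (any(maf <= 0 | maf > 0.5)) abort("maf must lie in (0, 0.5]")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  spec <- list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    site_density = site_density, n_snps = n_snps, n_genes = n_genes,
    n_cell_lines = n_cell_lines, n_tissues = n_tissues,
    n_samples = n_samples, planted_links = planted_links,
    planted_effects = planted_effects,
    n_decoy_contacts = n_decoy_contacts,
    maf = rep_len(maf, n_snps), noise_sd = noise_sd,
    low_rpkm_genes = low_rpkm_genes,
    separate_chromosomes = separate_chromosomes, seed = seed
  )
  structure(spec, class = "fixture_spec")
}

# random DNA with every GATC occurrence scrubbed, then GATC written in at
# exactly the requested 0-based cut positions
build_chrom_sequence <- function(len, cuts) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seq <- paste(chars, collapse = "")
  repeat {
    hit <- regexpr("GATC", seq, fixed = TRUE)
    if (hit < 0) break
    substr(seq, hit, hit) <- "T"
  }
  for (p in cuts) substr(seq, p + 1, p + 4) <- "GATC"
  seq
}

default_links <- function(spec) {
  n_linked <- max(1, floor(0.6 * spec$n_snps))
  tibble(
    snp = seq_len(n_linked),
    gene = sample.int(spec$n_genes, n_linked, replace = TRUE),
    cell_lines = purrr::map(seq_len(n_linked), function(i) {
      paste0("CL", sort(sample.int(spec$n_cell_lines,
                                   sample.int(spec$n_cell_lines, 1))))
    })
  )
}

default_effects <- function(spec, links) {
  # one effect per gene at most, so gene-tissue expression models never collide
  one_per_gene <- links[!duplicated(links$gene), ]
  n_eff <- max(1, floor(nrow(one_per_gene) / 2))
  tibble(
    snp = one_per_gene$snp[seq_len(n_eff)],
    gene = one_per_gene$gene[seq_len(n_eff)],
    tissue = sample.int(spec$n_tissues, n_eff, replace = TRUE),
    beta = 0.8
  )
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes FASTA, fragment BED, gene GTF, SNP TSV, contact TSV, genotype TSV,
#' one expression TSV per tissue, an RPKM TSV and a YAML manifest into
#' `dir`, all in the dialects the production readers consume.  Each SNP and
#' each gene sits on its own restriction fragment (disjoint sets), so the
#' planted links determine the spatial pair set exactly when there are no
#' decoys.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisible list: `paths` (named file paths), `truth`
#'   (`links` and `effects` tibbles resolved to rsid/gene_id, with
#'   interaction classes), `fragments`, `snps`, `genes`, `spec`.
#' @export
make_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    n_sites <- max(2, round(spec$chrom_length * spec$site_density / 1000))

    # controlled digestion: cut positions chosen, sequence built around them
    cuts_by_chrom <- lapply(chroms, function(ch) {
      cand <- seq(20L, spec$chrom_length - 24L, by = 12L)
      sort(sample(cand, min(n_sites, length(cand))))
    })
    names(cuts_by_chrom) <- chroms
    genome <- tibble(
      chrom = chroms,
      sequence = purrr::map_chr(cuts_by_chrom, function(cuts) {
        build_chrom_sequence(spec$chrom_length, cuts)
      })
    )
    fragments <- digest_genome(genome)

    n_frags <- nrow(fragments)
    if (n_frags < spec$n_snps + spec$n_genes) {
      abort(sprintf(
        "infeasible spec: %d fragments cannot host %d SNPs and %d genes on disjoint fragments",
        n_frags, spec$n_snps, spec$n_genes
      ))
    }
    # fragments long enough to carry a gene body or an interior SNP
    usable <- which(fragments$end - fragments$start >= 8)
    if (isTRUE(spec$separate_chromosomes)) {
      snp_pool <- usable[fragments$chrom[usable] == chroms[1]]
      gene_pool <- usable[fragments$chrom[usable] != chroms[1]]
      if (length(snp_pool) < spec$n_snps || length(gene_pool) < spec$n_genes) {
        abort("infeasible spec: not enough fragments per chromosome for the separated layout")
      }
      snp_frag_rows <- sample(snp_pool, spec$n_snps)
      gene_frag_rows <- sample(gene_pool, spec$n_genes)
    } else {
      picked <- sample(usable, spec$n_snps + spec$n_genes)
      snp_frag_rows <- picked[seq_len(spec$n_snps)]
      gene_frag_rows <- picked[spec$n_snps + seq_len(spec$n_genes)]
    }

    snps <- tibble(
      rsid = paste0("rs", seq_len(spec$n_snps)),
      chrom = fragments$chrom[snp_frag_rows],
      pos = as.integer(floor((fragments$start[snp_frag_rows] +
                                fragments$end[snp_frag_rows]) / 2)) + 1L,
      ref = "A", alt = "G",
      trait = "synthetic_trait",
      assoc_p = ifelse(runif(spec$n_snps) < 0.6,
                       10^runif(spec$n_snps, -12, log10(5e-8)),
                       10^runif(spec$n_snps, log10(5e-8), log10(9e-6)))
    )
    genes <- tibble(
      gene_id = paste0("G", seq_len(spec$n_genes)),
      gene_name = paste0("G", seq_len(spec$n_genes)),
      chrom = fragments$chrom[gene_frag_rows],
      start = fragments$start[gene_frag_rows] + 3L, # 1-based, inside fragment
      end = fragments$end[gene_frag_rows] - 1L,
      strand = sample(c("+", "-"), spec$n_genes, replace = TRUE)
    )
    genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)

    links <- spec$planted_links %||% default_links(spec)
    links <- as_tibble(links)
    if (!is.list(links$cell_lines)) {
      links$cell_lines <- strsplit(as.character(links$cell_lines), ",")
    }
    if (any(links$snp > spec$n_snps) || any(links$gene > spec$n_genes)) {
      abort("planted_links reference SNP or gene indices outside the panel")
    }
    effects <- spec$planted_effects %||% default_effects(spec, links)
    effects <- as_tibble(effects)
    if (nrow(dplyr::anti_join(effects[, c("snp", "gene")],
                              links[, c("snp", "gene")],
                              by = c("snp", "gene"))) > 0) {
      abort("every planted effect must also be a planted spatial link")
    }
    # one expression model per gene-tissue: colliding effects are ill-defined
    if (anyDuplicated(effects[, c("gene", "tissue")]) > 0) {
      abort("planted effects collide: one (gene, tissue) can carry only one effect")
    }

    contact_rows <- links |>
      mutate(
        chrom_a = fragments$chrom[snp_frag_rows[.data$snp]],
        fragment_a = fragments$fragment_id[snp_frag_rows[.data$snp]],
        chrom_b = fragments$chrom[gene_frag_rows[.data$gene]],
        fragment_b = fragments$fragment_id[gene_frag_rows[.data$gene]]
      ) |>
      tidyr::unnest(cols = "cell_lines") |>
      select(cell_line = "cell_lines", "chrom_a", "fragment_a",
             "chrom_b", "fragment_b")
    if (spec$n_decoy_contacts > 0) {
      non_snp <- setdiff(seq_len(n_frags), snp_frag_rows)
      da <- sample(non_snp, spec$n_decoy_contacts, replace = TRUE)
      db <- sample(non_snp, spec$n_decoy_contacts, replace = TRUE)
      contact_rows <- bind_rows(contact_rows, tibble(
        cell_line = paste0("CL", sample.int(spec$n_cell_lines,
                                            spec$n_decoy_contacts,
                                            replace = TRUE)),
        chrom_a = fragments$chrom[da], fragment_a = fragments$fragment_id[da],
        chrom_b = fragments$chrom[db], fragment_b = fragments$fragment_id[db]
      ))
    }

    genotypes <- tibble(rsid = snps$rsid)
    dos <- t(vapply(seq_len(spec$n_snps), function(i) {
      repeat {
        d <- rbinom(spec$n_samples, 2, spec$maf[i])
        if (length(unique(d)) >= 2) return(as.double(d))
      }
    }, double(spec$n_samples)))
    sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
    colnames(dos) <- sample_ids
    genotypes <- dplyr::bind_cols(genotypes, as_tibble(dos))

    tissues <- paste0("tissue", seq_len(spec$n_tissues))
    expression_by_tissue <- lapply(seq_len(spec$n_tissues), function(ti) {
      mat <- matrix(rnorm(spec$n_genes * spec$n_samples, 0, spec$noise_sd),
                    nrow = spec$n_genes,
                    dimnames = list(genes$gene_id, sample_ids))
      eff_t <- effects[effects$tissue == ti, ]
      for (r in seq_len(nrow(eff_t))) {
        g <- eff_t$gene[r]
        mat[g, ] <- eff_t$beta[r] * dos[eff_t$snp[r], ] +
          rnorm(spec$n_samples, 0, spec$noise_sd)
      }
      dplyr::bind_cols(tibble(gene_id = genes$gene_id), as_tibble(mat))
    })
    names(expression_by_tissue) <- tissues

    rpkm <- tidyr::expand_grid(gene_id = genes$gene_id, tissue = tissues) |>
      mutate(rpkm = ifelse(
        .data$gene_id %in% genes$gene_id[spec$low_rpkm_genes], 0.5, 5.0
      ))

    # ---- write the bundle --------------------------------------------------
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      fragments = file.path(dir, "fragments.bed"),
      genes = file.path(dir, "genes.gtf"),
      snps = file.path(dir, "snps.tsv"),
      contacts = file.path(dir, "contacts.tsv"),
      genotypes = file.path(dir, "genotypes.tsv"),
      rpkm = file.path(dir, "rpkm.tsv"),
      manifest = file.path(dir, "manifest.yaml")
    )
    dna <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$chrom))
    Biostrings::writeXStringSet(dna, paths$genome, width = 70)
    write_fragment_bed(fragments, paths$fragments)
    gtf_attr <- sprintf('gene_id "%s"; gene_name "%s";',
                        genes$gene_id, genes$gene_name)
    writeLines(sprintf("%s\tspateqtl\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       gtf_attr),
               paths$genes)
    readr::write_tsv(snps, paths$snps)
    readr::write_tsv(contact_rows |>
                       rename(fragment_id_a = "fragment_a",
                              fragment_id_b = "fragment_b"),
                     paths$contacts)
    readr::write_tsv(genotypes, paths$genotypes)
    expr_paths <- vapply(tissues, function(t) {
      p <- file.path(dir, paste0("expression_", t, ".tsv"))
      readr::write_tsv(expression_by_tissue[[t]], p)
      p
    }, character(1))
    paths$expression <- as.list(expr_paths)
    readr::write_tsv(rpkm, paths$rpkm)
    manifest <- c(spec[setdiff(names(spec), c("planted_links", "planted_effects"))],
                  list(n_planted_links = nrow(links),
                       n_planted_effects = nrow(effects)))
    manifest$maf <- as.numeric(manifest$maf)
    yaml::write_yaml(manifest, paths$manifest)

    truth_links <- links |>
      mutate(
        rsid = snps$rsid[.data$snp], gene_id = genes$gene_id[.data$gene],
        interaction_class = classify_cis_trans(
          snps$chrom[.data$snp], snps$pos[.data$snp],
          genes$chrom[.data$gene], genes$tss[.data$gene]
        )
      ) |>
      select("rsid", "gene_id", "cell_lines", "interaction_class")
    truth_effects <- effects |>
      mutate(
        rsid = snps$rsid[.data$snp], gene_id = genes$gene_id[.data$gene],
        tissue = tissues[.data$tissue],
        interaction_class = classify_cis_trans(
          snps$chrom[.data$snp], snps$pos[.data$snp],
          genes$chrom[.data$gene], genes$tss[.data$gene]
        )
      ) |>
      select("rsid", "gene_id", "tissue", "beta", "interaction_class")

    invisible(list(
      paths = paths,
      truth = list(links = truth_links, effects = truth_effects),
      fragments = fragments, snps = snps, genes = genes,
      genotypes = genotypes, expression_by_tissue = expression_by_tissue,
      contacts = contact_store(contact_rows), rpkm = rpkm, spec = spec
    ))
  })
}

#' Expected network counts under uniform background sampling
#'
#' Closed-form expectations of each count metric when SNP sets of size `k`
#' are drawn uniformly with replacement from the fixture's SNP panel,
#' assuming every planted effect is detected (the planted effects are sized
#' for power near 1) and no null test is called significant.  The
#' probability that at least one of a set of `d` panel SNPs appears in `k`
#' draws from `n` is `1 - (1 - d/n)^k` (occupancy).
#'
#' @param fixture A bundle from [make_fixture()].
#' @param k Background set size.
#' @return One-row tibble of expected counts (same columns as
#'   [summarize_network()]).
#' @export
implied_null_rate <- function(fixture, k) {
  n <- fixture$spec$n_snps
  p_one <- 1 - (1 - 1 / n)^k
  p_any <- function(d) 1 - (1 - d / n)^k
  links <- fixture$truth$links
  effects <- fixture$truth$effects
  eff_pairs <- distinct(effects, .data$rsid, .data$gene_id)
  egene_snps <- effects |>
    group_by(.data$gene_id) |>
    summarise(d = dplyr::n_distinct(.data$rsid), .groups = "drop")
  tibble(
    n_snps_input = k,
    n_spatial_pairs = nrow(distinct(links, .data$rsid, .data$gene_id)) * p_one,
    n_eqtl_snps = dplyr::n_distinct(effects$rsid) * p_one,
    n_egenes = sum(p_any(egene_snps$d)),
    n_eqtl_pairs = nrow(eff_pairs) * p_one,
    n_interactions = nrow(distinct(effects, .data$rsid, .data$gene_id,
                                   .data$tissue)) * p_one,
    n_trans_interactions = nrow(distinct(
      filter(effects, .data$interaction_class == "trans"),
      .data$rsid, .data$gene_id, .data$tissue
    )) * p_one
  )
}
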