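#' Read a SNP panel
#'
#' TSV dialect: columns `rsid`, `chrom`, `pos` and optionally `ref`, `alt`,
#' `trait`, `assoc_p`.  VCF dialect: fixed fields only (`ID`, `CHROM`,
#' `POS`, `REF`, `ALT`); trait and association p are absent.
#'
#' @param path Path to a `.tsv` or `.vcf` file.
#' @return SNP tibble.
#' @export
read_snps <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    return(tibble(
      rsid = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      trait = NA_character_, assoc_p = NA_real_
    ))
  }
  readr::read_tsv(path, col_types = readr::cols(
    rsid = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), .default = readr::col_guess()
  ), progress = FALSE)
}

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or named arguments.  Recognised fields:
#' `paths` (genome or fragments, snps, contacts, annotation, genotypes,
#' expression (directory or list of files), rpkm, precomputed), `alpha`,
#' `cis_window`, `rpkm_min`, `tier_genome_wide`, `tier_suggestive`,
#' `min_samples`, `include_self`, `normalize`, `apply_tiering`,
#' `monte_carlo` (`pool`, `k`, `iterations`), `seed`, `out_dir`.
#'
#' @param config YAML path or a named list.
#' @param ... Overrides applied on top.
#' @return A `spateq_config` list with defaults filled in.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    paths = list(),
    alpha = 0.05, cis_window = 1e6, rpkm_min = 1.0,
    tier_genome_wide = 5e-8, tier_suggestive = 9e-6,
    min_samples = 10, include_self = TRUE, normalize = TRUE,
    apply_tiering = FALSE,
    monte_carlo = list(pool = NULL, k = 483, iterations = 1000),
    seed = 1, out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$alpha < 0 || cfg$alpha > 1) abort("alpha must lie in [0, 1]")
  if (cfg$cis_window <= 0) abort("cis_window must be positive")
  structure(cfg, class = "spateq_config")
}

load_pipeline_inputs <- function(cfg) {
  p <- cfg$paths
  need <- function(name) {
    if (is.null(p[[name]]) || !file.exists(p[[name]])) {
      abort(sprintf("config paths$%s is missing or does not exist", name))
    }
    p[[name]]
  }
  fragments <- if (!is.null(p$fragments)) {
    read_fragment_bed(need("fragments"))
  } else {
    digest_genome(read_genome_fasta(need("genome")))
  }
  expr_paths <- p$expression
  if (length(expr_paths) == 1 && dir.exists(expr_paths[[1]])) {
    files <- list.files(expr_paths[[1]], pattern = "^expression_.*\\.tsv$",
                        full.names = TRUE)
    expr_paths <- as.list(files)
    names(expr_paths) <- sub("^expression_(.*)\\.tsv$", "\\1", basename(files))
  }
  if (is.null(names(expr_paths))) {
    names(expr_paths) <- sub("^expression_(.*)\\.tsv$", "\\1",
                             basename(unlist(expr_paths)))
  }
  list(
    fragments = fragments,
    snps = read_snps(need("snps")),
    store = load_contacts(need("contacts"), fragments),
    genes = read_gene_annotation(need("annotation")),
    genotypes = if (!is.null(p$genotypes)) read_genotypes(need("genotypes")),
    expression_by_tissue = if (!is.null(p$expression)) {
      lapply(expr_paths, read_expression)
    },
    rpkm = if (!is.null(p$rpkm)) read_rpkm(need("rpkm")),
    precomputed = if (!is.null(p$precomputed)) {
      readr::read_tsv(need("precomputed"), show_col_types = FALSE)
    }
  )
}

#' Run the spatial-eQTL pipeline end-to-end
#'
#' Executes digestion/loading, SNP placement, partner lookup, pair
#' building, the per-tissue association scan, family-wise selection, the
#' expressed-gene filter and counting, logging per-stage record counts.
#' When `out_dir` is set, writes `pairs.tsv`, `results.tsv`, `summary.tsv`,
#' a `run.log` and a `manifest.yaml` (config, seed, package version)
#' sufficient to reproduce the run.
#'
#' @param config A [pipeline_config()], YAML path, or named list.
#' @return An object of class `spateq_run`: list with `snps`, `pairs`,
#'   `results` (q-values and significance populated), `summary`
#'   (count vector), `config`, and `paths` of any written outputs.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "spateq_config")) config else pipeline_config(config)
  inputs <- load_pipeline_inputs(cfg)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    inform(line)
    log_lines <<- c(log_lines, line)
  }

  snps <- inputs$snps
  note("stage snps: %d input SNP(s)", nrow(snps))
  if (isTRUE(cfg$apply_tiering)) {
    snps <- tier_snps(snps, cfg$tier_genome_wide, cfg$tier_suggestive)
    note("stage tiering: %d SNP(s) retained", nrow(snps))
  }
  pairs <- build_pairs(snps, inputs$fragments, inputs$store, inputs$genes,
                       include_self = cfg$include_self,
                       cis_window = cfg$cis_window)
  note("stage pairs: %d spatial SNP-gene pair(s) (%d cis, %d trans)",
       nrow(pairs), sum(pairs$interaction_class == "cis"),
       sum(pairs$interaction_class == "trans"))
  results <- run_eqtl_scan(pairs, inputs$genotypes,
                           inputs$expression_by_tissue,
                           min_samples = cfg$min_samples,
                           normalize = cfg$normalize,
                           precomputed = inputs$precomputed)
  note("stage eqtl: %d association test(s)", nrow(results))
  results <- select_significant(results, alpha = cfg$alpha)
  if (!is.null(inputs$rpkm)) {
    results <- filter_expressed(results, inputs$rpkm,
                                threshold = cfg$rpkm_min)
    note("stage rpkm filter: %d result(s) on expressed genes", nrow(results))
  }
  note("stage significance: %d significant result(s)",
       sum(results$significant))
  summary <- summarize_network(snps, pairs, results)

  paths <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$pairs <- file.path(cfg$out_dir, "pairs.tsv")
    paths$results <- file.path(cfg$out_dir, "results.tsv")
    paths$summary <- file.path(cfg$out_dir, "summary.tsv")
    paths$log <- file.path(cfg$out_dir, "run.log")
    paths$manifest <- file.path(cfg$out_dir, "manifest.yaml")
    write_pairs_tsv(pairs, paths$pairs)
    readr::write_tsv(results, paths$results)
    readr::write_tsv(as_tibble(summary), paths$summary)
    writeLines(log_lines, paths$log)
    yaml::write_yaml(
      list(config = unclass(cfg),
           package_version = as.character(utils::packageVersion("spateqtl"))),
      paths$manifest
    )
  }
  structure(
    list(snps = snps, pairs = pairs, results = results, summary = summary,
         config = cfg, paths = paths, log = log_lines),
    class = "spateq_run"
  )
}

#' Monte Carlo enrichment against a completed run
#'
#' Draws background SNP sets from the configured pool, runs the pipeline on
#' each, and compares the observed counts of `run` with the null
#' distributions.  When the run's `out_dir` is set, writes a
#' `null_summary.tsv` in the usual shape (metric, min, max, mean, sd,
#' observed, t, p, percentile) and a per-iteration `null_values.tsv` audit
#' table.
#'
#' @param run A completed `spateq_run`.
#' @param pool Background SNP tibble; defaults to the config's
#'   `monte_carlo$pool` path.
#' @return List with `null` (a `spateq_null`) and `comparison` (tibble from
#'   [compare_observed()]).
#' @export
run_enrichment <- function(run, pool = NULL) {
  if (!inherits(run, "spateq_run")) abort("run must be a completed spateq_run")
  cfg <- run$config
  if (is.null(pool)) {
    if (is.null(cfg$monte_carlo$pool)) abort("no background pool configured")
    pool <- read_snps(cfg$monte_carlo$pool)
  }
  inputs <- load_pipeline_inputs(cfg)
  null <- run_null(
    pool, inputs$fragments, inputs$store, inputs$genes, inputs$genotypes,
    inputs$expression_by_tissue,
    k = cfg$monte_carlo$k, iterations = cfg$monte_carlo$iterations,
    seed = cfg$seed, alpha = cfg$alpha, rpkm_table = inputs$rpkm,
    min_samples = cfg$min_samples, normalize = cfg$normalize,
    include_self = cfg$include_self, cis_window = cfg$cis_window
  )
  comparison <- compare_observed(run$summary, null)
  if (!is.null(cfg$out_dir)) {
    out <- comparison |>
      rename(min = "null_min", max = "null_max", mean = "null_mean",
             sd = "null_sd")
    readr::write_tsv(out, file.path(cfg$out_dir, "null_summary.tsv"))
    readr::write_tsv(null$values, file.path(cfg$out_dir, "null_values.tsv"))
  }
  list(null = null, comparison = comparison)
}

#' @export
print.spateq_run <- function(x, ...) {
  cat("spatial-eQTL run\n")
  print(as_tibble(x$summary))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spateq_run <- function(x, ...) as_tibble(x$results)

#' @exportS3Method generics::glance
glance.spateq_run <- function(x, ...) as_tibble(x$summary)

#' Volcano plot of eQTL association results
#'
#' Effect size against -log10 p, coloured by cis/trans class, significant
#' results emphasised.
#'
#' @param results Result tibble from [run_eqtl_scan()] /
#'   [select_significant()].
#' @return A ggplot object.
#' @export
plot_eqtl_volcano <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(
    x = .data$beta, y = -log10(.data$p_value),
    colour = .data$interaction_class,
    alpha = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                na.value = 0.3) +
    ggplot2::labs(x = "effect per ALT allele (beta)",
                  y = expression(-log[10](p)),
                  colour = "class", alpha = "significant")
}
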