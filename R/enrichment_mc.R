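#' Draw a background SNP set
#'
#' Uniform draws with replacement from a background pool, deterministic
#' given the seed.
#'
#' @param pool SNP tibble (the background panel).
#' @param k Number of draws.
#' @param seed Integer seed.
#' @return A tibble of `k` rows sampled from `pool` (a multiset; the same
#'   SNP can appear repeatedly).
#' @export
sample_background <- function(pool, k, seed) {
  if (nrow(pool) == 0) abort("background pool is empty")
  if (k < 1) abort("k must be >= 1")
  idx <- with_local_seed(seed, sample.int(nrow(pool), k, replace = TRUE))
  pool[idx, ]
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Monte Carlo null distribution of network counts
#'
#' Repeatedly draws background SNP sets and runs the spatial-eQTL pipeline
#' (pairs, association scan, family-wise selection, optional expression
#' filter, counting) on each set, assembling a per-metric null
#' distribution.  The association test for a given SNP-gene-tissue triple
#' does not depend on which other SNPs were sampled, so the scan over the
#' whole pool is computed once and each iteration re-runs only sampling,
#' the family-wise correction, the expression filter, and counting —
#' numerically identical to re-running every stage, at a fraction of the
#' cost.
#'
#' Iteration i uses the substream seed `seed + i`, so results do not depend
#' on evaluation order.
#'
#' @param pool Background SNP tibble.
#' @param fragment_index,store,genes,genotypes,expression_by_tissue Loaded
#'   pipeline inputs (see [build_pairs()] and [run_eqtl_scan()]).
#' @param k Background set size per iteration (default 483).
#' @param iterations Number of Monte Carlo sets (default 1000).
#' @param seed Base seed.
#' @param alpha FDR level for [select_significant()].
#' @param rpkm_table Optional RPKM table for [filter_expressed()].
#' @param min_samples,normalize,include_self,cis_window Passed through to
#'   the pipeline stages.
#' @return An object of class `spateq_null`: list with `values` (tibble,
#'   one row per iteration, one column per count metric), `summary`
#'   (per-metric min/max/mean/sd), `k`, `iterations`, `seed`.
#' @export
run_null <- function(pool, fragment_index, store, genes, genotypes,
                     expression_by_tissue, k = 483, iterations = 1000,
                     seed = 1, alpha = 0.05, rpkm_table = NULL,
                     min_samples = 10, normalize = TRUE,
                     include_self = TRUE, cis_window = 1e6) {
  pool_pairs <- suppressMessages(build_pairs(
    pool, fragment_index, store, genes,
    include_self = include_self, cis_window = cis_window
  ))
  pool_results <- suppressMessages(run_eqtl_scan(
    pool_pairs, genotypes, expression_by_tissue,
    min_samples = min_samples, normalize = normalize
  ))

  one_iteration <- function(i) {
    snp_set <- sample_background(pool, k, seed + i)
    rs <- unique(snp_set$rsid)
    pairs_i <- filter(pool_pairs, .data$rsid %in% rs)
    res_i <- filter(pool_results, .data$rsid %in% rs)
    res_i <- select_significant(res_i, alpha = alpha)
    if (!is.null(rpkm_table)) {
      res_i <- suppressMessages(filter_expressed(res_i, rpkm_table))
    }
    counts <- summarize_network(snp_set, pairs_i, res_i)
    mutate(as_tibble(counts), iteration = i, .before = 1)
  }
  values <- purrr::map(seq_len(iterations), function(i) {
    tryCatch(one_iteration(i), error = function(e) {
      abort(sprintf("Monte Carlo iteration %d (substream seed %d) failed: %s",
                    i, seed + i, conditionMessage(e)))
    })
  }) |> bind_rows()

  summary <- values |>
    tidyr::pivot_longer(dplyr::all_of(summary_metrics),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$metric) |>
    summarise(
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    ) |>
    dplyr::slice(match(summary_metrics, .data$metric))

  structure(
    list(values = values, summary = summary, k = k,
         iterations = iterations, seed = seed),
    class = "spateq_null"
  )
}

#' Compare observed counts with a Monte Carlo null
#'
#' For each count metric, runs a one-sample two-sided t-test of the null
#' values against the observed count and reports the empirical
#' mid-percentile of the observed value within the null values (ties count
#' half, so percentiles are approximately uniform under the null; an
#' observed value above every null value is still 100).  When the null
#' values are constant the t-test is undefined and only the percentile is
#' reported.
#'
#' @param observed A `spateq_summary` row (or named list/vector of counts).
#' @param null A `spateq_null` object from [run_null()].
#' @return Tibble: `metric`, `observed`, `null_min`, `null_max`,
#'   `null_mean`, `null_sd`, `t`, `p_value`, `percentile`.
#' @export
compare_observed <- function(observed, null) {
  stopifnot(inherits(null, "spateq_null"))
  obs <- as.list(observed)
  purrr::map(null$summary$metric, function(m) {
    vals <- null$values[[m]]
    ob <- as.numeric(obs[[m]])
    n <- length(vals)
    s <- sd(vals)
    if (n >= 2 && s > 0) {
      tt <- stats::t.test(vals, mu = ob)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      t_stat <- NA_real_
      p <- NA_real_
    }
    tibble(
      metric = m, observed = ob,
      null_min = min(vals), null_max = max(vals),
      null_mean = mean(vals), null_sd = s,
      t = t_stat, p_value = p,
      percentile = 100 * (sum(vals < ob) + 0.5 * sum(vals == ob)) / n
    )
  }) |> bind_rows()
}

#' @exportS3Method generics::tidy
tidy.spateq_null <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.spateq_null <- function(x, ...) {
  tibble(iterations = x$iterations, k = x$k, seed = x$seed,
         mean_eqtl_snps = mean(x$values$n_eqtl_snps),
         mean_interactions = mean(x$values$n_interactions))
}

#' @export
print.spateq_null <- function(x, ...) {
  cat(sprintf("Monte Carlo null: %d iterations of %d SNPs (seed %d)\n",
              x$iterations, x$k, x$seed))
  print(x$summary)
  invisible(x)
}

#' Plot a Monte Carlo null distribution
#'
#' Histograms of the per-iteration counts, one facet per metric, with an
#' optional vertical line at the observed value.
#'
#' @param object A `spateq_null` object.
#' @param observed Optional `spateq_summary` row to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spateq_null <- function(object, observed = NULL, ...) {
  long <- tidyr::pivot_longer(object$values,
                              dplyr::all_of(summary_metrics),
                              names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "count per Monte Carlo iteration", y = "iterations")
  if (!is.null(observed)) {
    obs_long <- tidyr::pivot_longer(as_tibble(observed),
                                    dplyr::all_of(summary_metrics),
                                    names_to = "metric", values_to = "value")
    p <- p + ggplot2::geom_vline(
      data = obs_long, ggplot2::aes(xintercept = .data$value),
      colour = "firebrick", linetype = "dashed"
    )
  }
  p
}
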