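#' Rank-based inverse-normal transform
#'
#' Maps a vector to standard-normal quantiles at Blom plotting positions,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties sharing the mean rank.  This
#' is the usual expression-normalisation step before single-variant eQTL
#' regression.  Missing values stay missing; a (near-)constant vector cannot
#' be ranked meaningfully and is returned as all-`NA` with a
#' `"constant"` attribute so callers can drop the gene from testing.
#'
#' @param x Numeric vector (>= 3 non-missing values required).
#' @return Numeric vector of the same length, mean approximately 0.
#' @export
normalize_expression <- function(x) {
  obs <- !is.na(x)
  if (sum(obs) < 3) abort("normalize_expression needs >= 3 non-missing values")
  out <- rep(NA_real_, length(x))
  if (sd(x[obs]) == 0) {
    attr(out, "constant") <- TRUE
    return(out)
  }
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- qnorm((r - 3 / 8) / (sum(obs) + 1 / 4))
  out
}

#' Single-variant association test
#'
#' Ordinary least squares of expression on allele dosage with an intercept;
#' the slope is the effect of each additional ALT allele.  The two-sided
#' p-value comes from the t distribution with n - 2 degrees of freedom.
#' Samples missing either value are dropped pairwise.  If fewer than
#' `min_samples` complete pairs remain, or the dosages are constant, no test
#' is run and the reason is reported instead.
#'
#' @param dosages Numeric vector of ALT-allele counts in \[0, 2\].
#' @param expression Numeric vector, same length.
#' @param min_samples Minimum complete pairs (default 10).
#' @return One-row tibble: `beta`, `se`, `p_value`, `n_samples`, `tested`,
#'   `reason` (`NA` when tested).
#' @export
test_association <- function(dosages, expression, min_samples = 10) {
  stopifnot(length(dosages) == length(expression))
  ok <- !is.na(dosages) & !is.na(expression)
  x <- dosages[ok]
  y <- expression[ok]
  no_test <- function(reason) {
    tibble(beta = NA_real_, se = NA_real_, p_value = NA_real_,
           n_samples = length(x), tested = FALSE, reason = reason)
  }
  if (length(x) < min_samples) return(no_test("too_few_samples"))
  if (sd(x) == 0) return(no_test("constant_dosage"))
  fit <- ols_slope(x, y)
  tibble(beta = fit$beta, se = fit$se, p_value = fit$p_value,
         n_samples = length(x), tested = TRUE, reason = NA_character_)
}

# closed-form simple linear regression (slope, se, two-sided t-test p)
ols_slope <- function(x, y) {
  n <- length(x)
  xm <- x - mean(x)
  ym <- y - mean(y)
  sxx <- sum(xm^2)
  beta <- sum(xm * ym) / sxx
  rss <- sum((ym - beta * xm)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  if (se == 0) {
    p <- if (beta == 0) 1 else 0 # exact fit
  } else {
    p <- 2 * pt(-abs(beta / se), df = n - 2)
  }
  list(beta = beta, se = se, p_value = p)
}

#' Read a genotype dosage matrix
#'
#' TSV dialect: one row per SNP, first column `rsid`, remaining columns one
#' per sample, values 0/1/2 (ALT-allele count) or missing.  VCF dialect:
#' dosage is the number of ALT alleles in the `GT` field; half-calls and
#' missing genotypes become `NA`; multi-allelic records are dropped.
#'
#' @param path Path to a `.tsv` or `.vcf` file.
#' @return Tibble: `rsid` plus one numeric column per sample.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    biallelic <- !grepl(",", fix$ALT)
    alt_count <- function(g) {
      ifelse(is.na(g) | grepl("\\.", g), NA_real_,
             stringr::str_count(g, "1"))
    }
    dos <- apply(gt[biallelic, , drop = FALSE], 2, alt_count)
    out <- as_tibble(dos)
    out$rsid <- fix$ID[biallelic]
    return(select(out, "rsid", dplyr::everything()))
  }
  readr::read_tsv(path, col_types = readr::cols(
    rsid = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' Read a per-tissue expression matrix
#'
#' TSV: one row per gene, first column `gene_id`, one column per sample.
#'
#' @param path Path to the TSV.
#' @return Tibble: `gene_id` plus numeric sample columns.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' Read the RPKM abundance table
#'
#' Long TSV with columns `gene_id`, `tissue`, `rpkm`.
#'
#' @param path Path to the TSV.
#' @return Tibble with those three columns.
#' @export
read_rpkm <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), tissue = readr::col_character(),
    rpkm = readr::col_double()
  ), progress = FALSE)
}

#' Test every spatial SNP-gene pair in every tissue
#'
#' For each pair and each tissue in which the gene is measured, regresses
#' (rank-normalised) expression on genotype dosage over the intersection of
#' samples.  Pairs whose rsid is absent from the genotypes are skipped with
#' a message; genes with constant expression are dropped.  q-values are not
#' assigned here — run [select_significant()] afterwards.
#'
#' Alternatively, pass `precomputed`: a table of already-computed
#' associations (`rsid`, `gene_id`, `tissue`, `beta`, `p_value`, optionally
#' `q_value`), e.g. an export from a dedicated eQTL resource.  Rows matching
#' the pairs are passed through unchanged, keeping the spatial filter but
#' replacing the regression emulation.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param genotypes Genotype tibble from [read_genotypes()].
#' @param expression_by_tissue Named list of expression tibbles, one per
#'   tissue.
#' @param min_samples Minimum complete pairs per test (default 10).
#' @param normalize Apply [normalize_expression()] per gene within tissue
#'   (default `TRUE`).
#' @param precomputed Optional precomputed association table (see above).
#' @return Tibble: `rsid`, `gene_id`, `gene_name`, `tissue`,
#'   `interaction_class`, `beta`, `se`, `p_value`, `n_samples`, plus
#'   `q_value`/`significant` placeholders (`NA`).
#' @export
run_eqtl_scan <- function(pairs, genotypes = NULL, expression_by_tissue = NULL,
                          min_samples = 10, normalize = TRUE,
                          precomputed = NULL) {
  empty <- tibble(
    rsid = character(), gene_id = character(), gene_name = character(),
    tissue = character(), interaction_class = character(),
    beta = double(), se = double(), p_value = double(),
    n_samples = integer(), q_value = double(), significant = logical()
  )
  if (nrow(pairs) == 0) return(empty)
  key <- pairs[, c("rsid", "gene_id", "gene_name", "interaction_class")]

  if (!is.null(precomputed)) {
    out <- precomputed |>
      inner_join(key, by = intersect(c("rsid", "gene_id"), names(precomputed))) |>
      mutate(
        se = if ("se" %in% names(precomputed)) .data$se else NA_real_,
        n_samples = if ("n_samples" %in% names(precomputed)) .data$n_samples else NA_integer_,
        q_value = if ("q_value" %in% names(precomputed)) .data$q_value else NA_real_,
        significant = NA
      )
    return(select(out, dplyr::all_of(names(empty))))
  }

  stopifnot(!is.null(genotypes), !is.null(expression_by_tissue))
  missing_rs <- setdiff(unique(pairs$rsid), genotypes$rsid)
  if (length(missing_rs) > 0) {
    inform(sprintf("%d pair rsid(s) absent from genotypes; skipped", length(missing_rs)))
  }
  geno_samples <- setdiff(names(genotypes), "rsid")
  dos_mat <- as.matrix(genotypes[, geno_samples])
  rownames(dos_mat) <- genotypes$rsid

  results <- purrr::imap(expression_by_tissue, function(expr, tissue) {
    samples <- intersect(geno_samples, setdiff(names(expr), "gene_id"))
    if (length(samples) < min_samples) {
      abort(sprintf("tissue '%s': only %d shared samples (need >= %d)",
                    tissue, length(samples), min_samples))
    }
    expr_mat <- as.matrix(expr[, samples])
    rownames(expr_mat) <- expr$gene_id
    if (normalize) {
      expr_mat <- t(apply(expr_mat, 1, normalize_expression))
      colnames(expr_mat) <- samples
    }
    todo <- pairs |>
      filter(.data$rsid %in% rownames(dos_mat),
             .data$gene_id %in% rownames(expr_mat))
    if (nrow(todo) == 0) return(NULL)
    tests <- purrr::map2(todo$rsid, todo$gene_id, function(rs, g) {
      test_association(dos_mat[rs, samples], expr_mat[g, ],
                       min_samples = min_samples)
    }) |> bind_rows()
    bind_rows(tibble(
      rsid = todo$rsid, gene_id = todo$gene_id, gene_name = todo$gene_name,
      tissue = tissue, interaction_class = todo$interaction_class,
      beta = tests$beta, se = tests$se, p_value = tests$p_value,
      n_samples = tests$n_samples, tested = tests$tested
    ))
  })
  out <- bind_rows(results)
  if (nrow(out) == 0) return(empty)
  n_dropped <- sum(!out$tested)
  if (n_dropped > 0) {
    inform(sprintf("%d test(s) skipped (constant dosage/expression or too few samples)",
                   n_dropped))
  }
  out |>
    filter(.data$tested) |>
    mutate(q_value = NA_real_, significant = NA) |>
    select(dplyr::all_of(names(empty)))
}
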