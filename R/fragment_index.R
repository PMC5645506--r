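#' Read a genome from FASTA
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file into a tibble of
#' chromosome sequences.  Sequences are upper-cased; only A/C/G/T/N are
#' accepted downstream by [digest_genome()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `chrom` and `sequence`.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    chrom = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
}

validate_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "sequence") %in% names(genome)))
  if (any(!nzchar(genome$sequence))) {
    abort(paste0("empty sequence for chromosome(s): ",
      paste(genome$chrom[!nzchar(genome$sequence)], collapse = ", ")))
  }
  bad <- stringr::str_extract(genome$sequence, "[^ACGTN]")
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf(
      "invalid character '%s' in sequence for chromosome '%s' (alphabet is A/C/G/T/N)",
      bad[i], genome$chrom[i]
    ))
  }
  invisible(genome)
}

#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at each exact occurrence of the recognition site and
#' returns the resulting restriction fragments.  The default site `"GATC"` is
#' the MboI recognition sequence; MboI cuts 5' of the site, so the cut
#' coordinate is the first base of each occurrence and every non-leading
#' fragment begins with the site.  Matching is exact: occurrences overlapping
#' runs of `N` are not cut.  A site at position 0 would create an empty
#' leading fragment, which is suppressed.  Fragments tile each chromosome
#' exactly in 0-based half-open coordinates.
#'
#' @param genome A tibble with columns `chrom` and `sequence`, e.g. from
#'   [read_genome_fasta()].
#' @param recognition_site Literal DNA recognition site (default `"GATC"`).
#'   Self-overlapping sites are handled (the scanner advances one base after
#'   each match).
#' @return A tibble with columns `chrom`, `start` (0-based inclusive), `end`
#'   (0-based exclusive) and `fragment_id` (consecutive integers per
#'   chromosome, from 0).
#' @examples
#' digest_genome(tibble::tibble(chrom = "c1", sequence = "AAGATCTTGATCAA"))
#' @export
digest_genome <- function(genome, recognition_site = "GATC") {
  if (!is.character(recognition_site) || length(recognition_site) != 1 ||
      !nzchar(recognition_site)) {
    abort("recognition_site must be a non-empty DNA string")
  }
  validate_genome(genome)
  site <- Biostrings::DNAString(toupper(recognition_site))
  purrr::map2(genome$chrom, genome$sequence, function(chrom, seq) {
    subject <- Biostrings::DNAString(seq)
    # fixed = TRUE: literal matching only, so N never matches the site
    hits <- Biostrings::matchPattern(site, subject, fixed = TRUE)
    cuts <- Biostrings::start(hits) - 1L # cut 5' of the site, 0-based
    bounds <- sort(unique(c(0L, cuts, nchar(seq))))
    tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      fragment_id = seq_along(bounds[-1]) - 1L
    )
  }) |>
    bind_rows()
}

#' Locate the restriction fragment containing a position
#'
#' Maps 1-based genomic positions onto the unique fragment whose 0-based
#' half-open interval contains `pos - 1`.  Vectorised over `chrom`/`pos`.
#'
#' @param index Fragment tibble from [digest_genome()] or
#'   [read_fragment_bed()].
#' @param chrom Chromosome identifier(s).
#' @param pos 1-based position(s).
#' @return The matching rows of `index`, one per query, in query order.
#' @export
locate_fragment <- function(index, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  if (any(pos < 1)) abort("pos must be >= 1")
  by_chrom <- split(index, index$chrom)
  rows <- purrr::map2(chrom, pos, function(ch, p) {
    frags <- by_chrom[[ch]]
    if (is.null(frags)) abort(sprintf("unknown chromosome '%s'", ch))
    len <- max(frags$end)
    if (p > len) {
      abort(sprintf("position %d is beyond the end of chromosome '%s' (%d bp)",
                    p, ch, len))
    }
    frags[findInterval(p - 1, frags$start), ]
  })
  bind_rows(rows)
}

#' Write / read a fragment index as BED-like TSV
#'
#' The on-disk format is a 4-column headerless TSV: chrom, start (0-based),
#' end (exclusive), fragment_id.  A precomputed fragment map (e.g. a
#' published digestion) read back through [read_fragment_bed()] can be used
#' everywhere a fresh digestion can.
#'
#' @param index Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly (writer); fragment tibble (reader).
#' @export
write_fragment_bed <- function(index, path) {
  readr::write_tsv(index[, c("chrom", "start", "end", "fragment_id")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_bed
#' @export
read_fragment_bed <- function(path) {
  frags <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "fragment_id"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), fragment_id = readr::col_integer()
    ),
    progress = FALSE
  )
  bad <- frags$start >= frags$end
  if (any(bad)) abort(sprintf("fragment with start >= end at line %d", which(bad)[1]))
  frags
}
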