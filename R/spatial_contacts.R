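#' Load Hi-C fragment-pair contacts
#'
#' Reads a contact table recorded per cell line at restriction-fragment
#' resolution.  Contacts are presence/absence: the loader collapses mirrored
#' duplicates (a record and its (b, a) mirror denote the same contact) and
#' exact repeats, and drops records that reference fragments absent from the
#' fragment index (counted and reported).  Self-ligation records
#' (`frag_a == frag_b`) are retained, so genes on the SNP's own fragment can
#' enter the candidate set.
#'
#' Two header dialects are accepted:
#' \describe{
#'   \item{fragment ids}{`cell_line, chrom_a, fragment_id_a, chrom_b, fragment_id_b`}
#'   \item{coordinates}{`cell_line, chrom_a, start_a, chrom_b, start_b`
#'     (1-based positions, resolved through [locate_fragment()])}
#' }
#'
#' @param path Path to the contact TSV (header required).
#' @param fragment_index Fragment tibble from [digest_genome()].
#' @return A tibble of class `spateq_contacts` with columns `cell_line`,
#'   `chrom_a`, `fragment_a`, `chrom_b`, `fragment_b`, canonically ordered
#'   and deduplicated.
#' @export
load_contacts <- function(path, fragment_index) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  id_cols <- c("cell_line", "chrom_a", "fragment_id_a", "chrom_b", "fragment_id_b")
  coord_cols <- c("cell_line", "chrom_a", "start_a", "chrom_b", "start_b")
  if (nrow(raw) == 0) {
    return(new_contact_store(tibble(
      cell_line = character(), chrom_a = character(), fragment_a = integer(),
      chrom_b = character(), fragment_b = integer()
    )))
  }
  if (all(id_cols %in% names(raw))) {
    parse_int <- function(x, col) {
      v <- suppressWarnings(as.integer(x))
      if (any(is.na(v) & !is.na(x)) || any(is.na(x))) {
        line <- which(is.na(v))[1] + 1L # +1 for the header line
        abort(sprintf("malformed value in column '%s' at line %d of %s", col, line, path))
      }
      v
    }
    contacts <- tibble(
      cell_line = raw$cell_line,
      chrom_a = raw$chrom_a,
      fragment_a = parse_int(raw$fragment_id_a, "fragment_id_a"),
      chrom_b = raw$chrom_b,
      fragment_b = parse_int(raw$fragment_id_b, "fragment_id_b")
    )
  } else if (all(coord_cols %in% names(raw))) {
    pos_a <- suppressWarnings(as.integer(raw$start_a))
    pos_b <- suppressWarnings(as.integer(raw$start_b))
    if (any(is.na(pos_a)) || any(is.na(pos_b))) {
      abort(sprintf("malformed coordinate at line %d of %s",
                    which(is.na(pos_a) | is.na(pos_b))[1] + 1L, path))
    }
    fa <- locate_fragment(fragment_index, raw$chrom_a, pos_a)
    fb <- locate_fragment(fragment_index, raw$chrom_b, pos_b)
    contacts <- tibble(
      cell_line = raw$cell_line,
      chrom_a = fa$chrom, fragment_a = fa$fragment_id,
      chrom_b = fb$chrom, fragment_b = fb$fragment_id
    )
  } else {
    abort(paste0("unrecognised contact header in ", path,
                 "; expected fragment-id or coordinate dialect"))
  }

  known <- fragment_index |>
    select(chrom = "chrom", fragment = "fragment_id")
  ok_a <- has_fragment(contacts$chrom_a, contacts$fragment_a, known)
  ok_b <- has_fragment(contacts$chrom_b, contacts$fragment_b, known)
  n_bad <- sum(!(ok_a & ok_b))
  if (n_bad > 0) {
    warn(sprintf("rejected %d contact record(s) referencing fragments absent from the index", n_bad))
    contacts <- contacts[ok_a & ok_b, ]
  }
  new_contact_store(canonicalize_contacts(contacts))
}

has_fragment <- function(chrom, fragment, known) {
  paste(chrom, fragment) %in% paste(known$chrom, known$fragment)
}

# order each pair so (chrom_a, fragment_a) <= (chrom_b, fragment_b), then dedup
canonicalize_contacts <- function(contacts) {
  swap <- contacts$chrom_a > contacts$chrom_b |
    (contacts$chrom_a == contacts$chrom_b & contacts$fragment_a > contacts$fragment_b)
  out <- contacts
  out[swap, c("chrom_a", "fragment_a", "chrom_b", "fragment_b")] <-
    contacts[swap, c("chrom_b", "fragment_b", "chrom_a", "fragment_a")]
  distinct(out)
}

new_contact_store <- function(contacts) {
  structure(as_tibble(contacts), class = c("spateq_contacts", class(as_tibble(contacts))))
}

#' Build a contact store from an in-memory tibble
#'
#' Convenience constructor used by the fixture generator and tests; applies
#' the same mirror-collapse semantics as [load_contacts()].
#'
#' @param contacts Tibble with columns `cell_line`, `chrom_a`, `fragment_a`,
#'   `chrom_b`, `fragment_b`.
#' @return A `spateq_contacts` tibble.
#' @export
contact_store <- function(contacts) {
  new_contact_store(canonicalize_contacts(as_tibble(contacts)))
}

# both orientations of every contact, for symmetric joins
symmetric_contacts <- function(store) {
  fwd <- store
  rev <- store |>
    rename(chrom_a = "chrom_b", fragment_a = "fragment_b",
           chrom_b = "chrom_a", fragment_b = "fragment_a")
  distinct(bind_rows(as_tibble(fwd), as_tibble(rev)))
}

#' Partner fragments of a query fragment
#'
#' Returns the union, over all cell lines, of fragments recorded in contact
#' with the query, regardless of record orientation.  Presence/absence only:
#' repeated records do not change the result.  Each partner carries the set
#' of cell lines supporting the contact.
#'
#' @param store A `spateq_contacts` tibble from [load_contacts()].
#' @param chrom,fragment_id Query fragment.
#' @return Tibble with columns `chrom`, `fragment_id`, `cell_lines`
#'   (list-column of character vectors) and `n_cell_lines`.  Empty if the
#'   fragment has no recorded contacts.
#' @export
partners_of <- function(store, chrom, fragment_id) {
  sym <- symmetric_contacts(store)
  hits <- sym[sym$chrom_a == chrom & sym$fragment_a == fragment_id, ]
  hits |>
    group_by(chrom = .data$chrom_b, fragment_id = .data$fragment_b) |>
    summarise(cell_lines = list(sort(unique(.data$cell_line))), .groups = "drop") |>
    mutate(n_cell_lines = lengths(.data$cell_lines))
}
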