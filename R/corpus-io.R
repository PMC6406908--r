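#' Read a journal table
#'
#' Reads the table of tracked journals and their impact factors. The impact
#' factor is the per-journal citation weight used when aggregating article
#' counts into the annual impact index; it is treated as a static per-run
#' snapshot (one Journal Citation Reports year applied to all panel years).
#'
#' @param path Path to a CSV file with exactly the columns `name` and
#'   `impact_factor` (header required, UTF-8).
#'
#' @return A tibble with columns `journal` (character) and `impact_factor`
#'   (double), in file order.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("name,impact_factor", "Nature,40.137", "Science,37.205"), tf)
#' read_journal_table(tf)
#' @export
read_journal_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!setequal(names(df), c("name", "impact_factor"))) {
    stop_format(sprintf(
      "Journal table must have exactly the columns 'name' and 'impact_factor'; found: %s",
      paste(names(df), collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    warn("Journal table is empty.")
    return(tibble::tibble(journal = character(), impact_factor = double()))
  }
  impact <- suppressWarnings(as.numeric(df$impact_factor))
  bad <- which(!is.finite(impact) | impact <= 0)
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "Impact factors must be positive numbers; offending row(s): %s",
      paste(sprintf("%d ('%s')", bad, df$name[bad]), collapse = ", ")))
  }
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup) > 0L) {
    stop_validation(sprintf("Duplicate journal name(s): %s",
                            paste(dup, collapse = ", ")))
  }
  tibble::tibble(journal = df$name, impact_factor = impact)
}

#' Write a journal table
#'
#' @param journals A tibble with columns `journal` and `impact_factor`.
#' @param path Output CSV path; columns are written as `name,impact_factor`.
#' @return `path`, invisibly.
#' @export
write_journal_table <- function(journals, path) {
  check_journals(journals)
  readr::write_csv(
    tibble::tibble(name = journals$journal, impact_factor = journals$impact_factor),
    path)
  invisible(path)
}

check_journals <- function(journals) {
  if (!is.data.frame(journals) ||
      !all(c("journal", "impact_factor") %in% names(journals))) {
    stop_format("`journals` must be a data frame with columns 'journal' and 'impact_factor'.")
  }
  if (any(!is.finite(journals$impact_factor) | journals$impact_factor <= 0)) {
    stop_validation("All impact factors must be positive and finite.")
  }
  if (anyDuplicated(journals$journal)) {
    stop_validation("Journal names must be unique.")
  }
  invisible(journals)
}

#' Read a publication-count panel
#'
#' Reads per-(field, journal, year) article counts in long format and expands
#' them to a complete panel: any (field, journal, year) triple absent from the
#' file is a zero count (a search engine returning zero hits writes no row).
#' The year range is inferred as `[min, max]` of the years present and checked
#' to be contiguous.
#'
#' @param path Path to either a CSV file with columns
#'   `field,journal,year,count`, or a JSON file (extension `.json`) with the
#'   nested layout field -> journal -> year -> count.
#' @param journals Journal table (tibble with `journal`, `impact_factor`) or a
#'   character vector of journal names. Rows naming unknown journals are
#'   rejected.
#' @param fields Character vector of field keywords (or a data frame with a
#'   `field` column). Rows naming unknown fields are rejected.
#'
#' @return A complete count panel: a tibble with columns `field`, `journal`,
#'   `year` (integer), `count` (integer \eqn{\ge 0}) covering every
#'   (field, journal, year) combination.
#' @export
read_count_panel <- function(path, journals, fields) {
  journal_names <- if (is.data.frame(journals)) journals$journal else as.character(journals)
  field_names <- if (is.data.frame(fields)) fields$field else as.character(fields)

  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path)
    rows <- purrr::imap_dfr(raw, function(by_journal, fld) {
      purrr::imap_dfr(by_journal, function(by_year, jnl) {
        tibble::tibble(field = fld, journal = jnl,
                       year = names(by_year),
                       count = as.numeric(unlist(by_year, use.names = FALSE)))
      })
    })
    rows$year <- suppressWarnings(as.numeric(rows$year))
  } else {
    rows <- readr::read_csv(path, col_types = readr::cols(
      field = readr::col_character(), journal = readr::col_character(),
      year = readr::col_double(), count = readr::col_double()),
      progress = FALSE)
    if (!setequal(names(rows), c("field", "journal", "year", "count"))) {
      stop_format("Count panel CSV must have columns field,journal,year,count.")
    }
  }
  as_count_panel(rows, journals = journal_names, fields = field_names)
}

#' Build a complete count panel from long-format rows
#'
#' @param rows Data frame with columns `field`, `journal`, `year`, `count`;
#'   absent triples are taken as zero.
#' @param journals,fields As in [read_count_panel()].
#' @param years Optional contiguous integer year range; defaults to
#'   `min(rows$year):max(rows$year)` and is checked for gaps.
#' @return A complete count-panel tibble (see [read_count_panel()]).
#' @export
as_count_panel <- function(rows, journals, fields, years = NULL) {
  journal_names <- if (is.data.frame(journals)) journals$journal else as.character(journals)
  field_names <- if (is.data.frame(fields)) fields$field else as.character(fields)

  bad_count <- which(!is_whole(rows$count) | rows$count < 0)
  if (length(bad_count) > 0L) {
    stop_validation(sprintf(
      "Counts must be non-negative integers; offending row(s): %s",
      paste(bad_count, collapse = ", ")))
  }
  unknown_j <- setdiff(unique(rows$journal), journal_names)
  if (length(unknown_j) > 0L) {
    stop_validation(sprintf("Unknown journal(s) in panel: %s",
                            paste(unknown_j, collapse = ", ")))
  }
  unknown_f <- setdiff(unique(rows$field), field_names)
  if (length(unknown_f) > 0L) {
    stop_validation(sprintf("Unknown field(s) in panel: %s",
                            paste(unknown_f, collapse = ", ")))
  }
  if (is.null(years)) {
    if (nrow(rows) == 0L) stop_validation("Cannot infer a year range from an empty panel; pass `years`.")
    years <- seq(min(rows$year), max(rows$year))
  }
  if (any(!is_whole(years)) || !identical(as.integer(years), seq(min(years), max(years)))) {
    stop_validation("`years` must be a contiguous ascending integer range.")
  }
  missing_years <- setdiff(unique(rows$year), years)
  if (length(missing_years) > 0L) {
    stop_validation(sprintf("Row year(s) outside the panel range: %s",
                            paste(missing_years, collapse = ", ")))
  }

  grid <- tidyr::expand_grid(field = field_names, journal = journal_names,
                             year = as.integer(years))
  observed <- rows |>
    dplyr::mutate(year = as.integer(.data$year), count = as.integer(.data$count)) |>
    dplyr::group_by(.data$field, .data$journal, .data$year) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  grid |>
    dplyr::left_join(observed, by = c("field", "journal", "year")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Write a count panel
#'
#' Writes the nonzero rows of a panel in long CSV format
#' (`field,journal,year,count`). Zero rows are omitted: the absent-means-zero
#' contract of [read_count_panel()] restores them on read.
#'
#' @param panel A count-panel tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_panel <- function(panel, path) {
  panel |>
    dplyr::filter(.data$count > 0L) |>
    dplyr::arrange(.data$field, .data$journal, .data$year) |>
    readr::write_csv(path)
  invisible(path)
}

#' Build a PubMed query string
#'
#' Renders the exact search-window command used to count articles for one
#' field in one journal in one calendar year, e.g.
#' `((pilocytic astrocytoma) AND "Nature" [Journal]) AND ("2015"
#' [Date-Publication]: "2015" [Date-Publication])`. Broad keywords that would
#' match many unrelated articles can be "directed" by conjoining an auxiliary
#' disambiguation term, rendering the keyword clause as
#' `((keyword) AND (aux_term))`.
#'
#' @param keyword Field keyword (character, vectorized).
#' @param journal Verbatim journal title.
#' @param year 4-digit calendar year.
#' @param directed Logical; if `TRUE` the auxiliary term is conjoined with the
#'   keyword.
#' @param aux_term Auxiliary disambiguation term, default `"brain tumor"`.
#' @return Character vector of query strings.
#' @examples
#' build_pubmed_query("pilocytic astrocytoma", "Nature", 2015)
#' build_pubmed_query("single cell", "Nature", 2016, directed = TRUE)
#' @export
build_pubmed_query <- function(keyword, journal, year,
                               directed = FALSE, aux_term = "brain tumor") {
  if (any(!nzchar(keyword))) stop_validation("`keyword` must be non-empty.")
  if (any(!is_whole(year) | year < 1000 | year > 9999)) {
    stop_domain("`year` must be a 4-digit calendar year.")
  }
  kw_clause <- ifelse(directed,
                      sprintf("((%s) AND (%s))", keyword, aux_term),
                      sprintf("(%s)", keyword))
  sprintf(
    '(%s AND "%s" [Journal]) AND ("%d" [Date-Publication]: "%d" [Date-Publication])',
    kw_clause, journal, as.integer(year), as.integer(year))
}

#' Rank terms by frequency across a text collection
#'
#' Case-folded word-frequency analysis used to shortlist candidate field
#' keywords from titles or keyword lists. Tokenization lowercases, splits on
#' any run of characters that is neither alphanumeric nor a hyphen, and keeps
#' hyphenated tokens intact (so domain terms such as "PD-1" survive).
#'
#' @param texts Character vector of documents.
#' @param stopwords Character vector of terms to drop after case folding.
#' @param top_n Maximum number of terms to return (default all).
#' @return A tibble with columns `term` and `n`, sorted by `n` descending with
#'   lexicographic tie-breaking; at most `top_n` rows.
#' @examples
#' keyword_frequency(c("IDH IDH glioma", "the glioma"), stopwords = "the")
#' @export
keyword_frequency <- function(texts, stopwords = character(), top_n = Inf) {
  if (!is.infinite(top_n) && (!is_whole(top_n) || top_n < 1)) {
    stop_domain("`top_n` must be a positive integer.")
  }
  if (length(texts) == 0L) return(tibble::tibble(term = character(), n = integer()))
  tokens <- tolower(unlist(strsplit(tolower(texts), "[^\\p{L}\\p{N}-]+", perl = TRUE),
                           use.names = FALSE))
  tokens <- tokens[nzchar(tokens) & !grepl("^-+$", tokens)]
  tokens <- setdiff_keep(tokens, tolower(stopwords))
  if (length(tokens) == 0L) return(tibble::tibble(term = character(), n = integer()))
  out <- tibble::tibble(term = tokens) |>
    dplyr::count(.data$term) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$term)
  utils::head(out, n = if (is.infinite(top_n)) nrow(out) else top_n)
}

# keep duplicates, drop members of `drop`
setdiff_keep <- function(x, drop) x[!(x %in% drop)]
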