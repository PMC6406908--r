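test_that("journal table reads in file order, validates IFs and duplicates", {
  path <- system.file("extdata", "journals_example.csv", package = "bibtrend")
  journals <- read_journal_table(path)
  expect_equal(journals$journal[2], "Nature")
  expect_equal(journals$impact_factor[2], 40.137)
  expect_equal(journals$journal[4], "Child's nervous system")
  expect_equal(journals$impact_factor[4], 1.081)

  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,impact_factor", "A,2.0", "A,3.0"), tf)
  expect_error(read_journal_table(tf), class = "bibtrend_validation_error")

  writeLines(c("name,impact_factor", "A,0"), tf)
  expect_error(read_journal_table(tf), class = "bibtrend_validation_error")

  writeLines(c("name,weight", "A,2.0"), tf)
  expect_error(read_journal_table(tf), class = "bibtrend_format_error")

  writeLines("name,impact_factor", tf)
  expect_warning(empty <- read_journal_table(tf), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("count panel completes absent triples with zero and validates rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("field,journal,year,count",
               "f1,Nature,2015,6",
               "f1,Nature,2013,1"), tf)
  panel <- read_count_panel(tf, journals = c("Nature", "Science"), fields = "f1")
  expect_equal(nrow(panel), 2 * 3)  # 1 field x 2 journals x 2013:2015
  get <- function(j, y) panel$count[panel$journal == j & panel$year == y]
  expect_equal(get("Nature", 2015), 6L)
  expect_equal(get("Nature", 2014), 0L)  # absent means zero
  expect_equal(get("Science", 2015), 0L)

  writeLines(c("field,journal,year,count", "f1,Nature,2015,-1"), tf)
  expect_error(read_count_panel(tf, "Nature", "f1"),
               class = "bibtrend_validation_error")

  writeLines(c("field,journal,year,count", "f1,Unknown journal,2015,2"), tf)
  expect_error(read_count_panel(tf, "Nature", "f1"), "Unknown journal")

  writeLines(c("field,journal,year,count", "f9,Nature,2015,2"), tf)
  expect_error(read_count_panel(tf, "Nature", "f1"), "f9")
})

test_that("JSON panels load through the nested field/journal/year layout", {
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(f1 = list(Nature = list(`2014` = 2, `2015` = 6))),
                       tf, auto_unbox = TRUE)
  panel <- read_count_panel(tf, journals = "Nature", fields = c("f1", "f2"))
  expect_equal(sort(unique(panel$field)), c("f1", "f2"))
  expect_equal(panel$count[panel$field == "f1" & panel$year == 2015], 6L)
  expect_equal(sum(panel$count[panel$field == "f2"]), 0L)
})

test_that("panel round-trips through write/read, preserving nonzero counts", {
  withr::local_seed(42)
  panel <- random_panel(4, 3, 5)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_count_panel(panel, tf)
  back <- read_count_panel(tf, journals = sprintf("J%02d", 1:3),
                           fields = sprintf("f%02d", 1:4))
  expect_equal(
    dplyr::arrange(back, field, journal, year),
    dplyr::arrange(dplyr::mutate(panel, year = as.integer(year)), field, journal, year))
})

test_that("query strings match the search-window dialect byte for byte", {
  expect_identical(
    build_pubmed_query("pilocytic astrocytoma", "Nature", 2015),
    '((pilocytic astrocytoma) AND "Nature" [Journal]) AND ("2015" [Date-Publication]: "2015" [Date-Publication])')
  expect_identical(
    build_pubmed_query("pilocytic astrocytoma", "Nature", 2016),
    gsub("2015", "2016", build_pubmed_query("pilocytic astrocytoma", "Nature", 2015)))
  directed <- build_pubmed_query("single cell", "Nature", 2015, directed = TRUE)
  expect_identical(
    directed,
    '(((single cell) AND (brain tumor)) AND "Nature" [Journal]) AND ("2015" [Date-Publication]: "2015" [Date-Publication])')
  expect_error(build_pubmed_query("glioma", "Nature", 15),
               class = "bibtrend_domain_error")
})

test_that("query building is injective over keyword/journal/year", {
  combos <- tidyr::expand_grid(kw = c("glioma", "IDH", "single cell"),
                               journal = c("Nature", "Science"),
                               year = 2014:2016)
  queries <- purrr::pmap_chr(combos, function(kw, journal, year)
    build_pubmed_query(kw, journal, year))
  expect_equal(anyDuplicated(queries), 0L)
})

test_that("keyword frequency counts, filters stopwords and breaks ties lexicographically", {
  expect_equal(keyword_frequency("IDH IDH glioma", top_n = 2),
               tibble::tibble(term = c("idh", "glioma"), n = c(2L, 1L)))
  expect_equal(keyword_frequency("the glioma", stopwords = "the")$term, "glioma")
  expect_equal(keyword_frequency("PD-1 blockade")$term, c("blockade", "pd-1"))
  expect_equal(nrow(keyword_frequency(character())), 0L)

  # tie-break oracle: brute-force count and sort
  withr::local_seed(11)
  vocab <- c("apple", "pear", "zeta", "beta", "glioma", "idh")
  texts <- replicate(20, paste(sample(vocab, 8, replace = TRUE), collapse = " "))
  got <- keyword_frequency(texts)
  tokens <- unlist(strsplit(tolower(texts), " "))
  tab <- table(tokens)
  oracle <- tibble::tibble(term = names(tab), n = as.integer(tab))
  oracle <- oracle[order(-oracle$n, oracle$term), ]
  expect_equal(got$term, oracle$term)
  expect_equal(got$n, oracle$n)
})

test_that("keyword frequency counts sum to the non-stopword token total", {
  texts <- c("glioma and IDH and glioma", "tumor-treating fields for glioma")
  res <- keyword_frequency(texts, stopwords = c("and", "for"))
  # non-stopword tokens: glioma x3, idh, tumor-treating, fields
  expect_equal(sum(res$n), 6L)
})
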