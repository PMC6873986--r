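# Readers, writers, cohort assembly and signature round-trips.

write_tsv <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

test_that("read_expression_matrix parses and rejects malformed input", {
  path <- write_tsv(c("id\ts1\ts2", "gA\t1.5\t2", "gB\t0\t-1", "gC\t3\t4"))
  m <- read_expression_matrix(path)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("gA", "gB", "gC"))
  expect_equal(m["gB", "s2"], -1)

  dup <- write_tsv(c("id\ts1", "gA\t1", "gA\t2"))
  expect_error(read_expression_matrix(dup), "gA")

  holey <- write_tsv(c("id\ts1\ts2", "gA\t1\t", "gB\t2\t3"))
  expect_error(read_expression_matrix(holey), "gA")

  text <- write_tsv(c("id\ts1", "gA\toops"))
  expect_error(read_expression_matrix(text), "non-numeric")
  expect_error(read_expression_matrix(tempfile()), "not found")
})

test_that("csv detection and transpose work", {
  path <- write_tsv(c("id,gA,gB", "s1,1,2", "s2,3,4"), ext = "csv")
  m <- read_expression_matrix(path, transpose = TRUE)
  expect_identical(rownames(m), c("gA", "gB"))
  expect_equal(m["gB", "s1"], 2)
})

test_that("expression round-trips through write/read", {
  set.seed(3)
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  expect_equal(read_expression_matrix(path), m, tolerance = 1e-12)
})

test_that("read_clinical_table validates its invariants", {
  ok <- write_tsv(c("sample_id\ttime\tevent\textra", "s1\t5.0\t1\tx",
                    "s2\t7.0\t0\ty"))
  tab <- read_clinical_table(ok)
  expect_identical(nrow(tab), 2L)
  expect_identical(colnames(tab), c("sample_id", "time", "event"))

  expect_error(read_clinical_table(
    write_tsv(c("sample_id\ttime\tevent", "s1\t0\t1"))), "time")
  expect_error(read_clinical_table(
    write_tsv(c("sample_id\ttime\tevent", "s1\t5\t2"))), "event")
  expect_error(read_clinical_table(
    write_tsv(c("sample_id\ttime\tevent", "s1\t5\t1", "s1\t2\t0"))),
    "duplicated")
  expect_error(read_clinical_table(
    write_tsv(c("sample_id\ttime", "s1\t5"))), "event")
})

test_that("assemble_cohort inner-joins, reorders, and guards", {
  m <- matrix(1:9, 3, 3, dimnames = list(paste0("g", 1:3),
                                         c("s1", "s2", "s3")))
  clin <- data.frame(sample_id = c("s2", "s3", "s4"), time = c(1, 2, 3),
                     event = c(1, 0, 1), stringsAsFactors = FALSE)
  co <- suppressMessages(assemble_cohort(m, clin, "a"))
  expect_identical(colnames(co$expression), c("s2", "s3"))
  expect_identical(co$clinical$sample_id, colnames(co$expression))

  disjoint <- data.frame(sample_id = "zz", time = 1, event = 1,
                         stringsAsFactors = FALSE)
  expect_error(assemble_cohort(m, disjoint, "a"), "no samples shared")

  censored <- data.frame(sample_id = c("s1", "s2"), time = c(1, 2),
                         event = c(0, 0), stringsAsFactors = FALSE)
  expect_error(suppressMessages(assemble_cohort(m, censored, "a")),
               "no observed events")
})

test_that("assemble_cohort is insensitive to expression column order", {
  co <- make_cohort(seed = 5)
  perm <- sample(ncol(co$expression))
  again <- assemble_cohort(co$expression[, perm], co$clinical, co$name)
  expect_equal(again$expression, co$expression)
  expect_equal(again$clinical, co$clinical)
})

test_that("signatures round-trip bit-identically through JSON", {
  sig <- trained_signature(c("gB", "gA"), c(0.123456789012345, -2.5),
                           lambda = 0.31622776601683794,
                           provenance = list(alpha = 0.05,
                                             cohorts = c("x", "y")))
  path <- tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$gene_ids, sig$gene_ids)
  expect_identical(back$coefficients, sig$coefficients)
  expect_identical(back$lambda, sig$lambda)
  expect_identical(back$feature_space, sig$feature_space)
  expect_equal(back$provenance, sig$provenance)
})

test_that("malformed signature files and objects are refused", {
  expect_error(trained_signature(c("a", "b"), 1, 0), "length")
  expect_error(trained_signature("a", 1, -1), "nonnegative")

  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "discordsig-signature", version = 1,
                            genes = c("a"), lambda = 0),
                       path, auto_unbox = TRUE)
  expect_error(read_signature(path), "coefficients")

  jsonlite::write_json(list(format = "something-else"), path,
                       auto_unbox = TRUE)
  expect_error(read_signature(path), "not a signature")
})

test_that("cohort_collection enforces shared universe and unique names", {
  a <- make_cohort("a", seed = 1)
  b <- make_cohort("b", seed = 2)
  expect_s3_class(cohort_collection(list(a, b)), "cohort_collection")
  expect_error(cohort_collection(list(a, a)), "unique")
  b$expression <- b$expression[rev(rownames(b$expression)), ]
  expect_error(cohort_collection(list(a, b)), "universe")
})
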