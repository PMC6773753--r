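test_that("corpus files round-trip and report class counts faithfully", {
  corpus <- generate_tweets(generator_spec(n_tweets = 60, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(back$tweet_id, corpus$tweet_id)
  expect_equal(back$text, corpus$text)
  expect_equal(back$label, corpus$label)
  summary <- load_summary(back)
  recount <- table(factor(back$label, levels = tweet_classes()))
  expect_equal(summary$defect, unname(recount["defect"]))
  expect_equal(summary$possible_defect, unname(recount["possible_defect"]))
  expect_equal(summary$non_defect, unname(recount["non_defect"]))
  expect_equal(summary$rows_malformed, 0)
})

test_that("labels are case-folded with a warning and unknown labels refused", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tweet_id\tuser_id\ttext\tlabel",
               "1\tu1\tone tweet\tdefect",
               "2\tu2\tanother tweet\tpossible_defect",
               "3\tu3\ta third tweet\tnon_defect"), path)
  corpus <- read_corpus(path)
  expect_equal(nrow(corpus), 3)
  expect_equal(sort(class_counts(corpus)$n[1:3]), c(1, 1, 1))

  writeLines(c("tweet_id\tuser_id\ttext\tlabel",
               "1\tu1\tone tweet\tDefect"), path)
  expect_warning(corpus <- read_corpus(path), "case-folded")
  expect_equal(corpus$label, "defect")

  writeLines(c("tweet_id\tuser_id\ttext\tlabel",
               "1\tu1\tone tweet\tmaybe"), path)
  expect_error(read_corpus(path), "unknown label")
})

test_that("malformed rows are counted and reported, not silently dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tweet_id\tuser_id\ttext\tlabel",
               "1\tu1\tgood tweet\tdefect",
               "2\tu2\t   \tnon_defect"), path)
  expect_message(corpus <- read_corpus(path), "malformed")
  expect_equal(nrow(corpus), 1)
  expect_equal(load_summary(corpus)$rows_malformed, 1)
  expect_equal(load_summary(corpus)$rows_read, 2)
})

test_that("read_corpus rejects missing, empty and header-less files", {
  expect_error(read_corpus(file.path(tempdir(), "nope.tsv")), "not found")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tweet_id\tuser_id\ttext\tlabel", path)
  expect_error(read_corpus(path), "empty")
  writeLines(c("id\ttext", "1\thello"), path)
  expect_error(read_corpus(path), "header")
})

test_that("lexicon terms are lowercased, deduplicated, and merged with variants", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("spina bifida", "Spina Bifida"), path)
  lex <- read_lexicon(path)
  expect_equal(nrow(lex), 1)
  expect_equal(lex$term, "spina bifida")

  vpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hydrocephalus"), path)
  writeLines("hydrocephalus\thydrocephalis", vpath)
  lex <- read_lexicon(path, vpath)
  expect_equal(nrow(lex), 1)
  expect_equal(lex$variants[[1]], "hydrocephalis")

  writeLines(character(0), path)
  expect_error(read_lexicon(path), "empty lexicon")
})

test_that("the bundled fixture lexicon has the eight common defect terms", {
  lex <- read_lexicon(
    system.file("extdata", "birth_defect_terms.txt", package = "bdcohort"))
  expect_equal(nrow(lex), 8)
  expect_true(all(c("chd", "club foot", "down syndrome", "dwarfism",
                    "gastroschisis", "hydrocephalus", "microcephaly",
                    "trisomy 18") %in% lex$term))
})

test_that("cluster tables and name lexicons parse with first-wins duplicates", {
  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0011\tson\t120", "0011\tdaughter\t80"), cpath)
  clusters <- read_clusters(cpath)
  expect_equal(nrow(clusters), 2)
  expect_equal(clusters$cluster, c("0011", "0011"))

  writeLines(c("0011\tson\t120", "0111\tson\t80"), cpath)
  expect_equal(read_clusters(cpath)$cluster, "0011")
  writeLines(character(0), cpath)
  expect_error(read_clusters(cpath), "empty")

  npath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Emma", "emma", "Liam"), npath)
  expect_equal(read_names(npath)$name, c("emma", "liam"))

  # unseen word contributes no cluster feature
  writeLines(c("0011\tson\t120"), cpath)
  cf <- cluster_features(list("unknownword"), read_clusters(cpath))
  expect_equal(sum(cf), 0)
})

test_that("run configuration validates fractions and reads YAML", {
  cfg <- run_config(seed = 42, sampling = "smote")
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 42L)
  expect_error(run_config(test_frac = 1.2), "test_frac")
  expect_error(run_config(nonsense = 1), "unknown config key")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "classifier: nb", "test_frac: 0.25"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$classifier, "nb")
  expect_equal(cfg$test_frac, 0.25)
})
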