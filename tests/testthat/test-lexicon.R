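test_that("lexicon survives write -> load round trips, deterministically", {
  withr::local_seed(11)
  for (rep in 1:15) {
    L <- random_lexicon(n = sample(2:10, 1))
    lf <- withr::local_tempfile(fileext = ".tsv")
    dcf <- withr::local_tempfile(fileext = ".tsv")
    write_lexicon(L, lf, dcf)
    L2 <- load_lexicon(lf, dcf)
    expect_equal(L2$entries[order(names(L2$entries))],
                 L$entries[order(names(L$entries))])
    expect_equal(L2$drug_classes, L$drug_classes)
    # byte-identical on rewrite
    lf2 <- withr::local_tempfile(fileext = ".tsv")
    write_lexicon(L2, lf2, withr::local_tempfile(fileext = ".tsv"))
    expect_identical(readLines(lf), readLines(lf2))
  }
  # empty lexicon writes a header-only file
  ef <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lexicon(), ef)
  expect_length(readLines(ef), 1L)
  expect_equal(length(load_lexicon(ef)$entries), 0L)
})

test_that("lexicon format errors are caught and named", {
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term_key\tentry_class\tsense_rank\tdefinition_text\tsource_tag\tdrug_class_key",
               "ac\tACRONYM\t1\tfirst sense\tsrc\t",
               "ac\tACRONYM\t1\tsecond sense\tsrc\t"), lf)
  expect_error(load_lexicon(lf), "duplicate \\(term_key, sense_rank\\)")
  expect_error(load_lexicon(lf), "line 3")

  # dangling drug class reference
  expect_error(
    lexicon(list(definition_entry("hecoria", "DRUG", empty_senses(),
                                  "no such class"))),
    "referential-integrity")

  # non-contiguous sense ranks
  expect_error(
    definition_entry("x", "TERM", data.frame(
      sense_rank = c(1L, 3L), definition_text = c("a", "b"),
      source_tag = "s")),
    "contiguous")
})

test_that("resolve_definitions applies the display policy per entry class", {
  lex <- make_paper_lexicon()

  # acronym: most-frequent sense only
  ac <- resolve_definitions("ac", lex)
  expect_equal(nrow(ac), 1L)
  expect_match(ac$definition_text, "chemotherapy combination")

  # multi-purpose drug with senses: all senses, rank order
  drug <- resolve_definitions("lantus", lex)
  expect_equal(nrow(drug), 2L)
  expect_match(drug$definition_text[1], "long-acting insulin")
  expect_equal(drug$provenance, c("SENSE", "SENSE"))

  # sense-less drug: single class-level definition
  hec <- resolve_definitions("hecoria", lex)
  expect_equal(hec$definition_text, "A drug used to reduce immune response.")
  expect_equal(hec$provenance, "DRUG_CLASS")

  # unknown key: empty, not an error
  expect_equal(nrow(resolve_definitions("zzzz", lex)), 0L)

  # max_senses caps non-acronym display
  expect_equal(nrow(resolve_definitions("lantus", lex, max_senses = 1)), 1L)
})

test_that("concept table enforces its one-concept-per-surface dialect", {
  tab <- data.frame(
    surface_form = c("cushing's syndrome", "cushing disease"),
    concept_id = c("C0010481", "C0010481"),
    preferred_name = "Cushing Syndrome",
    semantic_types = "Disease or Syndrome", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(names(tab), collapse = "\t"),
               paste(tab[1, ], collapse = "\t"),
               paste(tab[2, ], collapse = "\t")), f)
  ct <- load_concept_table(f)
  expect_equal(concept_lookup(ct, "Cushing's Syndrome")$concept_id,
               concept_lookup(ct, "cushing disease")$concept_id)

  # same surface, different concepts -> format error
  expect_error(concept_table(data.frame(
    surface_form = c("ac", "ac"), concept_id = c("C1", "C2"),
    preferred_name = "AC", semantic_types = "Finding",
    stringsAsFactors = FALSE)), "multiple concept_ids")

  # empty semantic types -> format error
  expect_error(concept_table(data.frame(
    surface_form = "x", concept_id = "C1", preferred_name = "X",
    semantic_types = "", stringsAsFactors = FALSE)), "semantic_types")

  # header-only file -> empty table
  ef <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(tab), collapse = "\t"), ef)
  expect_length(load_concept_table(ef)$records, 0L)
})

test_that("semantic config and modifier list parse, with invariants", {
  cfg <- default_semantic_config()
  expect_true("Disease or Syndrome" %in% cfg$prioritized)
  expect_true("Pharmacologic Substance" %in% cfg$prioritized)
  expect_true("Laboratory or Test Result" %in% cfg$prioritized)
  expect_true("Geographic Area" %in% cfg$deprioritized)
  expect_true("Temporal Concept" %in% cfg$deprioritized)
  expect_length(cfg$prioritized, 21L)
  expect_length(cfg$deprioritized, 3L)

  expect_error(semantic_config(c("Finding", "A"), c("Finding", "B")),
               "config error")

  f <- withr::local_tempfile()
  writeLines(c("[prioritized]", "Finding", "[deprioritized]", "Finding"), f)
  expect_error(load_semantic_config(f), "config error")

  mods <- default_modifiers()
  expect_true(all(c("chronic", "severe", "left") %in% mods))
  expect_error(modifier_list(c("chronic", "very severe")), "single words")
})

test_that("key normalization is idempotent and collapses as specified", {
  expect_equal(normalize_key("  Cushing's   Syndrome "),
               "cushing's syndrome")
  expect_equal(normalize_surface("Cushing's syndrome"), "cushing syndrome")
  withr::local_seed(5)
  for (i in 1:50) {
    s <- paste(sample(c(LETTERS, letters, " ", "'", "\t"), 25,
                      replace = TRUE), collapse = "")
    expect_identical(normalize_key(normalize_key(s)), normalize_key(s))
    expect_identical(normalize_surface(normalize_surface(s)),
                     normalize_surface(s))
  }
})
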