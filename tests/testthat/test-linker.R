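test_that("classify_policy applies the ANY-prioritized / ALL-deprioritized rule", {
  cfg <- default_semantic_config()
  expect_equal(classify_policy("Disease or Syndrome", cfg), "FULL")
  expect_equal(classify_policy("Temporal Concept", cfg), "SKIP")
  expect_equal(classify_policy(c("Temporal Concept", "Disease or Syndrome"),
                               cfg), "FULL")
  expect_equal(classify_policy("Research Activity", cfg), "SHALLOW")
  expect_equal(classify_policy(c("Temporal Concept", "Research Activity"),
                               cfg), "SHALLOW")
})

test_that("trim_modifiers removes listed words in place", {
  mods <- modifier_list(c("chronic", "severe", "left"))
  expect_equal(trim_modifiers("chronic left heart failure", mods),
               "heart failure")
  expect_equal(trim_modifiers("severe", mods), "")
  expect_equal(trim_modifiers("community acquired pneumonia", mods),
               "community acquired pneumonia")
})

test_that("lookup walks the four stages and stops at the first hit", {
  lex <- make_paper_lexicon()
  mods <- default_modifiers()

  # stage 1: exact surface
  r1 <- lookup(make_match("bacteremia", "Bacteremia"), lex, "FULL", mods)
  expect_equal(r1$stage, 1L)
  expect_false(r1$partial)
  expect_equal(r1$items$definition_text,
               "The presence of bacteria, a type of germ, in the blood")

  # stage 2: preferred name
  r2 <- lookup(make_match("blood infection", "Bacteremia"), lex, "FULL",
               mods)
  expect_equal(r2$stage, 2L)

  # stage 3: modifier-trimmed surface
  r3 <- lookup(make_match("chronic left heart failure"), lex, "FULL", mods)
  expect_equal(r3$stage, 3L)
  expect_false(r3$partial)
  expect_equal(r3$items$definition_text,
               "When the heart cannot pump enough blood.")

  # stage 4: per-word fallback with labeled items in word order
  r4 <- lookup(make_match("community acquired pneumonia",
                          "Community-Acquired Pneumonia"),
               lex, "FULL", mods)
  expect_equal(r4$stage, 4L)
  expect_true(r4$partial)
  expect_equal(r4$items$label, c("community", "pneumonia"))
  expect_equal(r4$items$definition_text,
               c("A group of people.",
                 "An infection of the lungs, usually caused by viruses or bacteria."))

  # stage 4 with a single defined word
  r5 <- lookup(make_match("normal sinus rhythm"), lex, "FULL", mods)
  expect_equal(r5$stage, 4L)
  expect_equal(r5$items$label, "rhythm")

  # SHALLOW cannot reach stage 3
  expect_null(lookup(make_match("chronic left heart failure"), lex,
                     "SHALLOW", mods))
  # full miss
  expect_null(lookup(make_match("tidal volume"), lex, "FULL", mods))
})

test_that("lookup stage is minimal: oracle equivalence on random cases", {
  withr::local_seed(77)
  mods <- modifier_list(c("chronic", "severe", "left", "acute"))
  words <- c("alpha", "beta", "gamma", "delta", "epsi", "zeta",
             "chronic", "severe")
  for (i in 1:200) {
    lex_keys <- unique(replicate(sample(1:6, 1), paste(
      sample(words, sample(1:2, 1)), collapse = " ")))
    lex <- lexicon(lapply(lex_keys, function(k) {
      definition_entry(k, "TERM", data.frame(
        sense_rank = 1L, definition_text = paste("def of", k),
        source_tag = "s"))
    }))
    surface <- paste(sample(words, sample(1:3, 1)), collapse = " ")
    preferred <- paste(sample(words, sample(1:2, 1)), collapse = " ")
    policy <- sample(c("FULL", "SHALLOW"), 1)
    got <- lookup(make_match(surface, preferred), lex, policy, mods)
    want <- oracle_stage(surface, preferred, lex, policy, mods)
    if (is.na(want)) {
      expect_null(got, info = paste("case", i))
    } else {
      expect_equal(got$stage, want, info = paste("case", i))
      expect_equal(got$partial, want == 4L)
    }
  }
})

test_that("annotate is cache-transparent and honors SKIP", {
  lex <- make_paper_lexicon()
  ct <- make_paper_concepts()
  cfg <- default_semantic_config()
  mods <- default_modifiers()
  text <- paste("Blood cultures grew organisms consistent with bacteremia.",
                "Imaging ruled out community acquired pneumonia.",
                "ECG shows normal sinus rhythm. Continue Hecoria and AC.")
  with_cache <- annotate(text, ct, lex, cfg, mods, quiet = TRUE)
  without <- annotate(text, ct, lex, cfg, mods, use_cache = FALSE,
                      quiet = TRUE)
  expect_identical(serialize_annotations(with_cache),
                   serialize_annotations(without))
  expect_equal(vapply(with_cache$results, `[[`, integer(1), "stage"),
               c(1L, 4L, 4L, 1L, 1L))

  # a note of only deprioritized terms yields zero results
  ct_dep <- concept_table(data.frame(
    surface_form = c("bacteremia", "hecoria"), concept_id = c("C1", "C2"),
    preferred_name = c("Bacteremia", "Hecoria"),
    semantic_types = "Temporal Concept", stringsAsFactors = FALSE))
  skip_note <- annotate("bacteremia then hecoria", ct_dep, lex, cfg, mods,
                        quiet = TRUE)
  expect_length(skip_note$results, 0L)
})

test_that("annotation records round-trip and guard their text", {
  lex <- make_paper_lexicon()
  ct <- make_paper_concepts()
  note <- annotate("Assessment: bacteremia, on Lantus.", ct, lex,
                   default_semantic_config(), default_modifiers(),
                   quiet = TRUE)
  rec <- serialize_annotations(note)
  back <- parse_annotations(rec, note$text)
  expect_equal(results_frame(back), results_frame(note))
  expect_equal(lapply(back$results, `[[`, "items"),
               lapply(note$results, `[[`, "items"))
  expect_error(parse_annotations(rec, "some other text"), "integrity")

  empty <- annotate("nothing medical here", ct, lex,
                    default_semantic_config(), default_modifiers(),
                    quiet = TRUE)
  back_empty <- parse_annotations(serialize_annotations(empty), empty$text)
  expect_length(back_empty$results, 0L)
})

test_that("render_html escapes everything and emits no hyperlinks", {
  lex <- make_paper_lexicon()
  ct <- make_paper_concepts()
  cfg <- default_semantic_config()
  mods <- default_modifiers()

  plain <- annotate("x < y & <script>alert(1)</script>", ct, lex, cfg,
                    mods, quiet = TRUE)
  html <- render_html(plain)
  expect_false(grepl("<script>", html, fixed = TRUE))
  expect_true(grepl("&lt;script&gt;", html, fixed = TRUE))
  expect_false(grepl("<a ", html, fixed = TRUE))

  note <- annotate(
    "Cultures confirmed bacteremia. CXR: community acquired pneumonia.",
    ct, lex, cfg, mods, quiet = TRUE)
  got <- render_html(note)
  golden <- readLines(test_path("_golden", "render-fixture.txt"),
                      encoding = "UTF-8")
  expect_identical(got, paste(golden, collapse = "\n"))
  expect_true(grepl("[community]: A group of people.",
                    got, fixed = TRUE))
})
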