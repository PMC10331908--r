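lex <- material_lexicon()

test_that("exemplar descriptors map to their categories and unknowns never guess", {
  expect_equal(categorize_material("mud", lex), "binder")
  expect_equal(categorize_material("Spanish moss", lex), "grass")
  expect_equal(categorize_material("feathers", lex), "fibre")
  expect_equal(categorize_material("shell", lex), "mineral")
  expect_equal(categorize_material("  SALIVA ", lex), "binder")
  expect_equal(categorize_material("gzornenplatz", lex), "unknown")
  expect_error(categorize_material("   ", lex), "empty descriptor")
})

test_that("primary material follows emphasis > single category > first listed", {
  # emphasized descriptor wins over listing order
  p <- resolve_primary(record_row("sp1", "a", c("twig", "moss"), emphasized = "moss"), lex)
  expect_equal(p$primary, "fibre")
  expect_setequal(p$used, c("twig", "fibre"))
  expect_false(p$specialist)

  # a single reported category makes a specialist
  p <- resolve_primary(record_row("sp1", "a", "grass"), lex)
  expect_equal(p$primary, "grass")
  expect_true(p$specialist)

  # no emphasis: first categorizable material listed
  p <- resolve_primary(record_row("sp1", "a", c("leaf", "twig")), lex)
  expect_equal(p$primary, "leaf")
})

test_that("sources with conflicting candidates yield the mixed sentinel", {
  recs <- rbind(record_row("sp1", "a", c("feathers", "grass"), emphasized = "feathers"),
                record_row("sp1", "b", "grass"))
  p <- resolve_primary(recs, lex)
  expect_equal(p$primary, "mixed")
  expect_false(p$specialist)
  expect_setequal(p$used, c("fibre", "grass"))

  # agreeing sources do not
  recs <- rbind(record_row("sp1", "a", "grass"), record_row("sp1", "b", "grass"))
  expect_equal(resolve_primary(recs, lex)$primary, "grass")
})

test_that("descriptor order is irrelevant whenever an emphasis is present", {
  base <- c("twig", "moss", "mud", "grass")
  for (s in 1:10) {
    set.seed(s)
    perm <- sample(base)
    p <- resolve_primary(record_row("sp1", "a", perm, emphasized = "mud"), lex)
    expect_equal(p$primary, "binder")
    expect_setequal(p$used, c("twig", "fibre", "binder", "grass"))
  }
})

test_that("coding a corpus enforces the specialist identity and flags unscorable species", {
  recs <- rbind(
    record_row("sp1", "a", c("twig", "bark")),         # one category, two terms
    record_row("sp2", "a", c("mud", "grass")),
    record_row("sp2", "b", "mud"),
    record_row("sp3", "a", "gzornenplatz"),            # nothing scorable
    record_row("sp4", "a", c("silk", "blorp"))         # partial unknowns fine
  )
  suppressMessages(profiles <- code_materials(recs, lex))
  expect_s3_class(profiles, "material_profiles")
  expect_true(profiles$omit[profiles$species_id == "sp3"])
  expect_false(any(profiles$omit[profiles$species_id != "sp3"]))

  used_cols <- paste0("used_", material_categories())
  ok <- !profiles$omit
  n_used <- unname(rowSums(profiles[ok, used_cols]))
  expect_equal(profiles$specialist[ok], n_used == 1)
  expect_true(all(n_used >= 1))
  # sp1 uses only twig (twig + bark are both woody)
  expect_true(profiles$specialist[profiles$species_id == "sp1"])
  expect_identical(sort(attr(profiles, "unknown_terms")), c("blorp", "gzornenplatz"))
})

test_that("mixed arises only from two or more disagreeing sources", {
  cfg <- synth_config(n_species = 60, n_trees = 1, seed = 8)
  ds <- generate_dataset(cfg)
  # single-source synthetic profiles can never be mixed
  expect_false(any(ds$profiles$primary == "mixed"))
  used_cols <- paste0("used_", material_categories())
  expect_equal(ds$profiles$specialist, rowSums(ds$profiles[used_cols]) == 1)
})

test_that("material profiles survive a CSV round trip", {
  recs <- rbind(record_row("sp1", "a", c("mud", "grass")),
                record_row("sp2", "a", "silk"))
  profiles <- code_materials(recs, lex)
  path <- withr::local_tempfile(fileext = ".csv")
  write_material_profiles(profiles, path)
  back <- read_material_profiles(path)
  expect_equal(back$primary, profiles$primary)
  expect_equal(back$used_silk, profiles$used_silk)
})
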