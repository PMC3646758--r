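assim_path <- system.file("extdata", "synthetic_assimilation_matrix.tsv",
                          package = "oleagin")
hydro_path <- system.file("extdata", "synthetic_hydrophobic_matrix.tsv",
                          package = "oleagin")

test_that("a small matrix partitions into universal / unused / variable", {
  df <- data.frame(
    strain = rep(c("A", "B"), 3),
    substrate = rep(c("s1", "s2", "s3"), each = 2),
    medium = "MMB",
    score = c("growth", "growth", "none", "none", "growth", "none"),
    stringsAsFactors = FALSE)
  ss <- summarize_substrates(phenotype_matrix(df))
  expect_equal(ss$universal, "s1")
  expect_equal(ss$unused, "s2")
  expect_equal(ss$variable, "s3")
})

test_that("the packaged assimilation fixture gives the 3/21/7 partition", {
  m <- read_phenotype_matrix(assim_path)
  ss <- summarize_substrates(m, medium = "MMB")
  expect_setequal(ss$universal, c("fructose", "glycerol", "glucose"))
  expect_length(ss$unused, 21L)
  expect_length(ss$variable, 7L)
  # the three sets partition the 31 tested substrates
  all_subs <- unique(m$substrate)
  expect_setequal(c(ss$universal, ss$unused, ss$variable), all_subs)
  expect_length(all_subs, 31L)
})

test_that("random matrices match the brute-force per-substrate scan", {
  for (seed in 1:10) {
    m <- random_phenotype_matrix(5, 8, seed)
    for (weak_ok in c(TRUE, FALSE)) {
      ss <- summarize_substrates(m, weak_counts_as_growth = weak_ok)
      oracle <- oracle_partition(as.data.frame(m), weak_ok)
      expect_setequal(ss$universal, oracle$universal)
      expect_setequal(ss$unused, oracle$unused)
      expect_setequal(ss$variable, oracle$variable)
      # partition property
      expect_length(c(ss$universal, ss$unused, ss$variable), 8L)
    }
  }
})

test_that("counting weak as growth only moves substrates between universal and variable", {
  for (seed in 11:20) {
    m <- random_phenotype_matrix(4, 10, seed)
    lax <- summarize_substrates(m, weak_counts_as_growth = TRUE)
    strict <- summarize_substrates(m, weak_counts_as_growth = FALSE)
    expect_setequal(lax$unused, strict$unused)
    expect_true(all(strict$universal %in% lax$universal))
  }
})

test_that("untested combinations abort the summary with their names", {
  df <- data.frame(strain = c("A", "B", "A"), substrate = c("s1", "s1", "s2"),
                   medium = "MMB", score = "growth", stringsAsFactors = FALSE)
  expect_error(summarize_substrates(phenotype_matrix(df)), "B x s2")
  df$score[2] <- "untested"
  expect_error(summarize_substrates(phenotype_matrix(df)), "untested")
})

test_that("halo tables list the halo-forming strains", {
  m <- read_phenotype_matrix(hydro_path)
  expect_setequal(halo_table(m, "tributyrin", "YP"),
                  c("YALI", "YADE", "YAOS", "YAPH", "YAHO"))
  expect_warning(h <- halo_table(m, "hexadecane", "YP"), "no halo data")
  expect_length(h, 0L)
  # all-set and none-set corner cases
  df <- data.frame(strain = c("A", "B"), substrate = "tb", medium = "YP",
                   score = "growth", halo = TRUE, stringsAsFactors = FALSE)
  expect_setequal(halo_table(phenotype_matrix(df), "tb"), c("A", "B"))
  df$halo <- FALSE
  expect_length(halo_table(phenotype_matrix(df), "tb"), 0L)
})

test_that("toxicity and non-metabolisation flags follow the YP/MMB contrast", {
  m <- read_phenotype_matrix(hydro_path)
  fl <- toxicity_flags(m)
  # C6 compounds inhibit growth even on rich medium
  expect_true(fl$toxic_all[fl$substrate == "hexanoic acid"])
  expect_true(fl$toxic[fl$substrate == "methyl hexanoate"])
  expect_false(fl$toxic_all[fl$substrate == "methyl hexanoate"])
  # alkanes: not used on minimal medium by some strains, harmless on rich
  expect_true(fl$non_metabolized[fl$substrate == "hexadecane"])
  expect_false(fl$toxic[fl$substrate == "hexadecane"])
  # universally used substrates carry no flag
  expect_false(fl$toxic[fl$substrate == "tributyrin"])
  expect_false(fl$non_metabolized[fl$substrate == "tributyrin"])
  # missing YP-alone control is an error
  m2 <- phenotype_matrix(as.data.frame(m)[m$substrate != "none", ])
  expect_error(toxicity_flags(m2), "control")
})

test_that("phenotype matrices validate scores and round-trip through TSV", {
  df <- data.frame(strain = "A", substrate = "s", medium = "MMB",
                   score = "maybe", stringsAsFactors = FALSE)
  expect_error(phenotype_matrix(df), "invalid score")
  df$score <- "growth"
  dup <- rbind(df, df)
  expect_error(phenotype_matrix(dup), "duplicate")
  m <- read_phenotype_matrix(assim_path)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_matrix(m, path)
  expect_equal(as.data.frame(read_phenotype_matrix(path))$score, m$score)
})
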