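vtab <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(position = r[[1]], ref_aa = r[[2]], alt_aa = r[[3]],
               score = r[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("trafficking threshold is inclusive at 40%", {
  expect_equal(traffic_class(c(40, 39.9, 0, 100)),
               c("pass", "poor", "poor", "pass"))
  expect_error(traffic_class(-1), ">= 0")
})

test_that("conservative calls follow the physicochemical grouping", {
  expect_true(is_conservative("V", "I"))
  expect_false(is_conservative("R", "C"))
  expect_true(is_conservative("K", "R"))
  expect_false(is_conservative("G", "A"))
  expect_equal(is_conservative(c("V", "R"), c("I", "C")), c(TRUE, FALSE))
  expect_error(is_conservative("B", "A"), "nonstandard")
})

test_that("residue categories follow the precedence rules", {
  # no data
  empty <- data.frame(position = integer(), ref_aa = character(),
                      alt_aa = character(), score = numeric())
  grey <- categorize_residue(empty, position = 401)
  expect_equal(grey$category, "no_data")
  expect_equal(grey$code, 0L)
  # nothing passes: intolerant
  red <- categorize_residue(vtab(list(470, "N", "D", 2), list(470, "N", "K", 10),
                                 list(470, "N", "A", 39.9)))
  expect_equal(red$category, "intolerant")
  # only conservative substitutions accommodated
  yellow <- categorize_residue(vtab(
    list(476, "V", "I", 85), list(476, "V", "L", 60),
    list(476, "V", "R", 5), list(476, "V", "D", 10),
    list(476, "V", "K", 15), list(476, "V", "G", 20)))
  expect_equal(yellow$category, "conservative_only")
  expect_equal(yellow$n_conservative_pass, 2L)
  expect_equal(yellow$n_nonconservative_pass, 0L)
  # mostly passing: exchangeable
  blue <- categorize_residue(vtab(
    list(500, "L", "R", 80), list(500, "L", "D", 70),
    list(500, "L", "I", 90), list(500, "L", "P", 82)))
  expect_equal(blue$category, "exchangeable")
  # sparse passing including a non-conservative pass: low tolerance
  orange <- categorize_residue(vtab(
    list(402, "L", "D", 45), list(402, "L", "A", 5), list(402, "L", "V", 5),
    list(402, "L", "G", 5), list(402, "L", "P", 5)))
  expect_equal(orange$category, "low_tolerance")
  # middle pass fraction: moderate
  cyan <- categorize_residue(vtab(
    list(488, "R", "K", 80), list(488, "R", "C", 50),
    list(488, "R", "P", 10), list(488, "R", "G", 10)))
  expect_equal(cyan$category, "moderate")

  expect_error(categorize_residue(vtab(list(1, "A", "V", 50),
                                       list(2, "A", "V", 50))),
               "several positions")
  expect_error(categorize_residue(vtab(list(1, "A", "A", 50))), "synonymous")
})

test_that("categories are pure functions of the counts (order-invariant)", {
  set.seed(31)
  base <- vtab(list(10, "L", "I", 80), list(10, "L", "R", 10),
               list(10, "L", "D", 55), list(10, "L", "P", 35))
  ref <- categorize_residue(base)$category
  for (i in 1:10) {
    perm <- base[sample(nrow(base)), ]
    expect_equal(categorize_residue(perm)$category, ref)
  }
})

test_that("raising any score never strictens a residue's category", {
  set.seed(57)
  aas <- unlist(default_aa_groups(), use.names = FALSE)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    ref <- sample(aas, 1)
    alts <- sample(setdiff(aas, ref), n)
    scores <- runif(n, 0, 110)
    tab <- data.frame(position = 7, ref_aa = ref, alt_aa = alts,
                      score = scores, stringsAsFactors = FALSE)
    before <- categorize_residue(tab)$category
    j <- sample(n, 1)
    tab$score[j] <- tab$score[j] + runif(1, 0, 80)
    after <- categorize_residue(tab)$category
    expect_gte(tolerance_rank(after), tolerance_rank(before))
  }
})

test_that("whole-table categorization fills requested positions with no_data", {
  tab <- vtab(list(470, "N", "D", 2), list(472, "R", "P", 5),
              list(472, "R", "K", 95))
  cats <- categorize_variants(tab, positions = 470:473)
  expect_equal(cats$position, 470:473)
  expect_equal(cats$category[cats$position == 471], "no_data")
  expect_equal(cats$category[cats$position == 470], "intolerant")
})

test_that("annotation writer emits an attribute file and B-factor codes", {
  tab <- vtab(list(470, "N", "D", 2), list(471, "D", "E", 90),
              list(472, "R", "K", 95))
  cats <- categorize_variants(tab, positions = 470:473)
  attr_path <- withr::local_tempfile(fileext = ".tsv")
  pdb_in <- withr::local_tempfile(fileext = ".pdb")
  pdb_out <- withr::local_tempfile(fileext = ".pdb")
  writeLines(synthetic_pdb_lines(469:472), pdb_in)

  expect_warning(
    write_structure_annotation(cats, attr_path, pdb_in, pdb_out),
    "473")  # category position absent from the structure

  tsv <- read.delim(attr_path, comment.char = "#")
  expect_equal(tsv$position, 470:473)
  expect_equal(tsv$code[tsv$position == 470], 1L)

  out <- readLines(pdb_out)
  bfac <- as.numeric(substr(out, 61, 66))
  resseq <- as.integer(substr(out, 23, 26))
  expect_equal(bfac[resseq == 469], 0)  # not categorized: no_data
  expect_equal(bfac[resseq == 470], 1)
  expect_equal(nchar(out), nchar(synthetic_pdb_lines(469:472)))

  # attribute file only when no structure is given
  write_structure_annotation(cats, attr_path)
  expect_true(file.exists(attr_path))
  dup <- rbind(cats, cats[1, ])
  expect_error(write_structure_annotation(dup, attr_path), "duplicate")
})
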