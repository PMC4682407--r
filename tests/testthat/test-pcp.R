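test_that("the bundled AAindex file parses with the published values", {
  entries <- parse_aaindex(aaindex_fixture_path())
  expect_equal(nrow(entries), 5)
  kytj <- entries$values[[which(entries$accession == "KYTJ820101")]]
  expect_equal(kytj[["I"]], 4.5)
  expect_equal(kytj[["R"]], -4.5)
  expect_equal(entries$n_na, rep(0L, 5))
})

test_that("parsed hydropathy values agree with the aaindex compendium", {
  # independent source: seqinr ships the full AAindex data set
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  ref <- env$aaindex$KYTJ820101$I
  names(ref) <- seqinr::a(names(ref))
  mine <- parse_aaindex(aaindex_fixture_path())
  kytj <- mine$values[[which(mine$accession == "KYTJ820101")]]
  expect_equal(kytj, ref[names(kytj)])
})

test_that("NA tokens are recorded and malformed records rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "H SYN0000001",
    "D synthetic scale with two missing residues",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y",
    "    1  NA  3  4  5  6  7  8  9  10",
    "    11  12  13  14  NA  16  17  18  19  20",
    "//"
  ), path)
  e <- parse_aaindex(path)
  expect_equal(e$n_na, 2L)
  expect_true(is.na(e$values[[1]][["R"]]))
  expect_true(is.na(e$values[[1]][["P"]]))

  writeLines(c(
    "H SYNBAD0001",
    "D nineteen values only",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/V     H/W     I/Y",
    paste0("    ", paste(1:19, collapse = "  ")),
    "//"
  ), path)
  expect_error(parse_aaindex(path), "SYNBAD0001.*19")

  writeLines(c(
    "H DUP0000001", "D one",
    "I x", paste0("    ", paste(1:10, collapse = " ")),
    paste0("    ", paste(11:20, collapse = " ")), "//",
    "H DUP0000001", "D two",
    "I x", paste0("    ", paste(1:10, collapse = " ")),
    paste0("    ", paste(11:20, collapse = " ")), "//"
  ), path)
  expect_error(parse_aaindex(path), "Duplicate")
})

test_that("AAindex serialisation round-trips values and NA masks", {
  entries <- parse_aaindex(aaindex_fixture_path())
  entries$values[[2]][c("W", "C")] <- NA
  path <- withr::local_tempfile(fileext = ".txt")
  write_aaindex(entries, path)
  back <- parse_aaindex(path)
  expect_equal(back$accession, entries$accession)
  for (k in seq_len(nrow(entries))) {
    expect_equal(back$values[[k]], entries$values[[k]])
  }
})

test_that("PCP mining screens scales by correlation with the score vector", {
  entries <- parse_aaindex(aaindex_fixture_path())
  scores <- paper_fixture("table3_scores")
  hits <- mine_pcps(entries, scores)
  expect_equal(hits$accession[1], "OLSK800101")  # top candidate property
  expect_equal(hits$r[1], 0.86, tolerance = 0.005)
  expect_true(all(hits$r > 0.5))
  expect_true(!is.unsorted(-hits$r))

  # a scale equal to the scores is always a perfect hit
  self <- tibble::tibble(
    accession = "SELF000001", description = "the scores themselves",
    n_na = 0L, values = list(scores)
  )
  expect_equal(mine_pcps(self, scores)$r, 1)

  # anti-correlated scales: excluded under signed, included under absolute
  anti <- self
  anti$accession <- "ANTI000001"
  anti$values <- list(-scores)
  expect_equal(nrow(mine_pcps(anti, scores, mode = "signed")), 0)
  expect_equal(nrow(mine_pcps(anti, scores, mode = "absolute")), 1)

  # absolute-mode hits are a superset of signed-mode hits at equal min_r
  both <- dplyr::bind_rows(entries, anti)
  for (thr in c(0.3, 0.5, 0.7)) {
    s <- mine_pcps(both, scores, min_r = thr, mode = "signed")$accession
    a <- mine_pcps(both, scores, min_r = thr, mode = "absolute")$accession
    expect_true(all(s %in% a))
  }
})

test_that("the NA filter drops whole entries while pairwise keeps them", {
  entries <- parse_aaindex(aaindex_fixture_path())
  entries$values[[1]][["A"]] <- NA
  dropped <- mine_pcps(entries, paper_fixture("table3_scores"),
                       min_r = -1.1, mode = "absolute", na_policy = "drop_entry")
  kept <- mine_pcps(entries, paper_fixture("table3_scores"),
                    min_r = -1.1, mode = "absolute", na_policy = "pairwise_complete")
  expect_equal(nrow(dropped), 4)
  expect_equal(nrow(kept), 5)
  expect_equal(kept$n_used[kept$accession == entries$accession[1]], 19L)
})

test_that("embedded reference columns are keyed correctly", {
  sc <- paper_fixture("table3_scores")
  expect_equal(sc[["I"]], 571.9)
  expect_equal(sc[["P"]], 396.4)
  expect_equal(length(sc), 20)
  expect_equal(names(sc), amino_acids())
  kytj <- paper_fixture("table3_kytj")
  expect_equal(kytj[["R"]], -4.5)
  hyd <- paper_fixture("table4_hydration")
  expect_equal(hyd[["H"]], -20)
  expect_true(all(is.na(hyd[c("E", "R", "D", "K", "P")])))
  expect_equal(sum(is.na(hyd)), 5)
  expect_error(paper_fixture("nope"), "Unknown fixture")
})
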