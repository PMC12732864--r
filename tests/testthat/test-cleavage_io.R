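test_that("a well-formed TSV parses to records in file order", {
  tab <- tiny_table(3)
  path <- write_tmp_tsv(c(
    "enzyme\tprotein_id\tp1_index\twindow",
    sprintf("%s\t%s\t%d\t%s", tab$enzyme, tab$protein_id, tab$p1_index,
            tab$window)))
  got <- read_cleavage_table(path, quiet = TRUE)
  expect_equal(nrow(got), 3)
  expect_equal(got$protein_id, tab$protein_id)
  expect_equal(got$window, tab$window)
})

test_that("write-then-read round-trips any record table", {
  for (seed in 1:3) {
    tab <- tiny_table(n = 5 + seed, enzyme = paste0("enz", seed), seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_cleavage_table(tab, path)
    got <- read_cleavage_table(path, quiet = TRUE)
    expect_equal(as.data.frame(got), as.data.frame(tab))
    expect_equal(attr(got, "window_width"), attr(tab, "window_width"))
  }
})

test_that("malformed rows are rejected with their line number", {
  path <- write_tmp_tsv(c(
    "# comment line",
    "enzyme\tprotein_id\tp1_index\twindow",
    paste("enzA", "prot1", "10", strrep("A", 30), sep = "\t"),
    paste("enzA", "prot2", "10", strrep("A", 29), sep = "\t")))
  expect_error(read_cleavage_table(path, quiet = TRUE), "line 4")

  path2 <- write_tmp_tsv(c(
    "enzyme\tprotein_id\tp1_index\twindow",
    paste("enzA", "prot1", "10", paste0(strrep("A", 29), "B"), sep = "\t")))
  expect_error(read_cleavage_table(path2, quiet = TRUE), "illegal residue")

  path3 <- write_tmp_tsv(c(
    "enzyme\tprotein_id\twindow",
    paste("enzA", "prot1", strrep("A", 30), sep = "\t")))
  expect_error(read_cleavage_table(path3, quiet = TRUE), "p1_index")

  path4 <- write_tmp_tsv(c(
    "enzyme\tprotein_id\tp1_index\twindow",
    paste("enzA", "prot1", "10", sep = "\t")))
  expect_error(read_cleavage_table(path4, quiet = TRUE), "malformed row")
})

test_that("cleavage_table enforces the window invariants", {
  expect_error(cleavage_table("enzA", "p", 1, strrep("A", 29)), "length")
  expect_error(cleavage_table("enzA", "p", 1, paste0(strrep("A", 29), "Z")),
               "illegal")
  expect_error(cleavage_table("", "p", 1, strrep("A", 30)), "nonempty")
  expect_error(cleavage_table("enzA", "p", 0, strrep("A", 30)), "p1_index")
  expect_silent(cleavage_table("enzA", "p", 1,
                               paste0(strrep("X", 5), strrep("A", 25))))
})

test_that("subsite spans resolve to the documented position counts", {
  expect_length(subsite_span("P3", "P4'")$indices, 7)
  expect_length(subsite_span("P4", "P4'")$indices, 8)
  expect_length(subsite_span("P15", "P15'")$indices, 30)
  expect_identical(subsite_span("P3", "P4p")$indices,
                   subsite_span("P3", "P4'")$indices)
})

test_that("subsite label arithmetic is centered on the scissile bond", {
  w <- window_agk_lvf()
  expect_equal(extract_subsites(w, subsite_span("P1", "P1'")), "KL")
  expect_equal(extract_subsites(w, subsite_span("P3", "P1'")), "AGKL")
  expect_equal(extract_subsites(w, subsite_span("P15", "P15'")), w)
  for (k in c(1, 2, 5, 15)) {
    sp <- subsite_span(paste0("P", k), paste0("P", k, "'"))
    got <- extract_subsites(w, sp)
    expect_equal(nchar(got), 2 * k)
    expect_equal(got, substr(w, 15 - k + 1, 15 + k))
  }
})

test_that("invalid spans and labels are rejected", {
  expect_error(parse_subsite_label("Q3"), "invalid subsite label")
  expect_error(parse_subsite_label("P0"), "invalid subsite label")
  expect_error(subsite_span("P16", "P1'"), "outside")
  expect_error(subsite_span("P1'", "P3"), "N-to-C")
  tab <- cleavage_table("enzA", "p", 1, strrep("A", 10), window_width = 5)
  expect_error(extract_subsites(tab, subsite_span("P3", "P4'")),
               "cannot index")
})

test_that("drop_x_records removes exactly the spans containing placeholders", {
  wins <- c(paste0(strrep("X", 14), strrep("A", 16)),  # X reaches P2
            paste0(strrep("X", 10), strrep("A", 20)))  # X outside P3-P4'
  tab <- cleavage_table("enzA", c("p1", "p2"), c(1, 1), wins)
  kept <- drop_x_records(tab, SPAN_P3_P4p)
  expect_equal(kept$protein_id, "p2")
})
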