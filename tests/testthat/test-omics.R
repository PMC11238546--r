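# Length normalization, rpoA scaling, class aggregation, genus ratios.

test_that("hit table parsing round-trips and handles malformed rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tevalue\tbitscore\tqlen\tslen",
               "r1\tdesB\t1e-8\t57.2\t150\t400",
               "r2\trpoA\t1e-10\t80\t300\t330"), tmp)
  hits <- parse_hit_table(tmp)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$read_length_bp[1], 150)
  expect_equal(hits$subject_length_aa[1], 400)

  # round-trip through the writer
  out <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, out)
  expect_equal(parse_hit_table(out), hits)

  # malformed row skipped with a warning in lenient mode, error otherwise
  writeLines(c("r1\tdesB\t1e-8\t57.2\t150\t400",
               "bad row without tabs",
               "r2\trpoA\t1e-10\t80\t300\t330"), tmp)
  expect_warning(h2 <- parse_hit_table(tmp), "line")
  expect_equal(nrow(h2), 2L)
  expect_error(parse_hit_table(tmp, lenient = FALSE), "malformed")

  # empty file: empty result with a warning
  writeLines(character(0), tmp)
  expect_warning(h3 <- parse_hit_table(tmp), "empty")
  expect_equal(nrow(h3), 0L)
})

test_that("E-value filtering keeps exactly the sub-threshold hits", {
  hits <- data.frame(read_id = c("a", "b"), subject_id = "desB",
                     evalue = c(1e-6, 1e-4), bitscore = 50,
                     read_length_bp = 150, subject_length_aa = 400)
  expect_equal(nrow(filter_hits(hits, 1e-5, quiet = TRUE)), 1L)
  expect_equal(nrow(filter_hits(hits, 1e-3, quiet = TRUE)), 2L)
  expect_equal(attr(filter_hits(hits, 1e-5, quiet = TRUE), "n_removed"), 1L)
})

test_that("length normalization follows read/(3 x subject) exactly", {
  expect_equal(length_normalized_copies(300, 100), 1.0)
  expect_equal(length_normalized_copies(150, 400), 0.125)
  expect_error(length_normalized_copies(150, 0), "subject length")
  # 20-hit fixture against a spreadsheet-style sum
  set.seed(7)
  L <- sample(50:300, 20, replace = TRUE)
  S <- sample(100:700, 20, replace = TRUE)
  manual <- 0
  for (i in 1:20) manual <- manual + L[i] / (3 * S[i])
  expect_equal(sum(length_normalized_copies(L, S)), manual)
})

test_that("orthologue counting sums copies and flags missing rpoA", {
  hits <- data.frame(read_id = c("a", "b"), subject_id = "desB",
                     evalue = 1e-8, bitscore = 50,
                     read_length_bp = c(600, 600),
                     subject_length_aa = 400)
  tab <- count_orthologues(hits)
  expect_equal(unname(tab["sample1", "desB"]), 1.0)
  expect_error(normalize_by_rpoa(tab), "rpoA")
})

test_that("duplicate read ids keep the lowest E-value with a warning", {
  hits <- data.frame(read_id = c("a", "a"), subject_id = c("desB", "desD"),
                     evalue = c(1e-8, 1e-6), bitscore = 50,
                     read_length_bp = 300, subject_length_aa = 100)
  expect_warning(tab <- count_orthologues(hits), "duplicate")
  expect_equal(unname(tab[1, "desB"]), 1.0)
  expect_equal(unname(tab[1, "desD"]), 0)
})

test_that("rpoA normalization gives copies per genome and is depth invariant", {
  hits <- data.frame(read_id = c("a", "b", "c"),
                     subject_id = c("desB", "desB", "rpoA"),
                     evalue = 1e-8, bitscore = 50,
                     read_length_bp = c(600, 600, 495),
                     subject_length_aa = c(100, 100, 330))
  tab <- count_orthologues(hits)
  norm <- normalize_by_rpoa(tab)
  expect_equal(unname(norm[1, "desB"]), 4.0 / 0.5)

  # exact duplication of every read changes nothing after normalization
  dup <- hits
  dup$read_id <- paste0(dup$read_id, "_copy")
  norm2 <- normalize_by_rpoa(count_orthologues(rbind(hits, dup)))
  # marker_copies (an attribute) legitimately doubles; the abundances
  # themselves must be identical
  expect_equal(norm2[, "desB"], norm[, "desB"])
  expect_equal(dimnames(norm2), dimnames(norm))
})

test_that("class aggregation is an exact sum of members", {
  tab <- structure(matrix(c(1.0, 0.5, 0.3), nrow = 1,
                          dimnames = list("s1", c("desB", "desD", "entA"))),
                   class = c("gene_abundance", "matrix", "array"),
                   normalized = TRUE)
  cm <- data.frame(orthologue = c("desB", "desD", "entA", "vibA"),
                   class = c("hydroxamate", "hydroxamate", "catecholate",
                             "carboxylate"))
  agg <- aggregate_by_class(tab, cm)
  expect_equal(unname(agg[1, "hydroxamate"]), 1.5)
  expect_equal(unname(agg[1, "catecholate"]), 0.3)
  expect_equal(unname(agg[1, "carboxylate"]), 0)  # empty class -> 0
  cm_bad <- cm[cm$orthologue != "entA", ]
  expect_error(aggregate_by_class(tab, cm_bad), "entA")
})

test_that("genus desB/rpoA ratios handle zero-desB and absent-marker genera", {
  hits <- data.frame(
    read_id = sprintf("r%d", 1:4),
    subject_id = c("desB", "rpoA", "rpoA", "desB"),
    evalue = 1e-8, bitscore = 50,
    read_length_bp = c(300, 300, 300, 300),
    subject_length_aa = c(100, 100, 100, 100),
    genus = c("Streptomyces", "Streptomyces", "Arthrobacter", "Nocardia")
  )
  rat <- genus_marker_ratio(hits)
  str_row <- rat[rat$genus == "Streptomyces", ]
  expect_equal(str_row$ratio, 1.0)
  expect_equal(rat[rat$genus == "Arthrobacter", "ratio"], 0.0)
  noc <- rat[rat$genus == "Nocardia", ]
  expect_true(is.na(noc$ratio))
  expect_equal(noc$flag, "marker absent")
})

test_that("substrate comparison reports fold and Welch t consistently", {
  a <- structure(matrix(c(2, 2, 2), ncol = 1,
                        dimnames = list(NULL, "desB")),
                 class = c("gene_abundance", "matrix", "array"))
  b <- a
  res <- compare_substrates(a, b)
  expect_equal(res$fold, 1.0)
  expect_equal(res$p, 1.0)  # identical zero-variance groups

  # hand-computed Welch t on a 3-vs-3 fixture
  x <- c(1.2, 1.5, 1.1); y <- c(0.7, 0.6, 0.9)
  ta <- structure(matrix(x, ncol = 1, dimnames = list(NULL, "g")),
                  class = c("gene_abundance", "matrix", "array"))
  tb <- structure(matrix(y, ncol = 1, dimnames = list(NULL, "g")),
                  class = c("gene_abundance", "matrix", "array"))
  res2 <- compare_substrates(ta, tb)
  t_manual <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(res2$t, t_manual)
  expect_equal(res2$fold, mean(x) / mean(y))
})
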