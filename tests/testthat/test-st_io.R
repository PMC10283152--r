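test_that("dense TSV with coordinate-encoding spot ids parses correctly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("spot\tGENE1\tGENE2",
               "1x1\t0\t5",
               "1x2\t3\t1",
               "2x1\t2\t0"), f)
  sc <- read_counts(f, "dense-tsv")
  expect_equal(dim(sc$counts), c(3, 2))
  expect_equal(unname(sc$coords), cbind(c(1, 1, 2), c(1, 2, 1)))
  expect_equal(sc$gene_names, c("GENE1", "GENE2"))
  expect_equal(unname(sc$counts[, "GENE1"]), c(0, 3, 2))
})

test_that("malformed inputs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_error(read_counts(f, "dense-tsv"), "empty")

  writeLines(c("spot\tG1", "1x1\t2", "badid\t3"), f)
  expect_error(read_counts(f, "dense-tsv"), "badid")

  writeLines(c("spot\tG1", "1x1\t2.5", "1x2\t3"), f)
  expect_error(read_counts(f, "dense-tsv"), "non-integer")

  expect_error(read_counts(file.path(tempdir(), "nope.tsv"), "dense-tsv"),
               "not found")
})

test_that("dense TSV round-trip reproduces a simulated matrix exactly", {
  co <- simulate_cohort(3, 2, spec_null = sim_spec(n_spots = 25), seed = 9)
  counts <- simulate_counts(co$values + 4, co$coords, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  fc <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts, f, coords_path = fc)
  back <- read_counts(f, "dense-tsv", coords_path = fc)
  expect_equal(back$counts, counts$counts)
  expect_equal(back$coords, counts$coords)
})

test_that("MatrixMarket triplet route matches the dense route", {
  co <- simulate_cohort(4, 0, spec_null = sim_spec(n_spots = 25), seed = 2)
  counts <- simulate_counts(co$values + 4, co$coords, seed = 2)
  d <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(counts$counts, sparse = TRUE),
                  file.path(d, "m.mtx"))
  writeLines(counts$gene_names, file.path(d, "genes.txt"))
  writeLines(counts$spot_ids, file.path(d, "spots.txt"))
  write.table(data.frame(spot_id = counts$spot_ids,
                         x1 = counts$coords[, 1], x2 = counts$coords[, 2]),
              file.path(d, "coords.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_counts(file.path(d, "m.mtx"), "mtx-triplet",
                      coords_path = file.path(d, "coords.tsv"),
                      genes_path = file.path(d, "genes.txt"),
                      spots_path = file.path(d, "spots.txt"))
  expect_equal(back$counts, counts$counts)

  writeLines(counts$gene_names[-1], file.path(d, "genes.txt"))
  expect_error(read_counts(file.path(d, "m.mtx"), "mtx-triplet",
                           coords_path = file.path(d, "coords.tsv"),
                           genes_path = file.path(d, "genes.txt"),
                           spots_path = file.path(d, "spots.txt")),
               "do not match")
})

make_toy_counts <- function(counts, genes) {
  n <- nrow(counts)
  spatial_counts(counts, cbind(seq_len(n), rep(1, n)),
                 gene_names = genes,
                 spot_ids = paste0("s", seq_len(n)))
}

test_that("qc_filter drops spike-ins, mitochondrial genes and rare genes", {
  sc <- make_toy_counts(
    cbind(c(100, 400), c(1, 1), c(1, 2), c(5, 5), c(3, 4)),
    c("ERCC-00096", "G_low", "G_edge", "MT-CO1", "KRT14"))
  out <- qc_filter(sc)
  # high-count spike-in still removed; total 2 removed; total 3 retained
  expect_equal(out$gene_names, c("G_edge", "KRT14"))
  expect_setequal(out$qc_log$gene, c("ERCC-00096", "G_low", "MT-CO1"))
  expect_equal(out$qc_log$reason[out$qc_log$gene == "ERCC-00096"],
               "prefix:ERCC")
  expect_equal(out$qc_log$reason[out$qc_log$gene == "G_low"],
               "total_count<3")
  # spots unchanged
  expect_equal(out$spot_ids, sc$spot_ids)
})

test_that("qc_filter is an identity on clean matrices and is idempotent", {
  sc <- make_toy_counts(cbind(c(2, 3), c(10, 0)), c("A", "B"))
  once <- qc_filter(sc)
  expect_equal(once$counts, sc$counts)
  twice <- qc_filter(once)
  expect_equal(twice$counts, once$counts)
  expect_equal(twice$gene_names, once$gene_names)

  expect_error(qc_filter(make_toy_counts(cbind(c(1, 1)), "MT-ND1")),
               "every gene")
})

test_that("Anscombe normalisation matches hand computation", {
  # zero count -> 2*sqrt(3/8) regardless of library size
  sc <- make_toy_counts(cbind(c(4, 8), c(0, 0)), c("A", "B"))
  norm <- normalize_and_stabilize(sc)
  expect_equal(unname(norm$values[, "B"]), rep(2 * sqrt(3 / 8), 2),
               tolerance = 1e-12)
  # hand evaluation: lib sizes 4 and 8, median 6
  expect_equal(unname(norm$values[, "A"]),
               c(2 * sqrt(6 * 4 / 4 + 3 / 8), 2 * sqrt(6 * 8 / 8 + 3 / 8)),
               tolerance = 1e-12)

  # equal library sizes: scaling cancels, value = 2*sqrt(c + 3/8)
  sc2 <- make_toy_counts(cbind(c(1, 4), c(6, 3)), c("A", "B"))
  norm2 <- normalize_and_stabilize(sc2)
  expect_equal(unname(norm2$values), 2 * sqrt(unname(sc2$counts) + 3 / 8),
               tolerance = 1e-12)

  # zero library size is an error naming the spot
  sc3 <- make_toy_counts(cbind(c(0, 5)), "A")
  expect_error(normalize_and_stabilize(sc3), "s1")
})

test_that("normalisation is monotone within each spot", {
  set.seed(4)
  counts <- matrix(rpois(200, 5), 10, 20)
  sc <- spatial_counts(counts, cbind(seq_len(10), 0 * 1:10 + rnorm(10)))
  norm <- normalize_and_stabilize(sc)
  for (i in seq_len(10)) {
    ord <- order(counts[i, ])
    expect_true(all(diff(norm$values[i, ord]) >= 0))
    # strict where counts strictly increase
    strict <- diff(counts[i, ord]) > 0
    expect_true(all(diff(norm$values[i, ord])[strict] > 0))
  }
})
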