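test_that("read_counts parses MTX + sidecars, including hand-parsed fixture", {
  dir <- withr::local_tempdir()
  # 1-gene x 1-spot identity case
  write_mtx_by_hand(file.path(dir, "m1.mtx"), 1, 1, data.frame(i = 1, j = 1, x = 5))
  write_sidecars(dir, "gA", "BC1")
  m <- read_counts(file.path(dir, "m1.mtx"), file.path(dir, "features.tsv"),
                   file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(m$counts), matrix(5, 1, 1,
               dimnames = list("gA", "BC1")))

  # 3 genes x 2 spots, 4 nonzeros, checked against an independent
  # line-by-line parse of the same file
  entries <- data.frame(i = c(1, 2, 3, 3), j = c(1, 2, 1, 2), x = c(7, 1, 2, 9))
  p <- write_mtx_by_hand(file.path(dir, "m2.mtx"), 3, 2, entries)
  write_sidecars(dir, c("gA", "gB", "gC"), c("BC1", "BC2"))
  m2 <- read_counts(p, file.path(dir, "features.tsv"), file.path(dir, "barcodes.tsv"))
  oracle <- matrix(0, 3, 2)
  for (ln in readLines(p)[-(1:2)]) {
    v <- as.numeric(strsplit(ln, " ")[[1]])
    oracle[v[1], v[2]] <- v[3]
  }
  expect_equal(unname(as.matrix(m2$counts)), oracle)
  expect_equal(m2$gene_ids, c("gA", "gB", "gC"))
})

test_that("read_counts rejects inconsistent sidecars and malformed MTX", {
  dir <- withr::local_tempdir()
  write_mtx_by_hand(file.path(dir, "m.mtx"), 3, 2,
                    data.frame(i = 1, j = 1, x = 1))
  write_sidecars(dir, c("gA", "gB", "gC"), c("BC1", "BC2", "BC3"))
  expect_error(
    read_counts(file.path(dir, "m.mtx"), file.path(dir, "features.tsv"),
                file.path(dir, "barcodes.tsv")),
    "barcodes file has 3"
  )
  writeLines(c("not a matrix market header", "3 2 1", "1 1 1"),
             file.path(dir, "bad.mtx"))
  expect_error(
    read_counts(file.path(dir, "bad.mtx"), file.path(dir, "features.tsv"),
                file.path(dir, "barcodes.tsv")),
    "malformed MatrixMarket"
  )
})

test_that("gzipped inputs are auto-detected by magic bytes, not extension", {
  dir <- withr::local_tempdir()
  # gzipped file with a plain-text extension
  gz_path <- file.path(dir, "barcodes.tsv")  # deliberately no .gz suffix
  con <- gzfile(gz_path, "wt"); writeLines(c("BC1", "BC2"), con); close(con)
  write_mtx_by_hand(file.path(dir, "m.mtx"), 1, 2,
                    data.frame(i = 1, j = 2, x = 3))
  writeLines("gA\tgA\tGene Expression", file.path(dir, "features.tsv"))
  m <- read_counts(file.path(dir, "m.mtx"), file.path(dir, "features.tsv"), gz_path)
  expect_equal(m$barcodes, c("BC1", "BC2"))
})

test_that("write_counts / read_counts round-trips a random sparse fixture", {
  dir <- withr::local_tempdir()
  withr::with_seed(7, {
    dense <- matrix(rbinom(15 * 9, 1, 0.3) * rpois(15 * 9, 4), 15, 9)
  })
  m <- spot_matrix(dense, gene_ids = sprintf("g%02d", 1:15),
                   barcodes = sprintf("BC%02d", 1:9))
  write_counts(m, dir)
  m2 <- read_counts(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                    file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_identical(m2$barcodes, m$barcodes)
})

test_that("read_positions handles both dialects and validates in_tissue", {
  dir <- withr::local_tempdir()
  body <- c("BC1,1,0,0,100.5,200.5", "BC2,0,0,1,110.5,210.5")
  p1 <- file.path(dir, "legacy.csv"); writeLines(body, p1)
  p2 <- file.path(dir, "headered.csv")
  writeLines(c("barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
               body), p2)
  t1 <- read_positions(p1)
  t2 <- read_positions(p2)
  expect_identical(t1, t2)
  expect_equal(t1$barcode, c("BC1", "BC2"))
  expect_equal(t1$pixel_x, c(200.5, 210.5))  # pxl_col -> x
  expect_equal(t1$pixel_y, c(100.5, 110.5))  # pxl_row -> y

  p3 <- file.path(dir, "bad.csv")
  writeLines("BC1,2,0,0,1,1", p3)
  expect_error(read_positions(p3), "in_tissue must be 0 or 1")
})

test_that("attach_positions filters out-of-tissue spots and passes coords through", {
  dir <- withr::local_tempdir()
  m <- spot_matrix(matrix(1:6, 2, 3), gene_ids = c("gA", "gB"),
                   barcodes = c("BC1", "BC2", "BC3"))
  pos <- file.path(dir, "pos.csv")
  writeLines(c("BC1,1,0,0,20,10", "BC2,0,0,1,40,30", "BC3,1,1,0,60,50"), pos)
  p <- read_positions(pos)
  out <- attach_positions(m, p)
  expect_equal(out$barcodes, c("BC1", "BC3"))
  expect_equal(unname(out$coords), cbind(c(10, 50), c(20, 60)))

  # missing barcode
  m2 <- spot_matrix(matrix(1:2, 2, 1), gene_ids = c("gA", "gB"), barcodes = "BCX")
  expect_error(attach_positions(m2, p), "absent from positions")

  # duplicate coordinates among kept spots
  writeLines(c("BC1,1,0,0,20,10", "BC2,1,0,1,40,30", "BC3,1,1,0,20,10"), pos)
  expect_error(attach_positions(m, read_positions(pos)), "duplicate")
})

test_that("qc_filter uses strict inequalities and matches a loop oracle", {
  # boundary spots: exactly 500 UMI / exactly 300 genes must be removed
  n_genes <- 600
  counts <- matrix(0, n_genes, 4)
  counts[1:400, 1] <- 1; counts[1, 1] <- 101          # 500 UMI, 400 genes -> out
  counts[1:301, 2] <- 1; counts[1, 2] <- 201          # 501 UMI, 301 genes -> kept
  counts[1:300, 3] <- 2                               # 600 UMI, 300 genes -> out
  counts[1:320, 4] <- 2                               # 640 UMI, 320 genes -> kept
  m <- spot_matrix(counts, gene_ids = sprintf("g%03d", 1:n_genes),
                   barcodes = paste0("BC", 1:4))
  f <- qc_filter(m)
  expect_equal(f$barcodes, c("BC2", "BC4"))
  expect_equal(qc_report(f)$n_removed, 2)

  # 100 random spots vs brute-force per-spot loop
  withr::with_seed(11, {
    cm <- matrix(rpois(50 * 100, 12), 50, 100)
  })
  m2 <- spot_matrix(cm, gene_ids = sprintf("g%02d", 1:50),
                    barcodes = sprintf("BC%03d", 1:100))
  min_umi <- 600; min_genes <- 48
  keep_oracle <- logical(100)
  for (s in 1:100) {
    keep_oracle[s] <- sum(cm[, s]) > min_umi && sum(cm[, s] > 0) > min_genes
  }
  f2 <- qc_filter(m2, min_umi, min_genes)
  expect_equal(f2$barcodes, sprintf("BC%03d", which(keep_oracle)))

  # empty result is valid, and zero-spot input passes through
  empty <- qc_filter(m2, 1e9, 1e9)
  expect_equal(ncol(empty$counts), 0L)
  expect_equal(ncol(qc_filter(empty)$counts), 0L)
})

test_that("qc_filter is monotone in its thresholds; (0,0) keeps spots with any signal", {
  withr::with_seed(3, cm <- matrix(rbinom(30 * 40, 1, 0.4) * rpois(1200, 3), 30, 40))
  cm[, 1] <- 0  # an all-zero spot
  m <- spot_matrix(cm, gene_ids = sprintf("g%02d", 1:30),
                   barcodes = sprintf("BC%02d", 1:40))
  prev <- NULL
  for (th in list(c(0, 0), c(5, 2), c(20, 5), c(60, 10))) {
    kept <- qc_filter(m, th[1], th[2])$barcodes
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  at0 <- qc_filter(m, 0, 0)$barcodes
  expect_setequal(at0, m$barcodes[colSums(cm) >= 1 & colSums(cm > 0) >= 1])
})

test_that("normalize_spots: median scaling, log1p, zero pattern preserved", {
  # equal totals -> pure log1p
  cm <- matrix(c(4, 6, 6, 4), 2, 2)
  m <- normalize_spots(spot_matrix(cm, gene_ids = c("gA", "gB"),
                                   barcodes = c("BC1", "BC2")))
  expect_equal(as.matrix(m$normalized), log1p(as.matrix(m$counts)),
               ignore_attr = TRUE)

  # totals 100 and 300, median 200 -> scale factors 2 and 2/3
  cm2 <- matrix(c(40, 60, 100, 200), 2, 2)
  m2 <- normalize_spots(spot_matrix(cm2, gene_ids = c("gA", "gB"),
                                    barcodes = c("BC1", "BC2")))
  pre_log <- expm1(as.matrix(m2$normalized))
  expect_equal(unname(colSums(pre_log)), c(200, 200))
  expect_equal(unname(pre_log[, 1]), c(80, 120))  # hand: 2.0 * (40, 60)

  # zero-total spot errors; zero pattern preserved on sparse input
  cm3 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_error(normalize_spots(spot_matrix(cm3, gene_ids = c("gA", "gB"),
                                           barcodes = c("BC1", "BC2"))),
               "zero total")
  withr::with_seed(5, sp <- matrix(rbinom(200, 1, 0.3) * rpois(200, 9) +
                                     (row(matrix(0,10,20))==1), 10, 20))
  ms <- normalize_spots(spot_matrix(sp, gene_ids = sprintf("g%02d", 1:10),
                                    barcodes = sprintf("BC%02d", 1:20)))
  expect_equal(as.matrix(ms$normalized) == 0, as.matrix(ms$counts) == 0,
               ignore_attr = TRUE)
  expect_equal(dim(ms$normalized), dim(ms$counts))
})

test_that("read_proportions validates and renormalizes rows", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "props.csv")
  writeLines(c("barcode,Fibroblast,Macrophage",
               "BC1,0.5,0.5",
               "BC2,0.5000004,0.5000004"), p)
  pt <- read_proportions(p)
  expect_equal(unname(pt$proportions["BC1", ]), c(0.5, 0.5))
  expect_equal(sum(pt$proportions["BC2", ]), 1)

  writeLines(c("barcode,Fibroblast,Macrophage", "BC1,0.2,0.2"), p)
  expect_error(read_proportions(p), "deviate")
  writeLines(c("barcode,Fibroblast,Macrophage", "BC1,-0.1,1.1"), p)
  expect_error(read_proportions(p), "\\[0, 1\\]")
})
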