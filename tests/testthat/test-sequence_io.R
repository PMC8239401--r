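test_that("one-hot encoding follows the (A,C,G,T) channel convention", {
  m <- one_hot_encode("ACGT")
  expect_equal(unname(m), diag(4))
  expect_equal(colnames(m), c("A", "C", "G", "T"))
  expect_equal(unname(one_hot_encode("N")), matrix(0, 1, 4))
  expect_equal(one_hot_encode("acgt"), one_hot_encode("ACGT"))
  expect_error(one_hot_encode("ACXT"), "position 3")
})

test_that("one-hot row mass counts non-N bases and decoding round-trips", {
  set.seed(41)
  for (i in 1:20) {
    l <- sample(10:60, 1)
    s <- random_dna(l)
    m <- one_hot_encode(s)
    expect_equal(sum(m), l)                       # N-free: one hot per row
    expect_identical(decode_onehot(m), s)         # argmax round-trip
  }
  s <- "ACGNNT"
  m <- one_hot_encode(s)
  expect_equal(sum(m), 4)
  expect_identical(decode_onehot(m), s)
})

test_that("labelled FASTA reading enforces lengths and labels", {
  fa <- tempfile(fileext = ".fa")
  set.seed(5)
  seqs <- Biostrings::DNAStringSet(c(a = random_dna(500), b = random_dna(500)))
  Biostrings::writeXStringSet(seqs, fa)
  lab <- tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t0"), lab)

  d <- read_labeled_fasta(fa, lab)
  expect_s3_class(d, "tss_dataset")
  expect_equal(d$n, 2)
  expect_equal(d$l, 500)
  expect_equal(d$ids, c("a", "b"))
  expect_equal(d$labels, c(1L, 0L))
  expect_identical(d$sequences, unname(as.character(seqs)))

  # lower-case records are upper-cased
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y", "ggcc"), fa2)
  d2 <- read_labeled_fasta(fa2, c(x = 1, y = 0))
  expect_identical(d2$sequences, c("ACGT", "GGCC"))

  # length mismatch is fatal
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">x", strrep("A", 500), ">y", strrep("A", 499)), fa3)
  expect_error(read_labeled_fasta(fa3, c(x = 1, y = 0)), "length")

  # missing label names the id
  expect_error(read_labeled_fasta(fa, c(a = 1)), "b")
})

test_that("window extraction is 0-based half-open around the midpoint", {
  set.seed(6)
  contig <- random_dna(10000)
  genome <- Biostrings::DNAStringSet(c(chrA = contig))
  iv <- data.frame(chrom = "chrA", start = 1000, end = 1001,
                   id = c("m1000"))

  w <- extract_windows(iv, genome, flank = 250)
  expect_equal(w$windows$start, 750)
  expect_equal(w$windows$end, 1250)
  expect_equal(Biostrings::width(w$sequences), 500)
  expect_identical(as.character(w$sequences[[1]]), substr(contig, 751, 1250))

  w6 <- extract_windows(iv, genome, flank = 300)
  expect_equal(w6$windows$start, 700)
  expect_equal(w6$windows$end, 1300)
  expect_equal(Biostrings::width(w6$sequences), 600)

  # wider record: centre taken as midpoint
  wc <- extract_windows(data.frame(chrom = "chrA", start = 700, end = 1300),
                        genome, flank = 250)
  expect_equal(wc$windows$midpoint, 1000)

  # boundary windows are dropped with a message, deficit equals drop count
  ivb <- data.frame(chrom = "chrA", start = c(100, 1000), end = c(101, 1001),
                    id = c("edge", "ok"))
  expect_message(wb <- extract_windows(ivb, genome, flank = 250), "dropped")
  expect_equal(nrow(wb$windows), 1)
  expect_equal(wb$windows$id, "ok")

  expect_error(extract_windows(data.frame(chrom = "chrZ", start = 1, end = 2),
                               genome, flank = 10), "chrZ")
})

test_that("BED round-trip: generated midpoints recover the written windows", {
  dir <- tempfile()
  data <- generate_dataset(synthetic_spec(n_promoter = 4, n_enhancer = 4,
                                          seed = 9), out_dir = dir)
  genome <- Biostrings::DNAStringSet(
    c(synth1 = paste(data$sequences, collapse = "")))
  w <- extract_windows(file.path(dir, "midpoints.bed"), genome, flank = 250)
  expect_equal(nrow(w$windows), 8)
  expect_identical(unname(as.character(w$sequences)), data$sequences)
  expect_identical(names(w$sequences), data$ids)
})
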