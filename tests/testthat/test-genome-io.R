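# I/O: genome records, GFF3 round trips, tabular readers.

test_that("genome_record assigns 0-based consecutive ordinals by position", {
  gr <- genome_record(
    "g1",
    features = tibble::tibble(
      gene_id = c("b", "a", "c"), replicon_id = "chr",
      start = c(500, 100, 900), end = c(700, 300, 950), strand = "+"
    ),
    replicons = tibble::tibble(replicon_id = "chr", length = 1000)
  )
  f <- gr$features
  expect_equal(f$ordinal[match(c("a", "b", "c"), f$gene_id)], c(0L, 1L, 2L))
})

test_that("ordinals are invariant to the input row order", {
  feats <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8), replicon_id = "chr",
    start = (1:8) * 100, end = (1:8) * 100 + 50, strand = "+"
  )
  reps <- tibble::tibble(replicon_id = "chr", length = 2000)
  base <- genome_record("g", feats, reps)$features
  for (i in 1:10) {
    set.seed(i)
    perm <- genome_record("g", feats[sample(8), ], reps)$features
    expect_equal(dplyr::arrange(perm, gene_id), dplyr::arrange(base, gene_id))
  }
})

test_that("genome_record validates inputs", {
  reps <- tibble::tibble(replicon_id = "chr", length = 1000)
  feat <- function(...) tibble::tibble(..., strand = "+")
  expect_error(
    genome_record("g", feat(gene_id = c("a", "a"), replicon_id = "chr",
                            start = c(1, 50), end = c(20, 70)), reps),
    "duplicate gene_id")
  expect_error(
    genome_record("g", feat(gene_id = "a", replicon_id = "chr",
                            start = 30, end = 10), reps),
    "start must be <= end")
  expect_error(
    genome_record("g", feat(gene_id = "a", replicon_id = "chr",
                            start = 990, end = 1100), reps),
    "exceeds replicon length")
  expect_error(
    genome_record("g", feat(gene_id = "a", replicon_id = "plasmid",
                            start = 1, end = 10), reps),
    "unknown replicon")
})

test_that("write_gff3/read_gff3 round-trips features and circularity", {
  gr <- genome_record(
    "rt",
    features = tibble::tibble(
      gene_id = c("x1", "x2", "y1"),
      replicon_id = c("chr", "chr", "pA"),
      start = c(10, 400, 5), end = c(200, 600, 80),
      strand = c("+", "-", "+"),
      product = c("sulfurtransferase", NA, "hypothetical protein")
    ),
    replicons = tibble::tibble(replicon_id = c("chr", "pA"),
                               length = c(1000, 100),
                               circular = c(FALSE, TRUE))
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gr, path)
  back <- suppressWarnings(read_gff3(path, genome_id = "rt"))
  expect_equal(
    dplyr::arrange(back$features, gene_id),
    dplyr::arrange(gr$features, gene_id)
  )
  expect_equal(
    dplyr::arrange(back$replicons, replicon_id),
    dplyr::arrange(gr$replicons, replicon_id)
  )
})

test_that("read_gff3 rejects malformed lines with a line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr 1 1000",
               "chr\tsrc\tCDS\t1\t90\t.\t+\t0\tID=a",
               "chr\tsrc\tCDS\t1\t90"), path)
  expect_error(read_gff3(path), "line 4")
})

test_that("read_gff3 infers replicon length for orphan replicons with warning", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t11\t250\t.\t+\t0\tID=a"), path)
  expect_warning(gr <- read_gff3(path), "sequence-region")
  expect_equal(gr$replicons$length, 250)
})

test_that("FASTA round-trips", {
  seqs <- c(chr = "ACGTACGTGGCC", pA = "TTTTAAAA")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})

test_that("read_hits_tsv computes qcov from qcovhsp or length/qlen", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    # 14 columns: qcovhsp = 75 (percent) wins over length/qlen
    "q1\ts1\t60.0\t100\t0\t0\t1\t100\t1\t100\t1e-30\t200\t400\t75",
    # 13 columns: qcov = length/qlen = 300/600 = 0.50
    "q2\ts2\t55.0\t300\t0\t0\t1\t300\t1\t300\t1e-20\t150\t600"
  ), path)
  h <- read_hits_tsv(path)
  expect_equal(h$qcov, c(0.75, 0.50))
  expect_equal(h$subject_family, c("unknown", "unknown"))
})

test_that("read_hits_tsv applies the family map and warns on missing qcov", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\tdndC_ref\t60.0\t100\t0\t0\t1\t100\t1\t100\t1e-30\t200\t200\t80",
    # 12 columns only: no qlen/qcovhsp -> qcov NA
    "q2\tother\t55.0\t300\t0\t0\t1\t300\t1\t300\t1e-20\t150"
  ), path)
  expect_warning(h <- read_hits_tsv(path, c(dndC_ref = "dndC")), "qcov")
  expect_equal(h$subject_family, c("dndC", "unknown"))
  expect_true(is.na(h$qcov[2]))
})

test_that("read_hits_tsv reports parse errors with a row index", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t60\t100\t0\t0\t1\t100\t1\t100\t1e-30\t200",
               "q2\ts2\t60\t100"), path)
  expect_error(read_hits_tsv(path), "row 2")
  writeLines("q1\ts1\tsixty\t100\t0\t0\t1\t100\t1\t100\t1e-30\t200", path)
  expect_error(read_hits_tsv(path), "non-numeric pident")
  writeLines("q1\ts1\t60\t700\t0\t0\t1\t100\t1\t100\t1e-30\t200\t600\t120",
             path)
  expect_error(read_hits_tsv(path), "qcov outside")
})

test_that("read_taxonomy_tsv fills ranks and flags eligibility", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tgenus",
               "g1\tStreptomyces",
               "g2\t"), path)
  tx <- read_taxonomy_tsv(path)
  expect_true(all(c("phylum", "class", "order", "family", "genus",
                    "species") %in% names(tx)))
  expect_equal(tx$correlation_eligible, c(TRUE, FALSE))
})

test_that("read_prophage_tsv splits protein lists and invents region ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\treplicon_id\tstart\tend\tprotein_ids",
               "g1\tchr\t100\t900\tp1,p2 ,p3",
               "g1\tchr\t2000\t2500\t"), path)
  pr <- read_prophage_tsv(path)
  expect_equal(pr$protein_ids[[1]], c("p1", "p2", "p3"))
  expect_length(pr$protein_ids[[2]], 0)
  expect_equal(pr$region_id, c("g1|chr:100-900", "g1|chr:2000-2500"))
})

test_that("read_sites_tsv validates strand and recodes motif classes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("replicon_id\tposition\tstrand\tmotif_class",
               "chr\t10\t+\tGAAC",
               "chr\t55\t-\tGpsTTC"), path)
  st <- read_sites_tsv(path)
  expect_equal(st$motif_class, c("GpsAAC", "GpsTTC"))
  expect_equal(st$dinucleotide, c("d(GpsA)", "d(GpsT)"))
  writeLines(c("replicon_id\tposition\tstrand\tmotif_class",
               "chr\t10\tfwd\tGAAC"), path)
  expect_error(read_sites_tsv(path), "invalid strand")
})

test_that("read_de_tsv and read_competition_csv validate ranges", {
  de <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tfdr", "g1\t2.5\t1.2"), de)
  expect_error(read_de_tsv(de), "fdr")
  cc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,replicate,count_a,total", "0,1,52,100", "1,1,48,100"), cc)
  s <- read_competition_csv(cc)
  expect_equal(s$fraction_a, c(0.52, 0.48))
  writeLines(c("time,replicate,count_a,total", "0,1,0,0"), cc)
  expect_error(read_competition_csv(cc), "sum to 0")
})

test_that("readers abort with the missing column named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tstart\tend\tprotein_ids", "g\t1\t2\tp"), path)
  expect_error(read_prophage_tsv(path), "replicon_id")
})
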