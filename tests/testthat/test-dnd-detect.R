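# Dnd screening thresholds, adjacency cluster calling, R-M linkage.

make_hit <- function(query_id, family, evalue = 1e-50, bitscore = 200,
                     qcov = 0.9, subject_id = paste0(family, "_ref")) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 subject_family = family, pident = 50, aln_length = 300,
                 evalue = evalue, bitscore = bitscore, qlen = 400,
                 qcov = qcov)
}

test_that("e-value cutoff is strict and coverage cutoff inclusive", {
  hits <- dplyr::bind_rows(
    make_hit("at_cutoff", "dndC", evalue = 1e-10),
    make_hit("below_cutoff", "dndC", evalue = 0.99e-10),
    make_hit("cov_at", "dndD", qcov = 0.5),
    make_hit("cov_below", "dndD", qcov = 0.499),
    make_hit("na_cov", "dndE", qcov = NA_real_)
  )
  a <- assign_dnd_genes(hits)
  expect_setequal(a$gene_id, c("below_cutoff", "cov_at"))
})

test_that("non-dnd families are ignored", {
  a <- assign_dnd_genes(make_hit("q", "recA"))
  expect_equal(nrow(a), 0)
})

test_that("best hit wins by bitscore, then e-value, then family name", {
  hits <- dplyr::bind_rows(
    make_hit("p", "dndC", bitscore = 250),
    make_hit("p", "dndD", bitscore = 180),
    make_hit("q", "dndE", bitscore = 100, evalue = 1e-30),
    make_hit("q", "dndF", bitscore = 100, evalue = 1e-40),
    make_hit("r", "dndH", bitscore = 100, evalue = 1e-30),
    make_hit("r", "dndG", bitscore = 100, evalue = 1e-30)
  )
  a <- assign_dnd_genes(hits)
  expect_equal(a$family[a$gene_id == "p"], "dndC")
  expect_equal(a$family[a$gene_id == "q"], "dndF")
  expect_equal(a$family[a$gene_id == "r"], "dndG")  # lexicographic tie-break
})

test_that("strictly adjacent pairs are called at max_gap = 0", {
  g <- toy_genome(10)
  a <- toy_assignments(c(3, 4), c("dndC", "dndD"))
  calls <- call_adjacent_clusters(g, a, max_gap = 0)
  expect_equal(calls$cluster_type, "dndCD")
  expect_equal(calls$ordinal_first, 3L)
  expect_equal(calls$ordinal_last, 4L)
  # one intervening CDS: no call at 0, call at max_gap = 1
  a2 <- toy_assignments(c(3, 5), c("dndC", "dndD"))
  expect_equal(nrow(call_adjacent_clusters(g, a2, max_gap = 0)), 0)
  c2 <- call_adjacent_clusters(g, a2, max_gap = 1)
  expect_equal(c2$cluster_type, "dndCD")
  expect_equal(c(c2$ordinal_first, c2$ordinal_last), c(3L, 5L))
})

test_that("member order within the window is unconstrained", {
  g <- toy_genome(10)
  a <- toy_assignments(c(2, 3, 4, 5), c("dndE", "dndC", "dndB", "dndD"))
  calls <- call_adjacent_clusters(g, a)
  expect_equal(calls$cluster_type, "dndBCDE")
  expect_equal(c(calls$ordinal_first, calls$ordinal_last), c(2L, 5L))
})

test_that("duplicated families within a window block the call", {
  g <- toy_genome(10)
  # C C D: only the C,D pair at ordinals 1-2 forms a cluster
  a <- toy_assignments(c(0, 1, 2), c("dndC", "dndC", "dndD"))
  calls <- call_adjacent_clusters(g, a)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$ordinal_first, calls$ordinal_last), c(1L, 2L))
})

test_that("calls do not reuse genes (greedy left to right)", {
  g <- toy_genome(10)
  # C D C: first pair consumes D, leaving the trailing C unpaired
  a <- toy_assignments(c(0, 1, 2), c("dndC", "dndD", "dndC"))
  calls <- call_adjacent_clusters(g, a)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$ordinal_first, calls$ordinal_last), c(0L, 1L))
})

test_that("clusters wrap the origin on circular replicons only", {
  a <- toy_assignments(c(0, 1, 9), c("dndG", "dndH", "dndF"))
  circ <- call_adjacent_clusters(toy_genome(10, circular = TRUE), a)
  expect_equal(circ$cluster_type, "dndFGH")
  expect_equal(c(circ$ordinal_first, circ$ordinal_last), c(9L, 1L))
  lin <- call_adjacent_clusters(toy_genome(10, circular = FALSE), a)
  expect_equal(nrow(lin), 0)
})

test_that("assignments referencing unknown genes are rejected", {
  g <- toy_genome(5)
  a <- toy_assignments(c(0, 1), c("dndC", "dndD"))
  a$gene_id[2] <- "nonexistent"
  expect_error(call_adjacent_clusters(g, a), "unknown gene_id")
})

test_that("the set of called cluster types is monotone in max_gap", {
  for (seed in 1:60) {
    case <- random_toy_case(seed)
    prev <- character()
    for (gap in 0:3) {
      types <- unique(call_adjacent_clusters(case$genome, case$assignments,
                                             max_gap = gap)$cluster_type)
      expect_true(all(prev %in% types),
                  info = paste("seed", seed, "gap", gap))
      prev <- types
    }
  }
})

test_that("cluster calling matches the exhaustive window oracle", {
  for (seed in 1:150) {
    case <- random_toy_case(seed)
    got <- call_adjacent_clusters(case$genome, case$assignments,
                                  max_gap = case$max_gap)
    want <- oracle_clusters(case$genome, case$assignments,
                            max_gap = case$max_gap)
    got_df <- as.data.frame(got[c("genome_id", "cluster_type", "replicon_id",
                                  "ordinal_first", "ordinal_last")])
    got_df$ordinal_first <- as.integer(got_df$ordinal_first)
    got_df$ordinal_last <- as.integer(got_df$ordinal_last)
    want$ordinal_first <- as.integer(want$ordinal_first)
    want$ordinal_last <- as.integer(want$ordinal_last)
    rownames(got_df) <- NULL
    rownames(want) <- NULL
    expect_equal(got_df, want, info = paste("seed", seed))
  }
})

test_that("R-M linkage window is inclusive at 30 ORFs and fails at 31", {
  g <- toy_genome(40)
  mk_calls <- function(cd_first) dplyr::bind_rows(
    call_adjacent_clusters(g, toy_assignments(c(0, 1, 2),
                                              c("dndF", "dndG", "dndH"))),
    call_adjacent_clusters(g, toy_assignments(c(cd_first, cd_first + 1),
                                              c("dndC", "dndD")))
  )
  linked <- link_restriction_modification(mk_calls(32), g, window = 30)
  expect_true(linked$calls$rm_linked[linked$calls$cluster_type == "dndFGH"])
  expect_equal(linked$pairs$orf_distance, 30)
  unlinked <- link_restriction_modification(mk_calls(33), g, window = 30)
  expect_false(
    unlinked$calls$rm_linked[unlinked$calls$cluster_type == "dndFGH"])
  expect_equal(nrow(unlinked$pairs), 0)
})

test_that("adjacent spans have ORF distance 1", {
  g <- toy_genome(10)
  calls <- dplyr::bind_rows(
    call_adjacent_clusters(g, toy_assignments(c(0, 1, 2),
                                              c("dndF", "dndG", "dndH"))),
    call_adjacent_clusters(g, toy_assignments(c(3, 4), c("dndC", "dndD")))
  )
  lk <- link_restriction_modification(calls, g)
  expect_equal(lk$pairs$orf_distance, 1)
})

test_that("circular replicons use the shorter way around", {
  g <- toy_genome(40, circular = TRUE)
  calls <- dplyr::bind_rows(
    call_adjacent_clusters(g, toy_assignments(c(0, 1, 2),
                                              c("dndF", "dndG", "dndH"))),
    call_adjacent_clusters(g, toy_assignments(c(37, 38), c("dndC", "dndD")))
  )
  lk <- link_restriction_modification(calls, g, window = 30)
  # linear distance would be 35; around the origin it is 2
  expect_equal(lk$pairs$orf_distance, 2)
  expect_true(lk$calls$rm_linked[lk$calls$cluster_type == "dndFGH"])
})

test_that("profile_genomes reports presence, counts and R-M linkage", {
  g1 <- toy_genome(40, genome_id = "gA")
  g2 <- toy_genome(10, genome_id = "gB")
  a1 <- toy_assignments(c(0, 1, 2, 5, 6), c("dndF", "dndG", "dndH",
                                            "dndC", "dndD"))
  a1$genome_id <- "gA"
  a2 <- toy_assignments(3, "dndA_iscS")
  a2$genome_id <- "gB"
  calls <- dplyr::bind_rows(
    call_adjacent_clusters(g1, a1),
    call_adjacent_clusters(g2, a2)
  )
  prof <- profile_genomes(list(g1, g2), dplyr::bind_rows(a1, a2), calls)
  pa <- prof[prof$genome_id == "gA", ]
  expect_true(pa$dndFGH && pa$dndCD && !pa$dndBCDE)
  expect_equal(pa$n_dndC, 1L)
  expect_true(pa$rm_linked)
  pb <- prof[prof$genome_id == "gB", ]
  expect_true(pb$dndA_iscS && !pb$dndCD && !pb$rm_linked)
  expect_equal(pb$n_dndA_iscS, 1L)
})

test_that("profile_genomes rejects duplicate genome ids", {
  g <- toy_genome(5, genome_id = "dup")
  empty_a <- toy_assignments(integer(), character())
  empty_c <- call_adjacent_clusters(g, empty_a)
  expect_error(profile_genomes(list(g, g), empty_a, empty_c),
               "duplicate genome_id")
})
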