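# Occurrence tables, across/within-taxon associations, eligibility rules,
# pooled t test, BH FDR.

# A small deterministic cohort: two genera, hand-set feature counts.
toy_cohort <- function(n_per_genus = 5) {
  ids <- sprintf("g%02d", seq_len(2 * n_per_genus))
  profiles <- tibble::tibble(genome_id = ids)
  for (f in c(dnd_families(), names(dnd_cluster_types()))) {
    profiles[[f]] <- FALSE
    profiles[[paste0("n_", f)]] <- 0L
  }
  profiles$rm_linked <- FALSE
  taxonomy <- tibble::tibble(
    genome_id = ids,
    genus = rep(c("Alpha", "Beta"), each = n_per_genus)
  )
  counts <- tibble::tibble(genome_id = ids, prophage_count = 0L,
                           prophage_present = FALSE)
  list(profiles = profiles, taxonomy = taxonomy, counts = counts)
}

test_that("occurrence_by_taxon computes fractions and mean abundance", {
  co <- toy_cohort(5)
  # Alpha: 2/5 genomes carry dndCD (one with 2 copies); prophages 0,1,2,0,0
  co$profiles$dndCD[1:2] <- TRUE
  co$profiles$n_dndCD[1:2] <- c(1L, 2L)
  co$counts$prophage_count <- c(0L, 1L, 2L, 0L, 0L, rep(1L, 5))
  occ <- occurrence_by_taxon(co$profiles, co$counts, co$taxonomy,
                             rank = "genus", min_genomes = 5)
  a_cd <- occ[occ$taxon == "Alpha" & occ$feature == "dndCD", ]
  expect_equal(a_cd$occurrence, 2 / 5)
  expect_equal(a_cd$mean_abundance, 3 / 5)
  a_ph <- occ[occ$taxon == "Alpha" & occ$feature == "prophage", ]
  expect_equal(a_ph$occurrence, 2 / 5)
  b_ph <- occ[occ$taxon == "Beta" & occ$feature == "prophage", ]
  expect_equal(b_ph$occurrence, 1)
})

test_that("occurrence_by_taxon drops taxa below min_genomes inclusively", {
  co <- toy_cohort(5)
  occ5 <- occurrence_by_taxon(co$profiles, co$counts, co$taxonomy,
                              min_genomes = 5)
  expect_setequal(unique(occ5$taxon), c("Alpha", "Beta"))
  expect_warning(
    occ6 <- occurrence_by_taxon(co$profiles, co$counts, co$taxonomy,
                                min_genomes = 6),
    "empty")
  expect_equal(nrow(occ6), 0)
})

test_that("across_taxon_association reproduces hand OLS values", {
  res <- across_taxon_association(c(1, 2, 3), c(2, 4, 7))
  expect_equal(res$slope, 2.5)
  expect_equal(res$intercept, -2 / 3)
  expect_equal(res$r_squared, unname(cor(c(1, 2, 3), c(2, 4, 7))^2))
})

test_that("a perfect negative fit is significant_negative", {
  x <- seq(0.1, 0.9, length.out = 6)
  res <- across_taxon_association(x, 1 - 0.8 * x)
  expect_equal(res$statistic, -1)
  expect_equal(res$slope, -0.8)
  expect_equal(res$classification, "significant_negative")
})

test_that("across-taxon classification needs all three thresholds", {
  set.seed(42)
  x <- seq_len(30)
  strong_neg <- across_taxon_association(x, -x + rnorm(30, sd = 0.5))
  expect_equal(strong_neg$classification, "significant_negative")
  strong_pos <- across_taxon_association(x, x + rnorm(30, sd = 0.5))
  expect_equal(strong_pos$classification, "significant_positive")
  weak <- across_taxon_association(x, -0.1 * x + rnorm(30, sd = 10))
  expect_true(weak$classification %in% c("negative", "positive", "zero"))
  # strongly correlated but n too small for p < 0.001
  tiny <- across_taxon_association(c(1, 2, 3), c(3, 2.1, 1))
  expect_equal(tiny$classification, "negative")
})

test_that("degenerate across-taxon inputs are not computable", {
  expect_equal(across_taxon_association(c(1, 2), c(1, 2))$classification,
               "not_computable")
  expect_equal(across_taxon_association(c(1, 1, 1), c(1, 2, 3))$classification,
               "not_computable")
})

test_that("within_taxon_association classifies by sign and p-value", {
  res <- within_taxon_association(c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, -1)
  expect_equal(res$classification, "significant_negative")
  expect_equal(res$p_method, "exact")
  flat <- within_taxon_association(c(1, 1, 1), c(1, 2, 3))
  expect_equal(flat$classification, "not_computable")
})

test_that("eligibility requires 30 carrying genomes, inclusively", {
  co <- toy_cohort(40)
  # Alpha: exactly 30 carriers; Beta: 29 carriers
  co$counts$prophage_count[1:30] <- 1L
  co$counts$prophage_count[41:69] <- 1L
  elig <- eligibility_filter(co$profiles, co$counts, co$taxonomy,
                             min_carrying = 30)
  expect_true(elig$taxa$eligible[elig$taxa$taxon == "Alpha"])
  expect_false(elig$taxa$eligible[elig$taxa$taxon == "Beta"])
  expect_equal(elig$taxa$n_carrying, c(30L, 29L))
})

test_that("pairs are unachievable when the feature or prophages are absent", {
  co <- toy_cohort(35)
  co$counts$prophage_count[1:35] <- 1L   # Alpha has prophages, Beta none
  co$profiles$n_dndCD[1] <- 1L           # dndCD only in Alpha
  elig <- eligibility_filter(co$profiles, co$counts, co$taxonomy,
                             min_carrying = 30)
  p <- elig$pairs
  expect_true(p$achievable[p$taxon == "Alpha" & p$feature == "dndCD"])
  expect_false(p$achievable[p$taxon == "Alpha" & p$feature == "dndFGH"])
  expect_false(p$achievable[p$taxon == "Beta" & p$feature == "dndCD"])
})

test_that("within_taxon_scan flags excluded taxa and unachievable pairs", {
  co <- toy_cohort(35)
  set.seed(7)
  co$counts$prophage_count[1:35] <- rpois(35, 2) + 1L
  co$profiles$n_dndCD[1:35] <- rbinom(35, 1, 0.4)
  co$profiles$dndCD <- co$profiles$n_dndCD > 0
  scan <- within_taxon_scan(co$profiles, co$counts, co$taxonomy,
                            min_carrying = 30)
  a_cd <- scan[scan$taxon == "Alpha" & scan$feature == "dndCD", ]
  expect_equal(a_cd$flag, "ok")
  expect_false(is.na(a_cd$tau))
  a_fgh <- scan[scan$taxon == "Alpha" & scan$feature == "dndFGH", ]
  expect_equal(a_fgh$flag, "unachievable")
  expect_true(is.na(a_fgh$tau))
  expect_true(all(scan$flag[scan$taxon == "Beta"] == "taxon_excluded"))
})

test_that("scan tau agrees with a direct per-taxon computation", {
  co <- toy_cohort(35)
  set.seed(11)
  co$counts$prophage_count <- rpois(70, 2)
  co$counts$prophage_count[1:35] <- co$counts$prophage_count[1:35] + 1L
  co$profiles$n_dndBCDE[1:35] <- rbinom(35, 2, 0.5)
  co$profiles$dndBCDE <- co$profiles$n_dndBCDE > 0
  scan <- within_taxon_scan(co$profiles, co$counts, co$taxonomy,
                            min_carrying = 30)
  direct <- kendall_tau_b(co$profiles$n_dndBCDE[1:35],
                          co$counts$prophage_count[1:35])
  cell <- scan[scan$taxon == "Alpha" & scan$feature == "dndBCDE", ]
  expect_equal(cell$tau, direct$tau)
  expect_equal(cell$p_value, direct$p_value)
})

test_that("students_t_test reproduces a hand example", {
  res <- students_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(res$df, 4)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value)
})

test_that("students_t_test handles zero pooled variance", {
  same <- students_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(students_t_test(c(2, 2), c(3, 3)), "degenerate")
  expect_error(students_t_test(1, c(1, 2)), "n >= 2")
})

test_that("bh_fdr matches a manual step-up computation", {
  p <- c(0.005, 0.009, 0.05, 0.1, 0.2)
  # manual BH: sort ascending, p * m / rank, cumulative min from the bottom
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  manual <- numeric(m); manual[o] <- pmin(1, adj)
  expect_equal(bh_fdr(p), manual)
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
  expect_error(bh_fdr(c(0.5, NA)), "p-values")
})
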