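# Association framework: per-taxon occurrence tables, across-taxon
# OLS/Pearson, within-taxon Kendall tau-b, inclusion filters, association
# classification, and the generic tests used elsewhere (pooled Student's t,
# Benjamini-Hochberg FDR).

#' Per-taxon occurrence fractions and mean abundances
#'
#' Aggregates per-genome dnd profiles and prophage counts to taxon level.
#' Occurrence is the fraction of genomes carrying at least one copy of the
#' feature; abundance is the mean per-genome count. Only taxa with at least
#' `min_genomes` genomes are returned (the genus-level analyses use 100,
#' species-level 30).
#'
#' @param profiles Tibble from [profile_genomes()].
#' @param prophage_counts Tibble from [prophage_abundance()].
#' @param taxonomy Tibble from [read_taxonomy_tsv()] (needs `genome_id` and
#'   the `rank` column).
#' @param rank `"genus"` or `"species"`.
#' @param min_genomes Minimum genomes per taxon (inclusive; default 100).
#' @return Long tibble with one row per (taxon, feature): `taxon`, `rank`,
#'   `n_genomes`, `feature` (eight families, three cluster types and
#'   `"prophage"`), `n_present`, `occurrence`, `mean_abundance`.
#' @export
occurrence_by_taxon <- function(profiles, prophage_counts, taxonomy,
                                rank = c("genus", "species"),
                                min_genomes = 100L) {
  rank <- match.arg(rank)
  stopifnot(min_genomes >= 1)
  profiles <- as_tibble(profiles)
  require_columns(profiles, c("genome_id", dnd_feature_names()), "profiles")
  require_columns(taxonomy, c("genome_id", rank), "taxonomy")
  require_columns(prophage_counts, c("genome_id", "prophage_count"),
                  "prophage_counts")

  df <- profiles %>%
    left_join(select(prophage_counts, "genome_id", "prophage_count"),
              by = "genome_id") %>%
    mutate(prophage_count = dplyr::coalesce(.data$prophage_count, 0L)) %>%
    left_join(select(taxonomy, "genome_id", taxon = all_of(rank)),
              by = "genome_id") %>%
    filter(!is.na(.data$taxon) & nzchar(.data$taxon))

  features <- c(dnd_feature_names(), "prophage")
  long <- lapply(features, function(f) {
    cnt <- if (f == "prophage") df$prophage_count else df[[paste0("n_", f)]]
    tibble(taxon = df$taxon, feature = f, count = cnt)
  }) %>%
    bind_rows() %>%
    group_by(.data$taxon, .data$feature) %>%
    summarise(
      n_genomes = n(),
      n_present = sum(.data$count >= 1),
      occurrence = .data$n_present / .data$n_genomes,
      mean_abundance = mean(.data$count),
      .groups = "drop"
    ) %>%
    filter(.data$n_genomes >= min_genomes) %>%
    mutate(rank = rank, .after = "taxon")
  if (nrow(long) == 0) {
    warn(paste0("no ", rank, " with >= ", min_genomes,
                " genomes; occurrence table is empty"))
  }
  arrange(long, .data$taxon, .data$feature)
}

#' Across-taxon association: OLS regression and Pearson correlation
#'
#' Regresses dnd occurrence fractions (`y`) on prophage occurrence
#' fractions (`x`) across taxa and reports the Pearson coefficient with a
#' two-sided p-value from the t distribution on `n - 2` degrees of freedom.
#' The association is classified `significant_negative` when the evidence
#' bar \eqn{R^2 > 0.5}, \eqn{p < 0.001} and \eqn{r < -0.7} is met
#' (symmetrically `significant_positive` for \eqn{r > 0.7}); otherwise the
#' sign of `r` gives `negative`/`zero`/`positive`.
#'
#' @param x Predictor fractions (prophage occurrence per taxon).
#' @param y Response fractions (dnd feature occurrence per taxon).
#' @return One-row tibble: `method`, `n`, `slope`, `intercept`,
#'   `statistic` (Pearson r), `r_squared`, `p_value`, `classification`.
#' @export
across_taxon_association <- function(x, y) {
  ok <- complete.cases(x, y) & is.finite(x) & is.finite(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  nc <- tibble(method = "ols_pearson", n = n, slope = NA_real_,
               intercept = NA_real_, statistic = NA_real_,
               r_squared = NA_real_, p_value = NA_real_,
               classification = "not_computable")
  if (n < 3 || var(x) == 0 || var(y) == 0) return(nc)
  fit <- lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  r2 <- r^2
  p <- ct$p.value
  tibble(
    method = "ols_pearson", n = n,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    statistic = r, r_squared = r2, p_value = p,
    classification = classify_across(r, r2, p)
  )
}

classify_across <- function(r, r2, p) {
  if (r2 > 0.5 && p < 0.001 && r < -0.7) return("significant_negative")
  if (r2 > 0.5 && p < 0.001 && r > 0.7) return("significant_positive")
  if (r < 0) "negative" else if (r > 0) "positive" else "zero"
}

#' Within-taxon association: Kendall's tau-b on abundance counts
#'
#' Rank association between two per-genome abundance vectors (e.g. prophage
#' counts vs copies of a dnd feature) within one taxon, using the
#' tie-corrected tau-b of [kendall_tau_b()]. Counts are treated as ordinal
#' categorical variables. Classified `significant_negative`/
#' `significant_positive` when `p < 0.05`, otherwise by the sign of tau;
#' `not_computable` when either vector is constant.
#'
#' @param abundance_x,abundance_y Per-genome count vectors of equal length.
#' @return One-row tibble: `method`, `n`, `statistic` (tau-b), `p_value`,
#'   `p_method` (`"exact"` for n <= 10, else `"normal"`), `classification`.
#' @export
within_taxon_association <- function(abundance_x, abundance_y) {
  kt <- kendall_tau_b(abundance_x, abundance_y)
  classification <- if (is.na(kt$tau)) {
    "not_computable"
  } else if (!is.na(kt$p_value) && kt$p_value < 0.05) {
    if (kt$tau < 0) "significant_negative" else "significant_positive"
  } else if (kt$tau < 0) "negative" else if (kt$tau > 0) "positive" else "zero"
  tibble(method = "kendall_tau_b", n = kt$n, statistic = kt$tau,
         p_value = kt$p_value, p_method = kt$method,
         classification = classification)
}

#' Taxon inclusion filter and per-pair achievability
#'
#' A taxon enters the within-taxon analysis when at least `min_carrying`
#' of its genomes carry >= 1 prophage or >= 1 dnd gene/cluster. A
#' (taxon, feature) pair is additionally marked statistically unachievable
#' when the taxon has fewer than `min_carrying` genomes overall, or the
#' feature (or prophages) is absent from every genome of the taxon.
#'
#' @param profiles Tibble from [profile_genomes()].
#' @param prophage_counts Tibble from [prophage_abundance()].
#' @param taxonomy Taxonomy tibble with `genome_id` and the `rank` column.
#' @param rank `"genus"` or `"species"`.
#' @param min_carrying Threshold (inclusive, default 30).
#' @return A list with `taxa` (tibble: `taxon`, `n_genomes`, `n_carrying`,
#'   `eligible`) and `pairs` (tibble: `taxon`, `feature`, `achievable`).
#' @export
eligibility_filter <- function(profiles, prophage_counts, taxonomy,
                               rank = c("genus", "species"),
                               min_carrying = 30L) {
  rank <- match.arg(rank)
  df <- as_tibble(profiles) %>%
    left_join(select(prophage_counts, "genome_id", "prophage_count"),
              by = "genome_id") %>%
    mutate(prophage_count = dplyr::coalesce(.data$prophage_count, 0L)) %>%
    left_join(select(taxonomy, "genome_id", taxon = all_of(rank)),
              by = "genome_id") %>%
    filter(!is.na(.data$taxon) & nzchar(.data$taxon))

  dnd_cols <- paste0("n_", dnd_feature_names())
  df$carries_any <- df$prophage_count >= 1 |
    rowSums(as.matrix(df[dnd_cols])) >= 1

  taxa <- df %>%
    group_by(.data$taxon) %>%
    summarise(n_genomes = n(), n_carrying = sum(.data$carries_any),
              .groups = "drop") %>%
    mutate(eligible = .data$n_carrying >= min_carrying)

  pairs <- lapply(c(dnd_feature_names()), function(f) {
    df %>%
      group_by(.data$taxon) %>%
      summarise(
        feature = f,
        achievable = n() >= min_carrying &&
          sum(.data[[paste0("n_", f)]]) > 0 &&
          sum(.data$prophage_count) > 0,
        .groups = "drop"
      )
  }) %>% bind_rows() %>%
    select("taxon", "feature", "achievable") %>%
    arrange(.data$taxon, .data$feature)

  list(taxa = taxa, pairs = pairs)
}

#' Within-taxon association scan over all (taxon, feature) pairs
#'
#' Runs [within_taxon_association()] between each dnd feature's per-genome
#' abundance and the prophage abundance, inside every eligible taxon, and
#' returns a heatmap-ready long table. Unachievable pairs (see
#' [eligibility_filter()]) are kept with `NA` statistics and flagged, which
#' mirrors how such cells are crossed out rather than dropped.
#'
#' @inheritParams eligibility_filter
#' @param qvalues Add BH-adjusted q-values across all computed pairs
#'   (default `FALSE`; raw p-values are the primary output).
#' @return Tibble: `taxon`, `feature`, `n`, `tau`, `p_value`, `flag`
#'   (`"ok"`, `"unachievable"` or `"taxon_excluded"`), and `q_value` when
#'   requested.
#' @export
within_taxon_scan <- function(profiles, prophage_counts, taxonomy,
                              rank = c("genus", "species"),
                              min_carrying = 30L, qvalues = FALSE) {
  rank <- match.arg(rank)
  elig <- eligibility_filter(profiles, prophage_counts, taxonomy, rank,
                             min_carrying)
  df <- as_tibble(profiles) %>%
    left_join(select(prophage_counts, "genome_id", "prophage_count"),
              by = "genome_id") %>%
    mutate(prophage_count = dplyr::coalesce(.data$prophage_count, 0L)) %>%
    left_join(select(taxonomy, "genome_id", taxon = all_of(rank)),
              by = "genome_id") %>%
    filter(!is.na(.data$taxon) & nzchar(.data$taxon))

  grid <- elig$pairs %>%
    left_join(elig$taxa, by = "taxon")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    taxon <- grid$taxon[i]; feature <- grid$feature[i]
    sub <- filter(df, .data$taxon == !!taxon)
    base <- tibble(taxon = taxon, feature = feature, n = nrow(sub),
                   tau = NA_real_, p_value = NA_real_, flag = "ok")
    if (!grid$eligible[i]) {
      base$flag <- "taxon_excluded"
      return(base)
    }
    if (!grid$achievable[i]) {
      base$flag <- "unachievable"
      return(base)
    }
    res <- within_taxon_association(sub[[paste0("n_", feature)]],
                                    sub$prophage_count)
    base$tau <- res$statistic
    base$p_value <- res$p_value
    base
  })
  out <- bind_rows(rows)
  if (qvalues) {
    out$q_value <- NA_real_
    comp <- !is.na(out$p_value)
    out$q_value[comp] <- bh_fdr(out$p_value[comp])
  }
  out
}

#' Two-sided unpaired Student's t test (pooled variance)
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return One-row tibble: `statistic` (t), `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`. When both samples are constant with equal
#'   means, `t = 0`, `p = 1`; constant with unequal means is a degenerate
#'   input and raises an error.
#' @export
students_t_test <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs n >= 2")
  }
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                    p_value = 1, mean_a = mean(a), mean_b = mean(b),
                    n_a = length(a), n_b = length(b)))
    }
    abort("degenerate input: zero pooled variance with unequal means")
  }
  tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH step-up adjusted values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(pvalues, method = "BH")
}
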