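# PT consensus-motif scanning (GAAC/GTTC), modification-frequency
# arithmetic, site-to-gene mapping and PT/differential-expression coupling.
#
# PT modification sits on the phosphodiester after the G of the
# double-stranded 5'-GpsAAC-3' / 5'-GpsTTC-3' consensus: a GAAC match on the
# reference strand implies the paired GTTC on the complementary strand at
# the same locus.

#' Scan a sequence for PT consensus motifs
#'
#' Finds every occurrence of the given motifs on the reference strand
#' (overlapping matches allowed; `N` never matches). With
#' `ds_pairs = TRUE`, each reference-strand match is also reported as the
#' implied complementary-strand motif of the double-stranded consensus: a
#' `GAAC` at position `i` pairs with a minus-strand `GTTC` whose modified G
#' sits opposite position `i + 3`.
#'
#' @param sequence A single nucleotide sequence (character or
#'   `Biostrings::DNAString`), alphabet `A`/`C`/`G`/`T`/`N`.
#' @param motifs Character vector of motifs (default `c("GAAC", "GTTC")`).
#' @param replicon_id Replicon label for the output (default `"seq"`).
#' @param ds_pairs Also emit the implied minus-strand partner of each match.
#' @return Tibble with `replicon_id`, `motif`, `position` (1-based
#'   coordinate of the motif's G in reference-strand coordinates), `strand`.
#' @examples
#' scan_motifs("GAACGTTC")
#' @export
scan_motifs <- function(sequence, motifs = c("GAAC", "GTTC"),
                        replicon_id = "seq", ds_pairs = FALSE) {
  seq <- if (inherits(sequence, "DNAString")) sequence
         else Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(seq) == 0) return(empty_motif_hits())
  rows <- lapply(motifs, function(m) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(m), seq,
                                     fixed = TRUE)
    starts <- Biostrings::start(hits)
    if (length(starts) == 0) return(NULL)
    tibble(replicon_id = replicon_id, motif = m, position = starts,
           strand = "+")
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- empty_motif_hits()
  if (ds_pairs && nrow(out) > 0) {
    partner <- tibble(
      replicon_id = out$replicon_id,
      motif = as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(out$motif))),
      position = out$position + nchar(out$motif) - 1L,
      strand = "-"
    )
    out <- bind_rows(out, partner)
  }
  arrange(out, .data$position, .data$strand)
}

empty_motif_hits <- function() {
  tibble(replicon_id = character(), motif = character(),
         position = integer(), strand = character())
}

#' Count motif occurrences per class
#'
#' @inheritParams scan_motifs
#' @return Named integer vector of reference-strand occurrence counts.
#' @export
count_motifs <- function(sequence, motifs = c("GAAC", "GTTC")) {
  hits <- scan_motifs(sequence, motifs)
  vapply(motifs, function(m) sum(hits$motif == m), integer(1))
}

#' Modification frequency per 10^6 nt and per molecule
#'
#' @param count Number of modified dinucleotides observed.
#' @param denominator_nt Total nucleotides the count refers to.
#' @param molecule_length_bp Optional molecule length in bp; when given,
#'   the expected modifications per molecule are reported, using
#'   `2 * length` nt for double-stranded molecules.
#' @param double_stranded Is the molecule double stranded? (default `TRUE`)
#' @return One-row tibble: `count`, `denominator_nt`, `freq_per_1e6_nt`,
#'   `per_molecule` (`NA` without a molecule length).
#' @examples
#' # ~11 modifications per 14,745-bp double-stranded plasmid at 373/1e6 nt
#' modification_frequency(373, 1e6, molecule_length_bp = 14745)
#' @export
modification_frequency <- function(count, denominator_nt,
                                   molecule_length_bp = NULL,
                                   double_stranded = TRUE) {
  if (denominator_nt <= 0) abort("denominator_nt must be > 0")
  if (count < 0) abort("count must be >= 0")
  freq <- count / denominator_nt * 1e6
  per_molecule <- NA_real_
  if (!is.null(molecule_length_bp)) {
    molecule_nt <- molecule_length_bp * (if (double_stranded) 2 else 1)
    per_molecule <- freq * molecule_nt / 1e6
  }
  tibble(count = count, denominator_nt = denominator_nt,
         freq_per_1e6_nt = freq, per_molecule = per_molecule)
}

#' Percentage of consensus motifs that are modified
#'
#' @param modified_count Number of modified motif occurrences.
#' @param total_motif_count Total motif occurrences (the denominator).
#' @return Percentage, `100 * modified / total`.
#' @export
modified_fraction <- function(modified_count, total_motif_count) {
  if (total_motif_count <= 0) abort("total_motif_count must be > 0")
  if (modified_count < 0 || modified_count > total_motif_count) {
    abort("modified_count must lie in [0, total_motif_count]")
  }
  100 * modified_count / total_motif_count
}

#' Evaluate denominator conventions for modified-motif percentages
#'
#' The fraction of consensus motifs carrying a PT modification depends on
#' what counts as "all motifs": reference-strand occurrences per motif
#' class, occurrences on both strands, or double-stranded motif loci. This
#' helper computes the percentage for each convention from reference-strand
#' scan totals. For GAAC/GTTC the both-strand total of one class equals
#' `GAAC_ref + GTTC_ref` (the reverse complement of GAAC is GTTC), and that
#' is also the number of double-stranded loci.
#'
#' @param modified Named numeric vector: modified-site counts per class,
#'   names `GAAC` and `GTTC`.
#' @param totals Named numeric vector: reference-strand motif totals per
#'   class, names `GAAC` and `GTTC`.
#' @return Tibble with one row per (class, convention) and the resulting
#'   percentage.
#' @export
evaluate_motif_conventions <- function(modified, totals) {
  stopifnot(all(c("GAAC", "GTTC") %in% names(modified)),
            all(c("GAAC", "GTTC") %in% names(totals)))
  both <- totals[["GAAC"]] + totals[["GTTC"]]
  bind_rows(lapply(c("GAAC", "GTTC"), function(m) {
    tibble(
      motif = m,
      convention = c("reference_strand", "both_strands", "ds_pair"),
      total = c(totals[[m]], both, both),
      percent = vapply(c(totals[[m]], both, both),
                       function(tt) modified_fraction(modified[[m]], tt),
                       numeric(1))
    )
  }))
}

#' Map PT sites onto gene features
#'
#' Assigns each site to every CDS whose interval contains its position
#' (boundaries inclusive); sites covered by no CDS are intergenic. Overlap
#' is evaluated in reference-strand coordinates regardless of gene strand.
#'
#' @param sites Tibble from [read_sites_tsv()] (columns `replicon_id`,
#'   `position`, `motif_class`).
#' @param genome A [genome_record()].
#' @return A list with `gene_counts` (tibble: `gene_id`, `n_gpsa`,
#'   `n_gpst`, `n_total`, one row per CDS of the genome including
#'   zero-count genes), `site_assignments` (one row per (site, gene) pair)
#'   and `intergenic` (the sites assigned to no CDS).
#' @export
map_sites_to_features <- function(sites, genome) {
  stopifnot(inherits(genome, "genome_record"))
  sites <- as_tibble(sites)
  require_columns(sites, c("replicon_id", "position", "motif_class"), "sites")
  bad_rep <- setdiff(unique(sites$replicon_id),
                     genome$replicons$replicon_id)
  if (length(bad_rep) > 0) {
    abort(paste0("sites reference unknown replicon(s): ",
                 paste(bad_rep, collapse = ", ")))
  }
  len <- genome$replicons$length[
    match(sites$replicon_id, genome$replicons$replicon_id)]
  if (any(sites$position > len | sites$position < 1)) {
    abort("site position outside replicon bounds")
  }
  sites <- mutate(sites, .site = row_number())
  feats <- genome$features
  assignments <- if (nrow(feats) == 0 || nrow(sites) == 0) {
    tibble(.site = integer(), gene_id = character())
  } else {
    inner_join(
      sites, select(feats, "gene_id", "replicon_id", "start", "end"),
      by = join_by("replicon_id", between("position", "start", "end"))
    ) %>% select(".site", "gene_id", "replicon_id", "position",
                 "motif_class")
  }
  per_gene <- feats %>%
    select("gene_id") %>%
    left_join(
      assignments %>%
        group_by(.data$gene_id) %>%
        summarise(n_gpsa = sum(.data$motif_class == "GpsAAC"),
                  n_gpst = sum(.data$motif_class == "GpsTTC"),
                  .groups = "drop"),
      by = "gene_id"
    ) %>%
    mutate(n_gpsa = dplyr::coalesce(.data$n_gpsa, 0L),
           n_gpst = dplyr::coalesce(.data$n_gpst, 0L),
           n_total = .data$n_gpsa + .data$n_gpst)
  intergenic <- sites %>%
    filter(!.data$.site %in% assignments$.site) %>%
    select(-".site")
  list(gene_counts = per_gene,
       site_assignments = select(assignments, -".site"),
       intergenic = intergenic)
}

#' Couple PT-site content with differential expression
#'
#' Flags DEGs by `fdr < fdr_max` and linear fold change above `fc_min`
#' (two-sided, i.e. `|log2fc| > log2(fc_min)`), then compares DEGs and
#' non-DEGs on (a) the proportion of genes containing at least one PT site
#' and (b) the mean number of PT sites per gene (two-sided pooled Student's
#' t test via [students_t_test()]).
#'
#' @param de_table Tibble from [read_de_tsv()]: `gene_id`, `log2fc`, `fdr`.
#' @param gene_counts Tibble with `gene_id` and `n_total` PT sites per gene
#'   (see [map_sites_to_features()]); genes absent from it count 0 sites.
#' @param fdr_max FDR threshold (default 0.05).
#' @param fc_min Linear fold-change threshold (default 2).
#' @return One-row tibble: `n_genes`, `n_deg`, `prop_deg_with_sites`,
#'   `prop_nondeg_with_sites`, `mean_sites_deg`, `mean_sites_nondeg`,
#'   `t_statistic`, `t_df`, `t_p_value`, `flag` (`"ok"` or
#'   `"not_computable"` when either group is empty).
#' @export
deg_pt_coupling <- function(de_table, gene_counts, fdr_max = 0.05,
                            fc_min = 2) {
  de_table <- as_tibble(de_table)
  require_columns(de_table, c("gene_id", "log2fc", "fdr"), "de_table")
  gene_counts <- as_tibble(gene_counts)
  require_columns(gene_counts, c("gene_id", "n_total"), "gene_counts")

  df <- de_table %>%
    left_join(select(gene_counts, "gene_id", "n_total"), by = "gene_id") %>%
    mutate(
      n_total = dplyr::coalesce(.data$n_total, 0L),
      is_deg = .data$fdr < fdr_max & abs(.data$log2fc) > log2(fc_min)
    )
  deg <- filter(df, .data$is_deg)
  nondeg <- filter(df, !.data$is_deg)
  prop <- function(d) if (nrow(d) == 0) NA_real_ else mean(d$n_total >= 1)
  out <- tibble(
    n_genes = nrow(df), n_deg = nrow(deg),
    prop_deg_with_sites = prop(deg),
    prop_nondeg_with_sites = prop(nondeg),
    mean_sites_deg = if (nrow(deg) > 0) mean(deg$n_total) else NA_real_,
    mean_sites_nondeg = if (nrow(nondeg) > 0) mean(nondeg$n_total)
                        else NA_real_,
    t_statistic = NA_real_, t_df = NA_real_, t_p_value = NA_real_,
    flag = if (nrow(deg) == 0 || nrow(nondeg) == 0) "not_computable" else "ok"
  )
  if (out$flag == "ok" && nrow(deg) >= 2 && nrow(nondeg) >= 2 &&
      (var(deg$n_total) > 0 || var(nondeg$n_total) > 0 ||
       mean(deg$n_total) == mean(nondeg$n_total))) {
    tt <- students_t_test(deg$n_total, nondeg$n_total)
    out$t_statistic <- tt$statistic
    out$t_df <- tt$df
    out$t_p_value <- tt$p_value
  }
  out
}
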