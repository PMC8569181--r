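# Majority-rules viral taxonomy for prophage regions and per-genome
# prophage occurrence/abundance.

#' Assign viral-family taxonomy to prophage regions by majority rule
#'
#' Each protein of a region casts one vote: the family of its best hit
#' (highest bitscore) among hits with `bitscore >= bitscore_min`. A protein
#' with no qualifying hit, or with equal-best hits to different families,
#' abstains. The region is assigned the family whose vote fraction —
#' denominator: *all* proteins of the region — reaches `majority`; an exact
#' tie between two families at/above the threshold yields `"unclassified"`.
#'
#' @param regions Tibble of prophage regions (see [read_prophage_tsv()]):
#'   columns `region_id` and `protein_ids` (list-column).
#' @param hits Tibble of homology hits ([read_hits_tsv()]) whose `query_id`
#'   values are region protein ids and whose `subject_family` is the viral
#'   family of the reference protein.
#' @param bitscore_min Minimum bitscore for a hit to qualify (default 50).
#' @param majority Vote fraction required for assignment (default 0.5,
#'   inclusive).
#' @return Tibble with `region_id`, `family` (or `"unclassified"`),
#'   `fraction_assigned` (vote fraction of the winning family; for
#'   unclassified regions, the best fraction seen) and `n_proteins`.
#' @export
assign_family <- function(regions, hits, bitscore_min = 50, majority = 0.5) {
  regions <- as_tibble(regions)
  hits <- as_tibble(hits)
  require_columns(regions, c("region_id", "protein_ids"), "regions")
  if (nrow(hits) > 0) {
    require_columns(hits, c("query_id", "subject_family", "bitscore"), "hits")
  }
  qual <- if (nrow(hits) > 0) filter(hits, .data$bitscore >= bitscore_min)
          else hits

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    prots <- regions$protein_ids[[i]]
    if (length(prots) == 0) {
      abort(paste0("region ", regions$region_id[i],
                   " has an empty protein list"))
    }
    votes <- character()
    if (nrow(qual) > 0) {
      h <- filter(qual, .data$query_id %in% prots)
      if (nrow(h) > 0) {
        votes <- h %>%
          group_by(.data$query_id) %>%
          filter(.data$bitscore == max(.data$bitscore)) %>%
          summarise(fam = if (n_distinct(.data$subject_family) == 1)
                            .data$subject_family[1] else NA_character_,
                    .groups = "drop") %>%
          pull("fam")
        votes <- votes[!is.na(votes)]
      }
    }
    n <- length(prots)
    if (length(votes) == 0) {
      return(tibble(region_id = regions$region_id[i],
                    family = "unclassified", fraction_assigned = 0,
                    n_proteins = n))
    }
    tab <- sort(table(votes) / n, decreasing = TRUE)
    top <- tab[1]
    at_top <- names(tab)[tab == top]
    family <- if (top >= majority && length(at_top) == 1) at_top
              else "unclassified"
    tibble(region_id = regions$region_id[i], family = family,
           fraction_assigned = as.numeric(top), n_proteins = n)
  })
  bind_rows(rows)
}

#' Per-genome prophage counts and occurrence
#'
#' @param genomes Character vector of genome ids, or a data frame with a
#'   `genome_id` column (e.g. a taxonomy table). Genomes absent from
#'   `regions` get a count of 0.
#' @param regions Tibble of prophage regions with a `genome_id` column.
#' @return Tibble with `genome_id`, `prophage_count` and `prophage_present`.
#' @export
prophage_abundance <- function(genomes, regions) {
  ids <- if (is.data.frame(genomes)) {
    require_columns(genomes, "genome_id", "genomes")
    genomes$genome_id
  } else {
    as.character(genomes)
  }
  regions <- as_tibble(regions)
  if (nrow(regions) > 0) require_columns(regions, "genome_id", "regions")
  counts <- if (nrow(regions) > 0) {
    count(regions, .data$genome_id, name = "prophage_count")
  } else {
    tibble(genome_id = character(), prophage_count = integer())
  }
  tibble(genome_id = unique(ids)) %>%
    left_join(counts, by = "genome_id") %>%
    mutate(prophage_count = dplyr::coalesce(.data$prophage_count, 0L),
           prophage_present = .data$prophage_count >= 1)
}
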