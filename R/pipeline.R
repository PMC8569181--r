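# Configuration, report assembly and the end-to-end pipeline. Each stage
# runs when its inputs are configured, writes plain-text tables, and leaves
# a JSON summary with input digests and the thresholds used, so any stage
# can be re-run from intermediates.

#' Build a pipeline run configuration
#'
#' All thresholds default to the values used throughout the package:
#' e-value < 1e-10 and query coverage >= 50% for Dnd screening, strict
#' adjacency (max_gap = 0), a 30-ORF R-M window, bitscore >= 50 with a 50%
#' majority for prophage taxonomy, >= 100 genomes per genus (30 per
#' species), >= 30 feature-carrying genomes for within-taxon eligibility,
#' FDR < 0.05 with FC > 2 for DEGs, and a 1:100 serial-transfer dilution.
#'
#' @param gff Character vector of GFF3 paths (one per genome).
#' @param hits,family_map,prophages,viral_hits,viral_family_map,taxonomy,sites,de,competition
#'   Paths to the corresponding input tables; `NULL` skips the stages that
#'   need them. `viral_family_map` maps viral hit subject ids to viral
#'   families for the majority-rules taxonomy.
#' @param fasta Path to a FASTA file for motif scanning (optional).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the provenance block.
#' @param rank Taxonomic rank for co-occurrence (`"genus"` or `"species"`).
#' @param evalue,qcov,max_gap,rm_window,bitscore,majority,min_genomes,
#'   eligibility_min,fdr,fc,dilution,fitness_interval Thresholds; see above.
#' @return A `run_config` list.
#' @export
run_config <- function(gff = NULL, hits = NULL, family_map = NULL,
                       prophages = NULL, viral_hits = NULL,
                       viral_family_map = NULL, taxonomy = NULL,
                       fasta = NULL, sites = NULL, de = NULL,
                       competition = NULL, out_dir = "dndphage_out",
                       seed = 1L, rank = "genus", evalue = 1e-10,
                       qcov = 0.5, max_gap = 0L, rm_window = 30L,
                       bitscore = 50, majority = 0.5, min_genomes = 100L,
                       eligibility_min = 30L, fdr = 0.05, fc = 2,
                       dilution = 100, fitness_interval = c(0, 5)) {
  structure(
    list(gff = gff, hits = hits, family_map = family_map,
         prophages = prophages, viral_hits = viral_hits,
         viral_family_map = viral_family_map,
         taxonomy = taxonomy, fasta = fasta, sites = sites, de = de,
         competition = competition, out_dir = out_dir,
         seed = as.integer(seed), rank = rank, evalue = evalue, qcov = qcov,
         max_gap = max_gap, rm_window = rm_window, bitscore = bitscore,
         majority = majority, min_genomes = min_genomes,
         eligibility_min = eligibility_min, fdr = fdr, fc = fc,
         dilution = dilution, fitness_interval = fitness_interval),
    class = "run_config"
  )
}

#' Write/read a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are present in `config`: dnd detection
#' (GFF3 + hits), prophage profiling (regions, optionally viral hits),
#' co-occurrence statistics (profiles + prophage counts + taxonomy), PT
#' mapping (FASTA/GFF3 + sites, optionally a DE table) and fitness
#' (competition CSV). Writes TSV tables plus a `run_summary.json` with
#' provenance (input MD5 digests, thresholds, seed, package version) to
#' `config$out_dir`. Output is deterministic given config and seed.
#'
#' @param config A [run_config()].
#' @return A list of in-memory stage results, invisibly; side effect:
#'   files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  save_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(df[, !vapply(df, is.list, logical(1)), drop = FALSE], p)
    outputs <<- c(outputs, p)
    p
  }
  inputs <- purrr::compact(config[c("gff", "hits", "family_map",
                                    "prophages", "viral_hits",
                                    "viral_family_map", "taxonomy",
                                    "fasta", "sites", "de", "competition")])
  for (p in unlist(inputs)) {
    if (!file.exists(p)) abort(paste0("missing input file: ", p))
  }

  genomes <- NULL
  if (!is.null(config$gff)) {
    genomes <- lapply(config$gff, read_gff3)
    names(genomes) <- vapply(genomes, function(g) g$genome_id, "")
  }

  # ---- detect ----
  if (!is.null(genomes) && !is.null(config$hits)) {
    fam_map <- if (!is.null(config$family_map)) {
      read_family_map_tsv(config$family_map)
    } else NULL
    hits <- read_hits_tsv(config$hits, fam_map)
    assignments <- assign_dnd_genes(hits, config$evalue, config$qcov)
    gene_owner <- bind_rows(lapply(genomes, function(g) {
      tibble(genome_id = g$genome_id, gene_id = g$features$gene_id)
    }))
    assignments <- assignments %>%
      select(-any_of("genome_id")) %>%
      inner_join(gene_owner, by = "gene_id")
    calls <- bind_rows(lapply(genomes, function(g) {
      call_adjacent_clusters(
        g, filter(assignments, .data$genome_id == g$genome_id),
        max_gap = config$max_gap)
    }))
    profiles <- profile_genomes(genomes, assignments, calls,
                                rm_window = config$rm_window)
    results$assignments <- assignments
    results$calls <- calls
    results$profiles <- profiles
    save_tsv(assignments, "dnd_assignments.tsv")
    save_tsv(calls, "dnd_cluster_calls.tsv")
    save_tsv(profiles, "dnd_profiles.tsv")
  }

  # ---- prophage ----
  if (!is.null(config$prophages)) {
    regions <- read_prophage_tsv(config$prophages)
    genome_ids <- if (!is.null(config$taxonomy)) {
      read_taxonomy_tsv(config$taxonomy)$genome_id
    } else if (!is.null(results$profiles)) {
      results$profiles$genome_id
    } else {
      unique(regions$genome_id)
    }
    counts <- prophage_abundance(genome_ids, regions)
    results$prophage_counts <- counts
    save_tsv(counts, "prophage_counts.tsv")
    if (!is.null(config$viral_hits)) {
      vmap <- if (!is.null(config$viral_family_map)) {
        read_family_map_tsv(config$viral_family_map)
      } else NULL
      vhits <- read_hits_tsv(config$viral_hits, vmap)
      fams <- assign_family(regions, vhits, bitscore_min = config$bitscore,
                            majority = config$majority)
      results$prophage_families <- fams
      save_tsv(fams, "prophage_families.tsv")
    }
  }

  # ---- cooccur ----
  if (!is.null(results$profiles) && !is.null(results$prophage_counts) &&
      !is.null(config$taxonomy)) {
    taxonomy <- read_taxonomy_tsv(config$taxonomy)
    occ <- occurrence_by_taxon(results$profiles, results$prophage_counts,
                               taxonomy, rank = config$rank,
                               min_genomes = config$min_genomes)
    scan <- within_taxon_scan(results$profiles, results$prophage_counts,
                              taxonomy, rank = config$rank,
                              min_carrying = config$eligibility_min)
    across <- occ %>%
      tidyr::pivot_wider(id_cols = "taxon", names_from = "feature",
                         values_from = "occurrence") %>%
      (function(w) {
        bind_rows(lapply(dnd_feature_names(), function(f) {
          mutate(across_taxon_association(w$prophage, w[[f]]), feature = f,
                 .before = 1)
        }))
      })
    results$occurrence <- occ
    results$within_scan <- scan
    results$across <- across
    save_tsv(occ, "occurrence_by_taxon.tsv")
    save_tsv(scan, "within_taxon_tau.tsv")
    save_tsv(across, "across_taxon_association.tsv")
  }

  # ---- ptmap ----
  if (!is.null(config$fasta)) {
    seqs <- read_fasta(config$fasta)
    motif_hits <- bind_rows(lapply(names(seqs), function(id) {
      scan_motifs(seqs[[id]], replicon_id = id)
    }))
    results$motif_hits <- motif_hits
    save_tsv(motif_hits, "motif_scan.tsv")
  }
  if (!is.null(config$sites) && !is.null(genomes) && length(genomes) == 1) {
    sites <- read_sites_tsv(config$sites)
    mapping <- map_sites_to_features(sites, genomes[[1]])
    results$gene_site_counts <- mapping$gene_counts
    save_tsv(mapping$gene_counts, "gene_site_counts.tsv")
    if (!is.null(config$de)) {
      de <- read_de_tsv(config$de)
      coupling <- deg_pt_coupling(de, mapping$gene_counts,
                                  fdr_max = config$fdr, fc_min = config$fc)
      results$deg_coupling <- coupling
      save_tsv(coupling, "deg_pt_coupling.tsv")
    }
  }

  # ---- fitness ----
  if (!is.null(config$competition)) {
    series <- read_competition_csv(config$competition)
    fit <- relative_fitness(series, config$fitness_interval,
                            dilution_factor = config$dilution)
    results$fitness <- fit
    save_tsv(tidy(fit), "fitness_replicates.tsv")
    save_tsv(glance(fit), "fitness_summary.tsv")
  }

  summary <- list(
    package = "dndphage",
    version = as.character(utils::packageVersion("dndphage")),
    seed = config$seed,
    thresholds = config[c("evalue", "qcov", "max_gap", "rm_window",
                          "bitscore", "majority", "min_genomes",
                          "eligibility_min", "fdr", "fc", "dilution",
                          "rank")],
    inputs = lapply(inputs, function(p) {
      lapply(as.list(unname(unlist(p))), function(f) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      })
    }),
    outputs = lapply(as.list(outputs), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    stages_run = names(results)
  )
  jsonlite::write_json(summary, file.path(config$out_dir,
                                          "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

# ---- writers mirroring the readers (used by the simulator and CLI) -------

#' Write a hit table as BLAST outfmt-6 TSV (14 columns)
#'
#' Columns not tracked by the package (mismatch, gapopen, coordinates) are
#' written as zeros; `qcovhsp` is emitted in percent.
#'
#' @param hits Tibble in the [read_hits_tsv()] schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  lines <- sprintf(
    "%s\t%s\t%.2f\t%d\t0\t0\t0\t0\t0\t0\t%.3g\t%.1f\t%d\t%.2f",
    hits$query_id, hits$subject_id, hits$pident,
    as.integer(hits$aln_length), hits$evalue, hits$bitscore,
    as.integer(hits$qlen), hits$qcov * 100
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a subject-to-family map TSV
#'
#' @param family_map Named character vector (names = subject ids) or tibble
#'   with `subject_id`/`family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_map_tsv <- function(family_map, path) {
  df <- if (is.data.frame(family_map)) family_map
        else tibble(subject_id = names(family_map),
                    family = unname(family_map))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write prophage regions in the headered TSV dialect of
#' [read_prophage_tsv()]
#'
#' @param regions Region tibble with a `protein_ids` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prophage_tsv <- function(regions, path) {
  regions$protein_ids <- vapply(regions$protein_ids, paste, "",
                                collapse = ",")
  readr::write_tsv(regions, path)
  invisible(path)
}
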