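# Seeded generators for every input the pipeline consumes. Each generator
# is a pure function of (parameters, seed): the same seed gives identical
# output. Defaults emulate the census conditions the association analysis
# was designed for: genus panels of ~100 complete genomes, dndBCDE in
# ~1.8% and dndFGH in ~1.1% of genomes, a mean prophage load near 1.8 per
# genome, and a log-linear negative shift of the prophage rate in
# dnd-positive genomes.

#' Specification for a synthetic genome panel
#'
#' @param n_genera Number of genera.
#' @param genomes_per_genus Genomes per genus (single integer).
#' @param genes_per_genome CDS per genome.
#' @param cluster_prevalence Named numeric: planting probability per genome
#'   for `dndCD`, `dndBCDE`, `dndFGH`.
#' @param prophage_rate Poisson rate of prophages per dnd-free genome.
#' @param dependence_beta Log-rate shift of the prophage count for genomes
#'   carrying a dnd cluster: counts are Poisson(rate * exp(beta * I[dnd])),
#'   beta < 0 encodes a negative association.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_genera = 5L,
                       genomes_per_genus = 100L,
                       genes_per_genome = 100L,
                       cluster_prevalence = c(dndCD = 0.03, dndBCDE = 0.018,
                                              dndFGH = 0.011),
                       prophage_rate = 1.8,
                       dependence_beta = -1.5) {
  stopifnot(n_genera >= 1, genomes_per_genus >= 1, genes_per_genome >= 1,
            prophage_rate > 0,
            all(cluster_prevalence >= 0 & cluster_prevalence <= 1),
            all(names(dnd_cluster_types()) %in% names(cluster_prevalence)))
  structure(
    list(n_genera = as.integer(n_genera),
         genomes_per_genus = as.integer(genomes_per_genus),
         genes_per_genome = as.integer(genes_per_genome),
         cluster_prevalence = cluster_prevalence,
         prophage_rate = prophage_rate,
         dependence_beta = dependence_beta),
    class = "panel_spec"
  )
}

# canonical gene order used when planting a cluster
cluster_gene_order <- function(ct) {
  switch(ct,
         dndCD = c("dndC", "dndD"),
         dndBCDE = c("dndB", "dndC", "dndD", "dndE"),
         dndFGH = c("dndF", "dndG", "dndH"))
}

#' Simulate a genome panel with planted dnd clusters and prophage counts
#'
#' Generates per-genus genomes with consecutive gene ordinals, plants dnd
#' clusters as adjacent runs in canonical gene order, and draws per-genome
#' prophage counts from `Poisson(rate * exp(beta * I[dnd cluster present]))`.
#' Planting `dndBCDE` implies a `dndCD` sub-cluster (C and D are adjacent in
#' canonical order), which the truth tables record.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed (mandatory; the generator is a pure function of
#'   spec and seed).
#' @param include_features Emit the per-gene feature table (default `TRUE`;
#'   turn off for large statistical simulations that only need the
#'   genome-level truth).
#' @return A list of tibbles: `taxonomy` (genome_id + ranks), `genomes`
#'   (planted flags, `dnd_present`, `prophage_count`), `features`,
#'   `replicons`, `truth_assignments` (genome_id, gene_id, family),
#'   `truth_clusters` (planted and implied calls), `prophage_counts`,
#'   `prophage_regions`, plus `spec` and `seed`.
#' @export
simulate_panel <- function(spec, seed, include_features = TRUE) {
  stopifnot(inherits(spec, "panel_spec"), is.numeric(seed))
  cluster_len <- lengths(dnd_cluster_types())
  if (spec$genes_per_genome < sum(cluster_len) + 2 * length(cluster_len)) {
    abort("genes_per_genome too small to plant all cluster types")
  }
  withr::with_seed(as.integer(seed), {
    n_g <- spec$n_genera * spec$genomes_per_genus
    genus <- rep(sprintf("Genus_%02d", seq_len(spec$n_genera)),
                 each = spec$genomes_per_genus)
    genome_id <- sprintf("%s_g%04d", genus,
                         rep(seq_len(spec$genomes_per_genus),
                             times = spec$n_genera))
    taxonomy <- tibble(
      genome_id = genome_id,
      phylum = "Synthibacterota", class = "Synthibacteria",
      order = "Synthibacterales", family = "Synthibacteraceae",
      genus = genus,
      species = paste0(genus, "_sp")
    )

    cts <- names(dnd_cluster_types())
    planted <- vapply(cts, function(ct) {
      runif(n_g) < spec$cluster_prevalence[[ct]]
    }, logical(n_g))
    if (n_g == 1) planted <- matrix(planted, nrow = 1,
                                    dimnames = list(NULL, cts))
    dnd_present <- rowSums(planted) > 0
    rate <- spec$prophage_rate * exp(spec$dependence_beta * dnd_present)
    prophage_count <- rpois(n_g, rate)

    # place planted clusters at non-overlapping ordinal runs
    truth_clusters <- list()
    truth_assignments <- list()
    G <- spec$genes_per_genome
    for (i in seq_len(n_g)) {
      which_ct <- cts[planted[i, ]]
      if (length(which_ct) == 0) next
      taken <- integer()
      for (ct in which_ct) {
        fams <- cluster_gene_order(ct)
        k <- length(fams)
        repeat {
          start <- sample.int(G - k + 1L, 1L) - 1L
          run <- start:(start + k - 1L)
          if (!any(run %in% taken)) break
        }
        taken <- c(taken, run)
        gene_ids <- sprintf("%s_c%04d", genome_id[i], run + 1L)
        truth_assignments[[length(truth_assignments) + 1L]] <- tibble(
          genome_id = genome_id[i], gene_id = gene_ids, family = fams,
          ordinal = run
        )
        truth_clusters[[length(truth_clusters) + 1L]] <- tibble(
          genome_id = genome_id[i], cluster_type = ct,
          ordinal_first = run[1], ordinal_last = run[k], implied = FALSE
        )
        if (ct == "dndBCDE") {
          # canonical order makes C,D adjacent: a dndCD call is implied
          cd <- run[match(c("dndC", "dndD"), fams)]
          truth_clusters[[length(truth_clusters) + 1L]] <- tibble(
            genome_id = genome_id[i], cluster_type = "dndCD",
            ordinal_first = cd[1], ordinal_last = cd[2], implied = TRUE
          )
        }
      }
    }
    truth_assignments <- if (length(truth_assignments) > 0) {
      bind_rows(truth_assignments)
    } else {
      tibble(genome_id = character(), gene_id = character(),
             family = character(), ordinal = integer())
    }
    truth_clusters <- if (length(truth_clusters) > 0) bind_rows(truth_clusters)
      else tibble(genome_id = character(), cluster_type = character(),
                  ordinal_first = integer(), ordinal_last = integer(),
                  implied = logical())

    features <- NULL
    replicons <- tibble(genome_id = genome_id, replicon_id = "chr",
                        length = G * 1000, circular = FALSE)
    if (include_features) {
      ord <- rep(seq_len(G) - 1L, times = n_g)
      gid <- rep(genome_id, each = G)
      features <- tibble(
        genome_id = gid,
        gene_id = sprintf("%s_c%04d", gid, ord + 1L),
        replicon_id = "chr",
        start = ord * 1000 + 1, end = ord * 1000 + 900,
        strand = "+"
      )
    }

    # prophage regions backing the counts (protein ids for taxonomy votes)
    reg_gen <- rep(seq_len(n_g), prophage_count)
    prophage_regions <- if (length(reg_gen) > 0) {
      idx <- unlist(lapply(prophage_count[prophage_count > 0], seq_len))
      tibble(
        region_id = sprintf("%s_ph%02d", genome_id[reg_gen], idx),
        genome_id = genome_id[reg_gen],
        replicon_id = "chr",
        start = (idx - 1) * 40000 + 5000, end = (idx - 1) * 40000 + 25000,
        protein_ids = lapply(sprintf("%s_ph%02d", genome_id[reg_gen], idx),
                             function(r) sprintf("%s_p%02d", r, 1:10))
      )
    } else {
      tibble(region_id = character(), genome_id = character(),
             replicon_id = character(), start = numeric(), end = numeric(),
             protein_ids = list())
    }

    genomes <- tibble(
      genome_id = genome_id, genus = genus,
      planted_dndCD = planted[, "dndCD"],
      planted_dndBCDE = planted[, "dndBCDE"],
      planted_dndFGH = planted[, "dndFGH"],
      dnd_present = dnd_present,
      prophage_count = prophage_count
    )
    list(
      taxonomy = taxonomy, genomes = genomes, features = features,
      replicons = replicons, truth_assignments = truth_assignments,
      truth_clusters = truth_clusters,
      prophage_counts = tibble(genome_id = genome_id,
                               prophage_count = prophage_count,
                               prophage_present = prophage_count >= 1),
      prophage_regions = prophage_regions,
      spec = spec, seed = as.integer(seed)
    )
  })
}

#' Materialise genome records from a simulated panel
#'
#' @param panel Output of [simulate_panel()] (with features).
#' @return Named list of [genome_record()] objects.
#' @export
panel_genome_records <- function(panel) {
  if (is.null(panel$features)) {
    abort("panel was simulated with include_features = FALSE")
  }
  ids <- unique(panel$features$genome_id)
  recs <- lapply(ids, function(g) {
    genome_record(
      g,
      features = filter(panel$features, .data$genome_id == g) %>%
        select(-"genome_id"),
      replicons = filter(panel$replicons, .data$genome_id == g) %>%
        select(-"genome_id")
    )
  })
  setNames(recs, ids)
}

#' Simulate a homology hit table for planted dnd assignments
#'
#' True hits are drawn to pass the screening thresholds comfortably
#' (e-value <= 1e-12, query coverage >= 0.6); decoy hits fail at least one
#' threshold (half by e-value, half by coverage) while being allowed high
#' bitscores, so threshold filtering - not ranking - must remove them.
#'
#' @param truth_assignments Tibble with `genome_id`, `gene_id`, `family`
#'   (from [simulate_panel()]).
#' @param n_decoys Number of decoy hits (default: one per true hit).
#' @param seed Integer seed.
#' @return Tibble in the schema of [read_hits_tsv()] (plus `genome_id`).
#' @export
simulate_hit_table <- function(truth_assignments, n_decoys = NULL, seed) {
  stopifnot(is.numeric(seed))
  ta <- as_tibble(truth_assignments)
  n_true <- nrow(ta)
  n_decoys <- n_decoys %||% n_true
  withr::with_seed(as.integer(seed), {
    true_hits <- if (n_true > 0) {
      qlen <- round(runif(n_true, 200, 600))
      qcov <- runif(n_true, 0.6, 1)
      tibble(
        genome_id = ta$genome_id,
        query_id = ta$gene_id,
        subject_id = paste0(ta$family, "_ref"),
        subject_family = ta$family,
        pident = runif(n_true, 40, 95),
        aln_length = pmax(1, round(qcov * qlen)),
        evalue = 10^-runif(n_true, 12, 60),
        bitscore = runif(n_true, 100, 400),
        qlen = qlen,
        qcov = qcov
      )
    } else NULL
    decoys <- if (n_decoys > 0) {
      fams <- sample(dnd_families(), n_decoys, replace = TRUE)
      by_evalue <- runif(n_decoys) < 0.5
      qlen <- round(runif(n_decoys, 200, 600))
      qcov <- if_else(by_evalue, runif(n_decoys, 0.55, 1),
                      runif(n_decoys, 0.05, 0.49))
      tibble(
        genome_id = if (n_true > 0) sample(ta$genome_id, n_decoys,
                                           replace = TRUE)
                    else "decoy_genome",
        query_id = sprintf("decoy_q%04d", seq_len(n_decoys)),
        subject_id = paste0(fams, "_ref"),
        subject_family = fams,
        pident = runif(n_decoys, 25, 60),
        aln_length = pmax(1, round(qcov * qlen)),
        evalue = if_else(by_evalue, 10^-runif(n_decoys, 0, 9.5),
                         10^-runif(n_decoys, 12, 60)),
        bitscore = runif(n_decoys, 100, 500),
        qlen = qlen,
        qcov = qcov
      )
    } else NULL
    bind_rows(true_hits, decoys)
  })
}

#' Simulate per-protein viral hits for one prophage region
#'
#' A fraction `purity` of the region's proteins receive a qualifying best
#' hit (bitscore >= 50) to `true_family`; the remainder receive only
#' sub-threshold hits, so they abstain from the majority vote. The expected
#' assignment is `true_family` iff `round(purity * n) / n >= 0.5`.
#'
#' @param region One-row region tibble (columns `region_id`,
#'   `protein_ids`), e.g. a row of [simulate_panel()]'s `prophage_regions`.
#' @param true_family Viral family of the planted prophage.
#' @param purity Fraction of proteins with a qualifying hit to
#'   `true_family`.
#' @param seed Integer seed.
#' @param decoy_families Families used for the sub-threshold hits.
#' @return Tibble of hits in the [read_hits_tsv()] schema.
#' @export
simulate_prophage_proteins <- function(region, true_family, purity, seed,
                                       decoy_families = c("Myoviridae",
                                                          "Podoviridae")) {
  stopifnot(purity >= 0, purity <= 1, is.numeric(seed))
  region <- as_tibble(region)
  require_columns(region, c("region_id", "protein_ids"), "region")
  prots <- region$protein_ids[[1]]
  n <- length(prots)
  if (n == 0) abort("region has no proteins")
  n_true <- round(purity * n)
  withr::with_seed(as.integer(seed), {
    idx_true <- if (n_true > 0) sample.int(n, n_true) else integer()
    rows <- lapply(seq_len(n), function(i) {
      if (i %in% idx_true) {
        tibble(query_id = prots[i],
               subject_id = paste0(true_family, "_vp"),
               subject_family = true_family,
               pident = runif(1, 40, 90), aln_length = 200,
               evalue = 10^-runif(1, 5, 50),
               bitscore = runif(1, 60, 300), qlen = 250, qcov = 0.8)
      } else {
        fam <- sample(decoy_families, 1)
        tibble(query_id = prots[i],
               subject_id = paste0(fam, "_vp"),
               subject_family = fam,
               pident = runif(1, 20, 40), aln_length = 80,
               evalue = 10^-runif(1, 1, 4),
               bitscore = runif(1, 10, 49), qlen = 250, qcov = 0.32)
      }
    })
    bind_rows(rows)
  })
}

#' Simulate a sequence with planted PT consensus motifs
#'
#' Builds a background sequence free of accidental GAAC/GTTC occurrences
#' (rejection resampling of matching windows), plants exactly the requested
#' number of motifs of each class at non-overlapping positions, and emits a
#' `modified_fraction` of them (per class, rounded to whole sites) as PT
#' sites. The planted counts are therefore exactly recoverable by
#' [scan_motifs()] and [modified_fraction()].
#'
#' @param length Sequence length (nt).
#' @param n_motifs Named integer vector, e.g. `c(GAAC = 200, GTTC = 180)`.
#' @param modified_fraction Fraction of planted motifs emitted as modified
#'   PT sites (applied per class).
#' @param seed Integer seed.
#' @param replicon_id Replicon label (default `"chr"`).
#' @return A list: `sequence` (named character), `planted` (tibble of all
#'   planted motifs), `sites` (PT-site tibble in the [read_sites_tsv()]
#'   schema) and `n_motifs`.
#' @export
simulate_sequence_with_motifs <- function(length, n_motifs,
                                          modified_fraction, seed,
                                          replicon_id = "chr") {
  stopifnot(all(c("GAAC", "GTTC") %in% names(n_motifs)),
            modified_fraction >= 0, modified_fraction <= 1,
            is.numeric(seed))
  total_planted <- sum(n_motifs)
  if (length < 8 * total_planted + 8) {
    abort("sequence too short to place the requested motifs without overlap")
  }
  withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    seq_chr <- sample(bases, length, replace = TRUE)

    rescan <- function(s) scan_motifs(paste0(s, collapse = ""),
                                      replicon_id = replicon_id)
    # scrub accidental motifs
    for (it in 1:200) {
      hits <- rescan(seq_chr)
      if (nrow(hits) == 0) break
      for (p in hits$position) {
        seq_chr[p:(p + 3)] <- sample(bases, 4, replace = TRUE)
      }
    }
    if (nrow(rescan(seq_chr)) > 0) abort("failed to scrub accidental motifs")

    # plant at non-overlapping positions, away from the ends
    slots <- seq(5, length - 8, by = 4)
    starts <- sort(sample(slots, total_planted))
    motif <- sample(rep(names(n_motifs), times = n_motifs))
    for (i in seq_along(starts)) {
      seq_chr[starts[i]:(starts[i] + 3)] <-
        strsplit(motif[i], "")[[1]]
    }
    planted <- tibble(motif = motif, position = starts)

    # junction repair: resample bases around spurious new matches
    protected <- unlist(lapply(starts, function(s) s:(s + 3)))
    for (it in 1:200) {
      hits <- rescan(seq_chr)
      extra <- hits %>%
        anti_join(planted, by = c("motif", "position"))
      if (nrow(extra) == 0 && nrow(hits) == nrow(planted)) break
      for (p in extra$position) {
        win <- p:(p + 3)
        free <- setdiff(win, protected)
        if (length(free) == 0) abort("cannot place motifs without overlap")
        seq_chr[free] <- sample(bases, length(free), replace = TRUE)
      }
    }
    final_hits <- rescan(seq_chr)
    if (nrow(final_hits) != nrow(planted) ||
        nrow(anti_join(final_hits, planted,
                       by = c("motif", "position"))) > 0) {
      abort("failed to repair motif junctions")
    }

    sites <- planted %>%
      group_by(.data$motif) %>%
      slice(sort(sample.int(n(), round(modified_fraction * n())))) %>%
      ungroup() %>%
      mutate(replicon_id = replicon_id, strand = "+",
             motif_class = if_else(.data$motif == "GAAC", "GpsAAC",
                                   "GpsTTC"),
             dinucleotide = if_else(.data$motif == "GAAC", "d(GpsA)",
                                    "d(GpsT)")) %>%
      select("replicon_id", "position", "strand", "motif_class",
             "dinucleotide")
    list(sequence = setNames(paste0(seq_chr, collapse = ""), replicon_id),
         planted = planted, sites = sites, n_motifs = n_motifs)
  })
}

#' Simulate a serial-transfer competition assay
#'
#' The deterministic strain-fraction trajectory is obtained by inverting
#' the doubling model: each day the test strain grows `g` fold and the
#' reference strain `g^W` fold, with total regrowth equal to the dilution
#' factor; colony sampling is binomial per time point and replicate.
#'
#' @param true_W True relative fitness (reference over test strain).
#' @param f0 Test-strain fraction at T0.
#' @param n_transfers Number of daily transfers.
#' @param dilution_factor Fold dilution/regrowth per transfer (default 100).
#' @param colonies_per_sample Colonies screened per sample (default 100).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed.
#' @return A list: `series` (tibble `time`, `replicate`, `count_a`,
#'   `total`, `fraction_a`) and `trajectory` (deterministic fractions).
#' @export
simulate_competition <- function(true_W, f0, n_transfers,
                                 dilution_factor = 100,
                                 colonies_per_sample = 100, replicates = 3,
                                 seed) {
  stopifnot(true_W > 0, f0 > 0, f0 < 1, n_transfers >= 1, is.numeric(seed))
  f <- numeric(n_transfers + 1)
  f[1] <- f0
  for (t in seq_len(n_transfers)) {
    ft <- f[t]
    g <- uniroot(
      function(g) ft * g + (1 - ft) * g^true_W - dilution_factor,
      lower = 1e-9, upper = dilution_factor / min(ft, 1 - ft) + 1,
      tol = 1e-12
    )$root
    f[t + 1] <- ft * g / dilution_factor
    if (f[t + 1] < 1e-3 || f[t + 1] > 1 - 1e-3) {
      abort(paste0("trajectory approaches fixation at transfer ", t,
                   "; use a shorter horizon"))
    }
  }
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(time = 0:n_transfers,
                               replicate = seq_len(replicates))
    grid$count_a <- rbinom(nrow(grid), colonies_per_sample,
                           f[grid$time + 1])
    grid$total <- colonies_per_sample
    grid$fraction_a <- grid$count_a / grid$total
    list(series = grid,
         trajectory = tibble(time = 0:n_transfers, fraction_a = f))
  })
}

#' Simulate a differential-expression table with PT-site content
#'
#' Planted DEGs satisfy `fdr < 0.05` and linear `|FC| > 2` by construction;
#' all other genes fail at least one criterion. Each gene carries PT sites
#' with probability `pt_prob` (shifted by `enrichment` on the log-odds
#' scale for DEGs); site counts for site-carrying genes are
#' `1 + Poisson(extra_sites)`.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_deg Number of planted DEGs (default 57).
#' @param pt_prob Probability a (non-DEG) gene contains >= 1 PT site
#'   (default 0.331).
#' @param enrichment Log-odds shift of `pt_prob` for DEGs (default 0).
#' @param extra_sites Poisson mean of additional sites in site-carrying
#'   genes (default 1).
#' @param seed Integer seed.
#' @return A list: `de` (tibble `gene_id`, `log2fc`, `fdr`), `gene_counts`
#'   (tibble `gene_id`, `n_total`) and `truth` (tibble with `is_deg`).
#' @export
simulate_de_table <- function(n_genes = 5000L, n_deg = 57L,
                              pt_prob = 0.331, enrichment = 0,
                              extra_sites = 1, seed) {
  stopifnot(n_deg <= n_genes, pt_prob >= 0, pt_prob <= 1, is.numeric(seed))
  withr::with_seed(as.integer(seed), {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    is_deg <- seq_len(n_genes) %in% sample.int(n_genes, n_deg)
    log2fc <- numeric(n_genes)
    fdr <- numeric(n_genes)
    # DEGs: |log2FC| > 1 and fdr < 0.05
    sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
    log2fc[is_deg] <- sgn[is_deg] * runif(sum(is_deg), 1.1, 4)
    fdr[is_deg] <- runif(sum(is_deg), 0, 0.049)
    # non-DEGs fail at least one criterion
    small_fc <- runif(n_genes) < 0.5
    nd <- !is_deg
    log2fc[nd & small_fc] <- runif(sum(nd & small_fc), -0.99, 0.99)
    fdr[nd & small_fc] <- runif(sum(nd & small_fc), 0, 1)
    log2fc[nd & !small_fc] <- sgn[nd & !small_fc] *
      runif(sum(nd & !small_fc), 0, 4)
    fdr[nd & !small_fc] <- runif(sum(nd & !small_fc), 0.05, 1)

    p_site <- stats::plogis(stats::qlogis(pt_prob) + enrichment * is_deg)
    has_site <- runif(n_genes) < p_site
    n_total <- ifelse(has_site, 1 + rpois(n_genes, extra_sites), 0L)
    list(
      de = tibble(gene_id = gene_id, log2fc = log2fc, fdr = fdr),
      gene_counts = tibble(gene_id = gene_id, n_total = as.integer(n_total)),
      truth = tibble(gene_id = gene_id, is_deg = is_deg)
    )
  })
}
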