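# I/O and coordinate conventions.
#
# All user-facing coordinates are 1-based inclusive (the GFF3 and
# Bioconductor convention); widths are end - start + 1. Gene ordinals are
# 0-based ranks of CDS features along a replicon, sorted by start (ties by
# end, then gene_id), and are the unit of all adjacency and distance rules.

# ---- genome records ------------------------------------------------------

#' Construct an annotated genome record
#'
#' Bundles the gene features and replicon table of one genome. Feature
#' ordinals are (re)assigned on construction so that, within each replicon,
#' they form the consecutive sequence `0..N-1` ordered by start position.
#'
#' @param genome_id Genome identifier.
#' @param features Data frame with columns `gene_id`, `replicon_id`,
#'   `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`), and
#'   optionally `product`.
#' @param replicons Data frame with columns `replicon_id`, `length` (bp) and
#'   optionally `circular` (logical, default `FALSE`).
#' @param taxonomy Optional named list/one-row data frame with any of
#'   `phylum`, `class`, `order`, `family`, `genus`, `species`.
#' @return An object of class `genome_record`: a list with elements
#'   `genome_id`, `features` (tibble, with `ordinal` assigned), `replicons`
#'   (tibble) and `taxonomy`.
#' @examples
#' gr <- genome_record(
#'   "g1",
#'   features = tibble::tibble(
#'     gene_id = c("a", "b"), replicon_id = "chr",
#'     start = c(100, 400), end = c(300, 600), strand = "+"
#'   ),
#'   replicons = tibble::tibble(replicon_id = "chr", length = 1000)
#' )
#' gr$features$ordinal
#' @export
genome_record <- function(genome_id, features, replicons, taxonomy = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1)
  features <- as_tibble(features)
  replicons <- as_tibble(replicons)
  require_columns(replicons, c("replicon_id", "length"), "replicons")
  if (!"circular" %in% names(replicons)) replicons$circular <- FALSE
  replicons$length <- as.numeric(replicons$length)
  if (nrow(features) > 0) {
    require_columns(features, c("gene_id", "replicon_id", "start", "end", "strand"),
                    "features")
    if (!"product" %in% names(features)) features$product <- NA_character_
    bad <- !features$replicon_id %in% replicons$replicon_id
    if (any(bad)) {
      abort(paste0("features reference unknown replicon(s): ",
                   paste(unique(features$replicon_id[bad]), collapse = ", ")))
    }
    if (any(features$start > features$end)) {
      abort("feature start must be <= end (1-based inclusive coordinates)")
    }
    len <- replicons$length[match(features$replicon_id, replicons$replicon_id)]
    if (any(features$end > len)) {
      abort("feature end exceeds replicon length")
    }
    if (anyDuplicated(features$gene_id)) {
      abort("duplicate gene_id in features")
    }
    features <- assign_ordinals(features)
  } else {
    features <- tibble(
      gene_id = character(), replicon_id = character(), ordinal = integer(),
      start = numeric(), end = numeric(), strand = character(),
      product = character()
    )
  }
  structure(
    list(genome_id = genome_id, features = features, replicons = replicons,
         taxonomy = taxonomy),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ",
      nrow(x$features), " CDS on ", nrow(x$replicons), " replicon(s)\n",
      sep = "")
  invisible(x)
}

# ordinal = 0-based rank by (start, end, gene_id) within replicon
assign_ordinals <- function(features) {
  features %>%
    group_by(.data$replicon_id) %>%
    arrange(.data$start, .data$end, .data$gene_id, .by_group = TRUE) %>%
    mutate(ordinal = row_number() - 1L) %>%
    ungroup() %>%
    select("gene_id", "replicon_id", "ordinal", "start", "end", "strand",
           any_of("product"), dplyr::everything())
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("schema error in ", what, ": missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# ---- GFF3 ----------------------------------------------------------------

#' Read gene features from a GFF3 file
#'
#' Parses a GFF3 file (via rtracklayer) into a [genome_record()]. CDS
#' features are used when present, otherwise `gene` features. Replicon
#' lengths come from `##sequence-region` pragmas; circularity from `region`
#' features carrying `Is_circular=true` (the NCBI convention). Replicons
#' seen only through features get the maximal feature end as length, with a
#' warning.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return A [genome_record()].
#' @export
read_gff3 <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  body_end <- if (length(fasta_at) > 0) fasta_at[1] - 1L else length(lines)
  for (i in seq_len(body_end)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9) {
      abort(paste0("malformed GFF3 line ", i, " in ", path,
                   ": expected 9 tab-separated fields, found ", nf))
    }
  }

  # replicon table from sequence-region pragmas
  sr <- lines[startsWith(lines, "##sequence-region")]
  replicons <- if (length(sr) > 0) {
    parts <- strsplit(trimws(sub("^##sequence-region", "", sr)), "\\s+")
    tibble(
      replicon_id = vapply(parts, `[`, "", 1),
      length = as.numeric(vapply(parts, `[`, "", 3)),
      circular = FALSE
    )
  } else {
    tibble(replicon_id = character(), length = numeric(), circular = logical())
  }

  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)

  # circularity via region features with Is_circular=true
  if ("Is_circular" %in% names(mc)) {
    circ_ids <- as.character(GenomicRanges::seqnames(gr))[
      !is.na(mc$Is_circular) & tolower(as.character(mc$Is_circular)) == "true"
    ]
    replicons$circular <- replicons$replicon_id %in% circ_ids
  }

  types <- as.character(mc$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  cds <- gr[keep]
  if (length(cds) == 0) {
    warn(paste0("no CDS or gene features in ", path,
                "; returning an empty-feature record"))
  }
  mcc <- S4Vectors::mcols(cds)
  pick_attr <- function(nm) {
    if (nm %in% names(mcc)) as.character(mcc[[nm]]) else rep(NA_character_, length(cds))
  }
  gene_id <- dplyr::coalesce(pick_attr("ID"), pick_attr("locus_tag"),
                             pick_attr("Name"))
  gene_id[is.na(gene_id)] <- paste0("cds_", which(is.na(gene_id)))

  features <- tibble(
    gene_id = gene_id,
    replicon_id = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    product = pick_attr("product")
  )
  features$strand[!features$strand %in% c("+", "-")] <- "+"

  # replicons only seen via features: infer length
  orphan <- setdiff(unique(features$replicon_id), replicons$replicon_id)
  if (length(orphan) > 0) {
    warn(paste0("no ##sequence-region pragma for: ",
                paste(orphan, collapse = ", "),
                "; using max feature end as length"))
    inferred <- features %>%
      filter(.data$replicon_id %in% orphan) %>%
      group_by(.data$replicon_id) %>%
      summarise(length = max(.data$end), .groups = "drop") %>%
      mutate(circular = FALSE)
    replicons <- bind_rows(replicons, inferred)
  }

  genome_record(genome_id, features, replicons)
}

#' Write a genome record to GFF3
#'
#' Emits `##sequence-region` pragmas, one `region` feature per replicon
#' (with `Is_circular=true` where applicable) and one `CDS` row per gene
#' feature, so that `read_gff3(write_gff3(x))` round-trips the feature set
#' exactly.
#'
#' @param record A [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  esc <- function(x) gsub("[;=\t\n]", "_", x)
  out <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d",
                   record$replicons$replicon_id,
                   as.integer(record$replicons$length)))
  out <- c(out, sprintf(
    "%s\tdndphage\tregion\t1\t%d\t.\t+\t.\tID=region_%s%s",
    record$replicons$replicon_id, as.integer(record$replicons$length),
    esc(record$replicons$replicon_id),
    if_else(record$replicons$circular, ";Is_circular=true", "")
  ))
  f <- record$features
  if (nrow(f) > 0) {
    f <- f %>% arrange(.data$replicon_id, .data$start, .data$end, .data$gene_id)
    attrs <- sprintf("ID=%s", esc(f$gene_id))
    has_prod <- !is.na(f$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", esc(f$product[has_prod]))
    out <- c(out, sprintf("%s\tdndphage\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                          f$replicon_id, as.integer(f$start), as.integer(f$end),
                          f$strand, attrs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector of sequences
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- homology hits -------------------------------------------------------

#' Read a BLAST/DIAMOND tabular (outfmt 6) hit table
#'
#' Expects the standard 12-column order `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`, optionally
#' followed by `qlen` and `qcovhsp` (percent). Lines starting with `#` are
#' skipped. Query coverage is taken from `qcovhsp/100` when present,
#' otherwise computed as `length/qlen`.
#'
#' @param path Path to the TSV (no header).
#' @param family_map Mapping from `subject_id` to a family label: a named
#'   character vector (names are subject ids) or a data frame with columns
#'   `subject_id` and `family`. Unmapped subjects get family `"unknown"`.
#' @return Tibble with columns `query_id`, `subject_id`, `subject_family`,
#'   `pident`, `aln_length`, `evalue`, `bitscore`, `qlen`, `qcov`.
#' @export
read_hits_tsv <- function(path, family_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(paste0("parse error in ", path, ": row ", which(nf < 12)[1],
                 " has ", nf[which(nf < 12)[1]], " columns; >=12 required"))
  }
  col <- function(i) vapply(fields, function(x) if (length(x) >= i) x[i] else NA_character_, "")
  num <- function(i, nm) {
    v <- suppressWarnings(as.numeric(col(i)))
    bad <- which(is.na(v) & !is.na(col(i)))
    if (length(bad) > 0) {
      abort(paste0("parse error in ", path, ": non-numeric ", nm,
                   " at row ", bad[1]))
    }
    v
  }
  hits <- tibble(
    query_id = col(1), subject_id = col(2),
    pident = num(3, "pident"), aln_length = num(4, "length"),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    qlen = if (any(nf >= 13)) num(13, "qlen") else NA_real_,
    qcovhsp = if (any(nf >= 14)) num(14, "qcovhsp") else NA_real_
  )
  if (any(hits$evalue < 0, na.rm = TRUE) || any(hits$bitscore < 0, na.rm = TRUE)) {
    abort(paste0("parse error in ", path, ": negative evalue or bitscore"))
  }
  hits <- hits %>%
    mutate(qcov = if_else(!is.na(.data$qcovhsp), .data$qcovhsp / 100,
                          .data$aln_length / .data$qlen)) %>%
    select(-"qcovhsp")
  if (any(is.na(hits$qcov))) {
    warn(paste0("qcov missing for ", sum(is.na(hits$qcov)), " row(s) in ",
                path, " (no qlen/qcovhsp); these rows never pass a coverage",
                " filter"))
  }
  if (any(hits$qcov <= 0 | hits$qcov > 1, na.rm = TRUE)) {
    abort(paste0("parse error in ", path, ": qcov outside (0, 1]"))
  }
  hits$subject_family <- map_families(hits$subject_id, family_map)
  hits %>%
    select("query_id", "subject_id", "subject_family", "pident",
           "aln_length", "evalue", "bitscore", "qlen", "qcov")
}

empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    subject_family = character(), pident = numeric(),
    aln_length = numeric(), evalue = numeric(), bitscore = numeric(),
    qlen = numeric(), qcov = numeric()
  )
}

map_families <- function(subject_id, family_map) {
  if (is.null(family_map)) return(rep("unknown", length(subject_id)))
  if (is.data.frame(family_map)) {
    require_columns(family_map, c("subject_id", "family"), "family_map")
    fm <- setNames(family_map$family, family_map$subject_id)
  } else {
    fm <- family_map
  }
  fam <- unname(fm[subject_id])
  fam[is.na(fam)] <- "unknown"
  fam
}

#' Read a subject-to-family mapping (two-column TSV)
#'
#' @param path TSV with header columns `subject_id` and `family`.
#' @return Named character vector usable as `family_map` in
#'   [read_hits_tsv()].
#' @export
read_family_map_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("subject_id", "family"), path)
  setNames(df$family, df$subject_id)
}

# ---- headered tables -----------------------------------------------------

#' Read a genome taxonomy table
#'
#' @param path Headered TSV with required column `genome_id` and any of
#'   `phylum`, `class`, `order`, `family`, `genus`, `species`. Unknown
#'   columns are preserved.
#' @return Tibble with all six rank columns (missing ranks filled with `NA`)
#'   and a logical `correlation_eligible` column (`FALSE` when genus is
#'   absent, since genus-level analyses need it).
#' @export
read_taxonomy_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, "genome_id", path)
  for (rk in c("phylum", "class", "order", "family", "genus", "species")) {
    if (!rk %in% names(df)) df[[rk]] <- NA_character_
  }
  df$correlation_eligible <- !is.na(df$genus) & nzchar(df$genus)
  as_tibble(df)
}

#' Read a prophage region table
#'
#' Emulates a VIBRANT-style summary: one row per predicted prophage region.
#'
#' @param path Headered TSV with required columns `genome_id`,
#'   `replicon_id`, `start`, `end` and `protein_ids` (comma-separated
#'   protein identifiers; may be empty). Optional `region_id`.
#' @return Tibble with `region_id`, `genome_id`, `replicon_id`, `start`,
#'   `end` and a list-column `protein_ids`.
#' @export
read_prophage_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("genome_id", "replicon_id", "start", "end",
                        "protein_ids"), path)
  if (any(df$start > df$end)) abort(paste0("region start > end in ", path))
  if (!"region_id" %in% names(df)) {
    df$region_id <- sprintf("%s|%s:%d-%d", df$genome_id, df$replicon_id,
                            as.integer(df$start), as.integer(df$end))
  }
  df$protein_ids <- lapply(
    strsplit(dplyr::coalesce(as.character(df$protein_ids), ""), ","),
    function(x) {
      x <- trimws(x)
      x[nzchar(x)]
    }
  )
  df %>% select("region_id", "genome_id", "replicon_id", "start", "end",
                "protein_ids", dplyr::everything()) %>% as_tibble()
}

#' Read a PT-site table
#'
#' @param path Headered TSV with required columns `replicon_id`, `position`
#'   (1-based coordinate of the modified G on the reference strand),
#'   `strand` (`+`/`-`) and `motif_class` (`GpsAAC`/`GpsTTC`, `GAAC`/`GTTC`
#'   accepted).
#' @return Tibble with the validated columns plus the derived
#'   `dinucleotide` (`d(GpsA)` for GpsAAC, `d(GpsT)` for GpsTTC).
#' @export
read_sites_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("replicon_id", "position", "strand", "motif_class"),
                  path)
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(paste0("invalid strand '", df$strand[bad[1]], "' at row ", bad[1],
                 " in ", path, " (must be + or -)"))
  }
  df$motif_class <- dplyr::recode(df$motif_class,
                                  GAAC = "GpsAAC", GTTC = "GpsTTC")
  bad <- which(!df$motif_class %in% c("GpsAAC", "GpsTTC"))
  if (length(bad) > 0) {
    abort(paste0("invalid motif_class at row ", bad[1], " in ", path))
  }
  if (any(df$position < 1)) abort(paste0("position < 1 in ", path))
  df$dinucleotide <- if_else(df$motif_class == "GpsAAC", "d(GpsA)", "d(GpsT)")
  as_tibble(df)
}

#' Read a differential-expression table
#'
#' @param path Headered TSV with required columns `gene_id`, `log2fc` and
#'   `fdr` (BH-adjusted p-values).
#' @return Tibble with the three validated columns (extras preserved).
#' @export
read_de_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("gene_id", "log2fc", "fdr"), path)
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    abort(paste0("fdr outside [0, 1] in ", path))
  }
  as_tibble(df)
}

#' Read a competition-assay colony-count table
#'
#' @param path Headered CSV with required columns `time` (transfer index,
#'   T0 = 0), `replicate`, `count_a` (colonies of the test strain A) and
#'   `total` (colonies screened).
#' @return Tibble with the validated columns plus `fraction_a`.
#' @export
read_competition_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  require_columns(df, c("time", "replicate", "count_a", "total"), path)
  if (any(df$total <= 0)) {
    abort(paste0("validation error in ", path,
                 ": colony counts sum to 0 at time ",
                 df$time[which(df$total <= 0)[1]]))
  }
  if (any(df$count_a < 0 | df$count_a > df$total)) {
    abort(paste0("validation error in ", path, ": count_a outside [0, total]"))
  }
  df$fraction_a <- df$count_a / df$total
  as_tibble(df)
}

#' Fetch a nucleotide FASTA record from NCBI by accession
#'
#' Thin convenience wrapper around the NCBI E-utilities `efetch` endpoint;
#' needs network access.
#'
#' @param accession Nucleotide accession (e.g. `"NC_011566.1"`).
#' @param destfile Path to write the FASTA to.
#' @return `destfile`, invisibly. Errors when the download fails.
#' @export
fetch_genome_fasta <- function(accession, destfile) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&id=", accession, "&rettype=fasta&retmode=text"
  )
  status <- tryCatch(
    utils::download.file(url, destfile, quiet = TRUE, mode = "wb"),
    error = function(e) abort(paste0("download of ", accession,
                                     " failed: ", conditionMessage(e)))
  )
  if (!identical(status, 0L) || !file.exists(destfile) ||
      file.size(destfile) == 0) {
    abort(paste0("download of ", accession, " failed"))
  }
  invisible(destfile)
}
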