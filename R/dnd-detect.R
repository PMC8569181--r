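# Dnd family assignment, adjacency-based cluster calling and
# restriction-modification (R-M) linkage.

#' Assign Dnd families to proteins from homology hits
#'
#' Applies the screening thresholds used for Dnd protein identification —
#' e-value strictly below `evalue_max` and query coverage at least
#' `qcov_min` — then assigns each query protein the family of its best
#' surviving hit (highest bitscore, ties broken by lower e-value, then
#' lexicographically by family). Hits whose `subject_family` is not one of
#' the eight Dnd families (see [dnd_families()]) are ignored.
#'
#' @param hits Tibble of homology hits as returned by [read_hits_tsv()].
#' @param evalue_max Exclusive e-value cutoff (default `1e-10`).
#' @param qcov_min Inclusive query-coverage cutoff, fraction (default `0.5`).
#' @return Tibble with one row per assigned protein: `gene_id`, `family`,
#'   and the winning hit's `subject_id`, `pident`, `evalue`, `bitscore`,
#'   `qcov`. If `hits` carries a `genome_id` column it is preserved.
#' @examples
#' hits <- tibble::tibble(
#'   query_id = "p1", subject_id = c("C1", "D1"),
#'   subject_family = c("dndC", "dndD"), pident = 60, aln_length = 300,
#'   evalue = 1e-50, bitscore = c(250, 180), qlen = 400, qcov = 0.75
#' )
#' assign_dnd_genes(hits)
#' @export
assign_dnd_genes <- function(hits, evalue_max = 1e-10, qcov_min = 0.5) {
  stopifnot(evalue_max > 0, qcov_min > 0)
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(empty_assignments(hits))
  require_columns(hits, c("query_id", "subject_family", "evalue", "bitscore",
                          "qcov"), "hits")
  keep_cols <- intersect("genome_id", names(hits))
  hits %>%
    filter(.data$subject_family %in% dnd_families(),
           !is.na(.data$qcov),
           .data$evalue < evalue_max,
           .data$qcov >= qcov_min) %>%
    group_by(across(all_of(c(keep_cols, "query_id")))) %>%
    arrange(dplyr::desc(.data$bitscore), .data$evalue, .data$subject_family,
            .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    mutate(gene_id = .data$query_id, family = .data$subject_family) %>%
    select(all_of(keep_cols), "gene_id", "family", "subject_id",
           any_of(c("pident")), "evalue", "bitscore", "qcov") %>%
    arrange(across(all_of(c(keep_cols, "gene_id"))))
}

empty_assignments <- function(hits = NULL) {
  out <- tibble(
    gene_id = character(), family = character(), subject_id = character(),
    pident = numeric(), evalue = numeric(), bitscore = numeric(),
    qcov = numeric()
  )
  if (!is.null(hits) && "genome_id" %in% names(hits)) {
    out <- mutate(out, genome_id = character(), .before = 1)
  }
  out
}

#' Call dnd gene clusters from adjacent family assignments
#'
#' A cluster type (`dndCD`, `dndBCDE`, `dndFGH`) is called when one gene per
#' required family lies in a window of consecutive CDS ordinals on one
#' replicon with at most `max_gap` intervening non-member CDS. Member gene
#' order and strand are unconstrained. Calls are non-overlapping (greedy,
#' left to right, minimal windows). On circular replicons the ordinal
#' sequence wraps around the origin.
#'
#' @param genome A [genome_record()].
#' @param assignments Tibble from [assign_dnd_genes()] whose `gene_id`s
#'   refer to features of `genome`.
#' @param max_gap Maximum number of intervening non-member CDS (default 0,
#'   i.e. strictly adjacent).
#' @return Tibble of cluster calls: `genome_id`, `cluster_type`,
#'   `replicon_id`, `ordinal_first`, `ordinal_last` (`first > last` marks a
#'   call wrapping a circular origin), `gene_ids` (list-column), `n_members`.
#' @export
call_adjacent_clusters <- function(genome, assignments, max_gap = 0L) {
  stopifnot(inherits(genome, "genome_record"), max_gap >= 0)
  assignments <- as_tibble(assignments)
  if (nrow(assignments) == 0) return(empty_cluster_calls())
  require_columns(assignments, c("gene_id", "family"), "assignments")
  unknown <- setdiff(assignments$gene_id, genome$features$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("assignments reference unknown gene_id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  genes <- genome$features %>%
    inner_join(assignments, by = "gene_id",
               suffix = c("", ".assignment"))

  calls <- list()
  for (ct in names(dnd_cluster_types())) {
    req <- dnd_cluster_types()[[ct]]
    members <- genes %>%
      filter(.data$family %in% req) %>%
      arrange(.data$replicon_id, .data$ordinal)
    for (rep_id in unique(members$replicon_id)) {
      m <- filter(members, .data$replicon_id == rep_id)
      n_cds <- sum(genome$features$replicon_id == rep_id)
      circ <- genome$replicons$circular[
        match(rep_id, genome$replicons$replicon_id)]
      calls[[length(calls) + 1L]] <- scan_member_runs(
        m, req, max_gap, n_cds, isTRUE(circ), genome$genome_id, ct, rep_id)
    }
  }
  if (length(calls) == 0) return(empty_cluster_calls())
  out <- bind_rows(calls)
  if (nrow(out) == 0) return(empty_cluster_calls())
  arrange(out, .data$replicon_id, .data$ordinal_first, .data$cluster_type)
}

# Scan runs of k consecutive member genes (k = number of required
# families); a run is a call when its families are exactly the required set
# and the ordinal span contains at most max_gap non-member CDS. Greedy
# non-overlapping selection, left to right.
scan_member_runs <- function(m, req, max_gap, n_cds, circular, genome_id,
                             cluster_type, replicon_id) {
  k <- length(req)
  n_m <- nrow(m)
  if (n_m < k) return(empty_cluster_calls())
  ords <- m$ordinal
  ids <- m$gene_id
  fams <- m$family
  idx_limit <- n_m
  if (circular && n_m >= k) {
    # unroll: append wrapped copies so runs may cross the origin
    ords <- c(ords, m$ordinal + n_cds)
    ids <- c(ids, m$gene_id)
    fams <- c(fams, m$family)
  }
  res <- list()
  used <- character()  # genes consumed by accepted calls (wrap-safe overlap)
  for (i in seq_len(idx_limit)) {
    j <- i + k - 1L
    if (j > length(ords)) break
    span <- ords[j] - ords[i] + 1L
    ok <- span <= n_cds &&
      !any(ids[i:j] %in% used) &&
      !anyDuplicated(fams[i:j]) &&
      setequal(fams[i:j], req) &&
      (span - k) <= max_gap
    if (ok) {
      res[[length(res) + 1L]] <- tibble(
        genome_id = genome_id, cluster_type = cluster_type,
        replicon_id = replicon_id,
        ordinal_first = as.integer(ords[i] %% n_cds),
        ordinal_last = as.integer(ords[j] %% n_cds),
        gene_ids = list(ids[i:j]), n_members = k
      )
      used <- c(used, ids[i:j])
    }
  }
  if (length(res) == 0) return(empty_cluster_calls())
  bind_rows(res)
}

empty_cluster_calls <- function() {
  tibble(
    genome_id = character(), cluster_type = character(),
    replicon_id = character(), ordinal_first = integer(),
    ordinal_last = integer(), gene_ids = list(), n_members = integer()
  )
}

#' Link dndFGH restriction clusters to modification clusters
#'
#' A `dndFGH` call is R-M linked when a `dndCD` or `dndBCDE` call lies on
#' the same replicon within `window` ORFs: the ORF distance is the number of
#' ordinals between the nearest ends of the two spans (adjacent spans have
#' distance 1; overlapping spans distance 0), and on circular replicons the
#' shorter way around is used. Linkage is inclusive at the window
#' (`distance <= window`).
#'
#' @param calls Tibble of cluster calls from [call_adjacent_clusters()],
#'   all from the genome `genome`.
#' @param genome The [genome_record()] the calls belong to.
#' @param window Maximum ORF distance (default 30).
#' @return A list with `calls` (input with an `rm_linked` logical column;
#'   `NA` for non-dndFGH calls) and `pairs` (tibble of linked pairs with the
#'   ORF distance).
#' @export
link_restriction_modification <- function(calls, genome, window = 30L) {
  stopifnot(inherits(genome, "genome_record"), window >= 0)
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(list(calls = mutate(empty_cluster_calls(), rm_linked = logical()),
                pairs = empty_link_pairs()))
  }
  fgh <- filter(calls, .data$cluster_type == "dndFGH")
  mod <- filter(calls, .data$cluster_type %in% c("dndCD", "dndBCDE"))
  pairs <- list()
  linked <- rep(FALSE, nrow(fgh))
  if (nrow(fgh) > 0 && nrow(mod) > 0) {
    for (i in seq_len(nrow(fgh))) {
      for (j in seq_len(nrow(mod))) {
        if (fgh$replicon_id[i] != mod$replicon_id[j]) next
        rep_idx <- match(fgh$replicon_id[i], genome$replicons$replicon_id)
        n_cds <- sum(genome$features$replicon_id == fgh$replicon_id[i])
        d <- orf_distance(
          c(fgh$ordinal_first[i], fgh$ordinal_last[i]),
          c(mod$ordinal_first[j], mod$ordinal_last[j]),
          n_cds, isTRUE(genome$replicons$circular[rep_idx]))
        if (d <= window) {
          linked[i] <- TRUE
          pairs[[length(pairs) + 1L]] <- tibble(
            genome_id = genome$genome_id,
            replicon_id = fgh$replicon_id[i],
            restriction_span = sprintf("%d-%d", fgh$ordinal_first[i],
                                       fgh$ordinal_last[i]),
            modification_type = mod$cluster_type[j],
            modification_span = sprintf("%d-%d", mod$ordinal_first[j],
                                        mod$ordinal_last[j]),
            orf_distance = d
          )
        }
      }
    }
  }
  calls$rm_linked <- NA
  if (nrow(fgh) > 0) {
    is_fgh <- calls$cluster_type == "dndFGH"
    calls$rm_linked[is_fgh] <- linked[match(
      paste(calls$replicon_id[is_fgh], calls$ordinal_first[is_fgh]),
      paste(fgh$replicon_id, fgh$ordinal_first))]
  }
  list(calls = calls,
       pairs = if (length(pairs) > 0) bind_rows(pairs) else empty_link_pairs())
}

empty_link_pairs <- function() {
  tibble(
    genome_id = character(), replicon_id = character(),
    restriction_span = character(), modification_type = character(),
    modification_span = character(), orf_distance = numeric()
  )
}

# ORF distance between two ordinal spans on one replicon. Spans may wrap
# (first > last) on circular replicons.
orf_distance <- function(span_a, span_b, n_cds, circular) {
  expand <- function(sp) {
    if (sp[1] <= sp[2]) sp else c(sp[1], sp[2] + n_cds)  # unwrap
  }
  a <- expand(span_a); b <- expand(span_b)
  lin_dist <- function(a, b) {
    max(0, b[1] - a[2], a[1] - b[2])
  }
  d <- lin_dist(a, b)
  if (circular) {
    # other way around the circle between the outer ends
    lo <- min(a[1], b[1]); hi <- max(a[2], b[2])
    d2 <- n_cds - (hi - lo)
    d <- min(d, max(d2, 0))
  }
  d
}

#' Summarise per-genome dnd presence, counts and R-M linkage
#'
#' @param genomes A [genome_record()] or list of them (one per genome).
#' @param assignments Tibble of family assignments carrying `genome_id`
#'   (bind rows of per-genome [assign_dnd_genes()] outputs, adding
#'   `genome_id` where absent for a single genome).
#' @param calls Tibble of cluster calls carrying `genome_id`.
#' @param rm_window ORF window for R-M linkage (default 30).
#' @return Tibble with one row per genome: logical presence columns for the
#'   eight families and three cluster types, `rm_linked`, and count columns
#'   `n_<feature>`.
#' @export
profile_genomes <- function(genomes, assignments, calls, rm_window = 30L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  ids <- vapply(genomes, function(g) g$genome_id, "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate genome_id: ", ids[duplicated(ids)][1]))
  }
  assignments <- as_tibble(assignments)
  calls <- as_tibble(calls)
  if (nrow(assignments) > 0 && !"genome_id" %in% names(assignments)) {
    if (length(genomes) == 1) assignments$genome_id <- ids
    else abort("assignments must carry genome_id for multiple genomes")
  }
  if (nrow(calls) > 0) require_columns(calls, "genome_id", "calls")

  profs <- lapply(genomes, function(g) {
    a <- if (nrow(assignments) > 0) {
      filter(assignments, .data$genome_id == g$genome_id)
    } else assignments
    cl <- if (nrow(calls) > 0) filter(calls, .data$genome_id == g$genome_id)
          else calls
    rm_linked <- FALSE
    if (nrow(cl) > 0 && any(cl$cluster_type == "dndFGH")) {
      lk <- link_restriction_modification(cl, g, window = rm_window)
      rm_linked <- any(lk$calls$rm_linked, na.rm = TRUE)
    }
    row <- tibble(genome_id = g$genome_id)
    for (fam in dnd_families()) {
      cnt <- if (nrow(a) > 0) sum(a$family == fam) else 0L
      row[[fam]] <- cnt > 0
      row[[paste0("n_", fam)]] <- cnt
    }
    for (ct in names(dnd_cluster_types())) {
      cnt <- if (nrow(cl) > 0) sum(cl$cluster_type == ct) else 0L
      row[[ct]] <- cnt > 0
      row[[paste0("n_", ct)]] <- cnt
    }
    row$rm_linked <- rm_linked
    row
  })
  out <- bind_rows(profs)
  # cluster presence must imply member-family presence
  for (ct in names(dnd_cluster_types())) {
    members <- dnd_cluster_types()[[ct]]
    implied <- apply(out[members], 1, all)
    if (any(out[[ct]] & !implied)) {
      abort("internal consistency error: cluster flag without member flags")
    }
  }
  out
}
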