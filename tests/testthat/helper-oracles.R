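# Independent reference implementations ("oracles") used to cross-check the
# package. Each is written with a deliberately different algorithm from the
# production code.

# ---- Kendall tau-b, brute force -------------------------------------------
# Explicit double loop counting concordant/discordant/tied pairs.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- x[i] - x[j]; b <- y[i] - y[j]
      if (a == 0 && b == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (a == 0) tx <- tx + 1
      else if (b == 0) ty <- ty + 1
      else if (sign(a) == sign(b)) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) return(list(tau = NA_real_, s = C - D))
  list(tau = (C - D) / denom, s = C - D)
}

# Exact two-sided permutation p-value for S by full enumeration in R.
oracle_exact_kendall_p <- function(x, y) {
  s_of <- function(yy) {
    s <- 0
    n <- length(x)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- s + sign(x[i] - x[j]) * sign(yy[i] - yy[j])
      }
    }
    s
  }
  s_obs <- abs(s_of(y))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(y)
  mean(vapply(all_p, function(p) abs(s_of(p)) >= s_obs, logical(1)))
}

# ---- cluster calling, exhaustive window enumeration -----------------------
# Enumerates every ordinal window per (cluster type, replicon), keeps
# windows whose member genes are exactly one per required family with the
# window's endpoints on member genes and at most max_gap non-members
# inside, then picks calls greedily left-to-right without reusing a gene.
oracle_clusters <- function(genome, assignments, max_gap = 0) {
  feats <- merge(as.data.frame(genome$features),
                 as.data.frame(assignments[c("gene_id", "family")]),
                 by = "gene_id", all.x = TRUE)
  out <- list()
  for (ct in names(dnd_cluster_types())) {
    req <- dnd_cluster_types()[[ct]]
    k <- length(req)
    for (rep_id in unique(feats$replicon_id)) {
      f <- feats[feats$replicon_id == rep_id, ]
      f <- f[order(f$ordinal), ]
      n <- nrow(f)
      circ <- genome$replicons$circular[
        match(rep_id, genome$replicons$replicon_id)]
      # unrolled gene vector: index t (1-based) -> ordinal (t-1) %% n
      reach <- if (isTRUE(circ)) 2 * n else n
      cand <- list()
      for (a in seq_len(n)) {
        for (b in a:min(a + n - 1, reach)) {
          idx <- ((a:b - 1) %% n) + 1
          if (length(unique(idx)) < length(idx)) next
          w <- f[idx, ]
          memb <- w[!is.na(w$family) & w$family %in% req, ]
          if (nrow(memb) != k) next
          if (length(unique(memb$family)) != k) next
          if (!setequal(memb$family, req)) next
          # endpoints must be member genes (minimal window)
          if (is.na(w$family[1]) || !w$family[1] %in% req) next
          if (is.na(w$family[nrow(w)]) || !w$family[nrow(w)] %in% req) next
          if ((b - a + 1) - k > max_gap) next
          cand[[length(cand) + 1]] <- list(
            a = a, b = b, genes = w$gene_id,
            ordinal_first = (a - 1) %% n, ordinal_last = (b - 1) %% n
          )
        }
      }
      if (length(cand) == 0) next
      ord <- order(vapply(cand, function(cc) cc$a, numeric(1)),
                   vapply(cand, function(cc) cc$b, numeric(1)))
      used <- character()
      for (cc in cand[ord]) {
        if (any(cc$genes %in% used)) next
        used <- c(used, cc$genes)
        out[[length(out) + 1]] <- data.frame(
          genome_id = genome$genome_id, cluster_type = ct,
          replicon_id = rep_id, ordinal_first = cc$ordinal_first,
          ordinal_last = cc$ordinal_last, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(genome_id = character(), cluster_type = character(),
                      replicon_id = character(), ordinal_first = integer(),
                      ordinal_last = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$replicon_id, res$ordinal_first, res$cluster_type), ,
      drop = FALSE]
}

# ---- majority vote counting -----------------------------------------------
# Base-R vote count: per protein, best qualifying bitscore decides the
# vote; ties between families abstain. Returns the assigned family.
oracle_majority <- function(protein_ids, hits, bitscore_min = 50,
                            majority = 0.5) {
  votes <- character()
  for (p in protein_ids) {
    h <- hits[hits$query_id == p & hits$bitscore >= bitscore_min, ,
              drop = FALSE]
    if (nrow(h) == 0) next
    best <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    fams <- unique(best$subject_family)
    if (length(fams) == 1) votes <- c(votes, fams)
  }
  if (length(votes) == 0) return("unclassified")
  frac <- table(votes) / length(protein_ids)
  top <- max(frac)
  winners <- names(frac)[frac == top]
  if (top >= majority && length(winners) == 1) winners else "unclassified"
}

# ---- naive motif scan ------------------------------------------------------
oracle_scan <- function(seq_string, motifs = c("GAAC", "GTTC")) {
  chars <- strsplit(toupper(seq_string), "")[[1]]
  out <- list()
  for (m in motifs) {
    mc <- strsplit(m, "")[[1]]
    k <- length(mc)
    for (i in seq_len(max(0, length(chars) - k + 1))) {
      if (all(chars[i:(i + k - 1)] == mc)) {
        out[[length(out) + 1]] <- data.frame(motif = m, position = i,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif = character(), position = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$motif), , drop = FALSE]
}

# ---- toy genome builders ---------------------------------------------------
# A linear or circular toy genome with n_genes CDS of width 900 at 1 kb
# spacing.
toy_genome <- function(n_genes, genome_id = "toy", circular = FALSE,
                       replicon_id = "chr") {
  genome_record(
    genome_id,
    features = tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      replicon_id = replicon_id,
      start = (seq_len(n_genes) - 1) * 1000 + 1,
      end = (seq_len(n_genes) - 1) * 1000 + 900,
      strand = "+"
    ),
    replicons = tibble::tibble(replicon_id = replicon_id,
                               length = n_genes * 1000,
                               circular = circular)
  )
}

# Assignments placing `families` at the given 0-based ordinals of a toy
# genome (gene ids are g001.. in ordinal order).
toy_assignments <- function(ordinals, families) {
  tibble::tibble(
    gene_id = sprintf("g%03d", ordinals + 1),
    family = families,
    subject_id = paste0(families, "_ref"),
    pident = 50, evalue = 1e-50, bitscore = 200, qcov = 0.9
  )
}

# Random toy genome + random family assignments for property tests.
random_toy_case <- function(seed) {
  set.seed(seed)
  n <- sample(6:16, 1)
  circular <- runif(1) < 0.5
  g <- toy_genome(n, genome_id = paste0("rt", seed), circular = circular)
  n_assign <- sample(0:min(n, 9), 1)
  if (n_assign == 0) {
    return(list(genome = g,
                assignments = toy_assignments(integer(), character()),
                max_gap = sample(0:2, 1)))
  }
  ords <- sort(sample(0:(n - 1), n_assign))
  fams <- sample(dnd_families(), n_assign, replace = TRUE)
  list(genome = g, assignments = toy_assignments(ords, fams),
       max_gap = sample(0:2, 1))
}
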