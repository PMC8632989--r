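# Independent oracles and small fixture builders shared across tests.

# Literal edge-enumeration oracle for node diversity: for each neighbor i
# of j, enumerate the edges {i, u} with u outside the closed neighborhood
# N(j) u {j} and add their count over k(i) - 1.
oracle_phi <- function(A, j) {
  nj <- which(A[j, ] > 0)
  closed <- c(nj, j)
  s <- 0
  for (i in nj) {
    ki <- sum(A[i, ] > 0)
    if (ki < 2) next
    leaving <- setdiff(which(A[i, ] > 0), closed)
    s <- s + length(leaving) / (ki - 1)
  }
  s
}

oracle_phi_all <- function(A) {
  vapply(seq_len(nrow(A)), function(j) oracle_phi(A, j), 0)
}

# random symmetric 0/1 adjacency matrix without self-loops
rand_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# brute-force single-source BFS distances on an adjacency list (queue walk),
# independent of igraph's shortest-path machinery
bfs_dist <- function(adj, src) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (is.infinite(d[u])) {
        d[u] <- d[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

# exhaustive hypergeometric upper-tail probability by summing the mass
# function (independent of phyper)
oracle_hyper_tail <- function(k, m, N, q) {
  kk <- k:min(m, q)
  sum(choose(m, kk) * choose(N - m, q - kk)) / choose(N, q)
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- si * sj / nn
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small random association data frame (phenotype ids p01.., genes g01..)
rand_assoc_df <- function(n_phen, n_gene, min_genes = 1, max_genes = 6) {
  phen <- sprintf("p%02d", seq_len(n_phen))
  do.call(rbind, lapply(phen, function(p) {
    data.frame(phenotype_id = p, phenotype_label = p,
               gene = sample(sprintf("g%02d", seq_len(n_gene)),
                             sample(min_genes:max_genes, 1)),
               stringsAsFactors = FALSE)
  }))
}

# a small-but-complete synthetic configuration for fast unit tests
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_symptoms = 40, n_genes = 300,
                   n_records = 150, n_drugs = 25, ppi_edges_per_node = 4,
                   n_pathways = 15, assoc_max_genes = 40, ...)
}

# run the generator chain up to diversity tables; used by planted-effect
# and acceptance tests at full desk scale
run_synth_chain <- function(cfg) {
  inter <- generate_interactome(cfg)
  ppi_div <- all_node_diversity(inter$graph)
  asc <- generate_associations(cfg, ppi_div)
  recs <- generate_cluster_records(cfg, asc$labels)
  scn <- build_cooccurrence_network(recs)
  pd <- all_node_diversity(scn)
  names(pd) <- c("phenotype", "PE", "PD", "rank")
  md <- molecular_diversity(ppi_div, asc$assoc)
  merged <- merge(pd, md, by = "phenotype")
  merged <- merged[!is.na(merged$MGD), , drop = FALSE]
  list(cfg = cfg, interactome = inter, ppi_diversity = ppi_div,
       associations = asc, records = recs, scn = scn, pd = pd, md = md,
       merged = merged)
}
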