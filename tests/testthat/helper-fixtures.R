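# Fixtures built in code: a two-polymorphism mini panel, hand-written
# cohorts, and separable toy classification data.

mini_panel <- function() {
  polymorphism_panel(data.frame(
    name = c("MTRR_A66G", "MTHFR_C677T"),
    rsid = c("rs1801394", "rs1801133"),
    wild = c("AA", "CC"), het = c("AG", "CT"), mut = c("GG", "TT")))
}

# The worked three-record example: genotypes AA, GG, AG at MTRR 66A>G.
mini_cohort <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3"),
    group = c("AD", "control", "AD"),
    MTRR_A66G = c("AA", "GG", "AG"),
    MTHFR_C677T = c("CC", "CT", "TT"),
    folate = c(10, 20, 30),
    homocysteine = c(5, 15, 25),
    vitamin_b12 = c(100, 300, 200),
    stringsAsFactors = FALSE)
}

# Two well-separated Gaussian clusters labelled control/AD.
separable_data <- function(n_per_class = 10, p = 3, gap = 20, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = gap), n_per_class))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(c("control", "AD"), each = n_per_class))
}

# Brute-force KNN oracle: full distance scan + the package's tie rules
# (lower train index on distance ties, control on vote ties), written
# independently of the implementation's vectorized path.
knn_oracle <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1, function(row) {
    d <- sqrt(colSums((t(train_x) - row)^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(factor(train_y[ord], levels = c("control", "AD")))
    if (votes[["AD"]] > votes[["control"]]) "AD" else "control"
  })
}

# Exhaustive MST oracle: minimal total weight over all spanning trees,
# enumerated through Pruefer sequences (n^(n-2) labelled trees).
mst_oracle_weight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  pruefer_edges <- function(seq) {
    n <- length(seq) + 2
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (i in seq_along(seq)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, seq[i])
      degree[leaf] <- 0L
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- pruefer_edges(seqs[r, ])
    best <- min(best, sum(d[e]))
  }
  best
}
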