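# Independent brute-force oracles and tiny fixture builders shared by
# the test files. These deliberately avoid the package's own internals.

# O(n^2 k) farthest-point center generation: recompute every pairwise
# distance from scratch at each step.
bf_farthest_centers <- function(m, seed, k) {
  idx <- seed
  while (length(idx) < k) {
    d2 <- sapply(seq_len(nrow(m)), function(i)
      min(sapply(idx, function(c) sum((m[i, ] - m[c, ])^2))))
    idx <- c(idx, which.max(d2))
  }
  idx
}

# silhouette by direct pairwise enumeration; singleton clusters -> 0
bf_silhouette <- function(m, cl) {
  n <- nrow(m)
  dmat <- as.matrix(stats::dist(m))
  sapply(seq_len(n), function(i) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(dmat[i, own])
    b <- min(sapply(setdiff(unique(cl), cl[i]), function(g)
      mean(dmat[i, cl == g])))
    (b - a) / max(a, b)
  })
}

# hand-built 2-batch dataset: `peaks` columns, explicit QC placement
make_tiny_ds <- function(X, group, time, batch, acq_order = NULL,
                         replicate = NULL, mz = NULL, mode = "+") {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(acq_order)) acq_order <- seq_len(n)
  if (is.null(replicate)) replicate <- paste0("r", seq_len(n))
  if (is.null(mz)) mz <- seq(100, 100 + p - 1)
  mtb_dataset(
    X,
    data.frame(obs_id = paste0("o", seq_len(n)), group = rep_len(group, n),
               time = rep_len(time, n), batch = rep_len(batch, n),
               acq_order = acq_order, replicate = replicate),
    data.frame(peak_id = paste0("p", seq_len(p)), mz = mz,
               rt = seq_len(p), mode = mode))
}

# knowledge base with one glucose-like compound and an [M+H]+ adduct
make_tiny_kb <- function(masses = 180.063388,
                         pathways = data.frame(pathway_id = character(0),
                                               compound_id = character(0))) {
  mtb_knowledge_base(
    data.frame(compound_id = paste0("C", seq_along(masses)),
               name = paste0("cmp", seq_along(masses)),
               monoisotopic_mass = masses),
    data.frame(name = c("[M+H]+", "[M-H]-"), n = c(1L, 1L),
               charge = c(1L, -1L), mass_shift = c(1.007276, -1.007276)),
    pathways)
}

# wrap plain vectors as a 1-column matrix of input vectors
vec1 <- function(v) matrix(v, ncol = 1)
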