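# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration/arithmetic, not by calling package code.

# all permutations of seq_len(n), one per list element (iterative heap-less)
oracle_perms <- function(n) {
  out <- list(seq_len(1))
  if (n == 1) return(out)
  for (m in 2:n) {
    out <- unlist(lapply(out, function(p) {
      lapply(seq_len(m), function(pos) append(p, m, after = pos - 1))
    }), recursive = FALSE)
  }
  out
}

# most inferior contiguous qualifying triple by scanning every triple
oracle_slice_triple <- function(per_slice_counts, min_voxels,
                                orientation = "IS") {
  ok <- per_slice_counts >= min_voxels
  nz <- length(ok)
  hits <- integer()
  for (s in seq_len(nz - 2)) {
    if (ok[s] && ok[s + 1] && ok[s + 2]) hits <- c(hits, s)
  }
  if (!length(hits)) return(NULL)
  s <- if (orientation == "IS") min(hits) else max(hits)
  s:(s + 2)
}

# AUC as the exhaustive mean over (positive, negative) score pairs
oracle_auc_pairs <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random blob-ish 3-D logical mask with at least one voxel
random_mask <- function(dims, p = 0.2) {
  m <- array(runif(prod(dims)) < p, dims)
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}

# small cohort design for fast tests
tiny_design <- function(...) cohort_design("cohort1", n_pd = 12L, n_hv = 8L, ...)
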