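# Independent brute-force oracles used across the suite.

# All-pairs equality partition of SSR samples: two samples share a group
# iff their allele sets agree at every locus. Returns integer group ids.
oracle_equality_partition <- function(samples) {
  loci <- setdiff(names(samples), c("sample_id", "cytotype", "origin"))
  n <- nrow(samples)
  same <- function(i, j) all(vapply(loci, function(lc) {
    a <- sort(as.numeric(strsplit(samples[[lc]][i], "/")[[1]]))
    b <- sort(as.numeric(strsplit(samples[[lc]][j], "/")[[1]]))
    length(a) == length(b) && all(a == b)
  }, logical(1)))
  grp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      nxt <- nxt + 1L
      grp[i] <- nxt
      if (i < n) for (j in (i + 1):n) if (grp[j] == 0L && same(i, j)) grp[j] <- nxt
    }
  }
  grp
}

# Minimum spanning-tree weight by exhaustive enumeration of all labelled
# trees on n nodes via Pruefer sequences (n^(n-2) trees).
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2, n <= 7)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  decode <- function(pr) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (k in seq_along(pr)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, pr[k])
      degree[leaf] <- 0L
      degree[pr[k]] <- degree[pr[k]] - 1L
    }
    last <- which(degree == 1L)
    edges[n - 1, ] <- last
    edges
  }
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- decode(seqs[r, ])
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

# Closed-form simple-regression coefficients (normal equations).
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Sequential sums of squares of a balanced 2x2x2 design with factors
# A, B, C, computed from explicit mean contrasts. Balanced orthogonal
# design => each term SS = N/4 * (contrast of cell means)^2 for main
# effects and interactions built from +/-1 codings.
oracle_balanced_ss <- function(y, A, B, C) {
  a <- ifelse(A == levels(factor(A))[1], -1, 1)
  b <- ifelse(B == levels(factor(B))[1], -1, 1)
  cc <- ifelse(C == levels(factor(C))[1], -1, 1)
  ss <- function(sgn) sum(sgn * y)^2 / length(y)
  c(A = ss(a), B = ss(b), C = ss(cc),
    AB = ss(a * b), AC = ss(a * cc), BC = ss(b * cc),
    ABC = ss(a * b * cc))
}

# A deterministic multilocus population with the published modal counts:
# 44 samples (3 hybrid + 41 allopolyploid) carry the modal genotype, the
# other 35 (4 hybrid + 31 allopolyploid) each gain one private allele.
make_modal_population <- function() {
  loci <- spartina_loci()
  base <- data.frame(
    sample_id = sprintf("P%02d", 1:79),
    cytotype = c(rep("hybrid", 3), rep("allopolyploid", 41),
                 rep("hybrid", 4), rep("allopolyploid", 31)),
    origin = NA_character_, stringsAsFactors = FALSE)
  for (lc in names(loci))
    base[[lc]] <- paste(sort(loci[[lc]]$modal), collapse = "/")
  for (k in 1:35) {  # variant k gains a private MS02 allele
    i <- 44 + k
    base$MS02[i] <- paste(sort(c(loci$MS02$modal, 300L + k)), collapse = "/")
  }
  base
}

# Random SSR toy tables for property tests.
random_ssr_table <- function(n, n_loci = 3, max_alleles = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- seq(200, 280, by = 4)
  out <- data.frame(sample_id = sprintf("r%02d", seq_len(n)),
                    cytotype = "allopolyploid", origin = NA_character_,
                    stringsAsFactors = FALSE)
  for (l in seq_len(n_loci)) {
    out[[paste0("L", l)]] <- vapply(seq_len(n), function(i) {
      k <- sample.int(max_alleles, 1)
      paste(sort(sample(pool, k)), collapse = "/")
    }, character(1))
  }
  out
}

# Random orthogonal matrix (QR of a Gaussian matrix).
random_rotation <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k)))
}
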