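# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package:
# log-odds tables are rebuilt from the definition, scanning rescans every
# window in a plain loop, the hypergeometric tail is enumerated, and UPGMA
# is the textbook O(n^3) agglomeration.

ORACLE_LETTERS <- c("A", "C", "G", "T")

oracle_log_odds <- function(counts, pseudocount = 1, bg = rep(0.25, 4)) {
  w <- nrow(counts)
  lo <- matrix(0, w, 4)
  for (i in seq_len(w)) {
    tot <- sum(counts[i, ]) + 4 * pseudocount
    for (b in 1:4) lo[i, b] <- log2(((counts[i, b] + pseudocount) / tot) / bg[b])
  }
  lo
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# all hits with relative score strictly above threshold, both strands,
# minus-strand windows scored on the reverse complement of the window
oracle_scan <- function(counts, seq, threshold, both_strands = TRUE,
                        pseudocount = 1) {
  lo <- oracle_log_odds(counts, pseudocount)
  w <- nrow(counts)
  smin <- sum(apply(lo, 1, min)); smax <- sum(apply(lo, 1, max))
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- NULL
  if (length(chars) < w) {
    return(data.frame(offset = integer(0), strand = character(0),
                      raw_score = numeric(0), relative_score = numeric(0)))
  }
  for (i in 0:(length(chars) - w)) {
    win <- paste(chars[(i + 1):(i + w)], collapse = "")
    for (st in if (both_strands) c("+", "-") else "+") {
      ws <- if (st == "+") win else oracle_revcomp(win)
      idx <- match(strsplit(ws, "")[[1]], ORACLE_LETTERS)
      if (anyNA(idx)) next
      raw <- sum(lo[cbind(seq_len(w), idx)])
      rel <- if (smax == smin) 1 else (raw - smin) / (smax - smin)
      if (rel > threshold)
        hits <- rbind(hits, data.frame(offset = i, strand = st,
                                       raw_score = raw,
                                       relative_score = rel))
    }
  }
  if (is.null(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      raw_score = numeric(0), relative_score = numeric(0)))
  hits <- hits[order(hits$offset, match(hits$strand, c("+", "-"))), ]
  rownames(hits) <- NULL
  hits
}

# P(X >= k) by full enumeration of all C(N, n) draws via the pmf identity
oracle_hyper_sf <- function(k, N, K, n) {
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  kk <- k:min(K, n)
  kk <- kk[kk >= max(0, n - (N - K))]
  if (!length(kk)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook O(n^3) UPGMA on a distance matrix; returns the cophenetic
# distance matrix, which is invariant to the order in which tied merges
# are performed
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  dm <- matrix(Inf, n + (n - 1), n + (n - 1))
  dm[1:n, 1:n] <- d
  diag(dm) <- Inf
  coph <- matrix(0, n, n)
  nxt <- n
  alive <- seq_len(n)
  while (length(alive) > 1) {
    sub <- dm[alive, alive, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- alive[ij[1]]; b <- alive[ij[2]]
    h <- dm[a, b]
    nxt <- nxt + 1
    members[[nxt]] <- c(members[[a]], members[[b]])
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- h; coph[y, x] <- h
    }
    for (c in setdiff(alive, c(a, b))) {
      na <- length(members[[a]]); nb <- length(members[[b]])
      dm[nxt, c] <- (na * dm[a, c] + nb * dm[b, c]) / (na + nb)
      dm[c, nxt] <- dm[nxt, c]
    }
    alive <- c(setdiff(alive, c(a, b)), nxt)
  }
  coph
}

# random PWM counts matrix for property tests
random_counts <- function(width) {
  matrix(sample(0:20, width * 4, replace = TRUE), width, 4)
}

random_dna <- function(len, letters = ORACLE_LETTERS) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# minimal de_result-shaped input for report tests: n_up + n_down genes
# passing the DE criteria plus some unchanged filler
fake_de_result <- function(n_up, n_down, n_null = 10) {
  tab <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_up + n_down + n_null)),
    fc = c(rep(4, n_up + n_down), rep(1.1, n_null)),
    direction = c(rep("up", n_up), rep("down", n_down), rep("up", n_null)),
    padj = c(rep(1e-4, n_up + n_down), rep(0.9, n_null)),
    stringsAsFactors = FALSE)
  classify_de(tab)
}
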