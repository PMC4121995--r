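# Independent oracles: plain-R re-implementations of the documented
# models, structured differently from the package code paths they check.

.or_pairs <- c("AU", "CG", "GC", "GU", "UA", "UG")

or_can_pair <- function(a, b) paste0(a, b) %in% .or_pairs

# loop-decomposition energy of an explicit structure (pair list) under
# the bundled parameter tables
oracle_energy <- function(seq_rna, partner) {
  par <- energy_params()
  lp <- par$loop
  v <- strsplit(seq_rna, "", fixed = TRUE)[[1]]
  n <- length(v)
  pairs <- which(!is.na(partner) & partner > seq_len(n))
  if (!length(pairs)) return(0)
  e <- 0
  for (i in pairs) {
    j <- partner[i]
    # children: pairs directly enclosed by (i, j)
    inside <- i + 1L
    children <- list()
    u <- 0L
    while (inside < j) {
      if (is.na(partner[inside])) {
        u <- u + 1L
        inside <- inside + 1L
      } else {
        children[[length(children) + 1L]] <- c(inside, partner[inside])
        inside <- partner[inside] + 1L
      }
    }
    k <- length(children)
    if (k == 0L) {
      e <- e + lp$hairpin_base + lp$hairpin_per_nt * u
    } else if (k == 1L) {
      g1 <- children[[1]][1] - i - 1L
      g2 <- j - children[[1]][2] - 1L
      if (g1 == 0L && g2 == 0L) {
        p1 <- paste0(v[i], v[j])
        p2 <- paste0(v[children[[1]][1]], v[children[[1]][2]])
        e <- e + par$stack[p1, p2]
      } else if (g1 == 0L || g2 == 0L) {
        e <- e + lp$bulge_base + lp$bulge_per_nt * (g1 + g2)
      } else {
        e <- e + lp$internal_base + lp$internal_per_nt * (g1 + g2)
      }
    } else {
      e <- e + lp$multi_base + lp$multi_branch * (k + 1L) +
        lp$multi_unpaired * u
    }
  }
  e
}

# exhaustive enumeration of all pseudoknot-free structures (as partner
# vectors); pairs require complementarity and a hairpin loop >= 3
enumerate_structures <- function(seq_rna, min_hairpin = 3) {
  v <- strsplit(seq_rna, "", fixed = TRUE)[[1]]
  n <- length(v)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)             # i unpaired
    for (k in seq.int(i + min_hairpin + 1L, j)) {
      if (k > j) break
      if (!or_can_pair(v[i], v[k])) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (L in left) {
        for (R in right) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), L, R)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  if (n < min_hairpin + 2) return(list(rep(NA_integer_, n)))
  lapply(rec(1L, n), function(prs) {
    partner <- rep(NA_integer_, n)
    for (p in prs) {
      partner[p[1]] <- p[2]
      partner[p[2]] <- p[1]
    }
    partner
  })
}

# brute-force MFE: minimum oracle energy over all enumerated structures,
# ties toward fewer pairs
oracle_fold <- function(seq_rna, min_hairpin = 3) {
  structs <- enumerate_structures(seq_rna, min_hairpin)
  best <- c(Inf, Inf)
  for (partner in structs) {
    e <- oracle_energy(seq_rna, partner)
    np <- sum(!is.na(partner)) / 2
    if (e < best[1] - 1e-9 ||
        (abs(e - best[1]) < 1e-9 && np < best[2])) {
      best <- c(e, np)
    }
  }
  list(mfe = best[1], npairs = best[2])
}

# duplex oracle: memoised backward recursion over "last pair", covering
# every antiparallel alignment with bounded gaps
oracle_duplex <- function(mirna_rna, window_rna, max_gap = 15) {
  par <- energy_params()
  lp <- par$loop
  a <- strsplit(mirna_rna, "", fixed = TRUE)[[1]]
  wv <- rev(strsplit(window_rna, "", fixed = TRUE)[[1]])
  m <- length(a); w <- length(wv)
  memo <- new.env(parent = emptyenv())
  step <- function(g1, g2, p1, p2) {
    if (g1 == 0 && g2 == 0) return(par$stack[p1, p2])
    if (g1 == 0 || g2 == 0) return(lp$bulge_base + lp$bulge_per_nt * (g1 + g2))
    lp$internal_base + lp$internal_per_nt * (g1 + g2)
  }
  rec <- function(i, k) {
    key <- paste(i, k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0
    p1 <- paste0(a[i], wv[k])
    for (i2 in seq.int(i + 1L, min(m, i + 1L + max_gap))) {
      if (i2 > m) break
      for (k2 in seq.int(k + 1L, min(w, k + 1L + max_gap))) {
        if (k2 > w) break
        if (!or_can_pair(a[i2], wv[k2])) next
        cand <- step(i2 - i - 1L, k2 - k - 1L, p1, paste0(a[i2], wv[k2])) +
          rec(i2, k2)
        if (cand < best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(m)) {
    for (k in seq_len(w)) {
      if (!or_can_pair(a[i], wv[k])) next
      e <- rec(i, k)
      if (e < best) best <- e
    }
  }
  best
}

# exact two-library test by direct log-probability summation
oracle_two_lib <- function(x, y, N1, N2) {
  n <- x + y
  p <- N2 / (N1 + N2)
  lp <- lchoose(n, 0:n) + (0:n) * log(p) + (n - (0:n)) * log1p(-p)
  pr <- exp(lp)
  sum(pr[pr <= pr[y + 1] * (1 + 1e-9)])
}

# upper-tail hypergeometric by choose() summation
oracle_hyper <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_dna_test <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive all-positions substring scan on both strands
naive_hits <- function(genome_seq, tag) {
  out <- list()
  n <- nchar(genome_seq)
  k <- nchar(tag)
  rc <- revcomp(tag)
  for (s in seq_len(n - k + 1L)) {
    sub <- substr(genome_seq, s, s + k - 1L)
    if (sub == tag) out[[length(out) + 1L]] <- c(s - 1L, "+")
    if (sub == rc) out[[length(out) + 1L]] <- c(s - 1L, "-")
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), strand = m[, 2])
}

empty_hits_test <- function() {
  data.frame(tag = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0))
}
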