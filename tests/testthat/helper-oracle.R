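# independent brute-force alignment oracle: full-scan semi-global DP over
# every layout (no seeding, no windowing), enumerating all optimal
# placements. Used to validate the package's seeded aligner.

# S[s] for s = 1..nchar(ref): minimal edit distance of the whole read
# aligned to ref starting exactly at s, with a free 3' end. Computed as a
# reversed free-prefix/free-suffix DP, row-vectorized with the
# cummin trick to resolve the in-row dependency.
oracle_start_dists <- function(read, ref) {
  rr <- rev(utf8ToInt(read))
  rf <- rev(utf8ToInt(ref))
  m <- length(rr); n <- length(rf)
  prev <- rep(0L, n + 1L)
  idx <- 0:n
  for (i in seq_len(m)) {
    sub <- prev[1:n] + (rr[i] != rf)
    up <- prev[2:(n + 1L)] + 1L
    tmp <- pmin(sub, up)
    prev <- idx + cummin(c(i, tmp) - idx)
  }
  rev(prev[-1])
}

# dumb reference for oracle_start_dists on tiny inputs: anchored start, free
# end, via utils::adist over all end positions
dumb_start_dists <- function(read, ref) {
  n <- nchar(ref)
  vapply(seq_len(n), function(s) {
    min(utils::adist(read, substring(ref, s, s:n)))
  }, numeric(1))
}

# canonical anchored traceback mirroring the aligner's convention: smallest
# optimal end column, backward preference diagonal > deletion > insertion;
# yields the first-matched-base offset that defines the TSS
oracle_traceback <- function(read, lay, start, emax) {
  m <- nchar(read)
  w <- min(nchar(lay) - start + 1L, m + emax)
  r <- utf8ToInt(read)
  L <- utf8ToInt(substr(lay, start, start + w - 1L))
  D <- matrix(0L, m + 1L, w + 1L)
  D[1, ] <- 0:w
  idx0 <- 0:w
  for (i in seq_len(m)) {
    sub <- D[i, 1:w] + (r[i] != L)
    up <- D[i, 2:(w + 1L)] + 1L
    tmp <- pmin(sub, up)
    D[i + 1L, ] <- idx0 + cummin(c(i, tmp) - idx0)
  }
  jbest <- which.min(D[m + 1L, ]) - 1L  # smallest optimal end, 0-based
  i <- m; j <- jbest
  fmo <- -1L
  while (i > 0L || j > 0L) {
    cur <- D[i + 1L, j + 1L]
    if (i > 0L && j > 0L && cur == D[i, j] + (r[i] != L[j])) {
      if (r[i] == L[j]) fmo <- j - 1L
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && cur == D[i + 1L, j] + 1L) {
      j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  list(ref_len = jbest, fmo = max(fmo, 0L))
}

# exhaustive alignment over all contiguous and single-splice placements;
# returns list(status, edits, tss_idx, layout) matching align_reads()
# semantics (layout 1 = contiguous)
oracle_align <- function(read, layouts, max_edit_frac = 0.1, min_len = 20L) {
  m <- nchar(read)
  if (m < min_len) return(list(status = "too_short"))
  emax <- floor(max_edit_frac * m)
  cand <- list()
  best <- emax + 1L
  for (li in seq_along(layouts)) {
    S <- oracle_start_dists(read, layouts[[li]]$seq)
    hits <- which(S <= emax)
    for (s in hits) {
      cand[[length(cand) + 1L]] <- list(layout = li, s = s, dist = S[s])
      if (S[s] < best) best <- S[s]
    }
  }
  if (best > emax) return(list(status = "too_many_edits"))
  placements <- list()
  for (p in cand) {
    if (p$dist != best) next
    li <- p$layout; s <- p$s
    junc <- layouts[[li]]$junction
    t <- oracle_traceback(read, layouts[[li]]$seq, s, emax)
    q1 <- s + t$fmo                 # 1-based TSS layout position
    ref_end1 <- s - 1L + t$ref_len  # 1-based last consumed position
    crossing <- junc >= 0 && s <= junc && ref_end1 > junc
    tss <- if (junc < 0 || q1 <= junc) q1 else q1 + layouts[[li]]$delta
    key <- c(tss = tss, lay = if (crossing) li else 1L)
    placements[[paste(key, collapse = "_")]] <- key
  }
  if (length(placements) > 1) return(list(status = "ambiguous"))
  k <- placements[[1]]
  list(status = "aligned", edits = best, tss_idx = unname(k["tss"]),
       layout = unname(k["lay"]))
}

# mutate a read with a fixed number of random edits (for aligner tests)
mutate_read <- function(read, n_edits, seed) {
  withr::with_seed(seed, {
    x <- strsplit(read, "")[[1]]
    for (i in seq_len(n_edits)) {
      op <- sample(c("sub", "ins", "del"), 1)
      pos <- sample(length(x), 1)
      if (op == "sub") {
        x[pos] <- sample(setdiff(c("A", "C", "G", "T"), x[pos]), 1)
      } else if (op == "ins") {
        x <- append(x, sample(c("A", "C", "G", "T"), 1), after = pos)
      } else if (length(x) > 20) {
        x <- x[-pos]
      }
    }
    paste(x, collapse = "")
  })
}
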