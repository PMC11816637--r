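# Independent brute-force oracles, written for clarity not speed.

# Priority-flood watershed by linear scan of an explicit frontier list.
# Same documented contract as seeded_watershed(): 4-connected growth in
# non-descending relief order, FIFO tie-break with lexicographic (row, col)
# insertion, line pixels where >= 2 basins meet, sealed pockets re-seeded,
# basin-less pockets joining the line.
ws_oracle <- function(relief, seeds) {
  nr <- nrow(relief); nc <- ncol(relief)
  lab <- matrix(as.integer(seeds), nr, nc)
  queued <- matrix(FALSE, nr, nc)
  frontier <- matrix(numeric(0), ncol = 4) # value, ord, r, c
  ord <- 0
  nbrs <- function(r, c) {
    cand <- rbind(c(r - 1, c), c(r, c - 1), c(r, c + 1), c(r + 1, c))
    cand[cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc, ,
         drop = FALSE]
  }
  repeat {
    progress <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (lab[r, c] != 0 || queued[r, c]) next
      nb <- nbrs(r, c)
      if (any(lab[nb] > 0)) {
        ord <- ord + 1
        frontier <- rbind(frontier, c(relief[r, c], ord, r, c))
        queued[r, c] <- TRUE
      }
    }
    while (nrow(frontier) > 0) {
      i <- order(frontier[, 1], frontier[, 2])[1]
      e <- frontier[i, ]
      frontier <- frontier[-i, , drop = FALSE]
      r <- e[3]; c <- e[4]
      if (lab[r, c] != 0) next
      nb <- nbrs(r, c)
      ls <- unique(lab[nb][lab[nb] > 0])
      if (length(ls) >= 2) { lab[r, c] <- -1L; progress <- TRUE; next }
      if (length(ls) == 0) next
      lab[r, c] <- ls
      progress <- TRUE
      for (k in seq_len(nrow(nb))) {
        rr <- nb[k, 1]; cc <- nb[k, 2]
        if (lab[rr, cc] == 0 && !queued[rr, cc]) {
          ord <- ord + 1
          frontier <- rbind(frontier, c(relief[rr, cc], ord, rr, cc))
          queued[rr, cc] <- TRUE
        }
      }
    }
    if (!progress) break
    queued[lab == 0] <- FALSE
  }
  labels <- lab; labels[labels < 0] <- 0L
  list(labels = labels, line = lab <= 0)
}

# note: lab[nb] indexes with a 2-column matrix, giving the neighbour labels

# Exhaustive evaluation of the Kapur criterion over every split.
kapur_oracle <- function(counts) {
  p <- counts / sum(counts)
  K <- length(p)
  entropy <- function(q) {
    q <- q[q > 0] / sum(q)
    -sum(q * log(q))
  }
  crit <- rep(NA_real_, K)
  for (t in 2:K) {
    below <- p[1:(t - 1)]; above <- p[t:K]
    if (sum(below) <= 0 || sum(above) <= 0) next
    crit[t] <- entropy(below) + entropy(above)
  }
  top <- max(crit, na.rm = TRUE)
  which(!is.na(crit) & crit >= top - 1e-12)[1]
}

# groups with exact sample moments, for summary-statistics Tukey tests
exact_moment_group <- function(n, mean, sd) {
  z <- as.numeric(scale(stats::rnorm(n)))
  mean + sd * z
}
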