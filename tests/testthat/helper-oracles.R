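# Independent oracles: plain-loop reimplementations used to cross-check the
# package's vectorized/union-find code paths. Kept deliberately naive.

oracle_dist <- function(x, metric = "euclidean") {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- if (metric == "euclidean") {
      sqrt(sum((x[i, ] - x[j, ])^2))
    } else {
      xi <- x[i, ]; xj <- x[j, ]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) {
        if (all(xi == xj)) 0 else 1
      } else {
        num <- sum((xi - mean(xi)) * (xj - mean(xj)))
        den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
        1 - num / den
      }
    }
  }
  D
}

oracle_nn <- function(D) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    best <- Inf; who <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      if (D[i, j] < best) { best <- D[i, j]; who <- j }
    }
    who
  }, integer(1))
}

# Components of the undirected closure of the 1-NN digraph, by BFS.
oracle_components <- function(nn) {
  n <- length(nn)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n)) {
    adj[[i]] <- c(adj[[i]], nn[i])
    adj[[nn[i]]] <- c(adj[[nn[i]]], i)
  }
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    next_id <- next_id + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- next_id
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

same_partition <- function(a, b) {
  # label-invariant comparison
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Naive evaluation of one removal pass: recompute purity triples, binarized
# pairs, aggregates, beta thresholds and the removal conditions with plain
# loops, given the four lists of 31 partition label vectors.
oracle_pass_removals <- function(parts, e, eff, is_train, thr, s) {
  n <- length(e)
  agg <- function(label_list) {
    out <- matrix(0L, n, 2L)
    for (lab in label_list) {
      for (g in seq_len(max(lab))) {
        members <- which(lab == g)
        n1 <- sum(e[members] == 1L, na.rm = TRUE)
        n3 <- sum(e[members] == 3L, na.rm = TRUE)
        nl <- sum(!is.na(e[members]))
        if (nl > 0) {
          d1 <- n1 / nl; d3 <- n3 / nl
          if (d1 > d3) out[members, 1L] <- out[members, 1L] + 1L
          if (d1 < d3) out[members, 2L] <- out[members, 2L] + 1L
        }
      }
    }
    out
  }
  aggs <- lapply(parts, agg)
  potent <- which(is_train & eff >= thr)
  removed <- logical(n)
  for (l in which(!is_train)) {
    hit <- FALSE
    for (t in 1:4) {
      c1 <- aggs[[t]][l, 1L]; c2 <- aggs[[t]][l, 2L]
      p1 <- aggs[[t]][potent, 1L]; p2 <- aggs[[t]][potent, 2L]
      b2 <- max(p2)
      if (t <= 2) {
        b1 <- min(p1)
        if (c1 <= b1) hit <- TRUE
      } else {
        z <- p2[p1 == 0]
        b1 <- if (length(z)) max(z) else Inf
        if (c1 == 0 && c2 >= min(b1, 16 + s)) hit <- TRUE
      }
      if (c2 >= max(b2, 1)) hit <- TRUE
    }
    removed[l] <- hit
  }
  removed
}
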